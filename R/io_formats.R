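#' Read an OTU count table from disk
#'
#' Supports two dialects: a header-labelled wide matrix (first column sample
#' id, remaining columns OTU counts) including the mothur `.shared` layout
#' (whose bookkeeping columns `label` and `numOtus` are dropped and whose
#' `Group` column provides the sample id), and a tidy long table with columns
#' `sample`, `otu`, `count`.
#'
#' @param path file path (tab- or comma-separated, sniffed from the header)
#' @param format `"wide"` or `"long"`
#' @param taxonomy optional path to a 2-column TSV (otu_id, lineage)
#' @return an [otu_tab]; samples with zero total are dropped and itemized in
#'   the `"report"` attribute
#' @export
read_otu_table <- function(path, format = c("wide", "long"), taxonomy = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl(",", readLines(path, n = 1L))) "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed table in ", path, ": ", conditionMessage(e)))
  tax <- if (!is.null(taxonomy)) read_taxonomy(taxonomy) else NULL
  if (format == "long") {
    need <- c("sample", "otu", "count")
    if (!all(need %in% names(df))) stop("long format needs columns sample, otu, count")
    if (any(df$count < 0)) stop("negative count at line ",
                                which(df$count < 0)[1] + 1L)
    m <- tapply(df$count, list(df$sample, df$otu), sum, default = 0)
    return(otu_tab(m, taxonomy = tax))
  }
  # wide: tolerate mothur .shared bookkeeping columns
  if (all(c("label", "Group", "numOtus") %in% names(df))) {
    ids <- df$Group
    df <- df[, setdiff(names(df), c("label", "Group", "numOtus")), drop = FALSE]
  } else {
    ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, TRUE))[1]
    stop("non-numeric count column '", names(df)[bad], "'")
  }
  if (any(m < 0)) stop("negative count at line ", which(rowSums(m < 0) > 0)[1] + 1L)
  rownames(m) <- ids
  otu_tab(m, taxonomy = tax)
}

#' Write an OTU table
#'
#' @param tab an [otu_tab]
#' @param path output path
#' @param format `"wide"` (TSV, first column `sample`) or `"long"`
#' @export
write_otu_table <- function(tab, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    df <- data.frame(sample = sample_ids(tab), tab$counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(tab$counts > 0, arr.ind = TRUE)
    df <- data.frame(sample = sample_ids(tab)[idx[, 1]],
                     otu = otu_ids(tab)[idx[, 2]],
                     count = tab$counts[idx])
    df <- df[order(df$sample, df$otu), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read/write a 2-column taxonomy TSV (otu_id, lineage)
#' @param path file path
#' @return named character vector
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) != 2) stop("taxonomy must have exactly 2 columns")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' @rdname read_taxonomy
#' @param tax named character vector
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(data.frame(names(tax), unname(tax)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read sample metadata CSV
#'
#' Required columns: `sample_id`, `location_id`, `sector_id`,
#' `calendar_month` (ISO "YYYY-MM"). Chemistry columns pass through.
#' Month index (0-based from campaign start) and season are derived.
#'
#' @param path CSV path
#' @param campaign_start see [sample_metadata]
#' @return metadata data.frame
#' @export
read_sample_metadata <- function(path, campaign_start = NULL) {
  sample_metadata(utils::read.csv(path, stringsAsFactors = FALSE),
                  campaign_start = campaign_start)
}

#' @rdname read_sample_metadata
#' @param meta metadata data.frame
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny (newick)
#'
#' @param path newick file; must contain exactly one rooted tree with
#'   non-negative branch lengths
#' @return an `ape::phylo`
#' @export
read_phylogeny <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) stop("file contains more than one tree")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  if (!ape::is.rooted(tr)) stop("tree must be rooted")
  tr
}

#' Read a pipe-section inventory CSV
#'
#' Expected columns: `section_id`, `node_a`, `node_b`, `length_m`,
#' `diameter_m`, `install_year`, `material`. Lengths/diameters must be
#' positive. Connectivity from `dwtp_node` to every node named in
#' `sampling_nodes` is enforced.
#'
#' @param path CSV path
#' @param dwtp_node node id of the treatment plant (default "DWTP")
#' @param sampling_nodes node ids that must be reachable from `dwtp_node`;
#'   default: all nodes
#' @return data.frame of class `pipe_inventory`
#' @export
read_pipe_inventory <- function(path, dwtp_node = "DWTP", sampling_nodes = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pipe_inventory(df, dwtp_node = dwtp_node, sampling_nodes = sampling_nodes)
}

#' Validate a pipe inventory data.frame
#' @inheritParams read_pipe_inventory
#' @param df data.frame with the inventory columns
#' @export
pipe_inventory <- function(df, dwtp_node = "DWTP", sampling_nodes = NULL) {
  req <- c("section_id", "node_a", "node_b", "length_m", "diameter_m",
           "install_year", "material")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("pipe inventory missing columns: ", paste(miss, collapse = ", "))
  if (any(df$length_m <= 0) || any(df$diameter_m <= 0))
    stop("pipe lengths and diameters must be positive")
  if (anyDuplicated(df$section_id)) stop("duplicate section_id")
  g <- igraph::graph_from_data_frame(df[, c("node_a", "node_b")], directed = FALSE)
  if (dwtp_node %in% igraph::V(g)$name) {
    want <- if (is.null(sampling_nodes)) igraph::V(g)$name else sampling_nodes
    comp <- igraph::components(g)
    reach <- igraph::V(g)$name[comp$membership ==
                                 comp$membership[[dwtp_node]]]
    bad <- setdiff(want, reach)
    if (length(bad)) stop("nodes unreachable from ", dwtp_node, ": ",
                          paste(bad, collapse = ", "))
  }
  class(df) <- c("pipe_inventory", "data.frame")
  df
}

#' @rdname read_pipe_inventory
#' @param inv a `pipe_inventory`
#' @export
write_pipe_inventory <- function(inv, path) {
  utils::write.csv(as.data.frame(inv), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a labelled distance matrix
#'
#' Square PHYLIP-style plain text: first line the number of samples, then one
#' row per sample (label followed by the full row, full double precision).
#' The round trip is lossless. `read_distance_matrix` also accepts the
#' lower-triangle PHYLIP variant.
#'
#' @param dm symmetric numeric matrix with zero diagonal and dimnames
#' @param path file path
#' @export
write_distance_matrix <- function(dm, path) {
  dm <- validate_dm(dm)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(as.character(nrow(dm)), con)
  for (i in seq_len(nrow(dm)))
    writeLines(paste(c(rownames(dm)[i],
                       sprintf("%.17g", dm[i, ])), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @return for `read_distance_matrix`, the validated symmetric matrix (with a
#'   `"metric"` attribute if one was recorded)
#' @export
read_distance_matrix <- function(path) {
  ln <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(ln[1])))
  if (is.na(n)) stop("first line must be the matrix dimension")
  rows <- strsplit(ln[-1][seq_len(n)], "[\t ]+")
  labs <- vapply(rows, `[`, "", 1L)
  vals <- lapply(rows, function(r) as.numeric(r[-1]))
  lens <- lengths(vals)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  if (all(lens == n)) {
    for (i in seq_len(n)) m[i, ] <- vals[[i]]
  } else if (all(lens == seq_len(n) - 1L)) { # lower triangle
    for (i in seq_len(n)[-1]) m[i, seq_len(i - 1L)] <- vals[[i]]
    m <- m + t(m)
  } else {
    stop("file is neither square nor lower-triangle: row lengths ",
         paste(unique(lens), collapse = ","))
  }
  validate_dm(m)
}

# shared validation for distance matrices
validate_dm <- function(dm, tol = 1e-9) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  if (is.null(rownames(dm))) stop("distance matrix needs labels")
  if (max(abs(dm - t(dm))) > tol) stop("distance matrix asymmetric beyond ", tol)
  if (any(abs(diag(dm)) > tol)) stop("distance matrix diagonal must be zero")
  dm <- (dm + t(dm)) / 2
  diag(dm) <- 0
  colnames(dm) <- rownames(dm)
  dm
}
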