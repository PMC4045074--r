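#' OTU count table
#'
#' Container for a samples x OTUs matrix of non-negative integer read counts
#' with optional consensus taxonomy. This is the universal input of the
#' pipeline: every downstream stage (rarefaction, diversity, association
#' networks, occupancy-abundance modeling) consumes an `otu_tab`.
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns; dimnames
#'   required and unique. Values must be non-negative integers.
#' @param taxonomy optional named character vector mapping OTU id to a ranked
#'   lineage string. Names must be a subset of `colnames(counts)`.
#' @param drop_empty drop samples whose row sum is zero (recorded in the
#'   `"report"` attribute) instead of failing validation.
#' @return object of class `otu_tab`: list with elements `counts` and
#'   `taxonomy`, plus a `"report"` attribute itemizing any dropped samples.
#' @export
otu_tab <- function(counts, taxonomy = NULL, drop_empty = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "double"  # doubles carry exact integers; avoids overflow
  dropped <- character(0)
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    dropped <- rownames(counts)[rs == 0]
    if (!drop_empty) stop("samples with zero total count: ", paste(dropped, collapse = ", "))
    counts <- counts[rs > 0, , drop = FALSE]
  }
  if (!is.null(taxonomy)) {
    taxonomy <- unlist(taxonomy)
    if (is.null(names(taxonomy)) || !all(names(taxonomy) %in% colnames(counts)))
      stop("taxonomy names must be OTU ids present in the table")
  }
  out <- structure(list(counts = counts, taxonomy = taxonomy), class = "otu_tab")
  attr(out, "report") <- list(dropped_samples = dropped)
  out
}

#' @export
print.otu_tab <- function(x, ...) {
  cat(sprintf("otu_tab: %d samples x %d OTUs, %s total reads\n",
              nrow(x$counts), ncol(x$counts), format(sum(x$counts), big.mark = ",")))
  if (!is.null(x$taxonomy))
    cat(sprintf("  taxonomy for %d OTUs\n", length(x$taxonomy)))
  invisible(x)
}

#' @export
dim.otu_tab <- function(x) dim(x$counts)

#' Sample ids / OTU ids of an OTU table
#' @param x an `otu_tab`
#' @return character vector of ids
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname sample_ids
#' @export
otu_ids <- function(x) colnames(x$counts)

#' Relative abundances of an OTU table
#'
#' @param x an `otu_tab` or counts matrix
#' @return matrix of per-sample proportions (rows sum to 1)
#' @export
rel_abundance <- function(x) {
  m <- if (inherits(x, "otu_tab")) x$counts else as.matrix(x)
  sweep(m, 1, rowSums(m), "/")
}

#' Subset an OTU table
#'
#' @param x an `otu_tab`
#' @param samples,otus character or logical/integer index vectors; NULL keeps all
#' @return an `otu_tab`
#' @export
subset_otu_tab <- function(x, samples = NULL, otus = NULL) {
  m <- x$counts
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  if (!is.null(otus)) m <- m[, otus, drop = FALSE]
  tax <- x$taxonomy
  if (!is.null(tax)) tax <- tax[names(tax) %in% colnames(m)]
  otu_tab(m, taxonomy = tax)
}

#' Season of a calendar month
#'
#' Meteorological seasons: Dec-Feb winter, Mar-May spring, Jun-Aug summer,
#' Sep-Nov autumn.
#'
#' @param month integer month of year (1..12), vectorized
#' @return character vector in {"winter","spring","summer","autumn"}
#' @export
season_of <- function(month) {
  stopifnot(all(month %in% 1:12))
  c("winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "autumn", "autumn", "autumn", "winter")[month]
}

#' Build sample metadata
#'
#' Validates a per-sample metadata table and derives the 0-based campaign
#' month index and season from the ISO "YYYY-MM" calendar month.
#'
#' @param df data.frame with columns `sample_id`, `location_id`, `sector_id`,
#'   `calendar_month` ("YYYY-MM"); water-chemistry columns are carried through.
#' @param campaign_start "YYYY-MM" of month index 0; default the earliest
#'   calendar month present.
#' @return data.frame with added `month_index`, `month_of_year`, `season`
#' @export
sample_metadata <- function(df, campaign_start = NULL) {
  req <- c("sample_id", "location_id", "sector_id", "calendar_month")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  cm <- as.character(df$calendar_month)
  if (!all(grepl("^\\d{4}-\\d{2}$", cm))) stop("calendar_month must be 'YYYY-MM'")
  yr <- as.integer(substr(cm, 1, 4)); mo <- as.integer(substr(cm, 6, 7))
  if (is.null(campaign_start)) campaign_start <- cm[order(yr * 12 + mo)][1]
  y0 <- as.integer(substr(campaign_start, 1, 4))
  m0 <- as.integer(substr(campaign_start, 6, 7))
  df$month_index <- (yr - y0) * 12 + (mo - m0)
  df$month_of_year <- mo
  df$season <- season_of(mo)
  df
}

# metadata rows aligned to the samples of a table (errors on missing rows)
aligned_meta <- function(tab, meta) {
  ids <- sample_ids(tab)
  if (!all(ids %in% meta$sample_id))
    stop("metadata missing samples: ",
         paste(setdiff(ids, meta$sample_id), collapse = ", "))
  meta[match(ids, meta$sample_id), , drop = FALSE]
}
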