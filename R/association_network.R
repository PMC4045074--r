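#' Maximal information coefficient between two abundance vectors
#'
#' MIC is the maximum over axis-aligned grids (a x b cells, a*b <= B(n),
#' B(n) = max(4, floor(n^grid_exponent))) of the grid's normalized mutual
#' information I / log min(a, b). For n <= 10 every admissible grid is
#' enumerated exactly (oracle mode); for larger n the standard
#' equipartition-plus-dynamic-programming search is used. The slope sign is
#' the sign of the ordinary least-squares slope; the p-value is estimated by
#' permuting `y`.
#'
#' @param x,y numeric vectors of equal length n >= 8, not constant
#' @param grid_exponent grid-budget exponent (default 0.6)
#' @param n_perm permutations for the p-value (default 1000); 0 skips it
#' @param seed RNG seed for the permutations
#' @param exhaustive force/forbid oracle mode (default: n <= 10)
#' @return list of class `mic_result`: `mic`, `slope_sign` (+1/-1/0),
#'   `n_points`, `p_value`
#' @export
mic <- function(x, y, grid_exponent = 0.6, n_perm = 1000, seed = 1L,
                exhaustive = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 8) stop("need at least 8 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  if (is.null(exhaustive)) exhaustive <- n <= 10
  f <- if (exhaustive) function(a, b) mic_exhaustive_cpp(a, b, grid_exponent)
       else function(a, b) mic_cpp(a, b, grid_exponent)
  obs <- f(x, y)
  p <- NA_real_
  if (n_perm > 0) {
    null <- with_seed(seed, vapply(seq_len(n_perm),
                                   function(i) f(x, y[sample.int(n)]), 0))
    p <- (1 + sum(null >= obs - 1e-12)) / (1 + n_perm)
  }
  sl <- stats::cov(x, y)
  structure(list(mic = obs,
                 slope_sign = if (abs(sl) < 1e-15) 0L else as.integer(sign(sl)),
                 n_points = n, p_value = p),
            class = "mic_result")
}

# null MIC distribution for tie-free data of size n (MIC of ranks vs a
# random permutation of ranks), sorted ascending
mic_null <- function(n, n_null, seed, grid_exponent = 0.6) {
  x <- as.numeric(seq_len(n))
  sort(with_seed(seed, vapply(seq_len(n_null),
                              function(i) mic_cpp(x, sample(x), grid_exponent), 0)))
}

# permutation p-value with an exponential peaks-over-threshold tail.
# Bonferroni over thousands of pairs needs p far below the 1/(n_null+1)
# floor of a plain permutation estimate; beyond the k-th largest null draw
# the exceedance probability is extrapolated as
# (k/n_null) * exp(-(m - q_k) / mean(top_k - q_k)).
mic_pvalue <- function(m, null_sorted, k = 50) {
  n_null <- length(null_sorted)
  k <- min(k, n_null - 1)
  qk <- null_sorted[n_null - k]
  if (m <= qk)
    return((1 + sum(null_sorted >= m - 1e-12)) / (1 + n_null))
  top <- null_sorted[(n_null - k + 1):n_null]
  rate <- 1 / max(mean(top - qk), 1e-12)
  min((k / n_null) * exp(-(m - qk) * rate), 1)
}

#' Robust MIC association network over rarefaction events
#'
#' Implements the survey's stringency protocol. OTUs must exceed the
#' detection-frequency floor in every event. Within each event, MIC is
#' computed for a pair only if the two OTUs are jointly detected in at least
#' `ceil(cooccur * n_samples)` samples (and at least `cooccur_floor`
#' samples). A pair is "discovered" in an event when MIC > `mic_min` and the
#' Bonferroni-corrected permutation p (corrected over the pairs tested in
#' that event) is below `alpha_level`. An edge is emitted when a pair is
#' discovered in at least `min_discoveries` events with the same
#' least-squares slope sign every time; any sign flip discards the pair.
#'
#' p-values use a permutation null shared across pairs of an event (MIC of a
#' random permutation at the event's sample size), since the co-occurrence
#' gate fixes n per event; `n_null` draws, with an exponential
#' peaks-over-threshold tail so that MICs beyond the largest null draw get a
#' finite Bonferroni-correctable p rather than the 1/(n_null+1) floor.
#'
#' @param events `rarefaction_events` from [rarefy] (100 in the survey design)
#' @param detection_min per-event detection-frequency floor (default 0.30)
#' @param cooccur joint-detection fraction gate (default 0.70)
#' @param cooccur_floor absolute minimum of jointly detected samples (21)
#' @param mic_min MIC threshold (default 0.4)
#' @param alpha_level Bonferroni-corrected significance level (default 0.05)
#' @param min_discoveries minimum discovering events (default 10)
#' @param grid_exponent MIC grid-budget exponent
#' @param n_null permutation draws for the shared null (default 1000)
#' @param seed RNG seed
#' @return list of class `assoc_network`: `nodes` (otu_id,
#'   mean_rel_abundance, detection_frequency), `edges` (otu_a, otu_b, mic =
#'   median over discovering events, sign, discoveries), `n_otus_tested`,
#'   `params`
#' @export
robust_associations <- function(events, detection_min = 0.30, cooccur = 0.70,
                                cooccur_floor = 21, mic_min = 0.4,
                                alpha_level = 0.05, min_discoveries = 10,
                                grid_exponent = 0.6, n_null = 1000, seed = 1L) {
  stopifnot(length(events) >= 1)
  n_ev <- length(events)
  keep <- Reduce(`&`, lapply(events, function(e) colMeans(e$counts > 0) > detection_min))
  otus <- otu_ids(events[[1]])[keep]
  K <- length(otus)
  params <- list(detection_min = detection_min, cooccur = cooccur,
                 cooccur_floor = cooccur_floor, mic_min = mic_min,
                 alpha_level = alpha_level, min_discoveries = min_discoveries,
                 grid_exponent = grid_exponent, n_null = n_null, n_events = n_ev)
  empty <- function() {
    warning("no OTU pair qualifies; returning empty network")
    structure(list(nodes = data.frame(otu_id = character(0),
                                      mean_rel_abundance = numeric(0),
                                      detection_frequency = numeric(0)),
                   edges = data.frame(otu_a = character(0), otu_b = character(0),
                                      mic = numeric(0), sign = integer(0),
                                      discoveries = integer(0)),
                   n_otus_tested = K, params = params),
              class = "assoc_network")
  }
  if (K < 2) return(empty())

  N <- nrow(events[[1]]$counts)
  gate <- max(ceiling(cooccur * N), cooccur_floor)
  null <- mic_null(N, n_null, seed, grid_exponent)  # sorted ascending
  disc <- matrix(0L, K, K)
  pos <- matrix(0L, K, K)
  neg <- matrix(0L, K, K)
  mics <- vector("list", K * K)  # per-pair discovery MICs, index (i-1)*K+j
  ra_sum <- 0; det_sum <- 0
  for (ev in events) {
    sub <- ev$counts[, otus, drop = FALSE]
    ra <- rel_abundance(ev$counts)[, otus, drop = FALSE]
    det <- sub > 0
    ra_sum <- ra_sum + colMeans(ra)
    det_sum <- det_sum + colMeans(det)
    J <- crossprod(det)  # joint detection counts
    test <- which(upper.tri(J) & J >= gate, arr.ind = TRUE)
    if (nrow(test) == 0) next
    n_tested <- nrow(test)
    for (t in seq_len(n_tested)) {
      i <- test[t, 1]; j <- test[t, 2]
      m <- mic_cpp(ra[, i], ra[, j], grid_exponent)
      if (m <= mic_min) next
      if (mic_pvalue(m, null) * n_tested >= alpha_level) next
      jd <- det[, i] & det[, j]
      sl <- stats::cov(ra[jd, i], ra[jd, j])
      sgn <- if (abs(sl) < 1e-15) 0L else as.integer(sign(sl))
      disc[i, j] <- disc[i, j] + 1L
      if (sgn > 0) pos[i, j] <- pos[i, j] + 1L
      if (sgn < 0) neg[i, j] <- neg[i, j] + 1L
      id <- (i - 1L) * K + j
      mics[[id]] <- c(mics[[id]], m)
    }
  }
  ok <- which(disc >= min_discoveries & (pos == disc | neg == disc) &
                (pos + neg) == disc, arr.ind = TRUE)
  edges <- if (nrow(ok)) do.call(rbind, lapply(seq_len(nrow(ok)), function(t) {
    i <- ok[t, 1]; j <- ok[t, 2]
    data.frame(otu_a = otus[i], otu_b = otus[j],
               mic = stats::median(mics[[(i - 1L) * K + j]]),
               sign = if (pos[i, j] > 0) 1L else -1L,
               discoveries = disc[i, j])
  })) else data.frame(otu_a = character(0), otu_b = character(0),
                      mic = numeric(0), sign = integer(0),
                      discoveries = integer(0))
  structure(list(nodes = data.frame(otu_id = otus,
                                    mean_rel_abundance = ra_sum / n_ev,
                                    detection_frequency = det_sum / n_ev,
                                    row.names = NULL),
                 edges = edges, n_otus_tested = K, params = params),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("assoc_network: %d OTUs tested, %d nodes, %d edges (%d +, %d -)\n",
              x$n_otus_tested, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

#' Extract seasonal clusters from an association network
#'
#' Candidate clusters are the connected components of the positive-edge
#' subgraph. Bridge nodes — articulation points whose removal splits a
#' positive component into two or more parts of at least two nodes — are
#' peeled iteratively and labelled "unassigned" (their positive edges span
#' candidate clusters). Nodes with no positive edges but surviving negative
#' edges are "unassigned"; nodes with no edges at all are "isolated".
#' A validation report lists within-cluster negative edges.
#'
#' @param net an `assoc_network`
#' @return list of class `cluster_assignment`: `assignment` (named vector:
#'   cluster label, "unassigned" or "isolated"), `clusters` (list of member
#'   vectors, largest first), `validation` (within-cluster negative edges)
#' @export
extract_clusters <- function(net) {
  nodes <- net$nodes$otu_id
  asg <- stats::setNames(rep("isolated", length(nodes)), nodes)
  ed <- net$edges
  connected <- unique(c(ed$otu_a, ed$otu_b))
  asg[connected] <- "unassigned"
  pe <- ed[ed$sign > 0, , drop = FALSE]
  clusters <- list()
  if (nrow(pe)) {
    g <- igraph::graph_from_data_frame(pe[, c("otu_a", "otu_b")],
                                       directed = FALSE,
                                       vertices = unique(c(pe$otu_a, pe$otu_b)))
    repeat {
      # candidate bridges: articulation points whose removal splits their
      # component into >= 2 parts of >= 2 nodes; peel the lowest-degree one
      # (ties lexicographic) so cluster cores survive their own cut vertices
      arts <- igraph::as_ids(igraph::articulation_points(g))
      qual <- Filter(function(v) {
        g2 <- igraph::delete_vertices(g, v)
        nb <- igraph::as_ids(igraph::neighbors(g, v))
        comp2 <- igraph::components(g2)
        parts <- unique(comp2$membership[nb])
        length(parts) >= 2 && sum(comp2$csize[parts] >= 2) >= 2
      }, arts)
      if (length(qual) == 0) break
      deg <- igraph::degree(g, qual)
      v <- qual[order(deg, qual)][1]
      g <- igraph::delete_vertices(g, v)
    }
    comp <- igraph::components(g)
    memb <- split(names(comp$membership), comp$membership)
    memb <- memb[lengths(memb) >= 2]
    if (length(memb)) {
      ord <- order(-lengths(memb),
                   vapply(memb, function(m) sort(m)[1], ""))
      clusters <- unname(memb[ord])
      for (k in seq_along(clusters)) asg[clusters[[k]]] <- as.character(k)
    }
  }
  bad <- ed[ed$sign < 0 & asg[ed$otu_a] == asg[ed$otu_b] &
              !asg[ed$otu_a] %in% c("unassigned", "isolated"), , drop = FALSE]
  structure(list(assignment = asg, clusters = clusters,
                 validation = list(within_cluster_negative = bad)),
            class = "cluster_assignment")
}

#' Network density, clustering coefficient and degree table
#'
#' Density = |E| / (n(n-1)/2) over the connected node set (and per cluster
#' over each cluster's members); clustering coefficient = mean over nodes of
#' the local triangle density on the undirected unsigned graph, nodes of
#' degree < 2 contributing 0.
#'
#' @param net an `assoc_network`
#' @param assignment optional `cluster_assignment` for per-cluster densities
#' @return list: `density`, `cluster_density` (named), `clustering_coefficient`,
#'   `degrees` (data.frame)
#' @export
network_stats <- function(net, assignment = NULL) {
  ed <- net$edges
  if (nrow(ed) == 0) {
    warning("empty network")
    return(list(density = 0, cluster_density = numeric(0),
                clustering_coefficient = 0,
                degrees = data.frame(otu_id = character(0), degree = integer(0))))
  }
  g <- igraph::graph_from_data_frame(ed[, c("otu_a", "otu_b")], directed = FALSE)
  n <- igraph::vcount(g)
  dens <- igraph::ecount(g) / (n * (n - 1) / 2)
  cc <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  cd <- numeric(0)
  if (!is.null(assignment)) {
    cd <- vapply(seq_along(assignment$clusters), function(k) {
      mem <- assignment$clusters[[k]]
      within <- sum(ed$otu_a %in% mem & ed$otu_b %in% mem)
      within / (length(mem) * (length(mem) - 1) / 2)
    }, 0)
    names(cd) <- paste0("cluster", seq_along(cd))
  }
  dg <- igraph::degree(g)
  list(density = dens, cluster_density = cd, clustering_coefficient = cc,
       degrees = data.frame(otu_id = names(dg), degree = as.integer(dg),
                            row.names = NULL))
}

#' Monthly relative abundance of each cluster
#'
#' For each month, the mean over that month's samples of the summed relative
#' abundance of every cluster's member OTUs (plus the unassigned and
#' isolated groups); sums per month equal the subset's total abundance.
#'
#' @param tab an [otu_tab] (unrarefied or event-averaged)
#' @param assignment a `cluster_assignment`
#' @param meta metadata (provides `month_index`)
#' @return data.frame: month_index x group abundance (long format)
#' @export
cluster_timeseries <- function(tab, assignment, meta) {
  md <- aligned_meta(tab, meta)
  ra <- rel_abundance(tab)
  asg <- assignment$assignment
  groups <- split(names(asg), asg)
  rows <- list()
  for (mo in sort(unique(md$month_index))) {
    i <- which(md$month_index == mo)
    for (gname in names(groups)) {
      ids <- intersect(groups[[gname]], colnames(ra))
      rows[[length(rows) + 1]] <- data.frame(
        month_index = mo, group = gname,
        abundance = mean(rowSums(ra[i, ids, drop = FALSE])))
    }
  }
  do.call(rbind, rows)
}

#' Phylogenetic distinctness of two clusters (unweighted UniFrac + permutation)
#'
#' Unweighted UniFrac between the two clusters' leaf sets taken as presence
#' profiles; p-value by reassigning cluster labels at random over the union
#' (sizes preserved), or exhaustively over all label assignments.
#'
#' @param assignment a `cluster_assignment`
#' @param tree rooted phylogeny covering all members
#' @param clusters which two cluster labels to compare (default "1","2")
#' @param n_perm label permutations (default 999)
#' @param seed RNG seed
#' @param exhaustive enumerate all assignments (needs a small union)
#' @return list: `score`, `p_value`, `n_permutations`
#' @export
cluster_unifrac_test <- function(assignment, tree, clusters = c("1", "2"),
                                 n_perm = 999, seed = 1L, exhaustive = FALSE) {
  m1 <- names(assignment$assignment)[assignment$assignment == clusters[1]]
  m2 <- names(assignment$assignment)[assignment$assignment == clusters[2]]
  if (length(m1) == 0 || length(m2) == 0) stop("empty cluster")
  if (length(intersect(m1, m2))) stop("overlapping cluster membership")
  pool <- c(m1, m2)
  uf <- function(set1) {
    prof <- matrix(0, 2, length(pool), dimnames = list(c("c1", "c2"), pool))
    prof[1, set1] <- 1
    prof[2, setdiff(pool, set1)] <- 1
    beta_matrix(otu_tab(prof), "unweighted_unifrac", tree = tree)[1, 2]
  }
  obs <- uf(m1)
  k <- length(m1)
  if (exhaustive) {
    sets <- utils::combn(pool, k, simplify = FALSE)
    null <- vapply(sets, uf, 0)
    p <- mean(null >= obs - 1e-12)
    n_used <- length(sets)
  } else {
    null <- with_seed(seed, vapply(seq_len(n_perm),
                                   function(i) uf(sample(pool, k)), 0))
    p <- (1 + sum(null >= obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  list(score = obs, p_value = p, n_permutations = n_used)
}
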