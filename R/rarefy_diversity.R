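#' Rarefaction plan
#'
#' Fixes the subsampling depth, the number of subsampling events and the base
#' seed. Event `e` (1-based) is drawn under seed `base_seed + e`, making every
#' event bit-for-bit reproducible in isolation.
#'
#' @param depth reads per sample after subsampling (the survey design uses the
#'   shallowest retained sample, n = 834)
#' @param n_events number of independent subsampling events (100 for the
#'   association/occupancy stages, 1,000 for headline diversity matrices)
#' @param base_seed integer base seed
#' @return list of class `rarefaction_plan`
#' @export
rarefaction_plan <- function(depth = 834, n_events = 100, base_seed = 1L) {
  stopifnot(depth >= 1, n_events >= 1)
  if (base_seed + n_events >= 2^31) stop("base_seed too large")
  structure(list(depth = as.integer(depth), n_events = as.integer(n_events),
                 base_seed = as.integer(base_seed)),
            class = "rarefaction_plan")
}

# run expr under a private, fully specified RNG; restores global state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# subsample one count vector to `depth` reads without replacement
# (multivariate hypergeometric draw)
rarefy_row <- function(x, depth) {
  tot <- sum(x)
  if (tot == depth) return(x)
  picks <- sample.int(tot, depth)
  tabulate(findInterval(picks, cumsum(x), left.open = TRUE) + 1L,
           nbins = length(x))
}

#' Rarefy an OTU table
#'
#' Subsamples every sample to a common depth without replacement, repeated
#' over the plan's events. Samples shallower than the depth are dropped and
#' itemized (the survey discarded 9 such samples).
#'
#' @param tab an [otu_tab]
#' @param plan a [rarefaction_plan]
#' @return list of class `rarefaction_events`: one [otu_tab] per event, with
#'   attributes `plan` and `report` (dropped samples)
#' @export
rarefy <- function(tab, plan) {
  stopifnot(inherits(tab, "otu_tab"), inherits(plan, "rarefaction_plan"))
  m <- tab$counts
  shallow <- rownames(m)[rowSums(m) < plan$depth]
  if (length(shallow) == nrow(m)) stop("no sample reaches depth ", plan$depth)
  m <- m[!rownames(m) %in% shallow, , drop = FALSE]
  events <- vector("list", plan$n_events)
  for (e in seq_len(plan$n_events)) {
    events[[e]] <- with_seed(plan$base_seed + e, {
      r <- m
      for (i in seq_len(nrow(m))) r[i, ] <- rarefy_row(m[i, ], plan$depth)
      otu_tab(r, taxonomy = tab$taxonomy)
    })
  }
  structure(events, class = "rarefaction_events", plan = plan,
            report = list(dropped_samples = shallow))
}

#' Per-sample alpha diversity
#'
#' Richness (observed OTUs), Shannon diversity H = -sum p_i ln p_i,
#' nonparametric Shannon diversity (the Chao-Shen coverage-adjusted
#' estimator), and Shannon evenness H / ln(richness) (defined as 0 at
#' richness 1). Intended for tables rarefied to a common depth.
#'
#' @param tab an [otu_tab] (or counts matrix)
#' @return data.frame with columns sample_id, richness, shannon, np_shannon,
#'   evenness
#' @export
alpha_metrics <- function(tab) {
  m <- if (inherits(tab, "otu_tab")) tab$counts else as.matrix(tab)
  if (any(rowSums(m) == 0)) stop("all-zero sample")
  out <- t(apply(m, 1, function(x) {
    x <- x[x > 0]
    n <- sum(x); p <- x / n
    S <- length(x)
    H <- -sum(p * log(p))
    # Chao-Shen: coverage C = 1 - f1/n; Horvitz-Thompson correction for
    # unseen mass. All-singleton guard: f1 -> n-1 keeps C > 0.
    f1 <- sum(x == 1)
    if (f1 == n) f1 <- n - 1
    C <- 1 - f1 / n
    pa <- C * p
    npH <- if (C == 0) NA_real_ else -sum(pa * log(pa) / (1 - (1 - pa)^n))
    c(richness = S, shannon = H, np_shannon = npH,
      evenness = if (S == 1) 0 else H / log(S))
  }))
  data.frame(sample_id = rownames(m), out, row.names = NULL)
}

# per-branch community mass: rows = edges of `tree`, cols = samples.
# prop: samples x tips relative-abundance matrix (tip columns may be a
# superset ordering; matched by name).
branch_mass <- function(tree, prop) {
  absent <- setdiff(colnames(prop)[colSums(prop) > 0], tree$tip.label)
  if (length(absent)) stop("OTU absent from tree: ", paste(absent, collapse = ", "))
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  acc <- matrix(0, nnode, nrow(prop))
  present <- intersect(tree$tip.label, colnames(prop))
  acc[match(present, tree$tip.label), ] <- t(prop[, present, drop = FALSE])
  for (e in seq_len(nrow(tree$edge)))
    acc[tree$edge[e, 1], ] <- acc[tree$edge[e, 1], ] + acc[tree$edge[e, 2], ]
  list(mass = acc[tree$edge[, 2], , drop = FALSE], blen = tree$edge.length)
}

# UniFrac between columns i, j of a branch-mass structure
unifrac_pair <- function(bm, i, j, weighted) {
  a <- bm$mass[, i]; b <- bm$mass[, j]; bl <- bm$blen
  if (weighted) {
    den <- sum(bl * (a + b))
    if (den == 0) return(0)
    sum(bl * abs(a - b)) / den
  } else {
    pa <- a > 0; pb <- b > 0
    union <- pa | pb
    if (!any(union)) return(0)
    sum(bl[xor(pa, pb)]) / sum(bl[union])
  }
}

#' Pairwise beta diversity matrix
#'
#' Bray-Curtis and Jaccard via vegan; weighted (normalized, bounded in
#' \[0,1\]) and unweighted UniFrac computed on the supplied rooted tree by
#' postorder branch-mass accumulation.
#'
#' @param tab an [otu_tab]
#' @param metric one of `"bray_curtis"`, `"jaccard"`,
#'   `"unweighted_unifrac"`, `"weighted_unifrac"`
#' @param tree rooted `phylo` covering every OTU with nonzero count
#'   (UniFrac metrics only)
#' @return symmetric matrix with zero diagonal and a `"metric"` attribute
#' @export
beta_matrix <- function(tab, metric = c("bray_curtis", "jaccard",
                                        "unweighted_unifrac", "weighted_unifrac"),
                        tree = NULL) {
  metric <- match.arg(metric)
  m <- if (inherits(tab, "otu_tab")) tab$counts else as.matrix(tab)
  if (metric == "bray_curtis") {
    dm <- as.matrix(vegan::vegdist(m, method = "bray"))
  } else if (metric == "jaccard") {
    dm <- as.matrix(vegan::vegdist(m, method = "jaccard", binary = TRUE))
  } else {
    if (is.null(tree)) stop("tree required for UniFrac")
    bm <- branch_mass(tree, rel_abundance(m))
    n <- nrow(m)
    dm <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    w <- metric == "weighted_unifrac"
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      dm[i, j] <- dm[j, i] <- unifrac_pair(bm, i, j, weighted = w)
  }
  dm <- validate_dm(dm)
  attr(dm, "metric") <- metric
  dm
}

#' Element-wise mean of distance matrices over subsampling events
#'
#' @param dms list of symmetric matrices sharing an identical label set
#' @return the averaged matrix
#' @export
average_distance <- function(dms) {
  stopifnot(length(dms) >= 1)
  labs <- rownames(dms[[1]])
  for (d in dms)
    if (!identical(rownames(d), labs)) stop("distance matrices have mismatched labels")
  out <- Reduce(`+`, lapply(dms, unclass)) / length(dms)
  out <- validate_dm(out)
  attr(out, "metric") <- attr(dms[[1]], "metric")
  out
}

#' Beta diversity averaged over rarefaction events
#'
#' Convenience wrapper: computes `beta_matrix` for each rarefied event and
#' averages element-wise (metric values averaged over events).
#'
#' @param events a `rarefaction_events` list from [rarefy]
#' @inheritParams beta_matrix
#' @export
average_beta <- function(events, metric = "bray_curtis", tree = NULL) {
  average_distance(lapply(events, beta_matrix, metric = metric, tree = tree))
}

#' Principal-coordinate analysis
#'
#' Gower double-centering followed by eigendecomposition (classical MDS).
#' Negative eigenvalues are reported, never silently dropped; coordinates
#' span the positive-eigenvalue axes, ordered by eigenvalue.
#'
#' @param dm symmetric distance matrix
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all n),
#'   and `rel_eig` (eigenvalue / sum of positive eigenvalues)
#' @export
pcoa <- function(dm) {
  dm <- validate_dm(dm)
  n <- nrow(dm)
  # cmdscale warns when k exceeds the positive-eigenvalue count; negative
  # eigenvalues are reported downstream, so the warning is redundant here
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = n - 1,
                                          eig = TRUE))
  co <- fit$points
  if (is.null(co) || ncol(co) == 0) co <- matrix(0, n, 1, dimnames = list(rownames(dm), "Axis1"))
  else colnames(co) <- paste0("Axis", seq_len(ncol(co)))
  pos <- fit$eig[fit$eig > 0]
  list(coordinates = co, eigenvalues = fit$eig,
       rel_eig = fit$eig / if (length(pos)) sum(pos) else 1)
}
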