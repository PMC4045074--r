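#' @useDynLib aquadyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# all permutations of 1..n (n <= 8), one per row
all_permutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    ins <- cbind(sub[, seq_len(k - 1L), drop = FALSE], n,
                 sub[, seq(k, n - 1L)[seq_len(n - k)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- ins
    r <- r + nrow(sub)
  }
  out
}

# permutation p-value machinery shared by the grouping tests.
# stat_fn(perm_index_vector) -> scalar; larger = more extreme.
# Random mode: p = (1 + #{perm >= obs}) / (1 + n_perm).
# Exhaustive mode: all n! relabelings (identity included), p = mean(perm >= obs).
perm_pvalue <- function(n, stat_obs, stat_fn, n_perm, seed, exhaustive) {
  if (exhaustive) {
    P <- all_permutations(n)
    stats <- apply(P, 1, stat_fn)
    list(p = mean(stats >= stat_obs - 1e-12), n_perm = nrow(P), null = stats)
  } else {
    stats <- with_seed(seed, vapply(seq_len(n_perm),
                                    function(i) stat_fn(sample.int(n)), 0))
    list(p = (1 + sum(stats >= stat_obs - 1e-12)) / (1 + n_perm),
         n_perm = n_perm, null = stats)
  }
}

grouping_result <- function(test, statistic, p, n_perm, grouping) {
  structure(list(test = test, statistic = statistic, p_value = p,
                 n_permutations = n_perm, grouping = grouping),
            class = "grouping_result")
}

#' @export
print.grouping_result <- function(x, ...) {
  cat(sprintf("%s (%s): %s; p = %.4g [%d permutations]\n", x$test, x$grouping,
              paste(names(x$statistic), signif(unlist(x$statistic), 4),
                    sep = " = ", collapse = ", "),
              x$p_value, x$n_permutations))
  invisible(x)
}

check_groups <- function(dm, groups) {
  g <- as.factor(groups)
  if (length(g) != nrow(dm)) stop("groups length must match distance matrix")
  tb <- table(g)
  if (length(tb) < 2) stop("need at least 2 groups")
  if (any(tb < 2)) stop("singleton group: ", paste(names(tb)[tb < 2], collapse = ", "))
  g
}

#' PERMANOVA (one-way, distance-based)
#'
#' Pseudo-F from within/between sums of squared distances:
#' SS_total = sum of all squared pairwise distances / n, SS_within summed per
#' group, F = (SS_between/(a-1)) / (SS_within/(n-a)), R2 =
#' SS_between/SS_total. p-value by permutation of group labels using the
#' (1+b)/(1+n) estimator, or by exhaustive enumeration of all relabelings.
#'
#' @param dm symmetric distance matrix
#' @param groups factor-like group labels, one per sample
#' @param n_perm number of random permutations (default 999)
#' @param seed RNG seed for the permutations
#' @param exhaustive enumerate all n! relabelings (n <= 8) for an exact p
#' @param grouping name recorded in the result
#' @return a `grouping_result` with statistic components `F` and `R2`
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = 1L, exhaustive = FALSE,
                      grouping = deparse(substitute(groups))) {
  dm <- validate_dm(dm)
  g <- check_groups(dm, groups)
  D2 <- dm^2
  n <- nrow(dm); a <- nlevels(g)
  ss_total <- sum(D2) / (2 * n)
  ss_within <- function(gp) {
    ssw <- 0
    for (k in levels(gp)) {
      i <- which(gp == k)
      ssw <- ssw + sum(D2[i, i]) / (2 * length(i))
    }
    ssw
  }
  stat <- function(perm) {
    ssw <- ss_within(g[perm])
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- stat(seq_len(n))
  r2 <- 1 - ss_within(g) / ss_total
  pp <- perm_pvalue(n, f_obs, stat, n_perm, seed, exhaustive)
  grouping_result("PERMANOVA", list(F = f_obs, R2 = r2), pp$p, pp$n_perm, grouping)
}

#' ANOSIM
#'
#' R = (mean between-group rank - mean within-group rank) / (M/2) on the
#' average-tied ranks of the n(n-1)/2 pairwise distances, M = n(n-1)/2.
#' Permutation p as in [permanova].
#'
#' @inheritParams permanova
#' @return a `grouping_result` with statistic component `R`
#' @export
anosim <- function(dm, groups, n_perm = 999, seed = 1L, exhaustive = FALSE,
                   grouping = deparse(substitute(groups))) {
  dm <- validate_dm(dm)
  g <- check_groups(dm, groups)
  n <- nrow(dm)
  lt <- lower.tri(dm)
  rk <- matrix(0, n, n)
  rk[lt] <- rank(dm[lt])
  rk <- rk + t(rk)
  M <- n * (n - 1) / 2
  stat <- function(perm) {
    gp <- g[perm]
    same <- outer(gp, gp, "==")[lt]
    r <- rk[lt]
    (mean(r[!same]) - mean(r[same])) / (M / 2)
  }
  r_obs <- stat(seq_len(n))
  pp <- perm_pvalue(n, r_obs, stat, n_perm, seed, exhaustive)
  grouping_result("ANOSIM", list(R = r_obs), pp$p, pp$n_perm, grouping)
}

#' Mantel test
#'
#' Pearson correlation of the off-diagonal entries of two distance matrices
#' with matching labels; p by permuting rows/columns of the second matrix
#' (one-sided, large r extreme).
#'
#' @param dm_a,dm_b symmetric matrices with identical labels in identical order
#' @inheritParams permanova
#' @return a `grouping_result` with statistic component `r`
#' @export
mantel <- function(dm_a, dm_b, n_perm = 999, seed = 1L, exhaustive = FALSE,
                   grouping = "matrix-vs-matrix") {
  dm_a <- validate_dm(dm_a); dm_b <- validate_dm(dm_b)
  if (!identical(rownames(dm_a), rownames(dm_b)))
    stop("distance matrices must share labels in the same order")
  lt <- lower.tri(dm_a)
  va <- dm_a[lt]
  if (stats::sd(va) == 0 || stats::sd(dm_b[lt]) == 0)
    stop("Mantel r undefined for a constant matrix")
  n <- nrow(dm_a)
  stat <- function(perm) stats::cor(va, dm_b[perm, perm][lt])
  r_obs <- stat(seq_len(n))
  pp <- perm_pvalue(n, r_obs, stat, n_perm, seed, exhaustive)
  grouping_result("Mantel", list(r = r_obs), pp$p, pp$n_perm, grouping)
}

#' Beta dispersion (distance to group centroid) with ANOVA and Tukey HSD
#'
#' Wraps `vegan::betadisper` (PCoA embedding keeping negative-eigenvalue axes
#' with imaginary-part correction, distance of each sample to its group
#' centroid), followed by one-way ANOVA on those distances and Tukey HSD.
#'
#' @param dm symmetric distance matrix
#' @param groups group labels (groups of size 1 are allowed: distance 0,
#'   flagged)
#' @return list: `distances` (data.frame sample/group/distance), `anova_f`,
#'   `anova_p`, `tukey` (pairwise difference table), `flags`
#' @export
beta_dispersion <- function(dm, groups) {
  dm <- validate_dm(dm)
  g <- as.factor(groups)
  if (length(g) != nrow(dm)) stop("groups length must match distance matrix")
  mod <- vegan::betadisper(stats::as.dist(dm), g, type = "centroid")
  d <- as.numeric(mod$distances)
  flags <- character(0)
  if (any(table(g) == 1))
    flags <- c(flags, paste0("singleton group(s): ",
                             paste(names(table(g))[table(g) == 1], collapse = ", ")))
  if (all(abs(d) < 1e-12)) {
    flags <- c(flags, "all dispersions zero; ANOVA F undefined")
    return(list(distances = data.frame(sample_id = rownames(dm), group = g, distance = d),
                anova_f = NA_real_, anova_p = NA_real_, tukey = NULL, flags = flags))
  }
  an <- stats::anova(mod)
  tk <- stats::TukeyHSD(mod)$group
  list(distances = data.frame(sample_id = rownames(dm), group = g, distance = d),
       anova_f = an$`F value`[1], anova_p = an$`Pr(>F)`[1],
       tukey = tk, flags = flags)
}

#' Pearson correlation helper (alpha diversity vs water chemistry)
#'
#' Thin wrapper over `cor.test` across a set of metadata variables, the form
#' used to relate monthly richness to temperature, conductivity and the
#' source-water blend ratio.
#'
#' @param values numeric vector (e.g. per-sample richness)
#' @param meta metadata data.frame aligned to `values`
#' @param vars metadata column names to correlate against
#' @return data.frame with variable, r, p (two-sided t approximation), n
#' @export
chemistry_correlations <- function(values, meta, vars) {
  rows <- lapply(vars, function(v) {
    x <- meta[[v]]
    ok <- stats::complete.cases(values, x)
    ct <- stats::cor.test(values[ok], x[ok])
    data.frame(variable = v, r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
  do.call(rbind, rows)
}

#' Core-OTU selection curve
#'
#' For each filtering threshold, retain the OTUs passing it, rebuild the
#' Bray-Curtis matrix on the retained subset and Mantel-correlate it against
#' the full-table matrix. Thresholds are percentages: in
#' `"relative_abundance"` mode an OTU is kept if its grand mean relative
#' abundance exceeds `threshold`% (survey range 0.001-10%); in
#' `"detection_frequency"` mode if it is detected (count > 0) in more than
#' `threshold`% of samples (survey range 2-100%).
#'
#' @param tab an [otu_tab] (typically rarefied or event-averaged)
#' @param thresholds numeric vector of percentage thresholds
#' @param mode `"relative_abundance"` or `"detection_frequency"`
#' @param n_perm Mantel permutations per point (p not usually needed; keep low)
#' @param seed RNG seed
#' @return data.frame: threshold, n_otus, mantel_r (NA when flagged), flagged
#' @export
core_selection_curve <- function(tab, thresholds,
                                 mode = c("relative_abundance", "detection_frequency"),
                                 n_perm = 99, seed = 1L) {
  mode <- match.arg(mode)
  m <- tab$counts
  ra <- rel_abundance(m)
  score <- if (mode == "relative_abundance") 100 * colMeans(ra)
           else 100 * colMeans(m > 0)
  full <- beta_matrix(tab, "bray_curtis")
  rows <- lapply(thresholds, function(thr) {
    keep <- score > thr
    n_keep <- sum(keep)
    if (n_keep < 3)
      return(data.frame(threshold = thr, n_otus = n_keep, mantel_r = NA_real_,
                        flagged = TRUE))
    sub <- m[, keep, drop = FALSE]
    ok <- rowSums(sub) > 0
    r <- if (sum(ok) < 3) NA_real_ else
      mantel(beta_matrix(otu_tab(sub[ok, , drop = FALSE]), "bray_curtis"),
             full[ok, ok], n_perm = n_perm, seed = seed)$statistic$r
    data.frame(threshold = thr, n_otus = n_keep, mantel_r = r,
               flagged = is.na(r) || !all(ok))
  })
  do.call(rbind, rows)
}
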