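# Independent brute-force oracles used by the tests. These deliberately take
# different computational routes from the package implementation.

# all permutations of 1..n by recursive head selection (not the insertion
# scheme the package uses)
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  out <- NULL
  for (h in seq_len(n)) {
    rest <- oracle_perms(n - 1L)
    rest_vals <- setdiff(seq_len(n), h)
    out <- rbind(out, cbind(h, matrix(rest_vals[rest], nrow(rest), n - 1L)))
  }
  unname(out)
}

# PERMANOVA pseudo-F via the Gower-centered matrix trace identities
# (SS_between = tr(H G H) with H the group-design hat matrix)
oracle_permanova_f <- function(dm, groups) {
  n <- nrow(dm)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (dm^2) %*% J
  X <- stats::model.matrix(~ factor(groups))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  a <- length(unique(groups))
  ssb <- sum(diag(H %*% G %*% H))
  ssw <- sum(diag(G)) - ssb
  (ssb / (a - 1)) / (ssw / (n - a))
}

# ANOSIM R statistic straight from its definition on a fresh ranking
oracle_anosim_r <- function(dm, groups) {
  n <- nrow(dm)
  pairs <- utils::combn(n, 2)
  d <- dm[t(pairs)]
  rk <- rank(d)
  same <- groups[pairs[1, ]] == groups[pairs[2, ]]
  M <- n * (n - 1) / 2
  (mean(rk[!same]) - mean(rk[same])) / (M / 2)
}

oracle_mantel_r <- function(a, b) {
  stats::cor(a[lower.tri(a)], b[lower.tri(b)])
}

# exhaustive permutation p-value: proportion of all n! relabelings (identity
# included) with statistic >= observed
oracle_exhaustive_p <- function(stat_fn, n) {
  P <- oracle_perms(n)
  stats <- apply(P, 1, stat_fn)
  mean(stats >= stat_fn(seq_len(n)) - 1e-12)
}

# exhaustive MIC in plain R: every admissible grid over distinct-value cuts
oracle_mic <- function(x, y, alpha = 0.6) {
  n <- length(x)
  B <- max(4, floor(n^alpha))
  bx <- match(x, sort(unique(x))) - 1L
  by <- match(y, sort(unique(y))) - 1L
  dx <- max(bx) + 1L; dy <- max(by) + 1L
  best <- 0
  for (a in 2:max(2, B %/% 2)) {
    if (a * 2 > B || a > dx) break
    for (b in 2:max(2, B %/% a)) {
      if (a * b > B || b > dy) break
      cutx <- if (a == 2 && dx == 2) list(1L) else
        utils::combn(seq_len(dx - 1), a - 1, simplify = FALSE)
      cuty <- if (b == 2 && dy == 2) list(1L) else
        utils::combn(seq_len(dy - 1), b - 1, simplify = FALSE)
      for (cx in cutx) for (cy in cuty) {
        col <- findInterval(bx, cx) + 1L
        row <- findInterval(by, cy) + 1L
        tabj <- table(col, row)
        pj <- tabj / n
        pc <- rowSums(pj); pr <- colSums(pj)
        I <- sum(pj * log(pj / outer(pc, pr)), na.rm = TRUE)
        best <- max(best, I / log(min(a, b)))
      }
    }
  }
  best
}

# Rand index between two labelings restricted to shared names
oracle_rand <- function(lab1, lab2) {
  ids <- intersect(names(lab1), names(lab2))
  a <- lab1[ids]; b <- lab2[ids]
  n <- length(ids)
  agree <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  agree / (n * (n - 1) / 2)
}

# small labelled Euclidean distance matrix from a point configuration
dm_from_points <- function(pts, labels = paste0("s", seq_len(nrow(pts)))) {
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(labels, labels)
  d
}
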