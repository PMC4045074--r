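#' Interspecific occupancy-abundance model forms
#'
#' Occupancy probability P as a function of mean relative abundance mu
#' (a proportion in \[0,1\]) with the shape parameter beta fixed at 1:
#' Poisson P = 1 - exp(-mu) (parameter-free); Nachman P = 1 - exp(-alpha mu);
#' Hanski-Gyllenberg P = alpha mu / (1 + alpha mu); power P = min(alpha mu, 1)
#' (clipped at 1 inside the likelihood); negative binomial
#' P = 1 - (1 + mu/k)^(-k) with aggregation parameter k.
#'
#' @param model one of `"poisson"`, `"nachman"`, `"hanski_gyllenberg"`,
#'   `"power"`, `"negative_binomial"`
#' @param param alpha (or k for the negative binomial); ignored for Poisson
#' @param mu mean relative abundance(s), >= 0
#' @return occupancy probability/ies in \[0,1\]
#' @export
ioam_models <- c("poisson", "nachman", "hanski_gyllenberg", "power",
                 "negative_binomial")

#' @rdname ioam_models
#' @export
ioam_predict <- function(model, param, mu) {
  model <- match.arg(model, ioam_models)
  if (any(mu < 0)) stop("mu must be >= 0")
  if (model != "poisson" && (is.na(param) || param <= 0))
    stop("parameter must be positive")
  switch(model,
         poisson = 1 - exp(-mu),
         nachman = 1 - exp(-param * mu),
         hanski_gyllenberg = param * mu / (1 + param * mu),
         power = pmin(param * mu, 1),
         negative_binomial = 1 - (1 + mu / param)^(-param))
}

#' Occupancy points from rarefied data
#'
#' Per OTU per month: mu = mean over subsampling events of the mean relative
#' abundance over that month's samples; f = mean over events of the fraction
#' of that month's samples in which the OTU is detected. Since the sample
#' set is identical across events, this equals regrouping the event-averaged
#' relative-abundance and detection matrices. Zero-mu points are dropped
#' (at most one point per OTU per month).
#'
#' @param events `rarefaction_events` from [rarefy]
#' @param meta metadata providing `month_index` per sample
#' @return data.frame of class `occupancy_points`: otu_id, month_index, mu,
#'   f, n_sites
#' @export
occupancy_points <- function(events, meta) {
  avg <- event_averages(events)
  md <- meta[match(rownames(avg$ra), meta$sample_id), ]
  if (any(is.na(md$sample_id))) stop("metadata missing samples")
  small <- table(md$month_index)
  if (any(small < 2))
    warning("months with < 2 samples: ",
            paste(names(small)[small < 2], collapse = ", "))
  points_from_averages(avg$ra, avg$det, md$month_index)
}

# event-averaged relative-abundance and detection matrices (samples x OTUs)
event_averages <- function(events) {
  ra <- 0; det <- 0
  for (ev in events) {
    ra <- ra + rel_abundance(ev$counts)
    det <- det + (ev$counts > 0)
  }
  list(ra = ra / length(events), det = det / length(events))
}

# group rows by month and build the (mu, f) point set
points_from_averages <- function(ra, det, month) {
  tab <- table(month)
  mu <- rowsum(ra, month) / as.vector(tab)
  f <- rowsum(det, month) / as.vector(tab)
  idx <- which(mu > 0, arr.ind = TRUE)
  out <- data.frame(otu_id = colnames(mu)[idx[, 2]],
                    month_index = as.integer(rownames(mu))[idx[, 1]],
                    mu = mu[idx], f = f[idx],
                    n_sites = as.vector(tab)[idx[, 1]])
  out <- out[order(out$otu_id, out$month_index), ]
  rownames(out) <- NULL
  class(out) <- c("occupancy_points", "data.frame")
  out
}

# binomial log-likelihood with fractional successes o = f * n_sites
# (f is averaged over subsampling events, so integer occupancies do not
# exist); P clipped to [eps, 1-eps], clip events counted
ioam_loglik <- function(points, P, eps = 1e-12) {
  o <- points$f * points$n_sites
  clipped <- sum(P < eps | P > 1 - eps)
  P <- pmin(pmax(P, eps), 1 - eps)
  list(logL = sum(o * log(P) + (points$n_sites - o) * log(1 - P)),
       clipped = clipped)
}

#' Fit an occupancy-abundance model by maximum likelihood
#'
#' Maximizes the binomial log-likelihood sum(o log P + (n - o) log(1 - P)),
#' o = f * n_sites, over ln(alpha) (or ln(k)) on \[1e-6, 1e9\] by Brent-style
#' bounded search (`optimize`, tolerance 1e-10 in ln alpha). The Poisson
#' model has no free parameter: its log-likelihood is evaluated directly and
#' its convergence flag is "not_applicable". A fit ending at a search bound
#' is flagged "boundary". Mean absolute deviance mad = mean |f - P|; `sad`
#' is the corresponding sum.
#'
#' @param points an `occupancy_points` data.frame (>= 10 points unless
#'   `allow_few`)
#' @param model model name, see [ioam_models]
#' @param lower,upper parameter search bounds
#' @param allow_few skip the minimum-points check (single-point examples)
#' @return list of class `ioam_fit`: model, alpha (NA for poisson), logL,
#'   mad, sad, convergence, clipped, n_points
#' @export
ioam_fit <- function(points, model, lower = 1e-6, upper = 1e9,
                     allow_few = FALSE) {
  model <- match.arg(model, ioam_models)
  if (!allow_few && nrow(points) < 10) stop("need >= 10 occupancy points")
  if (model == "poisson") {
    ll <- ioam_loglik(points, ioam_predict(model, NA, points$mu))
    P <- ioam_predict(model, NA, points$mu)
    return(structure(list(model = model, alpha = NA_real_, logL = ll$logL,
                          mad = mean(abs(points$f - P)),
                          sad = sum(abs(points$f - P)),
                          convergence = "not_applicable",
                          clipped = ll$clipped, n_points = nrow(points)),
                     class = "ioam_fit"))
  }
  obj <- function(la) ioam_loglik(points, ioam_predict(model, exp(la), points$mu))$logL
  opt <- stats::optimize(obj, c(log(lower), log(upper)), maximum = TRUE,
                         tol = 1e-10)
  a <- exp(opt$maximum)
  conv <- if (opt$maximum < log(lower) + 1e-6 || opt$maximum > log(upper) - 1e-6)
    "boundary" else "converged"
  P <- ioam_predict(model, a, points$mu)
  ll <- ioam_loglik(points, P)
  structure(list(model = model, alpha = a, logL = ll$logL,
                 mad = mean(abs(points$f - pmin(P, 1))),
                 sad = sum(abs(points$f - pmin(P, 1))),
                 convergence = conv, clipped = ll$clipped,
                 n_points = nrow(points)),
            class = "ioam_fit")
}

#' @export
print.ioam_fit <- function(x, ...) {
  cat(sprintf("%s: alpha = %s, logL = %.2f, mad = %.4f (%s)\n", x$model,
              if (is.na(x$alpha)) "-" else signif(x$alpha, 4),
              x$logL, x$mad, x$convergence))
  invisible(x)
}

#' Fit and rank all five occupancy-abundance models
#'
#' @param points an `occupancy_points` data.frame
#' @return data.frame ranked by decreasing log-likelihood: model, alpha,
#'   logL, mad, sad, convergence
#' @export
compare_models <- function(points) {
  fits <- lapply(ioam_models, function(m) ioam_fit(points, m))
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(model = f$model, alpha = f$alpha, logL = f$logL, mad = f$mad,
               sad = f$sad, convergence = f$convergence)))
  df <- df[order(-df$logL), ]
  rownames(df) <- NULL
  df
}

#' Monthly alpha with a month-randomization permutation envelope
#'
#' Fits the Hanski-Gyllenberg model to each month's occupancy points to get
#' the observed monthly alpha, then repeatedly shuffles month labels among
#' samples within each sampling location (location structure preserved),
#' recomputes occupancy points per pseudo-month and refits, returning the
#' observed alpha against the permutation distribution (min / Q1 / Q3 / max,
#' 1,000 reps in the survey design).
#'
#' @param events `rarefaction_events` from [rarefy]
#' @param meta metadata providing `location_id` and `month_index`
#' @param n_reps permutation repetitions
#' @param seed RNG seed
#' @param model model fitted per month (default Hanski-Gyllenberg)
#' @return data.frame: month_index, alpha_obs, perm_min, perm_q1, perm_q3,
#'   perm_max, n_points
#' @export
monthly_alpha_envelope <- function(events, meta, n_reps = 1000, seed = 1L,
                                   model = "hanski_gyllenberg") {
  avg <- event_averages(events)
  md <- meta[match(rownames(avg$ra), meta$sample_id), ]
  if (any(is.na(md$sample_id))) stop("metadata missing samples")
  if (length(unique(md$month_index)) < 2) stop("need >= 2 months")
  fit_by_month <- function(month_labels) {
    pts <- points_from_averages(avg$ra, avg$det, month_labels)
    vapply(sort(unique(month_labels)), function(mo) {
      p <- pts[pts$month_index == mo, ]
      if (nrow(p) == 0) return(NA_real_)
      ioam_fit(p, model, allow_few = TRUE)$alpha
    }, 0)
  }
  months <- sort(unique(md$month_index))
  alpha_obs <- fit_by_month(md$month_index)
  loc_idx <- split(seq_len(nrow(md)), md$location_id)
  perm <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      lab <- md$month_index
      for (i in loc_idx) lab[i] <- lab[i][sample.int(length(i))]
      fit_by_month(lab)
    }, numeric(length(months)))
  })
  perm <- matrix(perm, nrow = length(months))
  qs <- apply(perm, 1, function(v)
    stats::quantile(v, c(0, 0.25, 0.75, 1), na.rm = TRUE, names = FALSE))
  pts_obs <- points_from_averages(avg$ra, avg$det, md$month_index)
  n_pts <- as.vector(table(factor(pts_obs$month_index, levels = months)))
  miss <- months[n_pts == 0]
  if (length(miss)) warning("months with no points: ", paste(miss, collapse = ", "))
  data.frame(month_index = months, alpha_obs = alpha_obs,
             perm_min = qs[1, ], perm_q1 = qs[2, ], perm_q3 = qs[3, ],
             perm_max = qs[4, ], n_points = n_pts)
}

#' Simulate occupancy points directly from an occupancy-abundance law
#'
#' Mean relative abundances are lognormal per OTU with multiplicative
#' month-to-month noise, normalized to proportions within each month (or
#' rescaled to a fixed mean `mu_mean` when `normalize = FALSE`; under
#' normalization the total Fisher information for the law's parameter is
#' bounded because the mu sum to 1, so estimation error does not shrink
#' with OTU count — the unnormalized mode restores that shrinkage);
#' occupancy is binomial: f = Binomial(n_sites, P_model(param, mu)) /
#' n_sites. Unlike points extracted from count tables, simulated points with
#' f = 0 are retained (the generator knows the taxon was present), keeping
#' the maximum-likelihood fit unbiased.
#'
#' @param n_otus,n_months,n_sites design size (survey scale: 4369 OTUs, 15
#'   months, 10 locations)
#' @param model,param the law (default Hanski-Gyllenberg, alpha = 896)
#' @param sdlog lognormal spread of baseline abundances
#' @param month_sdlog multiplicative month-to-month noise
#' @param normalize normalize mu to proportions per month (default); if
#'   FALSE, rescale to mean `mu_mean` regardless of OTU count
#' @param mu_mean mean abundance in the unnormalized mode
#' @param seed RNG seed
#' @return an `occupancy_points` data.frame (mu > 0; f may be 0)
#' @export
simulate_occupancy <- function(n_otus = 4369, n_months = 15, n_sites = 10,
                               model = "hanski_gyllenberg", param = 896,
                               sdlog = 2, month_sdlog = 0.5, normalize = TRUE,
                               mu_mean = 0.002, seed = 1L) {
  with_seed(seed, {
    base <- stats::rlnorm(n_otus, 0, sdlog)
    rows <- lapply(seq_len(n_months) - 1L, function(mo) {
      mu <- base * stats::rlnorm(n_otus, 0, month_sdlog)
      mu <- if (normalize) mu / sum(mu) else pmin(mu * mu_mean / mean(mu), 1)
      P <- ioam_predict(model, param, mu)
      f <- stats::rbinom(n_otus, n_sites, P) / n_sites
      data.frame(otu_id = sprintf("Otu%05d", seq_len(n_otus)),
                 month_index = mo, mu = mu, f = f, n_sites = n_sites)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("occupancy_points", "data.frame")
    out
  })
}
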