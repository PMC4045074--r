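test_that("model forms evaluate to their closed-form values", {
  # mu = 0 -> P = 0 for every model
  for (m in ioam_models)
    expect_equal(ioam_predict(m, 5, 0), 0, label = m)
  # Hanski-Gyllenberg midpoint: alpha * mu = 1 -> P = 1/2
  expect_equal(ioam_predict("hanski_gyllenberg", 896, 1 / 896), 0.5)
  expect_equal(ioam_predict("poisson", NA, 0.5), 1 - exp(-0.5))
  expect_equal(ioam_predict("power", 3, 0.5), 1)  # clipped at 1
  # negative binomial approaches Poisson as k -> infinity
  expect_equal(ioam_predict("negative_binomial", 1e8, 0.5),
               ioam_predict("poisson", NA, 0.5), tolerance = 1e-6)
  expect_error(ioam_predict("nachman", -1, 0.1), "positive")
  # P monotone non-decreasing in mu for every model
  mu <- seq(0, 0.2, length.out = 200)
  for (m in setdiff(ioam_models, "poisson"))
    expect_true(all(diff(ioam_predict(m, 40, mu)) >= -1e-15), label = m)
  # HG and Nachman agree to first order at small alpha*mu
  am <- seq(0.001, 0.1, length.out = 50)
  expect_true(all(abs(ioam_predict("hanski_gyllenberg", 1, am) -
                        ioam_predict("nachman", 1, am)) <= am^2))
})

test_that("occupancy points average correctly over events and months", {
  # OTU at a fixed 25% in every sample: mu = 0.25, f = 1 in every event
  m <- matrix(rep(c(5, 15), each = 4), 4, 2,
              dimnames = list(paste0("s", 1:4), c("A", "B")))
  meta <- sample_metadata(data.frame(
    sample_id = paste0("s", 1:4), location_id = paste0("L", 1:4),
    sector_id = "S1", calendar_month = rep(c("2010-06", "2010-07"), 2)))
  ev <- rarefy(otu_tab(m), rarefaction_plan(depth = 20, n_events = 3))
  pts <- occupancy_points(ev, meta)
  expect_equal(nrow(pts), 4)  # 2 OTUs x 2 months
  expect_true(all(pts$mu[pts$otu_id == "A"] == 0.25))
  expect_true(all(pts$f == 1))
  expect_true(all(pts$n_sites == 2))
  # OTU absent all month -> no point
  m2 <- m; m2[c(1, 3), 1] <- 0  # A absent in month 0 samples s1, s3
  ev2 <- rarefy(otu_tab(m2), rarefaction_plan(depth = 15, n_events = 2))
  pts2 <- occupancy_points(ev2, meta)
  expect_false(any(pts2$otu_id == "A" & pts2$month_index == 0))
})

test_that("occupancy extraction matches exhaustive rarefaction enumeration", {
  # one 3-sample month at tiny depth; compare against the exact
  # hypergeometric expectation of mu and f enumerated per sample
  m <- rbind(s1 = c(2, 8), s2 = c(5, 5), s3 = c(0, 10))
  colnames(m) <- c("A", "B")
  meta <- sample_metadata(data.frame(
    sample_id = rownames(m), location_id = paste0("L", 1:3), sector_id = "S1",
    calendar_month = "2010-06"))
  depth <- 4
  ev <- rarefy(otu_tab(m), rarefaction_plan(depth = depth, n_events = 4000,
                                            base_seed = 12))
  pts <- occupancy_points(ev, meta)
  # E[count of A] = depth * 2/10 etc.; E[mu] = mean over samples of E[c]/depth
  eA <- depth * m[, "A"] / rowSums(m)
  mu_exp <- mean(eA / depth)
  # P(A detected) = 1 - choose(8,4)/choose(10,4) for s1 (hypergeometric zero)
  p_det <- 1 - vapply(seq_len(3), function(i)
    choose(rowSums(m)[i] - m[i, "A"], depth) / choose(rowSums(m)[i], depth), 0)
  f_exp <- mean(p_det)
  a <- pts[pts$otu_id == "A", ]
  expect_equal(a$mu, mu_exp, tolerance = 0.02)
  expect_equal(a$f, f_exp, tolerance = 0.02)
})

test_that("maximum-likelihood fit recovers parameters and flags boundaries", {
  # single point mu with f = P_HG(alpha0, mu) -> alpha recovered exactly
  pt <- data.frame(otu_id = "x", month_index = 0, mu = 0.002,
                   f = ioam_predict("hanski_gyllenberg", 50, 0.002),
                   n_sites = 10)
  fit1 <- ioam_fit(pt, "hanski_gyllenberg", allow_few = TRUE)
  expect_equal(fit1$alpha, 50, tolerance = 1e-4)
  # parameter recovery on binomial-occupancy data at alpha = 50
  pts <- simulate_occupancy(n_otus = 500, n_months = 1, n_sites = 10,
                            param = 50, seed = 5)
  fit <- ioam_fit(pts, "hanski_gyllenberg")
  expect_true(fit$alpha >= 40 && fit$alpha <= 62)
  # recovery sharpens with more OTUs at a fixed abundance scale (mean
  # absolute error over seeds; with proportion-normalized mu the Fisher
  # information is bounded, so the fixed-scale mode is used here)
  err_at <- function(n) mean(vapply(5:7, function(s)
    abs(ioam_fit(simulate_occupancy(n_otus = n, n_months = 1, n_sites = 10,
                                    param = 50, normalize = FALSE, seed = s),
                 "hanski_gyllenberg")$alpha - 50), 0))
  expect_lt(err_at(8000), err_at(500))
  expect_equal(fit$convergence, "converged")
  # the fitted parameter is a local optimum on a grid
  grid <- exp(seq(log(fit$alpha) - 2, log(fit$alpha) + 2, length.out = 41))
  ll <- vapply(grid, function(a) aquadyn:::ioam_loglik(
    pts, ioam_predict("hanski_gyllenberg", a, pts$mu))$logL, 0)
  expect_gte(fit$logL, max(ll) - 1e-6)
  # Poisson has no parameter; impossible data drive others to a bound
  fp <- ioam_fit(pts, "poisson")
  expect_equal(fp$convergence, "not_applicable")
  expect_true(is.na(fp$alpha))
  flat <- data.frame(otu_id = paste0("o", 1:20), month_index = 0,
                     mu = rep(1e-6, 20), f = 1, n_sites = 10)
  expect_equal(ioam_fit(flat, "hanski_gyllenberg")$convergence, "boundary")
  expect_error(ioam_fit(pt, "hanski_gyllenberg"), ">= 10")
})

test_that("model comparison ranks the generating law first", {
  pts <- simulate_occupancy(n_otus = 2000, n_months = 5, n_sites = 10,
                            param = 300, seed = 9)
  cmp <- compare_models(pts)
  expect_equal(cmp$model[1], "hanski_gyllenberg")
  expect_equal(cmp$model[2], "nachman")   # its close cousin ranks second
  expect_gt(min(cmp$logL[1:2]), max(cmp$logL[3:5]))
  expect_true(all(diff(cmp$logL) <= 0))
  expect_equal(cmp$mad, cmp$sad / nrow(pts))
  # duplicated points leave the ranking invariant
  cmp2 <- compare_models(rbind(pts, pts))
  expect_equal(cmp2$model, cmp$model)
})

test_that("identity permutation reproduces observed monthly alpha exactly", {
  g <- generate(synthetic_spec(n_otus = 150, seed = 3))
  ev <- rarefy(g$table, rarefaction_plan(depth = 834, n_events = 4,
                                         base_seed = 2))
  avg <- aquadyn:::event_averages(ev)
  md <- g$meta[match(rownames(avg$ra), g$meta$sample_id), ]
  pts <- aquadyn:::points_from_averages(avg$ra, avg$det, md$month_index)
  env <- monthly_alpha_envelope(ev, g$meta, n_reps = 5, seed = 1)
  for (mo in c(0, 7, 14)) {
    direct <- ioam_fit(pts[pts$month_index == mo, ], "hanski_gyllenberg",
                       allow_few = TRUE)$alpha
    expect_equal(env$alpha_obs[env$month_index == mo], direct)
  }
  expect_equal(nrow(env), 15)
  expect_true(all(env$perm_min <= env$perm_q1 & env$perm_q1 <= env$perm_q3 &
                    env$perm_q3 <= env$perm_max))
})
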