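test_that("rarefaction preserves depth, bounds and reproducibility", {
  fx <- worked_fixture()
  plan <- rarefaction_plan(depth = 10, n_events = 3, base_seed = 7)
  ev <- rarefy(fx$table, plan)
  for (e in ev) {
    expect_true(all(rowSums(e$counts) == 10))
    expect_true(all(e$counts <= fx$table$counts))
  }
  # bit-for-bit reproducible per (base_seed, event)
  ev2 <- rarefy(fx$table, plan)
  expect_identical(ev[[2]]$counts, ev2[[2]]$counts)
  # depth equal to total is the identity
  ev20 <- rarefy(fx$table, rarefaction_plan(depth = 20, n_events = 1))
  expect_identical(ev20[[1]]$counts, fx$table$counts)
})

test_that("samples shallower than the depth are dropped and reported", {
  m <- rbind(deep = c(500, 500), shallow = c(5, 5))
  colnames(m) <- c("O1", "O2")
  ev <- rarefy(otu_tab(m), rarefaction_plan(depth = 100, n_events = 1))
  expect_equal(attr(ev, "report")$dropped_samples, "shallow")
  expect_equal(sample_ids(ev[[1]]), "deep")
  expect_error(rarefy(otu_tab(m), rarefaction_plan(depth = 1e6, n_events = 1)),
               "no sample")
})

test_that("rarefied counts match the hypergeometric expectation", {
  # OTU with 200 of 1000 reads at depth 100: E[count] = 100 * 200/1000 = 20
  m <- matrix(c(200, 800), 1, 2, dimnames = list("s", c("A", "B")))
  ev <- rarefy(otu_tab(m), rarefaction_plan(depth = 100, n_events = 1000,
                                            base_seed = 3))
  draws <- vapply(ev, function(e) e$counts[1, "A"], 0)
  # hypergeometric mean 20, sd of the mean over 1000 events ~ 0.12
  expect_equal(mean(draws), 20, tolerance = 0.025)
  expect_equal(stats::var(draws),
               100 * 0.2 * 0.8 * (1000 - 100) / (1000 - 1), tolerance = 0.1)
})

test_that("alpha metrics match direct evaluation", {
  fx <- worked_fixture()
  a <- alpha_metrics(fx$table)
  expect_equal(stats::setNames(a$richness, a$sample_id), fx$expected$richness)
  expect_equal(a$shannon[a$sample_id == "s1"], fx$expected$shannon_s1)
  # two OTUs at 50/50: H = ln 2, evenness 1
  a2 <- alpha_metrics(otu_tab(matrix(c(5, 5), 1, 2,
                                     dimnames = list("s", c("A", "B")))))
  expect_equal(a2$shannon, log(2))
  expect_equal(a2$evenness, 1)
  # single OTU: richness 1, H = 0, evenness defined as 0
  a1 <- alpha_metrics(otu_tab(matrix(9, 1, 1, dimnames = list("s", "A"))))
  expect_equal(unlist(a1[, c("richness", "shannon", "evenness")]),
               c(richness = 1, shannon = 0, evenness = 0))
  # Chao-Shen against direct formula evaluation for counts (5,3,2)
  x <- c(5, 3, 2); n <- 10; p <- x / n
  C <- 1 - sum(x == 1) / n
  pa <- C * p
  np_direct <- -sum(pa * log(pa) / (1 - (1 - pa)^n))
  a3 <- alpha_metrics(otu_tab(matrix(x, 1, 3,
                                     dimnames = list("s", c("A", "B", "C")))))
  expect_equal(a3$np_shannon, np_direct)
  expect_error(alpha_metrics(matrix(0, 1, 2, dimnames = list("s", c("A", "B")))),
               "all-zero")
})

test_that("beta metrics match hand-derived fixture values and invariants", {
  fx <- worked_fixture()
  bc <- beta_matrix(fx$table, "bray_curtis")
  jc <- beta_matrix(fx$table, "jaccard")
  expect_equal(bc["s1", "s2"], fx$expected$bray_s1_s2)
  expect_equal(bc["s5", "s7"], fx$expected$bray_s5_s7)
  expect_equal(jc["s1", "s3"], fx$expected$jaccard_s1_s3)
  expect_equal(jc["s1", "s2"], 0)  # identical membership
  for (dm in list(bc, jc)) {
    expect_true(all(dm >= 0 & dm <= 1))
    expect_equal(dm, t(dm))
    expect_true(all(diag(dm) == 0))
  }
})

test_that("UniFrac equals hand-summed branch fractions and phyloseq agrees", {
  fx <- worked_fixture()
  uw <- beta_matrix(fx$table, "unweighted_unifrac", tree = fx$tree)
  wu <- beta_matrix(fx$table, "weighted_unifrac", tree = fx$tree)
  expect_equal(uw["s1", "s3"], fx$expected$unweighted_unifrac_s1_s3)
  expect_equal(uw["s5", "s7"], fx$expected$unweighted_unifrac_s5_s7)
  expect_equal(wu["s5", "s7"], 1)  # disjoint communities
  expect_equal(wu["s1", "s1"], 0)
  # weighted UniFrac on a 3-leaf star with unit branches halves the L1
  # distance of leaf proportions (normalizing mass is 2 per unit branch)
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  m <- rbind(x = c(6, 3, 1), y = c(2, 3, 5))
  colnames(m) <- c("A", "B", "C")
  wu3 <- beta_matrix(otu_tab(m), "weighted_unifrac", tree = star)
  expect_equal(wu3["x", "y"], sum(abs(m[1, ] / 10 - m[2, ] / 10)) / 2)
  # independent cross-check against phyloseq on the fixture
  skip_if_not_installed("phyloseq")
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(fx$table$counts, taxa_are_rows = FALSE),
    phyloseq::phy_tree(fx$tree))
  expect_equal(max(abs(uw - as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))[
    rownames(uw), colnames(uw)])), 0, tolerance = 1e-12)
  expect_equal(max(abs(wu - as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                                        normalized = TRUE))[
    rownames(wu), colnames(wu)])), 0, tolerance = 1e-12)
})

test_that("UniFrac names missing OTUs", {
  fx <- worked_fixture()
  small_tree <- ape::drop.tip(fx$tree, "O6")
  expect_error(beta_matrix(fx$table, "unweighted_unifrac", tree = small_tree),
               "O6")
})

test_that("average_distance is the element-wise mean and checks labels", {
  d1 <- dm_from_points(matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE))
  d2 <- d1; d2[1, 2] <- d2[2, 1] <- 0.4
  avg <- average_distance(list(d1, d2))
  expect_equal(avg[1, 2], (1 + 0.4) / 2)
  expect_equal(average_distance(list(d1, d1)), aquadyn:::validate_dm(d1),
               ignore_attr = TRUE)
  d3 <- d1; rownames(d3) <- colnames(d3) <- c("x", "y")
  expect_error(average_distance(list(d1, d3)), "mismatch")
})

test_that("PCoA recovers Euclidean configurations and reports negative eigenvalues", {
  # two points at distance d -> 1D coordinates +/- d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  p2 <- pcoa(d2)
  expect_equal(sort(unname(p2$coordinates[, 1])), c(-1.5, 1.5))
  # four planar points: inter-point distances reconstructed exactly
  set.seed(1)
  pts <- matrix(rnorm(8), 4, 2)
  dm <- dm_from_points(pts)
  fit <- pcoa(dm)
  rec <- as.matrix(stats::dist(fit$coordinates[, 1:2]))
  expect_equal(unname(rec), unname(dm), tolerance = 1e-9)
  expect_length(fit$eigenvalues, 4)
  # identical points -> all-zero coordinates
  d0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(abs(pcoa(d0)$coordinates) < 1e-12))
  # a non-Euclidean matrix surfaces as a negative eigenvalue, not an error
  dn <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dn[1, 2] <- dn[2, 1] <- dn[3, 4] <- dn[4, 3] <- 2
  diag(dn) <- 0
  expect_true(min(pcoa(dn)$eigenvalues) < -1e-8)
})
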