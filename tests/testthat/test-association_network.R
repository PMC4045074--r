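test_that("MIC is 1 for noiseless functional relations and small for noise", {
  x <- as.numeric(1:20)
  expect_equal(mic(x, x, n_perm = 0)$mic, 1)
  expect_equal(mic(x, exp(x), n_perm = 0)$mic, 1)       # monotone transform
  expect_equal(mic(x, -2 * x, n_perm = 0)$slope_sign, -1L)
  set.seed(8)
  ps <- replicate(20, mic(rnorm(30), rnorm(30), n_perm = 99, seed = 1)$p_value)
  expect_gt(mean(ps), 0.2)                              # null p large on average
  ms <- replicate(20, mic(rnorm(60), rnorm(60), n_perm = 0)$mic)
  expect_lt(mean(ms), 0.45)
  expect_error(mic(rep(1, 10), rnorm(10)), "constant")
  expect_error(mic(rnorm(5), rnorm(5)), "8 points")
})

test_that("small-n MIC equals the exhaustive grid-partition oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(8:10, 1)
    x <- if (i %% 3 == 0) as.numeric(rpois(n, 2)) else rnorm(n)
    y <- if (i %% 4 == 0) as.numeric(rpois(n, 2)) else rnorm(n)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    expo <- sample(c(0.6, 1), 1)
    expect_equal(mic(x, y, grid_exponent = expo, n_perm = 0)$mic,
                 oracle_mic(x, y, alpha = expo), tolerance = 1e-12,
                 label = sprintf("case %d (n=%d, exp=%.1f)", i, n, expo))
  }
  # the large-n search heuristic can never exceed the true maximum
  set.seed(32)
  for (i in 1:25) {
    x <- rnorm(10); y <- rnorm(10)
    expect_lte(aquadyn:::mic_cpp(x, y, 1.0), oracle_mic(x, y, 1) + 1e-9)
  }
})

test_that("robust association protocol recovers planted seasonal clusters", {
  g <- generate(synthetic_spec(n_otus = 400, seed = 11))
  ev <- rarefy(g$table, rarefaction_plan(depth = 500, n_events = 24,
                                         base_seed = 7))
  # scaled down from the survey's 100 events / 1,000 null draws for test
  # runtime; discovery floor kept proportional (10/100 -> 3/24)
  net <- robust_associations(ev, min_discoveries = 3, n_null = 300, seed = 9)
  expect_gt(nrow(net$edges), 20)
  truth <- g$truth$cluster_members
  in1 <- net$edges$otu_a %in% truth$cluster1
  in2 <- net$edges$otu_a %in% truth$cluster2
  jn1 <- net$edges$otu_b %in% truth$cluster1
  jn2 <- net$edges$otu_b %in% truth$cluster2
  within <- (in1 & jn1) | (in2 & jn2)
  cross <- (in1 & jn2) | (in2 & jn1)
  expect_true(all(net$edges$sign[within] > 0))
  expect_true(all(net$edges$sign[cross] < 0))
  expect_true(all(within | cross))   # nothing outside the planted structure
  # order invariance: permuting OTU columns and event order changes nothing
  perm_cols <- function(e) {
    set.seed(1); p <- sample(ncol(e$counts))
    otu_tab(e$counts[, p])
  }
  ev_perm <- structure(lapply(rev(ev), perm_cols), class = "rarefaction_events")
  net2 <- robust_associations(ev_perm, min_discoveries = 3, n_null = 300,
                              seed = 9)
  key <- function(n) {
    e <- n$edges
    ab <- ifelse(e$otu_a < e$otu_b, paste(e$otu_a, e$otu_b),
                 paste(e$otu_b, e$otu_a))
    o <- order(ab)
    data.frame(ab = ab[o], mic = e$mic[o], sign = e$sign[o],
               disc = e$discoveries[o])
  }
  expect_equal(key(net), key(net2))
})

test_that("i.i.d. null tables produce (almost) no edges", {
  set.seed(77)
  n_s <- 60; n_o <- 30
  m <- matrix(rpois(n_s * n_o, 30), n_s, n_o,
              dimnames = list(paste0("s", 1:n_s), paste0("O", 1:n_o)))
  ev <- rarefy(otu_tab(m), rarefaction_plan(depth = 500, n_events = 10,
                                            base_seed = 2))
  net <- robust_associations(ev, min_discoveries = 2, n_null = 300, seed = 3,
                             cooccur_floor = 10)
  expect_lte(nrow(net$edges), 1)
})

test_that("cluster extraction handles cliques, bridges and isolates", {
  mknet <- function(edges, nodes) {
    structure(list(nodes = data.frame(otu_id = nodes,
                                      mean_rel_abundance = 0,
                                      detection_frequency = 1),
                   edges = edges, n_otus_tested = length(nodes),
                   params = list()), class = "assoc_network")
  }
  clique <- function(v, sgn) {
    p <- t(utils::combn(v, 2))
    data.frame(otu_a = p[, 1], otu_b = p[, 2], mic = 0.8, sign = sgn,
               discoveries = 10L)
  }
  # two positive cliques joined only by negative edges -> 2 clean clusters
  ed <- rbind(clique(c("a1", "a2", "a3"), 1L), clique(c("b1", "b2", "b3"), 1L),
              data.frame(otu_a = "a1", otu_b = "b1", mic = 0.6, sign = -1L,
                         discoveries = 10L))
  asg <- extract_clusters(mknet(ed, c(paste0("a", 1:3), paste0("b", 1:3), "iso")))
  expect_length(asg$clusters, 2)
  expect_equal(sort(unname(asg$assignment[c("a1", "a2", "a3")])), rep("1", 3))
  expect_equal(unname(asg$assignment["iso"]), "isolated")
  expect_equal(nrow(asg$validation$within_cluster_negative), 0)
  # a node with positive edges into both cliques becomes unassigned
  ed2 <- rbind(ed, data.frame(otu_a = c("bridge", "bridge"),
                              otu_b = c("a1", "b1"), mic = 0.7, sign = 1L,
                              discoveries = 10L))
  asg2 <- extract_clusters(mknet(ed2, c(paste0("a", 1:3), paste0("b", 1:3),
                                        "bridge")))
  expect_equal(unname(asg2$assignment["bridge"]), "unassigned")
  expect_length(asg2$clusters, 2)
  # only-negative node is unassigned; within-cluster negatives are reported
  ed3 <- rbind(clique(c("a1", "a2", "a3"), 1L),
               data.frame(otu_a = c("neg", "a1"), otu_b = c("a1", "a2"),
                          mic = 0.5, sign = -1L, discoveries = 10L))
  asg3 <- extract_clusters(mknet(ed3, c("a1", "a2", "a3", "neg")))
  expect_equal(unname(asg3$assignment["neg"]), "unassigned")
  expect_equal(nrow(asg3$validation$within_cluster_negative), 1)
})

test_that("network statistics match hand counts", {
  tri <- data.frame(otu_a = c("a", "b", "c"), otu_b = c("b", "c", "a"),
                    mic = 0.5, sign = 1L, discoveries = 10L)
  net <- structure(list(nodes = data.frame(otu_id = c("a", "b", "c"),
                                           mean_rel_abundance = 0,
                                           detection_frequency = 1),
                        edges = tri, n_otus_tested = 3, params = list()),
                   class = "assoc_network")
  st <- network_stats(net)
  expect_equal(st$density, 1)
  expect_equal(st$clustering_coefficient, 1)
  star <- data.frame(otu_a = "hub", otu_b = c("x", "y", "z"), mic = 0.5,
                     sign = 1L, discoveries = 10L)
  net$edges <- star
  expect_equal(network_stats(net)$clustering_coefficient, 0)
  # 5-node graph: hand-counted local triangle densities
  # edges: ab, ac, bc, cd, de -> local cc: a=1, b=1, c=1/3, d=0, e=0
  g5 <- data.frame(otu_a = c("a", "a", "b", "c", "d"),
                   otu_b = c("b", "c", "c", "d", "e"),
                   mic = 0.5, sign = 1L, discoveries = 10L)
  net$edges <- g5
  st5 <- network_stats(net)
  expect_equal(st5$clustering_coefficient, mean(c(1, 1, 1 / 3, 0, 0)))
  expect_equal(st5$density, 5 / choose(5, 2))
  expect_warning(st0 <- network_stats(structure(list(
    nodes = net$nodes[0, ], edges = tri[0, ], n_otus_tested = 0,
    params = list()), class = "assoc_network")), "empty")
  expect_equal(st0$density, 0)
})

test_that("cluster time series sum to the subset total and track seasons", {
  g <- generate(synthetic_spec(n_otus = 200, seed = 23))
  truth <- g$truth$cluster_members
  asg <- structure(list(
    assignment = c(stats::setNames(rep("1", length(truth$cluster1)),
                                   truth$cluster1),
                   stats::setNames(rep("2", length(truth$cluster2)),
                                   truth$cluster2)),
    clusters = truth, validation = list()), class = "cluster_assignment")
  ts <- cluster_timeseries(g$table, asg, g$meta)
  # winter cluster dominates mid-campaign, summer cluster at the ends
  w <- ts$abundance[ts$group == "1"]
  s <- ts$abundance[ts$group == "2"]
  expect_gt(w[7], s[7])    # December 2010
  expect_gt(s[2], w[2])    # July 2010
  expect_gt(s[14], w[14])  # July 2011 (annual reproducibility)
  # the two series cross twice over the cycle
  expect_gte(sum(diff(sign(w - s)) != 0), 2)
  # per-month group sums equal the subset's total relative abundance
  ra <- rel_abundance(g$table)
  ids <- intersect(names(asg$assignment), colnames(ra))
  mo0 <- g$meta$month_index[match(rownames(ra), g$meta$sample_id)]
  tot0 <- mean(rowSums(ra[mo0 == 0, ids]))
  expect_equal(sum(ts$abundance[ts$month_index == 0]), tot0)
})

test_that("cluster UniFrac test separates planted subtrees", {
  g <- generate(synthetic_spec(n_otus = 150, seed = 29))
  truth <- g$truth$cluster_members
  asg <- structure(list(
    assignment = c(stats::setNames(rep("1", length(truth$cluster1)),
                                   truth$cluster1),
                   stats::setNames(rep("2", length(truth$cluster2)),
                                   truth$cluster2))), class = "cluster_assignment")
  res <- cluster_unifrac_test(asg, g$tree, n_perm = 99, seed = 3)
  expect_gt(res$score, 0.8)   # disjoint subtrees under the root
  expect_lte(res$p_value, 0.05)
  # identical leaf sets give score 0
  asg0 <- structure(list(assignment = c(A = "1", B = "2")),
                    class = "cluster_assignment")
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_error(cluster_unifrac_test(
    structure(list(assignment = c(A = "1", A = "2")),
              class = "cluster_assignment"), tr), "overlap|empty")
  # exhaustive label permutation on a small tree matches direct enumeration
  tr10 <- ape::rtree(10, tip.label = paste0("t", 1:10))
  asg10 <- structure(list(
    assignment = c(stats::setNames(rep("1", 4), paste0("t", 1:4)),
                   stats::setNames(rep("2", 6), paste0("t", 5:10)))),
    class = "cluster_assignment")
  ex <- cluster_unifrac_test(asg10, tr10, exhaustive = TRUE)
  expect_equal(ex$n_permutations, choose(10, 4))
  uf_direct <- function(set1) {
    pool <- paste0("t", 1:10)
    m <- matrix(0, 2, 10, dimnames = list(c("x", "y"), pool))
    m[1, set1] <- 1; m[2, setdiff(pool, set1)] <- 1
    beta_matrix(otu_tab(m), "unweighted_unifrac", tree = tr10)[1, 2]
  }
  null <- vapply(utils::combn(paste0("t", 1:10), 4, simplify = FALSE),
                 uf_direct, 0)
  expect_equal(ex$p_value, mean(null >= ex$score - 1e-12))
})
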