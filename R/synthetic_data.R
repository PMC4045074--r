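#' Specification for the synthetic survey generator
#'
#' Defaults emulate the processed survey: ~4,369 OTUs over 15 monthly time
#' points at the treatment plant plus nine distribution-system locations in
#' three sectors; lognormal baseline abundances; two anti-phase seasonal OTU
#' clusters with a 12-month period (one peaking in winter, one in summer);
#' per-sample sequencing depths lognormal around ~3,000 reads (minimum
#' retained depth 834 in the survey); an occupancy-abundance law
#' (Hanski-Gyllenberg, alpha = 896) imposed by presence thinning; a
#' multiplicative spatial perturbation growing with pipe distance from the
#' plant; and location-specific OTU pools.
#'
#' @param n_otus number of OTUs
#' @param n_months number of monthly time points
#' @param campaign_start ISO "YYYY-MM" of month index 0
#' @param abund_sdlog lognormal sd of baseline abundances
#' @param cluster_sizes sizes of the two seasonal clusters
#' @param cluster_amplitude log-scale sinusoid amplitude
#' @param cluster_phase phase (months) per cluster; defaults put the peaks in
#'   mid-winter and mid-summer (anti-phase, 12-month period)
#' @param occupancy_model,occupancy_alpha the planted occupancy law
#' @param decay_rate multiplicative log-sd of the spatial perturbation per
#'   meter of pipe distance from the plant
#' @param unique_frac fraction of the OTU pool reserved as location-specific,
#'   split evenly over the nine distribution-system locations
#' @param depth_meanlog,depth_sdlog,depth_min per-sample read depth model
#' @param law_depth sequencing depth at which the occupancy law should hold
#'   after rarefaction (the survey analyzes at depth 834); presence thinning
#'   compensates detection loss at this depth
#' @param n_pipe_sections,total_pipe_length_m pipe inventory size (survey:
#'   881 sections, ~46 km)
#' @param seed master seed; the same spec and seed give byte-identical output
#' @return list of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_otus = 4369, n_months = 15,
                           campaign_start = "2010-06",
                           abund_sdlog = 2,
                           cluster_sizes = c(25, 30),
                           cluster_amplitude = 1.5,
                           cluster_phase = c(3.5, 9.5),
                           occupancy_model = "hanski_gyllenberg",
                           occupancy_alpha = 896,
                           decay_rate = 3e-5,
                           unique_frac = 0.25,
                           depth_meanlog = log(2200), depth_sdlog = 0.7,
                           depth_min = 500, law_depth = 834,
                           n_pipe_sections = 881,
                           total_pipe_length_m = 46000,
                           seed = 1L) {
  spec <- as.list(environment())
  if (sum(cluster_sizes) > n_otus) stop("clusters larger than the OTU pool")
  if (unique_frac < 0 || unique_frac >= 1) stop("unique_frac must be in [0,1)")
  structure(spec, class = "synthetic_spec")
}

# locations: plant + 3 sectors x 3; sector 1 is a linear chain, sectors 2/3
# branch (two and three branches), mirroring the surveyed layout
dwds_locations <- function() {
  data.frame(
    location_id = c("DWTP", "S1.1", "S1.2", "S1.3", "S2.1", "S2.2", "S2.3",
                    "S3.1", "S3.2", "S3.3"),
    sector_id = c("DWTP", rep("S1", 3), rep("S2", 3), rep("S3", 3)))
}

# logical pipe links (junction J3 gives sector 3 its three branches)
dwds_links <- function() {
  data.frame(
    from = c("DWTP", "S1.1", "S1.2", "DWTP", "S2.1", "S2.1", "DWTP", "J3",
             "J3", "J3"),
    to = c("S1.1", "S1.2", "S1.3", "S2.1", "S2.2", "S2.3", "J3", "S3.1",
           "S3.2", "S3.3"))
}

# subdivide logical links into n_sections pipe sections; returns inventory +
# per-location shortest-path bookkeeping
generate_pipes <- function(spec) {
  links <- dwds_links()
  nl <- nrow(links)
  share <- stats::rgamma(nl, 4, 1)
  link_len <- spec$total_pipe_length_m * share / sum(share)
  n_sec <- pmax(1, round(spec$n_pipe_sections * link_len /
                           sum(link_len)))
  # force the exact section count
  while (sum(n_sec) != spec$n_pipe_sections) {
    d <- spec$n_pipe_sections - sum(n_sec)
    i <- which.max(link_len / n_sec)
    n_sec[i] <- max(1, n_sec[i] + sign(d))
  }
  rows <- list()
  sid <- 0
  for (l in seq_len(nl)) {
    k <- n_sec[l]
    w <- stats::rgamma(k, 5, 1)
    lens <- link_len[l] * w / sum(w)
    nodes <- c(links$from[l],
               if (k > 1) sprintf("%s-%s.j%d", links$from[l], links$to[l],
                                  seq_len(k - 1)),
               links$to[l])
    rows[[l]] <- data.frame(
      section_id = sprintf("sec%04d", sid + seq_len(k)),
      node_a = nodes[-length(nodes)], node_b = nodes[-1],
      length_m = lens,
      diameter_m = stats::rlnorm(k, log(0.2), 0.4),
      install_year = sample(1920:2010, k, replace = TRUE),
      material = sample(c("cast_iron", "ductile_iron", "PVC", "concrete",
                          "steel"), k, replace = TRUE))
    sid <- sid + k
  }
  inv <- pipe_inventory(do.call(rbind, rows))
  # distance from plant along the (unique) path of this tree-shaped layout
  g <- igraph::graph_from_data_frame(inv[, c("node_a", "node_b")],
                                     directed = FALSE)
  locs <- dwds_locations()$location_id
  d <- igraph::distances(g, v = "DWTP", to = locs,
                         weights = inv$length_m)[1, ]
  list(inventory = inv,
       location_distance = stats::setNames(as.numeric(d), locs),
       totals = list(n_sections = nrow(inv),
                     total_length = sum(inv$length_m),
                     total_surface = sum(pi * inv$diameter_m * inv$length_m)))
}

# three-clade coalescent-style tree: the two seasonal clusters sit on their
# own subtrees (UniFrac-distinct by construction), everything else on a third
generate_tree <- function(otu_ids, members1, members2) {
  clade <- function(tips) {
    if (length(tips) == 1) return(paste0(tips, ":1"))
    tr <- ape::rcoal(length(tips), tip.label = tips)
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
    sub(";$", "", ape::write.tree(tr))
  }
  rest <- setdiff(otu_ids, c(members1, members2))
  txt <- sprintf("((%s:0.5,%s:0.5):0.5,%s:1);",
                 clade(members1), clade(members2), clade(rest))
  ape::read.tree(text = txt)
}

#' Generate a synthetic survey data set
#'
#' Builds the OTU count table, sample metadata, phylogeny and pipe inventory
#' with full ground-truth bookkeeping. Per-OTU baselines are lognormal; the
#' two seasonal clusters are modulated by anti-phase 12-month sinusoids;
#' expected abundances get a multiplicative lognormal perturbation whose
#' log-sd grows with pipe distance from the plant; location-specific OTUs
#' are zeroed everywhere else; presence is thinned so month-level detection
#' frequency follows the planted occupancy law (see Details); counts are
#' multinomial at the sample's depth.
#'
#' Thinning scheme: with P the law's target occupancy at the month's mean
#' abundance mu and d the analysis depth (`law_depth`), a present sample
#' carries conditional abundance ~ mu / p_pres, so detection-given-presence
#' is about 1 - exp(-d mu / p_pres); the presence probability solves
#' p_pres (1 - exp(-d mu / p_pres)) = P by fixed-point iteration (capped at
#' 1), so that realized detection = presence x detection-given-presence
#' targets the law after multinomial sequencing loss.
#'
#' @param spec a [synthetic_spec]
#' @return list: `table` ([otu_tab]), `meta`, `tree`, `pipes`
#'   (`pipe_inventory`), `truth` (cluster memberships, law, decay rate,
#'   unique-OTU lists, location distances, pipe totals, depths)
#' @export
generate <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    K <- spec$n_otus
    otus <- sprintf("Otu%05d", seq_len(K))
    base <- stats::rlnorm(K, 0, spec$abund_sdlog)
    names(base) <- otus
    ord <- order(-base)
    n_cl <- spec$cluster_sizes
    top <- ord[seq_len(sum(n_cl))]
    # interleave membership so both clusters span the abundance range
    odd <- seq(1, sum(n_cl), by = 2)
    pos1 <- odd[seq_len(min(length(odd), n_cl[1]))]
    if (length(pos1) < n_cl[1])
      pos1 <- c(pos1, setdiff(seq_len(sum(n_cl)), pos1)[seq_len(n_cl[1] - length(pos1))])
    members1 <- otus[top[pos1]]
    members2 <- otus[top[-pos1]]
    locs <- dwds_locations()
    dwds <- locs$location_id[locs$sector_id != "DWTP"]
    # location-specific pools drawn from the most abundant non-cluster OTUs
    # (biofilm-seeded taxa must be detectable to contribute membership)
    pool <- otus[ord[(sum(n_cl) + 1):K]]
    n_unique <- floor(spec$unique_frac * K / length(dwds))
    if (n_unique * length(dwds) > length(pool))
      stop("unique_frac too large for the OTU pool")
    unique_lists <- list()
    for (i in seq_along(dwds)) {
      unique_lists[[dwds[i]]] <- pool[((i - 1) * n_unique + 1):(i * n_unique)]
    }
    pipes <- generate_pipes(spec)
    y0 <- as.integer(substr(spec$campaign_start, 1, 4))
    m0 <- as.integer(substr(spec$campaign_start, 6, 7))
    cal <- sprintf("%04d-%02d", y0 + (m0 - 1 + 0:(spec$n_months - 1)) %/% 12,
                   (m0 - 1 + 0:(spec$n_months - 1)) %% 12 + 1)
    seas_mult <- function(mi) {
      mult <- rep(1, K)
      names(mult) <- otus
      mult[members1] <- exp(spec$cluster_amplitude *
                              sin(2 * pi * (mi - spec$cluster_phase[1]) / 12))
      mult[members2] <- exp(spec$cluster_amplitude *
                              sin(2 * pi * (mi - spec$cluster_phase[2]) / 12))
      mult
    }
    n_samp <- spec$n_months * nrow(locs)
    counts <- matrix(0, n_samp, K)
    meta_rows <- list()
    depths <- numeric(n_samp)
    r <- 0
    for (mi in 0:(spec$n_months - 1)) {
      sm <- seas_mult(mi)
      # expected relative abundance per location (before thinning)
      exp_loc <- matrix(0, nrow(locs), K, dimnames = list(locs$location_id, otus))
      for (li in seq_len(nrow(locs))) {
        L <- locs$location_id[li]
        e <- base * sm
        dist_L <- pipes$location_distance[[L]]
        if (dist_L > 0)
          e <- e * stats::rlnorm(K, 0, spec$decay_rate * dist_L)
        for (Lu in names(unique_lists))
          if (Lu != L) e[unique_lists[[Lu]]] <- 0
        exp_loc[li, ] <- e / sum(e)
      }
      # occupancy thinning toward the planted law at month level: solve
      # p_pres * (1 - exp(-law_depth * mu / p_pres)) = P by fixed point,
      # i.e. presence inflated to offset multinomial detection loss at the
      # depth the table will be analyzed at
      mu_m <- colMeans(exp_loc)
      P <- ioam_predict(spec$occupancy_model, spec$occupancy_alpha, mu_m)
      p_pres <- pmin(P, 1)
      for (it in 1:20) {
        dgp <- 1 - exp(-spec$law_depth * mu_m / pmax(p_pres, 1e-12))
        p_pres <- pmin(1, P / pmax(dgp, 1e-12))
      }
      p_pres[mu_m <= 0] <- 0
      for (li in seq_len(nrow(locs))) {
        r <- r + 1
        pres <- stats::runif(K) < p_pres
        e <- exp_loc[li, ] * pres
        if (sum(e) == 0) e[which.max(exp_loc[li, ])] <- 1
        depth <- max(spec$depth_min,
                     round(stats::rlnorm(1, spec$depth_meanlog, spec$depth_sdlog)))
        counts[r, ] <- stats::rmultinom(1, depth, e / sum(e))
        depths[r] <- depth
        meta_rows[[r]] <- data.frame(
          sample_id = paste0(locs$location_id[li], "_", cal[mi + 1]),
          location_id = locs$location_id[li],
          sector_id = locs$sector_id[li],
          calendar_month = cal[mi + 1])
      }
    }
    meta <- sample_metadata(do.call(rbind, meta_rows),
                            campaign_start = spec$campaign_start)
    rownames(counts) <- meta$sample_id
    colnames(counts) <- otus
    detected <- colSums(counts) > 0
    tab <- otu_tab(counts[, detected, drop = FALSE])
    tree <- generate_tree(otus, members1, members2)
    list(table = tab, meta = meta, tree = tree, pipes = pipes$inventory,
         truth = list(cluster_members = list(cluster1 = members1,
                                             cluster2 = members2),
                      occupancy_model = spec$occupancy_model,
                      occupancy_alpha = spec$occupancy_alpha,
                      decay_rate = spec$decay_rate,
                      unique_otus = unique_lists,
                      location_distance = pipes$location_distance,
                      pipe_totals = pipes$totals,
                      depths = stats::setNames(depths, meta$sample_id),
                      spec = spec))
  })
}

#' Miniature worked fixture with hand-computed expectations
#'
#' A deterministic 6-OTU x 8-sample x 2-month data set whose Bray-Curtis,
#' Jaccard, UniFrac, richness, Shannon and MIC values are small enough to
#' verify by hand; the hand-derived constants ship in `$expected`. Every row
#' sums to 20, so rarefying at depth 20 is the identity.
#'
#' @return list: `table`, `meta`, `tree`, `expected`
#' @export
worked_fixture <- function() {
  counts <- matrix(c(
    10, 5, 5, 0, 0, 0,
    5, 10, 5, 0, 0, 0,
    0, 0, 5, 10, 5, 0,
    0, 0, 0, 10, 5, 5,
    10, 10, 0, 0, 0, 0,
    0, 0, 10, 10, 0, 0,
    0, 0, 0, 0, 10, 10,
    5, 5, 0, 0, 5, 5), nrow = 8, byrow = TRUE,
    dimnames = list(paste0("s", 1:8), paste0("O", 1:6)))
  meta <- sample_metadata(data.frame(
    sample_id = paste0("s", 1:8),
    location_id = rep(c("L1", "L2", "L3", "L4"), 2),
    sector_id = rep(c("S1", "S1", "S2", "S2"), 2),
    calendar_month = rep(c("2010-06", "2010-07"), each = 4)))
  tree <- ape::read.tree(
    text = "(((O1:1,O2:1):1,(O3:1,O4:1):1):1,(O5:1,O6:1):2);")
  expected <- list(
    richness = c(s1 = 3, s2 = 3, s3 = 3, s4 = 3, s5 = 2, s6 = 2, s7 = 2, s8 = 4),
    shannon_s1 = 1.5 * log(2),           # p = (1/2, 1/4, 1/4)
    bray_s1_s2 = 0.25,                   # sum|x-y| = 10, sum(x+y) = 40
    bray_s5_s7 = 1,                      # disjoint
    jaccard_s1_s3 = 0.8,                 # 1 shared of 5 in the union
    unweighted_unifrac_s1_s3 = 0.7,      # unique 7 of union 10 branch length
    unweighted_unifrac_s5_s7 = 1,        # disjoint subtrees
    mic_o1_o2 = 1)                       # 2x2 split at 0 is deterministic
  list(table = otu_tab(counts), meta = meta, tree = tree, expected = expected)
}
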