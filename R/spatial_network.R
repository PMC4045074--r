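#' Build a pipe network graph from an inventory
#'
#' Nodes are junctions, sampling locations and the treatment plant; edges
#' carry length (m), surface area (pi * diameter * length, m^2), age (years
#' at `reference_date`) and material.
#'
#' @param inv a `pipe_inventory` (see [pipe_inventory])
#' @param reference_date date (or "YYYY-MM-DD" string) at which pipe ages are
#'   computed; the campaign midpoint in the survey design
#' @return igraph object of class `pipe_network` with edge attributes
#'   `length_m`, `surface_m2`, `age_yr`, `material`
#' @export
pipe_network <- function(inv, reference_date = "2011-01-15") {
  inv <- pipe_inventory(as.data.frame(inv))
  ref_yr <- as.integer(format(as.Date(reference_date), "%Y")) +
    (as.integer(format(as.Date(reference_date), "%j")) - 1) / 365
  ed <- data.frame(from = inv$node_a, to = inv$node_b,
                   section_id = inv$section_id,
                   length_m = inv$length_m,
                   surface_m2 = pi * inv$diameter_m * inv$length_m,
                   age_yr = pmax(ref_yr - inv$install_year, 0),
                   material = inv$material)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  if (igraph::components(g)$no != 1) stop("pipe network is not connected")
  class(g) <- c("pipe_network", class(g))
  g
}

#' Shortest water path between two nodes, with pipe metrics
#'
#' The path minimizes total pipe length; among equal-length paths the one
#' with smaller total surface area wins, then the lexicographically smallest
#' node sequence (deterministic tie-breaking). Metrics are summed along the
#' chosen path; age-weighted variants are sum(metric_e * age_e)
#' (length-years / surface-years).
#'
#' @param net a [pipe_network]
#' @param a,b node ids
#' @return list: `nodes` (path), `total_length`, `total_surface`,
#'   `age_weighted_length`, `age_weighted_surface`
#' @export
shortest_water_path <- function(net, a, b) {
  vn <- igraph::V(net)$name
  if (!a %in% vn || !b %in% vn) stop("unknown node")
  if (a == b)
    return(list(nodes = a, total_length = 0, total_surface = 0,
                age_weighted_length = 0, age_weighted_surface = 0))
  sp <- igraph::all_shortest_paths(net, from = a, to = b,
                                   weights = igraph::E(net)$length_m)
  paths <- sp$res
  if (length(paths) == 0) stop("nodes unreachable: ", a, " -> ", b)
  metrics <- lapply(paths, function(p) {
    ep <- igraph::E(net, path = p)
    list(nodes = igraph::as_ids(p),
         total_length = sum(ep$length_m),
         total_surface = sum(ep$surface_m2),
         age_weighted_length = sum(ep$length_m * ep$age_yr),
         age_weighted_surface = sum(ep$surface_m2 * ep$age_yr))
  })
  if (length(metrics) > 1) {
    surf <- vapply(metrics, `[[`, 0, "total_surface")
    metrics <- metrics[surf <= min(surf) + 1e-9]
    if (length(metrics) > 1) {
      key <- vapply(metrics, function(m) paste(m$nodes, collapse = "\001"), "")
      metrics <- metrics[order(key)]
    }
  }
  metrics[[1]]
}

#' Pairwise path metrics between sampling locations
#'
#' @param net a [pipe_network]
#' @param locations node ids
#' @return list of four symmetric matrices: `total_length`, `total_surface`,
#'   `age_weighted_length`, `age_weighted_surface`
#' @export
path_metrics_matrix <- function(net, locations) {
  k <- length(locations)
  comps <- c("total_length", "total_surface",
             "age_weighted_length", "age_weighted_surface")
  out <- lapply(comps, function(x)
    matrix(0, k, k, dimnames = list(locations, locations)))
  names(out) <- comps
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pm <- shortest_water_path(net, locations[i], locations[j])
    for (cc in comps) out[[cc]][i, j] <- out[[cc]][j, i] <- pm[[cc]]
  }
  out
}

#' Distance decay: pipe metrics vs community dissimilarity
#'
#' Pearson correlation between each path metric and the (time-averaged)
#' community dissimilarity, over all pairs of the supplied locations
#' (within-sector all-pairs in the survey design).
#'
#' @param net a [pipe_network]
#' @param dm location-level distance matrix (e.g. the 15-month average
#'   weighted UniFrac), labels = location node ids
#' @param locations location node ids to use (>= 3 pairs required)
#' @return data.frame: metric, r, p (two-sided), n_pairs
#' @export
distance_decay <- function(net, dm, locations = rownames(dm)) {
  dm <- validate_dm(dm)
  if (!all(locations %in% rownames(dm))) stop("locations missing from dm")
  k <- length(locations)
  if (k * (k - 1) / 2 < 3) stop("need at least 3 location pairs")
  pmm <- path_metrics_matrix(net, locations)
  lt <- lower.tri(matrix(0, k, k))
  dv <- dm[locations, locations][lt]
  rows <- lapply(names(pmm), function(cc) {
    ct <- stats::cor.test(pmm[[cc]][lt], dv)
    data.frame(metric = cc, r = unname(ct$estimate), p = ct$p.value,
               n_pairs = sum(lt))
  })
  do.call(rbind, rows)
}

#' Location-specific OTUs
#'
#' Pools counts per location over the campaign; an OTU is location-specific
#' if detected at exactly one location. Reports, per location, the fraction
#' of its membership (detected OTUs) and of its pooled relative abundance
#' contributed by its specific OTUs.
#'
#' @param tab an [otu_tab]
#' @param meta metadata (provides `location_id` per sample)
#' @return data.frame: location_id, n_otus, n_specific, frac_membership,
#'   frac_abundance
#' @export
site_specific_otus <- function(tab, meta) {
  md <- aligned_meta(tab, meta)
  locs <- unique(md$location_id)
  if (length(locs) < 2) stop("need >= 2 locations")
  pooled <- rowsum(tab$counts, md$location_id)  # locations x OTUs
  det <- pooled > 0
  n_locs_per_otu <- colSums(det)
  specific <- n_locs_per_otu == 1
  rows <- lapply(rownames(pooled), function(L) {
    here <- det[L, ]
    spec_here <- here & specific
    data.frame(location_id = L,
               n_otus = sum(here),
               n_specific = sum(spec_here),
               frac_membership = sum(spec_here) / sum(here),
               frac_abundance = sum(pooled[L, spec_here]) / sum(pooled[L, ]))
  })
  do.call(rbind, rows)
}
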