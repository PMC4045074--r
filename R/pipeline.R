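#' Location-level distance matrix averaged over months
#'
#' For each pair of locations, the mean over months (in which both were
#' sampled) of the distance between their same-month samples — the
#' "15-month average" dissimilarity used for distance decay.
#'
#' @param dm sample-level distance matrix
#' @param meta metadata (`location_id`, `month_index`)
#' @return symmetric location-level matrix
#' @export
location_average_dm <- function(dm, meta) {
  dm <- validate_dm(dm)
  md <- meta[match(rownames(dm), meta$sample_id), ]
  locs <- sort(unique(md$location_id))
  k <- length(locs)
  out <- matrix(0, k, k, dimnames = list(locs, locs))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    vals <- c()
    for (mo in intersect(md$month_index[md$location_id == locs[i]],
                         md$month_index[md$location_id == locs[j]])) {
      a <- which(md$location_id == locs[i] & md$month_index == mo)
      b <- which(md$location_id == locs[j] & md$month_index == mo)
      vals <- c(vals, as.vector(dm[a, b]))
    }
    out[i, j] <- out[j, i] <- mean(vals)
  }
  out
}

#' Run configuration for the full pipeline
#'
#' @param table an [otu_tab] or path to a wide OTU table
#' @param meta metadata data.frame or CSV path
#' @param tree `phylo`, newick path, or NULL (UniFrac stages skipped)
#' @param pipes `pipe_inventory`, CSV path, or NULL (spatial stage skipped)
#' @param out_dir output directory
#' @param seed master seed; per-stage seeds are derived by stage-name hashing
#' @param depth,n_events rarefaction plan
#' @param stages character vector of stages to run, any of "diversity",
#'   "stats", "spatial", "temporal", "coreselect", "associate", "ioam"
#' @param associate_args,ioam_args,coreselect_args parameter overrides passed
#'   to [robust_associations], [monthly_alpha_envelope] /
#'   [compare_models]-related steps and [core_selection_curve]
#' @return list of class `run_config`
#' @export
run_config <- function(table, meta, tree = NULL, pipes = NULL,
                       out_dir = "results", seed = 1L,
                       depth = 834, n_events = 100,
                       stages = c("diversity", "stats", "spatial", "temporal",
                                  "coreselect", "associate", "ioam"),
                       associate_args = list(), ioam_args = list(),
                       coreselect_args = list()) {
  structure(as.list(environment()), class = "run_config")
}

# deterministic per-stage seed from the master seed and the stage name
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h) %% 2147480000)
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order (rarefy, then diversity, stats / spatial /
#' temporal, core selection, association network, occupancy modeling); every
#' output file is recorded in a JSON manifest with md5 content hashes, along
#' with the resolved seeds. Any stage failure aborts with the stage name.
#'
#' @param config a [run_config]
#' @return (invisibly) the manifest list
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tab <- if (inherits(config$table, "otu_tab")) config$table
         else read_otu_table(config$table)
  meta <- if (is.data.frame(config$meta)) config$meta
          else read_sample_metadata(config$meta)
  tree <- if (is.null(config$tree) || inherits(config$tree, "phylo")) config$tree
          else read_phylogeny(config$tree)
  pipes <- if (is.null(config$pipes) || inherits(config$pipes, "pipe_inventory"))
    config$pipes else read_pipe_inventory(config$pipes)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  log <- list(seed = config$seed, stages = list())
  emit <- function(path) outputs <<- c(outputs, path)
  out <- function(name) file.path(config$out_dir, name)
  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    log$stages[[name]] <<- list(seed = stage_seed(config$seed, name))
    tryCatch(fn(stage_seed(config$seed, name)),
             error = function(e) {
               # partial manifest helps debugging a failed run
               write_manifest(config, outputs, log, failed = name)
               stop("stage '", name, "' failed: ", conditionMessage(e))
             })
    invisible(NULL)
  }

  plan <- rarefaction_plan(config$depth, config$n_events,
                           base_seed = stage_seed(config$seed, "rarefy"))
  events <- rarefy(tab, plan)
  meta_used <- meta[meta$sample_id %in% sample_ids(events[[1]]), ]
  metrics <- c("bray_curtis", "jaccard",
               if (!is.null(tree)) c("unweighted_unifrac", "weighted_unifrac"))
  dms <- list()

  run_stage("diversity", function(seed) {
    alpha <- Reduce(`+`, lapply(events, function(e) {
      a <- alpha_metrics(e)
      as.matrix(a[, -1])
    })) / length(events)
    alpha <- data.frame(sample_id = sample_ids(events[[1]]), alpha)
    utils::write.csv(alpha, out("alpha_diversity.csv"), row.names = FALSE)
    emit(out("alpha_diversity.csv"))
    for (m in metrics) {
      dms[[m]] <<- average_beta(events, metric = m, tree = tree)
      write_distance_matrix(dms[[m]], out(paste0(m, ".dist")))
      emit(out(paste0(m, ".dist")))
    }
    ord <- pcoa(dms[["bray_curtis"]])
    utils::write.csv(data.frame(sample_id = rownames(ord$coordinates),
                                ord$coordinates[, 1:min(4, ncol(ord$coordinates))]),
                     out("pcoa_bray_curtis.csv"), row.names = FALSE)
    emit(out("pcoa_bray_curtis.csv"))
  })
  if (length(dms) == 0)  # stats et al. need at least Bray-Curtis
    dms[["bray_curtis"]] <- average_beta(events, metric = "bray_curtis")

  run_stage("stats", function(seed) {
    md <- aligned_meta(events[[1]], meta)
    rows <- list()
    for (m in names(dms)) for (gv in c("calendar_month", "location_id",
                                       "season", "sector_id")) {
      g <- md[[gv]]
      if (length(unique(g)) < 2 || any(table(g) < 2)) next
      pm <- permanova(dms[[m]], g, seed = seed, grouping = gv)
      an <- anosim(dms[[m]], g, seed = seed + 1, grouping = gv)
      bd <- beta_dispersion(dms[[m]], g)
      rows[[length(rows) + 1]] <- data.frame(
        metric = m, grouping = gv,
        permanova_R2 = pm$statistic$R2, permanova_F = pm$statistic$F,
        permanova_p = pm$p_value, anosim_R = an$statistic$R,
        anosim_p = an$p_value, dispersion_F = bd$anova_f,
        dispersion_p = bd$anova_p)
    }
    utils::write.csv(do.call(rbind, rows), out("grouping_tests.csv"),
                     row.names = FALSE)
    emit(out("grouping_tests.csv"))
  })

  run_stage("spatial", function(seed) {
    if (is.null(pipes)) return(invisible(NULL))
    net <- pipe_network(pipes)
    rows <- list()
    for (m in names(dms)) {
      lavg <- location_average_dm(dms[[m]], meta_used)
      for (sec in setdiff(unique(meta_used$sector_id), "DWTP")) {
        locs <- intersect(rownames(lavg),
                          unique(meta_used$location_id[meta_used$sector_id == sec]))
        if (length(locs) * (length(locs) - 1) / 2 < 3) next
        dd <- distance_decay(net, lavg, locs)
        dd$metric_beta <- m; dd$sector <- sec
        rows[[length(rows) + 1]] <- dd
      }
    }
    if (length(rows)) {
      utils::write.csv(do.call(rbind, rows), out("distance_decay.csv"),
                       row.names = FALSE)
      emit(out("distance_decay.csv"))
    }
    sso <- site_specific_otus(tab, meta)
    utils::write.csv(sso, out("site_specific_otus.csv"), row.names = FALSE)
    emit(out("site_specific_otus.csv"))
  })

  run_stage("temporal", function(seed) {
    for (m in names(dms)) {
      lc <- time_lag_curve(dms[[m]], meta_used)
      utils::write.csv(lc, out(paste0("lag_curve_", m, ".csv")), row.names = FALSE)
      emit(out(paste0("lag_curve_", m, ".csv")))
    }
    if ("DWTP" %in% meta_used$sector_id) {
      dv <- dwtp_divergence(dms[[1]], meta_used)
      utils::write.csv(dv$by_location, out("dwtp_divergence.csv"), row.names = FALSE)
      emit(out("dwtp_divergence.csv"))
    }
  })

  run_stage("coreselect", function(seed) {
    args <- utils::modifyList(
      list(tab = events[[1]], thresholds = c(0.001, 0.01, 0.02, 0.1, 1),
           mode = "relative_abundance", seed = seed), config$coreselect_args)
    curve <- do.call(core_selection_curve, args)
    utils::write.csv(curve, out("core_selection.csv"), row.names = FALSE)
    emit(out("core_selection.csv"))
  })

  net_env <- new.env()
  run_stage("associate", function(seed) {
    args <- utils::modifyList(list(events = events, seed = seed),
                              config$associate_args)
    net <- do.call(robust_associations, args)
    asg <- extract_clusters(net)
    st <- network_stats(net, asg)
    assign("net", net, net_env)
    utils::write.table(net$edges, out("associations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(out("associations.tsv"))
    utils::write.csv(data.frame(otu_id = names(asg$assignment),
                                cluster = asg$assignment),
                     out("clusters.csv"), row.names = FALSE)
    emit(out("clusters.csv"))
    if (nrow(net$edges)) {
      g <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
      igraph::write_graph(g, out("network.graphml"), format = "graphml")
      emit(out("network.graphml"))
    }
    ts <- cluster_timeseries(tab, asg, meta)
    utils::write.csv(ts, out("cluster_timeseries.csv"), row.names = FALSE)
    emit(out("cluster_timeseries.csv"))
    stats_df <- data.frame(density = st$density,
                           clustering_coefficient = st$clustering_coefficient)
    utils::write.csv(stats_df, out("network_stats.csv"), row.names = FALSE)
    emit(out("network_stats.csv"))
  })

  run_stage("ioam", function(seed) {
    pts <- occupancy_points(events, meta)
    cmp <- compare_models(pts)
    utils::write.csv(cmp, out("ioam_models.csv"), row.names = FALSE)
    emit(out("ioam_models.csv"))
    args <- utils::modifyList(list(events = events, meta = meta,
                                   n_reps = 1000, seed = seed),
                              config$ioam_args)
    env <- do.call(monthly_alpha_envelope, args)
    utils::write.csv(env, out("ioam_monthly_alpha.csv"), row.names = FALSE)
    emit(out("ioam_monthly_alpha.csv"))
  })

  invisible(write_manifest(config, outputs, log))
}

write_manifest <- function(config, outputs, log, failed = NULL) {
  manifest <- list(
    seed = config$seed,
    versions = list(aquadyn = as.character(utils::packageVersion("aquadyn")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    depth = config$depth, n_events = config$n_events,
    stages = config$stages,
    failed_stage = failed,
    files = lapply(stats::setNames(outputs, basename(outputs)), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  manifest
}
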