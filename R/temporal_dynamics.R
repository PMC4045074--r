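#' Time-lag beta diversity curve
#'
#' For each sampling location, all within-location sample pairs are binned by
#' their month-index difference; the mean and population variance of the
#' beta-diversity distance per lag are pooled across locations. In a
#' seasonally cycling community the curve peaks near half the period (lag
#' 6-7 for an annual cycle) and dips near the full period (lag 11-12).
#'
#' @param dm sample-level distance matrix
#' @param meta metadata with `location_id` and `month_index` per sample
#' @return data.frame of class `lag_curve`: lag, mean, variance, n_pairs
#' @export
time_lag_curve <- function(dm, meta) {
  dm <- validate_dm(dm)
  ids <- rownames(dm)
  md <- meta[match(ids, meta$sample_id), ]
  if (any(is.na(md$sample_id))) stop("metadata missing samples in dm")
  if (length(unique(md$month_index)) < 2) stop("need >= 2 months")
  lag <- c(); val <- c()
  for (L in unique(md$location_id)) {
    i <- which(md$location_id == L)
    if (length(i) < 2) next
    pr <- utils::combn(i, 2)
    lag <- c(lag, abs(md$month_index[pr[1, ]] - md$month_index[pr[2, ]]))
    val <- c(val, dm[cbind(ids[pr[1, ]], ids[pr[2, ]])])
  }
  if (length(val) == 0) stop("no within-location sample pairs")
  keep <- lag > 0
  lag <- lag[keep]; val <- val[keep]
  out <- do.call(rbind, lapply(sort(unique(lag)), function(l) {
    v <- val[lag == l]
    data.frame(lag = l, mean = mean(v),
               variance = mean((v - mean(v))^2),  # population variance
               n_pairs = length(v))
  }))
  class(out) <- c("lag_curve", "data.frame")
  out
}

#' Divergence of distribution-system samples from the treatment plant
#'
#' For each month with a DWTP sample, the distance of every same-month DWDS
#' sample to the DWTP sample; aggregated per location and per sector.
#'
#' @param dm sample-level distance matrix
#' @param meta metadata (`location_id`, `sector_id`, `month_index`)
#' @param dwtp_sector sector id identifying treatment-plant samples
#' @return list: `monthly` (location, month_index, distance), `by_location`
#'   (mean, sd, n), `by_sector`, `overall` (mean, sd), `skipped_months`
#' @export
dwtp_divergence <- function(dm, meta, dwtp_sector = "DWTP") {
  dm <- validate_dm(dm)
  md <- meta[match(rownames(dm), meta$sample_id), ]
  if (any(is.na(md$sample_id))) stop("metadata missing samples in dm")
  is_plant <- md$sector_id == dwtp_sector
  months <- sort(unique(md$month_index))
  rows <- list(); skipped <- integer(0)
  for (mo in months) {
    p <- which(is_plant & md$month_index == mo)
    d <- which(!is_plant & md$month_index == mo)
    if (length(p) == 0) {
      skipped <- c(skipped, mo)
      next
    }
    if (length(d) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      location_id = md$location_id[d], sector_id = md$sector_id[d],
      month_index = mo,
      distance = rowMeans(dm[d, p, drop = FALSE]))
  }
  if (length(skipped))
    warning("months without a DWTP sample skipped: ", paste(skipped, collapse = ", "))
  monthly <- do.call(rbind, rows)
  agg <- function(key) {
    sp <- split(monthly$distance, monthly[[key]])
    data.frame(group = names(sp),
               mean = vapply(sp, mean, 0),
               sd = vapply(sp, stats::sd, 0),
               n = lengths(sp), row.names = NULL)
  }
  list(monthly = monthly,
       by_location = agg("location_id"),
       by_sector = agg("sector_id"),
       overall = c(mean = mean(monthly$distance), sd = stats::sd(monthly$distance)),
       skipped_months = skipped)
}
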