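#' Compare model predictions with measured size distributions
#'
#' Joins a [sweep_model()] prediction table with measured mean radii per
#' (concentration, well diameter) condition, tabulates the discrepancy,
#' and flags the direction of the concentration trend of each well size in
#' both columns — the qualitative comparison between the kinetic model and
#' the imaged distributions.
#'
#' @param sweep_table A [sweep_model()] result.
#' @param measured A data.frame with columns `concentration_M`,
#'   `well_diameter_m` and `mean_radius_um` (one row per condition).
#' @return A list with `table` (joined rows plus `model_r_um` and
#'   `discrepancy_um`) and `trends` (per well diameter, the sign —
#'   `"increasing"`, `"decreasing"` or `"flat"` — of radius vs
#'   concentration for model and measurement).
#' @export
compare_report <- function(sweep_table, measured) {
  need_s <- c("concentration_M", "well_diameter_m", "r_g_m")
  need_m <- c("concentration_M", "well_diameter_m", "mean_radius_um")
  if (!all(need_s %in% names(sweep_table)))
    stop("`sweep_table` must have columns: ", paste(need_s, collapse = ", "))
  if (!is.data.frame(measured) || nrow(measured) == 0)
    stop("`measured` must be a non-empty data.frame")
  if (!all(need_m %in% names(measured)))
    stop("`measured` must have columns: ", paste(need_m, collapse = ", "))

  key <- function(d) paste(signif(d$concentration_M, 10),
                           signif(d$well_diameter_m, 10))
  unmatched <- setdiff(key(measured), key(sweep_table))
  if (length(unmatched))
    stop("measured conditions absent from the sweep: ",
         paste(unmatched, collapse = "; "))

  tab <- merge(sweep_table, measured,
               by = c("concentration_M", "well_diameter_m"))
  tab$model_r_um <- tab$r_g_m * 1e6
  tab$discrepancy_um <- tab$mean_radius_um - tab$model_r_um
  tab <- tab[order(tab$well_diameter_m, tab$concentration_M), ]
  rownames(tab) <- NULL

  trend_of <- function(x, y) {
    if (length(unique(x)) < 2) return("flat")
    s <- stats::coef(stats::lm(y ~ x))[2]
    if (abs(s) < .Machine$double.eps^0.5) "flat"
    else if (s > 0) "increasing" else "decreasing"
  }
  trends <- do.call(rbind, lapply(split(tab, tab$well_diameter_m), function(d)
    data.frame(well_diameter_m = d$well_diameter_m[1],
               model_trend = trend_of(d$concentration_M, d$model_r_um),
               measured_trend = trend_of(d$concentration_M,
                                         d$mean_radius_um))))
  rownames(trends) <- NULL
  list(table = tab, trends = trends)
}

#' Write a provenance record for a run
#'
#' JSON record of the configuration, root seed and package version, so a
#' run can be reproduced bit-for-bit.
#'
#' @param path Output path (`.json`).
#' @param config A named list of run parameters.
#' @param seed The root seed used.
#' @return Invisibly, `path`.
#' @export
write_provenance <- function(path, config, seed) {
  rec <- list(package = "gelwell",
              version = as.character(utils::packageVersion("gelwell")),
              seed = seed, config = config)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
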