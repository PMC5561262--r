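#' Per-level statistics from quantified dilution-series wells
#'
#' Quantifies one channel of every QC-passing well of each level and
#' summarises each level with [level_stats()]. The measured value is
#' copies per reaction; a replicate counts as negative when it has zero
#' positive droplets on the channel.
#'
#' @param series Output of [make_dilution_series()], or an equivalent
#'   list of `list(level_id, assigned_by_channel, wells)` built from
#'   instrument data.
#' @param channel Channel to quantify (e.g. `"FAM"` for the summed GM
#'   channel).
#' @param min_droplets QC threshold.
#' @return List of [level_stats()], most concentrated first.
#' @export
series_level_stats <- function(series, channel = "FAM",
                               min_droplets = 8000) {
  stats_list <- lapply(series, function(lev) {
    wells <- Filter(function(w) qc_well(w, min_droplets)$pass, lev$wells)
    if (!length(wells))
      stop("all wells failed QC at level ", lev$level_id)
    n_rej <- length(lev$wells) - length(wells)
    if (n_rej > 0)
      message(sprintf("level %s: %d well(s) rejected by QC",
                      lev$level_id, n_rej))
    measured <- vapply(wells, function(w)
      estimate_concentration(w$positives[[channel]], w$n_droplets,
                             w$droplet_volume,
                             w$reaction_volume)$copies_per_reaction,
      numeric(1))
    neg <- sum(vapply(wells, function(w)
      w$positives[[channel]] == 0L, logical(1)))
    level_stats(lev$level_id, lev$assigned_by_channel[[channel]],
                measured, n_negative = neg)
  })
  order_by_assigned(stats_list)
}

#' Full dilution-series validation
#'
#' Runs the complete decision battery on per-level statistics: absolute
#' LOD and LOQ (with practical rounded-up values), dynamic-range
#' linearity over the levels at or above the LOQ, and the per-level
#' quantification acceptance checklist.
#'
#' @param levels List of [level_stats()] (e.g. from
#'   [series_level_stats()]).
#' @param thresholds An [mpr_thresholds()].
#' @return Object of class `validation_outcome`: `level_table`
#'   (data.frame), `lod`, `loq`, `lod_practical`, `loq_practical`,
#'   `fit`, `acceptance` (per-level checklist for levels at/above LOQ).
#' @export
validate_series <- function(levels, thresholds = mpr_thresholds()) {
  levels <- order_by_assigned(levels)
  lod <- determine_lod(levels)
  loq <- determine_loq(levels, thresholds$rsd_quant_limit)
  tab <- do.call(rbind, lapply(levels, function(l) data.frame(
    level_id = l$level_id, assigned = l$assigned, n = l$n,
    mean = l$mean, rsd_percent = l$rsd_percent,
    bias_percent = if (is.finite(l$bias_percent))
      round_half_up(l$bias_percent, 1) else NA_real_,
    n_negative = l$n_negative, stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  quant_idx <- if (loq$defined)
    which(tab$assigned >= loq$assigned) else integer(0)
  fit <- if (length(quant_idx) >= 3)
    dynamic_range_fit(tab$assigned[quant_idx], tab$mean[quant_idx],
                      thresholds$r2_min) else NULL
  acceptance <- if (length(quant_idx)) do.call(rbind, lapply(
    quant_idx, function(i) {
      chk <- evaluate_acceptance(levels[[i]], thresholds,
                                 "quantification")
      chk$level_id <- tab$level_id[i]
      chk[, c("level_id", setdiff(names(chk), "level_id"))]
    })) else NULL
  structure(
    list(level_table = tab, lod = lod, loq = loq,
         lod_practical = if (lod$defined) practical_limit(lod$value)
         else NA_real_,
         loq_practical = if (loq$defined) practical_limit(loq$value)
         else NA_real_,
         fit = fit, acceptance = acceptance, thresholds = thresholds),
    class = "validation_outcome")
}

#' @export
print.validation_outcome <- function(x, ...) {
  cat("<validation_outcome>\n")
  cat(sprintf("  LOD_abs: %s\n", if (x$lod$defined)
    sprintf("%.3g copies/reaction (level %s, practical %g)",
            x$lod$value, x$lod$level_id, x$lod_practical)
    else "undefined"))
  cat(sprintf("  LOQ_abs: %s\n", if (x$loq$defined)
    sprintf("%.3g copies/reaction (level %s, practical %g)",
            x$loq$value, x$loq$level_id, x$loq_practical)
    else "undefined"))
  if (!is.null(x$fit))
    cat(sprintf("  dynamic range: slope %.3f, R^2 %.5f (%s)\n",
                x$fit$slope, x$fit$r2,
                if (x$fit$pass) "pass" else "FAIL"))
  if (!is.null(x$acceptance))
    cat(sprintf("  acceptance: %d/%d checks passed\n",
                sum(x$acceptance$pass), nrow(x$acceptance)))
  invisible(x)
}

#' Simulate-and-validate in one call
#'
#' Convenience wrapper running the whole pipeline on a simulated
#' experiment: [make_dilution_series()] then [series_level_stats()] then
#' [validate_series()].
#'
#' @param design A [dilution_series_design()].
#' @param channel Channel to validate.
#' @param thresholds An [mpr_thresholds()].
#' @param stochastic Passed to the simulator.
#' @return A `validation_outcome`.
#' @examples
#' base <- simulation_design(c(ev = 512, Le1 = 26282),
#'                           channel_of = c(ev = "FAM", Le1 = "HEX"),
#'                           seed = 11)
#' des <- dilution_series_design(base, c(1, 6, 12, 60, 120, 240))
#' run_dilution_validation(des)
#' @export
run_dilution_validation <- function(design, channel = "FAM",
                                    thresholds = mpr_thresholds(),
                                    stochastic = TRUE) {
  series <- make_dilution_series(design, stochastic = stochastic)
  validate_series(series_level_stats(series, channel,
                                     thresholds$min_droplets),
                  thresholds)
}

#' Standard mix-1 dilution design for a multiplex panel
#'
#' Builds the canonical validation experiment: a DNA mix assigning each
#' GM-event a stock concentration of 128 copies/uL -- except A2704-12 at
#' 49 and MON89788 at 92 copies/uL, events whose reference materials run
#' lower -- plus the *Le*1 endogene, with 4 uL template in a 20 uL
#' reaction (so 512/196/368 copies per reaction per event), diluted
#' 6x to 12000x with 12 or 14 replicates over three runs.
#'
#' @param events Named numeric vector of stock concentrations
#'   (copies/uL) per GM-event; the default builds `n_events` generic
#'   events at 128 copies/uL.
#' @param n_events Number of generic GM-events when `events` is NULL.
#' @param endogene_copies_per_ul Endogene stock concentration
#'   (copies/uL); default 26282/4 so the undiluted reaction holds 26282
#'   endogene copies.
#' @param dilution_factors Dilution factors (default 1, 6, 12, 60, 120,
#'   240, 600, 1200, 6000, 12000).
#' @param replicates_per_run Replicate layout (default `c(4, 4, 4)`; use
#'   `c(4, 4, 6)` for a 14-replicate layout).
#' @param seed Simulation seed.
#' @param ... Passed to [simulation_design()].
#' @return A [dilution_series_design()].
#' @export
mix1_dilution_design <- function(events = NULL, n_events = 6,
                                 endogene_copies_per_ul = 26282 / 4,
                                 dilution_factors =
                                   c(1, 6, 12, 60, 120, 240, 600, 1200,
                                     6000, 12000),
                                 replicates_per_run = c(4, 4, 4),
                                 seed = NULL, ...) {
  if (is.null(events)) {
    events <- stats::setNames(rep(128, n_events),
                              sprintf("event%02d", seq_len(n_events)))
  }
  template_volume <- 4
  copies <- c(events, Le1 = endogene_copies_per_ul) * template_volume
  chan <- c(stats::setNames(rep("FAM", length(events)), names(events)),
            Le1 = "HEX")
  base <- simulation_design(copies, channel_of = chan, seed = seed, ...)
  dilution_series_design(base, dilution_factors, replicates_per_run)
}
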