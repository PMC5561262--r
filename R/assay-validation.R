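# Round half away from zero, as printed validation tables do (base
# round() is round-half-even, turning 48.15 into 48.1). A small relative
# fuzz absorbs binary representation error of decimal inputs.
round_half_up <- function(x, digits = 1) {
  z <- abs(x) * 10^digits
  sign(x) * floor(z + 0.5 + 1e-8 * pmax(1, z)) / 10^digits
}

#' Trueness: relative bias against an assigned value
#'
#' `100 * (measured - assigned) / assigned`, reported to one decimal place
#' as printed in validation tables. Threshold comparisons elsewhere in the
#' package always use the unrounded value (`digits = NA`).
#'
#' @param measured,assigned Numeric (vectorised); `assigned` must be
#'   positive.
#' @param digits Decimal places for rounding; `NA` disables rounding.
#' @return Numeric bias in percent.
#' @examples
#' bias_percent(7.9, 7.3)   # 8.2
#' @export
bias_percent <- function(measured, assigned, digits = 1) {
  if (any(!is.finite(assigned)) || any(assigned <= 0))
    stop("'assigned' must be positive")
  b <- 100 * (measured - assigned) / assigned
  if (is.na(digits)) b else round_half_up(b, digits)
}

#' Assigned value of a diluted certified reference material
#'
#' When a CRM is diluted before measurement the measured value is compared
#' to `certified / factor`, rounded to one decimal as reported.
#'
#' @param certified Certified value (e.g. % m/m).
#' @param factor Dilution factor, `>= 1`.
#' @param digits Decimal places (default 1).
#' @return The dilution-adjusted assigned value.
#' @examples
#' dilution_adjusted_assigned(96.3, 2)  # 48.2
#' @export
dilution_adjusted_assigned <- function(certified, factor, digits = 1) {
  if (any(factor <= 0)) stop("'factor' must be positive")
  if (any(factor < 1)) stop("'factor' must be >= 1")
  round_half_up(certified / factor, digits)
}

#' Relative standard deviation (coefficient of variation, percent)
#'
#' `100 * sd(values) / mean(values)` with the n-1 sample standard
#' deviation. Undefined (returns `NA`) for fewer than two values or a zero
#' mean.
#'
#' @param values Numeric vector of replicate results.
#' @return RSD in percent, or `NA_real_` when undefined.
#' @examples
#' rsd_percent(c(100, 110, 90))  # 10
#' @export
rsd_percent <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  100 * sd(values) / m
}

#' Per-level summary statistics for a dilution series
#'
#' Bundles the replicate measurements of one concentration level with its
#' assigned value and derives the mean, RSD, bias and negative-replicate
#' count used by the LOD/LOQ decision rules.
#'
#' @param level_id Identifier of the level.
#' @param assigned Assigned value (copies/reaction, or GM% for relative
#'   series).
#' @param measured Numeric vector of replicate measurements.
#' @param n_negative Number of replicates with no positive droplets;
#'   defaults to the count of zero measurements.
#' @return An object of class `level_stats` with fields `level_id`,
#'   `assigned`, `measured`, `n`, `mean`, `rsd_percent` (`NA` when
#'   undefined), `bias_percent` (unrounded), `n_negative`.
#' @export
level_stats <- function(level_id, assigned, measured,
                        n_negative = sum(measured == 0)) {
  stopifnot(length(measured) >= 1)
  if (n_negative > length(measured))
    stop("'n_negative' cannot exceed the number of replicates")
  m <- mean(measured)
  structure(
    list(level_id = as.character(level_id), assigned = assigned,
         measured = measured, n = length(measured), mean = m,
         rsd_percent = rsd_percent(measured),
         bias_percent = if (is.finite(assigned) && assigned > 0)
           bias_percent(m, assigned, digits = NA) else NA_real_,
         n_negative = as.integer(n_negative)),
    class = "level_stats")
}

order_by_assigned <- function(series) {
  stopifnot(length(series) >= 1,
            all(vapply(series, inherits, logical(1), "level_stats")))
  series[order(-vapply(series, `[[`, numeric(1), "assigned"))]
}

# Shared "consistently passing" scan: walk from the most concentrated
# level down while `pass` holds; the limit is the last level of that
# unbroken run. Returns NULL when even the top level fails.
consistent_limit <- function(series, pass) {
  series <- order_by_assigned(series)
  ok <- vapply(series, pass, logical(1))
  run <- cumprod(ok) == 1
  if (!any(run)) return(NULL)
  series[[max(which(run))]]
}

limit_result <- function(level) {
  if (is.null(level))
    return(list(defined = FALSE, level_id = NA_character_,
                value = NA_real_, assigned = NA_real_))
  list(defined = TRUE, level_id = level$level_id,
       value = level$mean, assigned = level$assigned)
}

#' Limit of detection from a dilution series
#'
#' The LOD is the lowest concentration that, together with every more
#' concentrated level, yielded positive signals in all replicates
#' ("consistently positive": one negative replicate at a higher
#' concentration breaks the run). The reported `value` is the mean
#' measured copy number of the qualifying level.
#'
#' @param series List of [level_stats()] (any order; sorted internally by
#'   assigned value, most concentrated first).
#' @return A list `defined`, `level_id`, `value` (mean measured),
#'   `assigned`.
#' @examples
#' s <- list(level_stats("a", 200, c(210, 190)),
#'           level_stats("b", 12, c(13, 11)),
#'           level_stats("c", 3, c(4, 0)))
#' determine_lod(s)$level_id  # "b"
#' @export
determine_lod <- function(series) {
  if (length(series) < 2) stop("need at least two levels")
  limit_result(consistent_limit(series, function(l) l$n_negative == 0L))
}

#' Limit of quantification from a dilution series
#'
#' The LOQ is the lowest concentration that, together with every more
#' concentrated level, yielded a replicate RSD strictly below
#' `rsd_limit` (default 25%). Levels with undefined RSD fail.
#'
#' @inheritParams determine_lod
#' @param rsd_limit RSD threshold in percent (default 25).
#' @return As [determine_lod()].
#' @export
determine_loq <- function(series, rsd_limit = 25) {
  if (length(series) < 2) stop("need at least two levels")
  ok_rsd <- vapply(series, function(l) is.finite(l$rsd_percent),
                   logical(1))
  if (!any(ok_rsd)) stop("no level has a defined RSD")
  limit_result(consistent_limit(series, function(l)
    is.finite(l$rsd_percent) && l$rsd_percent < rsd_limit))
}

#' Relative LOD and LOQ from a GM-percentage series
#'
#' Applies the same decision rules as [determine_lod()] and
#' [determine_loq()] to levels expressed as GM% relative to the
#' endogene.
#'
#' @param series List of [level_stats()] whose `assigned`/`measured` are
#'   GM percentages.
#' @param rsd_limit RSD threshold for the LOQ rule.
#' @return List with elements `lod_rel` and `loq_rel`, each as
#'   [determine_lod()].
#' @export
determine_relative_limits <- function(series, rsd_limit = 25) {
  list(lod_rel = determine_lod(series),
       loq_rel = determine_loq(series, rsd_limit))
}

#' Express an absolute copy-number limit relative to the endogene
#'
#' @param copies Copies per reaction.
#' @param endogene_copies Endogene copies per reaction.
#' @param digits Decimal places (default 2, as such limits are printed).
#' @return Percentage `100 * copies / endogene_copies`.
#' @examples
#' relative_from_absolute(39, 50000)  # 0.08
#' @export
relative_from_absolute <- function(copies, endogene_copies, digits = 2) {
  stopifnot(endogene_copies > 0)
  round_half_up(100 * copies / endogene_copies, digits)
}

#' Round a limit up to a practical reporting value
#'
#' Validation reports often state a conservative "practical" limit: the
#' raw passing-level mean rounded up to the nearest 10 copies (e.g. a
#' 38-copy LOQ reported as 40 copies/reaction).
#'
#' @param x Limit value (copies/reaction).
#' @param step Rounding step (default 10).
#' @return `step * ceiling(x / step)`.
#' @export
practical_limit <- function(x, step = 10) step * ceiling(x / step)

#' Dynamic-range linearity fit
#'
#' Ordinary least squares of measured on assigned values on the raw copy
#' scale; linearity is summarised by the squared Pearson correlation and
#' judged against `r2_min` (default 0.98).
#'
#' @param assigned,measured Numeric vectors (>= 3 distinct assigned
#'   values).
#' @param r2_min Acceptance threshold for R^2.
#' @return List `slope`, `intercept`, `r2`, `pass`, `n`.
#' @export
dynamic_range_fit <- function(assigned, measured, r2_min = 0.98) {
  stopifnot(length(assigned) == length(measured))
  if (length(assigned) < 3) stop("need at least three points")
  if (length(unique(assigned)) < 2 || sd(assigned) == 0)
    stop("assigned values are degenerate (all equal)")
  fit <- lm(measured ~ assigned)
  r2 <- cor(assigned, measured)^2
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = r2, pass = r2 >= r2_min, n = length(assigned))
}

#' Minimum-performance acceptance thresholds
#'
#' The method-performance requirements used throughout the package:
#' trueness bias within +/-25%, quantification RSD <= 25%, repeatability
#' RSD_r <= 35%, a relaxed RSD_r <= 50% for low-copy samples
#' (< 100 copies/reaction), linearity R^2 >= 0.98, at least 8000 accepted
#' droplets per well, and a primer-dimer alignment score of 7 as the
#' interaction flag.
#'
#' @param bias_limit,rsd_quant_limit,rsd_repeat_limit,rsd_lowcopy_limit
#'   Percent thresholds.
#' @param r2_min Linearity threshold.
#' @param min_droplets Well QC threshold.
#' @param dimer_flag_score Dimer-score flag threshold.
#' @return A named list of class `mpr_thresholds`.
#' @export
mpr_thresholds <- function(bias_limit = 25, rsd_quant_limit = 25,
                           rsd_repeat_limit = 35, rsd_lowcopy_limit = 50,
                           r2_min = 0.98, min_droplets = 8000,
                           dimer_flag_score = 7) {
  th <- list(bias_limit = bias_limit, rsd_quant_limit = rsd_quant_limit,
             rsd_repeat_limit = rsd_repeat_limit,
             rsd_lowcopy_limit = rsd_lowcopy_limit, r2_min = r2_min,
             min_droplets = min_droplets,
             dimer_flag_score = dimer_flag_score)
  if (any(unlist(th) <= 0)) stop("all thresholds must be positive")
  structure(th, class = "mpr_thresholds")
}

#' Acceptance checklist for a set of performance statistics
#'
#' Compares observed bias and RSD against the context-appropriate
#' thresholds: `"quantification"` uses RSD <= 25%, `"repeatability"`
#' RSD_r <= 35%, and `"low_copy"` (samples under ~100 copies/reaction)
#' RSD_r <= 50%. Bias, when supplied, is always judged against +/-25%.
#' Comparisons use unrounded values; each verdict carries the offending
#' value and its limit.
#'
#' @param stats A list (or [level_stats()]) with optional elements
#'   `bias_percent` and `rsd_percent`.
#' @param thresholds An [mpr_thresholds()].
#' @param context One of `"quantification"`, `"repeatability"`,
#'   `"low_copy"`.
#' @return data.frame with columns `check`, `value`, `limit`, `pass`,
#'   `reason`.
#' @examples
#' evaluate_acceptance(list(rsd_percent = 41.78), context = "repeatability")
#' @export
evaluate_acceptance <- function(stats, thresholds = mpr_thresholds(),
                                context = c("quantification",
                                            "repeatability", "low_copy")) {
  context <- match.arg(context)
  stopifnot(inherits(thresholds, "mpr_thresholds") || is.list(thresholds))
  rsd_limit <- switch(context,
                      quantification = thresholds$rsd_quant_limit,
                      repeatability = thresholds$rsd_repeat_limit,
                      low_copy = thresholds$rsd_lowcopy_limit)
  rows <- list()
  if (!is.null(stats$bias_percent) && is.finite(stats$bias_percent)) {
    v <- stats$bias_percent
    ok <- abs(v) <= thresholds$bias_limit
    rows[[length(rows) + 1L]] <- data.frame(
      check = "bias", value = v, limit = thresholds$bias_limit,
      pass = ok,
      reason = if (ok) "" else
        sprintf("|bias| %.2f%% exceeds %.0f%%", abs(v),
                thresholds$bias_limit),
      stringsAsFactors = FALSE)
  }
  if (!is.null(stats$rsd_percent) && is.finite(stats$rsd_percent)) {
    v <- stats$rsd_percent
    ok <- v <= rsd_limit
    rows[[length(rows) + 1L]] <- data.frame(
      check = paste0("rsd_", context), value = v, limit = rsd_limit,
      pass = ok,
      reason = if (ok) "" else
        sprintf("RSD %.2f%% exceeds %.0f%% (%s)", v, rsd_limit, context),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("'stats' carries neither 'bias_percent' nor 'rsd_percent'")
  do.call(rbind, rows)
}

#' Robustness: compare a modified protocol to the original
#'
#' The modified protocol must reproduce the original result within a 25%
#' deviation (computed as the bias of the modified mean against the
#' original mean) and keep its replicate RSD within the 35%
#' repeatability limit.
#'
#' @param original,modified [level_stats()] (or lists with `mean` and
#'   `rsd_percent`) for the same sample under the two protocols.
#' @param thresholds An [mpr_thresholds()].
#' @return List `deviation_percent` (1-decimal, signed), `rsd_percent`
#'   (modified protocol), `pass`, `reasons`.
#' @examples
#' o <- level_stats("60x", NA, c(10.2, 9.8, 10.0))
#' m <- level_stats("60x", NA, c(12.3, 11.7, 12.0))
#' robustness_compare(o, m)
#' @export
robustness_compare <- function(original, modified,
                               thresholds = mpr_thresholds()) {
  if (!is.finite(original$mean) || original$mean == 0)
    stop("original protocol mean must be nonzero")
  dev <- bias_percent(modified$mean, original$mean, digits = NA)
  reasons <- character(0)
  if (abs(dev) >= thresholds$bias_limit)
    reasons <- c(reasons, sprintf("deviation %.2f%% not below %.0f%%",
                                  dev, thresholds$bias_limit))
  rsd <- modified$rsd_percent
  if (is.finite(rsd) && rsd > thresholds$rsd_repeat_limit)
    reasons <- c(reasons, sprintf("RSD %.2f%% exceeds %.0f%%", rsd,
                                  thresholds$rsd_repeat_limit))
  list(deviation_percent = round_half_up(dev, 1), rsd_percent = rsd,
       pass = !length(reasons), reasons = reasons)
}

#' Inter-laboratory summary: per-lab bias and RSD_r, pooled RSD_R
#'
#' Repeatability (RSD_r) is computed within each laboratory;
#' reproducibility (RSD_R) pools every individual replicate result across
#' laboratories into one RSD (no variance-components decomposition). A
#' lab with fewer than two replicates contributes to bias only.
#'
#' @param results Named list: one numeric vector of replicate results per
#'   laboratory (>= 2 labs).
#' @param assigned Assigned value of the sample (optional; `NA` skips
#'   bias).
#' @return List with `per_lab` (data.frame: lab, n, mean, bias_percent,
#'   rsd_r) and `rsd_R`.
#' @examples
#' interlab_summary(list(NIB = c(1.0, 1.06), NVI = c(1.02, 1.1)), 0.91)
#' @export
interlab_summary <- function(results, assigned = NA_real_) {
  if (length(results) < 2) stop("need results from at least two labs")
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("'results' must be a named list (lab ids)")
  per_lab <- do.call(rbind, lapply(names(results), function(lab) {
    v <- results[[lab]]
    data.frame(lab = lab, n = length(v), mean = mean(v),
               bias_percent = if (is.finite(assigned) && assigned > 0)
                 bias_percent(mean(v), assigned) else NA_real_,
               rsd_r = rsd_percent(v), stringsAsFactors = FALSE)
  }))
  list(per_lab = per_lab, rsd_R = rsd_percent(unlist(results)))
}
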