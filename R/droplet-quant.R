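#' Classify droplet amplitudes at a fluorescence threshold
#'
#' A droplet is positive when its amplitude is greater than or equal to
#' the threshold (ties resolve to positive, matching manual-threshold
#' practice of placing the cut just below the positive cloud).
#'
#' @param amplitudes Numeric vector of per-droplet amplitudes.
#' @param threshold Positive fluorescence threshold.
#' @return Integer positive count. An empty amplitude vector returns 0
#'   with a warning.
#' @examples
#' classify_by_threshold(c(5000, 14000), 13200)  # 1
#' @export
classify_by_threshold <- function(amplitudes, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("'threshold' must be a single positive number")
  if (!length(amplitudes)) {
    warning("empty amplitude list; returning 0 positives")
    return(0L)
  }
  sum(amplitudes >= threshold)
}

#' Well-level quality control
#'
#' A well is rejected when the instrument flagged a clog or when fewer
#' than `min_droplets` droplets were accepted (the default 8000 is the
#' conventional cut for a 20 uL reaction; the comparison is strict, so
#' exactly 8000 droplets passes).
#'
#' @param well A [droplet_well()].
#' @param min_droplets Minimum accepted droplets (default 8000).
#' @return A list `pass` (logical) and `reasons` (character vector, empty
#'   on pass; `"clog"` and/or `"low_droplets"`).
#' @examples
#' qc_well(droplet_well("A01", 7999, c(FAM = 10)))$reasons
#' @export
qc_well <- function(well, min_droplets = 8000) {
  stopifnot(inherits(well, "droplet_well"))
  reasons <- character(0)
  if (isTRUE(well$clog)) reasons <- c(reasons, "clog")
  if (well$n_droplets < min_droplets) reasons <- c(reasons, "low_droplets")
  list(pass = !length(reasons), reasons = reasons)
}

#' Poisson-corrected concentration from partition counts
#'
#' The core digital-PCR inversion. With `x` positives among `n` accepted
#' droplets, the positive fraction is \eqn{p = x/n}, the mean copies per
#' droplet \eqn{\lambda = -\ln(1-p)}, the concentration
#' \eqn{c = \lambda / V_d} (copies/uL, with \eqn{V_d} the droplet volume
#' converted from nL), and copies per reaction \eqn{c \times V_{rxn}}.
#' The 95% confidence interval uses the delta-method standard error
#' \eqn{SE(\lambda) = \sqrt{p / (n (1-p))}} with z = 1.96.
#'
#' When every droplet is positive (`p = 1`) the point estimate is not
#' finite; the estimate is then computed at `p = (n - 0.5)/n` and flagged
#' `saturated = TRUE`, i.e. reported as a lower bound.
#'
#' @param positives Non-negative integer count of positive droplets.
#' @param n_droplets Positive integer count of accepted droplets.
#' @param droplet_volume Droplet volume in nL (default 0.85).
#' @param reaction_volume Reaction volume in uL (default 20).
#' @return An object of class `conc_estimate` with fields `p`, `lambda`,
#'   `conc` (copies/uL), `copies_per_reaction`, `se_conc`, `ci_low`,
#'   `ci_high` (copies/uL), `n_droplets`, `positives`, `saturated`.
#' @examples
#' estimate_concentration(3935, 10000)
#' @export
estimate_concentration <- function(positives, n_droplets,
                                   droplet_volume = 0.85,
                                   reaction_volume = 20) {
  positives <- as.integer(positives); n_droplets <- as.integer(n_droplets)
  if (is.na(n_droplets) || n_droplets < 1L)
    stop("'n_droplets' must be a positive integer")
  if (is.na(positives) || positives < 0L || positives > n_droplets)
    stop("'positives' must lie in [0, n_droplets]")
  stopifnot(droplet_volume > 0, reaction_volume > 0)
  vd_ul <- droplet_volume * 1e-3
  p_raw <- positives / n_droplets
  saturated <- p_raw >= 1
  p <- if (saturated) (n_droplets - 0.5) / n_droplets else p_raw
  lambda <- -log(1 - p)
  se_lambda <- sqrt(p / (n_droplets * (1 - p)))
  conc <- lambda / vd_ul
  se_conc <- se_lambda / vd_ul
  z <- 1.96
  structure(
    list(p = p, lambda = lambda, conc = conc,
         copies_per_reaction = conc * reaction_volume,
         se_conc = se_conc,
         ci_low = max(0, conc - z * se_conc),
         ci_high = conc + z * se_conc,
         n_droplets = n_droplets, positives = positives,
         droplet_volume = droplet_volume,
         reaction_volume = reaction_volume,
         saturated = saturated),
    class = "conc_estimate")
}

#' @export
print.conc_estimate <- function(x, ...) {
  cat(sprintf(
    "<conc_estimate> %.4g copies/uL (95%% CI %.4g-%.4g)%s\n",
    x$conc, x$ci_low, x$ci_high,
    if (x$saturated) " [saturated: lower bound]" else ""))
  cat(sprintf("  p = %.4g, lambda = %.4g, %d/%d droplets, %.4g copies/reaction\n",
              x$p, x$lambda, x$positives, x$n_droplets,
              x$copies_per_reaction))
  invisible(x)
}

#' Estimate concentrations for every channel of a well
#'
#' @param well A [droplet_well()].
#' @return Named list of [estimate_concentration()] results per channel.
#' @export
quantify_well <- function(well) {
  stopifnot(inherits(well, "droplet_well"))
  stats::setNames(lapply(channels_of(well), function(ch)
    estimate_concentration(well$positives[[ch]], well$n_droplets,
                           well$droplet_volume, well$reaction_volume)),
    channels_of(well))
}

#' Relative GM content from GM-channel and endogene estimates
#'
#' GM content is the copy-number ratio expressed as a percentage,
#' `100 * gm / endogene`, computed on concentrations (equivalently
#' copies/reaction for a shared reaction volume). The confidence interval
#' uses the independent-ratio delta method:
#' \eqn{SE(R)^2 = (1/e)^2 SE(g)^2 + (g/e^2)^2 SE(e)^2}.
#'
#' No zygosity or mass-conversion factor is applied: the copy ratio is
#' reported directly against certified mass/mass values.
#'
#' @param gm,endogene [estimate_concentration()] results for the GM
#'   (summed) channel and the endogene channel.
#' @return An object of class `gm_quant` with `gm_percent`, `se`,
#'   `ci_low`, `ci_high`, and the two copies-per-reaction inputs.
#' @examples
#' gm <- estimate_concentration(200, 15000)
#' en <- estimate_concentration(5000, 15000)
#' gm_percent(gm, en)
#' @export
gm_percent <- function(gm, endogene) {
  stopifnot(inherits(gm, "conc_estimate"),
            inherits(endogene, "conc_estimate"))
  if (endogene$conc <= 0)
    stop("endogene concentration must be positive")
  pct <- 100 * gm$conc / endogene$conc
  se <- 100 / endogene$conc *
    sqrt(gm$se_conc^2 + (gm$conc / endogene$conc)^2 * endogene$se_conc^2)
  z <- 1.96
  structure(
    list(gm_percent = pct, se = se,
         ci_low = max(0, pct - z * se), ci_high = pct + z * se,
         gm_copies_per_reaction = gm$copies_per_reaction,
         endogene_copies_per_reaction = endogene$copies_per_reaction,
         saturated = gm$saturated || endogene$saturated),
    class = "gm_quant")
}

#' @export
print.gm_quant <- function(x, ...) {
  cat(sprintf("<gm_quant> %.3f%% GM (95%% CI %.3f-%.3f)\n",
              x$gm_percent, x$ci_low, x$ci_high))
  invisible(x)
}

#' Total GM content across complementary panels
#'
#' Labelling thresholds apply to the summed GM content per ingredient, so
#' results from complementary multiplex panels run on the same sample
#' (hence the same endogene basis) are added. The CI adds variances.
#'
#' @param results List of [gm_percent()] results for one sample.
#' @return A `gm_quant` holding the summed percentage.
#' @export
combine_panels <- function(results) {
  if (!length(results)) stop("'results' must contain at least one result")
  stopifnot(all(vapply(results, inherits, logical(1), "gm_quant")))
  pct <- sum(vapply(results, `[[`, numeric(1), "gm_percent"))
  se <- sqrt(sum(vapply(results, `[[`, numeric(1), "se")^2))
  z <- 1.96
  structure(
    list(gm_percent = pct, se = se,
         ci_low = max(0, pct - z * se), ci_high = pct + z * se,
         gm_copies_per_reaction =
           sum(vapply(results, `[[`, numeric(1), "gm_copies_per_reaction")),
         endogene_copies_per_reaction =
           results[[1]]$endogene_copies_per_reaction,
         saturated = any(vapply(results, `[[`, logical(1), "saturated"))),
    class = "gm_quant")
}

#' Merge replicate wells into one concentration estimate
#'
#' Two aggregation modes. `"mean"` (default) averages the per-well
#' concentration estimates; this matches repeatability statistics that
#' are computed across replicate reactions. `"pool"` sums positives and
#' accepted droplets over wells and estimates once, appropriate when
#' replicate wells of one sample are treated as a single larger
#' partitioning. QC-failing wells are dropped first.
#'
#' @param wells List of [droplet_well()]s of the same sample.
#' @param channel Channel label to quantify.
#' @param mode `"mean"` or `"pool"`.
#' @param min_droplets QC threshold passed to [qc_well()].
#' @return A `conc_estimate`. In `"mean"` mode `p`/`lambda` are the values
#'   implied by the averaged concentration and the CI uses the standard
#'   error of the mean of per-well estimates.
#' @export
replicate_merge <- function(wells, channel, mode = c("mean", "pool"),
                            min_droplets = 8000) {
  mode <- match.arg(mode)
  stopifnot(length(wells) >= 1)
  keep <- vapply(wells, function(w) qc_well(w, min_droplets)$pass,
                 logical(1))
  if (!any(keep)) stop("all wells failed QC")
  wells <- wells[keep]
  vd <- unique(vapply(wells, `[[`, numeric(1), "droplet_volume"))
  vr <- unique(vapply(wells, `[[`, numeric(1), "reaction_volume"))
  if (length(vd) != 1L || length(vr) != 1L)
    stop("wells must share droplet and reaction volumes to be merged")
  if (mode == "pool") {
    pos <- sum(vapply(wells, function(w) w$positives[[channel]], numeric(1)))
    n <- sum(vapply(wells, `[[`, numeric(1), "n_droplets"))
    return(estimate_concentration(pos, n, vd, vr))
  }
  ests <- lapply(wells, function(w)
    estimate_concentration(w$positives[[channel]], w$n_droplets, vd, vr))
  concs <- vapply(ests, `[[`, numeric(1), "conc")
  k <- length(ests)
  conc <- mean(concs)
  se <- sqrt(sum(vapply(ests, `[[`, numeric(1), "se_conc")^2)) / k
  lambda <- conc * vd * 1e-3
  z <- 1.96
  structure(
    list(p = 1 - exp(-lambda), lambda = lambda, conc = conc,
         copies_per_reaction = conc * vr, se_conc = se,
         ci_low = max(0, conc - z * se), ci_high = conc + z * se,
         n_droplets = sum(vapply(wells, `[[`, numeric(1), "n_droplets")),
         positives = sum(vapply(wells, function(w)
           w$positives[[channel]], numeric(1))),
         droplet_volume = vd, reaction_volume = vr,
         saturated = any(vapply(ests, `[[`, logical(1), "saturated"))),
    class = "conc_estimate")
}
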