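#' Define a simulated multiplex ddPCR reaction
#'
#' A `simulation_design` states the true composition of one reaction: the
#' number of copies of every target per reaction, which fluorescence
#' channel each target reports on, and the partition geometry. Copies
#' distribute over droplets as independent Poisson counts with mean
#' \deqn{\lambda_i = \frac{c_i}{V_{rxn}} V_d}
#' where \eqn{c_i} is copies/reaction, \eqn{V_{rxn}} the reaction volume
#' (uL) and \eqn{V_d} the droplet volume (uL). A droplet is positive on a
#' channel iff it received at least one copy of any target assigned to
#' that channel -- the property that legitimises summed one-channel
#' multiplex quantification.
#'
#' @param targets Named numeric vector: true copies per reaction for each
#'   target (non-negative, finite).
#' @param channel_of Named character vector mapping every target to one
#'   channel label. Defaults to all targets on `"FAM"`.
#' @param n_droplets Either a single accepted-droplet count, or a length-2
#'   range from which each simulated well draws uniformly (emulating
#'   droplet-generator variation). Default `c(12000, 17000)`.
#' @param droplet_volume Droplet volume in nL (default 0.85).
#' @param reaction_volume Reaction volume in uL (default 20).
#' @param template_volume Template volume in uL (default 4); used when
#'   converting stock concentrations (copies/uL) to copies/reaction.
#' @param seed Optional integer seed; when set, simulation from this
#'   design is reproducible.
#'
#' @return An object of class `sim_design`.
#' @examples
#' d <- simulation_design(c(eventA = 512, Le1 = 26282),
#'                        channel_of = c(eventA = "FAM", Le1 = "HEX"))
#' @export
simulation_design <- function(targets, channel_of = NULL,
                              n_droplets = c(12000, 17000),
                              droplet_volume = 0.85, reaction_volume = 20,
                              template_volume = 4, seed = NULL) {
  if (is.null(names(targets)) || any(!nzchar(names(targets))))
    stop("'targets' must be a named numeric vector")
  targets <- vapply(targets, as.numeric, numeric(1))
  if (any(!is.finite(targets)) || any(targets < 0))
    stop("target copy numbers must be finite and non-negative")
  if (is.null(channel_of))
    channel_of <- stats::setNames(rep("FAM", length(targets)), names(targets))
  if (!all(names(targets) %in% names(channel_of)))
    stop("every target must map to exactly one channel in 'channel_of'")
  channel_of <- channel_of[names(targets)]
  if (length(n_droplets) == 1L) n_droplets <- rep(n_droplets, 2L)
  if (length(n_droplets) != 2L || any(n_droplets < 1) ||
      n_droplets[2] < n_droplets[1])
    stop("'n_droplets' must be a count or an increasing length-2 range")
  stopifnot(droplet_volume > 0, reaction_volume > 0, template_volume > 0)
  structure(
    list(targets = targets, channel_of = channel_of,
         n_droplets = as.integer(round(n_droplets)),
         droplet_volume = droplet_volume,
         reaction_volume = reaction_volume,
         template_volume = template_volume, seed = seed),
    class = "sim_design")
}

# Per-channel Poisson mean: sum of lambda_i over targets on the channel.
channel_lambda <- function(design) {
  vd_ul <- design$droplet_volume * 1e-3
  lam <- design$targets / design$reaction_volume * vd_ul
  tapply(lam, design$channel_of, sum)
}

#' Simulate one ddPCR well from a design
#'
#' Draws an accepted-droplet count, then per channel draws the number of
#' positive droplets. Under independent Poisson occupancy the probability
#' that a droplet is positive on a channel is
#' \eqn{1 - e^{-\sum_i \lambda_i}} over the targets on that channel, so
#' positives are Binomial(N, 1 - exp(-sum lambda)). With
#' `stochastic = FALSE` the expectation is returned (rounded), which gives
#' a noise-free series for linearity checks.
#'
#' @param design A [simulation_design()].
#' @param well_id,panel_id Identifiers stored in the well.
#' @param stochastic Draw from the model (`TRUE`, default) or return the
#'   deterministic expectation.
#' @return A [droplet_well()].
#' @examples
#' w <- simulate_well(simulation_design(c(t1 = 500), seed = 1))
#' @export
simulate_well <- function(design, well_id = "W01", panel_id = "sim",
                          stochastic = TRUE) {
  stopifnot(inherits(design, "sim_design"))
  with_local_seed(design$seed, {
    nd <- design$n_droplets
    n <- if (nd[1] == nd[2]) nd[1] else
      as.integer(round(runif(1, nd[1], nd[2])))
    lam <- channel_lambda(design)
    p_pos <- 1 - exp(-lam)
    pos <- if (stochastic) {
      vapply(p_pos, function(p) rbinom(1, n, p), numeric(1))
    } else round(n * p_pos)
    droplet_well(well_id, n,
                 stats::setNames(as.integer(pos), names(lam)),
                 panel_id = panel_id,
                 droplet_volume = design$droplet_volume,
                 reaction_volume = design$reaction_volume)
  })
}

#' Fluorescence amplitude model for simulated droplets
#'
#' Gaussian negative and positive clusters per channel. Cluster spreads
#' default to 5% of the cluster mean; a spread of zero gives perfectly
#' separated clusters so that threshold classification recovers the
#' simulated counts exactly.
#'
#' @param channels Character vector of channel labels.
#' @param neg_mean,pos_mean Numeric vectors (recycled) of cluster means in
#'   fluorescence units; every positive mean must exceed the corresponding
#'   negative mean.
#' @param neg_sd,pos_sd Cluster spreads; default 5% of the mean.
#' @return An object of class `amplitude_model`.
#' @export
amplitude_model <- function(channels = c("FAM", "HEX"),
                            neg_mean = c(2000, 600),
                            pos_mean = c(16000, 2600),
                            neg_sd = 0.05 * neg_mean,
                            pos_sd = 0.05 * pos_mean) {
  k <- length(channels)
  neg_mean <- rep_len(neg_mean, k); pos_mean <- rep_len(pos_mean, k)
  neg_sd <- rep_len(neg_sd, k); pos_sd <- rep_len(pos_sd, k)
  if (any(pos_mean <= neg_mean))
    stop("positive cluster mean must exceed negative cluster mean")
  if (any(neg_sd < 0) || any(pos_sd < 0)) stop("spreads must be >= 0")
  structure(list(channels = channels,
                 neg_mean = stats::setNames(neg_mean, channels),
                 pos_mean = stats::setNames(pos_mean, channels),
                 neg_sd = stats::setNames(neg_sd, channels),
                 pos_sd = stats::setNames(pos_sd, channels)),
            class = "amplitude_model")
}

#' Simulate per-droplet fluorescence amplitudes for a well
#'
#' For each channel, draws the well's positive count of amplitudes from
#' the positive cluster and the remainder from the negative cluster, then
#' shuffles droplet order. Classifying the result at any threshold between
#' the clusters recovers the counts; with zero spread the recovery is
#' exact at the midpoint threshold.
#'
#' @param well A [droplet_well()].
#' @param model An [amplitude_model()] covering the well's channels.
#' @param seed Optional seed.
#' @return The well with its `amplitudes` field filled (a named list of
#'   numeric vectors of length `n_droplets`).
#' @export
simulate_amplitudes <- function(well, model = amplitude_model(),
                                seed = NULL) {
  stopifnot(inherits(well, "droplet_well"),
            inherits(model, "amplitude_model"))
  miss <- setdiff(channels_of(well), model$channels)
  if (length(miss))
    stop("amplitude model lacks channel(s): ", paste(miss, collapse = ", "))
  with_local_seed(seed, {
    amps <- lapply(channels_of(well), function(ch) {
      k <- well$positives[[ch]]; n <- well$n_droplets
      a <- c(rnorm(k, model$pos_mean[[ch]], model$pos_sd[[ch]]),
             rnorm(n - k, model$neg_mean[[ch]], model$neg_sd[[ch]]))
      sample(a)
    })
    well$amplitudes <- stats::setNames(amps, channels_of(well))
    well
  })
}

#' Define a dilution-series experiment
#'
#' @param base A [simulation_design()] describing the undiluted mix
#'   (level 1); its `seed` seeds the whole series.
#' @param dilution_factors Strictly increasing positive dilution factors.
#'   A leading factor of 1 represents the undiluted mix itself.
#' @param replicates_per_run Integer vector, wells per run/day at every
#'   level (e.g. `c(4, 4, 6)` gives 14 replicates over three days).
#' @return An object of class `dilution_design`.
#' @export
dilution_series_design <- function(base, dilution_factors,
                                   replicates_per_run = c(4, 4, 4)) {
  stopifnot(inherits(base, "sim_design"))
  if (!length(dilution_factors)) stop("'dilution_factors' must be non-empty")
  if (any(dilution_factors <= 0) || is.unsorted(dilution_factors,
                                                strictly = TRUE))
    stop("'dilution_factors' must be positive and strictly increasing")
  if (any(replicates_per_run < 1))
    stop("replicate counts must be >= 1")
  structure(list(base = base,
                 dilution_factors = as.numeric(dilution_factors),
                 replicates_per_run = as.integer(replicates_per_run)),
            class = "dilution_design")
}

#' Simulate a full dilution series
#'
#' Level k carries `base copies / factor_k` of every target; each level is
#' simulated with the replicate layout (runs x replicates). Well ids
#' encode level, run and replicate (`L01_R2_3`).
#'
#' @param design A [dilution_series_design()].
#' @param stochastic Passed to [simulate_well()].
#' @return A list with one element per level:
#'   `list(level_id, factor, assigned, assigned_by_channel, wells)` where
#'   `assigned` is the per-target copies/reaction at that level.
#' @examples
#' base <- simulation_design(c(ev = 512, Le1 = 26282),
#'                           channel_of = c(ev = "FAM", Le1 = "HEX"),
#'                           seed = 7)
#' ser <- make_dilution_series(dilution_series_design(base, c(1, 10, 100)))
#' @export
make_dilution_series <- function(design, stochastic = TRUE) {
  stopifnot(inherits(design, "dilution_design"))
  base <- design$base
  with_local_seed(base$seed, {
    lapply(seq_along(design$dilution_factors), function(k) {
      f <- design$dilution_factors[k]
      assigned <- base$targets / f
      lev <- base
      lev$targets <- assigned
      lev$seed <- NULL           # series-level RNG stream already active
      wells <- list()
      for (run in seq_along(design$replicates_per_run)) {
        for (rep in seq_len(design$replicates_per_run[run])) {
          wid <- sprintf("L%02d_R%d_%d", k, run, rep)
          wells[[wid]] <- simulate_well(lev, well_id = wid,
                                        panel_id = "dilution_series",
                                        stochastic = stochastic)
        }
      }
      list(level_id = sprintf("L%02d", k), factor = f,
           assigned = assigned,
           assigned_by_channel = tapply(assigned, base$channel_of, sum),
           wells = wells)
    })
  })
}

#' Designs for a relative GM-content series at constant endogene
#'
#' Emulates mixing a GM-positive extract into wild-type DNA so that the
#' endogene stays at a constant copy number per reaction while the summed
#' GM-event content spans a percentage range. GM copies at level `q%` are
#' `endogene_copies * q / 100`, split equally across the GM targets unless
#' a `split` map of proportions is supplied.
#'
#' @param endogene_copies Endogene copies per reaction (positive).
#' @param gm_percent_levels Percentages in `[0, 100]` (0 gives an all-zero
#'   GM design, e.g. a wild-type control).
#' @param gm_targets Character vector of GM target names.
#' @param endogene_target Name of the endogene target.
#' @param split Optional named proportions over `gm_targets` (summing
#'   to 1) for unequal mixes.
#' @param gm_channel,endogene_channel Channel labels.
#' @param ... Further arguments passed to [simulation_design()].
#' @return A list of `sim_design` objects, one per level, with attribute
#'   `gm_percent` on each.
#' @examples
#' ds <- make_relative_series(50000, c(2, 0.1, 0.005), c("ev1", "ev2"))
#' @export
make_relative_series <- function(endogene_copies, gm_percent_levels,
                                 gm_targets, endogene_target = "Le1",
                                 split = NULL, gm_channel = "FAM",
                                 endogene_channel = "HEX", ...) {
  stopifnot(endogene_copies > 0, length(gm_targets) >= 1)
  if (any(gm_percent_levels < 0) || any(gm_percent_levels > 100))
    stop("GM percentages must lie in [0, 100]")
  if (is.null(split)) {
    split <- rep(1 / length(gm_targets), length(gm_targets))
    names(split) <- gm_targets
  } else {
    if (!setequal(names(split), gm_targets) ||
        abs(sum(split) - 1) > 1e-8)
      stop("'split' must cover exactly the GM targets and sum to 1")
    split <- split[gm_targets]
  }
  chan <- c(stats::setNames(rep(gm_channel, length(gm_targets)), gm_targets),
            stats::setNames(endogene_channel, endogene_target))
  lapply(gm_percent_levels, function(q) {
    gm_total <- endogene_copies * q / 100
    targets <- c(gm_total * split,
                 stats::setNames(endogene_copies, endogene_target))
    d <- simulation_design(targets, channel_of = chan, ...)
    attr(d, "gm_percent") <- q
    d
  })
}
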