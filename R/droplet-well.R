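#' One ddPCR well: accepted droplets and positives per channel
#'
#' The primary observation unit of the pipeline. A well records the number
#' of accepted droplets (partitions), the positive-droplet count on each
#' fluorescence channel, the droplet and reaction volumes needed to convert
#' counts to concentrations, and instrument QC flags. Per-droplet
#' fluorescence amplitudes are optional; counts are the primary interface.
#'
#' @param well_id Character scalar identifying the well.
#' @param n_droplets Positive integer, number of accepted droplets.
#' @param positives Named integer vector: positive droplets per channel
#'   (names are channel labels, e.g. `"FAM"`, `"HEX"`). Each entry must be
#'   between 0 and `n_droplets`.
#' @param panel_id Character scalar naming the assay panel.
#' @param droplet_volume Droplet volume in nL (default 0.85).
#' @param reaction_volume Reaction volume in uL (default 20).
#' @param clog Logical, `TRUE` when the instrument flagged a clog.
#' @param amplitudes Optional named list of per-droplet amplitude vectors,
#'   one per channel.
#'
#' @return An object of class `droplet_well`.
#' @examples
#' droplet_well("A01", 15000, c(FAM = 310, HEX = 5200))
#' @export
droplet_well <- function(well_id, n_droplets, positives,
                         panel_id = "panel",
                         droplet_volume = 0.85, reaction_volume = 20,
                         clog = FALSE, amplitudes = NULL) {
  stopifnot(is.character(well_id), length(well_id) == 1L)
  n_droplets <- as.integer(n_droplets)
  if (length(n_droplets) != 1L || is.na(n_droplets) || n_droplets < 1L)
    stop("'n_droplets' must be a single positive integer")
  if (is.null(names(positives)) || any(!nzchar(names(positives))))
    stop("'positives' must be a named vector (names are channel labels)")
  positives <- vapply(positives, as.integer, integer(1))
  if (any(is.na(positives)) || any(positives < 0L) ||
      any(positives > n_droplets))
    stop("each channel's positives must lie in [0, n_droplets]")
  if (!is.numeric(droplet_volume) || droplet_volume <= 0)
    stop("'droplet_volume' (nL) must be > 0")
  if (!is.numeric(reaction_volume) || reaction_volume <= 0)
    stop("'reaction_volume' (uL) must be > 0")
  if (!is.null(amplitudes)) {
    stopifnot(is.list(amplitudes), !is.null(names(amplitudes)))
  }
  structure(
    list(well_id = well_id, panel_id = panel_id,
         n_droplets = n_droplets, positives = positives,
         droplet_volume = as.numeric(droplet_volume),
         reaction_volume = as.numeric(reaction_volume),
         clog = isTRUE(clog), amplitudes = amplitudes),
    class = "droplet_well")
}

#' @export
print.droplet_well <- function(x, ...) {
  cat(sprintf("<droplet_well %s [%s]> %d accepted droplets%s\n",
              x$well_id, x$panel_id, x$n_droplets,
              if (x$clog) " (CLOG)" else ""))
  for (ch in names(x$positives))
    cat(sprintf("  %s: %d positive\n", ch, x$positives[[ch]]))
  invisible(x)
}

#' @export
as.data.frame.droplet_well <- function(x, ...) {
  row <- data.frame(well_id = x$well_id, panel_id = x$panel_id,
                    n_droplets = x$n_droplets,
                    droplet_volume_nl = x$droplet_volume,
                    reaction_volume_ul = x$reaction_volume,
                    clog = x$clog, stringsAsFactors = FALSE)
  for (ch in names(x$positives))
    row[[paste0("positives_", ch)]] <- x$positives[[ch]]
  row
}

channels_of <- function(well) names(well$positives)
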