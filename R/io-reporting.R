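#' Read a droplet-count table
#'
#' The droplet-count schema is a UTF-8 comma-separated table with one row
#' per well and columns `well_id`, `panel_id`, `n_droplets`,
#' `droplet_volume_nl`, `reaction_volume_ul`, `clog` (TRUE/FALSE or 0/1)
#' and one `positives_<CHANNEL>` column per fluorescence channel (e.g.
#' `positives_FAM`, `positives_HEX`). The reader validates rather than
#' coerces: rows whose positives exceed the accepted droplet count, or
#' with non-positive droplet counts, are reported by row number and the
#' read fails.
#'
#' @param path Path to the CSV file.
#' @return List of [droplet_well()] objects.
#' @export
read_droplet_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("well_id", "panel_id", "n_droplets", "droplet_volume_nl",
                "reaction_volume_ul", "clog")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("droplet table is missing column(s): ",
         paste(miss, collapse = ", "))
  pos_cols <- grep("^positives_", names(df), value = TRUE)
  if (!length(pos_cols))
    stop("droplet table has no positives_<CHANNEL> column")
  channels <- sub("^positives_", "", pos_cols)
  bad <- character(0)
  for (i in seq_len(nrow(df))) {
    if (!is.finite(df$n_droplets[i]) || df$n_droplets[i] < 1)
      bad <- c(bad, sprintf("row %d: invalid n_droplets", i))
    for (pc in pos_cols) {
      v <- df[[pc]][i]
      if (!is.finite(v) || v < 0 || v > df$n_droplets[i])
        bad <- c(bad, sprintf(
          "row %d (%s): %s = %s outside [0, n_droplets = %s]",
          i, df$well_id[i], pc, v, df$n_droplets[i]))
    }
  }
  if (length(bad))
    stop("malformed droplet table:\n  ", paste(bad, collapse = "\n  "))
  wells <- lapply(seq_len(nrow(df)), function(i) {
    pos <- stats::setNames(as.integer(unlist(df[i, pos_cols])), channels)
    droplet_well(df$well_id[i], df$n_droplets[i], pos,
                 panel_id = df$panel_id[i],
                 droplet_volume = df$droplet_volume_nl[i],
                 reaction_volume = df$reaction_volume_ul[i],
                 clog = as.logical(df$clog[i]))
  })
  message(sprintf("read %d well(s) from %s", length(wells), path))
  wells
}

#' Write wells in the droplet-count schema
#'
#' @param wells List of [droplet_well()]s (all sharing the same channel
#'   set).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_droplet_table <- function(wells, path) {
  if (!length(wells)) stop("no wells to write")
  rows <- do.call(rbind, lapply(wells, as.data.frame))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  message(sprintf("wrote %d well(s) to %s", length(wells), path))
  invisible(path)
}

#' Read a multiplex panel configuration
#'
#' Panel configurations are JSON with fields `name`, optional
#' `droplet_volume_nl` (default 0.85), optional `min_droplets`
#' (default 8000), `thresholds` (named amplitude thresholds, one per
#' channel) and `targets`, an array of `{name, channel, role}` where
#' role is `"gm"` or `"endogene"`. Exactly one endogene target is
#' required and every target channel must have a threshold.
#'
#' @param path Path to the JSON config.
#' @return A list of class `panel_config` with elements `name`,
#'   `droplet_volume`, `min_droplets`, `thresholds`, `targets`
#'   (data.frame), `gm_channel`, `endogene_channel`.
#' @export
read_panel_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$name) || is.null(cfg$targets) || is.null(cfg$thresholds))
    stop("panel config needs 'name', 'targets' and 'thresholds'")
  targets <- as.data.frame(cfg$targets, stringsAsFactors = FALSE)
  if (!all(c("name", "channel", "role") %in% names(targets)))
    stop("each target needs 'name', 'channel' and 'role'")
  if (!all(targets$role %in% c("gm", "endogene")))
    stop("target roles must be 'gm' or 'endogene'")
  n_endo <- sum(targets$role == "endogene")
  if (n_endo != 1L)
    stop("panel must declare exactly one endogene target (found ",
         n_endo, ")")
  thresholds <- unlist(cfg$thresholds)
  if (any(thresholds <= 0)) stop("amplitude thresholds must be positive")
  unknown <- setdiff(unique(targets$channel), names(thresholds))
  if (length(unknown))
    stop("unknown channel(s) without threshold: ",
         paste(unknown, collapse = ", "))
  structure(
    list(name = cfg$name,
         droplet_volume = cfg$droplet_volume_nl %||% 0.85,
         min_droplets = cfg$min_droplets %||% 8000,
         thresholds = thresholds, targets = targets,
         gm_channel = unique(targets$channel[targets$role == "gm"]),
         endogene_channel = targets$channel[targets$role == "endogene"]),
    class = "panel_config")
}

#' Quantify a set of wells under a panel configuration
#'
#' Applies well QC, estimates per-channel concentrations, and computes
#' each well's summed GM content relative to the endogene channel.
#' QC-rejected wells are logged and excluded from the result table.
#'
#' @param wells List of [droplet_well()]s.
#' @param panel A [read_panel_config()] result.
#' @return data.frame with one row per well and channel (concentration,
#'   CI, copies/reaction) plus `gm_percent` on endogene rows' partners;
#'   attribute `gm` holds per-well [gm_percent()] objects.
#' @export
quantify_wells <- function(wells, panel) {
  stopifnot(inherits(panel, "panel_config"))
  rows <- list(); gm_list <- list()
  for (w in wells) {
    qc <- qc_well(w, panel$min_droplets)
    if (!qc$pass) {
      message(sprintf("well %s rejected: %s", w$well_id,
                      paste(qc$reasons, collapse = ", ")))
      next
    }
    est <- quantify_well(w)
    gm_ch <- panel$gm_channel[1]
    endo_ch <- panel$endogene_channel
    gmq <- if (gm_ch %in% names(est) && endo_ch %in% names(est) &&
               est[[endo_ch]]$conc > 0)
      gm_percent(est[[gm_ch]], est[[endo_ch]]) else NULL
    gm_list[[w$well_id]] <- gmq
    for (ch in names(est)) {
      e <- est[[ch]]
      rows[[length(rows) + 1L]] <- data.frame(
        well_id = w$well_id, panel_id = w$panel_id, channel = ch,
        positives = e$positives, n_droplets = e$n_droplets,
        conc_copies_per_ul = e$conc, ci_low = e$ci_low,
        ci_high = e$ci_high, copies_per_reaction = e$copies_per_reaction,
        saturated = e$saturated,
        gm_percent = if (!is.null(gmq) && ch == gm_ch)
          gmq$gm_percent else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no wells passed QC")
  out <- do.call(rbind, rows)
  message(sprintf("quantified %d well(s), %d rejected",
                  length(gm_list), length(wells) - length(gm_list)))
  attr(out, "gm") <- gm_list
  out
}

#' Write a validation report
#'
#' Emits two files under a common prefix: `<prefix>_levels.csv`, the
#' machine-readable per-level table, and `<prefix>_summary.txt`, a
#' human-readable summary stating every limit, the dynamic-range fit and
#' each acceptance verdict with its observed value and threshold.
#' Output is deterministic: identical outcomes give byte-identical files.
#'
#' @param outcome A [validate_series()] result.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_validation_report <- function(outcome, prefix) {
  stopifnot(inherits(outcome, "validation_outcome"))
  if (!nrow(outcome$level_table)) stop("outcome has no levels")
  levels_path <- paste0(prefix, "_levels.csv")
  summary_path <- paste0(prefix, "_summary.txt")
  tab <- outcome$level_table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) round(x, 6))
  write.csv(tab, levels_path, row.names = FALSE, quote = FALSE)
  con <- file(summary_path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Validation report")
  w("=================")
  w("")
  fmt_lim <- function(lim, practical, label) {
    if (lim$defined)
      w("%s: %.4g copies/reaction (level %s, assigned %.4g; practical %g)",
        label, lim$value, lim$level_id, lim$assigned, practical)
    else w("%s: undefined (no consistently passing level)", label)
  }
  fmt_lim(outcome$lod, outcome$lod_practical, "LOD_abs")
  fmt_lim(outcome$loq, outcome$loq_practical, "LOQ_abs")
  w("")
  if (!is.null(outcome$fit)) {
    f <- outcome$fit
    w("Dynamic range (%d levels >= LOQ): slope %.4f, intercept %.4f,",
      f$n, f$slope, f$intercept)
    w("  R^2 = %.5f vs limit %.2f -> %s", f$r2,
      outcome$thresholds$r2_min, if (f$pass) "PASS" else "FAIL")
  } else {
    w("Dynamic range: not fitted (fewer than 3 quantifiable levels)")
  }
  w("")
  if (!is.null(outcome$acceptance)) {
    w("Acceptance checks:")
    a <- outcome$acceptance
    for (i in seq_len(nrow(a)))
      w("  [%s] level %s %s: %.2f vs limit %.0f%s",
        if (a$pass[i]) "pass" else "FAIL", a$level_id[i], a$check[i],
        a$value[i], a$limit[i],
        if (nzchar(a$reason[i])) paste0(" -- ", a$reason[i]) else "")
  }
  message(sprintf("wrote report: %s, %s", levels_path, summary_path))
  invisible(c(levels_path, summary_path))
}

#' Read a sample sheet
#'
#' CSV with columns `sample_id`, `assigned_value`, `dilution_factor`
#' (>= 1), `lab_id`, `run_id`, `wells` (semicolon-separated well ids).
#'
#' @param path CSV path.
#' @return data.frame with `wells` parsed into a list column.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "assigned_value", "dilution_factor", "lab_id",
            "run_id", "wells")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet is missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(df$dilution_factor < 1))
    stop("dilution factors must be >= 1 (rows: ",
         paste(which(df$dilution_factor < 1), collapse = ", "), ")")
  df$wells <- strsplit(df$wells, ";", fixed = TRUE)
  df
}

#' Read primers/probes from FASTA
#'
#' Record names ending in `_F`, `_R` or `_P` are parsed as the forward
#' primer, reverse primer or probe of the assay named by the remainder
#' (e.g. `lectin_F`).
#'
#' @param path FASTA path.
#' @return data.frame with `name`, `sequence`, `role`, `assay`.
#' @export
read_primer_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  role <- rep(NA_character_, length(nm))
  role[grepl("_F$", nm)] <- "forward"
  role[grepl("_R$", nm)] <- "reverse"
  role[grepl("_P$", nm)] <- "probe"
  if (anyNA(role))
    stop("FASTA names must end in _F, _R or _P: ",
         paste(nm[is.na(role)], collapse = ", "))
  data.frame(name = nm, sequence = as.character(seqs), role = role,
             assay = sub("_[FRP]$", "", nm), stringsAsFactors = FALSE)
}
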