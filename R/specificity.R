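#' @keywords internal
check_seq <- function(x, what = "sequence") {
  x <- toupper(x)
  if (!length(x) || any(!nzchar(x)))
    stop(what, " must be a non-empty DNA sequence")
  if (any(grepl("[^ACGT]", x)))
    stop(what, " may contain only A, C, G, T")
  x
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of ACGT sequences.
#' @return Reverse-complemented sequences.
#' @export
seq_revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTacgt", "TGCAtgca", s)
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' A primer or probe record
#'
#' @param name Oligo name.
#' @param sequence 5'->3' DNA sequence (ACGT only).
#' @param role One of `"forward"`, `"reverse"`, `"probe"`.
#' @param assay Assay (target) the oligo belongs to.
#' @return A one-row data.frame; rows from several calls can be
#'   `rbind`-ed into a panel table.
#' @export
primer_record <- function(name, sequence, role = c("forward", "reverse",
                                                   "probe"),
                          assay = name) {
  role <- match.arg(role)
  data.frame(name = name, sequence = check_seq(sequence), role = role,
             assay = assay, stringsAsFactors = FALSE)
}

#' Primer-dimer interaction score (ungapped local alignment)
#'
#' Scores the propensity of two oligos to form a duplex: the first
#' sequence is slid ungapped along the reverse complement of the second
#' at every relative offset, and each offset's best contiguous segment is
#' scored with +1 per matching base and -1 per mismatch (negative-scoring
#' segments floor at 0, the empty-segment convention). The score is the
#' maximum over offsets; ties report the first offset found. A score of 7
#' or more (a perfect 7-bp duplex, or a longer imperfect one) flags a
#' significant interaction.
#'
#' @param a,b DNA sequences (5'->3').
#' @param threshold Flag threshold (default 7).
#' @return A list of class `dimer_hit`: `primer_a`, `primer_b`, `score`,
#'   `offset` (shift of `a` relative to `revcomp(b)`), `flagged`.
#' @examples
#' dimer_score("ACGTACG", seq_revcomp("ACGTACG"))$score  # 7
#' @export
dimer_score <- function(a, b, threshold = 7) {
  a <- check_seq(a); b <- check_seq(b)
  av <- strsplit(a, "")[[1]]
  rb <- strsplit(seq_revcomp(b), "")[[1]]
  m <- length(av); n <- length(rb)
  best <- 0L; best_off <- 0L
  for (s in (1L - n):(m - 1L)) {
    i0 <- max(1L, 1L + s); i1 <- min(m, n + s)
    if (i0 > i1) next
    v <- ifelse(av[i0:i1] == rb[(i0:i1) - s], 1L, -1L)
    # Kadane: best contiguous segment sum, floored at 0
    cur <- 0L; mx <- 0L
    for (x in v) {
      cur <- max(0L, cur + x)
      mx <- max(mx, cur)
    }
    if (mx > best) { best <- mx; best_off <- s }
  }
  structure(list(primer_a = a, primer_b = b, score = as.integer(best),
                 offset = as.integer(best_off),
                 flagged = best >= threshold),
            class = "dimer_hit")
}

#' Screen every oligo pair of a panel for dimer risk
#'
#' Evaluates [dimer_score()] for each unordered pair of oligos, including
#' self-pairs (an oligo folding back on or dimerising with itself).
#'
#' @param primers data.frame with `name` and `sequence` columns (e.g.
#'   built from [primer_record()]), or a named character vector of
#'   sequences.
#' @param threshold Flag threshold (default 7).
#' @return data.frame with one row per pair: `a`, `b`, `score`, `offset`,
#'   `flagged`; the number of flagged pairs is attached as attribute
#'   `n_flagged`.
#' @export
screen_panel <- function(primers, threshold = 7) {
  if (is.character(primers)) {
    if (is.null(names(primers)))
      names(primers) <- paste0("oligo", seq_along(primers))
    primers <- data.frame(name = names(primers), sequence = primers,
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(primers),
            all(c("name", "sequence") %in% names(primers)),
            nrow(primers) >= 1)
  idx <- which(upper.tri(diag(nrow(primers)), diag = TRUE), arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    h <- dimer_score(primers$sequence[i], primers$sequence[j], threshold)
    data.frame(a = primers$name[i], b = primers$name[j],
               score = h$score, offset = h$offset, flagged = h$flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_flagged") <- sum(out$flagged)
  out
}

#' Enumerate the primer-pair combination space of a multiplex
#'
#' In a multiplex any two primers can in principle generate a product.
#' The combination space screened here pairs *every* primer of the panel
#' (all 2n forward and reverse primers of the n assays) with *every*
#' reverse primer, yielding 2n^2 combinations; this includes each reverse
#' primer paired with itself, the configuration that produces
#' single-primer amplicons at inverted repeats. For 6, 7 and 11 assays
#' this gives 72, 98 and 242 combinations.
#'
#' @param panel data.frame with columns `assay`, `role` (`"forward"` /
#'   `"reverse"`; probe rows are ignored) and optionally `name` and
#'   `sequence`.
#' @return data.frame of combinations with columns `left_name`,
#'   `right_name` (and `left_seq`, `right_seq` when sequences are
#'   present).
#' @examples
#' p <- rbind(primer_record("a_F", "ACGT", "forward", "a"),
#'            primer_record("a_R", "TTGC", "reverse", "a"))
#' nrow(enumerate_combinations(p))  # 2
#' @export
enumerate_combinations <- function(panel) {
  stopifnot(is.data.frame(panel), all(c("assay", "role") %in% names(panel)))
  panel <- panel[panel$role %in% c("forward", "reverse"), , drop = FALSE]
  if (is.null(panel$name))
    panel$name <- paste(panel$assay, substr(panel$role, 1, 1), sep = "_")
  tab <- table(panel$assay, panel$role)
  if (!all(tab == 1))
    stop("every assay must contribute exactly one forward and one ",
         "reverse primer")
  rev_idx <- which(panel$role == "reverse")
  grid <- expand.grid(left = seq_len(nrow(panel)), right = rev_idx,
                      KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(left_name = panel$name[grid$left],
                    right_name = panel$name[grid$right],
                    stringsAsFactors = FALSE)
  if (!is.null(panel$sequence)) {
    out$left_seq <- panel$sequence[grid$left]
    out$right_seq <- panel$sequence[grid$right]
  }
  out
}

# Annealing sites of a primer on the forward strand of a template, with
# up to max_mismatch substitutions and no gaps. orientation "fwd" matches
# the primer itself (primer acts leftward, extending right); "rev"
# matches its reverse complement (primer acts rightward).
primer_sites <- function(primer, template, max_mismatch,
                         orientation = c("fwd", "rev")) {
  orientation <- match.arg(orientation)
  pat <- if (orientation == "fwd") primer else seq_revcomp(primer)
  if (nchar(pat) > nchar(template)) return(NULL)
  hits <- Biostrings::matchPattern(pat, Biostrings::DNAString(template),
                                   max.mismatch = max_mismatch,
                                   with.indels = FALSE)
  if (!length(hits)) return(NULL)
  st <- Biostrings::start(hits); en <- Biostrings::end(hits)
  mm <- vapply(seq_along(st), function(i) {
    sub <- substring(template, st[i], en[i])
    sum(strsplit(sub, "")[[1]] != strsplit(pat, "")[[1]])
  }, integer(1))
  data.frame(start = st, end = en, mismatches = mm)
}

#' Mismatch-tolerant in-silico PCR
#'
#' Predicts the amplicons a primer pair would generate on a set of
#' template sequences. Each primer may anneal with up to
#' `max_mismatch` substitutions (no gaps, counted anywhere in the primer
#' including the 3' terminus). A product is reported for every convergent
#' pair of sites -- one primer matching the forward strand, the other's
#' reverse complement downstream of it -- within `max_amplicon`. Both
#' role assignments are considered (either primer may be the leftmost),
#' and a single primer can prime both directions across an inverted
#' repeat (`left` equal to `right`), which yields single-primer
#' amplicons. Coordinates are 0-based half-open on the forward strand.
#'
#' @param left,right Primer sequences (may be identical for
#'   single-primer screens). Optionally named via `left_name` /
#'   `right_name`.
#' @param templates Named character vector of template sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param max_mismatch Maximum substitutions per primer (default 1).
#' @param max_amplicon Maximum product length in bp (default 2000).
#' @param left_name,right_name Primer labels for the report.
#' @return data.frame of class `amplicon_prediction` with columns
#'   `template`, `left_primer`, `right_primer`, `start`, `end`, `length`,
#'   `mismatches_left`, `mismatches_right`, `sequence`. Zero rows when
#'   nothing amplifies.
#' @examples
#' tpl <- c(t1 = paste0(strrep("A", 50), "GACGTACGTTGCA",
#'                      strrep("C", 50), "TGCAACGTACGTC", strrep("A", 20)))
#' @export
insilico_pcr <- function(left, right, templates, max_mismatch = 1,
                         max_amplicon = 2000,
                         left_name = "left", right_name = "right") {
  left <- check_seq(left); right <- check_seq(right)
  if (methods::is(templates, "DNAStringSet"))
    templates <- stats::setNames(as.character(templates), names(templates))
  if (!length(templates)) stop("'templates' must be non-empty")
  templates <- check_seq(templates, "template")
  if (is.null(names(templates)))
    names(templates) <- paste0("template", seq_along(templates))
  if (any(nchar(c(left, right)) > max(nchar(templates))))
    stop("primer longer than every template")
  same <- identical(left, right)
  orientations <- list(list(l = left, r = right,
                            ln = left_name, rn = right_name))
  if (!same)
    orientations <- c(orientations,
                      list(list(l = right, r = left,
                                ln = right_name, rn = left_name)))
  rows <- list()
  for (tn in names(templates)) {
    tpl <- templates[[tn]]
    for (o in orientations) {
      fs <- primer_sites(o$l, tpl, max_mismatch, "fwd")
      rs <- primer_sites(o$r, tpl, max_mismatch, "rev")
      if (is.null(fs) || is.null(rs)) next
      for (i in seq_len(nrow(fs))) for (j in seq_len(nrow(rs))) {
        if (fs$start[i] == rs$start[j] && fs$end[i] == rs$end[j]) next
        if (rs$start[j] < fs$start[i] || rs$end[j] < fs$end[i]) next
        len <- rs$end[j] - fs$start[i] + 1L
        if (len > max_amplicon) next
        if (len < max(nchar(o$l), nchar(o$r))) next
        rows[[length(rows) + 1L]] <- data.frame(
          template = tn, left_primer = o$ln, right_primer = o$rn,
          start = fs$start[i] - 1L, end = rs$end[j], length = len,
          mismatches_left = fs$mismatches[i],
          mismatches_right = rs$mismatches[j],
          sequence = substring(tpl, fs$start[i], rs$end[j]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(template = character(0), left_primer = character(0),
               right_primer = character(0), start = integer(0),
               end = integer(0), length = integer(0),
               mismatches_left = integer(0), mismatches_right = integer(0),
               sequence = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("amplicon_prediction", "data.frame")
  out
}

#' Run in-silico PCR over a whole combination table
#'
#' @param combinations Output of [enumerate_combinations()] carrying
#'   `left_seq` / `right_seq` columns.
#' @param templates As in [insilico_pcr()].
#' @param ... Passed to [insilico_pcr()].
#' @return One `amplicon_prediction` data.frame over all combinations.
#' @export
insilico_pcr_all <- function(combinations, templates, ...) {
  stopifnot(all(c("left_seq", "right_seq") %in% names(combinations)))
  res <- lapply(seq_len(nrow(combinations)), function(i)
    insilico_pcr(combinations$left_seq[i], combinations$right_seq[i],
                 templates,
                 left_name = combinations$left_name[i],
                 right_name = combinations$right_name[i], ...))
  out <- unique(do.call(rbind, res))
  rownames(out) <- NULL
  class(out) <- c("amplicon_prediction", "data.frame")
  out
}

#' Which probes would detect a predicted amplicon?
#'
#' A predicted product only yields a false-positive droplet signal if a
#' labelled probe can hybridise to it. A probe matches when its sequence
#' or its reverse complement occurs in the amplicon with at most
#' `max_mismatch` substitutions.
#'
#' @param amplicon Amplicon sequence (character).
#' @param probes Named character vector of probe sequences, or a
#'   data.frame with `name`/`sequence`.
#' @param max_mismatch Maximum substitutions (default 1).
#' @return Character vector of matching probe names (empty when the
#'   product is detection-silent).
#' @export
probe_match <- function(amplicon, probes, max_mismatch = 1) {
  amplicon <- check_seq(amplicon, "amplicon")
  if (is.data.frame(probes))
    probes <- stats::setNames(probes$sequence, probes$name)
  if (is.null(names(probes)))
    names(probes) <- paste0("probe", seq_along(probes))
  hit <- vapply(probes, function(p) {
    p <- check_seq(p, "probe")
    if (nchar(p) > nchar(amplicon)) return(FALSE)
    subj <- Biostrings::DNAString(amplicon)
    length(Biostrings::matchPattern(p, subj, max.mismatch = max_mismatch,
                                    with.indels = FALSE)) > 0 ||
      length(Biostrings::matchPattern(seq_revcomp(p), subj,
                                      max.mismatch = max_mismatch,
                                      with.indels = FALSE)) > 0
  }, logical(1))
  names(probes)[hit]
}
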