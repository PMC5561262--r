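# Shared fixtures and independent oracles, built in code.

withr_local_dir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

withr_local_file <- function(name, env = parent.frame()) {
  file.path(withr::local_tempdir(.local_envir = env), name)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Nine synthetic 20-mers designed to be mutually orthogonal (every
# pairwise and self dimer score < 7); frozen from a seeded search.
ortho_oligos <- function() c(
  sA_F = "AACGTATAGTTCATCGAGAA", sA_R = "CAATCACAAAGCCGCGAGCC",
  sA_P = "AGTTTTCCCCATGCTTAATT",
  sB_F = "CAGTTCGCGAGAGCAGTACG", sB_R = "CTTACACTGGCTTCCACCCT",
  sB_P = "ACTGTCCGGTGATAACCTGG",
  sC_F = "CCGGATAGCCTCCCTCTTCA", sC_R = "AAACCTGGTGACCCGCAGCT",
  sC_P = "CTCCTGCGGCGAGTTATGGC")

ortho_panel <- function(include_probes = TRUE) {
  o <- ortho_oligos()
  df <- data.frame(name = names(o), sequence = unname(o),
                   role = rep(c("forward", "reverse", "probe"), 3),
                   assay = rep(c("sA", "sB", "sC"), each = 3),
                   stringsAsFactors = FALSE)
  if (include_probes) df else df[df$role != "probe", , drop = FALSE]
}

# Generic n-assay primer panel for combination-count checks (sequences
# irrelevant there).
generic_panel <- function(n) {
  do.call(rbind, lapply(seq_len(n), function(i) rbind(
    primer_record(sprintf("a%02d_F", i), "ACGTACGTACGTACGTACGT",
                  "forward", sprintf("a%02d", i)),
    primer_record(sprintf("a%02d_R", i), "TTGCGCGCATATATGCGCAA",
                  "reverse", sprintf("a%02d", i)))))
}

# Exhaustive dimer-score oracle: every offset of a against revcomp(b),
# every contiguous segment, +1/-1 scoring floored at 0.
brute_dimer_score <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  rb <- strsplit(seq_revcomp(toupper(b)), "")[[1]]
  m <- length(av); n <- length(rb)
  best <- 0L
  for (s in (1L - n):(m - 1L)) {
    i0 <- max(1L, 1L + s); i1 <- min(m, n + s)
    if (i0 > i1) next
    v <- ifelse(av[i0:i1] == rb[(i0:i1) - s], 1L, -1L)
    for (from in seq_along(v)) for (to in from:length(v))
      best <- max(best, sum(v[from:to]))
  }
  best
}

# Exact-substring oracle for in-silico PCR at zero mismatches: 1-based
# start positions of pattern in template.
substr_starts <- function(pattern, template) {
  out <- integer(0); from <- 1L
  repeat {
    hit <- regexpr(pattern, substring(template, from), fixed = TRUE)
    if (hit == -1L) break
    out <- c(out, from + hit - 1L)
    from <- from + hit       # allow overlapping hits
  }
  out
}

# Template with one exact product: left primer at 0-based [100, 120),
# revcomp(right) at [280, 300), probe inside the amplicon.
make_template_A <- function(oligos = ortho_oligos()) {
  set.seed(8101)
  paste0(random_seq(100), oligos[["sA_F"]], random_seq(60),
         oligos[["sA_P"]], random_seq(80), seq_revcomp(oligos[["sA_R"]]),
         random_seq(200))
}

# Inverted-repeat template: one primer and its reverse complement placed
# so the single-primer product spans `total` bp end-to-end.
make_template_ir <- function(primer, total = 207, flank = 150,
                             seed = 8102) {
  set.seed(seed)
  gap <- total - 2L * nchar(primer)
  stopifnot(gap >= 0)
  paste0(random_seq(flank), primer, random_seq(gap), seq_revcomp(primer),
         random_seq(flank))
}

# Level with an exactly prescribed mean and sample RSD: spread standard
# scores (mean 0, n-1 sd 1) around the target mean.
mk_level <- function(id, assigned, mean_val, rsd, n_negative = 0, n = 12) {
  sdv <- rsd / 100 * mean_val
  vals <- mean_val + sdv * as.numeric(scale(seq_len(n)))
  level_stats(id, assigned, vals, n_negative = n_negative)
}

# Dilution-series designs emulating the standard mix-1 validation
# experiment for the three panel sizes (stock copies/uL per GM-event;
# two events run lower than the 128 copies/uL default).
standard_assay_designs <- function() list(
  `6plex` = list(events = stats::setNames(rep(128, 5), paste0("ev", 1:5)),
                 reps = c(4, 4, 4)),
  `7plex` = list(events = c(ev1 = 128, ev2 = 128, ev3 = 128, ev4 = 128,
                            A2704.12 = 49, MON89788 = 92),
                 reps = c(4, 4, 6)),
  `11plex` = list(events = c(stats::setNames(rep(128, 8),
                                             paste0("ev", 1:8)),
                             A2704.12 = 49, MON89788 = 92),
                  reps = c(4, 4, 4)))
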