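test_that("dimer_score matches the hand-derived duplex cases", {
  a <- "ACGTACG"
  h <- dimer_score(a, seq_revcomp(a))
  expect_identical(h$score, 7L)     # perfect 7-bp duplex
  expect_true(h$flagged)

  h0 <- dimer_score("AAAAAA", "AAAAAA")  # revcomp is TTTTTT: no matches
  expect_identical(h0$score, 0L)
  expect_false(h0$flagged)

  expect_error(dimer_score("", "ACGT"), "non-empty")
  expect_error(dimer_score("ACGU", "ACGT"), "only A, C, G, T")
})

test_that("dimer_score is symmetric and equals the exhaustive oracle", {
  set.seed(61)
  for (i in 1:30) {
    a <- random_seq(sample(6:15, 1))
    b <- random_seq(sample(6:15, 1))
    expect_identical(dimer_score(a, b)$score, dimer_score(b, a)$score)
    expect_identical(dimer_score(a, b)$score, as.integer(brute_dimer_score(a, b)))
  }
  # self-pairs too
  for (i in 1:5) {
    a <- random_seq(sample(8:15, 1))
    expect_identical(dimer_score(a, a)$score, as.integer(brute_dimer_score(a, a)))
  }
})

test_that("screen_panel flags planted interactions and nothing else", {
  clean <- screen_panel(ortho_oligos())
  expect_identical(nrow(clean), 45L)        # 9 oligos: 36 pairs + 9 self
  expect_identical(attr(clean, "n_flagged"), 0L)

  # plant a complementary pair: exactly one flagged interaction
  bad <- c(ortho_oligos()[1:4],
           trap1 = "GGCCATTACGGAT", trap2 = seq_revcomp("GGCCATTACGGAT"))
  scr <- screen_panel(bad)
  flagged <- scr[scr$flagged, ]
  expect_identical(nrow(flagged), 1L)
  expect_setequal(c(flagged$a, flagged$b), c("trap1", "trap2"))

  single <- screen_panel(c(solo = "ACGGATCCATTTGGA"))
  expect_identical(nrow(single), 1L)        # one self-hit evaluated
})

test_that("enumerate_combinations yields the 2n^2 scheme", {
  expect_identical(nrow(enumerate_combinations(generic_panel(6))), 72L)
  expect_identical(nrow(enumerate_combinations(generic_panel(7))), 98L)
  expect_identical(nrow(enumerate_combinations(generic_panel(11))), 242L)
  for (n in 1:20)
    expect_identical(nrow(enumerate_combinations(generic_panel(n))),
                     as.integer(2 * n^2))
  # reverse self-pairs are part of the space
  combs <- enumerate_combinations(generic_panel(3))
  expect_true(any(combs$left_name == combs$right_name))
  # probes are ignored; missing primers are an error
  expect_identical(nrow(enumerate_combinations(ortho_panel())), 18L)
  broken <- generic_panel(2)[-2, ]
  expect_error(enumerate_combinations(broken), "exactly one")
})

test_that("insilico_pcr reports convergent sites with exact coordinates", {
  o <- ortho_oligos()
  fwd <- o[["sA_F"]]; rev <- o[["sA_R"]]
  set.seed(71)
  tpl <- paste0(random_seq(100), fwd, random_seq(160),
                seq_revcomp(rev), random_seq(200))
  # forward site [100,120), revcomp site [280,300) -> product [100,300)
  amp <- insilico_pcr(fwd, rev, c(t1 = tpl), max_mismatch = 0)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$start, 100L)
  expect_identical(amp$end, 300L)
  expect_identical(amp$length, 200L)
  expect_identical(amp$length, amp$end - amp$start)

  # strand invariance: the reverse-complement template gives the same
  # product mirrored
  amp_rc <- insilico_pcr(fwd, rev, c(t1 = seq_revcomp(tpl)),
                         max_mismatch = 0)
  expect_identical(nrow(amp_rc), 1L)
  expect_identical(amp_rc$length, amp$length)
  expect_identical(amp_rc$start, nchar(tpl) - amp$end)
  expect_identical(amp_rc$end, nchar(tpl) - amp$start)
  expect_identical(amp_rc$sequence, seq_revcomp(amp$sequence))

  expect_error(insilico_pcr(fwd, rev, c(t = "ACGT")), "longer")
})

test_that("a single primer amplifies across an inverted repeat", {
  primer <- ortho_oligos()[["sB_R"]]
  tpl <- make_template_ir(primer, total = 207)
  amp <- insilico_pcr(primer, primer, c(syn_ir = tpl), max_mismatch = 1,
                      left_name = "sB_R", right_name = "sB_R")
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$length, 207L)
  expect_identical(amp$left_primer, amp$right_primer)
  # one mismatch in a site is still found, two are not
  mut1 <- tpl                                # corrupt one base of a site
  substr(mut1, 161, 161) <- if (substr(tpl, 161, 161) == "A") "C" else "A"
  expect_identical(nrow(insilico_pcr(primer, primer, c(t = mut1),
                                     max_mismatch = 1)), 1L)
  expect_identical(nrow(insilico_pcr(primer, primer, c(t = mut1),
                                     max_mismatch = 0)), 0L)
})

test_that("insilico_pcr at zero mismatches equals exact substring search", {
  set.seed(81)
  o <- ortho_oligos()
  fwd <- o[["sC_F"]]; rev <- o[["sC_R"]]
  for (i in 1:8) {
    # random template with 0-3 planted site pairs
    k <- sample(0:3, 1)
    parts <- random_seq(120)
    for (j in seq_len(k))
      parts <- paste0(parts, fwd, random_seq(sample(30:150, 1)),
                      seq_revcomp(rev), random_seq(120))
    amp <- insilico_pcr(fwd, rev, c(t = parts), max_mismatch = 0,
                        max_amplicon = 10000)
    f_starts <- substr_starts(fwd, parts)
    r_ends <- substr_starts(seq_revcomp(rev), parts) + nchar(rev) - 1L
    expected <- 0L
    for (fs in f_starts) for (re in r_ends)
      if (re - fs + 1L >= max(nchar(fwd), nchar(rev)) && re >= fs + nchar(fwd) - 1L)
        expected <- expected + 1L
    expect_identical(nrow(amp), expected)
  }
})

test_that("probe_match honours mismatches and both strands", {
  o <- ortho_oligos()
  probes <- o[c("sA_P", "sB_P", "sC_P")]
  set.seed(91)
  amp <- paste0(random_seq(40), o[["sA_P"]], random_seq(40))
  expect_identical(probe_match(amp, probes), "sA_P")

  # reverse-strand-only occurrence still matches
  amp_rc <- paste0(random_seq(40), seq_revcomp(o[["sB_P"]]), random_seq(40))
  expect_identical(probe_match(amp_rc, probes), "sB_P")

  # one substitution tolerated, none with max_mismatch = 0
  p <- o[["sC_P"]]
  substr(p, 10, 10) <- if (substr(p, 10, 10) == "G") "T" else "G"
  amp_mm <- paste0(random_seq(30), p, random_seq(30))
  expect_identical(probe_match(amp_mm, probes), "sC_P")
  expect_identical(probe_match(amp_mm, probes, max_mismatch = 0),
                   character(0))

  # a product silent to every probe
  expect_identical(probe_match(random_seq(120), probes), character(0))
})

test_that("the synthetic panel screen is clean and finds only the planted products", {
  panel <- ortho_panel()
  tplA <- make_template_A()
  tplIR <- make_template_ir(ortho_oligos()[["sB_R"]])
  combos <- enumerate_combinations(panel)
  amps <- insilico_pcr_all(combos, c(tplA = tplA, tplIR = tplIR),
                           max_mismatch = 1)
  expect_identical(nrow(amps), 2L)
  byt <- split(amps, amps$template)
  expect_identical(byt$tplA$length, 200L)
  expect_identical(byt$tplIR$length, 207L)
  # the intended product carries its probe; the inverted-repeat product
  # is detection-silent
  probes <- panel[panel$role == "probe", ]
  expect_identical(probe_match(byt$tplA$sequence, probes), "sA_P")
  expect_identical(probe_match(byt$tplIR$sequence, probes), character(0))
})
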