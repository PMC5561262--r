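---
title: "Multiplex ddPCR quantification and validation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplex ddPCR quantification and validation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddplexr)
```

# The statistical model

A droplet digital PCR reaction of volume $V_{rxn}$ (µL) is partitioned
into $n$ accepted droplets of volume $V_d$ (nL). Template molecules of
target $i$ distribute over droplets as independent Poisson counts with
mean

$$\lambda_i = \frac{c_i}{V_{rxn}}\,V_d,$$

where $c_i$ is the copy number per reaction. A droplet is positive on a
fluorescence channel when it received at least one copy of *any* target
reporting on that channel, so the per-droplet positive probability on a
channel is $1 - e^{-\sum_i \lambda_i}$. This additivity is the whole
basis of summed one-channel multiplex quantification: a single channel
carrying all GM-event assays of a species measures the total GM copy
number, which is the regulated quantity (labelling thresholds apply per
ingredient). `estimate_concentration()` inverts the model:
$\hat p = x/n$, $\hat\lambda = -\ln(1-\hat p)$,
$\hat c = \hat\lambda / V_d$. Relative GM content is the copy ratio
$100\,\hat c_{GM}/\hat c_{endo}$ — reported directly against certified
mass/mass values, with no zygosity or conversion-factor correction.

**Assumptions.** Independent Poisson occupancy (no droplet coalescence,
no template aggregation), equal droplet volumes, perfect classification
of droplets given the counts, and statistical independence between
channels. Partial PCR inhibition does not bias the estimate as long as
positive droplets still amplify above threshold.

**Confidence intervals.** The delta method gives
$SE(\hat\lambda) = \sqrt{p/(n(1-p))}$; intervals use $z = 1.96$ and are
clamped at zero. The GM ratio uses the independent-ratio delta method,
and panel sums add variances. No CI method is canonical for ddPCR; the
normal approximation is accurate for the droplet counts (thousands) and
positive fractions this pipeline targets, and degrades only at a
handful of positive droplets, where results sit below the LOQ anyway.

**Saturation.** At $p = 1$ the estimator diverges; we substitute
$p = (n-\tfrac12)/n$, report the result as a lower bound and set
`saturated = TRUE`. This keeps downstream arithmetic finite while
signalling out-of-range.

**Well QC.** A well is rejected when the instrument flagged a clog or
fewer than 8000 droplets were accepted per 20 µL reaction. The
comparison is strict (`< 8000`), so exactly 8000 droplets passes.

**Replicate aggregation.** The default mode of `replicate_merge()`
averages per-well concentration estimates, because repeatability RSDs
are defined across replicate reactions. A `"pool"` mode (sum positives
and droplets, estimate once) is provided for merged-well workflows.
Whether original validation datasets averaged per-replicate GM% or
pooled droplets is not documented anywhere we know of; both modes are
first-class and tested.

# Validation statistics and decision rules

* **Bias (trueness):** $100(\text{measured}-\text{assigned})/\text{assigned}$,
  printed to one decimal. Printed tables round *half away from zero* —
  base R's `round()` is round-half-even and would turn $96.3/2 = 48.15$
  into 48.1 instead of the printed 48.2 — so the package carries a
  `round_half_up()` convention. All threshold comparisons use unrounded
  values; rounding is presentation only.
* **RSD:** $100\,s/\bar x$ with the $n-1$ sample standard deviation
  (the denominator is never stated in validation guidance; $n-1$ is the
  conventional choice). Undefined — and flagged, not silently zero —
  for $n<2$ or $\bar x = 0$.
* **LOD:** the least-concentrated level such that it *and every more
  concentrated level* had zero negative replicates. "Consistently" is
  interpreted as an unbroken run from the top of the series: one
  negative replicate at a stronger level breaks eligibility for
  everything below it. The reported value is the mean measured copy
  number of the qualifying level.
* **LOQ:** the same rule with replicate RSD strictly below 25%. Note
  the deliberate asymmetry kept from the source conventions: the LOQ
  *rule* is strict (`RSD < 25%`) while the acceptance *checklist* is
  inclusive (`RSD ≤ 25%`).
* **Practical limits:** `practical_limit()` rounds a limit up to the
  nearest 10 copies (a 38-copy LOQ is reported as 40 copies/reaction),
  mirroring conservative reporting practice. Both raw and practical
  values are returned.
* **Relative limits:** identical rules applied to GM% levels;
  `relative_from_absolute()` converts a copy-number limit at a given
  endogene basis (39 copies at 50 000 endogene copies → 0.08% at
  two-decimal rounding).
* **Dynamic range:** ordinary least squares of measured on assigned
  copies on the raw scale (as such series are conventionally plotted),
  not log scale; linearity is the squared Pearson correlation with an
  acceptance bound of $R^2 \ge 0.98$, fitted over levels at or above
  the LOQ (at least three).
* **Acceptance contexts:** bias is always judged against ±25%
  (inclusive). RSD limits depend on context: 25% for quantification,
  35% for between-day repeatability, 50% for low-copy samples
  (< ~100 copies/reaction), where guidance is deliberately less strict.
* **Robustness:** a modified protocol passes when its mean deviates
  from the original by strictly less than 25% (computed as a bias of
  modified vs original mean, on unrounded data) *and* its replicate RSD
  stays within the 35% repeatability limit. Published robustness tables
  computed deviations on unrounded data too: recomputing from printed
  rounded means reproduces them only approximately, which is expected
  and documented rather than "fixed".
* **Inter-laboratory summary:** RSD$_r$ within each lab; RSD$_R$ pools
  every individual replicate across labs into a single RSD (no
  variance-components model — none is specified by the guidance this
  mirrors). A lab with one replicate contributes to bias only. Note a
  small degrees-of-freedom consequence of pooling with the $n-1$ sd:
  two labs with *identical* result sets give
  RSD$_R$ = RSD$_r\sqrt{2(n-1)/(2n-1)}$, approaching equality as $n$
  grows. The test suite asserts this exact relation.

# The in-silico specificity screen

* **Dimer score.** `dimer_score(a, b)` slides `a` ungapped along the
  reverse complement of `b` at every offset and scores each offset's
  best contiguous segment at +1/match, −1/mismatch, floored at zero
  (empty-segment convention). The score is the maximum over offsets;
  ties report the first offset. A score of 7 — a perfect 7-bp duplex or
  a longer imperfect one — flags a significant interaction. Exhaustive
  enumeration over all offsets and segment boundaries serves as the
  test oracle. Tie-breaking beyond "first offset" is not observable in
  the score and is left unspecified.
* **Combination space.** `enumerate_combinations()` pairs every one of
  the $2n$ primers of an $n$-assay panel with every reverse primer:
  $2n^2$ combinations (72, 98, 242 for $n$ = 6, 7, 11). This scheme is
  pinned because it reproduces those counts exactly and contains the
  reverse-primer-with-itself pairs that generate single-primer products
  at inverted repeats. Whether forward×forward pairs belonged to the
  original screening space cannot be decided from the counts; under
  this scheme they do not. Probes are screened for dimers but excluded
  from the combination space (the count arithmetic implies primers
  only).
* **In-silico PCR.** A primer anneals where it matches the template
  with at most one substitution (default), counted anywhere in the
  primer including the 3′ terminus — no 3′-anchor rule is applied
  because none is specified for the screen this reproduces — and no
  gaps. Products are reported for every convergent site pair within
  2000 bp (configurable; real products of interest are ~100–300 bp),
  in 0-based half-open forward-strand coordinates, considering both
  role assignments of the pair. Identical left and right primers yield
  single-primer inverted-repeat products, e.g. the 207-bp geometry the
  shipped synthetic template reproduces. Site search is delegated to
  `Biostrings::matchPattern`; the pairing, orientation and length logic
  is owned here and checked against an exact-substring oracle at zero
  mismatches.
* **Probe matching.** A predicted product only matters for droplet
  readouts if a labelled probe hybridises to it: `probe_match()` checks
  both strands at ≤1 substitution. A product matched by no probe is
  detection-silent (it may still consume primers, which the screen does
  not model).

# The synthetic droplet generator

The generator exists so every downstream stage is testable without
instrument exports. It emulates the *statistical* structure the
estimator assumes and the standard experimental designs:

* independent Poisson occupancy per target per droplet, one shared
  GM channel plus an endogene channel;
* accepted droplet counts drawn uniformly from 12 000–17 000 per well
  (instrument-realistic variation; fixable to a constant);
* droplet volume 0.85 nL by default — instrument software versions have
  used values in the 0.83–0.91 nL range and rarely disclose them, so
  the value is configurable and all arithmetic carries it explicitly;
* reaction volume 20 µL, template volume 4 µL, hence the standard mix-1
  design: per-event stocks of 128 copies/µL (49 and 92 for the two
  events whose materials run lower) give 512/196/368 copies per
  reaction and panel sums of 2560/2612/4660 — matching the published
  assigned values 2557/2612/4658 within verification rounding. Where an
  experimentally re-assigned value is preferred, pass it via `events`;
  the generator does not guess which is canonical;
* dilution factors 6× to 12000×, replicate layouts 12 (4+4+4) or
  14 (4+4+6) over three runs; relative series at a constant 50 000
  endogene copies with GM content 0.005–2%, split equally across GM
  targets unless a split map is given;
* Gaussian amplitude clusters per channel with spreads defaulting to 5%
  of the cluster mean, for exercising threshold classification
  (inclusive comparison: amplitude ≥ threshold is positive).

**What it deliberately does not model:** PCR efficiency, "rain"
(intermediate amplitudes beyond Gaussian tails), droplet coalescence,
partial inhibition, or clog physics (clogs are injected boolean flags).
Consequently a green simulation-based test establishes that the
estimator and decision rules are implemented correctly and are
self-consistent — it does **not** establish wet-lab performance. One
visible consequence: in the pure-Poisson world, detection at very low
copy numbers is *better* than published experiments (a 4-copy level is
positive in all 14 replicates ~40% of the time), so simulated LOD
values scatter at and below the empirical ones. The acceptance check
therefore brackets the mean LOD/LOQ over three panel sizes and three
pre-registered seeds in [5, 30] and [25, 60] copies/reaction, intervals
containing the published 8–18 and 38–39.

# Numerical conventions

* All randomness flows through explicit seeds: a design seed makes a
  simulated well or series fully reproducible, and the RNG state of the
  caller is restored afterwards.
* Thresholds are compared on unrounded values; half-up rounding is
  applied only where a printed-table value is being reproduced.
* Degenerate inputs fail loudly: empty amplitude vectors warn and
  return zero; undefined RSDs are `NA`, never zero; readers reject
  invariant-violating rows (positives exceeding droplets) by row number
  instead of coercing.
* The LOD/LOQ scan is monotone by construction: flipping any replicate
  negative or raising any RSD can only move a limit toward higher
  concentration (property-tested).

# Known limitations

* The delta-method CI undercovers slightly when fewer than ~10 droplets
  are positive; exact binomial alternatives were not implemented
  because all quantitative decisions are gated at the LOQ.
* `insilico_pcr` enumerates site pairs exhaustively per template; it is
  intended for screening panels of assays against insert/flanking
  sequences and small genomic regions, not for whole-genome scans.
* The robustness and inter-laboratory helpers summarise data handed to
  them; they do not model lab effects.
* Amplitude simulation supports classification round-trips and
  misclassification-rate arguments, not cluster-calling research.
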