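---
title: "Methods: contact-map analysis of the bacterial nucleoid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact-map analysis of the bacterial nucleoid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoidC)
```

# Scope and model

`nucleoidC` analyzes ultra-high-resolution chromosome conformation capture
(Micro-C) maps of a single bacterial chromosome, where three elementary
structure classes dominate the distance-detrended signal:

* **Chromosomal hairpins (CHINs)** — loci symmetric around a center
  interact pairwise, producing an anti-diagonal ridge near the main
  diagonal. Stems span roughly 0.5–6 kb with a median near 2 kb, sit in
  AT-rich horizontally-transferred-gene (HTG) islands, and carry a bimodal
  H-NS/StpA ChIP signature on the two stem arms with a dip at the apex.
* **Hairpin domains (CHIDs)** — clusters of mutually overlapping
  alternative hairpins; a population average, since overlapping hairpins
  cannot coexist in one cell.
* **Operon-sized contact domains (OPCIDs)** — square on-diagonal domains
  coinciding with actively transcribed operons, with an enriched
  promoter–terminator (TSS–TES) corner dot whose strength grows with
  transcription activity.

The package provides the measurement machinery (balancing, expected
models, pile-ups, endpoint statistics, shuffle tests, RNA–DNA contact
quantification, detectors) and a synthetic-nucleoid generator that plants
all of these structures with known parameters, so every stage has a
ground-truth acceptance surface.

All coordinates are 0-based half-open on one chromosome; operon tables
declared `#coords=1-based-inclusive` are converted on read. Distances are
linear — no wrap across the replication origin — matching the upstream
contact-map tool stack, even though the chromosome is circular;
circularity is carried as metadata.

# Contact matrices and balancing

Contacts are stored sparsely as upper-triangular binned counts
(`contact_matrix`). `ice_balance()` performs iterative correction:
per-bin multiplicative weights are iterated until the coefficient of
variation of the balanced marginals falls below `tol` (default `1e-5`,
cap 400 iterations), then rescaled so unmasked balanced marginals average
one. Bins with zero marginal, and bins whose log marginal falls more than
`mad_max = 5` median absolute deviations *below* the median, are masked.

The MAD filter is deliberately one-sided. On deep synthetic maps without
per-bin biases, the dispersion of log marginals is tiny, and a two-sided
filter at 5 MADs would mask precisely the bins whose marginals are raised
by genuine planted structure — hairpin stems and domains — before any
detector sees them. Standard balancing practice filters under-covered
bins (repeats, deletions) only; a `mad_side = "both"` option retains the
symmetric rule for users who want it.

A related, less obvious property of iterative correction matters for
interpretation: on a map with *no* bin biases, ICE still equalizes
marginals, and a block feature that raises its bins' marginals (a 20-bin
square domain at 2× raises them by ~30%) is partly divided back out. The
balanced obs/exp of such a domain reads ~1.15, not 2. This is not an
implementation artifact — it is what marginal equalization does — and it
is why the tests that read back planted enrichments use unit weights (the
exact balance of a bias-free simulated map), while ICE's own contract
(convergence, oracle agreement, masking) is tested separately.

## Expected model and scaling

`expected_by_distance()` gives the per-diagonal mean of balanced values
over unmasked pairs, with the first `ignore_diags = 2` diagonals
undefined. The smoothed variant pools diagonals within geometric distance
bins (ratio 1.05) as `sum(diagonal sums)/sum(valid pairs)`; this is
piecewise constant rather than interpolated because pooling preserves the
total balanced mass per geometric bin exactly (to well below the `1e-9`
contract), which interpolation would break.

`scaling_curve()` reports mean raw contact frequency per bin pair in
log-spaced separation bins, normalized to unit integral beyond
`min_dist = 100` bp; a planted power-law decay with exponent α reproduces
a log–log slope of −α.

## Replicate reproducibility (SCC)

`scc()` implements the stratum-adjusted correlation coefficient: raw maps
are smoothed with a truncated 2D mean filter of half-width `h = 30` bins,
per-diagonal Pearson correlations are combined with weights
`N_d · sqrt(var(rank(x)/N) var(rank(y)/N))`. Two numerical choices:

* Ranks are taken on values rounded to 9 significant digits. Smoothed
  sparse counts contain exact ties, and a tie broken differently by
  `1e-15` float noise shifts the rank variance enough to move the SCC at
  the `1e-5` level; rounding makes the statistic implementation-stable.
* `max_dist` defaults to 5 kb. In this system the distance-detrended
  signal lives below ~6 kb (hairpin stems, operon-scale domains); strata
  far beyond the structure scale contain only Poisson noise, which can
  only dilute a replicate correlation. Users comparing maps with
  longer-range structure should raise it.

# Pile-ups and profiles

`local_rescaled_pileup()` averages on-diagonal obs/exp windows
(`[start − flank·L, end + flank·L)`) over features, rescaling each window
to a fixed pixel grid by area-weighted block averaging — each target
pixel averages the source bins it covers with fractional-coverage
weights. Block averaging is mass-preserving and deterministic for both
down- and up-sampling, which is why it is used instead of an
interpolation kernel; undefined pixels (masked bins, ignored diagonals)
are excluded from every average rather than zero-filled. 2D pile-ups are
not strand-flipped; 1D profiles are.

`signal_profile_around()` rescales each feature body to a fixed number of
positions with flanks kept at bp scale (an anchored mode is available),
reverses minus-strand features, and attaches a feature-resampling
bootstrap standard error (default 100 replicates, seeded).

# TSS–TES contact statistic

For each operon, the observed statistic sums ICE-balanced contacts in the
block formed by two 40-bp windows (4 bins at 10 bp; use 400 bp at 100 bp
resolution) centred at the oriented TSS and TES; windows snap to bin
boundaries with ties snapping left. The expected value averages the same
quantity over 10 random intervals of identical length placed uniformly on
the genome (windows at the interval ends), one seeded RNG stream per
operon so results are reproducible operon-by-operon. Placements are
confined to keep endpoint windows inside the linear genome, and
placements landing on >50% masked bins are redrawn (bounded, can be
disabled via `max_resample = 0`). The intra-operon control moves both
anchors 20% of the operon length inward from the oriented ends.

Activity grouping follows the two published schemes: quartile-style
groups of `redc_signal` rank (bottom 50%, 50–75%, 75–90%, top 10%) with
an optional strictly-greater length filter at the median operon length
(1,343 bp in the reference annotation), or zero-signal operons separated
first and the rest split by `redc_density` (bottom 50%, 50–90%, top 10%).
Ranks use average ties so labels are order-invariant.

# Shuffle colocalization test

`shuffle_test()` counts A-intervals whose overlap with the union of B
covers at least `f = 0.1` of their length, re-places A uniformly
(lengths preserved, overlaps allowed, no exclusion regions) 1,000 times,
and reports `p = min(N_greater, N_less)/N_shuffles` with strict
inequalities — the published formula, implemented verbatim. Two
consequences are documented rather than silently "fixed":

* the formula can return exactly 0; `p_floor = 1/n_shuffles` flags the
  resolution, and a conservative `(min+1)/(n+1)` variant is available;
* taking the *minimum* of two one-sided tail ratios without doubling
  makes the null rate of `p < a` about `2a`, plus an excess from ties on
  discrete overlap counts (measured ≈0.12–0.16 at `a = 0.05`). The test
  is powerful and direction-aware, but its p-values are anti-conservative
  at nominal level; treat thresholds accordingly.

# Red-C transcription activity

A feature's activity is the total multiplicity of RNA–DNA contacts whose
RNA coordinate lies in the feature and whose DNA coordinate maps within
10 kb (inclusive) of the RNA coordinate — RNA captured near its parental
locus. Mapping coordinates are taken as the single positions given in the
contacts table; multiplicity handling is explicit (no deduplication).
`redc_profile()` applies the same rule per genomic bin.

# Detectors

Detection operates on `log(obs/exp + 0.1)` (the pseudo-value avoids
−∞ on empty pixels) and is fully deterministic.

* **Hairpins** (`detect_chins`): every bin center is scored by Pearson
  correlation between its local window (half-width 12 bins, separations
  ≥ `ignore_diags`) and a bank of seven nested binary anti-diagonal ridge
  templates (`|i + j − 2c| ≤ 2`, extents geometric from 4 bins to the
  window span); the best template wins. The bank exists because a single
  template cannot cover 0.5–6 kb stems: short stems leave most of a large
  template empty, while windows small enough to match them have too few
  pixels for the 0.3 correlation threshold to be significant against
  thousands of scanned centers. With ~290-pixel windows, 0.3 is ≈5 SD of
  the null correlation, which keeps genome-wide false calls near zero.
  Candidates at or above threshold undergo non-maximum suppression within
  1 kb; stem extent is then estimated by step-fitting the anti-diagonal
  ridge profile — the extent maximizes the cumulative excess of the
  smoothed ridge obs/exp over the midpoint between baseline and peak,
  which is robust to local noise dips, unlike a first-crossing rule.
* **Hairpin domains** (`cluster_chids`): maximal chains of calls whose
  footprints lie within 1 kb, with at least 2 members.
* **OPCIDs** (`opcid_score`): log *median* pixel obs/exp inside the
  operon square minus the mean log median of two same-size flanking
  squares. The median (not the mean named in early drafts of the design)
  makes the score specific: a hairpin ridge crossing a silenced region
  shifts only a minority of pixels and scores ≈0, while a true square
  domain shifts the majority and scores ≈log(enrichment).
* **Hairpin–hairpin contacts** (`chin_contact_score`): pooled obs/exp
  (ratio of sums) in the rectangle where two stems intersect; ≈1 under
  the null, ≈ the planted enrichment over a dot of comparable scale.

No second-pass refinement at finer resolution is performed; detection
runs at the map's own resolution (100 bp in the synthetic default).

# The synthetic nucleoid

The generator states a world once and the tests live in it:

* 500 kb chromosome at 100 bp (5,000 bins), 2×10⁶ contacts — deep enough
  that per-cell intensities at structure scale are O(1)–O(10), small
  enough for seconds-scale tests; a full 4,641,652 bp mode exists.
* power-law decay `λ ∝ max(d,1)^−1.1`; features multiply λ, so each
  feature's obs/exp equals its enrichment analytically, and λ is
  normalized so the upper triangle sums to the stated depth exactly.
* hairpins: stem enrichment 3×, cross-section 2 bins, extents lognormal
  (median 2 kb, log-sd 0.5, clipped 0.5–6 kb), placed only inside HTG
  islands; domain members are staggered 1.5 kb apart so their footprints
  overlap while their apexes remain resolvable at 100 bp.
* OPCIDs: square enrichment 2× on the most active operons with a
  Gaussian TSS–TES corner dot whose strength is a fixed monotone function
  of planted activity (`1 + 2·density/median`).
* Red-C: per-operon Poisson counts at the planted rate; displacements
  Gaussian with 90% of mass within 10 kb (`sd = 10 kb / qnorm(0.95)`).
* ChIP tracks: H-NS-like bumps at `center ± extent/4` (sd `extent/8`)
  over a Poisson noise floor — two stem-arm peaks with an apex dip;
  RNAP-like plateaus over active operons.

Sampling is Poisson per upper-triangle cell with per-stream seeds derived
from one base seed; truths and all samples are bit-identical across runs.

What a green test does **not** establish: the generator has no long-range
plaid/CID structure, no supercoiling-driven features, no per-bin
coverage biases (GC, mappability), no repeat-induced masking patterns,
and its hairpin stems have a fixed cross-section (the real stem width is
unknown; 2 bins is a stated free parameter, not a claim about data). Real
maps add all of these, so detector thresholds transferred to real data
deserve re-validation against manual annotation.

# Degenerate inputs and tie-breaks

Windows and squares snap to bin boundaries with ties snapping left;
features whose padded windows leave the linear genome are dropped and
counted; zero-variance detection windows yield no call rather than a
score; expected ratios with zero denominators are flagged `NA`, never 0;
an all-masked diagonal has undefined, not zero, expected value.

# Known limitations

* p-values of the verbatim shuffle formula are anti-conservative (above).
* ICE attenuates block enrichments on bias-free maps (above); obs/exp
  read-backs on synthetic data are exact only under unit weights.
* SCC requires dense smoothing; matrices beyond 20,000 bins are refused
  rather than silently subsampled.
* The pipeline is single-chromosome by design; trans contacts and
  multi-replicon genomes are out of scope.
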