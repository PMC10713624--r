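---
title: "Models and methods behind adarkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind adarkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adarkit)
```

# Scope

`adarkit` reimplements the computational workflow of hairpin-reporter
screens of ADAR substrate specificity: library design, read simulation
under explicit enzyme models, per-adenosine quantification, detection of
the fixed editing offsets that structural disruptions induce, an
open/closed structure metaplot for endogenous sites, and offset-aware
arRNA design. Everything runs on synthetic data produced by the packaged
generators; no external sequencing data, folding engine or annotation
download is required. This vignette records the models, the parameter
choices and the numerical conventions, including the places where the
design was genuinely open and a choice had to be made.

# The reporter library

A reporter is a hairpin with a constant upper arm (146 bp by default), a
loop (46 nt) and a lower arm that is the reverse complement of the upper
arm. Perturbations are applied only to the lower arm, so the sequenced
upper arm is identical across a library and reads can be demultiplexed by
an 8-nt barcode placed 3' of the hairpin. Since barcode placement is
recorded in the manifest, quantification is placement-agnostic.

Coordinates are 0-based and half-open throughout. A duplex *register* `r`
means position `r` of the upper arm together with the lower-arm base
pairing it (lower-arm string index `L - 1 - r` for a stem of length `L`).

Design choices worth recording:

* **Mismatch substitution rule.** A mismatch at register `r` replaces the
  lower-arm base with the *identity* of its upper-arm partner (X opposite
  X). This guarantees a broken pair, is deterministic, and never creates
  an A·C pair — which matters because an A opposite a C is itself an
  editing-activating configuration and would confound a mismatch series.
* **Random disruptions** substitute each chosen register with one of the
  two bases that neither pair with nor match the upper base, drawn
  uniformly under a recorded seed.
* **Barcodes.** Rather than rejection sampling, barcodes with pairwise
  Hamming distance >= 2 are drawn from a check-digit code: the eighth base
  is the modular checksum of the first seven, so two distinct codewords
  differ in at least two positions by construction. Sampling of the 4^7
  prefixes is deterministic given the configured seed. Larger minimum
  distances fall back to greedy rejection.
* The synthetic default backbone (`example_backbone()`) is a random
  146-nt arm with exactly 44 adenosines, emulating the adenosine content
  of the synthetic reporter used in the screens. It is a synthetic
  stand-in: the published reporter sequences are not reproduced.

# The enzyme model

`editing_probability()` composes four factors, clamped to [0, 1]:

```
p = clamp( baseline * context * induction * suppression )
```

Distances are measured on the adenosine's own strand to each disruption
center: negative = the adenosine lies 5' (upstream) of the disruption.
Even-length disruption centers round toward the 5' side of the strand
being measured — a convention, not a fact about enzymes; the tests only
rely on it being applied consistently on both strands.

* **Baseline** is the per-adenosine editing probability on a perfect
  duplex: 0.5 for the ADAR2-like preset and 0.4 for the ADAR1-like one,
  chosen so that roughly half (respectively slightly fewer) of the 44
  adenosines are edited per molecule, matching the reported per-molecule
  medians (~22 and ~18 of 44).
* **Induction** is a triangular window of fold-change centered at the
  enzyme's offset: `1 + (fold - 1) * max(0, 1 - |d - offset|/(hw + 1))`
  with half-width `hw = 3` nt. The presets use −26 nt at fold 1.4
  (ADAR2-like) and −35 nt at fold 4.0 with a +30 secondary peak at fold
  1.5 (ADAR1-like), inside the reported fold ranges (~1.3–1.5 and
  ~3.3–6). A triangular peak rather than a boxcar makes the smoothed
  maximum well defined at the offset itself. With several disruptions the
  strongest induction applies.
* **Suppression** is a per-distance multiplier over −26..+29 with its
  minimum (0–0.05) at the disrupted register (distance 0 for ADAR1-like,
  +1 for ADAR2-like enzymes), partial local maxima at −9 and +6/+7, an
  extra local maximum at +15 for ADAR2-like enzymes, and recovery to 1 at
  the window edges. Only the window extent, the minimum location and the
  local-maximum positions are constrained by the screens; the magnitudes
  at the local maxima are unquantified there, so the piecewise-linear
  values in `default_suppression()` are a declared modelling choice. With
  several disruptions the strongest suppression applies.
* **Context** multiplies by a −1/+1-neighbour factor; the default matrix
  penalizes a G immediately 5' of the adenosine (0.3×) and is otherwise
  close to neutral, reflecting the shared deaminase-domain preference.
* **A·C boost.** An adenosine directly opposite an engineered C is
  boosted (1.5×) instead of suppressed; this one configuration is treated
  multiplicatively, independent of suppression by other disruptions.

Editing events are independent across adenosines within a molecule — the
simplest generative model consistent with the reported per-molecule
medians; real molecules likely show processive correlations that this
model deliberately omits.

# Read simulation

Per construct, `Poisson(coverage)` molecules are drawn (default coverage
4000, the screens' mean per-barcode depth); each adenosine of the modeled
arm is independently converted A→G with its model probability; uniform
substitution errors (default 0.001/base) are then applied independently
to each mate, and constant-quality Phred+33 FASTQ is emitted (mate 1 from
the amplicon 5' end, mate 2 reverse-complemented from the 3' end, default
100 nt each). The amplicon is `anchor + arm + barcode + anchor` with fixed
12-nt anchors. One RNG seed governs every draw, so output is
byte-identical across runs. Lower-arm editing requires the profile's
`symmetric` flag, with distances measured on the lower strand's own 5'→3'
axis.

Not modeled, deliberately: realistic Illumina error/quality profiles, PCR
duplicates, expression differences between enzymes (absolute levels are
confounded by overexpression in the screens and the package never
compares them across enzymes).

# Quantification and filters

Mates are merged by exact-overlap truncation: for each amplicon length in
the manifest, the suffix of mate 1 must equal the corresponding prefix of
the reverse-complemented mate 2 over at least 15 nt; any disagreement
drops the pair. This is a conservative, testable reading of "custom
truncation and matching"; with the default error rate it discards a few
percent of pairs, which is immaterial at the simulated depths. Merged
reads are then filtered: wrong anchors; barcode not an exact manifest
match (the distance-2 code makes single-error barcodes unambiguous
failures, and near-miss rescue would risk cross-talk); length
inconsistent with the barcode's construct; disagreement with the
reference at any non-adenosine position; any base other than A/G at an
adenosine position. The last rule is the package's interpretation of
discarding reads "misaligning at adenosine positions": a C or T at a
reference adenosine cannot be explained by editing and indicates
misassignment. Every dropped pair is tallied by reason, and kept +
dropped = input is a tested invariant.

Editing percent is `100 * G/(A + G)` per adenosine; zero-coverage
positions are missing, never 0%. Per-molecule edit counts and Pearson
replicate correlations (two-sided, t-distribution with n − 2 df) follow
directly.

# Offset analysis

Δ editing is the per-adenosine difference between a perturbed construct
and the perfect duplex; positions with reference editing <= 1% are
excluded from pooling (the screens' inclusion rule). Each construct of a
sliding series contributes `(distance, Δ)` points with the disruption
centered at 0; pooling uses all (construct, adenosine) points rather than
per-construct means, mirroring the per-distance percentile bands of the
screens' figures.

Smoothing is LOESS — locally weighted *linear* regression (degree 1,
tricube weights) with span interpreted as the fraction of points per
neighbourhood — via `stats::loess` with exact (`surface = "direct"`)
evaluation at the observed distances. Degree 1 is a declared choice (the
figure legends invoke LOESS without degree); the suite cross-checks the
fit against a longhand local-regression oracle. Default spans follow the
screens: 0.05 for sliding mismatches, 0.11 for bulges, 0.07 for
opposite-base series.

The peak is the argmax of the smoothed curve in a window of [−45, −15] —
wide enough that −26- and −35-class enzymes are both callable without
retuning — and the trough the argmin in [−5, +5]; exact ties break toward
the smaller absolute distance, and a curve whose windowed maximum is not
positive is flagged `no_induction`. Bulge-series distances are measured
from the insertion register on the unperturbed register scale (the
flanking-register alternative would shift every distance by at most one).

# Structure metaplot

Dot-bracket strings (balanced, non-crossing; pseudoknots are rejected —
structure prediction itself is out of scope and dot-bracket is an input)
are classified per position into stem, hairpin loop, bulge, internal
loop, multiloop and exterior by loop topology. "Open" means any non-stem
label: the endogenous analysis dichotomizes stem versus "loop or bulge"
without saying how multiloop or exterior positions were treated, and
any-non-stem is the reading that preserves that dichotomy.

Element pairs are filtered as in the endogenous analysis: both in UTRs,
oppositely oriented, within 2000 nt of each other, no third element in
the window spanning the pair. "Within 2000 nt" is measured as the gap
between the elements.

For each qualifying site (editing > 3%), the 81 offsets of the 80-nt
window are annotated open/closed/missing; per offset, sites split by that
annotation and the difference in mean editing is tested with a two-sided
Welch t-test (the source analysis says only "t-test"; unequal variances
are the safe default) and Benjamini–Hochberg adjustment across the 81
offsets (no multiplicity procedure is stated there; reporting unadjusted
significance over 81 correlated tests would be indefensible). Offsets
with a group smaller than 5 are reported untestable.

The element generator builds fold-back hairpins (100-bp arms, 30-nt
loop) with 3–6 short unpaired runs per arm and couples editing to
structure through one rule: a site is elevated (+15 editing-percent over
a baseline of 8, Gaussian noise SD 1.5) exactly when the structure is
open at the enzyme's characteristic downstream position (+35 for a −35
profile). Coupling at the exact offset — rather than anywhere in the
induction window — keeps the generator's ground truth unambiguous; the
smearing of the recovered differential to neighbouring offsets then comes
only from the autocorrelation of open runs, which is what the metaplot
must see through. What passing recovery tests show is therefore that the
window bookkeeping, the split and the test are correct — not that real
GTEX-derived editing tables would yield equally clean peaks.

# Guide design

All non-empty modes start from the 151-nt scaffold: the reverse
complement of the 151-nt target window centered on the target A, with a C
opposite the A (75 + 1 + 75). The ADAR2-selective mode adds a 3-nt
disruption whose near edge sits 26 bp (optionally 27) from the target A;
the ADAR1-selective mode a 4-nt disruption at 35 bp. Two conventions had
to be fixed:

* **Distance reference**: "26 or 27 bases away" is measured to the
  disruption's *near edge*, the more conservative reading.
* **Disruption side**: the disruption is placed 3' of the target A on its
  own strand, so the A sits at the induction offset (−26) established by
  the sliding-mismatch analysis; this is also the only placement
  consistent with an engineered disruption un-pairing an off-target 26 nt
  downstream of the target.

Engineered mismatch bases follow the same X-opposite-X rule as the
library. Off-target prediction flags non-target adenosines at the
enzyme's induction offset from any engineered disruption (including the
central A·C) on either side of it — induction is symmetric across the
duplex strands, and observed arRNA off-targets sit on the mirror side —
with mechanism tags separating the canonical upstream side from the
mirror side; adenosines un-paired by a disruption are tagged `depleted`
instead. Amplicon quantification reports non-target adenosines above 2%
as observed off-targets.

# Problem sizes and verification

The test suite and the acceptance script run entirely on synthetic data
at desk scale: the full 144-construct 3-nt sliding-mismatch series at
1000 reads per barcode for the offset recoveries (upper arm for both
enzyme classes, lower arm for the symmetric check), 500 structured
elements for the metaplot recovery and its null, and unit fixtures with
20–80-bp stems elsewhere. At these sizes each end-to-end recovery takes
seconds to tens of seconds and the recovered constants are stable across
seeds (the induction signal-to-noise at 1000× coverage is large: the
−26-nt peak is ~+18 Δ-editing-percent against a per-distance standard
error below 1).

Null behaviour is verified two ways: a null enzyme (fold 1, flat
suppression, neutral context) keeps the smoothed Δ curve within 3× the
Monte-Carlo standard error of each per-distance mean, and a null element
generator yields a flat metaplot with no offset surviving BH adjustment
at 1%.

# Known limitations

* The generative model is binomial and positionally independent; it
  cannot produce per-molecule editing correlations, hyper-edited
  molecules, or coverage-expression coupling.
* Suppression-profile magnitudes between anchor points are modelling
  choices; only their topology is constrained.
* The structure generator produces nested fold-backs only; crossing
  interactions and multi-element duplexes are not represented, and the
  element classifier deliberately rejects pseudoknots.
* Guide designs are evaluated in silico against the enzyme model;
  absolute editing efficiencies at endogenous loci are out of scope.
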