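---
title: "Methods: models, parameters and design choices in dualspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in dualspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualspec)
```

`dualspec` analyzes how a dual-specificity protein lysine
methyltransferase (PKMT) such as PRDM9 discriminates between its two
histone substrates, H3K4 and H3K36. This vignette is the package's own
account of the underlying models, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where more than one reasonable choice existed.

## Transition-state-like conformations

MD simulations cannot break or form bonds, so catalytic competence is
estimated geometrically: a frame counts as resembling the S~N~2
transition state of methyl transfer when all three criteria hold for
the target-lysine N&epsilon;, the cofactor methyl carbon C and the
cofactor sulfur S:

* d(N&epsilon;, C) < `dMax` (default 4 Å, **strict** inequality);
* attack angle between the C&delta;–N&epsilon; bond and the
  N&epsilon;&rarr;C direction within `attackCenter` ± `attackTol`
  (default 109° ± 30°, **inclusive** bounds);
* transfer-axis angle N&epsilon;–C–S within `linearCenter` ±
  `linearTol` (default 180° ± 30°, inclusive).

The asymmetry (strict distance, inclusive angles) mirrors the
convention the criteria are usually quoted in ("< 4 Å" vs "in a range
of"); at double precision it is unobservable on real data but it makes
the contract testable. Angles are computed from vector dot products
with the cosine clamped to [−1, 1]; the suite cross-checks them
against an independent law-of-cosines evaluation to 10^−9^ degrees.
Coincident atoms make an angle undefined and raise an error rather
than returning NaN.

The four atoms are located by atom-name convention (lysine `CD`/`NZ`;
cofactor `CE`/`SD`, the AdoMet names) with a full override map in
`resolveAtomMap()`, because cofactor naming varies across force-field
dialects.

### Binning and the exact test

Per-simulation TS counts are compared between substrates by binning
each simulation into *high* or *low* and applying a two-sided Fisher's
exact test. The binning threshold used in the original analyses of
this kind is not standardized, so the rule is a named, configurable
strategy reported in every output: the default is the **median of the
pooled per-simulation counts, ties assigned low** (strictly greater
than the threshold means high). This is reproducible and
parameter-free; a `fixed` threshold is available for sensitivity
scans. Because the true binning of any given published dataset may
differ, the package reports the p-value it computes together with the
2×2 table and the rule, rather than claiming to reproduce a particular
printed p-value.

The test itself sums hypergeometric probabilities, over all tables
with the observed margins, of tables no more probable than the
observed one (relative tie tolerance 10^−7^, the usual convention).
Probabilities come from `lchoose`, i.e. log-gamma, which is exact to
floating precision at any margin size; the suite verifies agreement
with a full `dhyper` enumeration to 10^−12^ on every table with
margins up to 12 and with `stats::fisher.test` (used only as an
independent oracle, never as the implementation).

The substrate-level effect size is the pooled TS-frequency ratio. Two
pooling bases are computed because published "x-fold" statements
rarely say which one they use: frame-weighted pooling
(&Sigma; ts / &Sigma; frames per substrate, the default) and the mean
of per-simulation fractions. Both appear in the report.

## Contact-fraction maps

Two residues are in contact in a frame when at least one pair of
non-hydrogen atoms between their selections lies strictly below the
cutoff (default 4.5 Å). "Heteroatom" in the usual contact-map sense is
interpreted as **any heavy atom**, since carbon-mediated hydrophobic
contacts (e.g. arginine–tyrosine stacking) must count. Peptide
selections are side-chain heavy atoms; glycine has no heavy side-chain
atom and is automatically promoted to all atoms. Sequence-neighbour
exclusion (|&Delta;resno| &le; 1 by default) applies only within one
chain: it is an artifact guard for intra-chain contacts and must never
remove the peptide–enzyme pairs the analysis is about.

The contact fraction is frames-in-contact / frames; the profile stores
integer counts, so fraction × n is an integer by construction.
Replicate simulations are pooled frame-weighted (summed counts over
summed frames), not as a mean of per-run fractions — the two differ
when runs have different lengths, and both are accessible. Fractions
are kept at full precision; rounding to two decimals is display-only.

## SPOT specificity arrays

Each specificity-scan array substitutes every position around the
target lysine (−3…+5 for the H3 1–15/K4 template, −4…+4 for the H3
29–43/K36 template; position 0 is the target lysine itself) with each
of the 18 proteinogenic residues other than tryptophan and cysteine
(excluded from synthesis for side-reaction and oxidation reasons). The
processing order is fixed: **per-array min-max normalization first,
then replicate averaging** — each replicate is mapped through
(x − min)/(max − min) using that array's extrema, then spots are
averaged across replicates. A constant array has no defined
normalization and raises an error instead of dividing by zero.

Per-spot replicate error is the mean absolute deviation from the
replicate mean, which for duplicates is |a − b|/2. "Mean absolute
error between duplicates" is ambiguous at n = 2, so the full-spread
variant |a − b| is available via `errorType = "range"`; the choice is
recorded on the profile. QC counts spots whose error strictly exceeds
a threshold on the percent scale.

The discrimination factor of residue *a* at position *p* is

$$DF(p, a) = \frac{\bar{I}(p, a) + \varepsilon}
  {\frac{1}{17}\sum_{b \neq a} (\bar{I}(p, b) + \varepsilon)}$$

the preference for *a* relative to the average of all alternatives at
that position. The exact formula used in earlier array studies is not
restated in the literature the package follows, so this
ratio-to-mean-of-others definition — the direct formalization of the
verbal definition — is adopted and tagged on the output
(`reference = "mean_of_others"`) so an alternative can be swapped in
without ambiguity. &epsilon; (default 10^−6^ on the normalized scale)
only guards all-zero rows; DF is scale-invariant per position up to
&epsilon; effects. Ranking is DF-descending with deterministic
alphabetical tie-breaks.

## Progress-curve kinetics

Methylation time courses for the two substrates are fitted jointly to

$$\mathrm{Signal}_s(t) = A + B\,(1 - e^{-k_s t}), \qquad s \in \{\mathrm{H3K4}, \mathrm{H3K36}\}$$

with **A and B shared** between the curves. The initial rate is the
slope at t = 0, B·k, so sharing B makes the initial-rate ratio equal
the rate-constant ratio exactly — that identity is what justifies
quoting a single fold-preference from the fit. Times are minutes
throughout; unit conversion is the caller's job.

Numerical choices: Levenberg–Marquardt (`minpack.lm::nls.lm`) with the
analytic Jacobian; initialization A&#8320; = min signal,
B&#8320; = max − min, and k&#8320; from a through-origin log-linear
fit of −log(1 − (S − A&#8320;)/B&#8320;) against t; B and both rates
bounded below by 10^−12^. All replicate experiments enter one
unweighted residual (a combined fit), with per-experiment fitting
possible by subsetting the input. Flat signals are rejected as
degenerate before optimization. Standard errors are the Gauss–Newton
covariance approximation &sigma;&sup2;(J&#7488;J)^−1^ at the optimum
and the ratio error is the delta method including the k4–k36
covariance; outputs label them as approximations since the underlying
experiments provide no replication structure at the level of the
fitted curve. On noiseless model data the fit recovers parameters to
10^−6^ relative error with residuals below 10^−10^ (tested), and
rescaling time by c scales both rates by 1/c leaving the ratio
unchanged (tested).

Mutant preference ratios use first-order error propagation,
ratio · sqrt((sem&#8324;/mean&#8324;)² + (sem&#8323;&#8326;/mean&#8323;&#8326;)²),
verified against a 10^5^-draw Monte-Carlo at ≤ 10 % relative errors.
Non-positive means (abolished activity) flag the ratio as undefined
rather than returning a misleading number.

## The synthetic-data generator

The generator produces inputs with exactly the statistical structure
each stage assumes, so planted parameters can be recovered and every
code path exercised without trajectories, membranes or gels.

* **Toy complex ensembles.** A minimal atom set (lysine C&delta;/N&epsilon;,
  cofactor methyl C/S, one heavy atom per planted contact residue) in
  which, per frame, the reaction geometry is drawn comfortably inside
  the TS region with probability `tsFraction`, and otherwise violates
  **exactly one** randomly chosen criterion by at least
  `geometryNoise` (default 5°; `geometryNoise/10` Å for the
  distance). No frame ever sits on a boundary, so classifier tests
  cannot flake. Planted contacts are placed at `in_distance` in an
  independent Bernoulli subset of frames and `out_distance` otherwise,
  in spatially separated blocks so non-planted pairs never touch. A
  random rigid motion per frame keeps the data from being axis-aligned
  while leaving every analyzed quantity invariant. Defaults encode the
  study design: 5000 frames per simulation at a 20 ps stride (100 ns
  runs), 21 simulations per substrate in 7 equilibration batches of 3.
* **Arrays.** Intensity = weight + Gaussian(0, `noiseSd`), clipped at
  0 (autoradiography signals are non-negative); replicates differ only
  in noise. `defaultSpotWeights()` plants qualitatively realistic
  preferences (e.g. R/K at −2 and A/T/V at −3 for H3K4; I/V at −1 and
  P at +2 for H3K36) over a tolerated baseline, with near-zero signal
  when the target lysine itself is substituted.
* **Progress curves.** Exact shared-model signals plus Gaussian noise.

All randomness flows from one integer seed through a fixed
stream-splitting rule (one derived sub-seed per replicate/experiment,
kept inside 32-bit range), so equal seeds give bit-identical outputs.

### Study-condition calibration

Where the study design states values, the defaults are those values:
21 simulations × 5000 frames, duplicate arrays of 18 residues × 9
positions, 3 kinetic experiments, and a planted wild-type rate ratio
k4/k36 = 5.2. Where it does not, one realistic value was chosen and
fixed:

* absolute rate k4 = 0.15 min^−1^ (saturation within a 60 min course,
  a typical scale for peptide methylation assays), A = 0.05, B = 1 on
  the wild-type-normalized scale, 8 time points over 0–60 min,
  kinetic noise SD 0.05 (5 % of the amplitude);
* per-simulation TS fractions bimodal — H3K4: 14 simulations at 0.14
  and 7 at 0.010; H3K36: 4 at 0.10 and 17 at 0.006 — reproducing both
  the observation that high-activity simulations are much more
  abundant with H3K4 and a pooled frame-weighted enrichment of
  ≈ 4.0-fold;
* array noise SD 0.05 (H3K4) and 0.12 (H3K36) on the normalized
  scale. Under the duplicate error model the per-spot error is
  half-normal with scale &sigma;/&radic;2, so these values put the
  expected number of spots exceeding the 10 % (H3K4) and 20 % (H3K36)
  error thresholds at roughly one to three per 162-spot array — the
  reproducibility level reported for careful SPOT experiments.

These are modelling choices made once, not quantities fitted to any
output.

### What the generator does *not* emulate

No force field, thermostat, solvent, or temporal autocorrelation:
frames are independent draws, whereas real MD frames 20 ps apart are
correlated, so binomial recovery bounds that hold here are optimistic
for real trajectories. Contact geometry is planted pairwise and cannot
produce cooperative multi-residue rearrangements. Array noise is
homoscedastic Gaussian, while autoradiography noise grows with
intensity. Kinetic noise ignores gel-loading covariance between lanes
of one experiment. Passing the recovery tests therefore demonstrates
correctness of the estimators, not that real data meet their
assumptions.

## Trajectory input and numbering

Supported coordinate sources: the plain frame-table dialect (one row
per atom per frame; self-describing, used by the generator), PDB
(single- or multi-model), and DCD alongside a PDB topology, both via
`bio3d`. XTC is not supported. Residue labels keep their native
numbering — peptide residues the H3 numbering, enzyme residues the
enzyme numbering (e.g. `E:Y361`) — and nothing user-visible is
re-indexed to 0-based. Whether hydrogens were stripped upstream does
not matter: every selection mode excludes them explicitly.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full study-scale
configurations (42 × 5000-frame ensembles, 200-replicate kinetic
recovery, exhaustive Fisher enumeration to margin 12) in well under a
minute on one core; the generator is vectorized over frames, which is
what makes these sizes cheap. Pipeline reports embed the resolved
configuration and seed, and rerunning from an embedded configuration
reproduces the report byte-for-byte.

## Known limitations

* The high/low binning rule and the discrimination-factor formula are
  field conventions without a single canonical definition; both are
  configurable and tagged in outputs, and conclusions sensitive to
  them should be checked under the alternatives.
* Fisher's exact test conditions on both margins; with 21 simulations
  per substrate its discreteness makes p-values coarse.
* The Gauss–Newton standard errors understate uncertainty when
  residuals are autocorrelated within an experiment.
* Contact fractions are reported without uncertainty; frames are
  correlated in real trajectories, so naive binomial errors would be
  anti-conservative and are deliberately not printed.
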