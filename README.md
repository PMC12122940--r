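# dualspec

Dual-substrate specificity analysis for protein lysine
methyltransferases (PKMTs).

PRDM9 is unusual among PKMTs: it trimethylates two histone marks,
H3K4 and H3K36, whose surrounding sequences share essentially no
residues. Dissecting how one active site reads two unrelated motifs
takes three complementary quantitative readouts, and `dualspec`
implements the downstream analysis for all of them:

1. **TS-like conformation scanning in MD trajectories.** A trajectory
   frame is classified as resembling the S\_N2 transition state of
   methyl transfer when, for the target lysine N&epsilon;, the AdoMet
   methyl carbon C and the AdoMet sulfur S:

   - d(N&epsilon;, C) &lt; 4 Å,
   - the attack angle &theta;(C&delta;–N&epsilon;, N&epsilon;&rarr;C) = 109° ± 30°,
   - the transfer axis &theta;(N&epsilon;–C–S) = 180° ± 30°.

   Per-simulation TS-frame counts are binned into high/low classes and
   substrate enrichment is tested with a two-sided Fisher's exact test
   (exact log-space hypergeometric enumeration, implemented in the
   package).

2. **Peptide–enzyme contact maps.** A residue pair is in contact in a
   frame if any heavy-atom pair between the two side chains (all atoms
   for glycine) lies below 4.5 Å; the contact fraction is the
   proportion of frames in contact, pooled frame-weighted over
   replicate simulations.

3. **SPOT specificity arrays and progress-curve kinetics.** Replicate
   arrays are min-max normalized, averaged with per-spot error
   (|a−b|/2 for duplicates), and summarized as per-position
   discrimination factors DF(p, a) = mean(p, a) / mean over all other
   residues at p. Methylation time courses for both substrates are
   fitted jointly to Signal = A + B(1 − exp(−k t)) with **shared A and
   B**, so the initial-rate ratio reduces exactly to
   k<sub>H3K4</sub>/k<sub>H3K36</sub>.

A synthetic-data generator plants known TS fractions, contact
fractions, array preferences and rate constants, so the entire
pipeline is testable end-to-end without raw trajectories, membranes or
gel images.

## Worked example

```r
library(dualspec)

# one 100 ns synthetic simulation: 12% TS-like frames planted,
# two planted side-chain contacts
ens <- makeToyComplexEnsemble(0.12, nFrames = 5000, seed = 101,
  contacts = contactPlant(c("P:R2", "P:T3"), c("E:Y361", "E:A287"),
                          c(0.9, 0.55)))
countTSFrames(ens)
#>   simulation_id substrate ts_frames total_frames
#> 1          sim1      H3K4       594         5000
contactFractionMap(ens, c("P:R2", "P:T3"), c("E:Y361", "E:A287"))
#> ContactProfile: 2 peptide x 2 enzyme residues over 5000 frames (cutoff 4.5 A)
#>      E:A287 E:Y361
#> P:R2   0.00    0.9
#> P:T3   0.55    0.0
```

594/5000 = 0.119 recovers the planted 12% TS fraction within binomial
error, and the contact fractions recover the planted 0.9 and 0.55.

```r
# 21 simulations per substrate, high/low binning + Fisher's exact test
counts <- simulateStudyTSCounts(seed = 7, nFramesPerSim = 1000)
enr <- tsEnrichment(counts$H3K4, counts$H3K36)
enr$table
#>       high low
#> H3K4    16   5
#> H3K36    5  16
c(p = enr$p, ratio = enr$ratioPooled$ratio)
#>           p       ratio
#> 0.001675265 3.980693
```

TS-like states are about 4-fold enriched with the H3K4 substrate and
the high/low split is significant.

```r
# wild-type kinetics: 3 experiments, shared-amplitude two-rate fit
pc <- makeProgressCurves(noiseSd = 0.05, seed = 11)
fitSharedProgress(pc$H3K4, pc$H3K36)
#> Shared-amplitude progress-curve fit (A, B shared)
#>   A        0.0369194  (approx. SE 0.0137)
#>   B          1.01847  (approx. SE 0.0232)
#>   kH3K4     0.149207  (approx. SE 0.0107)
#>   kH3K36    0.028784  (approx. SE 0.00203)
#>   kH3K4/kH3K36 = 5.184 (approx. SE 0.372)
#>   RSS 0.1252 over 48 points; converged: TRUE
```

The fitted ratio 5.18 ± 0.37 recovers the planted 5.2-fold preference
of the wild-type enzyme for H3K4 over H3K36.

A command-line wrapper over the same stages lives at
`inst/cli/dualspec.R`:

```sh
Rscript inst/cli/dualspec.R all --out out_dir --seed 1
```

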