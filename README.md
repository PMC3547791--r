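# RepeatPull

Analysis of constant-velocity steered pulling of tandem repeat proteins —
built around the seven-ankyrin-repeat oncoprotein Gankyrin, pulled alone or
in complex with its ligand S6-C — for people who study mechanical unfolding
with steered MD or single-molecule force spectroscopy and want the whole
trajectory-analysis stack as reusable, tested R functions.

Repeat proteins unfold under force repeat by repeat, producing sawtooth
force-extension profiles. A bound ligand stabilises exactly the repeats it
contacts, and that localised stabilisation reshapes everything measurable:
the unfolding forces, the order in which repeats unfold, the size of the
unfolding steps, and the work the pulling device transfers. RepeatPull
implements the full set of observables:

* **Transferred work and its per-repeat decomposition.** The work up to
  frame *N* is the discrete path integral
  *W(t_N) = Σ_{n≤N} F̄_n · Δd_n*, with *F̄_n* the average force vector of
  two successive frames and *Δd_n* the change in the end-to-end vector.
  Decomposing the end-to-end vector into telescoping per-repeat anchor
  segments *e_r* gives components *W_r* with *Σ_r W_r(t) = W(t)* exactly.
  Group comparisons use Welch's t-test at the 1% level.
* **Force-peak identification.** The force distribution's Gaussian body is
  fitted and the per-bin normalized deviation *(count − fit)/√count*
  locates the threshold above which peaks are unambiguous; peaks are local
  maxima with hysteresis prominence (30 pN).
* **Worm-like chain contour-length analysis.** Pre-peak segments are fitted
  to the Marko–Siggia force law
  *F = (k_BT/p)[1/(4(1−x/L_c)²) − 1/4 + x/L_c]* at fixed persistence length
  p = 3.8 Å; all within-run pairwise ΔL_c differences reveal the L = 56.8 Å
  (half-repeat) versus 2L (whole-repeat) step periodicity.
* **Unfolding order statistics.** Per-repeat CαCβ RMSD from the native
  structure defines unfolding midpoints (first crossing of 10 Å);
  repeat-by-position contingency tables are compared with an exact Fisher
  r×c test (own enumeration, with a seeded Monte-Carlo mode).
* **Contact and binding lifetimes.** Native contacts (Cα < 8 Å, sequence
  separation > 3), a 0.4-ns recurrence filter against transient flickers,
  and per-residue ligand-binding lifetimes (any atom < 5 Å; native binders
  bound > 80% of equilibration).
* **A seeded synthetic pulling simulator.** Bell kinetics at half-repeat
  granularity (rate k₀·exp(F·Δx‡/k_BT − ΔG_r)) on top of WLC elasticity
  with a 20 pN/Å spring at 0.05 or 0.01 Å/ps, emitting force traces,
  multi-model PDB coordinate trajectories, and complete ground truth — so
  every analysis stage is validated end to end at desk scale.

## Worked example

Simulate one ligand-bound pull at 0.05 Å/ps and run the core analyses:

```r
library(RepeatPull)

sim <- simulatePull(SimParams(bound = TRUE), seed = 42)
sim$truth
#> GroundTruth: 14 rupture events, 7 repeats unfolded
#>   total work 72620 pN A (1753 kBT)

unfoldingOrder(sim$truth)      # C-terminal repeat first, then inward
#> [1] 7 6 5 4 3 2 1

wp <- repeatWorkComponents(sim$trace)
wp
#> WorkProfile (run1): final W = 72612 pN A (1753 kBT), 7 repeats

pk <- detectPeaks(sim$trace, threshold = 100)
head(peaks(pk), 3)
#>    run time extension    force prominence
#> 1 run1  635  25.46398 147.9916   30.61495
#> 2 run1 2630 123.91526 170.1346   36.33711
#> 3 run1 4778 227.98977 235.7198   38.15960

fits <- fitPeakContours(sim$trace, pk)
estimatePeriodicity(contourLengthDifferences(fits))
#> ContourHistogram: 21 pairwise differences; period 113.6 A (score 1.00)
```

The bound construct unfolds C→N in whole-repeat steps: the fitted
contour-length increments are multiples of 2L = 113.6 Å, the transferred
work (1753 k_BT at this speed) and the per-repeat decomposition are exact
(the components sum to the total frame by frame), and the detected peaks
sit at the rupture events recorded in the ground truth. A free-state run
(`SimParams()`) instead shows frequent half-repeat (L) steps and lower
peak forces.

`runPipeline(config, outDir)` orchestrates whole cohorts — simulate,
analyse, compare bound versus free, and write a deterministic TSV/JSON
bundle with a manifest of seeds and checksums.

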