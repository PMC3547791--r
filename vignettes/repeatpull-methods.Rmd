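---
title: "Methods: mechanical unfolding analysis of pulled repeat proteins"
author: "RepeatPull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanical unfolding analysis of pulled repeat proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RepeatPull)
```

# Scope and data model

RepeatPull analyses constant-velocity pulling of tandem repeat proteins:
a harmonic spring (stiffness *k*, default 20 pN/Å) attached to the two
terminal backbone atoms has its equilibrium length increased at constant
speed *v* (0.05 or 0.01 Å/ps), and the applied force, the end-to-end
vector, and per-repeat boundary anchor positions are recorded at every
saved frame. Internally all coordinates are Å, times ps, forces pN, and
work pN·Å; thermal energy is `kBT(300) = 41.419` pN·Å, the factor used to
report work in units of $k_BT$.

Two containers carry the data. A `ForceTrace` holds the per-frame force
vector, end-to-end vector and anchor positions, with the validity invariant
that the end-to-end vector equals the difference of the terminal anchors to
1e-6 Å — this is what makes the per-repeat work decomposition exact. A
`PullingTrajectory` holds per-frame atomic coordinates with a `Topology`
(residues, atoms, repeat assignment, protein/ligand chain tags); a
`RepeatMap` assigns contiguous, ordered residue ranges to repeats and names
the anchor atoms, with adjacent repeats sharing boundary anchors so the
repeat segment vectors telescope.

# Transferred work and its decomposition

The work transferred by the external force up to frame $N$ is

$$W(t_N) = \sum_{n \le N} \bar{F}_n \cdot \Delta d_n,$$

where $\bar F_n$ averages the force *vectors* of frames $n-1$ and $n$ and
$\Delta d_n$ is the change in the end-to-end vector. Decomposing the
end-to-end vector into repeat segments $e_r = a_{r+1} - a_r$ (anchors
$a_1 \dots a_{R+1}$) gives components

$$W_r(t_N) = \sum_{n \le N} \bar F_n \cdot \Delta e_{r,n}, \qquad
\sum_r W_r(t) = W(t)$$

with the identity holding exactly (to rounding) at every frame because the
anchors telescope. The components need not be monotone: when contour is
released anywhere in the chain, the tension drops and every unfolded
segment recoils, so individual $e_r$ shrink while others grow. Group
comparisons of final works use Welch's two-sample t-test (unequal
variances) at the 1% level; for traces storing only a force magnitude an
option rebuilds the vector along the instantaneous end-to-end direction,
which is the loading geometry of end-pulled constructs.

# Force peaks

The marginal distribution of sampled force magnitudes has a Gaussian body
(many small, independent contributions) and a high-force tail contributed
by ruptures. `fitForceDistribution()` histograms the sample (5 pN bins),
fits a Gaussian to the body — bins within ±2 fitted sd of the mode, window
re-centred once on the fit (two passes) — and forms the per-bin normalized
deviation $(c_i - \hat c_i)/\sqrt{\max(c_i, 1)}$, the deviation in units of
the Poisson error. `selectForceThreshold()` takes the bin of maximal
deviation above mean + 1 sd (ties toward lower force) and flags the
threshold unreliable when that maximum is below 3, i.e. when no tail stands
out of counting noise. On data with a tail that decays from its onset — the
shape rupture tails have — the selected threshold sits at the onset; for a
flat (uniform) injected tail the argmax is located anywhere inside the
tail, which the tests account for.

`detectPeaks()` smooths the force series with a centred moving average
(default 15 frames, shrinking windows at the edges), walks it with a
hysteresis state machine — a candidate maximum becomes a peak only after
the smoothed force has dropped by the prominence (default 30 pN), and a new
candidate opens only after a rise of the same size — and then refines each
peak to the raw-force apex within one smoothing window. Boundary frames are
never peaks: a rising final segment is not a rupture. The default smoothing
width is chosen so that, over a full 16k-frame trace at the reference noise
level (σ = 10 pN), the extremes of the smoothed noise stay well inside the
hysteresis band; with 5-frame smoothing the band is breached by noise
alone. Peak-time localisation on a noisy, gently sloped ramp is good to a
few tens of ps — far below the ~1 ns spacing of rupture events — which sets
the matching tolerance used in validation (±50 ps at σ = 10).

# Worm-like chain contour lengths and periodicity

Pre-peak segments (from the force minimum after the previous peak to the
peak frame, restricted to a strictly increasing extension subsequence) are
fitted to the Marko–Siggia interpolation

$$F(x) = \frac{k_BT}{p}\left[\frac{1}{4(1-x/L_c)^2} - \frac14 +
\frac{x}{L_c}\right]$$

with persistence length fixed at p = 3.8 Å and only $L_c$ free, by least
squares with `optimize()` bracketed in $(1.001, 5)\times$ the maximum
extension. Extension means the scalar end-to-end distance; pulling is along
the end-to-end vector, so the projection equals the distance. Noiseless
self-consistency recovers $L_c$ to well under 0.5% across 60–800 Å.

All within-run ordered-pair differences $\Delta L_c$ are pooled across runs
and scanned for periodicity. The raw score of a candidate period $P$ — the
fraction of differences within ±10 Å of a positive multiple of $P$ — cannot
by itself prefer $2L$ over $L$, since every multiple of $2L$ is a multiple
of $L$. The period is therefore selected by the raw fraction minus the
fraction expected for uniformly distributed differences (the portion of the
axis covered by the tolerance windows), which penalises short periods whose
extra multiples go unused, and then refined by least squares through the
assigned multiples. The reported score remains the raw fraction. An exact
comb at multiples of $L$ yields ($L$, score 1); a comb at multiples of
$2L$ yields $2L$.

# Unfolding order

Per-repeat unfolding is monitored by the CαCβ RMSD of each repeat from its
native conformation after optimal superposition (Kabsch, via bio3d). The
unfolding midpoint is the first time the RMSD reaches 10 Å, linearly
interpolated between frames; repeats that never cross are flagged and
excluded from the rank permutation, and ties break by time then repeat
index. Midpoints are insensitive to the exact threshold across 7–15 Å
because unfolded repeats plateau near 20–30 Å.

Order statistics are tabulated repeat-by-position; condition contrasts use
the 2×positions table of one repeat's position under two conditions. The
exact Fisher r×c test enumerates all tables with the observed margins
depth-first (margin pruning, enumeration cap 2e6 tables) and sums the
multivariate hypergeometric probability of tables no more probable than the
observed one (relative tolerance 1e-7 on ties); beyond the cap, or on
request, a seeded Monte-Carlo mode draws tables with `r2dtable` and uses
the add-one estimator. Empty rows or columns are dropped first; they cannot
affect the conditional test.

Kernel density estimates replace histograms throughout (`kde1d`): each
point becomes a Gaussian of fixed bandwidth (1.6 ns for unfolding times,
50 $k_BT$ for work, 20 Å × 20 pN for the extension–force plane), the grid
spans the data ±4 bandwidths, and the result is renormalised to integrate
to 1 on the grid.

# Contacts and ligand binding

Residue pairs with native Cα–Cα distance strictly below 8 Å and sequence
separation strictly greater than 3 define native contacts, classified
intra-/inter-repeat and turn/helix from the repeat map's region annotation.
Presence along a trajectory uses the same strict cutoff per frame. The
recurrence filter keeps a contact only if some maximal run of consecutive
present frames spans at least 0.4 ns (first to last frame, boundary
inclusive), which removes alternating-frame flickers; the lifetime is the
end of the last qualifying run, averaged over runs with its standard error.
Ligand binding uses any-atom distance strictly below 5 Å; native binders
are residues bound in strictly more than 80% of the equilibration span.
Binding lifetimes pass through the same recurrence filter by default — the
lifetime definitions for contacts and binding are worded slightly
differently in the literature, so a flag (`recurrenceFilter = FALSE`)
switches to the raw last observation.

# The synthetic pulling generator

The generator replaces cluster-scale atomistic simulations with a model
containing exactly the physics the analyses measure.

**Elasticity.** At spring-end position $X(t) = X_0 + vt$ the chain
extension $x$ solves $k(X - x - R_{\mathrm{fold}}) =
F_{\mathrm{WLC}}(x; L_c)$, with $L_c$ the currently unfolded contour
(initially a 30 Å terminal linker) and $R_{\mathrm{fold}}$ the rigid rise
of folded repeats. The root is found by bisection to 1e-10 Å in a small C++
kernel. The default folded rise is 0 — the folded core is treated as a
point on the pulling axis — so fitted contour-length increments are exact
multiples of L; a nonzero rise (the physical ~10 Å per repeat) shifts each
increment by half the rise and is available as a parameter.

**Kinetics.** Each repeat is two Bell half-repeat elements that rupture at
rate $k_0\exp(F\,\Delta x^\ddagger/k_BT - \Delta G_r)$, evaluated as
fixed-step Bernoulli trials on a 0.1 ps grid (per-step probability < 0.01
at the forces reached), sampled exactly by inversion of the discrete
survival function. Rupture releases L = 56.8 Å of contour and the force
relaxes through the re-solved balance; with probability $q$
(`halfCoupling`) the partner half ruptures at the same instant. Small $q$
produces half-repeat (L) steps, $q \to 1$ whole-repeat (2L) steps — one
knob for the free-versus-bound periodicity contrast (defaults 0.25 free,
0.95 bound).

**Who is allowed to unfold.** Only the outermost repeats of the contiguous
folded block are competent — tension is relayed into the stack from the
pulled termini. Combined with an intrinsic stability gradient (0.7 $k_BT$
per repeat, C-terminal repeat most labile), this produces the sequential,
predominantly C→N unfolding characteristic of ankyrin arrays, with
occasional N-terminal entry providing pathway diversity. An
all-repeats-competent rule cannot reproduce a strong "repeat 7 then repeat
6 first" restriction when repeats 1–6 are uniformly stabilised, because
repeats 6 and 5 would then compete at equal rates after repeat 7 unfolds.

**Ligand.** The bound state adds per-repeat stabilisation, by default
4 $k_BT$ on repeats 1–5 and 1.5 $k_BT$ on repeat 6: the interface spans
repeats 1–6 but the central repeats are the mechanical hot spots and the
effect on repeat 6 is weakest. A 4 $k_BT$ shift raises rupture forces by
$\Delta\Delta G\, k_BT/\Delta x^\ddagger \approx 80$ pN, well clear of the
run-to-run spread.

**Calibration.** The atomistic reference provides no rate parameters; they
were calibrated once so that rupture forces land in the 100–400 pN window
typical of these pulls: $\Delta x^\ddagger = 2$ Å (a typical Bell
activation distance for repeat proteins) and $k_0 = 2\times10^{-5}$/ps.
Low-force ruptures during reload still occur and stay below the noise
floor, as they do in real traces. These values are synthetic calibration
choices, not fits to data.

**Reported noise.** Zero-mean Gaussian noise (σ = 10 pN) is added to the
reported force only; dynamics and ground truth are noise-free. This yields
the Gaussian-bodied force distribution the peak-threshold rule assumes,
with ruptures supplying the high-force tail.

**Anchors and ground truth.** Per-repeat anchors are laid along the pulling
axis with each repeat's extension equal to its rigid rise plus its share of
the WLC extension in proportion to its released contour — physically, every
unfolded segment carries the same fractional extension at the common
tension — giving the work decomposition a telescoping ground truth. The
`GroundTruth` object records every rupture (time, exact force, cumulative
contour), per-repeat unfolding times and order, and the noise-free total
and per-repeat works.

**Coordinate trajectories.** `makeNativeTemplate()` builds a deterministic
toy repeat array (two antiparalell pseudo-helix strands of Cα/Cβ sites per
repeat, 7 Å block rise so native contacts exist within and between adjacent
repeats only; first quarter of each repeat tagged as the turn) with
optional ligand beads within 5 Å of designated repeats.
`synthesizeTrajectory()` morphs each half-repeat from its native block to
an extended segment across a 40 ps window centred on its rupture time. The
extended segment is drawn out of the stack laterally, so a half-unfolded
repeat already reads ≈18 Å RMSD (keeping the 7–15 Å threshold sweep inside
one unfolding window), and carries a small helical dressing so the
superposition never degenerates on exactly collinear coordinates. Ligand
beads track their repeat's interface until that repeat ruptures, then
drift away. Jitter 0 reproduces the native template exactly before the
first rupture.

# What the generator does and does not emulate

It reproduces: constant-velocity harmonic loading, WLC elasticity of
released contour, stochastic force-dependent rupture with half-repeat
granularity, sequential edge unfolding with C→N bias, ligand-localised
stabilisation, L/2L step periodicity, Gaussian-bodied reported-force noise
with a rupture tail, and frame saving at 1–4 ps.

It does not contain: atomistic degrees of freedom or a solvent model (no
force-field ruggedness, so the noise is exactly Gaussian rather than merely
Gaussian-bodied), refolding or retry events, inter-repeat cooperativity
beyond the half-coupling knob, non-native interactions in the generated
coordinates, or any geometric coupling between the coordinate trajectories
and the force traces beyond the shared rupture schedule. Passing tests
therefore demonstrate that the analysis stack recovers known ground truth
under realistic signal and noise scales — not that it would be free of
artefacts on trajectories with structured, correlated noise.

# Problem sizes and numerical choices

Validation runs use full-length pulls: 800 Å of spring travel, i.e. 16 ns
at 0.05 Å/ps (1 ps frames) and 80 ns at 0.01 Å/ps (4 ps frames), with
kinetics on a 0.1 ps grid. The test suite uses 12-run cohorts for the
bound/free contrasts, 50 seeds for order-recovery and work-identity
checks, 200 seeds for peak-detection operating characteristics, 1000
traces for the pure-noise null, and 500 random tables (total ≤ 20) for the
Fisher oracle; coordinate trajectories for RMSD/contact analyses are
synthesized at 20–80 ps frame spacing. The acceptance script uses 12+12
runs at 0.01 Å/ps.

Numerical conventions worth knowing: bisection tolerance 1e-10 Å for the
force balance; `optimize()` tolerance ~1e-7 × extension for contour fits;
strict inequalities at every cutoff (8 Å, 5 Å, 80%); recurrence spans are
inclusive of their boundary; midpoint ties break by time then repeat index;
the exact Fisher tie tolerance is 1e-7 relative; result tables are written
with fixed 6-significant-digit formatting so identical inputs give
byte-identical files.

# Known limitations

Single-run per-repeat work components carry ~5% rms noise from the
reported-force noise integrated along a non-monotone extension path;
cohort means are the meaningful quantity. Peak times on gently sloped
noisy ramps are defined only to a few tens of ps. The exact Fisher
enumeration is practical for small tables (sums of ~tens); larger tables
fall back to Monte Carlo. The toy coordinate geometry supports RMSD,
contact and binding analyses but is not a physical structure; its contour
bookkeeping (3.55 Å per residue when extended) matches the 2L = 113.6 Å
repeat contour only approximately at the residue level.
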