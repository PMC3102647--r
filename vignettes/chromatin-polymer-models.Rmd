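---
title: "Polymer models of hierarchical chromatin folding: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polymer models of hierarchical chromatin folding: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromfold)
```

# Scope

`chromfold` collects the analytic and simulation machinery needed to reason
about eukaryotic genome organization as a polymer problem, at three
hierarchical levels:

1. **Gene locus** (tens of kbp to a few Mbp): worm-like-chain (WLC)
   compaction under a change of persistence length, and the resulting
   amplification of intra-locus contacts.
2. **Genome-wide**: a freely-jointed-chain (FJC) bookkeeping device — the
   folding index — that ties contour length, folded size, scaling exponent
   and persistence length together across organization levels.
3. **Simulation models**: lattice Monte Carlo of phantom semiflexible
   chains with flexible hinges, deterministic two-angle nucleosome-fiber
   geometry, and Gaussian-chain loop models (random loop and
   random-walk/giant-loop) with scaling and moment-ratio diagnostics.

The models are deliberately minimal. They contain no excluded volume
(except as a diagnostic for fiber geometry), no electrostatics, no histone
tails, no linker histones and no fitting to imaging or conformation-capture
data. What they buy with that austerity is exactness: nearly every quantity
the package computes has a closed form or an independent oracle, and the
test suite leans on those.

# Gene locus: WLC compaction and Flory amplification

The locus is a WLC with fixed contour length $L_c$ and variable persistence
length $L_p$. Its mean-square end-to-end distance is the Kratky–Porod
result

$$\langle R^2 \rangle = 2 L_p L_c - 2 L_p^2\left(1 - e^{-L_c/L_p}\right),$$

with the rod limit $\langle R^2\rangle \to L_c^2$ for $L_c \ll L_p$ and the
ideal-chain limit $\langle R^2\rangle \to 2 L_p L_c$ for $L_c \gg L_p$
(`wlcSquaredEndToEnd()`). Chromatin remodeling — nucleosome depletion,
histone modification — is modelled as a drop of $L_p$ at fixed $L_c$.
In the ideal-chain limit the squared-size ratio is simply

$$\frac{\langle R^2\rangle_f}{\langle R^2\rangle_i} =
\frac{L_p^f}{L_p^i},$$

so the 280 nm $\to$ 140 nm softening reported for nucleosome-depleted
fibers halves $\langle R^2\rangle$ (`compactionRatio(280, 140)` returns
exactly 1/2); the RMS locus size shrinks by
$100(1 - \sqrt{1/2}) \approx 29.3\%$, i.e. about 30%, the magnitude seen
for the IgH locus during B-cell development. `compactionRatio()` treats
the ideal-chain limit as the default and switches to the full
Kratky–Porod ratio when a contour length is supplied; the returned
`idealLimit` attribute flags contour lengths under 100 persistence
lengths, where the ideal reading is unsafe.

The functional consequence follows from a Flory-type counting argument:
binary contacts scale with the squared segment concentration, $n_b \sim
c^2$, $c \sim 1/V$, and with spherical symmetry $V \propto \langle
R^2\rangle^{3/2}$, so

$$\frac{n_b^f}{n_b^i} = \left(\frac{\langle R^2\rangle_f}{\langle
R^2\rangle_i}\right)^{-3}.$$

Halving $\langle R^2\rangle$ therefore yields an 8-fold gain in binary
(promoter–enhancer) contacts (`floryAmplification()`).

```{r}
floryAmplification(compactionRatio(280, 140))
```

# Genome-wide: the folding index

At the whole-genome scale the chain is an FJC of $N_r = L_c/2L_p$ Kuhn
segments of length $l = 2L_p$, with characteristic folded size $C_s = 2 L_p
N_r^{\nu}$. The exponent $\nu$ is the inverse fractal dimension: 1 for a
rod, 1/2 for an ideal chain, 1/3 for a space-filling (fractal-globule-like)
state. The folding index

$$\Phi = \frac{L_c}{C_s} = N_r^{1-\nu}$$

acts as a lens of variable resolution across organization levels. For the
human genome at the naked-DNA level ($6\times10^9$ bp at 2.94 bp/nm gives
$L_c \approx 2$ m; $L_p = 50$ nm; $\nu = 1/3$) the package computes $N_r =
2\times10^7$ and $C_s = 27.1\ \mu$m — the scale of a cell nucleus
(`fjcSummary(50, 1/3, 2e9)`).

Two conventions for $\Phi$ coexist and we report both rather than forcing
agreement. The ratio route with the folded size rounded to the nuclear
scale, $\Phi = 2\,\mathrm{m} / 25\ \mu\mathrm{m} = 8\times10^4$
(`foldingIndexFromSizes()`), and the self-consistent route $\Phi =
N_r^{1-\nu} = 7.4\times10^4$ (`fjcSummary()`). The few-percent gap is
purely the rounding of $C_s$ to 25 µm.

Pinning the folded size to the invariant nuclear size $C_{s,0}$ and
inverting gives persistence length as a function of folding index,

$$L_p = \frac{C_{s,0}}{2}\,\Phi^{-\nu/(1-\nu)}
\qquad\left(\nu = \tfrac13:\; \Phi = (C_{s,0}/2L_p)^2\right),$$

implemented as `persistenceFromFolding()` with the tabulated curve from
`foldingCurve()`. The generalization to arbitrary $\nu$ uses $\Phi =
N_r^{1-\nu}$ with $N_r = (C_{s,0}/2L_p)^{1/\nu}$; the $\nu = 1/3$ case is
the canonical one and the generalization is this package's extension.
$\nu = 1$ is rejected as degenerate (a rod never folds). The inversion
round-trips to relative error below $10^{-12}$ across $L_p \in [1,
10^4]$ nm, which the test suite asserts.

# Lattice Monte Carlo with flexible hinges

The hinge-collapse mechanism is checked by simulation: phantom (freely
self-intersecting) chains on the simple cubic lattice with the per-vertex
bending energy

$$E = \sum_v \varepsilon_v\,(1 - \cos\theta_v), \qquad
\cos\theta_v \in \{-1, 0, 1\},$$

at temperature $1\,k_BT$. The energy model is the simplest one-parameter
bending penalty consistent with a stated stiff/flexible gap of
$2\,k_BT$ per segment: stiff vertices carry $\varepsilon = 2\,k_BT$,
hinge (nucleosome-depleted) vertices $\varepsilon = 0$, and reversals are
allowed. With $\varepsilon \equiv 0$ every configuration is equally
weighted and all ideal-chain identities hold exactly, which is the
engine's principal self-check.

**Moves and defaults.** Metropolis sampling mixes three moves: pivot
(random interior bead, random element of the 48-element octahedral group
applied to the tail; probability 0.2), single-bead corner flip (0.7) and
end-bond redraw (0.1). Pivot moves decorrelate the global conformation of
a phantom chain within a few sweeps; the local moves keep acceptance
healthy for stiff chains. One sweep is $N$ attempted moves for an
$N$-bond chain. Defaults: $10N$ equilibration sweeps, samples every 2
sweeps. The short sampling interval is a deliberate choice: with a 20%
pivot fraction the autocorrelation time is a few sweeps, and error bars
are taken across independent replicate seeds rather than within runs, so
residual within-run correlation does not bias the reported uncertainty.
Replicate seeds derive from a master seed by a counter-based affine hash
(`splitSeed()`), so growing a replicate set never reshuffles earlier
replicates.

**Oracles.** For a uniformly stiff chain the six lattice directions form a
transfer matrix with Boltzmann weights $e^{-\varepsilon(1-\cos\theta)}$
whose rows all share the same sum; vertex angles are therefore i.i.d. and

$$\langle\cos\theta\rangle =
\frac{1 - e^{-2\varepsilon}}{1 + 4e^{-\varepsilon} + e^{-2\varepsilon}},
\qquad L_p = -\frac{1}{\ln\langle\cos\theta\rangle},$$

which at $\varepsilon = 2\,k_BT$ gives $\langle\cos\theta\rangle = 0.6294$
and $L_p = 2.16$ bonds. The tangent-correlation estimator
(`tangentCorrelationLp()`, least squares on
$\ln\langle t_i\cdot t_{i+s}\rangle$ vs $s$) is tested against this value,
the sampled energy histogram of a 3-bond chain against exhaustive $6^3$
enumeration, and $\langle R_g^2\rangle$ of the flexible chain against the
closed form $(N_b^2-1)/6N_b$, itself validated by exhaustive enumeration
at small $N$.

**The hinge experiment.** `rgRatioExperiment()` compares stiff chains
carrying $k$ single-vertex hinges at the equally spaced interior positions
$\lfloor j(n_v+1)/(k+1)\rfloor$ against the fully flexible chain,
reporting

$$R(k) = \frac{\langle R_g^2\rangle(k\ \text{hinges, stiff background})}
{\langle R_g^2\rangle(\text{fully flexible})}$$

with replicate-level standard errors. This ratio definition is the
package's own (recorded in the output's `ratio_definition` attribute):
$R(k)$ decreases with hinge count and grows with chain length, the
qualitative collapse direction. Only that direction is asserted — the
single-vertex hinge perturbation is intentionally minimal, so at large
$N$ its effect approaches the replicate noise floor and only
equality-within-error is claimed there. Whether literature hinges were
single vertices or extended regions is not derivable from their summary
tables, so the width is a parameter (`regionWidth`), and no quantitative
table values are reproduced.

# Two-angle fiber geometry

The nucleosome fiber is built deterministically from two angles: the
linker entry–exit angle $\alpha$ and the rotation $\beta$ between
consecutive nucleosomes, the latter set by the linker length $L$ through
the DNA helical repeat, $\beta = 360^\circ (L \bmod 10.5)/10.5$
(`betaFromLinker()`). Conventions the literature leaves open are declared
explicitly:

* Nucleosomes are spheres (default diameter 11 nm) at kink vertices;
  linkers are straight segments of length $L \times 0.34$ nm/bp.
* $\alpha$ uses the supplement convention: $\alpha = 180^\circ$ means no
  kink (straight fiber), and the kink deflection is $\delta = 180^\circ -
  \alpha$.
* $\beta$ is a right-handed rotation about the incoming linker direction,
  applied before the kink.
* The fiber axis — never defined in the two-angle literature — is the
  sliding-window centroid path (window 5). The packing ratio is
  nucleosomes per 11 nm of axis arc length, computed as
  $11\,(\text{axis intervals})/(\text{arc length})$, which reduces exactly
  to $11/\text{spacing}$ for a straight fiber. The fiber diameter is twice
  the maximal radial distance of centers from the axis polyline (end
  segments extended, so ends are measured radially) plus the nucleosome
  diameter.

These choices reproduce the expected phase behavior — zigzags at large
$\alpha$, compact solenoid-like fibers at small $\alpha$ with higher
packing ratio — and make all straight-fiber quantities exact, which the
tests exploit. `detectClashes()` reports sphere overlaps between
non-adjacent nucleosomes; no Monte Carlo relaxation is performed.

# Loop models and scaling diagnostics

**Random loop model.** A Gaussian backbone of $n$ beads (default
granularity 10 kbp/bead) gains an extra harmonic bond between each pair of
beads separated by at least 15 beads (150 kbp) independently with
probability $p$ (`randomLoopTopology()`). For any fixed topology the model
is an exactly solvable Gaussian network: with connectivity Laplacian
$\Gamma$,

$$\langle r_{ij}^2\rangle = b^2\left(\Gamma^+_{ii} + \Gamma^+_{jj} -
2\Gamma^+_{ij}\right),$$

the graph resistance distance (`gaussianDistanceMatrix()`, symmetric
eigendecomposition with the single translation mode removed). Loop bonds
default to the backbone spring constant (`loopStrength` is configurable;
the source model's constants are not published). Averaging over topology
draws models cell-to-cell loop variability (`randomLoopProfile()`); as $p$
grows the distance profile flattens and the fitted exponent tends to zero
— distances become independent of genomic separation. Because loops pin
distant beads together, intra-chain distances understate the size of
looped structures; `gaussianRadiusOfGyration()`
($b^2\,\mathrm{tr}\,\Gamma^+/n$) is reported alongside as the appropriate
size measure.

**RW-GL.** The random-walk/giant-loop construction hangs consecutive
closed loops (default 200 beads = 2 Mbp, mid-range of the 1–3 Mbp
literature scale) off a Gaussian backbone: each loop is a Brownian bridge
returning to its anchor, anchors take Gaussian backbone steps
(`rwglProfile()`). Within a loop of $m$ beads the mean-square distance at
separation $s$ is exactly $b^2 s(m-s)/m$; beyond the loop scale the
profile levels off relative to the linear ideal-chain growth.

**FJC ensembles.** `fjcEnsemble()` generates unconfined lattice walks
(ideal chains, $\langle R^2(s)\rangle = s$) and density-confined walks
with reflecting walls in a cubic box of side $\lceil (N/\rho)^{1/3}
\rceil$. The confined construction at fixed density is used for the
fractal-globule comparison: chain size grows as $N^{1/3}$ by volume
conservation, checked by fitting RMS radius of gyration against $N$
(`fitScalingExponent()`). The default density of 0.5 beads/site
represents a chromatin-dense nucleus while leaving the walk mobile.
Contact probabilities (`contactProbability()`, default capture radius 2
bond lengths, with sensitivity to the radius reported rather than hidden)
decay as the Gaussian return probability $s^{-3/2}$ for unconfined
chains. Moment ratios $\langle r^4\rangle/\langle r^2\rangle^2$
(`momentRatio()`) discriminate statistics: 1 for a rod, 5/3 for a
Gaussian chain.

# What the generators do and do not emulate

The built-in generators are the package's synthetic-data module: phantom
semiflexible lattice chains with region-wise bending energies, Gaussian
chains with random long-range bonds, and density-confined random walks.
They emulate the statistical features the models predict — ideal-chain
scaling, hinge-induced collapse, distance plateaus, $N^{1/3}$ confinement
scaling — under exactly the stated assumptions. They do **not** emulate
excluded volume, topological constraints (the confined walk is a
space-filling ideal chain, not a true unknotted collapsed globule),
chromatin heterogeneity, dynamic loop turnover, or any feature of real
imaging/conformation-capture data. A passing test therefore certifies the
implementation of the model, not the fidelity of the model to in-vivo
chromatin.

# Numerical choices

* Internal unit is nm in the analytic layer; lattice models use bond
  units. bp↔nm conversions use 2.94 bp/nm where a genomic distance enters
  the folding index, and 0.34 nm/bp DNA rise in the fiber builder; both
  are arguments, never hard-coded.
* Laplacian pseudo-inversion drops eigenvalues below
  $100\,n\,\epsilon_{\mathrm{mach}}\,\lambda_{\max}$; exactly one null
  mode (translation) is expected, and any further rank deficiency is an
  error rather than a silent regularization.
* Log–log scaling fits use ordinary least squares; standard errors are the
  regression errors and are indicative only when points are correlated.
* Monte Carlo error bars are replicate-level standard errors across
  independent seeds, not autocorrelation-corrected within-run estimates.
* Stochastic tests fix their seeds and compare at 3–4 standard errors;
  where several standard-error comparisons run simultaneously, the
  aggregate mean deviation is tested at its own 3-SE tolerance.
* Degenerate inputs fail loudly: zero-sample requests, hinge counts that
  do not fit, loop cutoffs beyond the chain, $\nu = 1$ inversions,
  sub-Kuhn contour lengths, nonpositive correlations in a persistence
  fit.

# Problem sizes used by the tests

The suite (about 30 s on one core) uses: freely rotating chain oracle at
$2\times10^4$ chains of 200 segments; Monte Carlo oracle suite at 64–256
bonds with 8–12 replicates; the hinge experiment at $N \in \{16, 64,
256\}$, $k \in 0..3$, 32 replicate seeds; Gaussian-network sampling
checks at up to 50 beads and $10^5$ draws; ensemble scaling at chains up
to 4096 beads, 64 chains. These sizes put every standard-error tolerance
comfortably above the measured fluctuations while keeping the suite fast;
they are stated here so that readers can judge the statistical weight of
each check.

# Known limitations

* The lattice bending model restricts angles to $\{0°, 90°, 180°\}$; its
  persistence lengths are in bond units and map onto continuous-fiber
  values only through the tangent-correlation definition.
* The confined-walk "globule" reproduces the $N^{1/3}$ size scaling but
  not the contact-probability exponent of a true fractal globule
  ($s^{-1}$); the package's contact diagnostics on confined walks reflect
  a reflected ideal chain, and the $\nu = 1/3$ claim is made only for
  size-vs-$N$ at fixed density.
* The two-angle builder performs no relaxation; clash lists describe the
  idealized geometry.
* Gaussian loop models are phantom chains; territory-scale segregation
  effects driven by excluded volume are outside scope.
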