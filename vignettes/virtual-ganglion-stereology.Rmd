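---
title: "Design-based stereology on a virtual ganglion: models, estimators and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based stereology on a virtual ganglion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ganglia)
library(ggplot2)
```

# Why a virtual ganglion?

Stereological estimates of a ganglion's volume and cell numbers are produced
from a handful of thick histological sections. The microscopist never knows
the truth, so the estimators themselves — Cavalieri point counting, the
optical disector, Voronoi-based spatial classification — can only be
validated on material where the truth *is* known. `ganglia` therefore ships a
ground-truthed simulator of the whole histological chain: a 3-D cell
population inside an ellipsoidal ganglion, serial sectioning with tissue
shrinkage, systematic sampling, and the counting rules. Every estimator in
the package is validated against the phantoms' known volume, cell numbers,
spatial arrangement and apoptosis rate.

The default study design mirrors a six-group chronic sleep deprivation (CSD)
/ curcumin experiment on the rat superior cervical ganglion (SCG): groups
`control`, `curcumin`, `CSD`, `CSD_curcumin`, `grid_floor` and
`grid_floor_curcumin`, six animals per group.

# The phantom and the virtual microtome

A `ganglion_phantom` holds the somata of one animal's ganglion inside an
ellipsoid with semi-axes $(a, b, c)$; the third axis is the longitudinal axis
along which the block is cut. The default $(200, 150, 300)\,\mu m$ ellipsoid
has volume $V = \tfrac{4}{3}\pi abc \approx 3.77\times 10^{7}\,\mu m^3$ and
yields 24 serial sections at a block advance of $25\,\mu m$, so sampling
every second section gives the 8–12 sections per ganglion that the
estimators are designed around.

Neuron positions follow the group's spatial regime:

* **regular** — a cubic lattice with pitch $(V/n)^{1/3}$, random phase, and
  Gaussian positional jitter of 5% of the pitch. Healthy ganglia classify as
  regular, and a jittered lattice is the standard generator of that regime.
* **random** — a homogeneous Poisson process (uniform positions, Poisson
  total), i.e. complete spatial randomness (CSR).
* **clustered** — a Thomas process (Poisson parents, Gaussian-scattered
  offspring) restricted to the ellipsoid, with the offspring intensity
  rescaled so the expected total still matches the group's true count.

Satellite glial cells are attached to randomly chosen neurons at radial
offsets just outside the neuron's nucleus, emulating the perineuronal
satellite sheath; nucleus radii are log-normal (neurons $\approx 6\,\mu m$,
glia $\approx 2.5\,\mu m$). Apoptosis labels are i.i.d. Bernoulli with a
per-group probability.

Group effects enter as multipliers on the true volume (through the
semi-axes) and on the expected neuron and glia counts. The defaults encode
the direction and magnitude of the simulated CSD lesion — volume $-31.9\%$,
neurons $-12.6\%$, glia $-26.5\%$ relative to control, CSD arrangement
switched from regular to random, apoptosis probability raised from 0.02 to
0.20 with curcumin co-treatment at 0.08 — while the curcumin-only groups
carry small positive multipliers. The apoptosis probabilities and the
curcumin multipliers are free parameters chosen to preserve the ordering
CSD ≫ CSD+curcumin ≈ control; they are design inputs of the simulator, not
measured quantities.

The virtual microtome (`section_phantom()`) cuts perpendicular to the long
axis starting at the rostral pole, producing `ceiling(extent/BA)` sections.
Each cell belongs to the unique section containing the *leading (top) edge*
of its nucleus — the same event the optical disector counts — so sectioning
conserves every cell exactly once. Measured section thickness is
`shrinkage_factor * BA` with 2% per-section noise (defaults: $0.92 \times
25 = 23\,\mu m$), and focal depths inside a section are rescaled
accordingly. Shrinkage is deliberately *not* corrected in the volume
estimate: the estimates are apparent volumes, comparable across groups
because shrinkage acts equally on all of them.

# Cavalieri volume estimation

For systematically sampled sections $i$ with point counts $P_i$ on a square
grid with area per point $a(p)$,

$$\hat V \;=\; \Big(\sum_i P_i\, a(p)\Big)\, d ,$$

where $d = k \cdot BA$ is the distance between sampled section planes and
$k$ the sampling period. The grid has one uniformly random offset per
ganglion, shared by its sections, and the section period has a uniformly
random start — systematic uniform random sampling (SURS) in both dimensions.
The default grid spacing of $65\,\mu m$ puts roughly 150–250 points on a
default ganglion, a realistic point-counting workload.

The error predictor is the Gundersen–Jensen SURS estimator for smoothness
class $m = 1$:

$$\nu = 0.0724\,\frac{\bar B}{\sqrt{\bar A}}\sqrt{n \textstyle\sum P},
\qquad
\mathrm{Var}_{SURS} = \frac{3(C_0 - \nu) - 4C_1 + C_2}{240},
\qquad
CE = \frac{\sqrt{\nu + \mathrm{Var}_{SURS}}}{\sum P},$$

with $C_q = \sum_i P_i P_{i+q}$ and $\bar B/\sqrt{\bar A}$ the mean
boundary-to-root-area shape ratio of the profiles (computed analytically
from the section ellipses; $2\sqrt{\pi}$ for circles). The point-counting
nugget $\nu$ can be disabled (`nugget = FALSE`) to expose the pure
systematic component. Note a subtlety of this classical formula: for a
perfectly constant sequence $P_i \equiv c$ the quadratic sums leave a small
residue ($3n - 4(n-1) + (n-2) = 2$), so the systematic term is near zero but
not exactly zero; the package implements the formula as published rather
than forcing the degenerate case to zero.

On 200 simulated default ganglia the mean CE is about 2% and the mean
estimate is within a fraction of a percent of the true ellipsoid volume.
The only systematic deviation is the midpoint-rule error of evaluating
section areas at mid-depth, about 0.1% for these smooth shapes — far inside
the 2% unbiasedness tolerance the package tests enforce.

# Optical-disector cell numbers

Counting uses unbiased frames of area $a/f = 3492\,\mu m^2$ on a systematic
field grid (default steps $155\,\mu m$), inside a depth window obtained by
discarding guard zones at the section faces: the upper 10% and lower 20% of
the measured thickness for neurons, the reverse for satellite glia. The
Z-axis histogram (`zaxis_histogram()`) shows where nuclei sit through the
thickness and justifies the guard choice; `select_counting_window()` also
reports which percentage of nuclei the window retains (70% for a uniform
depth distribution, more when the histogram is concentrated mid-section —
which is how empirical reports of 78–81% retention arise).

The density and total are

$$N_v = \frac{\sum Q^-}{\sum P \cdot (a/f) \cdot h}\cdot\frac{\bar t}{BA},
\qquad \hat N = N_v \cdot \hat V,$$

with $h$ the disector height, $\bar t$ the mean measured thickness and the
$\bar t/BA$ factor the standard correction for counting in shrunken
sections; setting $\bar t = BA$ recovers the uncorrected formula exactly.
The included-nucleus fraction is *not* applied as a second correction — the
printed formula already corrects once, and applying both would
double-correct.

Two conventions deserve explicit statement:

* **Forbidden line.** A profile is counted when it lies at least partly
  inside the frame without touching the staircase exclusion line: the left
  border with its infinite upward extension, the bottom border, and the
  infinite downward extension of the right border below the bottom-right
  corner. With this (and only this) disambiguation a complete tiling of
  frames counts every convex profile exactly once — a property the test
  suite verifies literally, by exhaustive tiling against the phantom truth.
  The measure of frame positions that count a given profile equals the
  frame area, which is what makes sparse systematic fields unbiased.
* **Field accounting.** $\sum Q^-$ is tallied over the complete systematic
  tiling covering the section, so nuclei at the tissue edge are never lost,
  while $\sum P$ counts the fields a microscopist would actually apply —
  frames whose centre lands on tissue, including fields with zero counts.
  On homogeneous material this makes counts per sampled frame volume an
  unbiased density estimate without modelling the tissue boundary.
* **Depth ties.** The counting window is half-open, $g_t \bar t \le z <
  (1-g_b)\bar t$, so a nucleus exactly at a boundary belongs to exactly one
  of two adjacent disectors.

The default field steps put $\sum Q^- \approx 500$ on a default ganglion,
so the Poisson component of the CE,
$CE = \sqrt{1/\sum Q^- + \mathrm{Var}_{SURS}(Q_i)/(\sum Q^-)^2}$, sits near
$1/\sqrt{500} \approx 4.5\%$ — the 4–5% working range of a well-designed
counting study. Over 100 simulations the total-number estimate recovers the
phantom truth within about 1%.

# Voronoi classification of the neuronal arrangement

For a planar pattern of neuron positions the package tessellates the
observation window (via `deldir`), drops polygons touching the window edge
(whose areas are truncated by the window, not by neighbours; the
`clip_to_window` policy is retained for partition checks), and summarises
the polygon areas by their coefficient of variation,

$$CV = \frac{\mathrm{sd}(\text{areas})}{\mathrm{mean}(\text{areas})}\times 100,$$

using the sample (n−1) standard deviation. Classification bands: CV < 33%
regular, 33–64% (closed band, as the bands are quoted) random, > 64%
clustered. The CSR reference value is ≈ 53%, comfortably inside the random
band; 5%-jittered lattices score ≈ 5% and tight Thomas clusters score in
the hundreds, so the classifier margins are wide.

Sections are thick relative to a cell layer, so projecting a whole section
flattens ~1.6 lattice layers on top of each other and would destroy the
regularity signal. The package therefore analyses the *densest focal slab*
of about one soma diameter (10 µm) within a section
(`section_focus_pattern()`) — emulating a microscopist focusing on the
plane of best cell density — and crops it to the inscribed rectangle of the
section ellipse so that the tissue boundary does not masquerade as spatial
pattern. Per animal, polygon areas are pooled across the three most central
sampled sections before the CV is taken; the pooling order is a convention
(per-animal pooling, then CV) and is stated here because reasonable
alternatives (mean of per-field CVs) give slightly different numbers.

# Apoptotic index and body weight

The TUNEL-style apoptotic index over sampled fields is
$\text{AI} = \text{apoptotic cells}/\text{total cells} \times 100\%$,
pooled by default as summed counts over the (default ten) fields; the
mean-of-fields alternative is provided and the two coincide exactly when
field totals are equal. Body-weight change is
$[(\text{day-21 weight}) \times 100 / (\text{day-1 weight})] - 100$.

# The statistical decision tree

`compare_groups()` reproduces the decision tree used in this literature:
Kolmogorov–Smirnov normality per group (with estimated parameters) and
Levene's variance-homogeneity test (mean-centred, as in SPSS) route the
endpoint to one-way/two-way ANOVA with Tukey's post hoc, or to
Kruskal–Wallis with Dunn's post hoc (implemented from the rank-sum z
statistic with tie correction, unadjusted by default). Volumes and cell
numbers are compared pairwise with two-tailed Mann–Whitney U tests, and
Voronoi polygon-area variability with Levene's test. Constant groups are
flagged degenerate and sent down the nonparametric branch; identical data
yield $p = 1$ and no declared difference. Forced-branch calibration over
1000 null resimulations keeps each branch's empirical type-I error inside
[0.03, 0.07] at $\alpha = 0.05$.

# End-to-end studies

```{r study, fig.width = 6, fig.height = 3.5}
cfg <- study_config(groups = c("control", "CSD"), animals_per_group = 3,
                    neuron_count_true = 5000, glia_per_neuron_mean = 1)
report <- run_study(cfg, master_seed = 2026)
glance(report)
autoplot(report, "n_neuron")
```

`run_study()` derives one seed per (animal, analysis stage) from the master
seed with a counter-based splitting scheme, so results are bit-reproducible
and re-running a single animal (`analyze_animal()`) regenerates exactly its
rows. `write_study_report()` writes the per-animal table, group summaries,
comparison tables and a JSON manifest of the full configuration.

# Problem sizes, determinism and limitations

The validation suite runs at deliberately moderate sizes chosen to make the
Monte-Carlo noise small relative to the tested tolerances: 200 seeds for
Cavalieri bias/CE, 100 for disector recovery/CE, 50 patterns of 500 points
for each spatial calibration, 1000 resimulations for test size. These sizes
are the package's own validation design.

What the phantoms do *not* emulate — and hence what passing tests cannot
certify — includes: non-ellipsoidal and lobulated ganglion shapes, spatial
gradients in cell density, anisotropic shrinkage and section compression,
lost caps (nuclei torn off the cut faces; the guard-zone machinery is
exercised with uniform depth profiles and constructed depletions instead),
over- and under-projection of profiles, observer misclassification of
neurons versus glia, and staining artefacts. The estimators operate on
detected cell coordinates and counts; image segmentation is outside the
package's scope, as are alternative counting designs (physical disector,
nucleator) and 3-D tessellation.
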