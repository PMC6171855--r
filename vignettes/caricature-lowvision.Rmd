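---
title: "Shape caricaturing and low-vision simulation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape caricaturing and low-vision simulation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carilow)
```

## The problem this package models

In low-resolution vision — peripheral/macular-degeneration blur, or the
phosphenised percept of a retinal prosthesis — faces are hard to tell
apart. Caricaturing is a candidate image enhancement: exaggerate how an
individual face's *shape* deviates from a category-matched average face, so
every identity becomes more distinctive. The practical question is how much
of the caricature benefit survives when the landmarks driving the
exaggeration come from a real-time automatic detector (68 points, no
forehead/ear/brow-width/mid-nose-width coverage) instead of detailed hand
annotation (147 points).

`carilow` implements the full measurement pipeline for that question as
reusable, tested code, exercised end to end on synthetic faces and
simulated raters: caricature geometry and shape-only warping, the two
low-vision renderers, the pairwise dissimilarity-rating experiment design,
a rater simulator with a controllable true effect structure, and the
repeated-measures analysis culminating in the *relative effectiveness*
statistic.

## Caricature model

For veridical landmarks $v_i$, average landmarks $a_i$ and strength $s$,

$$p'_i = v_i + s\,(v_i - a_i),$$

so each landmark stays on the ray from the average through the veridical
position and its distance from the average scales by exactly $1+s$: $s=1$
is a doubling, and the behavioural studies' operating point is $s=0.6$
(above which morphing artefacts appear in real photographs). Two useful
exact identities follow, and both are enforced in the tests at $10^{-9}$
relative tolerance:

* composing strengths $s_1$ then $s_2$ equals one caricature at
  $s_1+s_2+s_1 s_2$;
* caricaturing *both* members of a same-category pair (same average) scales
  the distance between the two faces by exactly $1+s$ — the geometric core
  of why caricatured pairs look more different.

Strengths above 1 are refused unless explicitly overridden, since the
validated regime ends there. Anti-caricatures ($s<0$) are out of scope.

### Shape-only warping

The original stimuli were produced with closed-source morphing software;
this package standardises on the reproducible textbook realisation of
"warp, not fade": control points = landmarks plus eight fixed frame anchors
(corners and edge midpoints); Delaunay triangulation computed once on the
*source* control points and reused for the destination; backward mapping
with bilinear interpolation; pixels outside every destination triangle pass
through unchanged (no holes, stable background); an identity warp returns
the input bit-exactly. Destination triangles that collapse to zero area are
an error naming the triangle; orientation flips (folds) are detected and
reported with a warning rather than silently rendered. Whether the original
software applied smoothing beyond piecewise-affine warping is unknowable
from its description and is not emulated. The per-triangle fill runs in
C++ (Rcpp); the Delaunay construction (Bowyer–Watson, deterministic under
point order) is in R because no triangulation package is part of this
package's dependency set.

## Low-vision simulators

### Eccentricity-dependent blur

Acuity falls with eccentricity $E$ following the standard inverse-linear
law $f_c(E) = f_0\,E_2/(E_2+E)$, with defaults $f_0 = 30$ cycles/degree
(foveal cutoff) and $E_2 = 2.5°$ (eccentricity at which the cutoff
halves); both are exposed as parameters so exact constants from any
specific calibration can be dropped in. "Kernel size from the cutoff" is
defined as the Gaussian whose modulation transfer is $0.5$ at $f_c$:
$\mathrm{MTF}(f) = \exp(-2\pi^2\sigma^2 f^2)$ with
$\sigma = \sqrt{\ln 2/2}\,/\,(\pi f_c)$ degrees. The filter is applied in
the frequency domain (periodic boundary), which makes it exactly linear,
shift-invariant and mean-preserving, and lets the tests check the MTF
against the closed form: a grating at $f_c$ comes out at $0.500$ of its
input amplitude. Conversion from degrees to pixels uses the image's
angular-size metadata (default: the face subtends 18.11° along the
horizontal, a real head at 54 cm); the experiments' conditions are
$E \in \{20°, 30°\}$ plus the high-resolution passthrough $E=0$.

### Phosphenisation

A rows×cols electrode grid (40×40 or 32×32) is laid cell-centred over the
face box (landmark bounding box — hairline to below the chin — or the full
frame). Optionally a random 30% of sites is dropped (failed electrodes):
exactly $\mathrm{round}(0.3N)$ sites, sampled without replacement under a
seed, and one mask is drawn per condition and held fixed across trials —
a broken array does not re-randomise between stimuli. Each surviving site
reads the nearest-neighbour pixel intensity, quantised to $L=8$ uniform
levels. Rendering under-determination is resolved as follows: brightness is
conveyed jointly by peak amplitude $a=\ell/(L-1)$ and size
$\sigma_p = \Delta\,(0.30 + 0.10\,a)$ (where $\Delta$ is the grid
spacing), a simple linear coupling consistent with "both size and
centre-brightness carry intensity"; overlapping Gaussians are *summed*
(additive light) and clipped to $[0,1]$, not max-composited, so outputs
are bit-reproducible. Whether the original grid was square on the image or
anisotropic to the face box is not stated; here the grid spans the face
box per axis. Metamorphopsia, scotomata and gaze-contingent rendering are
deliberately not simulated.

## Synthetic faces

Faces are schematic, not photorealistic: every contract downstream is
geometric or photometric, so realism would add nothing testable. The
147-point template is a parametric layout covering every region of the
hand-annotation scheme (27-point jaw outline, 17-point hairline, 11 points
per ear, 10 per brow as a closed contour, 8 per eye, 19 nose points
including mid-width, 26 lip points); it is bilaterally symmetric, and the
male and female templates differ in a jaw-width parameter. The 68-point
set is a deterministic selection from the 147 points following the common
automatic-detector convention (jaw 17, brows 5+5, nose 9, eyes 6+6, mouth
12+8), which by construction omits forehead, ears, brow width and
mid-nose width. Since the original 147 coordinates were published only as
a figure, this layout is scheme-*defining* for the package: faithful to
region coverage, not to original pixel positions.

Identities are smooth displacement fields from the sex template: a
per-feature random affine (shift sd $0.008\,w$ px, axis scaling sd 4%) plus
small per-point jitter (sd $0.0015\,w$ px), scaled by a distinctiveness
multiplier. The ears ride with the outline group, and template clearances
(ear–jaw gap, forehead headroom, nose–mouth gap) are sized so that a 60%
exaggeration of a plausible identity does not fold the warp — mirroring
the empirical observation that 60% avoids morphing artefacts; residual
sliver-triangle folds are possible for extreme draws and are reported by
the warp. Non-frontal views apply horizontal foreshortening
$x' = x_c + (x-x_c)\cos(\mathrm{yaw})$ about the frame midline and drop
the occluded ear (147 → 136 points); the viewpoints are front, ±10° and
−30°. Average faces use a 50-identity pool per sex, disjoint from the 26
test identities. Rendering fills the landmark contours with flat tones
plus a mild vertical gradient on the head, so rendering caricatured
landmarks and warping the rendered veridical face agree except in narrow
contour bands (the tests bound the disagreeing fraction at 10% of pixels).
The default frame is 128×128 px: large enough for 40×40 phosphene grids
and sub-pixel landmark geometry, small enough that the full 312-image
inventory builds in seconds.

## Experiment design

Each sex's 13 identities are split once (seeded) into subsets of 7 and 6;
every within-subset pair is rated once per condition: $(21+15)\times 2 =
72$ trials in each of the nine resolution × caricature conditions, 648 per
participant. Both members of a pair always share the trial's condition.
The blur experiment (high-resolution, Blur20, Blur30) is blocked by face
sex with block order counterbalanced (odd-numbered participants start with
male faces — the counterbalancing granularity is not specified in the
source procedure, so strict alternation was chosen) and all nine
conditions intermixed within a block. The phosphene experiment is
additionally blocked by resolution in the fixed order 40x40ND, 40x40DO,
32x32DO, with a rescale marker at each block start: participants re-anchor
the 1–9 scale per resolution, which lifts low-resolution ratings off the
floor but makes *between*-resolution mean comparisons invalid. Viewpoint
(4 options), presented size (uniform 4.3–9.1°) and left/right placement
are not constrained by the design and are drawn under the seed. A schedule
is exhaustively reconstructible from (experiment, seed).

## Rater model

Each trial's latent dissimilarity is the mean Euclidean distance between
the two identities' ground-truth landmarks at the trial's viewpoint (face
A's viewpoint; face B's is presentation metadata). The rating is

$$r = \mathrm{clip}\big(\mathrm{round}\big(\mathrm{affine}_{\mathrm{block}}
(g\,d + \varepsilon)\big), 1, 9\big),$$

where the block affine maps the block's latent range onto $[1,9]$
(modelling scale use and the per-block re-anchoring instruction),
$\varepsilon$ is Gaussian with sd $\sigma_r$ times the block's latent sd,
and $g$ is the condition gain. Linear scale use is assumed, as in the
source analysis. Defaults, chosen once as the generator's study
conditions:

* $g_{C147} = 1.6$ — not free: it is the exact geometric distance scaling
  of a 60% caricature of both pair members away from a shared average;
* 68-point effectiveness (fraction of the $g_{C147}-1$ gain realised):
  0.68 for high-resolution, 0.65 for blurred, 0.39 for phosphenised
  viewing — the per-format effect structure reported behaviourally, whose
  six-plot average is ≈52%;
* caricature-effect attenuation 0.6 at the two degraded phosphene
  resolutions, reproducing the reported pattern that the *overall*
  caricature effect (V to C-147p gap) shrinks at lower prosthetic
  resolutions, which drives the caricature × resolution interaction there;
* $\sigma_r = 1.5$. No quantitative rater-noise estimate exists to
  reconstruct; this value was calibrated once so that simulated condition
  means concentrate in the central band of the scale and simulated test
  statistics have realistic magnitudes. Under the linear
  latent→affine→round model the veridical condition means settle around
  3.3–4.5 depending on block structure: the schematic cohort's
  pair-distance spread is wider than real faces', so the empirical 4–6
  band is approached but not exactly reproduced — a known limitation of
  the generator, not of the analysis.

Because the block affine removes shift and scale, the relative
effectiveness statistic is invariant to everything the rescaling
instruction distorts, and the simulator is invariant to global rescaling
of the latent distances (asserted bit-exactly in the tests).

## Analysis

Scoring averages ratings per participant × resolution × caricature cell
(optionally split by face sex for the preliminary 3×3×2 within-subjects
check, which collapses over sex when no sex effect appears). Contrasts are
two-tailed paired t tests computed from the closed formula (defined — as
$t=0$ — even for identical samples, where `t.test()` errors); ANOVAs are
fully within-subjects via `stats::aov` with `Error()` strata, reported
with uncorrected degrees of freedom (no sphericity correction, matching
the source analysis; the 3×3 interaction has df (4, 76) at $N=20$), and
every ANOVA output is tested against an independent brute-force
sums-of-squares oracle. Error bars use the within-subject SEM
$\sqrt{\mathrm{MSE}/N}$ from the one-way repeated-measures ANOVA on
caricature level — the printed formula "MSE divided by $\sqrt N$" is
dimensionally inconsistent and is implemented in the standard form.

Relative effectiveness is

$$\mathrm{RE} = 100\,\frac{\bar C_{68} - \bar V}{\bar C_{147} - \bar V},$$

100 when the two caricatures are equally effective, 0 when the 68-point
caricature adds nothing, undefined (an error, not a number) when the
147-point gap is below tolerance. The source text prints the reciprocal
formula while reporting values (52% overall) that only the orientation
above produces; the package implements the text-consistent orientation and
exposes the literal printed form behind `orientation = "printed"`. The
overall figure averages the six per-plot REs (one per resolution per
experiment); per-format figures average the high-resolution plot, the two
blur plots and the three phosphene plots respectively. The
between-experiment comparison of caricature benefit is reported
descriptively only (a Welch t; the deposited analysis' df for this test
does not match two independent groups of 20, and the exact variant used
is unknowable).

`reproduce_published()` pushes a deposited per-trial ratings table (XLSX
via `readxl`, or delimited text) through exactly this analysis; a mapping
argument adapts unknown column/level namings. The deposited workbook is
not distributed with the package, so the tests exercise this path on
simulated data written in the documented schema, and parameter recovery
(below) stands as the quantitative validation of the analysis stage.

## What the tests do and do not show

The test suite validates geometry, simulators and statistics against
independent oracles (closed forms, explicit enumeration, brute-force sums
of squares) and validates the *pipeline* by parameter recovery: with a
uniform programmed effectiveness ratio of 0.52, a single simulated
20-participant pair of experiments recovers RE within ±5 percentage
points, and the mean over 200 replicates within ±2; recovery is unbiased
across ratios 0.2–0.8 (25 replicates each in the routine suite — the
Monte-Carlo error at that size, ≈0.25 pp, is well inside the 2 pp bound).
Problem sizes throughout (128 px frames, 20 simulated participants,
25–200 replicates) were chosen so the full suite runs in a few minutes
while keeping Monte-Carlo error far from every asserted bound.

Passing tests show the machinery is correct and the estimator unbiased
under the generator's assumptions. They cannot show that real raters are
linear, that real face-to-face perceptual distance is the mean landmark
distance, or that photographic texture (which the synthetic renderer only
sketches) carries no identity information — those are substantive
assumptions of the underlying method, inherited knowingly here.

## Known limitations

* Synthetic faces have no texture/reflectance detail; the "warp not fade"
  distinction is structural (the code never blends intensities), but
  texture-driven perceptual effects cannot emerge from these stimuli.
* The blur constants and the phosphene size–brightness coupling are
  declared approximations with exposed parameters; any calibrated
  constants can be substituted without code changes.
* The 68-point caricature is driven by the derived 68-point landmarks;
  regions those landmarks do not cover move only through the warp's
  triangulation, which is the mechanism under study, not an artefact.
* Rating simulation is deliberately minimal (no sequential effects, no
  participant-specific scale habits beyond the block affine, no lapses).
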