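---
title: "Derivative-preserving mapping of neuron traces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Derivative-preserving mapping of neuron traces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurojet)
```

## The problem

Neuron reconstructions are stored as sparse sequences of 3D points
("knots", e.g. the SWC format), with the neuron conventionally taken to
be piecewise linear between knots. To compare morphologies across brains,
traces must be carried into a common coordinate system by a
transformation $\phi:\mathbb{R}^3 \to \mathbb{R}^3$ that is, in general,
nonlinear. The conventional approach — *zeroth-order mapping* — moves
only the knot positions, $x_i \mapsto \phi(x_i)$, and re-draws straight
segments between the images. This ignores how $\phi$ bends the segment
interiors: two different samplings of the same neuron can map to visibly
different shapes, and the error grows with the knot spacing and with the
nonlinearity of $\phi$.

neurojet implements *first-order mapping*: each knot carries not only a
position but a tangent, and the pair is transported by the jet-space
action of $\phi$. The mapped segment is then reconstructed with a cubic
Hermite spline that honors the transported endpoint tangents.

## Jets and the group action

A $k$-jet of a curve $c$ at parameter $t$ is the tuple
$(c(t), \partial_t c(t), \dots, \partial_t^k c(t))$. Diffeomorphisms act
on jets so that acting commutes with composing the map with the curve;
for $k = 2$,

$$\phi \cdot (t, x_0, x_1, x_2) =
  \big(t,\ \phi(x_0),\ D\phi(x_0)\,x_1,\
  D\phi(x_0)\,x_2 + D^2\phi(x_0)(x_1, x_1)\big).$$

`jet_transform()` implements this action for $k \le 2$; the tests verify
the group-action axioms (identity, compatibility with composition) and
the commutation property numerically, since those axioms are what make
transported derivatives meaningful rather than decorative. Mapping uses
$k = 1$; the order-2 action is provided because the Hessian term is
cheap to state and useful for future quintic reconstruction, but no
production mapping path uses it.

Branches are parameterized by arc length, so the order-1 lift of a
piecewise-linear branch assigns each segment its unit chord
$(x_{i+1} - x_i)/|x_{i+1} - x_i|$ as a one-sided derivative at both
endpoints (`prolong()`). Interior knots therefore carry a possibly
different derivative on each side; we deliberately follow the one-sided
convention of the original SWC representation rather than averaging
tangents into a $C^1$ field, because the one-sided choice treats each
segment independently and makes segment-level mapping exact at the knots
by construction. Mapped tangents $D\phi\, u$ are used as-is (they are
generally not unit norm); renormalizing them would change the Hermite
interpolant and break the fourth-order error behavior.

## The three mapping schemes

For a segment $[x_0, x_1]$ of length $L$ all three schemes are evaluated
on the identical parameter grid $\{0, 2, 4, \dots\} \cap [0, L)$ plus
$L$ (microns; the pitch is a parameter, default 2):

* **ground truth**: sample the *source* segment on that grid and apply
  $\phi$ to every sample — the true image of the piecewise-linear curve.
* **order 0**: apply $\phi$ to the endpoints and interpolate linearly.
* **order 1**: additionally transport the chord through $D\phi$ at both
  endpoints and evaluate the unique cubic Hermite interpolant.

As printed in the obvious pseudo-code, a loop sampling "every 2 microns"
with $N = \lceil L/2 \rceil + 1$ points would step past $L$ (e.g.
$L = 5$ would visit $s = 6$); we clamp interior samples to $s < L$ and
append $s = L$, identically for all three schemes, so comparisons are
always between samples at the same source parameters.

Whole traces are handled by decomposing the tree into non-bifurcating
branches — recursively extracting the root-to-leaf path of maximal arc
length, with ties broken toward the smaller leaf id for determinism —
mapping each segment, and re-fusing the junction copies
(`decompose_branches()`, `map_trace()`). Junction copies are images of
the same point under the same function, so they must agree to within
1e-9 microns; a larger discrepancy is reported as an error rather than
averaged, since it can only arise from a bug or a non-function
"transformation". Dense outputs chain each branch's samples and attach
the branch's first sample to the fused junction node, which preserves
the rooted-tree topology exactly.

## Error bounds

Two complementary worst-case bounds are implemented.

`jacobian_error_bound()` bounds the zeroth-order error of an arc-length
parameterized piecewise-linear curve by
$\max_i \sup_t \tfrac12(\|D\phi(c(t)) - I\|_2\,|t_i - t_{i-1}| +
|\epsilon_i - \epsilon_{i-1}|)$ with $\epsilon_i = c(t_i) - \phi(c(t_i))$.
The supremum over each interval is approximated by dense probing
(default 100 points per interval), which makes the computed value a
lower estimate of the exact supremum; the probe count is reported so
users can tighten it. The interval index is taken over
$[t_{i-1}, t_i]$ for $i = 2, \dots, n$ (knots numbered from 1).

`spline_error_bounds()` gives the pair of comparable bounds driven by
derivative maxima $M_2, M_3, M_4$ of the transformed curve
$f = \phi \circ c$ and the largest knot spacing $\delta$:
$\tfrac34 M_4 (\delta/2)^4 + \tfrac32 (\delta/2)^2 M_3 (\delta/2) +
\tfrac32 (\delta/2)^2 M_2$ for order 0, and
$\tfrac{3}{4!} M_4 (\delta/2)^4$ for order 1. The second is always at
least as tight and both are attained by worst-case curves. The maxima
are either supplied directly (keeping the arithmetic testable in
isolation) or estimated by `estimate_curve_derivative_maxima()` with
central finite differences confined to segment interiors (each segment
is a separate smooth piece of $f$), inset two stencil steps from the
knots where $f$ is merely continuous. Estimated maxima over a dense
probe grid are at least the at-knot values the order-0 bound formally
needs, so using them keeps the bound valid, merely (slightly) looser.

## Random deformations

Test-bed transformations are generated in the LDDMM spirit: i.i.d.
zero-mean Gaussian momenta with standard deviation $\sigma$
(microns/time) at every node of a regular grid, smoothed into a velocity
field, and integrated over unit time. Design choices, made once:

* **Smoothing**: separable Gaussian kernel, default width (standard
  deviation) 500 microns — the spatial scale at which displacement
  profiles of such fields are usually summarized. The kernel is
  normalized to unit mass, so smoothing is a weighted average of the
  momenta; the resulting velocity magnitude is a fixed, resolution-
  dependent fraction of $\sigma$ and strictly monotone in it. At the
  grid boundary the kernel is renormalized over its in-grid support.
* **Integration**: the flow $\dot x = v(x)$ with a stationary velocity
  field and $N$ Euler steps (default 10). Full geodesic shooting with
  momentum transport is out of scope: the mapping algorithms and bounds
  are agnostic to how $\phi$ was produced, and a stationary-velocity
  flow already yields large, smooth, invertible deformations whose
  severity is controlled by a single knob.
* **Invertibility audit**: the Jacobian determinant of the integrated
  map, by central differences on the grid, must be positive at every
  interior node; otherwise the velocity is scaled by 0.7 and the flow
  re-integrated (bounded retries, recorded in the descriptor).
* **Interpolation**: trilinear, on the displacement field. Simple,
  monotone, and adequate for fields smoothed at 500 microns; it makes
  $\phi$ piecewise-trilinear, so its Jacobian is obtained by forward
  differences (step 1e-3 microns; analytic maps default to 1e-5).
* **Domain**: queries outside the grid are errors, never
  extrapolations — silent extrapolation would corrupt mapping
  experiments. The grid must cover the (origin-centered) trace plus a
  kernel-width margin.

The generator is a pure function of its config, including the seed, and
it restores the caller's RNG state.

## Synthetic traces

`generate_trace()` grows branches with an integrated random-walk
tangent model: the heading persists and receives a Gaussian perturbation
of magnitude `curvature_scale` per micron of path, knots are placed at
`sampling_period` microns with ±30% jitter, and side branches sprout
from uniformly chosen non-leaf nodes. Defaults — 3 branches, 8–20 knots
per branch, 10-micron sampling, curvature 0.02/micron, 250-micron
extent — emulate a desk-scale reconstruction in the sampling regime
where conventional mapping is still accurate, so improvements measured
there are conservative. What the generator does *not* emulate: radius
variation (mapping ignores radii), somata, sampling-density correlated
with curvature as human tracers produce, or multi-millimeter axon
arbors. Passing tests on synthetic traces therefore demonstrate the
numerics of mapping, not fidelity to any particular species' anatomy.

## Experiment protocols

`run_sigma_sweep()` centers each trace at the origin (mean of node
positions; the center convention is a fixed package choice), generates a
deformation per $(trace, \sigma)$ with $\sigma \in \{80, 160, 320,
640\}$ by default, and scores both schemes against dense ground truth by
branch-matched discrete Frechet distance and by KS statistics of path
angle, branch angle, tortuosity, and segment length. The same generator
seed is reused across $\sigma$ levels for a given trace, so severity
levels are scaled versions of one deformation and comparisons across
$\sigma$ are paired.

`run_node_removal_study()` scores redundancy of near-straight knots:
every non-branching, non-terminal node with path angle above 170 degrees
is tentatively removed, the parent-to-child segment is mapped with each
scheme, and the result is compared with the ground-truth mapping of the
original two-segment span (span-level ground truth, using the dense
2-micron samplings of both curves); a node is removable if the discrete
Frechet error is at most 1 micron. An input with no candidates returns
an empty-result flag rather than an error.

Problem sizes used by the shipped tests and the acceptance script — 20
synthetic traces of ~40 knots, grids of ~3000 nodes, 1000 random
polyline pairs for the Frechet cross-check — were chosen as the smallest
sizes at which the Monte-Carlo trends are stable across seeds.

## Numerical choices and degenerate inputs

* Repeat trace nodes (a child at exactly its parent's position) are
  rejected at read time: they make arc-length parameterization
  degenerate, and curated real datasets exclude them for the same
  reason. Non-consecutive revisits of a position are accepted — each
  segment's parameterization remains valid.
* Zero-length segments cannot reach the mapping layer (the reader
  rejects them); `prolong()` still guards against them.
* The discrete Frechet DP is the standard $O(nm)$ dynamic program,
  compiled; the test suite pins it against exhaustive coupling
  enumeration on all shapes up to 7x7.
* Tortuosity of a branch whose endpoints coincide is undefined and
  dropped from summaries.
* SWC positions are written with 17 significant digits so a write/read
  cycle reproduces the node table exactly.

## Known limitations

* The deformation generator uses a stationary velocity field, not
  EPDiff geodesic shooting; its $\sigma$ controls severity monotonically
  but the absolute displacement scale depends on grid spacing and
  kernel width, so histograms from other implementations are not
  reproduced point-for-point.
* Morphometric definitions (angles at nodes, per-branch tortuosity) are
  fixed, documented conventions; other toolkits differ in detail, and
  only distribution *comparisons* between mappings of the same trace
  are intended to be meaningful.
* Second-order mapping is not a production path: the order-2 action
  exists, but no quintic reconstruction is built on it.
* Loop-containing graphs and multi-point soma contours are out of
  scope; soma points are treated as ordinary nodes.
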