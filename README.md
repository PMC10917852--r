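# neurojet

Derivative-preserving mapping of neuron traces under nonlinear
diffeomorphisms.

## The problem

Digital neuron reconstructions (SWC files) are sparse sequences of 3D
knots joined by straight segments. To pool morphologies across brains,
traces are pushed through a nonlinear transformation
φ: ℝ³ → ℝ³ into a common coordinate space. Standard pipelines move only
the knot positions (*zeroth-order* mapping), which ignores how φ bends
the segments between knots: the mapped shape then depends on how the
neuron happened to be sampled, and the error grows with knot spacing and
with the nonlinearity of φ.

neurojet additionally transports each knot's tangent through the
Jacobian of the transformation — the order-1 jet-space group action

    φ · (t, x₀, x₁) = (t, φ(x₀), Dφ(x₀) x₁)

— and reconstructs each mapped segment with a cubic Hermite spline
matching the transported endpoint positions and tangents
(*first-order* mapping). For a segment of knot spacing δ the worst-case
deviation from the true image shrinks from O(δ²) (zeroth order) to
O(δ⁴) (first order); both rates, and the corresponding closed-form
bounds, are computed by the package and verified by its tests.

The package covers the full workflow:

* `read_swc()` / `write_swc()` — strict SWC I/O with tree validation;
* `decompose_branches()` / `reassemble()` — split a tree-shaped trace
  into non-bifurcating branches (longest root-to-leaf path first) and
  fuse mapped branches back together;
* `jet_transform()`, `prolong()` — the jet action (orders 0–2) and the
  arc-length lift of a branch;
* `map_trace()` and the segment-level `map_segment_*()` — ground-truth,
  zeroth- and first-order mapping on a dense 2 µm grid;
* `jacobian_error_bound()`, `spline_error_bounds()`,
  `estimate_curve_derivative_maxima()` — worst-case error bounds;
* `random_diffeomorphism()` — LDDMM-style random deformations from
  Gaussian initial momenta (severity knob σ), with invertibility audit;
* `discrete_frechet()`, `trace_frechet()`, `morphometry()`,
  `ks_statistic()` — evaluation metrics;
* `generate_trace()`, `run_sigma_sweep()`, `run_node_removal_study()` —
  synthetic traces and the two benchmark protocols.

A thin command-line wrapper with `map`, `bound`, `evaluate`,
`sigma-sweep` and `node-removal` subcommands ships in `inst/cli/`.

## Worked example

```r
library(neurojet)

# a synthetic 3-branch trace, ~10 um knot spacing, centered at the origin
tr  <- center_trace(generate_trace(synthetic_trace_config(n_branches = 3,
                                                          seed = 42)))
tr
#> neuron_trace: 56 nodes, 3 leaves

# a strong random deformation covering the trace plus a kernel margin
ext <- max(abs(as.matrix(tr$nodes[, c("x", "y", "z")]))) + 500
phi <- random_diffeomorphism(random_diffeo_config(sigma = 640,
                                                  grid_extent = ext,
                                                  seed = 7))

gt <- map_trace(tr, phi, "ground_truth")  # dense 2 um truth
m0 <- map_trace(tr, phi, 0)               # positions only
m1 <- map_trace(tr, phi, 1)               # positions + tangents

trace_frechet(m0, gt)   # 0.0100 um
trace_frechet(m1, gt)   # 0.0055 um

# a priori worst-case bound for zeroth-order mapping of branch 1
br <- decompose_branches(tr)$branches[[1]]
jacobian_error_bound(br, phi)
#> zeroth-order mapping error bound: 0.4277518 um
#>   max knot spacing: 12.77565 um; 100 probes per interval
```

Read: under this deformation the conventional mapping is off by up to
about a hundredth of a micron somewhere along the trace (sub-micron
because the trace is densely sampled relative to the 500 µm deformation
scale); carrying tangents roughly halves that error, and the
Jacobian-based bound guarantees before mapping that the zeroth-order
error cannot exceed ~0.43 µm on the longest branch. With sparser knots
the gap widens quickly — error scales as δ² vs δ⁴.

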