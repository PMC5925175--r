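# tissuecut

Batch simulation of surgical soft-tissue cutting with a coupled
mesh–meshless model, for researchers prototyping surgical-simulation and
haptics algorithms.

Virtual-surgery systems need two things at once from a soft-tissue model: a
renderable surface whose incision looks right, and interior mechanics that
survive topology change. `tissuecut` couples the two standard answers. The
tissue surface is a triangle mesh; an incision is modelled with two quadratic
Bézier curves

P(t) = (1−t)² P₀ + 2t(1−t) P₁ + t² P₂,  t ∈ [0, 1],

through the cut's endpoints and the extremal affected vertices on each side
of the chord, and the surface is retriangulated so the sampled curves become
the free wound boundary. The interior is a cloud of meshless point elements
with MLS displacement-gradient elasticity: per point, the moment matrix
M = Σⱼ ωᵢⱼ xᵢⱼ xᵢⱼᵀ maps weighted neighbor displacement differences to a
gradient estimate, from which Green strain
ε = ½(∇U + ∇Uᵀ + ∇Uᵀ∇U), Hookean stress σ = Eε, and antisymmetric pairwise
forces follow, integrated by explicit (optionally damped) Euler steps. Two
signed-distance level sets — the blade plane and the vertical plane at the
cutting depth — classify point elements into cutting-affected "+"/"−" flaps
and unaffected points that are skipped entirely. Interpolated *virtual
points* on the incision boundary carry the surface opening into the meshless
solve as prescribed displacements, and an oscillating modulation
Γ(t, d) = e^(−at) sin(bt)·k·d shapes the haptic feedback force series.

See `vignettes/coupled-cutting.Rmd` for the model details, parameter
defaults and numerical choices.

## Worked example

A straight, constant-depth cut across the top face of a synthetic box model
(9 × 9 × 9 mm, 3 mm point lattice, subdivided surface):

```r
library(tissuecut)

model <- make_box_model(c(9, 9, 9), 3, surface_segments = 3L, density = 0.05)
model$mesh
#> surface_mesh: 56 vertices, 108 triangles
#>   boundary edges: 0, Euler characteristic: 2

cfg <- sim_config(
  model = list(type = "box", extent = c(9, 9, 9), spacing = 3,
               surface_segments = 3L, density = 0.05),
  trajectory = replicate(15, list(tip = c(0.5, 4.5, 9),
                                  handle = c(8.5, 4.5, 9), depth = 5),
                         simplify = FALSE),
  material = material_params(E = 1, h = 6.6, dt = 0.01, damping = 0.3),
  samples_per_curve = 8L, steps_per_pose = 20L, opening_scale = 0.5,
  seed = 1L)
s <- run_cutting(cfg)
s
#> cutting_session: 15 poses, 64 point elements
#>   final affected: 32, max displacement 0.2314 mm

head(s$pose_log, 3)
#>   pose affected unaffected path_len gradient_evals   max_disp
#> 1    1       32         32        2            640 0.01818238
#> 2    2       32         32        2            640 0.03790380
#> 3    3       32         32        2            640 0.05674364
```

Half the 64 point elements lie above the 5 mm cutting depth and are
classified affected; only those incur solver work (`gradient_evals` =
32 affected × 20 steps). The wound opens to a maximum interior displacement
of 0.23 mm, the cut mesh gains one boundary loop (the open wound), and
`s$force_series` holds the modulated feedback force whose oscillation peaks
decay with the Γ envelope. The bundled empirical porcine-liver cutting-force
fit peaks at 42.85 N at 3.170 mm blade displacement:

```r
co <- force_fit_coeffs()
xs <- seq(0, 6, by = 1e-4)
max(empirical_force(xs, co))        # 42.84742 N
xs[which.max(empirical_force(xs, co))]   # 3.17 mm
```

A thin command-line wrapper ships in `inst/cli/tissuecut.R` with `synth`,
`simulate` (YAML configs) and `validate` subcommands.

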