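# efgm — meshfree simulation of myocardial electrical propagation

`efgm` simulates the spread of electrical activation through cardiac tissue
with the **element-free Galerkin method (EFGM)**: the tissue is a cloud of
unstructured sample nodes (no mesh, no connectivity), field variables are
approximated by moving-least-squares (MLS) shape functions built on the fly
around each evaluation point, and the weak form of the monodomain
reaction–diffusion equation

∇·(**D** ∇v\_m) = A\_m (C\_m ∂v\_m/∂t + I\_ion) − I\_s,  (**D**∇v\_m)·**n** = 0 on the surface,

is integrated with Gauss quadrature on a regular background mesh that merely
covers the domain. It is aimed at computational electrophysiologists and
numerical-methods researchers who want a transparent, fully scriptable
meshfree reference solver with verification experiments built in.

The core pieces:

* **MLS approximation** (`mls_shape`): φ = p(x)ᵀA⁻¹B with A = PᵀWP, B = PᵀW
  over the nodes whose influence domains (radius d\_max · c\_I) cover the
  point; cubic or quartic compactly supported weights; linear or quadratic
  basis; analytic first derivatives via d(A⁻¹)/dx = −A⁻¹(dA/dx)A⁻¹.
* **Assembly** (`assemble`): sparse mass and stiffness matrices
  M\_ij = ∫φ\_iφ\_j dΩ, K\_ij = ∫∇φ\_iᵀ**D**∇φ\_j dΩ, with per-point
  anisotropic tensors **D** = σ\_cf I + (σ\_f − σ\_cf) f fᵀ built from
  MLS-interpolated nodal fiber directions.
* **Membrane models** (`cubic_current`, `fhn_rhs`): the cubic polynomial
  ionic model with the closed-form cable conduction velocity
  γ = √(gσ/(A\_m C\_m²)) · S/√(S+1), S = v\_p/(2v\_th) − 1
  (`analytic_velocity`), and a modified FitzHugh–Nagumo model.
* **Time integration** (`integrate_euler`, `integrate_rk4_adaptive`),
  **activation maps** (`activation_times`: time of maximum upstroke) and
  **conduction velocities** (`conduction_velocity`).
* **Verification experiments** (`run_heat2d`, `run_cable1d`, `run_cube3d`,
  `run_ventricle`) with hand-rolled FDM/FEM baselines, plus synthetic
  geometry generators up to an idealized fiber-wrapped ventricular shell.

## Worked example: conduction velocity on a 1D cable

The cubic ionic model admits an exact traveling-front speed, which makes the
cable the one quantitative benchmark in cardiac tissue. Simulate a 20 mm
fiber at σ = 0.5 mS/mm with the meshfree solver at 0.2 mm spacing and
compare:

```r
library(efgm)

p <- cubic_ionic_params()        # rest -85 mV, threshold/plateau 10/100 mV
analytic_velocity(p, sigma = 0.5)
#> [1] 0.5656854

row <- data.frame(method = "efgm", kind = "cubic", d_max = 1.5, h = 0.2)
rep <- run_cable1d(sigma = 0.5, rows = row, params = p)
rep$rows[, c("method", "h", "mean_velocity", "rms")]
#>   method   h mean_velocity          rms
#> 1   efgm 0.2     0.5657775 0.0001083240
```

The simulated mean front speed (0.56578 mm/ms) matches the closed form
(0.56569 mm/ms) to 0.02%, and the RMS of the node-wise velocities about the
analytic value is about 1e-4 mm/ms. A 3D plane wave in the 60 mm cube:

```r
g <- make_regular_grid(rbind(rep(0, 3), rep(60, 3)), 10)   # 10^3 nodes
run <- cube_wave_run(g$cloud, g$domain, 9, "isotropic", points_per_axis = 2)
run$speed
#> [1] 0.2015201
```

i.e. a FitzHugh–Nagumo plane wave at ~0.20 mm/ms, which stabilizes under
node refinement at or before the 10×10×10 lattice. Snapshots
(`write_snapshots`) and activation maps (`write_activation_csv`) export to
legacy VTK and CSV; `exec/efgm` wraps the experiments for shell use
(`Rscript exec/efgm verify cable1d`).

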