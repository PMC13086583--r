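# torquepuck

Hydrodynamic torque-dipole transmission from confined swimming bacteria to
symmetric microdiscs ("pucks"), as an R package: the Stokes-flow solver, the
analytic angular-dynamics model, a chiral-bath collision model, synthetic data
generators, and trajectory-level inference.

## The problem

A swimming *E. coli* is force- and torque-free, but its rotary flagellar motor
makes it a hydrodynamic **torque dipole**: the flagellar bundle spins one way
(torque `+Γ_M x̂` on the fluid at position `r₁`) and the cell body counter-rotates
(`−Γ_M x̂` at `r₂`), with dipole length `ℓ_D = |r₁ − r₂|`. In open fluid this
far-field signature is negligible next to the force dipole. But when the
bacterium swims through a narrow square channel (half-width `W`) cut into the
underside of a sedimented microdisc, each rotlet drives a shear traction on the
channel's top wall — which belongs to the disc — and transmits a **net vertical
torque** even though the disc is perfectly symmetric:

```
Γ₁ = −Λ (x₁ − x_C)/W · Γ_M          (single rotlet)
Γ  = −Λ (ℓ_D / W) · Γ_M            (the full dipole; position-independent)
```

`Λ` is a positive dimensionless transmission constant, independent of every
physical parameter; this package computes it by a regularized-Stokeslet
boundary-element solve of the no-slip duct problem, cross-validated against an
independent staggered-grid finite-difference Stokes solver. With rotational
mobility `M_Θ` (Stokes–Einstein, `M_Θ = D_Θ/k_BT`) the puck angle during a
crossing at speed `U_s` follows, as a function of bacterial position
`X_B = U_s t`,

```
ΔΘ(X_B) = −Λ (ℓ_D/W)(M_Θ/U_s) Γ_M · X_B                         (both rotlets confined)
ΔΘ(X_B) = (Λ/W)(M_Θ/U_s) Γ_M [X_B²/2 + X_B(ℓ_B − ℓ_D − R) + ℓ_B(ℓ_B − 2R)/2]
                                                                 (body has exited)
```

a clockwise dip followed by an anticlockwise recovery — the "down–up" shape —
with the reversal at `X* = 2R − ℓ_B`, where the two branches are exactly
continuous. The dipole length scales with the body, `ℓ_D = α ℓ_B`; `α` is the
model's only fitting parameter. Plain discs in a dilute bath of
clockwise-circling bacteria are also covered by a minimal
collision-rectification model (rectified fraction `ℓ_B/R_c`) that yields
`ω ∝ 1/R` and thermal `D_Θ ∝ R⁻³`.

Units everywhere: µm, s, pN (torque pN·µm, angles rad, viscosity
10⁻³ pN·s·µm⁻²).

## Worked example

```r
library(torquepuck)

b <- torque_dipole_spec(motor_torque = 2, body_length = 5,
                        dipole_ratio = 1.5, swim_speed = 20)
p <- puck_state(10, diffusivity = 6e-5)
print(p)
#> puck: R = 10 um, M_Theta = 0.01458 rad/s/(pN um), D_Theta = 6e-05 rad^2/s (T = 298.15 K)

reversal_point(b, p, W = 1, lambda = 0.17)
#> reversal at X* = 15 um, dip depth 0.0279 rad
```

The reversal sits at `X* = 2R − ℓ_B = 15` µm and the dip depth
`ΔΘ_max = Λ(ℓ_D/W)(M_Θ/U_s)Γ_M(2R − ℓ_B) ≈ 0.028` rad — a few-degree clockwise
swing per crossing. Simulating noisy crossings at the acquisition rate
(10 frames/s, thermal `D_Θ = 6×10⁻⁵ rad²/s`) and fitting back the dipole ratio:

```r
trs <- lapply(1:50, function(i)
  generate_crossing(b, p, W = 1, lambda = 0.17, seed = i))
fit_alpha(trs)
#> dipole-ratio fit: alpha = 1.407 +/- 0.110 (pooled, 50 traces, 326 samples)
```

which recovers the generating `α = 1.5` within its confidence interval. A
single 5-µm bacterium trapped in a chamber drives

```r
chamber_rate(chamber_layout(occupancy = 5), NULL, p, W = 1, lambda = 0.17)
#> -0.0372 rad/s
```

i.e. clockwise rotation at the few-times-10⁻² rad/s scale, and an order of
magnitude above the contact-push estimate
`chamber_push_estimate(0.2, 0.5, p$mobility)` ≈ 1.5×10⁻³ rad/s. The
transmission constant itself:

```r
compute_lambda(channel_geometry(1, truncation_factor = 20))
#> torque-transmission constant Lambda = 0.1943 +/- 0.0015
```

A YAML-configured pipeline front-end (`run_pipeline()`, with a thin CLI at
`inst/cli/torquepuck.R`) exposes the same steps as subcommands (`lambda`,
`profile`, `simulate-crossing`, `simulate-bath`, `simulate-chamber`,
`estimate`, `fit-alpha`, `collapse`) with seeds and config hashes recorded in
every result envelope.

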