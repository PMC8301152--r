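# sphincterFE

Finite-strain, plane-stress finite-element modelling of internal urethral
sphincter opening, for the computational assessment of hole-drilling surgery
in primary bladder neck obstruction (PBNO).

## The problem

In PBNO the internal urethral sphincter fails to open during voiding. A
proposed laser procedure drills a small number of through-holes (radius
0.5 mm) into the fibrotic part of the sphincter instead of incising it, to
restore opening while preserving the muscle ring and anterograde
ejaculation. `sphincterFE` asks the mechanical question behind that
procedure: given a two-dimensional cross-section of the sphincter under
intraluminal pressure, how much open area is lost to fibrosis, and how much
of it do the drilled holes recover?

The model is a parametric 2D domain: a circular lumen surrounded by a stiff
dense-connective (transitional epithelium) ring and a soft spongy stratum
(lamina propria) divided into four parts by thin slits, with two 1-mm
ligaments connecting the upper and lower halves. The two lower spongy parts
can be fibrotic, and 0-7 circular holes are drilled into the fibrotic
region (aligned on one arc, or staggered on two). Every tissue is a
five-parameter Mooney-Rivlin hyperelastic solid,

    W = C10 (I1b - 3) + C01 (I2b - 3) + C20 (I1b - 3)^2 + C02 (I2b - 3)^2
        + C11 (I1b - 3)(I2b - 3) + (1/d1) (J - 1)^2,

with `I1b`, `I2b` the isochoric invariants of the right Cauchy-Green tensor
and `J` the volume ratio; fibrosis is a tenfold deviatoric stiffening of the
spongy tissue. The lumen carries a follower pressure (1960 Pa working
pressure, i.e. about 20 cm H2O), plane stress is enforced pointwise through
the thickness stretch, and equilibrium is solved by a total-Lagrangian
Newton method driven by an area-controlled continuation that is robust near
the structure's pressure limit point.

The quantitative outputs mirror the clinical question: the deformed lumen
area `A` per configuration, the opening loss
`delta_l = 100 (A(Hi) - A(P0)) / A(H0)` and the opening recovery
`delta_r = 100 (A(Hi) - A(H0)) / A(H0)`, where `P0` is the sane
configuration, `H0` the fibrotic one, and `Hn` the fibrotic one with `n`
drilled holes.

## A worked example

```r
library(sphincterFE)

# solve the six-hole case at the 1960 Pa working pressure
sol <- solve_case("H6")
lumen_area(sol)
#> [1] 17.39556

# sweep the intraluminal pressure from 196 to 2584 Pa on the same mesh
sw <- sweep_pressure("H6", mesh = sol$mesh)
round(sw$areas_mm2, 3)
#>  [1] 12.908 13.272 13.658 14.070 14.510 14.983 15.497 16.060 16.686 17.396
#> [11] 18.223 19.232 20.576
```

The first number is the deformed open cross-sectional area of the lumen at
the working pressure, in mm^2 (undeformed: 12.57 mm^2). The sweep shows the
nonlinear growth of the opening with pressure; the six-hole case sits
between the fibrotic no-hole case and the sane case at every pressure.

The built-in verification oracles can be re-run at any time:

```r
print(verify("fast"), digits = 3)
#>                        check    value tolerance pass
#> 1       reference_state_zero 0.00e+00     1e-12 TRUE
#> 2              pk2_stress_fd 1.58e-09     1e-06 TRUE
#> 3        material_tangent_fd 2.99e-09     1e-05 TRUE
#> 4  plane_stress_minimisation 2.62e-11     1e-08 TRUE
#> 5      single_element_forces 4.94e-09     1e-08 TRUE
#> 6         follower_resultant 1.73e-17     1e-10 TRUE
#> 7 follower_traction_integral 3.66e-04     1e-03 TRUE
```

A thin command-line front-end with `geometry`, `run`, `sweep`, `verify` and
`report` subcommands is installed at `inst/cli/sphincterFE.R`.

See the methods vignette (`vignettes/sphincter-model.Rmd`) for the model,
its assumptions, the calibration of the default geometry, and a candid
account of what this 2D idealisation can and cannot reproduce.

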