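# activemuscle

Transversely isotropic hyperelastic constitutive models for active skeletal
muscle tissue, with the standard homogeneous load cases, activation dynamics,
parameter identification, and a command-line interface.

Four models are implemented and cross-compared:

| Model | Class | Activation level |
|-------|-------|------------------|
| ASE   | active stress | — (stress added directly along the fiber) |
| GASA  | generalized active strain | explicit, Lambert-W |
| ASA   | active strain | implicit, Newton with bisection fallback |
| GASAM | modified generalized active strain | closed form, with an extra stress term from its deformation dependence |

All four use the fiber structural tensor `M = m ⊗ m` and are formulated both
fully incompressibly (with a reaction pressure determined by the traction-free
faces of each load case) and nearly incompressibly (with a volumetric penalty).
The ASE passive matrix is Neo-Hookean with a piecewise fiber law (toe
region plus linear region, C1-continuous at the transition stretch); the
active-strain family shares a single generalized-invariant exponential energy,
so its three members have identical passive behavior by construction.

## Quick start

```r
library(activemuscle)

# Reference parameter sets (rotator-cuff calibration)
p <- reference_params("gasam")

# Tetanic uniaxial response along the fiber, nominal stress in kPa
response_sweep(p, "UTCAF", c(0.85, 1, 1.15, 1.3), muscle_activation("tetanic"))
#>   loadcase  state model    x    P_kPa
#> 1    UTCAF active gasam 0.85 35.69056
#> 2    UTCAF active gasam 1.00 58.64675
#> 3    UTCAF active gasam 1.15 71.58352
#> 4    UTCAF active gasam 1.30 78.86585

# Stretch at which the tetanically contracting, unloaded muscle equilibrates
stress_free_stretch(p)                       # 0.7092946  (~ 0.71)
stress_free_stretch(reference_params("ase")) # 0.6839797  (~ 0.68)
```

The six load cases (`LOAD_CASES`) are uniaxial tension/compression along and
transverse to the fiber (`UTCAF`, `UTCTF`), simple shear along the fiber
(`SAF`), and the three pure shears (`PSAF`, `PSTF`, `PSTIF`). Activation can
be `"passive"`, `"tetanic"` (optionally scaled), a tanh ramp, or a
motor-unit twitch-superposition time course (`f_twitch`, `twitch_train`).

## Parameter identification

Fitting is staged: passive parameters from passive curves across load modes,
then active parameters from the tetanic uniaxial curve. Bounded
Levenberg–Marquardt (`minpack.lm`) with deterministic multi-start restarts;
parameters whose Jacobian column is numerically null are reported in
`fit$unidentifiable` with a warning.

```r
curves <- generate_curves(p, noise_sd_rel = 0.01, seed = 42)  # synthetic data
fit <- fit_passive(curves[1:6], p)     # start from the reference values
fit$estimates
#>      alpha       beta      gamma     omega0
#>  2.4351716  0.5667331 26.8622147  0.6418252
fit_active(curves[[7]], fit$params)$estimates
#>       Popt lambda_opt lambda_min
#> 64.9224316  1.1901240  0.5620497
```

For the ASE model the maximal fiber stress multiplies both fiber terms, so
only the products `sigma_max * D1` (passive) and `sigma_max * a` (active) are
identifiable from stress data; the shear moduli `G1`, `G2` are unidentifiable
from uniaxial-along-fiber data alone and are flagged as such.

## Command-line interface

`exec/muscletool` wraps the package:

```sh
exec/muscletool sweep --model gasa,asa --mode UTCAF --grid 0.7,1.3,25 \
    --activation tetanic --out sweep.tsv
exec/muscletool stressfree --model gasam --activation tetanic --out sf.json
exec/muscletool isometric --model ase --out iso.json
exec/muscletool generate --model gasam --noise 0.02 --seed 7 --out curves.tsv
exec/muscletool fit --model gasam --curves curves.tsv --out fit.json
exec/muscletool verify
```

`verify` runs four internal consistency checks (load-case determinants,
passive family identity, tetanic GASA/ASA equality, stress-free reference
state) and exits nonzero on failure.

## Tests

```r
testthat::test_dir("tests/testthat", package = "activemuscle",
                   load_package = "installed")
```

The suite checks, among other things, that every model's second
Piola–Kirchhoff stress matches central finite differences of its strain
energy over random admissible deformations, that the nearly incompressible
responses converge to the incompressible ones as the penalty grows, and that
staged fitting recovers the generating parameters from noiseless synthetic
curves started a factor of two away.

See `vignettes/muscle-models.Rmd` for the model equations and the numerical
decisions.
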