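---
title: "Methods: a nine-compartment CNS PBPK simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a nine-compartment CNS PBPK simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnspbpk)
```

## The model and its assumptions

`cnspbpk` predicts unbound drug concentration–time profiles in nine CNS
compartments — brain microvessels (MV), brain extracellular and
intracellular fluid (ECF, ICF), lysosomes, the brain-cell-membrane
phospholipid pool (BCM), and four CSF spaces (lateral ventricles LV,
third+fourth ventricles TFV, cisterna magna CM, subarachnoid space SAS) —
driven by an empirical compartmental plasma model through the cerebral
blood flow. The plasma model is a *forcing function*: cerebral uptake does
not feed back into it, and drug leaving the SAS with the CSF flow goes to
an absorption sink (returning it to an externally forced plasma would be a
no-op).

Mechanistic content, per flux:

* **Transcellular transport** crosses membranes (BBB and BCSFB
  endothelium/epithelium, brain-cell membranes, lysosomal membranes) as
  `J(A→B) = P_trans · SA · PHF_A · Cu_A`: only the neutral fraction
  `PHF` crosses, so opposing `PHF` values on the two sides produce
  pH-gradient ion trapping (a base with pKb 8–10 accumulates in the pH 5
  lysosome; a neutral drug equilibrates at ratio 1).
* **Paracellular transport** is aqueous diffusion through tight-junction
  pores, equal for all charge species, with a Renkin hindrance polynomial
  `(1−λ)²(1−2.104λ+2.09λ³−0.95λ⁵)` in λ = molecular/pore radius, clamped
  to zero at λ ≥ 1.
* **Non-specific binding** is a pair of diffusion clearances between
  ECF/ICF water and the membrane phospholipid pool constructed so that
  `CL_wo/CL_ow = 10^logP`; at equilibrium the membrane:water concentration
  ratio is exactly the octanol–water partition coefficient. The BCM volume
  is 5% of total brain volume (the phospholipid volume fraction).
* **Bulk flows** move drug irrespective of gradients: ECF bulk flow into
  the LV, and the CSF stream LV→TFV→CM→SAS→sink carrying
  `Q_CSF + Q_ECF` (the ECF outflow is entrained into the CSF cascade;
  there is no direct ECF↔SAS exchange — SAS kinetics are flow-mediated
  only).
* **Asymmetry factors** lump everything not modelled explicitly (active
  transport, metabolism) into multipliers `AF_in`, `AF_ef` ≥ 1 on the
  *total* passive influx/efflux clearance of each barrier (BBB, BCSFB_LV,
  BCSFB_TFV). They are calibrated so that the steady state under constant
  unit unbound plasma reproduces the drug's regional `Kp_uu` targets
  (ECF, LV, CM) simultaneously. The branch rule is: `Kp_uu < 1` ⇒ active
  efflux, fix `AF_in = 1`, solve `AF_ef`; `Kp_uu > 1` ⇒ fix `AF_ef = 1`,
  solve `AF_in`; `Kp_uu = 1` ⇒ both 1. An `af_applies_to =
  "transcellular"` switch restricts the multiplier to the transcellular
  route, in case the originating equations did so.

CSF compartments track total drug; transport and reported concentrations
use the unbound fraction `f_u,CSF` (1 for every fixture drug except
indomethacin, 0.47).

## Numerical approach

Between dose events the entire system — plasma block plus CNS block — is a
linear time-invariant ODE `dx/dt = Ax + b(t)` with piecewise-constant
(infusions) or piecewise-linear (sampled forcing profiles) inputs. Instead
of a stiff integrator, the package propagates states *exactly* with matrix
exponentials of an augmented system and caches the exponential per unique
(segment, Δt); steady states come from a direct linear solve of the rate
matrix with row equilibration (rate constants span many orders of
magnitude while the asymmetry-factor solver probes its bracket). The AF
calibration itself is Gauss–Seidel over the three barriers with monotone
1-D root finds on log10(AF) in [1, 1e12], expanding the upper bracket in
decade steps; convergence is declared at a relative `Kp_uu` residual of
1e-9, comfortably inside the 0.1% round-trip contract. A target that
cannot be reached with AF ≥ 1 (e.g. a `Kp_uu` close to 1 at a barrier
whose passive influx is smaller than the CSF bulk washout) raises a
diagnostic error rather than clamping.

Tie-breaks and conventions: `T_max` is the time of the *first* maximum on
the simulation grid; AUC is trapezoidal on the grid; percentile bands use
`stats::quantile` type 7 (linear interpolation); observed data are matched
to simulation times exactly, never interpolated.

## Parameters that matter

* **Physiology** (per species, JSON configs with per-field units and
  provenance): compartment volumes (mL), flows `Q_CBF`, `Q_ECF`, `Q_CSF`
  (mL/min), barrier surface areas (cm²), tight-junction pore radius (nm,
  default 0.9), paracellular path length (µm, default 0.5) and surface
  fraction (default 1e-4), compartment pH (plasma 7.4, ECF 7.3, ICF 7.0,
  lysosomes 5.0, CSF 7.3). `v_bcm` derives as 5% of brain volume and
  `sa_bcm` from spherical-cell geometry (`n_cells · 4πr²`); both stay
  coupled to their parents under perturbation unless pinned. The original
  physiology table is not public; these are best-effort literature values
  (means where several exist) and every field can be overridden. The BCSFB
  areas count the choroid-plexus apical microvilli — with bare epithelial
  areas the passive influx at the BCSFB would be smaller than the CSF
  washout and `Kp_uu` targets near 1 would be unreachable under the branch
  rule, which is physiologically the statement that those microvilli
  matter.
* **Transport coefficients** (`transport_config()`): the supplementary
  permeability equations of the source lineage are not printed, so the
  package uses documented stand-ins with every constant exposed: aqueous
  diffusivity `D = 6e-4 · (100/MW)^(1/3)` cm²/min (Stokes–Einstein-type
  size scaling anchored at 1e-5 cm²/s for MW 100) and transmembrane
  permeability `log10 P_trans = 0.6·logP − 3.0 − 0.5·log10(MW)` (cm/min),
  putting a logP 0, MW 300 drug at ~1e-6 cm/s. An owner of the original
  supplement can reproduce it exactly by overriding the coefficients.
* **Membrane-binding kinetic scale** `CL_wo` defaults to `Q_CBF`: large
  against the barrier clearances (near-equilibrium binding, matching the
  move from instantaneous to diffusion-clearance binding) while keeping
  the dynamics time-resolved.
* **Variability**: inter-individual variability is exponential,
  `p·e^η`, `η ~ N(0, ω²)` with ω = CV/100 by default (the CV→ω transform
  is not printed in the source; `cv_transform = "lognormal"` gives
  `ω² = log(1+CV²)`). Residual error is `pred·(1+ε_prop) + ε_add`.
  Physiology variability (`add_physiology_iiv`) is multiplicative
  log-normal with `sdlog = sqrt(log(1+(CV/100)²))` so the realized CV
  matches the nominal 30%/50%.

## What the synthetic data emulate — and what they do not

`generate_synthetic_observed()` stands in for in vivo microdialysis
datasets, which are not redistributable. It simulates individuals from the
*same* model family (plasma IIV, optional log-normal observation noise)
and samples them at stated times. A green closed-loop test therefore
establishes that the estimator pipeline (VPC medians, fold errors) is
correct and self-consistent — it cannot establish predictive accuracy
against real animals or patients, which is why the published fold-error
values against in vivo data are not reproduced here. Real microdialysis
data additionally carry probe recovery error, BLQ censoring, and model
misspecification that the generator deliberately omits.

## Design choices where the design was open

* **Flux orientation**: transcellular flux is sourced on the donor side's
  neutral fraction (`P·SA·PHF_A·Cu_A`), which yields ion trapping; the
  original orientation lives in an unavailable supplement.
* **AF placement** on the total passive clearance (switchable, see above).
* **ECF entrainment**: `Q_ECF` joins the CSF stream at the LV and stays in
  it through the SAS sink.
* **Lysosomes** exchange with ICF only, as a single lumped compartment
  (volume ≈1% of cell volume, pH 5.0).
* **Sensitivity analysis** does not re-solve AFs after perturbing
  physiology (the perturbation probes physiology at fixed drug
  disposition); `resolve_af = TRUE` gives the other reading.
* **`Kp_uu = 1` pins AF = (1,1)** even though the passive steady state is
  then not exactly 1 (bulk washout and pH asymmetry leave a ~2% residual
  for a neutral drug in human physiology): the branch rule is followed
  literally rather than solving an AF < 1.
* **Scenario plasma model**: the altered-CSF-dynamics study uses the
  packaged human 1-compartment model as the shared simple forcing (the
  source states a fixed 1-compartment model without printing its
  parameters); it is configurable.
* **Human Kp_uu for scenario drugs**: human-specific sets where the source
  provides them (acetaminophen: 1), otherwise the rat values, logged per
  drug by the fixture loader.

## Known limitations

* No receptor binding, brain metabolism, or brain-cell active transport —
  absorbed into the barrier AFs; predictions for strongly
  receptor-bound drugs in whole-brain terms will be biased accordingly.
* No saturable (nonlinear) transport; superposition holds by construction.
* Charged-species transcellular transport is neglected entirely, and
  cationic preference of the paracellular route is not modelled.
* CSF flow is constant along the cascade; pulsatility and regional
  production are not represented.
* Plasma parameters are used as printed, with no covariates or
  re-estimation; parameter sets whose deep peripheral compartments look
  unphysiological are reproduced verbatim by design.
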