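# cnspbpk

Physiologically based pharmacokinetic (PBPK) simulation of unbound drug
concentrations in the central nervous system, for modelers and DMPK
scientists who need brain and cerebrospinal-fluid (CSF) exposure predictions
from plasma pharmacokinetics plus physicochemistry alone — no brain tissue
measurements required.

## The model

An empirical compartmental plasma model (1–3 compartments, fixed literature
parameters, exponential inter-individual variability `p·e^η` and
proportional/additive residual error) drives a nine-compartment CNS model
through the cerebral blood flow `Q_CBF`:

```
plasma ⇄ brain microvessels (MV)
             MV ⇄ brain ECF          (BBB:   paracellular + transcellular)
             MV ⇄ lateral ventricles (BCSFB_LV)
             MV ⇄ 3rd/4th ventricles (BCSFB_TFV)
  ECF ⇄ ICF ⇄ lysosomes              (membranes, neutral species only)
  ECF, ICF ⇄ brain cell membrane     (phospholipid non-specific binding)
  ECF → LV → TFV → CM → SAS → sink   (bulk flows Q_ECF, Q_CSF)
```

Key mechanisms, in the field's standard notation:

* **Ionization.** Per compartment the neutral fraction is
  `PHF = PHF_acidic · PHF_basic` with
  `PHF_acidic = 1/(1+10^(pH−pKa))`, `PHF_basic = 1/(1+10^(pKb−pH))`.
  Only neutral species cross membranes (`J = P_trans·SA·PHF·Cu`), so pH
  gradients produce ion trapping (e.g. lysosomal accumulation of bases);
  charged species use the paracellular route only.
* **Paracellular transport.** Aqueous diffusion through tight-junction
  pores with a Renkin hindrance factor in λ = molecular radius / pore
  radius, identical for all charge species.
* **Non-specific binding.** Drug partitions into the brain-cell-membrane
  phospholipid pool (5% of brain volume) via diffusion clearances with
  `CL_wo/CL_ow = P_oct-water = 10^logP`, so the membrane:water ratio at
  steady state equals the octanol–water partition coefficient.
* **Asymmetry factors.** Active transport and metabolism are lumped into
  `AF_in`/`AF_ef` multipliers on the passive barrier clearances, calibrated
  so the steady state under constant unit plasma reproduces the drug's
  `Kp_uu = Cl_in/Cl_out` in ECF, LV and cisterna magna simultaneously
  (`Kp_uu < 1` ⇒ solve `AF_ef`; `> 1` ⇒ solve `AF_in`; `= 1` ⇒ both 1).
* **Evaluation.** Replicate-simulation visual predictive checks (median and
  95% interval of 200 simulations) and fold-error statistics
  `%AFE = 100·10^mean(RA)`, `%AAFE`, `%MARA`, and SMAPE, with
  `RA = mean log10(MedP/Obs)` per drug.

Everything is linear and time-invariant between dose events, so the package
integrates nothing numerically: trajectories are propagated exactly with
piecewise matrix exponentials and steady states come from a direct linear
solve.

## Worked example

```r
library(cnspbpk)
phys  <- default_physiology("rat")
drug  <- drug_fixture("morphine", "rat")     # Kp_uu 0.38 (4 mg/kg group)
spec  <- plasma_fixture("morphine", "rat")   # 3-compartment plasma model
sys   <- build_system(phys, drug)            # calibrates asymmetry factors
sys
#> <cns_system> morphine in rat physiology
#>   bbb       CL_trans 0.05179  CL_para 0.007197 mL/min | Kp_uu 0.38 -> AF_in 1 AF_ef 2.669
#>   bcsfb_lv  CL_trans 0.02363  CL_para 0.003284 mL/min | Kp_uu 0.38 -> AF_in 1 AF_ef 2.089
#>   bcsfb_tfv CL_trans 0.01182  CL_para 0.001642 mL/min | Kp_uu 0.38 -> AF_in 1 AF_ef 2.694
#>   binding CL_wo 1.2 CL_ow 0.1619 (P_octw 7.413)

sim <- simulate_pbpk(sys, spec, list(dose_event(4e6, "iv-bolus")),
                     times = seq(0, 360, by = 2))
sim
#> <cns_simulation> morphine (rat): 9 compartments x 181 times [0, 360] min
#>  compartment      cmax tmax        auc
#>           mv 7727.5383    2   89670.42
#>          ecf  203.1830   36   34684.23
#>          icf  204.2604   38   34940.04
#>          lys 3792.9408  276 1046110.35
#>          bcm 1509.9412   38  258145.30
#>           lv 1555.9773    4   38415.49
#>          tfv 1126.1758    6   38599.20
#>           cm  829.5396   14   38694.66
#>          sas  246.5718   52   37336.40

round(cns_steady_state(sys, cu_plasma = 1), 4)
#>      mv     ecf     icf     lys     bcm      lv     tfv      cm     sas
#>  0.9992  0.3800  0.3833 38.0274  2.8293  0.3800  0.3800  0.3800  0.3800
```

Morphine (a base, `pKb` 9.12, `logP` 0.87) shows: ECF/LV/CM pinned at their
`Kp_uu` target of 0.38 by the calibrated efflux asymmetry factors;
~100-fold lysosomal trapping from the pH 5 lumen; and a membrane
concentration ≈ `P_oct-water · Cu` from phospholipid binding. Unbound
concentrations are ng/mL, times min, AUC ng·min/mL.

A command-line interface covers the main workflows, e.g.

```sh
Rscript -e 'cnspbpk::cns_cli()' simulate --drug acetaminophen --species rat \
    --dose 2e6 --tmax 240 --out out/
Rscript -e 'cnspbpk::cns_cli()' scenario --drug acetaminophen \
    --volume-fold 5 --flow-fold 1 --dose 1e9 --tmax 1440 --out out/
```

## Scope notes

Receptor binding, brain metabolism and brain-cell active transport are not
modelled (they are lumped into the barrier asymmetry factors); plasma
parameters are fixed inputs, not estimated; disease-physiology libraries are
out of scope (any physiology field can be overridden or perturbed instead).
See `vignettes/cns-pbpk-methods.Rmd` for assumptions, parameter provenance
and limitations.
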