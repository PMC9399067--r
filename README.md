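# celldosim

In vitro cellular dosimetry and radiobiology for alpha- and beta-emitting
radioligands, built around the comparison of actinium-225- and
lutetium-177-labelled PSMA ligands in prostate-cancer cells.

Radioligand therapy delivers dose at the scale of single cells, where the
absorbed dose to the nucleus — not the activity concentration in the
medium — drives cell killing. `celldosim` implements the complete
computational chain needed to turn bench measurements (gamma-counter
uptake and excretion, colony counts, fluorescence microscopy) into
absorbed doses and a relative biological effectiveness (RBE):

* **Decay data and Bateman mathematics** — embedded decay chains for
  Lu-177 and the Ac-225 cascade (Ac-225 → Fr-221 → At-217 → Bi-213 →
  Po-213/Tl-209 → Pb-209), closed-form Bateman activities with branching,
  and branching-weighted energy bookkeeping.
* **Cellular S values** — a desk-scale transport engine producing
  absorbed dose rate to the nucleus per unit activity, S (Gy·(Bq·s)⁻¹),
  for membrane, cytoplasm, medium and neighbouring-cell sources: alpha
  particles by continuous-slowing-down chord transport, electrons by the
  Cole analytic range–energy model with beta-spectrum sampling.
* **Kinetics** — instant-uptake bound activity (%AA/100,000 cells),
  membrane/internalized partition, exponential-plus-plateau clearance
  fitting, and closed-form time-integrated activity Ã (Bq·s).
* **MIRD dose accumulation** — D = Σ Ã(source) × S(source→nucleus) per
  phase (spherical cells in suspension during incubation, ellipsoidal
  attached cells during colony growth), cumulated over the 7-day assay.
* **Dose response and RBE** — survival fractions with Poisson counting
  errors, weighted log-linear fits of SF = exp(−αD) through the origin,
  and RBE = α(test)/α(reference) with delta-method error propagation.
* **Foci imaging** — maximum projection, DAPI-based nucleus segmentation,
  per-nucleus mean + k·SD thresholding and watershed splitting for
  53BP1-focus counting; Hough-transform cell sizing from brightfield
  images.
* **Synthetic data** — seeded generators for every input (colony counts,
  retention series, displacement curves, two-channel image stacks with
  ground truth), so the whole pipeline is testable end to end.

## Worked example

```r
library(celldosim)

## decay physics: the Ac-225 cascade carries four alphas (~27.5 MeV)
ac <- load_chain("Ac-225")
alpha_emissions_per_decay(ac)
#> [1] 4
charged_energy_per_decay(ac, "alpha")
#> [1] 27.47877
daughter_equilibration_time(ac) / 60   # Fr-221 98% ingrowth, minutes
#> [1] 27.09962

## cumulated 7-day dose at 0.4 MBq/mL Lu-177 (average-size cells)
dt <- dose_table("Lu-177")
subset(dt, size_class == "average" & concentration_bq_per_ml == 4e5,
       select = c(concentration_bq_per_ml, total_gy))
#>    concentration_bq_per_ml total_gy
#> 13                   4e+05 2.078497

## full synthetic pipeline: dose-response fits and RBE
rep <- run_pipeline(list(seed = 4))
rep
#> <celldosim_report>
#>   S values: 27 rows ( reference )
#>   alpha[Lu-177] = 0.168 +/- 0.027 1/Gy
#>   alpha[Ac-225] = 0.68 +/- 0.045 1/Gy
#>   RBE = 4.04 +/- 0.7
```

The report's α values are fitted radiosensitivity slopes (per Gy) from
simulated triplicate clonogenic assays at the accumulated doses; the RBE
is their ratio with propagated uncertainty — individual seeds scatter
around the generating RBE of 4.19 within the quoted error.

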