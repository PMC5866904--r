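# gadnca

Noncompartmental pharmacokinetics of gadoxetate (Gd-EOB-DTPA) as a
quantitative liver-function readout.

## The problem

Gadoxetate is a hepatobiliary MR contrast agent taken up by the same hepatic
organic-anion transporters as indocyanine green, so how fast the liver clears
it from blood reflects functional liver mass. In a rat partial-hepatectomy
design — a sham-operated control group and groups with 70% and 90% of the
liver resected — serial serum gadolinium concentrations after an IV bolus
(0.1 mmol Gd/kg, samples at 1, 3, 5, 10, 20, 30, 60 and 90 min, measured by
ICP-MS) give graded liver-function deficits whose separation can be tested
statistically. `gadnca` implements that entire analysis as a reusable,
tested pipeline for anyone estimating organ function from the disposition of
a transporter-substrate probe:

1. **Synthetic cohort generator** — a two-compartment IV-bolus disposition
   model with log-normal between-subject variability, proportional assay
   noise and LLOQ censoring, defaulting to the hepatectomy study design
   (n = 16/14/20), so the full pipeline runs and is testable with no animal
   data.
2. **NCA core** — for each subject: Cmax/Tmax; log-linear back-extrapolation
   of C(0); AUC and AUMC by the linear-up/log-down trapezoidal rule,

   AUC over [t₁,t₂] = Δt·(C₁+C₂)/2 (ascending), Δt·(C₁−C₂)/ln(C₁/C₂)
   (descending);

   the terminal rate constant λz by best-adjusted-R² log-linear regression;
   extrapolation to infinity AUC∞ = AUC_last + Ĉ_last/λz; and the derived
   parameters CL = dose/AUC∞, Vz = CL/λz, MRT = AUMC∞/AUC∞,
   Vss = dose·AUMC∞/AUC∞² = CL·MRT, t½β = ln2/λz, t½,eff = 0.693·MRT.
3. **Liver-weight arithmetic** — relative lobe weights (% of total),
   combined lobe percentages and post-hepatectomy regeneration rates.
4. **Group statistics** — per-parameter group means ± SD, one-way ANOVA,
   Bonferroni-corrected pairwise Student t tests, and the Spearman trend of
   clearance across the ordered groups.
5. **Pipeline/CLI** — `cmd_simulate()`, `cmd_nca()`, `cmd_compare()`,
   `cmd_all()` over CSV/JSON files with run manifests, plus a thin Rscript
   wrapper (`inst/cli/gadnca.R`).

## Worked example

```r
library(gadnca)

cfg <- cohort_config(seed = 42)          # default hepatectomy design
prof <- simulate_subject(cfg, "control", 1)
run_nca(prof)
#> <nca_result> subject control_001 (control)
#>   Cmax 270.3 umol/L at 1 min; AUClast 1822.8, AUCinf 1840.8 umol*min/L (1.0% extrapolated)
#>   CL 14.57 mL/min, Vss 167.3 mL, Vz 354.9 mL, MRT 11.5 min, t1/2b 16.9 min
```

Cmax is the highest measured serum concentration; AUC_last/AUC_inf are the
areas under the concentration–time curve to the last sample and extrapolated
to infinity (the extrapolated share is a quality measure); CL is the volume
of serum cleared of gadoxetate per minute — the liver-function readout — and
Vss/Vz are distribution volumes.

```r
tab <- nca_cohort(simulate_cohort(cfg))$parameters
compare_groups(tab, c("cl", "v_ss", "auc_last"),
               group_order = c("control", "hep70", "hep90"))
#>  parameter   group  n   mean     sd
#>         cl control 16   14.1    2.7
#>         cl   hep70 14    6.1    2.3
#>         cl   hep90 20    2.7    0.6
#>  ...
#>   cl  F = 151.25, p = <0.001;  control vs hep70: <0.001; control vs hep90: <0.001; hep70 vs hep90: <0.001
#>  ...
#> Spearman trend of CL across groups: rho = -0.932, p = <0.001
```

Clearance drops roughly in proportion to remaining functional liver mass,
separates all three groups pairwise, and decreases monotonically across the
ordered groups (negative Spearman rho).

Liver-weight arithmetic on the bundled reference dissection:

```r
ref <- reference_liver_weights()
round(relative_lobe_weights(ref$control), 1)
#> left_lateral       median        right      caudate    paracaval
#>         30.9         33.1         17.3          6.4         11.0
round(regeneration_rate(ref$remnant_90_g, ref$control$total_weight))
#> [1] 37
```

From the shell:

```sh
Rscript inst/cli/gadnca.R all --config config.json --out-dir run1 --seed 42
```

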