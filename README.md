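# accuprofile

Total-error **accuracy-profile validation** of quantitative bioanalytical
assays, for analysts and biostatisticians who need to decide — from a small
multi-day replicate experiment — over which concentration range a method is
fit for purpose.

A method is acceptable at a concentration level when a single future
measurement `x` of a sample with true value `μ_T` satisfies

```
P( |x − μ_T| / μ_T × 100 < λ ) ≥ β
```

with acceptance limits `±λ` (default 15% of nominal) and probability `β`
(default 0.95). The operational tool is the **β-expectation tolerance
interval** of the relative error at each level, computed from a balanced
`p` series × `n` replicates design via one-way random-effects variance
components: with `R = (RSD_IP² − RSD_r²)/RSD_r²` (untruncated — it may be
negative),

```
B² = (R+1)/(nR+1)
ν  = (R+1)² / [ (R+1/n)²/(p−1) + (1−1/n)/(pn) ]      (Satterthwaite df)
k  = t((1+β)/2, ⌊ν⌋) · sqrt(1 + 1/(p·n·B²))
limits = bias ± k · RSD_IP                            (all in % of nominal)
```

The method is validated over the range where those limits stay inside `±λ`;
the lowest such concentration is the LLOQ.

The package covers the whole chain: per-day linear calibration with inverse
prediction (`fit_calibration()`, `back_calculate_dataset()`), per-level
trueness/precision/tolerance statistics (`variance_components()`,
`tolerance_interval()`, `level_statistics()`), the accuracy-profile decision
(`build_profile()`, `determine_limits_of_quantification()`,
`profile_plot_data()`), extraction-recovery statistics
(`recovery_statistics()`), summary-table reproduction from published
per-level triples (`run_summary_mode()`), a full raw-data pipeline
(`run_validation()`), and a synthetic plasma-assay generator with a
Monte-Carlo coverage harness (`simulate_responses()`, `simulate_coverage()`).
A thin command-line wrapper with `validate` / `summary` / `simulate` /
`coverage` subcommands ships in `inst/scripts/accuprofile.R`.

## Worked example

The packaged dataset `tki_plasma_summary()` holds the published per-level
validation summaries of two UPLC plasma assays for the tyrosine kinase
inhibitors afatinib (AFA, 5–250 ng/mL) and ibrutinib (IBR, 5–400 ng/mL),
validated on 3 days × 4 replicates. The tolerance limits are a deterministic
function of the printed triples, so the whole decision is reproducible
without raw data:

```r
library(accuprofile)
prof <- run_summary_mode(tki_plasma_summary("AFA"), p = 3, n = 4)
prof
#> Accuracy profile for AFA (beta = 0.95, acceptance limits +/-15%, p = 3, n = 4)
#>  conc  bias rsd_r rsd_ip tol_lower tol_upper valid
#>     5 -0.24  5.60   5.65    -13.37     12.89  TRUE
#>    25  1.31  5.54   4.94     -9.97     12.59  TRUE
#>    75  0.63  2.70   2.63     -5.43      6.69  TRUE
#>   125  1.29  2.23   2.42     -4.51      7.09  TRUE
#>   175  0.56  1.87   1.66     -3.23      4.35  TRUE
#>   250 -0.25  1.63   1.91     -5.10      4.60  TRUE
#> Method validated over 5-250 ng/mL (LLOQ = 5 ng/mL)
```

Reading: at 5 ng/mL the assay shows −0.24% bias, 5.60% repeatability RSD and
5.65% intermediate-precision RSD; 95% of future single results are expected
to fall within [−13.37%, +12.89%] of the nominal value — inside ±15%, so the
level is valid. Every level passes, hence the method is validated over
5–250 ng/mL with an LLOQ of 5 ng/mL. Note the second and fifth levels print
`rsd_ip < rsd_r`: the between-day ANOVA variance estimate is negative there,
and it is deliberately not truncated — the published limits are only
reproduced under that convention.

The same pipeline runs end to end on raw replicate data (here synthetic):

```r
pars <- default_simulation_params("afatinib", seed = 3)
sim  <- simulate_responses(pars)           # CS/VS responses + recovery areas
run  <- run_validation(sim$cs_records, sim$vs_records, sim$recovery_records)
run$status        # 0 = every level valid, 2 = at least one failure
```

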