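# pvsignal

Disproportionality signal detection for spontaneous adverse-event report
corpora in the FAERS quarterly-extract format.

Spontaneous reporting databases have no denominator, so drug safety
screening works on *reporting disproportionality*: for each drug–event
pair, a 2×2 table

|                 | event | no event |
|-----------------|-------|----------|
| target drug     | a     | b        |
| all other drugs | c     | d        |

is screened with the field's standard four-estimator battery:

* **ROR** = (a·d)/(b·c), with Wald 95% CI and Haldane–Anscombe +0.5
  correction for zero cells;
* **PRR** = [a/(a+b)]/[c/(c+d)] with the Yates-corrected χ² and the MHRA
  composite criterion (a ≥ 3, PRR ≥ 2, χ² ≥ 4);
* **BCPNN IC** = posterior log2 observed-to-expected under Bate's Beta
  priors, flagged when IC025 > 0;
* **MGPS EBGM** = DuMouchel's empirical-Bayes gamma-Poisson shrinker,
  flagged when EBGM05 > 2.

Around the estimators, the package implements the whole pipeline a FAERS
analysis needs: reading the `$`-delimited DEMO/DRUG/REAC/OUTC/THER
quarterly tables, hierarchical case deduplication (keep latest `FDA_DT`,
ties broken by larger `PRIMARYID`) with deletion-list removal, PT→SOC
coding through a user-supplied MedDRA mapping (a synthetic toy dictionary
ships for tests), descriptive characteristics tables, and Weibull
time-to-onset modelling. A synthetic quarter generator with plantable
drug–event reporting-rate ratios provides ground truth for every stage;
no external data are required to use or test the package.

## Worked example

Generate a synthetic quarter with a planted rate-ratio-5 signal on
Diarrhoea, run the pipeline, and inspect the results:

```r
library(pvsignal)

cfg <- plant_signal(synth_config(n_cases = 20000, seed = 42),
                    event = "Diarrhoea", rr = 5)
bundle <- generate_quarter(cfg)
dir <- file.path(tempdir(), "demo_quarter")
write_faers_ascii(bundle, dir)

reports <- code_events(assemble_reports(read_quarter(dir)), toy_meddra_map())
sig <- detect_signals(reports, "CHOLESTYRAMINE", level = "pt")
head(format_signal_table(sig[sig$signal], digits = 2), 3)
#>        term Case reports     ROR (95% CI)     PRR (chi2)  IC (IC025) EBGM (EBGM05)
#> 1 Diarrhoea          606 6.64 (5.93-7.44) 4.86 (1332.41) 1.81 (1.66)   3.53 (3.53)
```

The planted pair is recovered: 606 of the 1,917 target-drug cases report
Diarrhoea, the ROR and PRR sit near the planted ratio (the empirical-Bayes
EBGM is deliberately shrunk toward 1), and all four positive-signal flags
fire. Descriptives and onset modelling run off the same objects:

```r
target <- select_primary_suspect(reports, "CHOLESTYRAMINE")
characteristics_table(target)$sex
#>        category    n   pct
#> 1        Female 1189 62.02
#> 2          Male  474 24.73
#> 3 Not specified  254 13.25

ons <- collect_onsets(target)
weibull_fit(ons$samples$onset_days)
#> <weibull_fit> shape = 0.7902, scale = 9.0740 d (n = 463, 74 zero-day shifted to 0.5 d; logLik -1525.66)
```

The fitted shape < 1 indicates an early-failure hazard: most events occur
shortly after starting therapy (the generator's truth was shape 0.8,
scale 10 d). `bin_onsets()` tabulates the standard reporting intervals
and the cumulative percentage within 30 days.

A thin command-line wrapper covers the same flow:

```sh
Rscript inst/scripts/pvsignal.R synth --n-cases 20000 --rr 5 --seed 1 --out q1
Rscript inst/scripts/pvsignal.R run --quarters q1 --drug CHOLESTYRAMINE --out results_dir
```

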