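# invabc

Invasion-history inference for serially sampled populations, from
microsatellite genotypes and mitochondrial sequence data.

When an invasive species (the motivating case is the Asian tiger
mosquito in the Indo-Pacific) establishes in new regions, the route and
timing of each introduction leave a signature in neutral genetic
variation. `invabc` reconstructs that history by approximate Bayesian
computation (ABC): competing demographic **scenarios** — population
splits, admixture, founder bottlenecks, all with parameter priors — are
simulated under a **serial-sample structured coalescent** (generalized
stepwise mutation for microsatellites, HKY for mtDNA), summarised into
DIYABC-style statistics, and scored against the observed data by
rejection plus multinomial-logistic regression:

- scenario posterior probabilities with 95% confidence intervals,
- type I/II error of the scenario choice from pseudo-observed datasets,
- parameter posteriors (introduction years, effective sizes) by
  local-linear regression adjustment,
- a PCA model check in summary-statistic space.

The package also carries the companion statistics used to characterise
spatio-temporal structure: per-population diversity (Na, Ne, Ho, He,
uHe, F), pairwise Weir–Cockerham θ / G″ST / Jost's D / ΦPT with
permutation significance, Mantel tests, bottleneck detection
(Garza–Williamson M-ratio with the 0.68 critical value, and the
heterozygosity-excess test under a 90%/0.15 two-phase mutation model),
and mtDNA haplotype analysis (collapsing, Hd, π, Tajima's D,
minimum-spanning networks).

## Worked example

The `analysis/` scripts run the full workflow on a synthetic
study-shaped dataset (six regions, two of them sampled in two years,
13 loci + 445-bp COI, truth = scenario 4 with representative
parameters). `Rscript analysis/01_simulate_study.R` writes the dataset;
`Rscript analysis/05_abc_invasion_history.R` then prints:

```
scenario posterior probabilities [95% CI]:
  s1  P = 0.315 [0.251, 0.379]
  s2  P = 0.280 [0.218, 0.342]
  s3  P = 0.055 [0.023, 0.087]
  s4  P = 0.350 [0.284, 0.416]
chosen scenario: s4 (truth in results/truth.yaml)
introduction-time posteriors (calendar years, median [95% CI]):
  T_PAP  1956 [1937, 1974]
  T_PNG  1970 [1955, 1983]
  T_SOL  1980 [1968, 1990]
  T_TS   2004 [2001, 2006]
```

Scenario 4 (the generating route: New Guinea colonized twice from
mainland SE Asia, the Solomons via PNG, the Torres Strait/Fly region
from Indonesia) attains the highest posterior, with scenario 1 — the
same route except a SE-Asian Solomons source — as the closest
alternative; the introduction-time posteriors centre on the years the
data were generated under (1962/1972/1979/2005-equivalents). The flat
posterior is expected: the candidate routes differ only in the sources
of closely related populations, so discrimination is intrinsically
moderate (the error-rate table the script also prints quantifies this).

Steps 02–04 print the diversity table, pairwise-differentiation
matrices and Mantel test, the bottleneck flags, and the mtDNA
haplotype/diversity tables, and write everything as CSV/TSV under
`results/`.

## Layout

- `R/`, `src/` — the package: genotype/alignment IO and QC, population
  statistics, bottleneck tests, mtDNA analysis, scenario model,
  coalescent engine (Rcpp), summary statistics, ABC inference,
  synthetic-data generators.
- `analysis/01–05` — the numbered workflow over the package.
- `vignettes/invasion-history-methods.Rmd` — models, assumptions,
  defaults and limitations.
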