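---
title: "Inferring invasion history from microsatellites and mtDNA: models and methods"
author: "invabc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring invasion history from microsatellites and mtDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Invasive insects such as the Asian tiger mosquito spread between regions
through human transport, leaving a genetic record of where each founding
population came from and when. Given diploid microsatellite genotypes
(here a 13-locus panel, two dinucleotide and eleven trinucleotide loci,
allele sizes in bp) and a 445-bp mitochondrial *COI* fragment from
several regional populations — some sampled in more than one year —
`invabc` addresses two questions:

1. *Which invasion route best explains the data?* Competing demographic
   scenarios (who colonized whom, and when) are compared by approximate
   Bayesian computation (ABC): millions of datasets are simulated under
   each scenario's priors, and scenarios are scored by how closely their
   simulations reproduce the observed summary statistics.
2. *What does the spatio-temporal structure look like?* Diversity
   summaries, pairwise differentiation with permutation tests, bottleneck
   statistics and mtDNA haplotype analysis characterise the populations
   the scenarios model.

## The coalescent simulator

The engine simulates gene genealogies backward in time under a
multi-population model with piecewise-constant effective sizes
(`sim_tree` in compiled code, surfaced as `simulate_gene_tree()`). Within
a population of effective size $N_e$ carrying $k$ ancestral lineages,
pairs coalesce at rate $\binom{k}{2} / (p\,N_e)$ per generation, where
$p$ is the ploidy scale (2 for autosomal diploid loci, $1/4$ for the
maternally inherited haploid mtDNA locus, which the engine simulates at
$N_e/4$ relative to the autosomal $N_e$ — a convention, exposed as
`mt_ne_scale`). This is the standard continuous-time (Kingman)
approximation; generation-by-generation Wright–Fisher dynamics are not
simulated. Serial samples enter the genealogy as tips at their sampling
times; population splits move all lineages of the daughter into the
parent (viewed backward); admixture events reroute each lineage
independently with the admixture proportion.

Two mutation models are superimposed on the genealogy:

* **Generalized stepwise model (GSM)** for microsatellites: mutations
  arrive as a Poisson process along branches; each changes the repeat
  count by ±1 with probability $p_{\text{GSM}}$ and otherwise by
  ±(1 + a geometric number of extra steps). Repeat counts reflect at a
  floor of 2. Di- and trinucleotide loci carry separate mean-rate
  parameters (log-uniform priors between $10^{-6}$ and $10^{-3}$ per
  locus per generation), and per-locus rates are dispersed around the
  mean with a gamma distribution of shape 2 (configurable). A 40-allele
  size window is *not* enforced.
* **HKY** for sequences: unequal base frequencies and a
  transition/transversion parameter $\kappa$; the per-site rate prior is
  uniform between $7\times10^{-10}$ and $10^{-7}$ per generation. The
  continuous-time chain is simulated exactly by uniformization
  (candidate events at the uniform bound rate, thinned through the
  embedded chain), which is distributionally identical to drawing from
  the matrix-exponential transition probabilities and much faster at
  these rates. The root sequence is drawn from the stationary
  frequencies. $\kappa = 1$ with equal frequencies reduces to
  Jukes–Cantor, which the tests exploit.

## Scenarios, priors and time

A `scenario()` is declarative: populations, an event list whose numeric
fields may be expressions over named parameters, priors
(uniform, log-uniform, or truncated normal) and order conditions enforced
by rejection at sampling time. Time is measured internally in
generations before present with present = 2015 and 10 generations per
year; calendar years appear only at the configuration surface.

`build_study_scenarios()` ships five candidate Australasian invasion
routes over seven populations — an unsampled ancestor (ANC) splitting
into mainland SE Asia (SEA) and Indonesia (IDN), plus Papua (PAP), Papua
New Guinea (PNG), the Solomon Islands (SOL) and the Torres Strait/Fly
region (TS). Constraints common to all five: TS is always introduced
from IDN, and each introduction carries a founder bottleneck (a
reduced-$N_e$ epoch, prior $U(10, 10^4)$, of prior duration immediately
after the introduction). Scenario 4 colonizes PAP and PNG from SEA in
separate events and SOL from PNG; scenario 1 is identical except SOL
originates from SEA. Scenarios 2, 3 and 5 are alternative routings of
the same introductions (through PAP, or from IDN); their exact published
forms are supplementary material not reproduced here, so they are
shipped as plausible alternatives and are fully overridable. Default
time priors are truncated normals centred on the historical
first-detection years (Papua 1962, PNG 1972, Solomons 1979, Torres
Strait 2005) and a log-uniform ANC split over 1,790–27,600 years before
present; stable $N_e$ priors are $U(10, 10^6)$. An optional sixth
scenario models SOL as an SEA×PNG admixture.

The sample design follows the study shape: 30 diploid individuals per
sample event except Papua (20), with second sample years for PNG (1995)
and TS (2007) — 230 individuals over 8 events.

## Summary statistics and ABC

`summary_stats()` computes the same vector for observed and simulated
data (identical code path, so missing-data handling matches by
construction). Per sample: mean allele count, mean unbiased genic
diversity, mean allele-size variance (repeat units) and mean
Garza–Williamson index; haplotype count, segregating sites, mean
pairwise differences and Tajima's D for the sequence locus. Per sample
pair: Weir–Cockerham $\theta$, shared-allele distance and Goldstein's
$(\delta\mu)^2$; Hudson's $F_{ST}$ and mean between-sample differences
for sequences. Statistics undefined for a dataset (Tajima's D at
$S = 0$, sequence $F_{ST}$ at zero between-diversity) are imputed 0 with
a mask bit; masked columns and zero-spread columns drop out of the
rejection distance, which is Euclidean on MAD-normalized statistics.

Scenario choice fits a multinomial logistic regression of scenario
label on the normalized statistic differences over the retained rows
(default: the closest 1%) and evaluates it at the observed point; 95%
confidence intervals come from the fit's asymptotic covariance by the
delta method (at the observed point only the intercept block
contributes). Complete separation or a degenerate fit falls back to
rejection proportions with a normal-approximation interval. When the
statistic space is wide relative to the retained set (the full study
design produces ~200 statistics), the regression runs on the leading
principal axes of the normalized differences; the rotation is applied
without centering so the observed point stays at the origin. Parameter
estimation uses Beaumont local-linear adjustment with Epanechnikov
weights and log/logit transforms, with a small ridge penalty as the
rank-deficiency fallback. Confidence in scenario choice is estimated by
re-running the entire pipeline on pseudo-observed datasets (PODs) drawn
from each scenario's prior: type I error of a scenario is the fraction
of its own PODs it loses; type II is the fraction of other scenarios'
PODs it wins. A PCA of the normalized reference-table statistics with
the observed vector (and optionally posterior-predictive simulations)
projected into it serves as the model check.

## Companion statistics

* Diversity per population×locus: $N$, $N_a$, $N_e^{\text{eff}} =
  1/\sum p^2$, $H_o$, $H_e = 1 - \sum p^2$, $uH_e = \frac{2n}{2n-1}H_e$,
  $F = 1 - H_o/H_e$ (undefined at monomorphic loci). Imputed genotype
  calls are tagged and excluded here.
* Pairwise differentiation: Weir–Cockerham $\theta$ (ratio of sums over
  alleles and loci); Jost's $D$ and $G''_{ST}$ from unbiased $H_S$/$H_T$
  (Nei–Chesson corrections), averaging $H_S$ and $H_T$ across loci before
  the ratio (a mean-of-ratios option exists); $\Phi_{PT}$ from a
  two-level AMOVA on squared codominant-genotypic distances (half the
  squared difference of allele-count vectors). Estimates are reported
  raw (small negatives possible); significance comes from permuting
  individuals between the two populations,
  $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{\text{perm}} + 1)$,
  9,999 permutations by convention. The Mantel test correlates
  lower-triangle genetic and great-circle geographic distances with a
  one-tailed permutation p-value; coordinates are user configuration.
* Bottlenecks: the Garza–Williamson M-ratio $k/(r+1)$ in repeat units
  (mean across loci; critical value 0.68) and the Cornuet–Luikart
  heterozygosity-excess test under a two-phase model (90% single-step;
  the multistep size is 1 + geometric with variance 0.15 — our reading
  of the "15% variance" setting of the standard implementation — and
  1,000 retained equilibrium simulations per locus; two-tailed Wilcoxon
  signed-rank across loci). Equilibrium simulations condition on the
  observed allele count; the scaled mutation rate is proposed from a
  short grid centred where the expected allele count matches, which
  affects only acceptance, not the conditional law. Loci with more than
  30 alleles are skipped (conditioning cost grows steeply and such loci
  carry no bottleneck signal).
* mtDNA: haplotype collapsing (exact identity, or N-tolerant
  compatibility with the lowest record index anchoring each haplotype),
  $H_d = \frac{n}{n-1}(1 - \sum p_i^2)$, $\pi$ with pairwise deletion of
  N/gap sites, Tajima's D with complete deletion (so $S$ and the
  pairwise differences refer to the same sites), and a minimum-spanning
  haplotype network over Hamming distances with unsampled intermediate
  nodes on multi-step edges — an approximation to a
  statistical-parsimony network adequate for visualization (edges above
  a configurable cap are dropped and components reported).

## The synthetic-data generator

`generate_study_like()` wraps the simulator in the study shape: 13 loci
(2 di- + 11 trinucleotide), 445-bp sequences, the 8-event/230-individual
sample design, and a 3% missing-call rate (field microsatellite data are
rarely complete; the exact study rate is not published). It emulates
neutral, unlinked loci under the declared demography. It does **not**
emulate genotyping error, null alleles, selection, continuous migration
or recombination — so passing tests demonstrate the statistical
machinery is correct under the model, not that the model captures every
feature of real data. Deterministic toy fixtures
(`make_toy_fixtures()`) carry hand-computable expected statistics for
estimator tests.

## Numerical choices and problem sizes

Simulation studies in the test-suite are sized to run on one CPU in a
few minutes: TMRCA calibration uses 2,000 replicates (5% tolerance,
≈2.2% Monte-Carlo error); bottleneck-test calibration uses 200
equilibrium replicates at $\theta = 5$ (13 loci, 30 diploids) judged
against the binomial 99% interval around the 5% level; scenario
recovery uses a three-population split-order toy (5 loci, 10 diploids
per population, 20,000 reference rows per scenario, 50 PODs); split-time
coverage uses a two-population toy (15,000 rows, 40 PODs).

Two known limitations are worth stating plainly. First, the two-tailed
heterozygosity-excess test at 13 loci has limited power: across a broad
grid of staged 100-fold crashes the rejection rate peaks around 0.45–0.5,
consistent with published power analyses of this test; it reliably
*signals* the excess (positive median standardized excess) but often
fails the 5% level on any single dataset. Second, the five study
scenarios differ only in the source of closely related introductions, so
scenario discrimination is intrinsically moderate — the study itself
reports type I/II errors near 0.45 at 15,000,000 simulations. At the
reduced table sizes used here (thousands of rows per scenario) posterior
probabilities for the generating scenario are correspondingly flatter,
though the correct scenario is typically ranked first and the
introduction-time posteriors centre on the true years.

Other defaults chosen where the design was open: rejection tolerance 1%
(the common logistic-approach default); delta-method confidence
intervals for scenario posteriors; per-locus gamma rate dispersion with
shape 2; GSM extra-step geometric parameter 0.5; HKY $\kappa$ prior
$U(2, 20)$ and insect-mtDNA-like base frequencies (A 0.31, C 0.15,
G 0.15, T 0.39), all configurable.
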