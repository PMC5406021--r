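# Study-like synthetic data with known truth, and small deterministic toy
# fixtures with oracle-checkable expected statistics. Everything here is
# generated in code; nothing is hand-edited.

#' Study-shaped sampling template
#'
#' The default template mirrors the study design the scenarios model:
#' six regional populations with temporal (second-year) samples for PNG
#' and the Torres Strait/Fly region, 30 diploid individuals per sample
#' event except Papua with 20, a 13-locus panel (2 di- + 11
#' trinucleotide), a 445-bp haploid sequence locus, and a small
#' missing-call rate typical of field microsatellite data.
#'
#' @param missing_rate fraction of genotype calls set to missing.
#' @param seq_L sequence length in bp.
#' @param include_seq carry the mtDNA locus?
#' @return A `study_template` list.
#' @export
study_template <- function(missing_rate = 0.03, seq_L = 445,
                           include_seq = TRUE) {
  structure(list(panel = default_panel(), missing_rate = missing_rate,
                 seq_L = seq_L, include_seq = include_seq),
            class = "study_template")
}

#' Generate a study-like dataset with a known truth ledger
#'
#' Draws (or takes) a parameter vector for the scenario, simulates a full
#' dataset under the template, injects missing calls at the template
#' rate, and returns observed-data objects together with a truth record
#' (scenario id, parameters, seed) for recovery tests.
#'
#' @param s a `scenario`.
#' @param truth named parameter vector; drawn from the priors when NULL.
#' @param template a [study_template()].
#' @param seed RNG seed (recorded in the truth ledger).
#' @return List with `geno` (`genotype_matrix`), `aln` (`coi_alignment`
#'   or NULL), `sim` (internal `sim_dataset`), `truth` (list: scenario,
#'   params, seed).
#' @export
generate_study_like <- function(s, truth = NULL, template = study_template(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(truth)) truth <- sample_priors(s, 1)[1, ]
  cs <- compile_scenario(s, truth)
  sim <- simulate_dataset(cs, panel = template$panel,
                          include_seq = template$include_seq,
                          seq_L = template$seq_L)
  geno <- as_genotype_matrix(sim)
  if (template$missing_rate > 0) {
    n <- nrow(geno$ind); L <- nrow(geno$panel)
    drop <- matrix(runif(n * L) < template$missing_rate, n, L)
    geno$a1[drop] <- NA_integer_
    geno$a2[drop] <- NA_integer_
  }
  aln <- if (template$include_seq) as_coi_alignment(sim) else NULL
  list(geno = geno, aln = aln, sim = sim,
       truth = list(scenario = s$id, params = truth, seed = seed))
}

# a genotype_matrix built directly from a matrix of allele-size pairs
.toy_geno <- function(calls, pops, panel = NULL) {
  n <- nrow(calls)
  L <- ncol(calls) / 2
  if (is.null(panel))
    panel <- locus_panel(sprintf("T%02d", seq_len(L)), rep(2L, L))
  a1 <- calls[, seq(1, 2 * L, by = 2), drop = FALSE]
  a2 <- calls[, seq(2, 2 * L, by = 2), drop = FALSE]
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  ind <- data.frame(id = sprintf("t%03d", seq_len(n)), pop = pops,
                    year = 2015L, stringsAsFactors = FALSE)
  new_genotype_matrix(ind, panel, a1, a2)
}

#' Deterministic toy fixtures with expected-statistic sidecars
#'
#' Small constructed datasets for estimator tests:
#' * `fixed_diff`: two populations fixed for different alleles at every
#'   locus (expected Fst = D = G''ST = DAS = 1, PhiPT = 1);
#' * `textbook_2pop`: a single-locus two-population sample with allele
#'   counts popA \{100: 18, 102: 2\}, popB \{100: 6, 102: 14\} for direct
#'   Weir-Cockerham evaluation;
#' * `het_excess`: four individuals all heterozygous 100/102 (Ho = 1,
#'   He = 0.5, F = -1);
#' * `six_seqs`: a 6-sequence alignment toy over 2 populations for
#'   diversity and Tajima's D oracles.
#'
#' Each fixture carries a `sidecar` of expected values that tests verify
#' against both the package estimators and brute-force oracles.
#'
#' @return Named list of fixtures (`data` + `sidecar`).
#' @export
make_toy_fixtures <- function() {
  out <- list()

  calls <- rbind(matrix(c(100L, 100L), 4, 6, byrow = TRUE),
                 matrix(c(108L, 108L), 4, 6, byrow = TRUE))
  out$fixed_diff <- list(
    data = .toy_geno(calls, rep(c("A", "B"), each = 4)),
    sidecar = list(fst = 1, jostD = 1, gppst = 1, phipt = 1, das = 1))

  # 10 diploids per pop at one locus; 18/2 vs 6/14 gene copies of 100/102
  a <- c(rep(100L, 18), rep(102L, 2))
  b <- c(rep(100L, 6), rep(102L, 14))
  calls <- cbind(c(a[seq(1, 19, 2)], b[seq(1, 19, 2)]),
                 c(a[seq(2, 20, 2)], b[seq(2, 20, 2)]))
  out$textbook_2pop <- list(
    data = .toy_geno(calls, rep(c("A", "B"), each = 10)),
    sidecar = list(pA = 0.9, pB = 0.3))

  calls <- matrix(c(100L, 102L), 4, 2, byrow = TRUE)
  out$het_excess <- list(
    data = .toy_geno(calls, rep("A", 4)),
    sidecar = list(Ho = 1, He = 0.5, F = -1))

  seqs <- c("AAAAATTTTTGGGGGCCCCC",
            "AAAAATTTTTGGGGGCCCCC",
            "AAAAATTTTTGGGGGCCCCA",
            "AATAATTTTTGGGGGCCCCC",
            "AATAATTTTTGGGTGCCCCC",
            "AAAAATTTTTGGGGGCCCCC")
  out$six_seqs <- list(
    data = coi_alignment(seqs, id = paste0("s", 1:6),
                         pop = rep(c("A", "B"), each = 3), year = 2015),
    sidecar = list(n_hap = 4, L = 20))
  out
}

#' Three-scenario split-order toy for ABC validation
#'
#' Three populations A, B, C sampled today (10 diploids each, 5
#' trinucleotide loci, no sequence locus) under three topologies that
#' differ only in split order: ((A,B),C), ((A,C),B) and ((B,C),A), with a
#' recent split time `TR`, an old split time `TO` and a shared Ne per
#' population. Used for scenario-recovery checks: the generating topology
#' should win the logistic posterior for most pseudo-observed datasets.
#'
#' @return Named list of three `scenario` objects.
#' @export
toy_split_scenarios <- function() {
  priors <- list(
    NE = prior_spec("uniform", 500, 5000),
    TR = prior_spec("uniform", 50, 500),
    TO = prior_spec("uniform", 1000, 5000),
    MU_TRI = prior_spec("loguniform", 1e-4, 1e-3))
  samples <- data.frame(pop = c("A", "B", "C"), year = 2015, n = 10)
  mk <- function(id, recent_pop, recent_parent, old_pop, old_parent) {
    scenario(id, populations = c("A", "B", "C"),
             ne0 = list(A = "NE", B = "NE", C = "NE"),
             events = list(
               list(kind = "split", pop = recent_pop,
                    parent = recent_parent, time = "TR"),
               list(kind = "split", pop = old_pop, parent = old_parent,
                    time = "TO")),
             priors = priors, conditions = "TO > TR", samples = samples)
  }
  list(t1 = mk("t1", "B", "A", "C", "A"),
       t2 = mk("t2", "C", "A", "B", "A"),
       t3 = mk("t3", "C", "B", "B", "A"))
}

#' Two-population split-time toy for parameter recovery
#'
#' Population B splits from A at time `T_SPLIT` (uniform prior); shared
#' Ne and microsatellite mutation-rate priors. Used for
#' interval-coverage checks of the local-linear posterior for the split
#' time.
#'
#' @return A `scenario`.
#' @export
toy_two_pop_scenario <- function() {
  scenario("split2", populations = c("A", "B"),
           ne0 = list(A = "NE", B = "NE"),
           events = list(list(kind = "split", pop = "B", parent = "A",
                              time = "T_SPLIT")),
           priors = list(
             NE = prior_spec("uniform", 1000, 4000),
             T_SPLIT = prior_spec("uniform", 100, 3000),
             MU_TRI = prior_spec("loguniform", 1e-4, 1e-3)),
           conditions = character(),
           samples = data.frame(pop = c("A", "B"), year = 2015, n = 10))
}

#' Small panel for toy simulations
#' @param n_loci number of trinucleotide loci.
#' @return A [locus_panel()].
#' @export
toy_panel <- function(n_loci = 5) {
  locus_panel(sprintf("T%02d", seq_len(n_loci)), rep(3L, n_loci))
}
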