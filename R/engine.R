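# R surface of the coalescent engine: gene-tree simulation under a
# compiled scenario, microsatellite (GSM) and sequence (HKY) mutation, and
# whole-dataset simulation typed exactly like observed data.
#
# The continuous-time (Kingman) approximation is used throughout: within a
# population of effective size Ne, a pair of lineages coalesces at rate
# 1/(ploidy * Ne) per generation. The mtDNA locus is haploid and maternal,
# simulated at Ne/4 relative to the autosomal diploid Ne (configurable).

#' Microsatellite mutation model (generalized stepwise)
#'
#' Mutations arrive as a Poisson process along branches; each changes the
#' repeat count by +-1 with probability `p_gsm`, otherwise by +-(1 +
#' geometric extra steps with success probability `p_geom`). A reflecting
#' boundary at 2 repeats keeps alleles positive. Per-locus rates can be
#' dispersed around the mean with a gamma of shape `rate_shape`.
#'
#' @param mean_rate mean per-locus, per-generation mutation rate.
#' @param p_gsm single-step probability (1 = strict stepwise model).
#' @param p_geom geometric parameter for extra steps.
#' @param rate_shape gamma shape for across-locus rate heterogeneity.
#' @return A `mutation_model_msat`.
#' @export
mutation_model_msat <- function(mean_rate, p_gsm = 1, p_geom = 0.5,
                                rate_shape = 2) {
  stopifnot(mean_rate >= 0, p_gsm > 0, p_gsm <= 1, p_geom > 0, p_geom < 1)
  structure(list(mean_rate = mean_rate, p_gsm = p_gsm, p_geom = p_geom,
                 rate_shape = rate_shape), class = "mutation_model_msat")
}

#' Sequence mutation model (HKY)
#'
#' HKY substitution with transition/transversion parameter `kappa` and
#' stationary base frequencies; `rate` is the per-site, per-generation
#' substitution rate at stationarity. `kappa = 1` with equal frequencies
#' collapses to Jukes-Cantor.
#'
#' @param rate per-site per-generation substitution rate.
#' @param kappa transition/transversion rate parameter (> 0).
#' @param freqs stationary frequencies for A, C, G, T (sum to 1).
#' @return A `mutation_model_seq`.
#' @export
mutation_model_seq <- function(rate, kappa = 10,
                               freqs = c(A = 0.31, C = 0.15, G = 0.15,
                                         T = 0.39)) {
  stopifnot(rate >= 0, kappa > 0, length(freqs) == 4,
            abs(sum(freqs) - 1) < 1e-8)
  structure(list(rate = rate, kappa = kappa, freqs = freqs),
            class = "mutation_model_seq")
}

#' Simulate a gene tree under a compiled scenario
#'
#' Backward-in-time structured coalescent with serial samples: lineages
#' coalesce within populations at rate k(k-1)/2 / (ploidy * Ne); at split
#' times all of a daughter's lineages move to the parent; at admixture
#' times each lineage reroutes independently; Ne epochs are honoured
#' piecewise. Tips sampled at time t can only coalesce deeper than t.
#'
#' @param cs a `compiled_scenario` (see [compile_scenario()]).
#' @param ploidy 1 (haploid locus, `n` gene copies per sample of size n)
#'   or 2 (diploid, `2n` copies).
#' @param ne_scale multiplier applied to Ne in the coalescence rate;
#'   defaults to `ploidy`. Use 0.25 for maternal mtDNA at Ne/4.
#' @return A `gene_tree`: `parent` (0-based, -1 at the root), `time`
#'   (generations before present), `ntips`, and `tips` (tip metadata:
#'   sample block, population, time, individual, copy).
#' @export
simulate_gene_tree <- function(cs, ploidy = 2, ne_scale = NULL) {
  if (is.null(ne_scale)) ne_scale <- ploidy
  ncopy <- cs$samples$n * ploidy
  res <- sim_tree_cpp(cs$npop, cs$ne0, ne_scale,
                      cs$ev_time, cs$ev_type, cs$ev_pop, cs$ev_dest,
                      cs$ev_dest2, cs$ev_prob, cs$ev_ne,
                      as.integer(cs$samples$pop), cs$samples$time,
                      as.integer(ncopy))
  blocks <- rep(seq_len(nrow(cs$samples)), ncopy)
  tips <- data.frame(
    block = blocks,
    pop = cs$populations[cs$samples$pop[blocks] + 1L],
    time = cs$samples$time[blocks],
    individual = unlist(lapply(seq_len(nrow(cs$samples)), function(b)
      rep(seq_len(cs$samples$n[b]), each = ploidy))),
    copy = unlist(lapply(seq_len(nrow(cs$samples)), function(b)
      rep(seq_len(ploidy), cs$samples$n[b]))))
  structure(list(parent = res$parent, time = res$time, ntips = res$ntips,
                 tips = tips), class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("gene_tree: %d tips, TMRCA %.1f generations\n", x$ntips,
              max(x$time)))
  invisible(x)
}

#' Drop microsatellite mutations on a gene tree
#'
#' @param tree a `gene_tree`.
#' @param model a [mutation_model_msat()]; its `mean_rate` is used as the
#'   locus rate (draw per-locus rates upstream if heterogeneity is
#'   wanted).
#' @param ancestral_state root repeat count.
#' @return Integer vector of tip repeat counts (tip order).
#' @export
mutate_microsat <- function(tree, model, ancestral_state = 30) {
  stopifnot(ancestral_state >= 2)
  mutate_msat_cpp(tree$parent, tree$time, tree$ntips, model$mean_rate,
                  model$p_gsm, model$p_geom, as.integer(ancestral_state))
}

#' Evolve sequences along a gene tree under HKY
#'
#' The root sequence is drawn from the stationary frequencies and the
#' HKY continuous-time chain is simulated exactly along each branch.
#'
#' @param tree a `gene_tree`.
#' @param model a [mutation_model_seq()].
#' @param L sequence length in bp.
#' @return Integer matrix (tips x L) with states 0..3 = A, C, G, T.
#' @export
mutate_sequence <- function(tree, model, L = 445) {
  stopifnot(L >= 1)
  mutate_seq_cpp(tree$parent, tree$time, tree$ntips, as.integer(L),
                 model$rate, model$kappa, as.numeric(model$freqs))
}

#' Simulate a complete dataset under a scenario
#'
#' Simulates independent diploid gene trees per microsatellite locus
#' (per-locus rates gamma-dispersed around the di-/trinucleotide mean
#' rates) and, optionally, one haploid mtDNA tree at `Ne/4`, then drops
#' mutations and assembles the result in the internal form the
#' summary-statistic kernels consume. Parameter names follow
#' [build_study_scenarios()] (`MU_DI`, `MU_TRI`, `P_GSM_DI`, `P_GSM_TRI`,
#' `MU_SEQ`, `KAPPA`); absent parameters fall back to `defaults`.
#'
#' @param cs a `compiled_scenario`.
#' @param panel a [locus_panel()].
#' @param include_seq simulate the mtDNA locus too?
#' @param seq_L sequence length.
#' @param mt_ne_scale coalescence-rate scale for the mtDNA locus
#'   (default 0.25 = Ne/4, haploid maternal).
#' @param defaults fallback mutation settings used when the scenario's
#'   parameter vector does not carry them.
#' @return A `sim_dataset`: `repeats` (individuals x 2*loci repeat
#'   counts), `seqs` (individuals x L integer states or NULL), `groups`
#'   (sample blocks: pop, year, n), `grp` (0-based block per individual),
#'   `panel`.
#' @export
simulate_dataset <- function(cs, panel = default_panel(),
                             include_seq = TRUE, seq_L = 445,
                             mt_ne_scale = 0.25,
                             defaults = list(MU_DI = 5e-4, MU_TRI = 5e-4,
                                             P_GSM_DI = 1, P_GSM_TRI = 1,
                                             MU_SEQ = 2e-8, KAPPA = 10,
                                             rate_shape = 2,
                                             p_geom = 0.5)) {
  p <- as.list(cs$params)
  get <- function(nm) if (!is.null(p[[nm]])) p[[nm]] else defaults[[nm]]
  nind <- sum(cs$samples$n)
  L <- nrow(panel)
  repeats <- matrix(NA_integer_, nind, 2 * L)
  for (l in seq_len(L)) {
    di <- panel$motif[l] == 2
    mu <- get(if (di) "MU_DI" else "MU_TRI")
    pg <- get(if (di) "P_GSM_DI" else "P_GSM_TRI")
    rate <- rgamma(1, shape = defaults$rate_shape,
                   scale = mu / defaults$rate_shape)
    tree <- simulate_gene_tree(cs, ploidy = 2)
    mm <- mutation_model_msat(rate, p_gsm = pg, p_geom = defaults$p_geom)
    states <- mutate_microsat(tree, mm, ancestral_state = 30)
    # tips come in (individual, copy) order within blocks
    repeats[, 2 * l - 1] <- states[tree$tips$copy == 1]
    repeats[, 2 * l] <- states[tree$tips$copy == 2]
  }
  seqs <- NULL
  if (include_seq) {
    tr <- simulate_gene_tree(cs, ploidy = 1, ne_scale = mt_ne_scale)
    sm <- mutation_model_seq(get("MU_SEQ"), kappa = get("KAPPA"))
    seqs <- mutate_sequence(tr, sm, L = seq_L)
  }
  grp <- rep(seq_len(nrow(cs$samples)) - 1L, cs$samples$n)
  groups <- data.frame(
    pop = cs$populations[cs$samples$pop + 1L],
    year = generations_to_years(cs$samples$time),
    n = cs$samples$n)
  structure(list(repeats = repeats, seqs = seqs, groups = groups,
                 grp = grp, panel = panel), class = "sim_dataset")
}

#' Convert a simulated dataset to a genotype matrix
#'
#' Repeat counts become allele sizes in bp (`base_size + motif * repeat`),
#' typed exactly as data read from a genotype table. Sample blocks of the
#' same population at different years get `pop` labels suffixed with the
#' year.
#'
#' @param sim a `sim_dataset`.
#' @param base_size constant bp offset per locus.
#' @param label_years suffix population labels of temporal samples with
#'   their year?
#' @return A `genotype_matrix`.
#' @export
as_genotype_matrix <- function(sim, base_size = 100, label_years = TRUE) {
  panel <- sim$panel
  n <- nrow(sim$repeats)
  L <- nrow(panel)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    a1[, l] <- as.integer(base_size + panel$motif[l] * sim$repeats[, 2 * l - 1])
    a2[, l] <- as.integer(base_size + panel$motif[l] * sim$repeats[, 2 * l])
    swap <- !is.na(a1[, l]) & a1[, l] > a2[, l]
    tmp <- a1[swap, l]; a1[swap, l] <- a2[swap, l]; a2[swap, l] <- tmp
  }
  blk <- sim$grp + 1L
  pop <- sim$groups$pop[blk]
  multi <- sim$groups$pop %in%
    sim$groups$pop[duplicated(sim$groups$pop)]
  if (label_years && any(multi)) {
    lab <- ifelse(multi[blk],
                  paste0(sim$groups$pop[blk], "_", sim$groups$year[blk]),
                  pop)
    pop <- lab
  }
  ind <- data.frame(
    id = sprintf("ind%04d", seq_len(n)), pop = pop,
    year = as.integer(round(sim$groups$year[blk])),
    stringsAsFactors = FALSE)
  new_genotype_matrix(ind, panel, a1, a2)
}

#' Convert simulated sequences to an alignment
#'
#' @param sim a `sim_dataset` with sequences.
#' @param label_years as in [as_genotype_matrix()].
#' @return A `coi_alignment`.
#' @export
as_coi_alignment <- function(sim, label_years = TRUE) {
  if (is.null(sim$seqs)) stop("dataset was simulated without sequences")
  blk <- sim$grp + 1L
  pop <- sim$groups$pop[blk]
  multi <- sim$groups$pop %in% sim$groups$pop[duplicated(sim$groups$pop)]
  if (label_years && any(multi))
    pop <- ifelse(multi[blk], paste0(pop, "_", sim$groups$year[blk]), pop)
  chars <- matrix(c("A", "C", "G", "T")[sim$seqs + 1L], nrow(sim$seqs))
  coi_alignment(chars, id = sprintf("ind%04d", seq_len(nrow(chars))),
                pop = pop, year = as.integer(round(sim$groups$year[blk])))
}
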