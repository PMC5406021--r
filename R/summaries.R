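# DIYABC-style summary-statistic vectors, computed identically for
# observed and simulated datasets. Per sample: mean allele count, mean
# genic diversity, mean allele-size variance, mean M index
# (microsatellites); haplotype count, segregating sites, mean pairwise
# differences, Tajima's D (sequences). Per sample pair: Weir-Cockerham
# Fst, shared-allele distance, (delta mu)^2; sequence Fst (Hudson) and
# mean between-sample differences. Undefined entries are imputed 0 with a
# mask bit so rejection distances can ignore them.

.msat_names <- c("NAL", "HET", "VAR", "MGW")
.msat_pair_names <- c("FST", "DAS", "DM2")
.seq_names <- c("NHA", "NSS", "MPD", "DTA")
.seq_pair_names <- c("FSH", "MPB")

.pair_labels <- function(k) {
  if (k < 2) return(character(0))
  cb <- combn(k, 2)
  sprintf("%d.%d", cb[1, ], cb[2, ])
}

# cross product of stat names and group/pair labels in value order
.cross_names <- function(labels, stat_names) {
  if (!length(labels)) return(character(0))
  as.character(t(outer(labels, stat_names,
                       function(p, s) paste0(s, ".", p))))
}

#' Microsatellite summary statistics
#'
#' One-sample statistics per sample group (mean number of alleles, mean
#' unbiased genic diversity, mean allele-size variance in repeat units,
#' mean Garza-Williamson index) and two-sample statistics per group pair
#' (Weir-Cockerham Fst, shared-allele distance DAS, Goldstein's
#' (delta mu)^2), in a fixed name order.
#'
#' @param sim a `sim_dataset` (see [simulate_dataset()] or
#'   [make_abc_dataset()]).
#' @return List with `stats` (named numeric vector) and `mask` (logical,
#'   TRUE where the statistic was undefined and imputed 0).
#' @export
microsat_stats <- function(sim) {
  ngrp <- nrow(sim$groups)
  res <- msat_stats_cpp(sim$repeats, as.integer(sim$grp), ngrp,
                        as.integer(sim$panel$motif))
  ones <- as.numeric(t(res$ones))
  ones_names <- .cross_names(as.character(seq_len(ngrp)), .msat_names)
  pl <- .pair_labels(ngrp)
  pair <- as.numeric(t(res$pair))
  pairmask <- as.logical(t(res$pairmask))
  pair_names <- .cross_names(pl, .msat_pair_names)
  stats <- c(setNames(ones, ones_names), setNames(pair, pair_names))
  mask <- c(setNames(rep(FALSE, length(ones)), ones_names),
            setNames(pairmask, pair_names))
  stats[mask] <- 0
  list(stats = stats, mask = mask)
}

#' Sequence summary statistics
#'
#' Haplotype count, segregating sites, mean pairwise differences and
#' Tajima's D per sample group; Hudson's Fst (from within/between mean
#' pairwise differences) and mean between-group differences per pair.
#' Tajima's D is undefined at S = 0 (imputed 0, masked), as is sequence
#' Fst when the between-group diversity is 0.
#'
#' @param sim a `sim_dataset` with sequences.
#' @return As [microsat_stats()].
#' @export
sequence_stats <- function(sim) {
  if (is.null(sim$seqs)) stop("dataset carries no sequences")
  ngrp <- nrow(sim$groups)
  gseq <- if (!is.null(sim$grp_seq)) sim$grp_seq else sim$grp
  res <- seq_stats_cpp(sim$seqs, as.integer(gseq), ngrp)
  ones <- as.numeric(t(res$ones))
  onesmask <- as.logical(t(res$onesmask))
  ones_names <- .cross_names(as.character(seq_len(ngrp)), .seq_names)
  pl <- .pair_labels(ngrp)
  pair <- as.numeric(t(res$pair))
  pairmask <- as.logical(t(res$pairmask))
  pair_names <- .cross_names(pl, .seq_pair_names)
  stats <- c(setNames(ones, ones_names), setNames(pair, pair_names))
  mask <- c(setNames(onesmask, ones_names), setNames(pairmask, pair_names))
  stats[mask] <- 0
  list(stats = stats, mask = mask)
}

#' Assemble a full summary-statistic vector
#'
#' Concatenates the microsatellite and (when present) sequence parts in
#' canonical order; observed and simulated vectors built this way share
#' names and order by construction.
#'
#' @param sim a `sim_dataset`.
#' @param include_seq include sequence statistics?
#' @return List with `stats` and `mask`.
#' @export
summary_stats <- function(sim, include_seq = !is.null(sim$seqs)) {
  ms <- microsat_stats(sim)
  if (!include_seq) return(ms)
  ss <- sequence_stats(sim)
  list(stats = c(ms$stats, ss$stats), mask = c(ms$mask, ss$mask))
}

#' Build the internal ABC dataset form from observed data
#'
#' Converts a genotype matrix (allele sizes in bp) and an optional
#' alignment into the internal representation the summary-statistic
#' kernels consume: repeat units per locus (anchored at the per-locus
#' minimum observed allele) and integer sequence states. Sample groups
#' are defined by (population, year) in the order given by `groups`;
#' individuals not matching any group are dropped. Alignment columns
#' containing N or gaps are removed (the statistics menu assumes complete
#' data, as simulated datasets are).
#'
#' @param g a `genotype_matrix`.
#' @param aln optional `coi_alignment`.
#' @param groups data frame with columns `pop` and optionally `year`
#'   defining the sample design; defaults to the populations of `g`.
#' @return A `sim_dataset`.
#' @export
make_abc_dataset <- function(g, aln = NULL, groups = NULL) {
  if (is.null(groups))
    groups <- data.frame(pop = unique(g$ind$pop), year = NA_integer_)
  if (is.null(groups$year)) groups$year <- NA_integer_
  # match individuals on pop alone when the group has no year, else pop+year
  blk <- rep(NA_integer_, nrow(g$ind))
  for (b in seq_len(nrow(groups))) {
    hit <- g$ind$pop == groups$pop[b] &
      (is.na(groups$year[b]) | g$ind$year == groups$year[b])
    blk[hit & is.na(blk)] <- b
  }
  keep <- !is.na(blk)
  gsub <- g[keep]
  blk <- blk[keep]
  L <- nrow(g$panel)
  repeats <- matrix(NA_integer_, sum(keep), 2 * L)
  for (l in seq_len(L)) {
    sizes <- c(gsub$a1[, l], gsub$a2[, l])
    base <- min(sizes, na.rm = TRUE)
    ru <- function(x) as.integer((x - base) %/% g$panel$motif[l])
    repeats[, 2 * l - 1] <- ru(gsub$a1[, l])
    repeats[, 2 * l] <- ru(gsub$a2[, l])
  }
  seqs <- NULL
  grp_seq <- NULL
  if (!is.null(aln)) {
    ablk <- rep(NA_integer_, nrow(aln$seq))
    for (b in seq_len(nrow(groups))) {
      hit <- aln$meta$pop == groups$pop[b] &
        (is.na(groups$year[b]) | aln$meta$year == groups$year[b])
      ablk[hit & is.na(ablk)] <- b
    }
    akeep <- !is.na(ablk)
    s <- aln$seq[akeep, , drop = FALSE]
    full <- apply(s != "N" & s != "-", 2, all)
    s <- s[, full, drop = FALSE]
    seqs <- matrix(match(s, c("A", "C", "G", "T")) - 1L, nrow(s))
    grp_seq <- ablk[akeep] - 1L
  }
  n_per <- tabulate(blk, nbins = nrow(groups))
  structure(list(repeats = repeats, seqs = seqs,
                 groups = data.frame(pop = groups$pop, year = groups$year,
                                     n = n_per),
                 grp = blk - 1L, grp_seq = grp_seq, panel = g$panel),
            class = "sim_dataset")
}
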