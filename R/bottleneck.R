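# Bottleneck detection from microsatellites: the Garza-Williamson M-ratio
# (k alleles over allele range + 1, in repeat units; bottleneck flagged at
# the conventional critical value 0.68) and the Cornuet-Luikart
# heterozygosity-excess test, which compares observed heterozygosity with
# its equilibrium distribution conditional on the observed allele count
# under a two-phase mutation model (TPM).

#' Two-phase mutation model parameters
#'
#' The TPM mixes single-step mutations (proportion `p_smm`) with
#' multi-step mutations whose step size is 1 + a geometric draw; the
#' geometric success probability is chosen so the variance of the
#' multi-step size distribution equals `variance_multistep`. The defaults
#' (90% single-step, variance 0.15, 1000 equilibrium iterations) are the
#' settings used for the study data.
#'
#' @param p_smm proportion of single-step mutations.
#' @param variance_multistep variance of the multi-step size distribution.
#' @param iterations equilibrium simulations retained per locus.
#' @return A `tpm_params` list; `p_geom` is the derived geometric
#'   parameter.
#' @export
tpm_params <- function(p_smm = 0.9, variance_multistep = 0.15,
                       iterations = 1000) {
  stopifnot(p_smm > 0, p_smm <= 1, variance_multistep > 0, iterations >= 1)
  # size = 1 + Geom0(q) has variance (1-q)/q^2; solve for q
  v <- variance_multistep
  q <- (-1 + sqrt(1 + 4 * v)) / (2 * v)
  structure(list(p_smm = p_smm, variance_multistep = v, p_geom = q,
                 iterations = as.integer(iterations)),
            class = "tpm_params")
}

# theta proposal grid centred on the value whose equilibrium allele count
# is near k (stepwise-model heuristic); conditioning on k removes the
# proposal from the retained distribution
.heq_grid <- function(k) {
  star <- min(2000, max(0.1, 0.15 * k^1.9))
  star * c(0.3, 0.6, 1, 1.8, 3.2)
}

# allele sizes -> whole repeat units for one locus; errors if the observed
# sizes are not congruent modulo the motif length
.repeat_units <- function(sizes, motif, locus) {
  rel <- sizes - min(sizes)
  if (any(rel %% motif != 0))
    stop("allele sizes at locus ", locus,
         " are not whole repeat units apart (motif ", motif, " bp)")
  rel %/% motif
}

#' Garza-Williamson M-ratio
#'
#' Per locus, M = k / (r + 1), where k is the number of distinct alleles
#' and r the allele range in repeat units; the per-population value is the
#' mean across loci. Mean M at or below the critical value 0.68 flags a
#' historical bottleneck.
#'
#' @param g a `genotype_matrix`.
#' @param population population label.
#' @param critical bottleneck critical value for the mean (default 0.68).
#' @return List with `per_locus` data frame (`locus`, `k`, `r`, `M`),
#'   `mean_M`, and `bottleneck` flag.
#' @export
m_ratio <- function(g, population, critical = 0.68) {
  rows <- list()
  for (l in seq_len(nrow(g$panel))) {
    cp <- .copies(g, population, l)
    copies <- c(cp$a1, cp$a2)
    if (!length(copies)) next
    ru <- .repeat_units(copies, g$panel$motif[l], g$panel$locus[l])
    k <- length(unique(ru))
    r <- max(ru) - min(ru)
    rows[[length(rows) + 1]] <- data.frame(
      locus = g$panel$locus[l], k = k, r = r, M = k / (r + 1),
      stringsAsFactors = FALSE)
  }
  per_locus <- do.call(rbind, rows)
  m <- mean(per_locus$M)
  list(per_locus = per_locus, mean_M = m, bottleneck = m <= critical)
}

#' Equilibrium heterozygosity distribution conditional on allele count
#'
#' Cornuet-Luikart procedure: coalescent genealogies of `n` gene copies
#' are simulated with TPM mutations superimposed, and only simulations
#' showing exactly `k` alleles are retained; the unbiased expected
#' heterozygosity of each accepted simulation forms the equilibrium (Heq)
#' distribution. The scaled mutation rate is proposed from a grid
#' (conditioning on k removes its influence; the grid only keeps
#' acceptance workable).
#'
#' @param k observed allele count (2 <= k <= n).
#' @param n number of gene copies.
#' @param tpm a [tpm_params()].
#' @param iters accepted simulations to collect (defaults to
#'   `tpm$iterations`).
#' @param theta_grid proposal grid for theta = 4 N mu; by default a short
#'   log-spaced grid centred where the expected allele count is near `k`,
#'   which keeps acceptance high without affecting the conditional
#'   distribution.
#' @param seed RNG seed.
#' @return List with `values`, `mean`, `sd`.
#' @export
heq_distribution <- function(k, n, tpm = tpm_params(), iters = NULL,
                             theta_grid = NULL, seed = NULL) {
  stopifnot(k >= 2, k <= n)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(theta_grid)) theta_grid <- .heq_grid(k)
  if (is.null(iters)) iters <- tpm$iterations
  v <- heq_tpm_cpp(as.integer(k), as.integer(n), tpm$p_smm, tpm$p_geom,
                   as.integer(iters), theta_grid, 5e6)
  list(values = v, mean = mean(v), sd = sd(v))
}

#' Heterozygosity-excess bottleneck test
#'
#' For each polymorphic locus of a population, the observed unbiased
#' heterozygosity is compared with the equilibrium distribution expected
#' for the observed allele count under the TPM; the standardized excess is
#' `(He_obs - mean Heq) / sd Heq`. Significance across loci uses a
#' two-tailed Wilcoxon signed-rank test. Populations recently passed
#' through a bottleneck show an excess (allele count drops faster than
#' heterozygosity).
#'
#' @param g a `genotype_matrix`.
#' @param population population label.
#' @param tpm a [tpm_params()].
#' @param iters accepted equilibrium simulations per locus.
#' @param max_k loci with more distinct alleles than this are skipped
#'   with a warning: conditioning equilibrium simulations on very large
#'   allele counts is prohibitively expensive, and such hyper-diverse
#'   loci carry essentially no bottleneck signal.
#' @param seed RNG seed.
#' @return List with `per_locus` data frame (`locus`, `k`, `n_copies`,
#'   `He_obs`, `Heq_mean`, `Heq_sd`, `excess`), `n_excess`, `n_deficit`,
#'   `wilcoxon_p` (NA with fewer than 4 polymorphic loci), `tpm`.
#' @export
het_excess_test <- function(g, population, tpm = tpm_params(), iters = NULL,
                            max_k = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(iters)) iters <- tpm$iterations
  rows <- list()
  for (l in seq_len(nrow(g$panel))) {
    cp <- .copies(g, population, l)
    copies <- c(cp$a1, cp$a2)
    nc <- length(copies)
    if (nc < 4) next
    k <- length(unique(copies))
    if (k < 2) next
    if (k > max_k) {
      warning("locus ", g$panel$locus[l], " skipped: ", k,
              " alleles exceed max_k = ", max_k)
      next
    }
    pr <- as.numeric(table(copies)) / nc
    he_obs <- nc / (nc - 1) * (1 - sum(pr^2))
    heq <- tryCatch(
      heq_tpm_cpp(as.integer(k), as.integer(nc), tpm$p_smm, tpm$p_geom,
                  as.integer(iters), .heq_grid(k), 5e6),
      error = function(e) {
        warning("locus ", g$panel$locus[l], " skipped (k = ", k,
                " of ", nc, " copies unreachable at equilibrium): ",
                conditionMessage(e))
        NULL
      })
    if (is.null(heq)) next
    m <- mean(heq); s <- sd(heq)
    rows[[length(rows) + 1]] <- data.frame(
      locus = g$panel$locus[l], k = k, n_copies = nc, He_obs = he_obs,
      Heq_mean = m, Heq_sd = s,
      excess = if (s > 0) (he_obs - m) / s else NA_real_,
      stringsAsFactors = FALSE)
  }
  per_locus <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(), k = integer(), n_copies = integer(),
               He_obs = numeric(), Heq_mean = numeric(), Heq_sd = numeric(),
               excess = numeric())
  ex <- per_locus$excess[!is.na(per_locus$excess)]
  p <- if (length(ex) >= 4)
    suppressWarnings(wilcox.test(ex, alternative = "two.sided")$p.value)
  else NA_real_
  list(per_locus = per_locus,
       n_excess = sum(ex > 0), n_deficit = sum(ex < 0),
       wilcoxon_p = p, tpm = tpm)
}

#' Bottleneck report for many populations
#'
#' Runs [m_ratio()] and [het_excess_test()] for each population with at
#' least `min_n` individuals and tabulates the flags (mean M at or below
#' `critical`; two-tailed Wilcoxon P below `alpha`).
#'
#' @param g a `genotype_matrix`.
#' @param populations populations to test (default all).
#' @param min_n minimum individuals for a population to be testable.
#' @param tpm a [tpm_params()].
#' @param critical M-ratio critical value.
#' @param alpha Wilcoxon significance level.
#' @param seed RNG seed.
#' @return Data frame with one row per tested population.
#' @export
bottleneck_report <- function(g, populations = unique(g$ind$pop), min_n = 4,
                              tpm = tpm_params(), critical = 0.68,
                              alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (p in populations) {
    n <- sum(g$ind$pop == p)
    if (n < min_n) next
    mr <- m_ratio(g, p, critical)
    he <- het_excess_test(g, p, tpm)
    rows[[length(rows) + 1]] <- data.frame(
      pop = p, n = n, mean_M = mr$mean_M, M_bottleneck = mr$bottleneck,
      wilcoxon_p = he$wilcoxon_p,
      He_bottleneck = !is.na(he$wilcoxon_p) & he$wilcoxon_p < alpha &
        he$n_excess > he$n_deficit,
      n_excess = he$n_excess, n_deficit = he$n_deficit,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
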