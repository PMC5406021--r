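# Per-population diversity, pairwise differentiation with permutation
# significance, and the Mantel test. Estimator conventions:
#  - theta: Weir & Cockerham (1984), ratio of sums across alleles and loci
#  - Jost's D / G''ST: unbiased HS/HT (Nei & Chesson corrections), HS and
#    HT averaged across loci before the ratio (Meirmans & Hedrick)
#  - PhiPT: AMOVA on squared codominant-genotypic distances
#    (Smouse & Peakall), the allele-size-independent band-sharing metric

# gene copies for one population x locus (excluding missing; optionally
# excluding imputed calls)
.copies <- function(g, pop, locus, exclude_imputed = FALSE) {
  l <- if (is.character(locus)) match(locus, g$panel$locus) else locus
  sel <- g$ind$pop == pop & !is.na(g$a1[, l])
  if (exclude_imputed) sel <- sel & !g$imputed[, l]
  list(a1 = g$a1[sel, l], a2 = g$a2[sel, l])
}

#' Per-population diversity summary
#'
#' For every population and locus: number of scored individuals (N),
#' allele count (Na), effective allele number (Ne_eff = 1 / sum p^2),
#' observed heterozygosity (Ho), expected heterozygosity (He = 1 - sum
#' p^2), its unbiased version (uHe = 2n/(2n-1) He) and the fixation index
#' (F = 1 - Ho/He, undefined at monomorphic loci). Imputed calls are
#' excluded. Means and standard errors across loci are reported per
#' population.
#'
#' @param g a `genotype_matrix`.
#' @return List with `per_locus` and `means` data frames.
#' @export
diversity_summary <- function(g) {
  rows <- list()
  for (p in unique(g$ind$pop)) {
    for (l in seq_len(nrow(g$panel))) {
      cp <- .copies(g, p, l, exclude_imputed = TRUE)
      n <- length(cp$a1)
      if (n == 0) next
      copies <- c(cp$a1, cp$a2)
      pr <- as.numeric(table(copies)) / (2 * n)
      he <- 1 - sum(pr^2)
      ho <- mean(cp$a1 != cp$a2)
      rows[[length(rows) + 1]] <- data.frame(
        pop = p, locus = g$panel$locus[l], N = n,
        Na = length(pr), Ne_eff = 1 / sum(pr^2), Ho = ho, He = he,
        uHe = 2 * n / (2 * n - 1) * he,
        F = if (he > 0) 1 - ho / he else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  per_locus <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       se = sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  means <- do.call(rbind, lapply(split(per_locus, per_locus$pop), function(d) {
    out <- data.frame(pop = d$pop[1])
    for (col in c("N", "Na", "Ne_eff", "Ho", "He", "uHe", "F")) {
      a <- agg(d[[col]])
      out[[paste0(col, "_mean")]] <- a["mean"]
      out[[paste0(col, "_se")]] <- a["se"]
    }
    out
  }))
  rownames(means) <- NULL
  list(per_locus = per_locus, means = means)
}

# Weir-Cockerham variance components for one locus, two populations.
# Returns c(num, den) = (sum of a, sum of a+b+c) over alleles.
.wc_locus <- function(cpA, cpB) {
  nA <- length(cpA$a1); nB <- length(cpB$a1)
  if (nA < 1 || nB < 1) return(c(0, 0))
  alleles <- sort(unique(c(cpA$a1, cpA$a2, cpB$a1, cpB$a2)))
  if (length(alleles) < 2) return(c(0, 0))
  r <- 2
  nbar <- (nA + nB) / 2
  nc <- (nA + nB - (nA^2 + nB^2) / (nA + nB)) / (r - 1)
  num <- den <- 0
  for (u in alleles) {
    pA <- (sum(cpA$a1 == u) + sum(cpA$a2 == u)) / (2 * nA)
    pB <- (sum(cpB$a1 == u) + sum(cpB$a2 == u)) / (2 * nB)
    hA <- sum((cpA$a1 == u) != (cpA$a2 == u)) / nA
    hB <- sum((cpB$a1 == u) != (cpB$a2 == u)) / nB
    pbar <- (nA * pA + nB * pB) / (nA + nB)
    s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
    hbar <- (nA * hA + nB * hB) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  c(num, den)
}

#' Pairwise Weir-Cockerham theta
#'
#' Multilocus Fst estimate between two populations: Weir & Cockerham's
#' theta, combining variance components as a ratio of sums across alleles
#' and loci. Loci missing in either population are skipped; an error is
#' raised when no locus is scored in both.
#'
#' @param g a `genotype_matrix`.
#' @param popA,popB population labels.
#' @return Numeric theta (can be slightly negative by sampling noise).
#' @export
pairwise_fst <- function(g, popA, popB) {
  num <- den <- 0
  shared <- 0L
  for (l in seq_len(nrow(g$panel))) {
    cpA <- .copies(g, popA, l)
    cpB <- .copies(g, popB, l)
    if (length(cpA$a1) < 1 || length(cpB$a1) < 1) next
    shared <- shared + 1L
    w <- .wc_locus(cpA, cpB)
    num <- num + w[1]
    den <- den + w[2]
  }
  if (shared == 0) stop("no shared scored loci between ", popA, " and ", popB)
  if (den == 0) return(0)
  num / den
}

# unbiased HS/HT for one locus, two populations (Nei & Chesson)
.hs_ht_locus <- function(cpA, cpB) {
  nA <- length(cpA$a1); nB <- length(cpB$a1)
  alleles <- sort(unique(c(cpA$a1, cpA$a2, cpB$a1, cpB$a2)))
  pA <- vapply(alleles, function(u)
    (sum(cpA$a1 == u) + sum(cpA$a2 == u)) / (2 * nA), 0)
  pB <- vapply(alleles, function(u)
    (sum(cpB$a1 == u) + sum(cpB$a2 == u)) / (2 * nB), 0)
  nh <- 2 / (1 / nA + 1 / nB)                  # harmonic mean sample size
  hs_raw <- mean(c(1 - sum(pA^2), 1 - sum(pB^2)))
  ht_raw <- 1 - sum(((pA + pB) / 2)^2)
  hs <- 2 * nh / (2 * nh - 1) * hs_raw
  ht <- ht_raw + hs / (2 * nh * 2)
  c(hs = hs, ht = ht)
}

#' Pairwise Jost's D and G''ST
#'
#' Differentiation between two populations based on unbiased within- and
#' total-heterozygosity estimates: with k = 2 demes,
#' `D = (k/(k-1)) (HT-HS)/(1-HS)` and
#' `G''ST = k (HT-HS) / ((k HT - HS)(1-HS))`. The multilocus value
#' averages HS and HT across loci before forming the ratio (default) or
#' averages per-locus ratios (`multilocus = "mean_of_ratios"`).
#'
#' @param g a `genotype_matrix`.
#' @param popA,popB population labels.
#' @param multilocus `"pooled"` (average HS, HT first) or
#'   `"mean_of_ratios"`.
#' @return List with elements `D` and `Gppst` (either may be `NaN` when
#'   HS = 1).
#' @export
pairwise_jost <- function(g, popA, popB,
                          multilocus = c("pooled", "mean_of_ratios")) {
  multilocus <- match.arg(multilocus)
  hs <- ht <- numeric(0)
  for (l in seq_len(nrow(g$panel))) {
    cpA <- .copies(g, popA, l)
    cpB <- .copies(g, popB, l)
    if (length(cpA$a1) < 1 || length(cpB$a1) < 1) next
    v <- .hs_ht_locus(cpA, cpB)
    hs <- c(hs, v["hs"]); ht <- c(ht, v["ht"])
  }
  if (!length(hs)) stop("no shared scored loci between ", popA, " and ", popB)
  k <- 2
  dg <- function(HS, HT) {
    list(D = k / (k - 1) * (HT - HS) / (1 - HS),
         Gppst = k * (HT - HS) / ((k * HT - HS) * (1 - HS)))
  }
  if (multilocus == "pooled") {
    dg(mean(hs), mean(ht))
  } else {
    per <- mapply(function(a, b) unlist(dg(a, b)), hs, ht)
    list(D = mean(per["D", ]), Gppst = mean(per["Gppst", ]))
  }
}

# squared codominant-genotypic distance between two individuals at one
# locus: half the squared difference of allele-count vectors
# (AA-AA 0, AA-AB 1, AB-AB 0, AA-BB 4, AA-BC 3, AB-CD 2)
.geno_dist2 <- function(a1, a2, b1, b2) {
  alleles <- unique(c(a1, a2, b1, b2))
  ca <- vapply(alleles, function(u) sum(c(a1, a2) == u), 0L)
  cb <- vapply(alleles, function(u) sum(c(b1, b2) == u), 0L)
  sum((ca - cb)^2) / 2
}

# summed squared distance matrix across loci for the individuals of two pops
.dist2_matrix <- function(g, idx) {
  n <- length(idx)
  D <- matrix(0, n, n)
  for (l in seq_len(nrow(g$panel))) {
    a1 <- g$a1[idx, l]; a2 <- g$a2[idx, l]
    ok <- !is.na(a1)
    for (i in seq_len(n - 1)) {
      if (!ok[i]) next
      for (j in (i + 1):n) {
        if (!ok[j]) next
        d <- .geno_dist2(a1[i], a2[i], a1[j], a2[j])
        D[i, j] <- D[i, j] + d
        D[j, i] <- D[i, j]
      }
    }
  }
  D
}

# PhiPT from a squared-distance matrix and group sizes
.phipt_from_dist <- function(D, grp) {
  N <- nrow(D)
  pops <- unique(grp)
  P <- length(pops)
  ss_total <- sum(D[upper.tri(D)]) / N
  ss_within <- 0
  for (p in pops) {
    sel <- which(grp == p)
    if (length(sel) > 1) {
      Dp <- D[sel, sel, drop = FALSE]
      ss_within <- ss_within + sum(Dp[upper.tri(Dp)]) / length(sel)
    }
  }
  ss_among <- ss_total - ss_within
  df_a <- P - 1
  df_w <- N - P
  ms_a <- ss_among / df_a
  ms_w <- ss_within / df_w
  n0 <- (N - sum(table(grp)^2) / N) / df_a
  va <- (ms_a - ms_w) / n0
  vw <- ms_w
  if (va + vw <= 0) return(0)
  va / (va + vw)
}

#' Pairwise PhiPT (AMOVA)
#'
#' Among-population fraction of molecular variance between two
#' populations, computed from squared codominant-genotypic distances
#' between individuals (allele-size independent). This is the AMOVA-based
#' Fst analogue commonly paired with Mantel tests of isolation by
#' distance.
#'
#' @param g a `genotype_matrix`.
#' @param popA,popB population labels.
#' @return PhiPT in `[0, 1]` (small negative variance components clip to 0).
#' @export
pairwise_phipt <- function(g, popA, popB) {
  idx <- which(g$ind$pop %in% c(popA, popB))
  if (length(unique(g$ind$pop[idx])) < 2)
    stop("both populations must contain individuals")
  D <- .dist2_matrix(g, idx)
  .phipt_from_dist(D, g$ind$pop[idx])
}

#' Permutation test for a pairwise statistic
#'
#' Individuals are permuted between the two populations and the statistic
#' recomputed; the p-value is `(1 + #[perm >= observed]) / (n_perm + 1)`.
#'
#' @param stat_fn function `(g, popA, popB) -> numeric` (for example
#'   [pairwise_fst()]).
#' @param g a `genotype_matrix`.
#' @param popA,popB population labels.
#' @param n_perm number of permutations (the study convention is 9,999).
#' @param seed RNG seed.
#' @return List with `observed`, `p`, `n_perm`.
#' @export
permutation_test <- function(stat_fn, g, popA, popB, n_perm = 9999,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 1) stop("n_perm must be at least 1")
  idx <- which(g$ind$pop %in% c(popA, popB))
  sub <- g[idx]
  obs <- stat_fn(sub, popA, popB)
  labs <- sub$ind$pop
  count <- 0L
  for (b in seq_len(n_perm)) {
    sub$ind$pop <- sample(labs)
    stat <- tryCatch(stat_fn(sub, popA, popB), error = function(e) NA_real_)
    if (!is.na(stat) && stat >= obs) count <- count + 1L
  }
  list(observed = obs, p = (1 + count) / (n_perm + 1), n_perm = n_perm)
}

#' Mantel test of genetic against geographic distance
#'
#' Pearson correlation of the lower-triangle entries of two distance
#' matrices, a least-squares line `genetic = slope * geographic +
#' intercept`, and a one-tailed permutation p-value obtained by jointly
#' permuting the rows and columns of one matrix.
#'
#' @param genetic,geographic square symmetric distance matrices with
#'   matching dimensions (and matching dimnames when present).
#' @param n_perm number of matrix permutations.
#' @param seed RNG seed.
#' @return List with `r`, `R2`, `slope`, `intercept`, `p`, `n_perm`.
#' @export
mantel_test <- function(genetic, geographic, n_perm = 9999, seed = NULL) {
  genetic <- as.matrix(genetic); geographic <- as.matrix(geographic)
  if (!all(dim(genetic) == dim(geographic)))
    stop("distance matrices must have matching dimensions")
  if (!is.null(dimnames(genetic)[[1]]) && !is.null(dimnames(geographic)[[1]]) &&
      !identical(dimnames(genetic)[[1]], dimnames(geographic)[[1]]))
    stop("distance matrix labels do not match")
  if (!is.null(seed)) set.seed(seed)
  lt <- lower.tri(genetic)
  y <- genetic[lt]; x <- geographic[lt]
  if (sd(y) == 0 || sd(x) == 0)
    stop("constant distance matrix: correlation undefined")
  r <- stats::cor(x, y)
  fit <- lm(y ~ x)
  count <- 0L
  n <- nrow(genetic)
  for (b in seq_len(n_perm)) {
    o <- sample(n)
    rp <- stats::cor(x, genetic[o, o][lt])
    if (rp >= r) count <- count + 1L
  }
  list(r = r, R2 = r^2, slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       p = (1 + count) / (n_perm + 1), n_perm = n_perm)
}

#' Great-circle distance matrix
#'
#' Haversine distances in km between labelled coordinates, for Mantel
#' tests against genetic distance.
#'
#' @param coords data frame with columns `pop`, `lat`, `lon` (degrees).
#' @return Symmetric matrix of distances in km with `pop` dimnames.
#' @export
geo_dist_km <- function(coords) {
  stopifnot(all(c("pop", "lat", "lon") %in% names(coords)))
  n <- nrow(coords)
  rad <- pi / 180
  D <- matrix(0, n, n, dimnames = list(coords$pop, coords$pop))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dlat <- (coords$lat[j] - coords$lat[i]) * rad
      dlon <- (coords$lon[j] - coords$lon[i]) * rad
      a <- sin(dlat / 2)^2 +
        cos(coords$lat[i] * rad) * cos(coords$lat[j] * rad) * sin(dlon / 2)^2
      D[i, j] <- D[j, i] <- 6371 * 2 * asin(min(1, sqrt(a)))
    }
  }
  D
}

#' All pairwise differentiation matrices
#'
#' Computes the chosen statistic for every population pair, optionally
#' with permutation p-values; matrices are symmetric with zero diagonal.
#'
#' @param g a `genotype_matrix`.
#' @param stat one of `"fst"`, `"jostd"`, `"gppst"`, `"phipt"`.
#' @param n_perm permutations for significance (0 skips testing).
#' @param seed RNG seed.
#' @return List with `stat` matrix and (when requested) `p` matrix.
#' @export
pairwise_matrix <- function(g, stat = c("fst", "jostd", "gppst", "phipt"),
                            n_perm = 0, seed = NULL) {
  stat <- match.arg(stat)
  fn <- switch(stat,
    fst = pairwise_fst,
    jostd = function(g, a, b) pairwise_jost(g, a, b)$D,
    gppst = function(g, a, b) pairwise_jost(g, a, b)$Gppst,
    phipt = pairwise_phipt)
  pops <- unique(g$ind$pop)
  k <- length(pops)
  M <- matrix(0, k, k, dimnames = list(pops, pops))
  P <- if (n_perm > 0) matrix(NA_real_, k, k, dimnames = list(pops, pops))
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (n_perm > 0) {
        pt <- permutation_test(fn, g, pops[i], pops[j], n_perm)
        M[i, j] <- M[j, i] <- pt$observed
        P[i, j] <- P[j, i] <- pt$p
      } else {
        M[i, j] <- M[j, i] <- fn(g, pops[i], pops[j])
      }
    }
  }
  out <- list(stat = M)
  if (n_perm > 0) out$p <- P
  out
}
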