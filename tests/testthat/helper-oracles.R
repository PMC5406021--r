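# Independent brute-force oracles used to verify the package estimators.
# These are deliberately written along different routes than the package
# code (ANOVA mean squares instead of the a/b/c components, literal
# formula transcriptions, exhaustive enumeration) so a shared bug is
# unlikely.

# gene-copy list per population x locus from a genotype_matrix
oracle_copies <- function(g, pop, l) {
  sel <- g$ind$pop == pop & !is.na(g$a1[, l])
  rbind(g$a1[sel, l], g$a2[sel, l])  # 2 x n matrix, columns = individuals
}

# Weir-Cockerham theta via the ANOVA mean-square formulation (Weir 1996):
# per allele, sums of squares among populations, among individuals within
# populations, and within individuals; variance components from the mean
# squares; theta as ratio of sums across alleles and loci.
oracle_wc_theta <- function(g, popA, popB) {
  num <- 0; den <- 0
  for (l in seq_len(nrow(g$panel))) {
    cpA <- oracle_copies(g, popA, l)
    cpB <- oracle_copies(g, popB, l)
    nA <- ncol(cpA); nB <- ncol(cpB)
    if (nA < 1 || nB < 1) next
    N <- nA + nB
    r <- 2
    nc <- (N - (nA^2 + nB^2) / N) / (r - 1)
    for (u in unique(c(cpA, cpB))) {
      piA <- mean(cpA == u); piB <- mean(cpB == u)
      pbar <- (2 * nA * piA + 2 * nB * piB) / (2 * N)
      hA <- mean((cpA[1, ] == u) != (cpA[2, ] == u))
      hB <- mean((cpB[1, ] == u) != (cpB[2, ] == u))
      SSP <- 2 * nA * (piA - pbar)^2 + 2 * nB * (piB - pbar)^2
      SSI <- (2 * nA * piA * (1 - piA) - nA * hA / 2) +
             (2 * nB * piB * (1 - piB) - nB * hB / 2)
      SSG <- (nA * hA + nB * hB) / 2
      MSP <- SSP / (r - 1)
      MSI <- SSI / (N - r)
      MSG <- SSG / N
      s2a <- (MSP - MSI) / (2 * nc)
      s2b <- (MSI - MSG) / 2
      s2w <- MSG
      num <- num + s2a
      den <- den + s2a + s2b + s2w
    }
  }
  num / den
}

# Jost's D and G''ST by direct transcription of the two-deme formulas
oracle_jost <- function(g, popA, popB) {
  hs_all <- c(); ht_all <- c()
  for (l in seq_len(nrow(g$panel))) {
    cpA <- oracle_copies(g, popA, l); cpB <- oracle_copies(g, popB, l)
    nA <- ncol(cpA); nB <- ncol(cpB)
    if (nA < 1 || nB < 1) next
    alle <- unique(c(cpA, cpB))
    fA <- sapply(alle, function(u) mean(cpA == u))
    fB <- sapply(alle, function(u) mean(cpB == u))
    nh <- 2 / (1 / nA + 1 / nB)
    HsR <- ((1 - sum(fA^2)) + (1 - sum(fB^2))) / 2
    HtR <- 1 - sum(((fA + fB) / 2)^2)
    Hs <- HsR * 2 * nh / (2 * nh - 1)
    Ht <- HtR + Hs / (4 * nh)
    hs_all <- c(hs_all, Hs); ht_all <- c(ht_all, Ht)
  }
  HS <- mean(hs_all); HT <- mean(ht_all)
  list(D = 2 * (HT - HS) / (1 - HS),
       Gppst = 2 * (HT - HS) / ((2 * HT - HS) * (1 - HS)))
}

# PhiPT by literal two-level AMOVA with explicit loops over individual
# pairs and the standard squared genotype distance table
oracle_phipt <- function(g, popA, popB) {
  idx <- which(g$ind$pop %in% c(popA, popB))
  grp <- g$ind$pop[idx]
  n <- length(idx)
  d2 <- function(i, j) {
    tot <- 0
    for (l in seq_len(nrow(g$panel))) {
      a <- c(g$a1[idx[i], l], g$a2[idx[i], l])
      b <- c(g$a1[idx[j], l], g$a2[idx[j], l])
      if (any(is.na(a)) || any(is.na(b))) next
      alle <- unique(c(a, b))
      ca <- sapply(alle, function(u) sum(a == u))
      cb <- sapply(alle, function(u) sum(b == u))
      tot <- tot + sum((ca - cb)^2) / 2
    }
    tot
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) D[i, j] <- D[j, i] <- d2(i, j)
  ssT <- sum(D[upper.tri(D)]) / n
  ssW <- 0
  for (p in c(popA, popB)) {
    sel <- which(grp == p)
    Dp <- D[sel, sel]
    ssW <- ssW + sum(Dp[upper.tri(Dp)]) / length(sel)
  }
  ssA <- ssT - ssW
  P <- 2
  msA <- ssA / (P - 1); msW <- ssW / (n - P)
  n0 <- (n - sum(table(grp)^2) / n) / (P - 1)
  vA <- (msA - msW) / n0
  if (vA + msW <= 0) return(0)
  vA / (vA + msW)
}

# nucleotide diversity by counting differing sites over all pairs at once
oracle_pi <- function(seqmat) {
  n <- nrow(seqmat)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !(seqmat[i, ] %in% c("N", "-")) & !(seqmat[j, ] %in% c("N", "-"))
    tot <- tot + sum(seqmat[i, ok] != seqmat[j, ok]) / sum(ok)
    np <- np + 1
  }
  tot / np
}

# haplotype diversity from raw counts
oracle_hd <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

# M-ratio directly from allele size vectors
oracle_m_ratio <- function(sizes, motif) {
  ru <- (sizes - min(sizes)) / motif
  length(unique(ru)) / (max(ru) - min(ru) + 1)
}

# minimum spanning-tree weight by exhaustive enumeration of edge subsets
# (feasible for <= 6 nodes)
oracle_mst_weight <- function(D) {
  n <- nrow(D)
  edges <- t(combn(n, 2))
  ne <- nrow(edges)
  best <- Inf
  for (comb in combn(ne, n - 1, simplify = FALSE)) {
    # connectivity check by union-find
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in comb) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (!ok) next
    w <- sum(D[edges[comb, , drop = FALSE]])
    best <- min(best, w)
  }
  best
}

# equilibrium Heq distribution under the TPM, plain-R re-implementation
# (independent of the C++ path): coalescent times, mutation placement by
# branch, step propagation, fixed-k acceptance
oracle_heq <- function(k_target, n, p_smm, p_geom, iters, theta, seed) {
  set.seed(seed)
  out <- numeric(0)
  while (length(out) < iters) {
    # coalescent tree
    parent <- integer(2 * n - 1); tim <- numeric(2 * n - 1)
    active <- 1:n; nxt <- n + 1; t <- 0
    while (length(active) > 1) {
      kk <- length(active)
      t <- t + rexp(1, kk * (kk - 1) / 2)
      pair <- sample(active, 2)
      parent[pair] <- nxt; tim[nxt] <- t
      active <- c(setdiff(active, pair), nxt)
      nxt <- nxt + 1
    }
    state <- integer(2 * n - 1)
    for (v in (2 * n - 2):1) {
      len <- tim[parent[v]] - tim[v]
      nm <- rpois(1, theta / 2 * len)
      s <- state[parent[v]]
      if (nm > 0) for (m in 1:nm) {
        step <- 1
        if (runif(1) >= p_smm) step <- step + rgeom(1, p_geom)
        s <- s + sample(c(-1, 1), 1) * step
      }
      state[v] <- s
    }
    cnt <- table(state[1:n])
    if (length(cnt) != k_target) next
    p <- as.numeric(cnt) / n
    out <- c(out, n / (n - 1) * (1 - sum(p^2)))
  }
  out
}

# small helpers shared across tests -----------------------------------

# equilibrium single-population scenario (no events)
eq_scenario <- function(ne, n_ind = 30) {
  scenario("eq", "A", ne0 = list(A = ne), events = list(), priors = list(),
           samples = data.frame(pop = "A", year = 2015, n = n_ind))
}

# compiled single-pop scenario with a staged crash (backward: Ne now ->
# larger historical Ne beyond `when`)
crash_scenario <- function(ne_now, ne_old, when, n_ind = 30) {
  scenario("crash", "A", ne0 = list(A = ne_now),
           events = list(list(kind = "ne_change", pop = "A", time = when,
                              ne = ne_old)),
           priors = list(),
           samples = data.frame(pop = "A", year = 2015, n = n_ind))
}

# simulate an equilibrium genotype_matrix under a compiled scenario with
# TPM-style mutation settings
sim_equilibrium_geno <- function(cs, panel, mu = 5e-4, p_gsm = 1,
                                 p_geom = 0.5) {
  sim <- simulate_dataset(cs, panel = panel, include_seq = FALSE,
                          defaults = list(MU_DI = mu, MU_TRI = mu,
                                          P_GSM_DI = p_gsm,
                                          P_GSM_TRI = p_gsm,
                                          rate_shape = 2, p_geom = p_geom))
  as_genotype_matrix(sim)
}

tri_panel <- function(n = 13) locus_panel(sprintf("L%02d", seq_len(n)),
                                          rep(3L, n))

# Tajima's D via the site-frequency route (mean pairwise differences from
# per-site allele counts rather than pairwise sequence loops), with the
# constants transcribed literally
oracle_tajima <- function(seqmat) {
  n <- nrow(seqmat)
  keep <- apply(seqmat, 2, function(cc) !any(cc %in% c("N", "-")))
  s <- seqmat[, keep, drop = FALSE]
  S <- 0; khat <- 0
  for (j in seq_len(ncol(s))) {
    cnt <- table(s[, j])
    if (length(cnt) > 1) S <- S + 1
    khat <- khat + (n^2 - sum(cnt^2)) / (n * (n - 1))
  }
  if (S == 0) return(list(D = NA_real_, S = S, k = khat))
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  D <- (khat - S / a1) /
    sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
  list(D = D, S = S, k = khat)
}
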