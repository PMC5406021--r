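# Diversity summaries, pairwise differentiation (against independent
# oracles), permutation significance and the Mantel test.

fx <- make_toy_fixtures()

test_that("diversity summary matches closed forms on constructed data", {
  # all-heterozygous toy: Ho = 1, He = 0.5, F = -1
  d <- diversity_summary(fx$het_excess$data)$per_locus
  expect_equal(d$Ho, 1)
  expect_equal(d$He, 0.5)
  expect_equal(d$F, -1)
  # uHe = (2n/(2n-1)) He: 10 diploids at 0.5/0.5 -> (20/19) * 0.5
  pan <- locus_panel("L1", 2L)
  g <- invabc:::new_genotype_matrix(
    data.frame(id = sprintf("i%d", 1:10), pop = "P", year = 2015L),
    pan, matrix(rep(100L, 10)), matrix(rep(102L, 10)))
  d2 <- diversity_summary(g)$per_locus
  expect_equal(d2$He, 0.5)
  expect_equal(d2$uHe, 20 / 19 * 0.5)
  # monomorphic population
  gm <- invabc:::new_genotype_matrix(
    data.frame(id = sprintf("i%d", 1:5), pop = "P", year = 2015L),
    pan, matrix(rep(100L, 5)), matrix(rep(100L, 5)))
  dm <- diversity_summary(gm)$per_locus
  expect_equal(dm$Ho, 0)
  expect_equal(dm$He, 0)
  expect_equal(dm$Na, 1)
  expect_equal(dm$Ne_eff, 1)
  expect_true(is.na(dm$F))
})

test_that("Weir-Cockerham theta agrees with the ANOVA oracle", {
  g <- fx$textbook_2pop$data
  theta <- pairwise_fst(g, "A", "B")
  expect_equal(theta, oracle_wc_theta(g, "A", "B"), tolerance = 1e-12)
  # fixed different alleles at every locus
  expect_equal(pairwise_fst(fx$fixed_diff$data, "A", "B"), 1)
  # null case: one panmictic sample split in two, theta near 0
  set.seed(31)
  cs <- compile_scenario(eq_scenario(2000, 200), c(x = 1))
  g0 <- sim_equilibrium_geno(cs, tri_panel(5))
  g0$ind$pop <- rep(c("A", "B"), 100)
  expect_lt(abs(pairwise_fst(g0, "A", "B")), 0.02)
})

test_that("Jost's D and G''ST match the direct-formula oracle", {
  g <- fx$textbook_2pop$data
  j <- pairwise_jost(g, "A", "B")
  o <- oracle_jost(g, "A", "B")
  expect_equal(j$D, o$D, tolerance = 1e-12)
  expect_equal(j$Gppst, o$Gppst, tolerance = 1e-12)
  jf <- pairwise_jost(fx$fixed_diff$data, "A", "B")
  expect_equal(jf$D, 1, tolerance = 1e-12)
  expect_equal(jf$Gppst, 1, tolerance = 1e-12)
  # identical populations: D and G''ST near zero (small-sample corrections
  # leave a downward bias of order 1/n)
  pan <- locus_panel("L1", 2L)
  g2 <- invabc:::new_genotype_matrix(
    data.frame(id = sprintf("i%d", 1:80), pop = rep(c("A", "B"), each = 40),
               year = 2015L),
    pan, matrix(rep(c(100L, 102L), 40)), matrix(rep(c(102L, 104L), 40)))
  j2 <- pairwise_jost(g2, "A", "B")
  expect_lt(abs(j2$D), 0.05)
})

test_that("PhiPT matches the AMOVA oracle and its limits", {
  # clones vs clones of a different genotype -> PhiPT = 1
  pan <- locus_panel("L1", 2L)
  g1 <- invabc:::new_genotype_matrix(
    data.frame(id = sprintf("i%d", 1:4), pop = rep(c("A", "B"), each = 2),
               year = 2015L),
    pan, matrix(c(100L, 100L, 104L, 104L)), matrix(c(100L, 100L, 104L, 104L)))
  expect_equal(pairwise_phipt(g1, "A", "B"), 1)
  # 6-individual toy vs literal AMOVA hand computation
  g6 <- invabc:::new_genotype_matrix(
    data.frame(id = sprintf("i%d", 1:6), pop = rep(c("A", "B"), each = 3),
               year = 2015L),
    locus_panel(c("L1", "L2"), c(2L, 2L)),
    cbind(c(100L, 100L, 102L, 104L, 104L, 106L),
          c(150L, 152L, 150L, 154L, 154L, 152L)),
    cbind(c(100L, 102L, 102L, 104L, 106L, 106L),
          c(152L, 152L, 150L, 154L, 152L, 154L)))
  expect_equal(pairwise_phipt(g6, "A", "B"), oracle_phipt(g6, "A", "B"),
               tolerance = 1e-12)
  # panmictic split: PhiPT near 0
  set.seed(32)
  cs <- compile_scenario(eq_scenario(2000, 60), c(x = 1))
  g0 <- sim_equilibrium_geno(cs, tri_panel(5))
  g0$ind$pop <- rep(c("A", "B"), 30)
  expect_lt(pairwise_phipt(g0, "A", "B"), 0.05)
})

test_that("differentiation is invariant to label order and allele relabeling", {
  g <- fx$textbook_2pop$data
  expect_equal(pairwise_fst(g, "A", "B"), pairwise_fst(g, "B", "A"))
  expect_equal(pairwise_jost(g, "A", "B")$D, pairwise_jost(g, "B", "A")$D)
  g2 <- g
  g2$a1 <- g2$a1 + 10L  # shift all allele sizes (relabeling)
  g2$a2 <- g2$a2 + 10L
  expect_equal(pairwise_fst(g2, "A", "B"), pairwise_fst(g, "A", "B"))
})

test_that("permutation p-values behave at the boundaries", {
  g <- fx$textbook_2pop$data
  # constant statistic: every permutation ties the observed value -> p = 1
  const_stat <- function(g, a, b) 1
  expect_equal(permutation_test(const_stat, g, "A", "B", n_perm = 99,
                                seed = 1)$p, 1)
  # strongly differentiated data: observed exceeds permuted values
  pt <- permutation_test(pairwise_fst, fx$fixed_diff$data, "A", "B",
                         n_perm = 99, seed = 2)
  expect_lt(pt$p, 0.05)
  expect_equal(pt$observed, 1)
})

test_that("Mantel test recovers perfect correlation and matches direct r", {
  set.seed(9)
  X <- matrix(runif(25), 5, 5); X <- X + t(X); diag(X) <- 0
  m <- mantel_test(X, X, n_perm = 99, seed = 1)
  expect_equal(m$r, 1)
  expect_lt(m$p, 0.05)
  Y <- matrix(runif(25), 5, 5); Y <- Y + t(Y); diag(Y) <- 0
  m2 <- mantel_test(Y, X, n_perm = 99, seed = 1)
  expect_equal(m2$r, cor(X[lower.tri(X)], Y[lower.tri(Y)]))
  fit <- lm(Y[lower.tri(Y)] ~ X[lower.tri(X)])
  expect_equal(m2$slope, unname(coef(fit)[2]))
  expect_equal(m2$intercept, unname(coef(fit)[1]))
  # constant genetic distances: correlation undefined
  Z <- matrix(1, 5, 5); diag(Z) <- 0
  expect_error(mantel_test(Z, X), "constant")
  expect_error(mantel_test(X[1:4, 1:4], Y), "dimensions")
})

test_that("estimated Fst decreases with migration in an island model", {
  # two demes exchanging migrants, approximated by a merge time inversely
  # related to migration: recent contact -> low Fst. Simulated via split
  # ages as a proxy grid; Fst must increase with divergence time.
  set.seed(33)
  ages <- c(50, 200, 800, 2000, 5000)
  fsts <- vapply(ages, function(a) {
    scn <- scenario("m", c("A", "B"), ne0 = list(A = 1000, B = 1000),
                    events = list(list(kind = "split", pop = "B",
                                       parent = "A", time = a)),
                    priors = list(),
                    samples = data.frame(pop = c("A", "B"), year = 2015,
                                         n = 25))
    cs <- compile_scenario(scn, c(x = 1))
    mean(replicate(25, {
      g <- sim_equilibrium_geno(cs, tri_panel(5))
      pairwise_fst(g, "A", "B")
    }))
  }, 0)
  expect_gt(cor(ages, fsts, method = "spearman"), 0)
  expect_true(all(diff(rank(fsts)) > 0) || cor(ages, fsts, method = "spearman") > 0.8)
})
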