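# Coalescent engine: tree structure under serial sampling and splits,
# mutation models, and whole-dataset simulation.

test_that("serial tips only coalesce deeper than their sampling time", {
  scn <- scenario("serial", "A", ne0 = list(A = 500), events = list(),
                  priors = list(),
                  samples = data.frame(pop = "A", year = c(2015, 1995),
                                       n = c(5, 5)))
  cs <- compile_scenario(scn, c(x = 1))
  for (r in 1:20) {
    tr <- simulate_gene_tree(cs, ploidy = 2)
    old <- which(tr$tips$time == 200)
    expect_true(all(tr$time[tr$parent[old] + 1] > 200))
    expect_equal(tr$ntips, 20)
    expect_false(any(is.na(tr$time)))
  }
})

test_that("cross-population coalescence never predates the split", {
  scn <- scenario("split", c("A", "B"), ne0 = list(A = 300, B = 300),
                  events = list(list(kind = "split", pop = "B",
                                     parent = "A", time = 400)),
                  priors = list(),
                  samples = data.frame(pop = c("A", "B"), year = 2015,
                                       n = c(4, 4)))
  cs <- compile_scenario(scn, c(x = 1))
  for (r in 1:20) {
    tr <- simulate_gene_tree(cs, ploidy = 1)
    # MRCA of any cross-population pair is at or beyond the split time
    pops <- tr$tips$pop
    anc <- function(i) {
      path <- integer(0); v <- i - 1L
      while (v >= 0) { path <- c(path, v); v <- tr$parent[v + 1] }
      path
    }
    pa <- anc(1)
    for (j in which(pops == "B")) {
      common <- intersect(pa, anc(j))
      expect_gte(min(tr$time[common + 1]), 400)
    }
  }
})

test_that("stranded lineages in unconnected populations are an error", {
  scn <- scenario("bad", c("A", "B"), ne0 = list(A = 100, B = 100),
                  events = list(), priors = list(),
                  samples = data.frame(pop = c("A", "B"), year = 2015,
                                       n = c(2, 2)))
  cs <- compile_scenario(scn, c(x = 1))
  expect_error(simulate_gene_tree(cs, ploidy = 1), "stranded")
})

test_that("microsatellite mutation variance matches the Poisson law", {
  # hand-built 2-tip tree with one root: path length 2*T between the tips
  T <- 1000
  tree <- structure(list(parent = c(2L, 2L, -1L), time = c(0, 0, T),
                         ntips = 2L), class = "gene_tree")
  mu <- 2e-3
  set.seed(13)
  d <- replicate(3000, {
    st <- mutate_microsat(tree, mutation_model_msat(mu, p_gsm = 1),
                          ancestral_state = 1000)
    st[1] - st[2]
  })
  # under the strict stepwise model, Var(tip difference) = E[mutations]
  expect_lt(abs(mean(d)), 0.15)
  expect_lt(abs(var(d) - mu * 2 * T) / (mu * 2 * T), 0.15)
  # rate 0 leaves every tip at the ancestral state
  st0 <- mutate_microsat(tree, mutation_model_msat(0), 30)
  expect_equal(st0, c(30L, 30L))
  # reflecting boundary keeps repeats at 2 or more
  stb <- replicate(200, min(mutate_microsat(
    tree, mutation_model_msat(0.05, p_gsm = 0.7, p_geom = 0.3), 3)))
  expect_true(all(stb >= 2))
})

test_that("HKY sequence simulation reduces to Jukes-Cantor and mixes", {
  T <- 5e7   # long branches: pairwise identity approaches stationarity
  tree <- structure(list(parent = c(2L, 2L, -1L), time = c(0, 0, T),
                         ntips = 2L), class = "gene_tree")
  set.seed(14)
  m_jc <- mutation_model_seq(1e-7, kappa = 1, freqs = rep(0.25, 4))
  sq <- mutate_sequence(tree, m_jc, L = 4000)
  ident <- mean(sq[1, ] == sq[2, ])
  expect_equal(ident, 0.25, tolerance = 0.05)      # sum pi_i^2 = 0.25
  # under JC each of the 3 alternative states is equally likely: among
  # differing sites, transitions make up ~1/3
  diffs <- which(sq[1, ] != sq[2, ])
  is_ts <- (sq[1, diffs] + sq[2, diffs] == 2 & sq[1, diffs] != 1) |
           (sq[1, diffs] + sq[2, diffs] == 4 & sq[1, diffs] != 0)
  expect_equal(mean(is_ts), 1 / 3, tolerance = 0.06)
  # unequal frequencies: identity approaches sum pi_i^2 of the model
  fr <- c(0.31, 0.15, 0.15, 0.39)
  sq2 <- mutate_sequence(tree, mutation_model_seq(1e-7, kappa = 8,
                                                  freqs = fr), L = 4000)
  expect_equal(mean(sq2[1, ] == sq2[2, ]), sum(fr^2), tolerance = 0.05)
  # at low divergence a strong kappa makes transitions dominate (the
  # saturated regime above loses this signal by multiple hits)
  short <- structure(list(parent = c(2L, 2L, -1L), time = c(0, 0, 5e5),
                          ntips = 2L), class = "gene_tree")
  sq3 <- mutate_sequence(short, mutation_model_seq(1e-7, kappa = 8,
                                                   freqs = rep(0.25, 4)),
                         L = 8000)
  diffs2 <- which(sq3[1, ] != sq3[2, ])
  is_ts2 <- (sq3[1, diffs2] + sq3[2, diffs2] == 2 & sq3[1, diffs2] != 1) |
            (sq3[1, diffs2] + sq3[2, diffs2] == 4 & sq3[1, diffs2] != 0)
  expect_gt(mean(is_ts2), 0.5)
  # rate 0: identical sequences
  sq0 <- mutate_sequence(tree, mutation_model_seq(0), L = 100)
  expect_equal(sq0[1, ], sq0[2, ])
})

test_that("dataset simulation is seeded, typed and degenerate-safe", {
  s <- toy_split_scenarios()$t1
  p <- sample_priors(s, 1, seed = 4)[1, ]
  cs <- compile_scenario(s, p)
  set.seed(99)
  d1 <- simulate_dataset(cs, panel = toy_panel(), include_seq = TRUE,
                         seq_L = 60)
  set.seed(99)
  d2 <- simulate_dataset(cs, panel = toy_panel(), include_seq = TRUE,
                         seq_L = 60)
  expect_identical(d1$repeats, d2$repeats)
  expect_identical(d1$seqs, d2$seqs)
  expect_equal(nrow(d1$repeats), 30)
  expect_false(any(is.na(d1$repeats)))
  # zero mutation rates produce a monomorphic dataset
  p0 <- p; p0["MU_TRI"] <- 0
  cs0 <- compile_scenario(s, p0)
  d0 <- simulate_dataset(cs0, panel = toy_panel(), include_seq = FALSE,
                         defaults = list(MU_DI = 0, MU_TRI = 0,
                                         P_GSM_DI = 1, P_GSM_TRI = 1,
                                         MU_SEQ = 0, KAPPA = 10,
                                         rate_shape = 2, p_geom = 0.5))
  expect_equal(length(unique(as.vector(d0$repeats))), 1)
  # conversion to observed-data types preserves shapes and round-trips
  g <- as_genotype_matrix(d1)
  expect_s3_class(g, "genotype_matrix")
  expect_equal(dim(g), c(30L, 5L))
  aln <- as_coi_alignment(d1)
  expect_equal(ncol(aln$seq), 60)
})

test_that("a study-shaped scenario simulates end-to-end", {
  s4 <- build_study_scenarios()$s4
  p <- sample_priors(s4, 1, seed = 21)[1, ]
  cs <- compile_scenario(s4, p)
  set.seed(22)
  sim <- simulate_dataset(cs, panel = default_panel(), include_seq = TRUE)
  expect_equal(nrow(sim$repeats), 230)   # 7 x 30 + 20 across 8 sample events
  expect_equal(ncol(sim$repeats), 26)
  expect_equal(dim(sim$seqs), c(230L, 445L))
  expect_false(any(is.na(sim$repeats)))
  g <- as_genotype_matrix(sim)
  # temporal samples of the same population get year-suffixed labels
  expect_true(any(grepl("PNG_1995", g$ind$pop)))
  expect_equal(length(unique(g$ind$pop)), 8)
})

test_that("within-population diversity grows with theta", {
  set.seed(23)
  he_at <- function(theta) {
    ne <- theta / (4 * 5e-4)
    cs <- compile_scenario(eq_scenario(ne, 15), c(x = 1))
    mean(replicate(60, {
      sim <- simulate_dataset(cs, panel = toy_panel(3), include_seq = FALSE,
                              defaults = list(MU_DI = 5e-4, MU_TRI = 5e-4,
                                              P_GSM_DI = 1, P_GSM_TRI = 1,
                                              rate_shape = 1e6,
                                              p_geom = 0.5))
      microsat_stats(sim)$stats[["HET.1"]]
    }))
  }
  hes <- vapply(c(0.4, 4, 40), he_at, 0)
  expect_true(all(diff(hes) > 0))
})
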