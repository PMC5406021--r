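# Reading, correcting, filtering and imputing microsatellite genotype
# tables.

make_table_file <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

small_panel <- locus_panel(c("La", "Lb"), c(2L, 3L), c("FAM", "VIC"))

test_that("genotype tables round-trip losslessly and encode missing as 0", {
  df <- data.frame(id = c("i1", "i2", "i3"), pop = "P1", year = 2015,
                   La.1 = c(100, 102, 0), La.2 = c(100, 104, 0),
                   Lb.1 = c(150, 153, 156), Lb.2 = c(153, 153, 159))
  g <- read_genotype_table(make_table_file(df), small_panel)
  expect_equal(dim(g), c(3L, 2L))
  expect_true(is.na(g$a1["i3", "La"]))      # 0,0 cell pair is MISSING
  expect_equal(sum(is.na(g$a1)), 1)
  out <- tempfile(fileext = ".csv")
  write_genotype_table(g, out)
  g2 <- read_genotype_table(out, small_panel)
  expect_identical(g$a1, g2$a1)
  expect_identical(g$a2, g2$a2)
  expect_identical(g$ind, g2$ind)
})

test_that("malformed genotype tables are rejected", {
  df <- data.frame(id = c("i1", "i1"), pop = "P1", year = 2015,
                   La.1 = c(100, 102), La.2 = c(100, 104),
                   Lb.1 = c(150, 153), Lb.2 = c(153, 153))
  expect_error(read_genotype_table(make_table_file(df), small_panel),
               "duplicate")
  df2 <- data.frame(id = "i1", pop = "P1", year = 2015, La.1 = 100,
                    La.2 = 100)
  expect_error(read_genotype_table(make_table_file(df2), small_panel),
               "expected 4 allele columns")
  df3 <- data.frame(id = "i1", pop = "P1", year = 2015,
                    La.1 = "100.5", La.2 = "100",
                    Lb.1 = "150", Lb.2 = "153")
  expect_error(read_genotype_table(make_table_file(df3), small_panel),
               "non-integer")
})

test_that("dye-shift correction shifts by locus offset and inverts", {
  fx <- make_toy_fixtures()$fixed_diff$data
  shifts0 <- data.frame(locus = fx$panel$locus, dye = fx$panel$dye,
                        offset = 0L)
  expect_identical(apply_dye_shift(fx, shifts0)$a1, fx$a1)
  shifts <- shifts0
  shifts$offset[1] <- 2L
  g2 <- apply_dye_shift(fx, shifts)
  expect_equal(g2$a1[, 1], fx$a1[, 1] + 2L, ignore_attr = TRUE)
  expect_equal(g2$a1[, 2], fx$a1[, 2], ignore_attr = TRUE)
  shifts$offset[1] <- -2L
  expect_identical(apply_dye_shift(g2, shifts)$a1, fx$a1)
  # 184 with +2 becomes 186
  g3 <- fx; g3$a1[1, 1] <- 184L; g3$a2[1, 1] <- 184L
  s <- shifts0; s$offset[1] <- 2L
  expect_equal(apply_dye_shift(g3, s)$a1[1, 1], 186L, ignore_attr = TRUE)
})

test_that("individuals under the minimum-scored-loci rule are removed", {
  panel <- locus_panel(sprintf("L%02d", 1:13), c(2L, 2L, rep(3L, 11)))
  a <- matrix(100L, 3, 13)
  g <- invabc:::new_genotype_matrix(
    data.frame(id = c("full", "nine", "eight"), pop = "P", year = 2015L),
    panel, a, a)
  g$a1["nine", 10:13] <- NA_integer_; g$a2["nine", 10:13] <- NA_integer_
  g$a1["eight", 9:13] <- NA_integer_; g$a2["eight", 9:13] <- NA_integer_
  f <- filter_min_loci(g, 9)
  expect_setequal(f$ind$id, c("full", "nine"))   # 9 scored kept, 8 dropped
  expect_equal(attr(f, "removed"), "eight")
  # idempotent, and identity on complete data
  expect_equal(dim(filter_min_loci(f, 9))[1], 2L)
  g_all <- invabc:::new_genotype_matrix(
    data.frame(id = "x", pop = "P", year = 2015L), panel,
    matrix(100L, 1, 13), matrix(100L, 1, 13))
  expect_equal(filter_min_loci(g_all, 9)$ind, g_all$ind)
})

test_that("imputation follows population frequencies and flags calls", {
  panel <- locus_panel("L1", 2L)
  mkg <- function(a1, a2, pop) invabc:::new_genotype_matrix(
    data.frame(id = sprintf("i%d", seq_along(a1)), pop = pop, year = 2015L),
    panel, matrix(as.integer(a1)), matrix(as.integer(a2)))
  # monomorphic population forces the draw
  g <- mkg(c(200, 200, NA), c(200, 200, NA), "P")
  gi <- impute_missing(g, "sampled", seed = 1)
  expect_equal(unname(gi$a1[3, 1]), 200L)
  expect_equal(unname(gi$a2[3, 1]), 200L)
  expect_true(gi$imputed[3, 1])
  # expected mode takes the modal allele: freqs {100: 0.6, 102: 0.4}
  g <- mkg(c(100, 100, 100, 102, NA), c(100, 102, 102, 100, NA), "P")
  ge <- impute_missing(g, "expected")
  expect_equal(unname(ge$a1[5, 1]), 100L)
  # seeded sampling is reproducible
  g <- mkg(c(100, 102, 100, NA, NA), c(102, 102, 100, NA, NA), "P")
  r1 <- impute_missing(g, "sampled", seed = 7)
  r2 <- impute_missing(g, "sampled", seed = 7)
  expect_identical(r1$a1, r2$a1)
  # population x locus with zero data is flagged, not imputed
  g <- mkg(c(NA, NA), c(NA, NA), "P")
  gu <- impute_missing(g, "sampled", seed = 1)
  expect_true(is.na(gu$a1[1, 1]))
  expect_false(is.null(attr(gu, "unimputable")))
})

test_that("allele frequencies sum to one over scored gene copies", {
  panel <- locus_panel("L1", 2L)
  g <- invabc:::new_genotype_matrix(
    data.frame(id = c("i1", "i2", "i3"), pop = "P", year = 2015L),
    panel, matrix(c(100L, 100L, NA)), matrix(c(102L, 100L, NA)))
  af <- allele_frequencies(g)
  # hand count over 4 scored gene copies: 100 x3, 102 x1
  expect_equal(af$freq[af$allele == 100], 0.75)
  expect_equal(af$freq[af$allele == 102], 0.25)
  expect_equal(unique(af$n_copies), 4L)
  expect_equal(sum(af$freq), 1, tolerance = 1e-12)
  # five homozygous diploids: single allele at frequency 1, 10 copies
  g5 <- invabc:::new_genotype_matrix(
    data.frame(id = sprintf("i%d", 1:5), pop = "P", year = 2015L),
    panel, matrix(rep(100L, 5)), matrix(rep(100L, 5)))
  af5 <- allele_frequencies(g5)
  expect_equal(af5$freq, 1)
  expect_equal(af5$n_copies, 10L)
})
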