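# Haplotype collapsing, diversity statistics, Tajima's D and the
# haplotype network.

fx6 <- make_toy_fixtures()$six_seqs$data

test_that("open-reading-frame check finds internal stop codons per frame", {
  # TAA in frame 0 at codon 2, internal
  aln <- coi_alignment(c("ATGTAAATGATGATG", "ATGACAATGATGATG"))
  orf <- check_orf(aln, frame = 0)
  expect_equal(orf$pass, c(FALSE, TRUE))
  expect_equal(orf$n_stops[1], 1)
  # repeated ACG never forms a stop
  aln2 <- coi_alignment(paste(rep("ACG", 5), collapse = ""))
  expect_true(all(check_orf(aln2, 0)$pass))
  # the flagged sequence can pass in a shifted frame
  expect_true(check_orf(aln, frame = 1)$pass[1])
})

test_that("haplotype collapsing groups identical sequences", {
  aln <- coi_alignment(c("AAAA", "AAAA", "AAAA", "AAAT"),
                       pop = c("P1", "P1", "P2", "P2"))
  h <- collapse_haplotypes(aln)
  expect_equal(nrow(h$haplotypes), 2)
  expect_equal(sort(rowSums(h$counts), decreasing = TRUE), c(3, 1),
               ignore_attr = TRUE)
  expect_equal(sum(h$counts), 4)
  # all distinct -> n haplotypes
  alnD <- coi_alignment(c("AAAA", "AAAT", "AATT", "ATTT"))
  expect_equal(nrow(collapse_haplotypes(alnD)$haplotypes), 4)
  # collapsing a set of representatives reproduces the same partition
  h2 <- collapse_haplotypes(coi_alignment(apply(h$haplotypes, 1, paste,
                                                collapse = "")))
  expect_equal(nrow(h2$haplotypes), nrow(h$haplotypes))
})

test_that("ignore-N mode joins N-compatible records deterministically", {
  aln <- coi_alignment(c("AAGA", "AANA", "AATA"))
  hs <- collapse_haplotypes(aln, "strict")
  expect_equal(nrow(hs$haplotypes), 3)
  hn <- collapse_haplotypes(aln, "ignore-N")
  # record 1 anchors a haplotype; the N record is compatible with it;
  # record 3 conflicts with the anchor's G
  expect_equal(nrow(hn$haplotypes), 2)
  expect_equal(unname(hn$membership[1]), unname(hn$membership[2]))
  # an all-N-ambiguous record joins the first (lowest-id) anchor
  aln2 <- coi_alignment(c("AANA", "AAGA", "AATA"))
  hn2 <- collapse_haplotypes(aln2, "ignore-N")
  expect_equal(nrow(hn2$haplotypes), 1)
})

test_that("haplotype and nucleotide diversity match closed forms", {
  # counts (3,1): Hd = (4/3)(1 - 9/16 - 1/16) = 0.5
  aln <- coi_alignment(c("AAAA", "AAAA", "AAAA", "AAAT"))
  h <- collapse_haplotypes(aln)
  expect_equal(haplotype_diversity(h), 0.5)
  expect_equal(haplotype_diversity(h), oracle_hd(c(3, 1)))
  # single haplotype -> 0; two records two haplotypes -> 1
  expect_equal(haplotype_diversity(collapse_haplotypes(
    coi_alignment(c("AAAA", "AAAA")))), 0)
  expect_equal(haplotype_diversity(collapse_haplotypes(
    coi_alignment(c("AAAA", "AAAT")))), 1)
  # pi: identical -> 0; 1 difference in 445 sites -> 1/445
  s <- paste(rep("A", 445), collapse = "")
  s2 <- sub("^A", "T", s)
  expect_equal(nucleotide_diversity(coi_alignment(c(s, s))), 0)
  expect_equal(nucleotide_diversity(coi_alignment(c(s, s2))), 1 / 445)
  # 6-sequence toy equals the brute-force pair average
  pi6 <- nucleotide_diversity(fx6)
  expect_equal(pi6, oracle_pi(fx6$seq), tolerance = 1e-12)
})

test_that("Tajima's D matches a site-frequency-route oracle digit-for-digit", {
  set.seed(41)
  # random 12-sequence alignment with plenty of segregating sites
  mat <- matrix(sample(c("A", "C", "G", "T"), 12 * 60, TRUE,
                       prob = c(0.5, 0.2, 0.2, 0.1)), 12, 60)
  aln <- coi_alignment(mat)
  td <- tajimas_d(aln)
  ot <- oracle_tajima(mat)
  expect_equal(td$D, ot$D, tolerance = 1e-10)
  expect_equal(td$S, ot$S)
  expect_equal(td$pi, ot$k, tolerance = 1e-10)
  # S = 0 -> undefined
  aln0 <- coi_alignment(c("AAAA", "AAAA", "AAAA", "AAAA"))
  expect_true(is.na(tajimas_d(aln0)$D))
  expect_equal(tajimas_d(aln0)$S, 0)
})

test_that("neutral coalescent Tajima's D is centred near zero", {
  set.seed(42)
  scn <- eq_scenario(1, 20)  # haploid tree built directly below
  ds <- replicate(300, {
    cs <- compile_scenario(scn, c(x = 1))
    tree <- simulate_gene_tree(cs, ploidy = 1, ne_scale = 1)
    # theta = 5 per locus: per-site rate over L sites
    sq <- mutate_sequence(tree, mutation_model_seq(5 / 2 / 500 / 1,
                                                   kappa = 1,
                                                   freqs = rep(0.25, 4)),
                          L = 500)
    chars <- matrix(c("A", "C", "G", "T")[sq + 1L], nrow(sq))
    tajimas_d(coi_alignment(chars))$D
  })
  expect_lt(abs(mean(ds, na.rm = TRUE)), 0.15)
})

test_that("haplotype network is a minimum spanning tree with intermediates", {
  # 2 haplotypes 1 step apart: single edge of weight 1
  h2 <- collapse_haplotypes(coi_alignment(c("AAAA", "AAAT")))
  n2 <- haplotype_network(h2)
  expect_equal(nrow(n2$edges), 1)
  expect_equal(n2$edges$weight, 1)
  expect_equal(n2$edges$n_intermediates, 0)
  # star: centre plus 3 singletons one step away in different sites
  star <- coi_alignment(c("AAAA", "TAAA", "ATAA", "AATA"))
  ns <- haplotype_network(collapse_haplotypes(star))
  expect_equal(nrow(ns$edges), 3)
  expect_true(all(ns$edges$from == "H1" | ns$edges$to == "H1"))
  # 5-haplotype toy: total weight equals the exhaustive minimum
  set.seed(17)
  seqs <- apply(matrix(sample(c("A", "C", "G", "T"), 5 * 12, TRUE), 5, 12),
                1, paste, collapse = "")
  h5 <- collapse_haplotypes(coi_alignment(seqs))
  net <- haplotype_network(h5)
  D <- matrix(0, 5, 5)
  for (i in 1:4) for (j in (i + 1):5)
    D[i, j] <- D[j, i] <- sum(h5$haplotypes[i, ] != h5$haplotypes[j, ])
  expect_equal(sum(net$edges$weight), oracle_mst_weight(D))
  # long edges are decorated with unsampled intermediates
  expect_equal(net$edges$n_intermediates, pmax(0, net$edges$weight - 1))
})

test_that("diversity statistics ignore record order and FASTA round-trips", {
  o <- sample(1:6)
  shuffled <- coi_alignment(fx6$seq[o, ], id = fx6$meta$id[o],
                            pop = fx6$meta$pop[o], year = fx6$meta$year[o])
  expect_equal(nucleotide_diversity(shuffled), nucleotide_diversity(fx6))
  expect_equal(haplotype_diversity(collapse_haplotypes(shuffled)),
               haplotype_diversity(collapse_haplotypes(fx6)))
  path <- tempfile(fileext = ".fasta")
  write_coi_fasta(fx6, path)
  back <- read_coi_fasta(path)
  expect_equal(back$seq, fx6$seq, ignore_attr = TRUE)
  expect_equal(back$meta$pop, fx6$meta$pop)
  tbl <- mtdna_diversity_table(fx6)
  expect_equal(tbl$n[tbl$pop == "All"], 6)
  expect_equal(tbl$n_hap[tbl$pop == "All"],
               make_toy_fixtures()$six_seqs$sidecar$n_hap)
})
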