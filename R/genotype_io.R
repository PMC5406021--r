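#' Define a microsatellite locus panel
#'
#' A panel records, for each locus, the repeat-unit length (2 for
#' dinucleotide, 3 for trinucleotide repeats) and the fluorescent dye used
#' for genotyping; the dye matters only for dye-shift correction of legacy
#' allele scores.
#'
#' @param name character vector of unique locus names.
#' @param motif_length integer vector of repeat-unit sizes in bp (2 or 3).
#' @param dye dye label per locus (`"VIC"`, `"NED"`, `"PET"` or `"FAM"`).
#' @return A `locus_panel` data frame with columns `locus`, `motif`, `dye`.
#' @examples
#' locus_panel(c("L1", "L2"), c(2, 3), c("FAM", "VIC"))
#' @export
locus_panel <- function(name, motif_length, dye = rep("FAM", length(name))) {
  name <- as.character(name)
  motif_length <- as.integer(motif_length)
  if (anyDuplicated(name)) stop("locus names must be unique")
  if (!all(motif_length %in% c(2L, 3L)))
    stop("motif_length must be 2 (di-) or 3 (trinucleotide)")
  if (!all(dye %in% c("VIC", "NED", "PET", "FAM")))
    stop("dye must be one of VIC, NED, PET, FAM")
  out <- data.frame(locus = name, motif = motif_length, dye = dye,
                    stringsAsFactors = FALSE)
  class(out) <- c("locus_panel", "data.frame")
  out
}

#' Default 13-locus microsatellite panel
#'
#' Two dinucleotide and eleven trinucleotide loci, mirroring the panel
#' shape used for *Aedes albopictus* population genotyping.
#'
#' @return A [locus_panel()] of 13 loci.
#' @export
default_panel <- function() {
  locus_panel(
    name = sprintf("L%02d", 1:13),
    motif_length = c(2L, 2L, rep(3L, 11L)),
    dye = rep(c("FAM", "VIC", "NED", "PET"), length.out = 13)
  )
}

new_genotype_matrix <- function(ind, panel, a1, a2, imputed = NULL) {
  n <- nrow(ind); L <- nrow(panel)
  stopifnot(nrow(a1) == n, nrow(a2) == n, ncol(a1) == L, ncol(a2) == L)
  if (is.null(imputed)) imputed <- matrix(FALSE, n, L)
  dimnames(a1) <- dimnames(a2) <- dimnames(imputed) <-
    list(ind$id, panel$locus)
  structure(list(ind = ind, panel = panel, a1 = a1, a2 = a2,
                 imputed = imputed),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- sum(is.na(x$a1))
  cat(sprintf(
    "genotype_matrix: %d individuals x %d loci, %d populations, %d missing calls (%d imputed)\n",
    nrow(x$ind), nrow(x$panel), length(unique(x$ind$pop)), miss,
    sum(x$imputed)))
  invisible(x)
}

#' Number of individuals and loci
#' @param x a `genotype_matrix`.
#' @export
dim.genotype_matrix <- function(x) c(nrow(x$ind), nrow(x$panel))

#' Subset a genotype matrix by individuals
#' @param x a `genotype_matrix`.
#' @param i row (individual) index.
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, ...) {
  new_genotype_matrix(x$ind[i, , drop = FALSE], x$panel,
                      x$a1[i, , drop = FALSE], x$a2[i, , drop = FALSE],
                      x$imputed[i, , drop = FALSE])
}

#' Read a microsatellite genotype table
#'
#' Reads a delimited text file in GenAlEx-like "two columns per locus"
#' layout: a header row, then one row per individual with columns
#' `id, pop, year, <locus1>.1, <locus1>.2, <locus2>.1, ...` giving allele
#' sizes in bp. `0`, empty cells and `NA` all encode a missing allele; a
#' call with only one missing allele is demoted to fully missing with a
#' warning, since both gene copies of a genotype are scored together.
#'
#' @param path file path.
#' @param panel a [locus_panel()]; the file must contain two allele columns
#'   per panel locus, in panel order.
#' @param sep field separator (default comma).
#' @return A `genotype_matrix`.
#' @export
read_genotype_table <- function(path, panel, sep = ",") {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (ncol(raw) < 4) stop("genotype table needs id, pop, year + allele columns")
  meta <- raw[, 1:3]
  names(meta) <- c("id", "pop", "year")
  meta$id <- as.character(meta$id)
  meta$pop <- as.character(meta$pop)
  meta$year <- as.integer(meta$year)
  if (anyDuplicated(meta$id))
    stop("duplicate individual ids: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  acols <- raw[, -(1:3), drop = FALSE]
  if (ncol(acols) %% 2 != 0) stop("odd number of allele columns")
  if (ncol(acols) != 2 * nrow(panel))
    stop(sprintf("expected %d allele columns for a %d-locus panel, found %d",
                 2 * nrow(panel), nrow(panel), ncol(acols)))
  num <- function(v) {
    v[v %in% c("", "0", "NA")] <- NA
    x <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & (is.na(x) | x != round(x) | x <= 0)
    if (any(bad))
      stop("non-integer allele size: ", paste(unique(v[bad]), collapse = ", "))
    as.integer(x)
  }
  L <- nrow(panel)
  a1 <- matrix(NA_integer_, nrow(meta), L)
  a2 <- matrix(NA_integer_, nrow(meta), L)
  for (l in seq_len(L)) {
    a1[, l] <- num(as.character(acols[[2 * l - 1]]))
    a2[, l] <- num(as.character(acols[[2 * l]]))
  }
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    warning(sum(half), " half-missing calls set to fully missing")
    a1[half] <- NA_integer_
    a2[half] <- NA_integer_
  }
  new_genotype_matrix(meta, panel, a1, a2)
}

#' Write a genotype table
#'
#' Writes the same layout [read_genotype_table()] reads; missing alleles
#' are written as `0`. Read-write-read round-trips are lossless.
#'
#' @param g a `genotype_matrix`.
#' @param path output file path.
#' @export
write_genotype_table <- function(g, path) {
  L <- nrow(g$panel)
  out <- g$ind
  for (l in seq_len(L)) {
    out[[paste0(g$panel$locus[l], ".1")]] <- ifelse(is.na(g$a1[, l]), 0L, g$a1[, l])
    out[[paste0(g$panel$locus[l], ".2")]] <- ifelse(is.na(g$a2[, l]), 0L, g$a2[, l])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Correct dye-shifted allele scores
#'
#' Legacy datasets genotyped with inconsistent fluorescent dyes show a
#' constant per-locus offset in scored allele size ("dye shift"). Given a
#' map of offsets per (locus, dye), every allele at a locus is shifted by
#' the offset registered for that locus's dye. Loci without an entry get
#' offset 0 with a warning. Missing calls are unchanged.
#'
#' @param g a `genotype_matrix`.
#' @param shifts data frame with columns `locus`, `dye`, `offset` (bp).
#' @return The corrected `genotype_matrix`.
#' @export
apply_dye_shift <- function(g, shifts) {
  stopifnot(all(c("locus", "dye", "offset") %in% names(shifts)))
  off <- integer(nrow(g$panel))
  for (l in seq_len(nrow(g$panel))) {
    hit <- shifts$locus == g$panel$locus[l] & shifts$dye == g$panel$dye[l]
    if (any(hit)) {
      off[l] <- as.integer(shifts$offset[which(hit)[1]])
    } else {
      off[l] <- 0L
      warning("no dye-shift entry for locus ", g$panel$locus[l],
              " (dye ", g$panel$dye[l], "); offset 0 assumed")
    }
  }
  g$a1 <- sweep(g$a1, 2, off, `+`)
  g$a2 <- sweep(g$a2, 2, off, `+`)
  g
}

#' Drop individuals genotyped at too few loci
#'
#' Individuals with fewer than `min_scored` scored loci are removed as
#' poor-quality samples (default 9 of 13, the rule used for the study
#' dataset). Idempotent.
#'
#' @param g a `genotype_matrix`.
#' @param min_scored minimum number of scored loci to retain an individual.
#' @return Filtered `genotype_matrix`; removed ids in `attr(, "removed")`.
#' @export
filter_min_loci <- function(g, min_scored = 9) {
  if (min_scored > nrow(g$panel))
    stop("min_scored exceeds the number of loci in the panel")
  scored <- rowSums(!is.na(g$a1))
  keep <- scored >= min_scored
  out <- g[keep]
  attr(out, "removed") <- g$ind$id[!keep]
  out
}

#' Population allele frequencies
#'
#' Frequencies over scored (non-missing) gene copies, per population and
#' locus; they sum to 1 within each population-locus combination.
#'
#' @param g a `genotype_matrix`.
#' @param exclude_imputed if `TRUE` (default), imputed calls are left out
#'   of the counts.
#' @return Long data frame: `pop`, `locus`, `allele`, `count`, `n_copies`,
#'   `freq`.
#' @export
allele_frequencies <- function(g, exclude_imputed = TRUE) {
  rows <- list()
  for (p in unique(g$ind$pop)) {
    sel <- g$ind$pop == p
    for (l in seq_len(nrow(g$panel))) {
      use <- sel & !is.na(g$a1[, l])
      if (exclude_imputed) use <- use & !g$imputed[, l]
      copies <- c(g$a1[use, l], g$a2[use, l])
      if (!length(copies)) next
      tab <- table(copies)
      rows[[length(rows) + 1]] <- data.frame(
        pop = p, locus = g$panel$locus[l],
        allele = as.integer(names(tab)), count = as.integer(tab),
        n_copies = length(copies),
        freq = as.numeric(tab) / length(copies),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Impute missing genotypes from population allele frequencies
#'
#' Missing calls are replaced within their own population only. In
#' `"sampled"` mode each missing allele is drawn i.i.d. from the
#' population's allele frequencies at that locus (GenoDive-style); in
#' `"expected"` mode the modal allele is substituted deterministically
#' (smallest allele on ties). Population-locus combinations with no scored
#' data are left missing and flagged. Imputed calls are tagged in
#' `g$imputed` so downstream statistics can exclude them.
#'
#' @param g a `genotype_matrix`.
#' @param mode `"sampled"` or `"expected"`.
#' @param seed RNG seed for `"sampled"` mode.
#' @return The imputed `genotype_matrix`; unimputable (pop, locus) pairs in
#'   `attr(, "unimputable")`.
#' @export
impute_missing <- function(g, mode = c("sampled", "expected"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  unimp <- list()
  for (p in unique(g$ind$pop)) {
    sel <- which(g$ind$pop == p)
    for (l in seq_len(nrow(g$panel))) {
      miss <- sel[is.na(g$a1[sel, l])]
      if (!length(miss)) next
      scored <- sel[!is.na(g$a1[sel, l])]
      copies <- c(g$a1[scored, l], g$a2[scored, l])
      if (!length(copies)) {
        unimp[[length(unimp) + 1]] <- c(pop = p, locus = g$panel$locus[l])
        next
      }
      tab <- table(copies)
      alleles <- as.integer(names(tab))
      if (mode == "sampled") {
        pr <- as.numeric(tab) / sum(tab)
        draw <- function(m) alleles[sample.int(length(alleles), m,
                                               replace = TRUE, prob = pr)]
        g$a1[miss, l] <- draw(length(miss))
        g$a2[miss, l] <- draw(length(miss))
      } else {
        modal <- alleles[which.max(tab)]
        g$a1[miss, l] <- modal
        g$a2[miss, l] <- modal
      }
      # unordered pair convention: keep the smaller allele first
      swap <- g$a1[miss, l] > g$a2[miss, l]
      if (any(swap)) {
        tmp <- g$a1[miss[swap], l]
        g$a1[miss[swap], l] <- g$a2[miss[swap], l]
        g$a2[miss[swap], l] <- tmp
      }
      g$imputed[miss, l] <- TRUE
    }
  }
  attr(g, "unimputable") <-
    if (length(unimp)) do.call(rbind, unimp) else NULL
  g
}

#' Genotype QC summary
#'
#' Counts of individuals, loci, missing and imputed calls, suitable for a
#' JSON QC report.
#'
#' @param g a `genotype_matrix`.
#' @param removed optional character vector of ids dropped by
#'   [filter_min_loci()].
#' @return A list of QC counts.
#' @export
qc_report <- function(g, removed = character()) {
  list(
    n_individuals = nrow(g$ind),
    n_loci = nrow(g$panel),
    n_populations = length(unique(g$ind$pop)),
    n_missing_calls = sum(is.na(g$a1)),
    n_imputed_calls = sum(g$imputed),
    removed_individuals = as.character(removed)
  )
}
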