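# Aligned mtDNA (COI) sequence analysis: haplotype collapsing, diversity,
# Tajima's D and a minimum-spanning haplotype network.

#' Construct a sequence alignment object
#'
#' Holds equal-length aligned haploid sequences (characters over
#' A, C, G, T, N, -) with per-record population and collection-year
#' metadata.
#'
#' @param seqs character matrix (records x sites) or vector of equal-length
#'   strings.
#' @param id,pop,year per-record metadata; ids must be unique.
#' @return A `coi_alignment`.
#' @export
coi_alignment <- function(seqs, id = NULL, pop = "pop1", year = NA_integer_) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    if (length(unique(nchar(seqs))) != 1)
      stop("sequences must share one alignment length")
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  seqs <- toupper(seqs)
  if (!all(seqs %in% c("A", "C", "G", "T", "N", "-")))
    stop("alignment may contain only A, C, G, T, N, -")
  n <- nrow(seqs)
  if (is.null(id)) id <- paste0("seq", seq_len(n))
  if (anyDuplicated(id)) stop("record ids must be unique")
  meta <- data.frame(id = as.character(id),
                     pop = rep_len(as.character(pop), n),
                     year = rep_len(as.integer(year), n),
                     stringsAsFactors = FALSE)
  rownames(seqs) <- meta$id
  structure(list(meta = meta, seq = seqs), class = "coi_alignment")
}

#' @export
print.coi_alignment <- function(x, ...) {
  cat(sprintf("coi_alignment: %d sequences x %d bp, %d populations\n",
              nrow(x$seq), ncol(x$seq), length(unique(x$meta$pop))))
  invisible(x)
}

.aln_subset <- function(aln, subset = NULL) {
  if (is.null(subset)) return(aln)
  keep <- aln$meta$pop %in% subset
  structure(list(meta = aln$meta[keep, , drop = FALSE],
                 seq = aln$seq[keep, , drop = FALSE]),
            class = "coi_alignment")
}

#' Read aligned sequences from FASTA
#'
#' FASTA headers follow the convention `id|pop|year` (missing fields
#' tolerated); alternatively a metadata data frame keyed by `id` can
#' supply `pop` and `year`.
#'
#' @param path FASTA file.
#' @param meta optional data frame with columns `id`, `pop`, `year`.
#' @return A `coi_alignment`.
#' @export
read_coi_fasta <- function(path, meta = NULL) {
  d <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                     as.matrix = TRUE)
  seqs <- toupper(unname(d))
  labels <- rownames(d)
  parts <- strsplit(labels, "|", fixed = TRUE)
  id <- vapply(parts, `[`, "", 1)
  pop <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "pop1", "")
  year <- vapply(parts, function(p)
    if (length(p) >= 3) suppressWarnings(as.integer(p[3])) else NA_integer_,
    0L)
  if (!is.null(meta)) {
    m <- meta[match(id, meta$id), ]
    pop <- ifelse(is.na(m$pop), pop, as.character(m$pop))
    year <- ifelse(is.na(m$year), year, as.integer(m$year))
  }
  coi_alignment(seqs, id = id, pop = pop, year = year)
}

#' Write an alignment to FASTA
#'
#' Headers carry the `id|pop|year` convention so [read_coi_fasta()]
#' round-trips losslessly.
#'
#' @param aln a `coi_alignment`.
#' @param path output path.
#' @export
write_coi_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln$seq))) {
    writeLines(sprintf(">%s|%s|%s", aln$meta$id[i], aln$meta$pop[i],
                       aln$meta$year[i]), con)
    writeLines(paste(aln$seq[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Check reading frames for internal stop codons
#'
#' Scans each sequence in the given frame for internal stop codons under
#' the invertebrate mitochondrial code (TAA and TAG; AGA/AGG code serine
#' in this code and are not stops). A sequence that passes in one frame
#' may fail in another; the trimmed fragment's frame is configuration.
#'
#' @param aln a `coi_alignment`.
#' @param frame 0, 1 or 2 (offset of the first full codon).
#' @return Data frame with `id`, `n_stops`, `stop_positions`, `pass`.
#' @export
check_orf <- function(aln, frame = 0) {
  stopifnot(frame %in% 0:2)
  stops <- c("TAA", "TAG")
  out <- lapply(seq_len(nrow(aln$seq)), function(i) {
    s <- aln$seq[i, ]
    starts <- seq(frame + 1, ncol(aln$seq) - 2, by = 3)
    starts <- starts[starts + 2 <= ncol(aln$seq)]
    # the final (possibly terminal) codon is not an "internal" stop
    starts <- head(starts, -1)
    codons <- vapply(starts, function(j) paste(s[j:(j + 2)], collapse = ""), "")
    hit <- which(codons %in% stops)
    data.frame(id = aln$meta$id[i], n_stops = length(hit),
               stop_positions = paste(starts[hit], collapse = ";"),
               pass = length(hit) == 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Collapse aligned sequences into haplotypes
#'
#' `strict` mode groups by exact string identity (N differs from every
#' base). `ignore-N` mode treats records as the same haplotype when they
#' agree at every site where both have a called base; records are scanned
#' in input order and each joins the first compatible haplotype, whose
#' anchor (lowest record index) supplies the representative sequence --
#' a deterministic tie-break.
#'
#' @param aln a `coi_alignment`.
#' @param ambiguous `"strict"` or `"ignore-N"`.
#' @return A `haplotype_set`: `haplotypes` (character matrix of
#'   representative sequences, rownames H1..), `membership` (record id ->
#'   haplotype label), `counts` (haplotype x population table).
#' @export
collapse_haplotypes <- function(aln, ambiguous = c("strict", "ignore-N")) {
  ambiguous <- match.arg(ambiguous)
  n <- nrow(aln$seq)
  member <- integer(n)
  anchors <- integer(0)
  if (ambiguous == "strict") {
    key <- apply(aln$seq, 1, paste, collapse = "")
    fac <- factor(key, levels = unique(key))
    member <- as.integer(fac)
    anchors <- match(levels(fac), key)
  } else {
    ok <- aln$seq != "N" & aln$seq != "-"
    for (i in seq_len(n)) {
      placed <- FALSE
      for (h in seq_along(anchors)) {
        a <- anchors[h]
        cmp <- ok[i, ] & ok[a, ]
        if (all(aln$seq[i, cmp] == aln$seq[a, cmp])) {
          member[i] <- h
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        anchors <- c(anchors, i)
        member[i] <- length(anchors)
      }
    }
  }
  haps <- aln$seq[anchors, , drop = FALSE]
  labels <- paste0("H", seq_along(anchors))
  rownames(haps) <- labels
  counts <- table(factor(labels[member], levels = labels), aln$meta$pop)
  structure(list(haplotypes = haps,
                 membership = setNames(labels[member], aln$meta$id),
                 counts = unclass(counts), n = n),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes over %d records\n",
              nrow(x$haplotypes), x$n))
  invisible(x)
}

#' Haplotype diversity
#'
#' `Hd = (n/(n-1)) (1 - sum p_i^2)` over haplotype frequencies; undefined
#' (NA) for samples of fewer than 2 records.
#'
#' @param h a `haplotype_set` from [collapse_haplotypes()].
#' @param subset optional population labels to restrict to.
#' @return Numeric Hd, or `NA` when n < 2.
#' @export
haplotype_diversity <- function(h, subset = NULL) {
  cnt <- if (is.null(subset)) rowSums(h$counts)
         else rowSums(h$counts[, colnames(h$counts) %in% subset, drop = FALSE])
  n <- sum(cnt)
  if (n < 2) return(NA_real_)
  p <- cnt / n
  n / (n - 1) * (1 - sum(p^2))
}

# pairwise proportion of differing sites, non-N positions only
.pair_pdiff <- function(s1, s2) {
  cmp <- s1 != "N" & s1 != "-" & s2 != "N" & s2 != "-"
  if (!any(cmp)) return(NA_real_)
  mean(s1[cmp] != s2[cmp])
}

#' Nucleotide diversity
#'
#' Mean pairwise proportion of differing sites, with sites missing (N or
#' gap) in either sequence excluded from that pair's comparison
#' (pairwise deletion).
#'
#' @param aln a `coi_alignment`.
#' @param subset optional population labels.
#' @return Numeric pi per site, or `NA` when n < 2.
#' @export
nucleotide_diversity <- function(aln, subset = NULL) {
  a <- .aln_subset(aln, subset)
  n <- nrow(a$seq)
  if (n < 2) return(NA_real_)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- .pair_pdiff(a$seq[i, ], a$seq[j, ])
      if (!is.na(d)) { tot <- tot + d; np <- np + 1 }
    }
  }
  if (np == 0) return(NA_real_)
  tot / np
}

#' Tajima's D
#'
#' The standard neutrality statistic contrasting mean pairwise
#' differences with the segregating-site estimate of theta, using the
#' a1..e2 constants computed from the sample size. Sites containing N or
#' a gap in any sequence are excluded (complete deletion), so S and the
#' pairwise differences refer to the same sites.
#'
#' @param aln a `coi_alignment`.
#' @param subset optional population labels.
#' @return List with `D` (NA when S = 0 or n < 4), `S`, `pi` (mean
#'   pairwise differences, in sites), `n`.
#' @export
tajimas_d <- function(aln, subset = NULL) {
  a <- .aln_subset(aln, subset)
  n <- nrow(a$seq)
  keep <- apply(a$seq != "N" & a$seq != "-", 2, all)
  s <- a$seq[, keep, drop = FALSE]
  S <- sum(apply(s, 2, function(col) length(unique(col)) > 1))
  k <- 0
  if (n >= 2) {
    for (i in seq_len(n - 1))
      for (j in (i + 1):n) k <- k + sum(s[i, ] != s[j, ])
    k <- k / (n * (n - 1) / 2)
  }
  if (n < 4 || S == 0)
    return(list(D = NA_real_, S = S, pi = k, n = n))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(D = D, S = S, pi = k, n = n)
}

# Hamming distance between two haplotype sequences (pairwise deletion)
.hap_dist <- function(s1, s2) {
  cmp <- s1 != "N" & s1 != "-" & s2 != "N" & s2 != "-"
  sum(s1[cmp] != s2[cmp])
}

#' Minimum-spanning haplotype network
#'
#' Builds a minimum-spanning network over pairwise Hamming distances
#' between haplotypes (Prim's algorithm), approximating a
#' statistical-parsimony network for visualization. Edges longer than
#' `max_distance` substitutions are not used, which can split the network
#' into components; edges of weight w > 1 imply w - 1 unsampled
#' intermediate haplotypes, reported per edge.
#'
#' @param h a `haplotype_set` with at least 2 haplotypes.
#' @param max_distance maximum connection distance (default unlimited).
#' @return List with `nodes` (label, count), `edges` (from, to, weight,
#'   n_intermediates), `components` (node -> component id).
#' @export
haplotype_network <- function(h, max_distance = Inf) {
  nh <- nrow(h$haplotypes)
  if (nh < 2) stop("need at least 2 haplotypes")
  D <- matrix(0, nh, nh)
  for (i in seq_len(nh - 1))
    for (j in (i + 1):nh)
      D[i, j] <- D[j, i] <- .hap_dist(h$haplotypes[i, ], h$haplotypes[j, ])
  W <- D
  W[W > max_distance] <- Inf
  labels <- rownames(h$haplotypes)

  comp <- integer(nh)
  edges <- list()
  cid <- 0L
  remaining <- seq_len(nh)
  while (length(remaining)) {
    cid <- cid + 1L
    # Prim's from the first remaining node, restricted to reachable nodes
    intree <- remaining[1]
    comp[intree] <- cid
    repeat {
      out <- setdiff(remaining, intree)
      if (!length(out)) break
      sub <- W[intree, out, drop = FALSE]
      if (!any(is.finite(sub))) break
      idx <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      from <- intree[idx[1]]; to <- out[idx[2]]
      w <- W[from, to]
      edges[[length(edges) + 1]] <- data.frame(
        from = labels[from], to = labels[to], weight = w,
        n_intermediates = max(0, w - 1))
      intree <- c(intree, to)
      comp[to] <- cid
    }
    remaining <- setdiff(remaining, intree)
  }
  list(nodes = data.frame(label = labels, count = rowSums(h$counts),
                          stringsAsFactors = FALSE),
       edges = if (length(edges)) do.call(rbind, edges) else
         data.frame(from = character(), to = character(), weight = numeric(),
                    n_intermediates = numeric()),
       components = setNames(comp, labels))
}

#' Write a haplotype network edge list
#'
#' Tab-separated `from  to  weight  n_intermediates`.
#'
#' @param net result of [haplotype_network()].
#' @param path output path.
#' @export
write_network_tsv <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Per-population mtDNA diversity table
#'
#' n, haplotype count, Hd and pi per population plus a total row,
#' mirroring the standard mtDNA summary-table layout.
#'
#' @param aln a `coi_alignment`.
#' @param ambiguous haplotype-collapsing mode (see
#'   [collapse_haplotypes()]).
#' @return Data frame with columns `pop`, `n`, `n_hap`, `Hd`, `pi`.
#' @export
mtdna_diversity_table <- function(aln, ambiguous = "strict") {
  h <- collapse_haplotypes(aln, ambiguous)
  pops <- unique(aln$meta$pop)
  rows <- lapply(pops, function(p) {
    cnt <- h$counts[, p]
    data.frame(pop = p, n = sum(cnt), n_hap = sum(cnt > 0),
               Hd = haplotype_diversity(h, p),
               pi = nucleotide_diversity(aln, p), stringsAsFactors = FALSE)
  })
  total <- data.frame(pop = "All", n = h$n,
                      n_hap = nrow(h$haplotypes),
                      Hd = haplotype_diversity(h),
                      pi = nucleotide_diversity(aln),
                      stringsAsFactors = FALSE)
  rbind(do.call(rbind, rows), total)
}
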