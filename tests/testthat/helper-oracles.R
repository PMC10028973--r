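# Shared fixtures and independent brute-force oracles used across tests.

# one-contig track from a plain numeric vector (NA = missing)
quick_track <- function(scores, contig = "chr1") {
  score_track(setNames(list(scores), contig))
}

# brute-force constrained-base membership vector over [0, n)
oracle_membership <- function(cs, contig, n) {
  pos <- cs_positions(cs, contig)
  out <- logical(n)
  out[pos + 1] <- TRUE
  out
}

# brute-force count + nearest for a query interval
oracle_region_query <- function(cs, contig, start, end, n) {
  memb <- oracle_membership(cs, contig, n)
  count <- sum(memb[(start + 1):end])
  pos <- which(memb) - 1
  nearest <- if (length(pos) == 0) Inf else min(abs(start - pos))
  list(count = count, nearest = nearest)
}

# exhaustive Benjamini-Hochberg: largest k with p_(k) <= k q / n
oracle_bh_reject <- function(p, q) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  ks <- which(ps <= seq_len(n) * q / n)
  if (length(ks) == 0) return(rep(FALSE, n))
  k <- max(ks)
  rej <- rep(FALSE, n)
  rej[o[seq_len(k)]] <- TRUE
  rej
}

# nearest-neighbor median spacing by full pairwise enumeration
oracle_median_nn <- function(pos) {
  d <- vapply(seq_along(pos), function(i)
    min(abs(pos[i] - pos[-i])), numeric(1))
  median(d)
}

# small simulated genome, memoized per (seed, size) within a test run
.sim_cache <- new.env()
cached_genome <- function(seed = 42, size = 3e5, ...) {
  key <- paste0(seed, "_", size, "_", paste(c(...), collapse = "_"))
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_genome(
      sim_config(contig_lengths = c(chr1 = size), seed = seed, ...))
  }
  .sim_cache[[key]]
}

# hand-built annotation: one plus-strand and one minus-strand gene on a
# designed reference, small enough to reason about base by base
toy_gene_setup <- function(seq_plus_cds = "ATGCTTTGGTAA") {
  # gene1 (+): span [10, 40), exon [10, 40), CDS [14, 26), UTRs around it
  # gene2 (-): span [60, 90), exon [60, 90), CDS [66, 84)
  L <- 120
  base <- rep("A", L)
  base[15:26] <- strsplit(seq_plus_cds, "")[[1]] # CDS of gene1 (0-based 14..25)
  # gene2 CDS on minus strand: put reverse complement of ATGGAAGGGTTTCCCTAA
  cds2 <- "ATGGAAGGGTTTCCCTAA"
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- rev(unname(comp[strsplit(cds2, "")[[1]]]))
  base[67:84] <- rc # 0-based 66..83
  reference <- c(chr1 = paste(base, collapse = ""))
  genes <- data.frame(gene_id = c("g1", "g2"), contig = "chr1",
                      strand = c("+", "-"), start = c(10, 60),
                      end = c(40, 90))
  parts <- rbind(
    data.frame(gene_id = "g1", class = "exon", start = 10, end = 40),
    data.frame(gene_id = "g1", class = "UTR5", start = 10, end = 14),
    data.frame(gene_id = "g1", class = "CDS", start = 14, end = 26),
    data.frame(gene_id = "g1", class = "UTR3", start = 26, end = 40),
    data.frame(gene_id = "g2", class = "exon", start = 60, end = 90),
    data.frame(gene_id = "g2", class = "UTR3", start = 60, end = 66),
    data.frame(gene_id = "g2", class = "CDS", start = 66, end = 84),
    data.frame(gene_id = "g2", class = "UTR5", start = 84, end = 90))
  ann <- genome_annotation(genes, parts, c(chr1 = L),
                           promoter_up = 20, promoter_down = 5)
  list(ann = ann, reference = reference, L = L)
}

cs_count_multi_public <- function(cs, df) {
  vapply(seq_len(nrow(df)), function(i)
    cs_count(cs, df$contig[i], df$start[i], df$end[i]), numeric(1))
}

toy_variant <- function(contig = "chr1", pos, ref, alt, ac = 1, an = 1000) {
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
             AC = ac, AN = an, AF = ac / an)
}
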