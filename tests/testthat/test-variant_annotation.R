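# Variant annotation: coding context, region priority, AF spectrum
# summaries, depletion and enrichment models.

test_that("codon context follows the standard genetic code on both strands", {
  setup <- toy_gene_setup() # g1 (+) CDS = ATG CTT TGG TAA
  cs <- constrained_set()
  tr <- quick_track(rep(0.5, setup$L))
  # third base of TGG (Trp), alt A -> TGA stop: non-synonymous, can_stop
  v <- toy_variant(pos = 22, ref = "G", alt = "A")
  a <- annotate_variants(v, tr, cs, setup$ann, setup$reference)
  expect_equal(a$region_class, "CDS")
  expect_equal(a$codon_pos, 3L)
  expect_equal(a$consequence, "nonsynonymous")
  expect_true(a$can_stop)
  # third base of CTT (Leu): all substitutions synonymous, no stop reachable
  v <- toy_variant(pos = 19, ref = "T", alt = "A")
  a <- annotate_variants(v, tr, cs, setup$ann, setup$reference)
  expect_equal(a$codon_pos, 3L)
  expect_equal(a$consequence, "synonymous")
  expect_false(a$can_stop)
  # minus-strand gene g2, CDS starts at genomic end: position 83 is the
  # first base of ATG in transcript orientation
  rc_ref <- substr(setup$reference[["chr1"]], 84, 84)
  v <- toy_variant(pos = 83, ref = rc_ref, alt = "C")
  a <- annotate_variants(v, tr, cs, setup$ann, setup$reference)
  expect_equal(a$codon_pos, 1L)
})

test_that("genetic-code calls agree with an independent translation oracle", {
  # one plus-strand gene whose CDS enumerates all 64 codons
  codons <- names(Biostrings::GENETIC_CODE)
  cds_seq <- paste(codons, collapse = "")
  L <- 20 + nchar(cds_seq) + 20
  base <- rep("A", L)
  base[21:(20 + nchar(cds_seq))] <- strsplit(cds_seq, "")[[1]]
  reference <- c(c = paste(base, collapse = ""))
  genes <- data.frame(gene_id = "g", contig = "c", strand = "+",
                      start = 20, end = 20 + nchar(cds_seq))
  parts <- rbind(data.frame(gene_id = "g", class = "exon", start = 20,
                            end = 20 + nchar(cds_seq)),
                 data.frame(gene_id = "g", class = "CDS", start = 20,
                            end = 20 + nchar(cds_seq)))
  ann <- genome_annotation(genes, parts, c(c = L))
  tr <- quick_track(rep(0, L), contig = "c")
  cs <- constrained_set()

  set.seed(2)
  idx <- sample(0:(nchar(cds_seq) - 1), 120)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- 20 + i
    ref <- substr(cds_seq, i + 1, i + 1)
    alt <- sample(setdiff(bases, ref), 1)
    a <- annotate_variants(toy_variant(contig = "c", pos = pos, ref = ref,
                                       alt = alt), tr, cs, ann, reference)
    cod_i <- i %/% 3
    off <- i %% 3
    codon <- codons[cod_i + 1]
    # oracle via seqinr translation
    tr_aa <- function(cd) seqinr::translate(strsplit(tolower(cd), "")[[1]])
    alt_codon <- codon
    substr(alt_codon, off + 1, off + 1) <- alt
    expect_equal(a$codon_pos, off + 1)
    expect_equal(a$consequence,
                 if (tr_aa(codon) == tr_aa(alt_codon)) "synonymous"
                 else "nonsynonymous")
    stops <- vapply(setdiff(bases, substr(codon, off + 1, off + 1)),
                    function(b) {
                      cd <- codon
                      substr(cd, off + 1, off + 1) <- b
                      tr_aa(cd) == "*"
                    }, logical(1))
    expect_equal(a$can_stop, any(stops))
  }
})

test_that("region class resolution is total and priority-ordered", {
  setup <- toy_gene_setup()
  tr <- quick_track(rep(0.5, setup$L))
  cs <- constrained_set()
  pos <- 0:(setup$L - 1)
  v <- toy_variant(pos = pos, ref = rep("A", length(pos)),
                   alt = rep("C", length(pos)))
  suppressWarnings(a <- annotate_variants(v, tr, cs, setup$ann,
                                          setup$reference))
  expect_true(all(a$region_class %in% c("CDS", "UTR5", "UTR3", "promoter",
                                        "enhancer", "intron", "intergenic")))
  # CDS beats everything: gene1 promoter [TSS-20, TSS+5) does not reach CDS,
  # but UTR5 bases [10,14) also sit in the promoter's downstream window
  expect_equal(unique(a$region_class[a$pos %in% 14:25]), "CDS")
  expect_equal(unique(a$region_class[a$pos %in% 10:13]), "UTR5")
  expect_equal(unique(a$region_class[a$pos %in% 0:9]), "promoter")
})

test_that("constrained variants carry flag and zero distance", {
  setup <- toy_gene_setup()
  tr <- quick_track(rep(3, setup$L))
  cs <- constrained_set(data.frame(contig = "chr1", start = 50, end = 55))
  v <- toy_variant(pos = c(52, 40), ref = c("A", "A"), alt = c("C", "C"))
  a <- annotate_variants(v, tr, cs, setup$ann, setup$reference)
  expect_true(a$constrained[1])
  expect_equal(a$dist_constrained[1], 0)
  expect_false(a$constrained[2])
  expect_equal(a$dist_constrained[2], 10)
  expect_error(annotate_variants(toy_variant(contig = "chrZ", pos = 1,
                                             ref = "A", alt = "C"),
                                 tr, cs, setup$ann, setup$reference),
               "unknown contig")
})

test_that("CpG and C/G flags read the plus-strand reference context", {
  reference <- c(c = "TACGTT")
  genes <- data.frame(gene_id = "g", contig = "c", strand = "+",
                      start = 0, end = 6)
  parts <- data.frame(gene_id = "g", class = "exon", start = 0, end = 6)
  ann <- genome_annotation(genes, parts, c(c = 6), promoter_up = 0,
                           promoter_down = 0)
  tr <- quick_track(rep(0, 6), contig = "c")
  v <- toy_variant(contig = "c", pos = 0:5,
                   ref = strsplit("TACGTT", "")[[1]], alt = rep("A", 6))
  v$alt[1] <- "C"
  suppressWarnings(a <- annotate_variants(v, tr, constrained_set(), ann,
                                          reference))
  expect_equal(a$ref_cg, c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(a$cpg, c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
})

test_that("AF-bin summaries match hand-computed fractions and correlations", {
  df <- data.frame(constrained = c(TRUE, TRUE, TRUE),
                   af_bin = af_bin(c(1, 8, 80), 10000),
                   AC = c(1, 10, 100), score = c(3, 2, 1),
                   region_class = "intergenic")
  suppressWarnings(out <- af_constraint_summary(df))
  expect_equal(unname(out$rho["overall"]), -1)
  got <- out$bins$frac_constrained[out$bins$n > 0]
  expect_true(all(got == 1))
})

test_that("af_bin partitions the spectrum with common taking precedence", {
  ac <- c(1, 2, 10, 11, 100, 49, 50, 5000)
  b <- af_bin(ac, an = 10000)
  expect_equal(as.character(b),
               c("AC=1", "AC2-10", "AC2-10", "AC11-100", "common",
                 "AC11-100", "common", "common"))
  expect_false(anyNA(b))
})

test_that("depletion test reproduces the printed fold and closed-form p", {
  out <- depletion_test(185, 10000, 0.0353)
  expect_equal(round(out$fold, 3), 0.524)
  expect_lt(out$p, 1e-10)
  expect_equal(depletion_test(353, 10000, 0.0353)$fold, 1.0)
  # zero successes out of 100 at p = 0.5: both tails collapse to 2 * 0.5^100
  expect_equal(depletion_test(0, 100, 0.5)$p, 2 * 0.5^100)
  expect_error(depletion_test(101, 100, 0.5), "exceeds")
  # fold is scale-invariant in n at fixed fractions
  expect_equal(depletion_test(37, 1000, 0.05)$fold,
               depletion_test(370, 10000, 0.05)$fold)
})

test_that("single-feature enrichment equals the 2x2 contingency odds ratio", {
  # constrained x CDS table [[90, 10], [50, 50]]
  df <- data.frame(
    constrained = rep(c(TRUE, TRUE, FALSE, FALSE), c(90, 10, 50, 50)),
    CDS = rep(c(TRUE, FALSE, TRUE, FALSE), c(90, 10, 50, 50)))
  out <- feature_enrichment_model(df, features = "CDS")
  expect_equal(out$or, 9.0, tolerance = 1e-6)
  # independence -> OR 1
  df2 <- data.frame(
    constrained = rep(c(TRUE, FALSE), each = 100),
    CDS = rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 60, 40, 60)))
  out2 <- feature_enrichment_model(df2, features = "CDS")
  expect_equal(out2$or, 1.0, tolerance = 1e-6)
  # complete separation is flagged, not fatal
  df3 <- data.frame(constrained = rep(c(TRUE, FALSE), each = 50),
                    CDS = rep(c(TRUE, FALSE), each = 50))
  out3 <- feature_enrichment_model(df3, features = "CDS")
  expect_true(out3$separated)
  expect_identical(out3$or, Inf)
})

test_that("a planted CDS odds ratio of 5 is recovered with nominal coverage", {
  set.seed(33)
  cover <- 0
  for (rep in 1:100) {
    n <- 2000
    cds <- runif(n) < 0.3
    p <- stats::plogis(-2 + log(5) * cds)
    df <- data.frame(constrained = runif(n) < p, CDS = cds)
    out <- feature_enrichment_model(df, features = "CDS")
    cover <- cover + (out$ci_lo <= 5 && out$ci_hi >= 5)
  }
  expect_gte(cover, 90)
})

test_that("VCF round trip preserves records and splits multiallelics", {
  v <- data.frame(contig = "chr1", pos = c(5, 10), ref = c("A", "C"),
                  alt = c("T", "G"), AC = c(1, 7), AN = 100)
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(v, tmp)
  v2 <- read_variants_vcf(tmp)
  expect_equal(v2[, c("contig", "pos", "ref", "alt", "AC", "AN")],
               v[, c("contig", "pos", "ref", "alt", "AC", "AN")],
               ignore_attr = TRUE)
  # hand-written multiallelic record
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"x\">",
               "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"x\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tA\tC,G\t.\t.\tAC=3,9;AN=50"), tmp)
  v3 <- read_variants_vcf(tmp)
  expect_equal(nrow(v3), 2)
  expect_equal(v3$AC, c(3, 9))
  expect_equal(v3$pos, c(99, 99))
})
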