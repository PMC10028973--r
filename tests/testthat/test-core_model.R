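# Shared data model: interval normalization, track expansion, queries and
# round-trip I/O.

test_that("constrained-set normalization is canonical and idempotent", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(1:30, 1)
    s <- sample(0:500, n, replace = TRUE)
    m <- data.frame(contig = "c", start = s, end = s + sample(1:20, n,
                                                              replace = TRUE))
    cs <- constrained_set(m)
    # total equals brute-force union size
    memb <- rep(FALSE, 600)
    for (i in seq_len(n)) memb[(m$start[i] + 1):m$end[i]] <- TRUE
    expect_equal(cs_total(cs), sum(memb))
    # idempotent: rebuilding from its own intervals changes nothing
    cs2 <- constrained_set(cs$intervals)
    expect_identical(cs$intervals, cs2$intervals)
    # canonical: disjoint, sorted, non-adjacent
    iv <- cs$intervals[["c"]]
    if (nrow(iv) > 1) expect_true(all(iv[-1, 1] > iv[-nrow(iv), 2]))
  }
})

test_that("adjacent intervals merge during normalization", {
  cs <- constrained_set(data.frame(contig = "c", start = c(0, 10),
                                   end = c(10, 20)))
  expect_equal(nrow(cs$intervals[["c"]]), 1)
  expect_equal(cs_total(cs), 20)
})

test_that("region_query matches hand-derived counts and distances", {
  cs <- constrained_set(data.frame(contig = "chr1", start = 10, end = 20))
  expect_equal(region_query(cs, "chr1", 0, 50)$count, 10)
  expect_equal(region_query(cs, "chr1", 10)$nearest, 0)
  expect_equal(region_query(cs, "chr1", 25)$nearest, 6)
  expect_error(region_query(cs, "chrX", 0), "unknown contig")
})

test_that("region_query equals the per-base brute-force oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n_iv <- sample(0:15, 1)
    cs <- if (n_iv == 0) {
      constrained_set(list(c = NULL))
    } else {
      s <- sample(0:900, n_iv, replace = TRUE)
      constrained_set(data.frame(contig = "c", start = s,
                                 end = s + sample(1:30, n_iv,
                                                  replace = TRUE)))
    }
    for (qq in 1:25) {
      a <- sample(0:950, 1)
      b <- a + sample(1:50, 1)
      got <- region_query(cs, "c", a, b)
      want <- oracle_region_query(cs, "c", a, b, 1000)
      expect_equal(got$count, want$count)
      expect_equal(got$nearest, want$nearest)
    }
  }
})

test_that("bedGraph expansion, missing bases and round trip", {
  tmp <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(character(0), tmp)
  tr <- read_score_track(tmp, c(chr1 = 100))
  expect_equal(track_length(tr), 100)
  expect_equal(universe_size(tr), 0)

  writeLines("chr1\t10\t13\t2.5", tmp)
  tr <- read_score_track(tmp, c(chr1 = 100))
  expect_equal(track_score(tr, "chr1", 10:12), rep(2.5, 3))
  expect_true(all(is.na(track_score(tr, "chr1", c(0:9, 13:99)))))

  # full-precision round trip of an irregular track
  set.seed(3)
  s <- rep(NA_real_, 200)
  idx <- sample(200, 120)
  s[idx] <- rnorm(120)
  tr0 <- quick_track(s)
  out <- withr::local_tempfile(fileext = ".bedGraph")
  write_score_track(tr0, out)
  tr1 <- read_score_track(out, c(chr1 = 200))
  expect_identical(tr1$scores, tr0$scores)
})

test_that("bedGraph conflicts and bounds are rejected", {
  tmp <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t5\t15\t1.0", "chr1\t10\t12\t2.0"), tmp)
  expect_error(read_score_track(tmp, c(chr1 = 100)), "conflicting")
  writeLines(c("chr1\t5\t15\t1.0", "chr1\t10\t12\t1.0"), tmp)
  expect_silent(tr <- read_score_track(tmp, c(chr1 = 100)))
  writeLines("chr1\t95\t105\t1.0", tmp)
  expect_error(read_score_track(tmp, c(chr1 = 100)), "out of bounds")
})

test_that("GFF3 coordinates convert to half-open and round trip", {
  setup <- toy_gene_setup()
  tmp <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(setup$ann, tmp)
  ann2 <- read_annotation(tmp, c(chr1 = setup$L),
                          promoter_up = 20, promoter_down = 5)
  expect_equal(ann2$genes[, c("gene_id", "strand", "start", "end")],
               setup$ann$genes[, c("gene_id", "strand", "start", "end")],
               ignore_attr = TRUE)
  for (cl in c("CDS", "UTR5", "UTR3", "intron", "promoter")) {
    expect_identical(ann_part_set(ann2, cl)$intervals,
                     ann_part_set(setup$ann, cl)$intervals)
  }
  # explicit coordinate convention: a GFF3 exon 11..20 is internal [10, 20)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c\tx\tgene\t11\t20\t.\t+\t.\tID=g",
               "c\tx\tmRNA\t11\t20\t.\t+\t.\tID=t;Parent=g",
               "c\tx\texon\t11\t20\t.\t+\t.\tParent=t"), gff)
  a <- read_annotation(gff, c(c = 100))
  ex <- a$parts[a$parts$class == "exon", ]
  expect_equal(c(ex$start, ex$end), c(10, 20))
})

test_that("introns are the gene span minus exons", {
  genes <- data.frame(gene_id = "g", contig = "c", strand = "+",
                      start = 0, end = 30)
  parts <- data.frame(gene_id = "g", class = "exon",
                      start = c(0, 20), end = c(10, 30))
  ann <- genome_annotation(genes, parts, c(c = 100))
  intr <- ann$parts[ann$parts$class == "intron", ]
  expect_equal(c(intr$start, intr$end), c(10, 20))
})

test_that("promoter window follows the strand and clips at the contig", {
  genes <- data.frame(gene_id = "g", contig = "c", strand = "-",
                      start = 100, end = 200)
  parts <- data.frame(gene_id = "g", class = "exon", start = 100, end = 200)
  ann <- genome_annotation(genes, parts, c(c = 5000),
                           promoter_up = 2000, promoter_down = 200)
  pr <- ann$parts[ann$parts$class == "promoter", ]
  # TSS is base 199; 200 bases downstream reach back to 0, 2000 upstream to
  # 2200
  expect_equal(c(pr$start, pr$end), c(0, 2200))
  # plus strand: window is [TSS - up, TSS + down)
  genes$strand <- "+"
  ann <- genome_annotation(genes, parts, c(c = 5000),
                           promoter_up = 2000, promoter_down = 200)
  pr <- ann$parts[ann$parts$class == "promoter", ]
  expect_equal(c(pr$start, pr$end), c(0, 300))
})

test_that("genes without exons are skipped with a warning", {
  genes <- data.frame(gene_id = c("a", "b"), contig = "c", strand = "+",
                      start = c(0, 50), end = c(30, 80))
  parts <- data.frame(gene_id = "a", class = "exon", start = 0, end = 30)
  expect_warning(ann <- genome_annotation(genes, parts, c(c = 100)),
                 "zero exons")
  expect_equal(ann$genes$gene_id, "a")
})

test_that("BED3 write/read round trip preserves the set", {
  cs <- constrained_set(data.frame(contig = c("chr1", "chr1", "chr2"),
                                   start = c(5, 50, 0), end = c(10, 70, 3)))
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_bed3(cs, tmp)
  cs2 <- read_bed3(tmp)
  expect_identical(cs2$intervals, cs$intervals)
})

test_that("set operations agree with base-level logic", {
  a <- constrained_set(data.frame(contig = "c", start = 0, end = 10))
  b <- constrained_set(data.frame(contig = "c", start = 5, end = 15))
  expect_equal(cs_total(cs_intersect(a, b)), 5)
  expect_equal(cs_total(cs_union(a, b)), 15)
  expect_equal(cs_total(cs_setdiff(a, b)), 5)
})
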