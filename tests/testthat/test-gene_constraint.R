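# Gene-level metrics: fractions, excess z, residual model, entropy,
# deciles, outlier clustering, census, score comparisons.

test_that("part constraint fractions count bases correctly", {
  genes <- data.frame(gene_id = c("a", "b"), contig = "c", strand = "+",
                      start = c(0, 500), end = c(200, 700))
  parts <- rbind(
    data.frame(gene_id = "a", class = "exon", start = 0, end = 200),
    data.frame(gene_id = "a", class = "CDS", start = 50, end = 150),
    data.frame(gene_id = "b", class = "exon", start = 500, end = 700),
    data.frame(gene_id = "b", class = "CDS", start = 500, end = 650))
  suppressWarnings(ann <- genome_annotation(genes, parts, c(c = 2000),
                                            promoter_up = 10,
                                            promoter_down = 0))
  cs <- constrained_set(data.frame(contig = "c", start = 50, end = 85))
  out <- part_constraint_fractions(ann, cs)
  expect_equal(out$frac_cds_cons[out$gene_id == "a"], 0.35)
  expect_equal(out$frac_cds_cons[out$gene_id == "b"], 0)
  expect_true(all(is.na(out$frac_enh_cons))) # no linked enhancers
  cs_all <- constrained_set(data.frame(contig = "c", start = 0, end = 2000))
  out2 <- part_constraint_fractions(ann, cs_all)
  expect_equal(out2$frac_cds_cons, c(1, 1))
})

test_that("gene CDS fractions on simulated genomes equal the serialized truth", {
  g <- cached_genome(seed = 13, size = 2e5)
  out <- part_constraint_fractions(g$annotation, g$truth$constrained)
  want <- g$truth$gene_frac
  expect_identical(out$frac_cds_cons[match(want$gene_id, out$gene_id)],
                   want$frac_cds_cons)
})

test_that("excess-constraint z matches the binomial arithmetic", {
  expect_equal(excess_constraint_z(50, 100, 0.3), 20 / sqrt(21))
  expect_equal(round(excess_constraint_z(50, 100, 0.3), 3), 4.364)
  expect_equal(excess_constraint_z(30, 100, 0.3), 0)
  expect_equal(round(excess_constraint_z(0, 100, 0.3), 3), -6.547)
  expect_error(excess_constraint_z(101, 100, 0.3), "exceeds")
  # when r comes from the same gene universe the raw excesses sum to zero
  set.seed(5)
  L <- sample(100:1000, 20)
  k <- rbinom(20, L, 0.2)
  r <- sum(k) / sum(L)
  expect_equal(sum(k - L * r), 0, tolerance = 1e-9)
})

test_that("residual constraint behaves at the null and at a perfect fit", {
  set.seed(14)
  n <- 1000
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  f <- rnorm(n) # orthogonal to the covariates
  res <- residual_constraint(f, X)
  expect_gt(cor(res, scale(f)[, 1]), 0.99)
  # exactly linear fractions leave zero residuals
  f2 <- 0.2 + 0.1 * X$x1
  expect_equal(suppressWarnings(residual_constraint(f2, X)), rep(0, n))
  # collinear columns are dropped with a warning
  X3 <- data.frame(x1 = X$x1, x2 = X$x1 * 2)
  expect_warning(res3 <- residual_constraint(f, X3), "collinear")
  expect_equal(length(res3), n)
})

test_that("planted residual outliers surface in the top decile", {
  set.seed(15)
  hits <- 0
  for (rep in 1:10) {
    n <- 500
    X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    f <- 0.3 + 0.05 * X$x1 - 0.03 * X$x2 + rnorm(n, 0, 0.02)
    planted <- sample(n, 10)
    f[planted] <- f[planted] + 0.15
    res <- residual_constraint(f, X)
    dec <- assign_deciles(res)
    hits <- hits + all(dec[planted] == 9)
  }
  expect_gte(hits, 9)
})

test_that("entropy score matches closed-form hand cases", {
  mono <- matrix(rep("A", 30), nrow = 3)
  expect_equal(entropy_constraint(mono), 1.0)
  half <- matrix(c(rep("A", 5), rep("C", 5)), nrow = 1)
  expect_equal(round(entropy_constraint(half), 4), 0.7686)
  # uniform usage of all 20 residues drives the score toward 0
  unif <- matrix(rep(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 50),
                 nrow = 1)
  expect_lt(entropy_constraint(unif), 0.01)
  # permutation invariance in species order
  set.seed(16)
  m <- simulate_alignment_columns(runif(20), 12, seed = 4)
  expect_equal(entropy_constraint(m), entropy_constraint(m[, sample(12)]))
  # replacing a monomorphic column with a uniform one lowers the score
  m2 <- rbind(mono, strsplit("ACDEFGHIKL", "")[[1]][1:10])
  expect_lt(entropy_constraint(rbind(mono[1:2, , drop = FALSE],
                                     matrix(strsplit("ACDEFGHIKL", "")[[1]],
                                            nrow = 1))),
            entropy_constraint(mono))
  # gap handling: columns with < 2 residues are skipped with a warning
  gappy <- matrix(c("A", "-", "-", "A", "A", "A"), nrow = 2, byrow = TRUE)
  expect_warning(s <- entropy_constraint(gappy), "skipped")
  expect_equal(s, 1.0)
})

test_that("decile labels split ranks evenly and respect ties and missing", {
  x <- seq_len(20)
  d <- assign_deciles(x)
  expect_equal(as.vector(table(d)), rep(2, 10))
  x2 <- c(1, 2, NA, 4:10)
  d2 <- assign_deciles(x2)
  expect_equal(d2[3], 99L)
  d3 <- assign_deciles(rep(7, 10))
  expect_equal(unique(d3), 4L) # shared midrank decile
  # invariance under order-preserving transformation
  y <- rnorm(50)
  expect_identical(assign_deciles(y), assign_deciles(exp(y)))
  expect_warning(d4 <- assign_deciles(c(NA_real_, NA_real_)), "missing")
  expect_equal(d4, c(99L, 99L))
})

test_that("density clustering separates blobs and flags isolated genes", {
  set.seed(17)
  X <- rbind(matrix(rnorm(200, 0, 0.1), ncol = 2),
             matrix(rnorm(200, 10, 0.1), ncol = 2),
             matrix(c(50, 50, -50, 40, 60, -60), ncol = 2, byrow = TRUE))
  # eps is meant on the raw coordinate scale here
  out <- detect_outlier_genes(X, eps = 1, minpts = 5,
                              min_cluster_frac = 0.02, standardize = FALSE)
  expect_equal(length(unique(out$cluster[out$cluster > 0])), 2)
  expect_equal(sum(out$cluster == 0), 3)
  expect_equal(sum(out$outlier), 3)

  one <- matrix(rnorm(100, 0, 0.05), ncol = 2)
  out1 <- detect_outlier_genes(one, eps = 1, minpts = 5,
                               standardize = FALSE)
  expect_equal(length(unique(out1$cluster)), 1)
  expect_equal(sum(out1$outlier), 0)

  outh <- detect_outlier_genes(X, eps = 1000, minpts = 5,
                               standardize = FALSE)
  expect_equal(unique(outh$cluster), 1L)
  expect_error(detect_outlier_genes(X, eps = 0), "eps")
})

test_that("constrained common CDS SNP census counts and selects genes", {
  setup <- toy_gene_setup()
  tr <- quick_track(rep(3, setup$L))
  cs <- constrained_set(data.frame(contig = "chr1", start = 14, end = 26))
  v <- toy_variant(pos = c(15, 20, 70), ref = "A", alt = "C",
                   ac = c(60, 60, 60), an = 10000)
  suppressWarnings(a <- annotate_variants(v, tr, cs, setup$ann,
                                          setup$reference))
  out <- constrained_cds_snp_census(setup$ann, a)
  expect_equal(out$counts$n[out$counts$gene_id == "g1"], 2L)
  expect_equal(out$counts$n[out$counts$gene_id == "g2"], 0L)
  expect_equal(out$zero_fraction, 0.5)
  # no constrained variants at all
  out0 <- constrained_cds_snp_census(setup$ann, a[a$pos > 100, ])
  expect_equal(out0$zero_fraction, 1.0)
})

test_that("top-k% selection uses floor rounding", {
  scores <- setNames(rnorm(19109), paste0("g", 1:19109))
  expect_equal(length(top_fraction_genes(scores, 5)), 955)
  expect_equal(length(top_fraction_genes(scores[1:10], 25)), 2)
})

test_that("gene score comparisons return rank correlations", {
  expect_equal(compare_gene_scores(1:10, 1:10)$spearman, 1.0)
  expect_equal(compare_gene_scores(1:10, -(1:10))$spearman, -1.0)
  out <- compare_gene_scores(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(out$spearman, 0.8)
  expect_equal(out$n, 4)
  expect_warning(z <- compare_gene_scores(rep(1, 5), 1:5), "variance")
  expect_true(is.na(z$spearman))
  expect_error(compare_gene_scores(c(1, NA, NA, 2), c(1, 1, 1, 2)), "shared")
})

test_that("default gene covariates are computable on simulated genomes", {
  g <- cached_genome(seed = 13, size = 5e5, genes_per_mb = 60)
  cov <- gene_covariates(g$annotation, g$reference)
  expect_equal(nrow(cov), nrow(g$annotation$genes))
  expect_equal(ncol(cov), 12)
  expect_true(all(vapply(cov, is.numeric, logical(1))))
  expect_false(anyNA(cov))
  pf <- part_constraint_fractions(g$annotation, g$truth$constrained)
  res <- residual_constraint(pf$frac_cds_cons, cov)
  expect_equal(length(res), nrow(cov))
})
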