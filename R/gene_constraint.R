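# Per-gene constraint metrics: part-wise constrained fractions, binomial
# excess-constraint z, covariate-adjusted residual constraint, alignment-
# column entropy, decile labels (99 = missing), density-based outlier genes,
# and the constrained-common-CDS-SNP census.

#' Part-wise constrained fractions per gene
#'
#' For each gene: constrained bases in the base union of the part divided by
#' the part length, for CDS (fracCdsCons), promoter, and linked enhancers.
#' Enhancers linked to several genes count fully toward each. Genes lacking
#' a part get `NA`.
#'
#' @param ann a `GenomeAnnotation`.
#' @param constrained a `ConstrainedSet`.
#' @return data.frame with columns `gene_id`, `frac_cds_cons`,
#'   `frac_prom_cons`, `frac_enh_cons`, `cds_len`, `n_cds_cons`.
#' @export
part_constraint_fractions <- function(ann, constrained) {
  frac_of <- function(part_set) {
    tot <- cs_total(part_set)
    if (tot == 0) return(c(NA_real_, 0, 0))
    k <- cs_total(cs_intersect(part_set, constrained))
    c(k / tot, tot, k)
  }
  rows <- lapply(ann$genes$gene_id, function(g) {
    cds <- frac_of(ann_part_set(ann, "CDS", g))
    prom <- frac_of(ann_part_set(ann, "promoter", g))
    enh <- frac_of(ann_part_set(ann, "enhancer", g))
    data.frame(gene_id = g, frac_cds_cons = cds[1], frac_prom_cons = prom[1],
               frac_enh_cons = enh[1], cds_len = cds[2], n_cds_cons = cds[3])
  })
  do.call(rbind, rows)
}

#' Binomial excess-constraint z-score
#'
#' Standardized excess of constrained CDS bases over the genome-wide CDS
#' constrained rate: `z = (k - L r) / sqrt(L r (1 - r))` (normal
#' approximation to the binomial).
#'
#' @param k constrained CDS bases in the gene.
#' @param L CDS length (> 0).
#' @param r genome-wide CDS constrained rate in (0, 1).
#' @return numeric z (vectorized).
#' @export
excess_constraint_z <- function(k, L, r) {
  stopifnot(all(L > 0), r > 0, r < 1)
  if (any(k > L)) stop("k exceeds CDS length")
  (k - L * r) / sqrt(L * r * (1 - r))
}

#' Covariate-adjusted residual constraint
#'
#' Ordinary least squares of the per-gene constrained fraction on a numeric
#' covariate table; the score is the standardized residual, so genes more
#' constrained than their covariates predict score positive. Collinear
#' covariate columns are dropped with a warning.
#'
#' @param fractions numeric vector (e.g. fracCdsCons), NA allowed (dropped).
#' @param covariates data.frame of numeric covariates, rows parallel to
#'   `fractions`. See [gene_covariates()] for the package default set.
#' @return numeric vector of residual scores, `NA` where the input was `NA`.
#' @export
residual_constraint <- function(fractions, covariates) {
  stopifnot(nrow(covariates) == length(fractions))
  keep <- !is.na(fractions) & complete.cases(covariates)
  if (sum(keep) <= ncol(covariates) + 1)
    stop("need more genes than covariates to fit the residual model")
  X <- covariates[keep, , drop = FALSE]
  const <- vapply(X, function(x) sd(x) == 0, logical(1))
  X <- X[, !const, drop = FALSE]
  fit <- lm(fractions[keep] ~ ., data = X)
  if (any(is.na(coef(fit)))) {
    dropped <- names(coef(fit))[is.na(coef(fit))]
    warning("dropping collinear covariate(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, !(names(X) %in% dropped), drop = FALSE]
    fit <- lm(fractions[keep] ~ ., data = X)
  }
  out <- rep(NA_real_, length(fractions))
  # a perfect fit has zero residual variance; standardized residuals are 0
  out[keep] <- if (summary(fit)$sigma < 1e-10) 0 else rstandard(fit)
  out
}

#' Top-k% gene selection with floor rounding
#'
#' @param scores named numeric vector (gene ids as names); `NA` excluded.
#' @param top_pct percentage (default 5).
#' @return character vector of the `floor(top_pct/100 * length(scores))`
#'   highest-scoring gene ids.
#' @export
top_fraction_genes <- function(scores, top_pct = 5) {
  k <- floor(top_pct / 100 * length(scores))
  names(sort(scores, decreasing = TRUE, na.last = TRUE))[seq_len(k)]
}

# substitution table over all 64 codons x 3 offsets: number of synonymous
# substitutions and whether any substitution creates a stop
.codon_sub_table <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- names(Biostrings::GENETIC_CODE)
  out <- list()
  for (cd in codons) {
    for (off in 0:2) {
      ref <- substr(cd, off + 1, off + 1)
      alts <- setdiff(bases, ref)
      aas <- vapply(alts, function(b) .aa(.sub_codon(cd, off, b)),
                    character(1))
      out[[paste0(cd, off)]] <- c(n_syn = sum(aas == .aa(cd)),
                                  can_stop = as.numeric(any(aas == "*")))
    }
  }
  out
}

#' Default per-gene covariates for the residual-constraint model
#'
#' Twelve numeric covariates per gene: log CDS length, gene-body GC fraction
#' (computed on the span, so it is not a linear combination of the
#' codon-position terms), GC fraction at the three codon positions,
#' fraction of CDS positions where some substitution creates a stop
#' codon, mean fraction of synonymous substitutions per CDS position, log
#' exon count, log mean exon length, log distance of the gene to the contig
#' end, promoter GC fraction, and log total UTR length.
#'
#' @param ann a `GenomeAnnotation`.
#' @param reference named character vector of contig sequences.
#' @return data.frame, one row per gene in `ann$genes` order.
#' @export
gene_covariates <- function(ann, reference) {
  subtab <- .codon_sub_table()
  rows <- lapply(seq_len(nrow(ann$genes)), function(i) {
    g <- ann$genes[i, ]
    p <- ann$parts[ann$parts$gene_id == g$gene_id, , drop = FALSE]
    cds <- as.matrix(p[p$class == "CDS", c("start", "end"), drop = FALSE])
    cds <- cds[order(cds[, 1]), , drop = FALSE]
    ex <- p[p$class == "exon", , drop = FALSE]
    utr <- p[p$class %in% c("UTR5", "UTR3"), , drop = FALSE]
    prom <- p[p$class == "promoter", , drop = FALSE]
    gc <- function(s) if (nchar(s) == 0) 0 else
      mean(strsplit(s, "")[[1]] %in% c("C", "G"))
    seq_of <- function(m) paste(vapply(seq_len(nrow(m)), function(j)
      substr(reference[[g$contig]], m[j, 1] + 1, m[j, 2]), character(1)),
      collapse = "")
    gene_seq <- substr(reference[[g$contig]], g$start + 1, g$end)
    # transcript-order CDS sequence for codon decomposition
    tx_pos <- .tx_positions(cds, g$strand, 0, sum(cds[, 2] - cds[, 1]))
    tx_b <- vapply(tx_pos + 1, function(x)
      substr(reference[[g$contig]], x, x), character(1))
    if (g$strand == "-") tx_b <- unname(.COMPLEMENT[tx_b])
    ncod <- length(tx_b) %/% 3
    tx_b <- tx_b[seq_len(ncod * 3)]
    cods <- vapply(seq_len(ncod), function(k)
      paste(tx_b[(3 * k - 2):(3 * k)], collapse = ""), character(1))
    keys <- paste0(rep(cods, each = 3), 0:2)
    subs <- vapply(keys, function(k) subtab[[k]], numeric(2))
    pos_gc <- vapply(1:3, function(ph)
      mean(tx_b[seq(ph, length(tx_b), by = 3)] %in% c("C", "G")), numeric(1))
    data.frame(
      log_cds_len = log(max(1, sum(cds[, 2] - cds[, 1]))),
      gene_gc = gc(gene_seq),
      gc_pos1 = pos_gc[1], gc_pos2 = pos_gc[2], gc_pos3 = pos_gc[3],
      frac_can_stop = mean(subs["can_stop", ]),
      syn_site_frac = mean(subs["n_syn", ] / 3),
      log_exon_count = log(nrow(ex)),
      log_mean_exon_len = log(mean(ex$end - ex$start)),
      log_dist_contig_end = log(1 + min(g$start,
        ann$contig_lengths[[g$contig]] - g$end)),
      promoter_gc = if (nrow(prom) > 0)
        gc(seq_of(as.matrix(prom[, c("start", "end")]))) else 0,
      log_utr_len = log(1 + sum(utr$end - utr$start)))
  })
  do.call(rbind, rows)
}

#' Alignment-column entropy constraint score
#'
#' Per column, the normalized Shannon entropy of amino-acid frequencies
#' `H_norm = -(sum f ln f) / ln 20` (gaps excluded, no small-sample bias
#' correction); the gene score is `1 - mean(H_norm)`, so 1 means fully
#' conserved columns and values near 0 mean residue usage close to uniform.
#'
#' @param columns character matrix, alignment columns x species; `-` marks a
#'   gap.
#' @return numeric score in \[0, 1\].
#' @export
entropy_constraint <- function(columns) {
  if (is.vector(columns)) columns <- matrix(columns, nrow = 1)
  stopifnot(nrow(columns) >= 1)
  h <- apply(columns, 1, function(col) {
    col <- col[col != "-" & !is.na(col)]
    if (length(col) < 2) return(NA_real_)
    f <- table(col) / length(col)
    -sum(f * log(f)) / log(20)
  })
  if (any(is.na(h))) {
    warning(sum(is.na(h)), " column(s) with < 2 non-gap residues skipped")
    h <- h[!is.na(h)]
  }
  if (length(h) == 0) stop("no usable columns")
  1 - mean(h)
}

#' Decile labels with 99 for missing
#'
#' Non-missing scores are ranked ascending and assigned
#' `floor(10 * (rank - 1) / n)`; tied scores share the decile of their
#' midrank, so a block of equal scores lands in a single decile. Missing
#' scores get the label 99.
#'
#' @param scores numeric vector, `NA` = missing.
#' @return integer labels in `{0..9, 99}`.
#' @export
assign_deciles <- function(scores) {
  out <- rep(99L, length(scores))
  ok <- !is.na(scores)
  if (!any(ok)) {
    warning("all scores missing")
    return(out)
  }
  r <- rank(scores[ok], ties.method = "average")
  out[ok] <- pmin(9L, as.integer(floor(10 * (r - 1) / sum(ok))))
  out
}

# classic DBSCAN on a feature matrix (euclidean, distance-matrix version);
# label 0 = noise
.dbscan <- function(X, eps, minpts) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  nbr <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nbr, length, integer(1)) >= minpts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue) > 0) {
      q <- queue[1]
      queue <- queue[-1]
      if (!core[q]) next
      new <- nbr[[q]][labels[nbr[[q]]] == 0L]
      labels[new] <- cl
      queue <- c(queue, new)
    }
  }
  labels
}

#' Density-based outlier genes over a metric matrix
#'
#' Standardizes the metric matrix (missing values are mean-imputed and
#' flagged in companion indicator columns), clusters genes with DBSCAN
#' (`eps`, `minpts`), and flags as outliers all noise points plus members of
#' clusters smaller than `min_cluster_frac` of the genes.
#'
#' @param metrics numeric matrix or data.frame, genes x metrics.
#' @param eps DBSCAN radius (> 0) on the standardized scale.
#' @param minpts DBSCAN core-point neighborhood size.
#' @param min_cluster_frac clusters below this fraction of genes count as
#'   outlier clusters (default 0.01).
#' @param standardize center and scale each metric first (default TRUE; turn
#'   off when `eps` is meant on the raw metric scale).
#' @return data.frame with columns `cluster` (0 = noise) and `outlier`.
#' @export
detect_outlier_genes <- function(metrics, eps = 1, minpts = 5,
                                 min_cluster_frac = 0.01,
                                 standardize = TRUE) {
  if (eps <= 0) stop("eps must be > 0")
  X <- as.data.frame(metrics)
  stopifnot(nrow(X) >= 10)
  for (cn in names(X)) {
    x <- as.numeric(X[[cn]])
    if (anyNA(x)) {
      X[[paste0(cn, "_missing")]] <- as.numeric(is.na(x))
      x[is.na(x)] <- mean(x, na.rm = TRUE)
    }
    X[[cn]] <- if (standardize && sd(x) > 0) (x - mean(x)) / sd(x) else x
  }
  labels <- .dbscan(as.matrix(X), eps, minpts)
  sizes <- table(labels[labels > 0])
  small <- as.integer(names(sizes)[sizes < min_cluster_frac * nrow(X)])
  data.frame(cluster = labels,
             outlier = labels == 0L | labels %in% small)
}

#' Census of constrained common CDS SNPs per gene
#'
#' Counts, per gene, the annotated variants that are common, constrained and
#' in that gene's CDS; reports the fraction of genes with zero such SNPs and
#' the most-constrained gene list by a score with floor-rounded top-k%
#' selection.
#'
#' @param ann a `GenomeAnnotation`.
#' @param annotated output of [annotate_variants()].
#' @param scores optional named numeric vector (by gene id) used for the
#'   top-k% selection; defaults to the census counts.
#' @param top_pct top percentage for the selection (default 5).
#' @return list with `counts` (data.frame `gene_id`, `n`), `zero_fraction`,
#'   and `top_genes` (character vector, `floor(top_pct/100 * n_genes)`
#'   genes).
#' @export
constrained_cds_snp_census <- function(ann, annotated, scores = NULL,
                                       top_pct = 5) {
  com <- annotated[annotated$af_bin == "common" & annotated$constrained &
                     annotated$region_class == "CDS", , drop = FALSE]
  counts <- data.frame(gene_id = ann$genes$gene_id, n = 0L)
  if (nrow(com) > 0) {
    cds_parts <- ann$parts[ann$parts$class == "CDS", , drop = FALSE]
    for (i in seq_len(nrow(com))) {
      gs <- unique(cds_parts$gene_id[cds_parts$contig == com$contig[i] &
                                       cds_parts$start <= com$pos[i] &
                                       cds_parts$end > com$pos[i]])
      counts$n[counts$gene_id %in% gs] <- counts$n[counts$gene_id %in% gs] + 1L
    }
  }
  if (is.null(scores)) scores <- setNames(counts$n, counts$gene_id)
  list(counts = counts, zero_fraction = mean(counts$n == 0),
       top_genes = top_fraction_genes(scores, top_pct))
}

#' Correlate two per-gene scores
#'
#' Spearman and Pearson correlations over genes non-missing in both vectors.
#'
#' @param a,b numeric vectors over the same genes (NA = missing).
#' @return list with `spearman`, `pearson`, `n`.
#' @export
compare_gene_scores <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("need at least 3 shared genes")
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
    warning("zero variance; correlations undefined")
    return(list(spearman = NA_real_, pearson = NA_real_, n = sum(ok)))
  }
  list(spearman = cor(a[ok], b[ok], method = "spearman"),
       pearson = cor(a[ok], b[ok]), n = sum(ok))
}
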