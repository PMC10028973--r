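# Variant-level constraint annotation: score and constraint context, region
# class with a fixed priority, coding context from the standard genetic code,
# base-composition flags, and allele-frequency bins.

.REGION_PRIORITY <- c("CDS", "UTR5", "UTR3", "promoter", "enhancer",
                      "intron", "intergenic")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# CDS-local (transcript) coordinate of genomic positions within a gene's CDS
.cds_local <- function(cds_mat, strand, pos) {
  if (strand == "-") cds_mat <- cds_mat[rev(seq_len(nrow(cds_mat))), ,
                                        drop = FALSE]
  w <- cds_mat[, 2] - cds_mat[, 1]
  c0 <- cumsum(w) - w
  vapply(pos, function(g) {
    for (i in seq_len(nrow(cds_mat))) {
      if (g >= cds_mat[i, 1] && g < cds_mat[i, 2]) {
        return(if (strand == "+") c0[i] + g - cds_mat[i, 1]
               else c0[i] + cds_mat[i, 2] - 1 - g)
      }
    }
    NA_real_
  }, numeric(1))
}

# genomic positions (in transcript order) of transcript coords a..(b-1)
.tx_positions <- function(cds_mat, strand, a, b) {
  df <- .tx_to_genomic(cds_mat, strand, a, b, "x", "x")
  pos <- unlist(lapply(seq_len(nrow(df)), function(i)
    seq.int(df$start[i], df$end[i] - 1)), use.names = FALSE)
  if (strand == "-") rev(sort(pos)) else sort(pos)
}

# codon context of one genomic position inside a gene's CDS
.codon_context <- function(ann, reference, gene_id, contig, pos) {
  p <- ann$parts
  cds <- as.matrix(p[p$gene_id == gene_id & p$class == "CDS",
                     c("start", "end"), drop = FALSE])
  cds <- cds[order(cds[, 1]), , drop = FALSE]
  strand <- ann$genes$strand[ann$genes$gene_id == gene_id]
  local <- .cds_local(cds, strand, pos)
  if (is.na(local)) return(NULL)
  ci <- local %/% 3
  offset <- local %% 3 # 0-based within codon
  gpos <- .tx_positions(cds, strand, ci * 3, ci * 3 + 3)
  if (length(gpos) < 3) return(NULL) # partial terminal codon
  bases <- vapply(gpos + 1, function(x) substr(reference[[contig]], x, x),
                  character(1))
  if (strand == "-") bases <- unname(.COMPLEMENT[bases])
  list(codon = paste(bases, collapse = ""), codon_pos = offset + 1,
       offset = offset, strand = strand)
}

.aa <- function(codon) Biostrings::GENETIC_CODE[[codon]]

.sub_codon <- function(codon, offset, base) {
  substr(codon, offset + 1, offset + 1) <- base
  codon
}

#' Annotate variants with constraint and coding context
#'
#' Adds, per variant: the conservation score at the position, the constrained
#' flag and distance to the nearest constrained base, a single region class
#' resolved by the priority CDS > UTR5 > UTR3 > promoter > enhancer > intron
#' > intergenic, codon position / synonymy / can-mutate-to-stop from the
#' standard genetic code (CDS variants only; computed strand-aware in
#' transcript orientation), C-or-G reference-base and CpG-dinucleotide flags
#' (plus-strand reference context), and an allele-frequency bin label.
#'
#' @param variants data.frame as returned by [simulate_variants()] or
#'   [read_variants_vcf()].
#' @param track `ScoreTrack` of conservation scores.
#' @param constrained `ConstrainedSet` of called constrained bases.
#' @param ann `GenomeAnnotation`.
#' @param reference named character vector of contig sequences.
#' @param common_af allele frequency defining the common bin (default 0.005).
#' @return the input data.frame with columns `score`, `constrained`,
#'   `dist_constrained`, `region_class`, `codon_pos`, `consequence`
#'   (`synonymous`/`nonsynonymous`/`NA`), `can_stop`, `ref_cg`, `cpg`,
#'   `af_bin` appended. Variants whose stated ref allele disagrees with the
#'   reference sequence are flagged in `ref_mismatch` with a warning.
#' @export
annotate_variants <- function(variants, track, constrained, ann, reference,
                              common_af = 0.005) {
  v <- variants
  n <- nrow(v)
  if (any(!v$contig %in% names(track$scores)))
    stop("variant on unknown contig")
  v$score <- NA_real_
  v$constrained <- FALSE
  v$dist_constrained <- NA_real_
  for (ct in unique(v$contig)) {
    i <- which(v$contig == ct)
    v$score[i] <- track_score(track, ct, v$pos[i])
    v$constrained[i] <- cs_member(constrained, ct, v$pos[i])
    v$dist_constrained[i] <- vapply(v$pos[i], function(p)
      region_query(constrained, ct, p)$nearest, numeric(1))
  }

  # reference agreement
  refb <- .ref_base(reference, v$contig, v$pos)
  v$ref_mismatch <- refb != v$ref
  if (any(v$ref_mismatch))
    warning(sum(v$ref_mismatch), " variant(s) disagree with the reference")

  # region class by priority
  sets <- lapply(setNames(.REGION_PRIORITY[1:6], .REGION_PRIORITY[1:6]),
                 function(cl) ann_part_set(ann, cl))
  v$region_class <- "intergenic"
  for (cl in rev(.REGION_PRIORITY[1:6])) { # apply lowest priority first
    for (ct in unique(v$contig)) {
      i <- which(v$contig == ct)
      hit <- cs_member(sets[[cl]], ct, v$pos[i])
      v$region_class[i[hit]] <- cl
    }
  }

  # coding context
  v$codon_pos <- NA_integer_
  v$consequence <- NA_character_
  v$can_stop <- NA
  cds_rows <- which(v$region_class == "CDS")
  if (length(cds_rows) > 0) {
    cds_parts <- ann$parts[ann$parts$class == "CDS", , drop = FALSE]
    for (i in cds_rows) {
      gs <- unique(cds_parts$gene_id[cds_parts$contig == v$contig[i] &
                                       cds_parts$start <= v$pos[i] &
                                       cds_parts$end > v$pos[i]])
      if (length(gs) == 0) next
      ctx <- .codon_context(ann, reference, gs[1], v$contig[i], v$pos[i])
      if (is.null(ctx)) next
      v$codon_pos[i] <- ctx$codon_pos
      alt_tx <- if (ctx$strand == "-") .COMPLEMENT[[v$alt[i]]] else v$alt[i]
      ref_aa <- .aa(ctx$codon)
      alt_aa <- .aa(.sub_codon(ctx$codon, ctx$offset, alt_tx))
      v$consequence[i] <- if (identical(ref_aa, alt_aa)) "synonymous" else
        "nonsynonymous"
      others <- setdiff(c("A", "C", "G", "T"),
                        substr(ctx$codon, ctx$offset + 1, ctx$offset + 1))
      v$can_stop[i] <- any(vapply(others, function(b)
        .aa(.sub_codon(ctx$codon, ctx$offset, b)) == "*", logical(1)))
    }
  }

  # base composition flags (plus-strand reference context)
  v$ref_cg <- refb %in% c("C", "G")
  nextb <- .ref_base_safe(reference, v$contig, v$pos + 1)
  prevb <- .ref_base_safe(reference, v$contig, v$pos - 1)
  v$cpg <- (refb == "C" & nextb == "G") | (refb == "G" & prevb == "C")

  v$af_bin <- af_bin(v$AC, v$AN, common_af = common_af)
  v
}

.ref_base_safe <- function(reference, contig, pos) {
  out <- rep(NA_character_, length(pos))
  ok <- pos >= 0 & pos < nchar(reference[contig])
  if (any(ok)) out[ok] <- .ref_base(reference, contig[ok], pos[ok])
  out
}

#' Allele-frequency bin labels
#'
#' Default six-bin scheme spanning singletons to common variants: the common
#' bin (`AF >= common_af`) takes precedence, then allele-count bins
#' `AC=1`, `AC2-10`, `AC11-100`, `AC101-1000`, with any residual rare
#' variant labeled `rare_other`.
#'
#' @param ac,an allele counts and total allele numbers.
#' @param common_af common-variant frequency cutoff.
#' @return factor of bin labels with levels in spectrum order.
#' @export
af_bin <- function(ac, an, common_af = 0.005) {
  lab <- ifelse(ac / an >= common_af, "common",
         ifelse(ac == 1, "AC=1",
         ifelse(ac <= 10, "AC2-10",
         ifelse(ac <= 100, "AC11-100",
         ifelse(ac <= 1000, "AC101-1000", "rare_other")))))
  factor(lab, levels = c("AC=1", "AC2-10", "AC11-100", "AC101-1000",
                         "rare_other", "common"))
}

#' Constraint across the allele-frequency spectrum
#'
#' Per-bin constrained fractions plus the Spearman rank correlation between
#' allele count and conservation score, overall and within the CDS subset
#' (midranks for ties).
#'
#' @param annotated output of [annotate_variants()].
#' @return list with `bins` (data.frame: `af_bin`, `n`, `frac_constrained`)
#'   and `rho` (named vector: `overall`, `cds`).
#' @export
af_constraint_summary <- function(annotated) {
  sp <- split(annotated$constrained, annotated$af_bin)
  bins <- data.frame(af_bin = names(sp),
                     n = vapply(sp, length, integer(1)),
                     frac_constrained = vapply(sp, function(x)
                       if (length(x) == 0) NA_real_ else mean(x), numeric(1)))
  if (any(bins$n == 0)) warning("empty allele-frequency bin(s)")
  cds <- annotated$region_class == "CDS"
  rho <- c(overall = cor(annotated$AC, annotated$score, method = "spearman"),
           cds = if (sum(cds) >= 3)
             cor(annotated$AC[cds], annotated$score[cds],
                 method = "spearman") else NA_real_)
  list(bins = bins, rho = rho)
}

#' Depletion (or enrichment) of constrained bases against expectation
#'
#' Fold change of the observed constrained fraction over the genome-wide
#' expectation, with a two-sided exact binomial p-value. Fold below 1 means
#' depletion.
#'
#' @param observed_constrained number of constrained successes.
#' @param n total trials.
#' @param expected_fraction genome-wide expectation in (0, 1).
#' @return list with `fold`, `p`, `observed_fraction`, `expected_fraction`.
#' @export
depletion_test <- function(observed_constrained, n, expected_fraction) {
  stopifnot(n > 0, expected_fraction > 0, expected_fraction < 1)
  if (observed_constrained > n) stop("observed exceeds n")
  bt <- binom.test(observed_constrained, n, p = expected_fraction)
  list(fold = (observed_constrained / n) / expected_fraction,
       p = bt$p.value,
       observed_fraction = observed_constrained / n,
       expected_fraction = expected_fraction)
}

#' Feature enrichment of constrained status among variants
#'
#' Logistic model of the constrained flag on binary feature indicators
#' (unregularized IRLS via [glm]); reported odds ratios are exponentiated
#' coefficients with Wald confidence intervals. With a single binary
#' predictor the OR equals the 2x2 contingency odds ratio. Complete
#' separation is reported as a flagged infinite OR rather than an error.
#'
#' @param annotated output of [annotate_variants()] (or any data.frame with
#'   a logical `constrained` column).
#' @param features character vector of feature column names; defaults to
#'   indicators derived from the annotation (`CDS`, `promoter`, `enhancer`,
#'   `ref_cg`, `cpg`).
#' @param conf_level confidence level for the Wald interval.
#' @return data.frame with columns `feature`, `or`, `ci_lo`, `ci_hi`, `p`,
#'   `separated`.
#' @export
feature_enrichment_model <- function(annotated, features = NULL,
                                     conf_level = 0.95) {
  df <- annotated
  if (is.null(features)) {
    df$CDS <- df$region_class == "CDS"
    df$promoter <- df$region_class == "promoter"
    df$enhancer <- df$region_class == "enhancer"
    features <- intersect(c("CDS", "promoter", "enhancer", "ref_cg", "cpg"),
                          names(df))
  }
  if (length(unique(df$constrained)) < 2)
    stop("need both constrained and unconstrained variants")
  X <- df[, features, drop = FALSE]
  X[] <- lapply(X, as.numeric)
  fit <- suppressWarnings(
    glm(df$constrained ~ ., data = X, family = binomial()))
  co <- coef(fit)[-1]
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit)))[-1])
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  separated <- !fit$converged | abs(co) > 15
  pz <- 2 * stats::pnorm(-abs(co / se))
  data.frame(feature = features,
             or = ifelse(separated, ifelse(co > 0, Inf, 0), exp(co)),
             ci_lo = exp(co - zq * se), ci_hi = exp(co + zq * se),
             p = pz, separated = separated, row.names = NULL)
}
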