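# CNV/SV constrained-base burden: per-call and per-sample burden against a
# constrained set, case-control testing on the three conventional burden
# measures, and frequency-stratified constraint fractions.

#' Constrained-base burden of CNV calls
#'
#' Per-CNV constrained-base counts and per-sample totals for the three
#' burden measures: number of CNVs, total CNV bases, and total constrained
#' bases impacted (overall and per CNV class). Overlapping CNVs within one
#' sample count bases multiply by default (per-call additivity); set
#' `merge_overlaps = TRUE` to merge a sample's calls per class before
#' counting.
#'
#' @param cnvs data.frame with columns `sample`, `label`, `contig`, `start`,
#'   `end`, `class` (and optionally `AC`, `AN`, `AF`).
#' @param constrained a `ConstrainedSet`.
#' @param merge_overlaps merge each sample's overlapping calls first?
#' @return list with `per_cnv` (input plus `n_constrained`) and `per_sample`
#'   (columns `sample`, `label`, `n_cnvs`, `total_bases`, `cons_bases`, and
#'   `cons_bases_DEL`/`_DUP`/`_INV`).
#' @export
compute_burden <- function(cnvs, constrained, merge_overlaps = FALSE) {
  stopifnot(all(cnvs$end > cnvs$start))
  cnvs$n_constrained <- NA_real_
  for (ct in unique(cnvs$contig)) {
    i <- cnvs$contig == ct
    cnvs$n_constrained[i] <- cs_count(constrained, ct, cnvs$start[i],
                                      cnvs$end[i])
  }
  key <- unique(cnvs[, c("sample", "label")])
  per_sample <- data.frame(sample = key$sample, label = key$label)
  agg <- function(sub) {
    if (merge_overlaps && nrow(sub) > 0) {
      merged <- lapply(split(sub, sub$class), function(s) {
        m <- constrained_set(s[, c("contig", "start", "end")])
        df <- cs_to_df(m)
        df$n_constrained <- cs_count_multi(constrained, df)
        df
      })
      sub2 <- do.call(rbind, merged)
      c(n = nrow(sub), bases = sum(sub2$end - sub2$start),
        cons = sum(sub2$n_constrained))
    } else {
      c(n = nrow(sub), bases = sum(as.numeric(sub$end - sub$start)),
        cons = sum(sub$n_constrained))
    }
  }
  sp <- split(cnvs, cnvs$sample)
  per_sample$n_cnvs <- 0
  per_sample$total_bases <- 0
  per_sample$cons_bases <- 0
  for (cl in c("DEL", "DUP", "INV")) per_sample[[paste0("cons_bases_", cl)]] <- 0
  for (i in seq_len(nrow(per_sample))) {
    sub <- sp[[per_sample$sample[i]]]
    if (is.null(sub)) next
    a <- agg(sub)
    per_sample$n_cnvs[i] <- a[["n"]]
    per_sample$total_bases[i] <- a[["bases"]]
    per_sample$cons_bases[i] <- a[["cons"]]
    for (cl in c("DEL", "DUP", "INV")) {
      per_sample[[paste0("cons_bases_", cl)]][i] <-
        agg(sub[sub$class == cl, , drop = FALSE])[["cons"]]
    }
  }
  list(per_cnv = cnvs, per_sample = per_sample)
}

# vectorized count over a data.frame of intervals
cs_count_multi <- function(cs, df) {
  out <- numeric(nrow(df))
  for (ct in unique(df$contig)) {
    i <- df$contig == ct
    out[i] <- cs_count(cs, ct, df$start[i], df$end[i])
  }
  out
}

.ranksum_p <- function(x, y) {
  if (length(unique(c(x, y))) == 1) {
    warning("constant burden in both arms")
    return(1)
  }
  n <- length(x) + length(y)
  exact <- n <= 30 && !any(duplicated(c(x, y)))
  suppressWarnings(wilcox.test(x, y, exact = exact, correct = FALSE)$p.value)
}

#' Case-control burden tests
#'
#' Two-sided rank-sum p-values (exact for samples of at most 30 without
#' ties, tie-corrected normal approximation otherwise) for the three burden
#' measures, overall and restricted to deletions, plus a logistic model of
#' the case label on each standardized measure.
#'
#' @param burden output of [compute_burden()] (the `per_sample` element is
#'   used) or the per-sample data.frame itself.
#' @return data.frame with columns `measure`, `p_ranksum`, `logit_coef`,
#'   `p_logit`, `mean_case`, `mean_control`.
#' @export
burden_test <- function(burden) {
  tab <- if (is.data.frame(burden)) burden else burden$per_sample
  if (!any(tab$label == "case") || !any(tab$label == "control"))
    stop("need at least one case and one control")
  measures <- c(n_cnvs = "n_cnvs", total_bases = "total_bases",
                cons_bases = "cons_bases", cons_bases_DEL = "cons_bases_DEL")
  rows <- lapply(names(measures), function(m) {
    x <- tab[[measures[[m]]]][tab$label == "case"]
    y <- tab[[measures[[m]]]][tab$label == "control"]
    pr <- .ranksum_p(x, y)
    v <- tab[[measures[[m]]]]
    if (sd(v) > 0) {
      fit <- suppressWarnings(glm((tab$label == "case") ~ scale(v),
                                  family = binomial()))
      co <- summary(fit)$coefficients
      lc <- co[2, 1]; pl <- co[2, 4]
    } else {
      lc <- NA_real_; pl <- NA_real_
    }
    data.frame(measure = m, p_ranksum = pr, logit_coef = lc, p_logit = pl,
               mean_case = mean(x), mean_control = mean(y))
  })
  do.call(rbind, rows)
}

#' Constraint fractions of SVs by frequency stratum
#'
#' For each CNV class and frequency stratum (singleton `AC = 1`, common
#' `AF >= common_af`, `other`), the summed constrained bases over summed SV
#' bases. Empty strata are `NA`.
#'
#' @param svs data.frame with columns `contig`, `start`, `end`, `class`,
#'   `AC`, `AF`.
#' @param constrained a `ConstrainedSet`.
#' @param common_af common-variant frequency cutoff (default 0.005).
#' @return data.frame with columns `class`, `stratum`, `n_svs`, `bases`,
#'   `cons_bases`, `frac_constrained`.
#' @export
sv_frequency_strata <- function(svs, constrained, common_af = 0.005) {
  stopifnot(all(c("AC", "AF") %in% names(svs)))
  svs$n_constrained <- cs_count_multi(constrained, svs)
  svs$stratum <- ifelse(svs$AC == 1, "singleton",
                        ifelse(svs$AF >= common_af, "common", "other"))
  grid <- expand.grid(class = sort(unique(svs$class)),
                      stratum = c("singleton", "other", "common"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- svs[svs$class == grid$class[i] & svs$stratum == grid$stratum[i], ]
    b <- sum(as.numeric(sub$end - sub$start))
    data.frame(class = grid$class[i], stratum = grid$stratum[i],
               n_svs = nrow(sub), bases = b,
               cons_bases = sum(sub$n_constrained),
               frac_constrained = if (b > 0) sum(sub$n_constrained) / b
               else NA_real_)
  })
  do.call(rbind, rows)
}
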