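# Somatic non-coding constraint mutation (NCCM) scan: call mutations at
# conserved non-coding bases, aggregate them over gene loci (introns, UTRs
# and flanking sequence, CDS excluded), flag recurrently mutated candidate
# driver loci, and stratify them by patient age group and subgroup.

#' Gene locus for the NCCM scan
#'
#' Union of the gene's introns, UTRs and `flank` bases on either side of the
#' gene span, minus all CDS bases (of any gene), clipped to the contig.
#'
#' @param ann a `GenomeAnnotation`.
#' @param gene_id gene id.
#' @param flank flank size in bases (default 100 kb).
#' @param exclude_utrs also remove UTR bases from the locus (default FALSE;
#'   the UTRs are part of the locus).
#' @return a `ConstrainedSet` holding the locus intervals.
#' @export
gene_locus <- function(ann, gene_id, flank = 1e5, exclude_utrs = FALSE) {
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  if (nrow(g) == 0) stop("unknown gene: ", gene_id)
  L <- ann$contig_lengths[[g$contig]]
  span <- constrained_set(data.frame(
    contig = g$contig, start = max(0, g$start - flank),
    end = min(L, g$end + flank)))
  parts <- ann$parts[ann$parts$gene_id == gene_id &
                       ann$parts$class %in% c("intron", "UTR5", "UTR3"), ]
  locus <- cs_union(span, constrained_set(
    parts[, c("contig", "start", "end")]))
  drop <- ann_part_set(ann, "CDS")
  if (exclude_utrs)
    drop <- cs_union(drop, cs_union(ann_part_set(ann, "UTR5"),
                                    ann_part_set(ann, "UTR3")))
  cs_setdiff(locus, drop)
}

#' Call non-coding constraint mutations
#'
#' A somatic mutation is an NCCM iff its conservation score is at least
#' `threshold` (inclusive) and the position lies outside every CDS interval.
#' Mutations at unscored bases are excluded and their count reported.
#'
#' @param somatic data.frame with columns `patient`, `age`, `subgroup`,
#'   `contig`, `pos`, `ref`, `alt`.
#' @param track `ScoreTrack`.
#' @param ann `GenomeAnnotation`.
#' @param threshold NCCM score threshold (default 1.2).
#' @return list with `nccms` (the qualifying rows plus a `score` column) and
#'   `n_unscored` (mutations dropped for missing scores).
#' @export
call_nccms <- function(somatic, track, ann, threshold = 1.2) {
  s <- somatic
  s$score <- NA_real_
  for (ct in unique(s$contig)) {
    i <- s$contig == ct
    s$score[i] <- track_score(track, ct, s$pos[i])
  }
  n_unscored <- sum(is.na(s$score))
  if (n_unscored > 0)
    message(n_unscored, " mutation(s) at unscored bases excluded")
  s <- s[!is.na(s$score), , drop = FALSE]
  cds <- ann_part_set(ann, "CDS")
  in_cds <- logical(nrow(s))
  for (ct in unique(s$contig)) {
    i <- s$contig == ct
    in_cds[i] <- cs_member(cds, ct, s$pos[i])
  }
  list(nccms = s[s$score >= threshold & !in_cds, , drop = FALSE],
       n_unscored = n_unscored)
}

#' Per-gene NCCM locus rates
#'
#' Counts NCCMs in each gene's locus (see [gene_locus()]); a mutation counts
#' toward every gene whose locus contains it. The rate denominator is the
#' de-duplicated union length of the locus, expressed per 100 kb.
#'
#' @param nccms NCCM table from [call_nccms()] (`$nccms`).
#' @param ann a `GenomeAnnotation`.
#' @param flank locus flank (default 100 kb).
#' @return data.frame with columns `gene_id`, `locus_len`, `n_nccms`,
#'   `n_patients`, `rate_per_100kb`.
#' @export
locus_rates <- function(nccms, ann, flank = 1e5) {
  rows <- lapply(ann$genes$gene_id, function(g) {
    loc <- gene_locus(ann, g, flank = flank)
    len <- cs_total(loc)
    if (len == 0) {
      warning("zero-length locus for ", g, "; skipped")
      return(NULL)
    }
    hit <- rep(FALSE, nrow(nccms))
    for (ct in unique(nccms$contig)) {
      i <- nccms$contig == ct
      if (!ct %in% names(loc$intervals)) next
      hit[i] <- cs_member(loc, ct, nccms$pos[i])
    }
    data.frame(gene_id = g, locus_len = len, n_nccms = sum(hit),
               n_patients = length(unique(nccms$patient[hit])),
               rate_per_100kb = sum(hit) / (len / 1e5))
  })
  do.call(rbind, rows)
}

#' Flag candidate driver loci
#'
#' Inclusive thresholds on the NCCM rate (per 100 kb) and the per-gene NCCM
#' count.
#'
#' @param reports output of [locus_rates()].
#' @param rate_min rate threshold (default 2 per 100 kb).
#' @param count_min count threshold (default 5).
#' @return list with `rate_flagged` and `count_flagged` gene id vectors, and
#'   `reports` with logical columns `rate_flag`, `count_flag` appended.
#' @export
flag_candidate_drivers <- function(reports, rate_min = 2.0, count_min = 5) {
  reports$rate_flag <- reports$rate_per_100kb >= rate_min
  reports$count_flag <- reports$n_nccms >= count_min
  list(rate_flagged = reports$gene_id[reports$rate_flag],
       count_flagged = reports$gene_id[reports$count_flag],
       reports = reports)
}

#' Stratify flagged loci by patient age group and subgroup
#'
#' Per locus, distinct NCCM-bearing patients are tallied as pediatric
#' (`age < age_cut`) or adult; the locus is assigned `adult` or `pediatric`
#' when that group reaches the dominance fraction (inclusive), otherwise
#' `mixed`. Patients without an age are excluded from the stratification.
#'
#' @param reports output of [locus_rates()] (typically the flagged subset).
#' @param nccms NCCM table from [call_nccms()].
#' @param ann a `GenomeAnnotation`.
#' @param flank locus flank used for the scan.
#' @param age_cut pediatric/adult boundary (default 18: adult is `>= 18`).
#' @param dominance fraction of patients required to call a group
#'   (default 2/3).
#' @return `reports` with columns `n_pediatric`, `n_adult`, `group`, and
#'   `subgroups` (comma-separated `label:count` tally) appended.
#' @export
stratify_by_group <- function(reports, nccms, ann, flank = 1e5,
                              age_cut = 18, dominance = 2 / 3) {
  if (anyNA(nccms$age)) {
    message(sum(is.na(nccms$age)), " NCCM(s) from age-less patients excluded")
    nccms <- nccms[!is.na(nccms$age), , drop = FALSE]
  }
  out <- reports
  out$n_pediatric <- 0L
  out$n_adult <- 0L
  out$group <- NA_character_
  out$subgroups <- ""
  for (i in seq_len(nrow(out))) {
    loc <- gene_locus(ann, out$gene_id[i], flank = flank)
    hit <- rep(FALSE, nrow(nccms))
    for (ct in unique(nccms$contig)) {
      j <- nccms$contig == ct
      if (ct %in% names(loc$intervals))
        hit[j] <- cs_member(loc, ct, nccms$pos[j])
    }
    pts <- unique(nccms[hit, c("patient", "age", "subgroup")])
    ped <- sum(pts$age < age_cut)
    ad <- sum(pts$age >= age_cut)
    out$n_pediatric[i] <- ped
    out$n_adult[i] <- ad
    tot <- ped + ad
    out$group[i] <- if (tot == 0) "none"
      else if (ad / tot >= dominance) "adult"
      else if (ped / tot >= dominance) "pediatric"
      else "mixed"
    tal <- table(pts$subgroup)
    out$subgroups[i] <- paste(sprintf("%s:%d", names(tal), as.integer(tal)),
                              collapse = ",")
  }
  out
}
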