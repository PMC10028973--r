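# UNICORNs: UNannotated Intergenic COnstraint RegioNs. Clusters of
# constrained bases outside every annotated interval, with matched
# non-constrained background sampling and fine-mapping PIP comparisons.

#' Detect unannotated intergenic constraint regions
#'
#' Constrained bases outside the annotation catalog are merged when
#' separated by gaps of at most `merge_gap` bases; any catalog bases swept
#' into a merged region are subtracted back out, so output regions never
#' overlap the catalog. Regions shorter than `min_len` or containing fewer
#' than `min_cons` constrained bases are dropped.
#'
#' @param constrained a `ConstrainedSet`.
#' @param catalog a `ConstrainedSet` holding the union of all annotated
#'   intervals (gene bodies plus buffer, promoters, enhancers, ...).
#' @param merge_gap maximum gap merged (default 10).
#' @param min_len minimum region length (default 20, inclusive).
#' @param min_cons minimum constrained bases per region (default 10).
#' @param track optional `ScoreTrack` for per-region mean scores.
#' @return data.frame with columns `contig`, `start`, `end`, `length`,
#'   `n_constrained`, `mean_score`, sorted by position.
#' @export
detect_unicorns <- function(constrained, catalog, merge_gap = 10,
                            min_len = 20, min_cons = 10, track = NULL) {
  outside <- cs_setdiff(constrained, catalog)
  rows <- lapply(names(outside$intervals), function(ct) {
    m <- outside$intervals[[ct]]
    if (nrow(m) == 0) return(NULL)
    merged <- .ir_to_mat(IRanges::reduce(.mat_to_ir(m),
                                         min.gapwidth = merge_gap + 1L))
    # subtract any catalog bases a merge swept in
    clean <- cs_setdiff(constrained_set(setNames(list(merged), ct)),
                        catalog)$intervals[[ct]]
    if (is.null(clean) || nrow(clean) == 0) return(NULL)
    data.frame(contig = ct, start = clean[, 1], end = clean[, 2])
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      n_constrained = numeric(0), mean_score = numeric(0)))
  df$length <- df$end - df$start
  df$n_constrained <- cs_count_multi(constrained, df)
  df <- df[df$length >= min_len & df$n_constrained >= min_cons, ,
           drop = FALSE]
  df$mean_score <- rep(NA_real_, nrow(df))
  if (!is.null(track) && nrow(df) > 0) {
    df$mean_score <- vapply(seq_len(nrow(df)), function(i)
      mean(track_score(track, df$contig[i],
                       df$start[i]:(df$end[i] - 1)), na.rm = TRUE),
      numeric(1))
  }
  df <- df[order(df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Sample matched unannotated non-constrained background regions
#'
#' For each UNICORN, samples a length-equal interval on the same contig that
#' overlaps neither the annotation catalog, nor any constrained base, nor a
#' previously placed region; after `max_tries` rejections the search relaxes
#' to any contig with a warning. The length multiset of every background set
#' equals the UNICORN length multiset.
#'
#' @param unicorns data.frame from [detect_unicorns()].
#' @param contig_lengths named vector of contig lengths.
#' @param catalog,constrained `ConstrainedSet`s to avoid.
#' @param n_sets number of background sets (default 1).
#' @param seed random seed.
#' @param max_tries same-contig attempts per region before relaxing.
#' @return list of `n_sets` data.frames with columns `contig`, `start`,
#'   `end`.
#' @export
sample_matched_background <- function(unicorns, contig_lengths, catalog,
                                      constrained, n_sets = 1, seed = 1,
                                      max_tries = 1000) {
  set.seed(seed)
  avoid <- cs_union(catalog, constrained)
  avoid <- cs_union(avoid,
                    constrained_set(unicorns[, c("contig", "start", "end")]))
  lapply(seq_len(n_sets), function(s) {
    placed <- avoid
    rows <- lapply(seq_len(nrow(unicorns)), function(i) {
      len <- unicorns$end[i] - unicorns$start[i]
      try_contigs <- c(rep(unicorns$contig[i], max_tries),
                       sample(names(contig_lengths), max_tries,
                              replace = TRUE, prob = contig_lengths))
      relaxed <- FALSE
      for (t in seq_along(try_contigs)) {
        if (t == max_tries + 1) {
          warning("relaxing to any contig for region ", i)
          relaxed <- TRUE
        }
        ct <- try_contigs[t]
        if (contig_lengths[[ct]] <= len) next
        st <- sample.int(contig_lengths[[ct]] - len, 1) - 1L
        if (cs_count(placed, ct, st, st + len) == 0) {
          placed <<- cs_union(placed, constrained_set(
            data.frame(contig = ct, start = st, end = st + len)))
          return(data.frame(contig = ct, start = st, end = st + len))
        }
      }
      stop(sprintf("no eligible placement for region %s:%d-%d",
                   unicorns$contig[i], unicorns$start[i], unicorns$end[i]))
    })
    do.call(rbind, rows)
  })
}

.assign_set <- function(pip, region_sets) {
  lab <- rep("rest", nrow(pip))
  for (nm in names(region_sets)) {
    rs <- constrained_set(region_sets[[nm]][, c("contig", "start", "end")])
    for (ct in unique(pip$contig)) {
      i <- pip$contig == ct
      if (ct %in% names(rs$intervals))
        lab[i][cs_member(rs, ct, pip$pos[i])] <- nm
    }
  }
  lab
}

#' Compare fine-mapping PIPs across region sets
#'
#' Assigns each SNP to `unicorn`, `matched` or `rest`, reports per-set SNP
#' counts and mean PIPs, and tests whether the mean PIP inside UNICORNs
#' exceeds the matched background by permutation (labels shuffled over the
#' SNPs of the two sets; one-sided, +1 correction). Per-trait p-values are
#' Bonferroni-corrected across traits.
#'
#' @param pip data.frame with columns `contig`, `pos` (0-based), `trait`,
#'   `pip`.
#' @param unicorns,background data.frames with `contig`, `start`, `end`
#'   (disjoint).
#' @param n_perm number of permutations (default 1000).
#' @param seed random seed.
#' @return list with `summary` (per-set `n`, `mean_pip`), `p` (overall
#'   permutation p), and `per_trait` (data.frame `trait`, `n_unicorn`,
#'   `n_matched`, `diff`, `p`, `p_bonferroni`).
#' @export
compare_pip <- function(pip, unicorns, background, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1, all(pip$pip >= 0 & pip$pip <= 1))
  pip$set <- .assign_set(pip, list(unicorn = unicorns, matched = background))
  sp <- split(pip$pip, factor(pip$set, levels = c("unicorn", "matched",
                                                  "rest")))
  summary <- data.frame(set = names(sp),
                        n = vapply(sp, length, integer(1)),
                        mean_pip = vapply(sp, function(x)
                          if (length(x) == 0) NA_real_ else mean(x),
                          numeric(1)))
  if (any(summary$n == 0)) warning("empty region set(s)")
  set.seed(seed)
  perm_p <- function(sub) {
    x <- sub$pip[sub$set == "unicorn"]
    y <- sub$pip[sub$set == "matched"]
    if (length(x) == 0 || length(y) == 0) return(NA_real_)
    obs <- mean(x) - mean(y)
    pool <- c(x, y)
    nx <- length(x)
    null <- vapply(seq_len(n_perm), function(k) {
      i <- sample.int(length(pool), nx)
      mean(pool[i]) - mean(pool[-i])
    }, numeric(1))
    (1 + sum(null >= obs)) / (n_perm + 1)
  }
  p_all <- perm_p(pip)
  traits <- sort(unique(pip$trait))
  per_trait <- do.call(rbind, lapply(traits, function(tr) {
    sub <- pip[pip$trait == tr, , drop = FALSE]
    x <- sub$pip[sub$set == "unicorn"]; y <- sub$pip[sub$set == "matched"]
    data.frame(trait = tr, n_unicorn = length(x), n_matched = length(y),
               diff = mean(x) - mean(y), p = perm_p(sub))
  }))
  if (!is.null(per_trait))
    per_trait$p_bonferroni <- pmin(1, per_trait$p * length(traits))
  list(summary = summary, p = p_all, per_trait = per_trait)
}
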