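# FDR-based constraint calling. Scores are signed -log10 p-values under
# neutrality; only the conservation side (score > 0) is tested, so the
# one-sided p-value is 10^(-score) for positive scores and 1 otherwise.

#' Call constrained bases by genome-wide Benjamini-Hochberg thresholding
#'
#' Converts every non-missing base to a conservation-side p-value
#' (`10^-score` for positive scores, 1 otherwise), applies BH across the
#' whole universe at level `q`, and returns the score threshold `t*` (the
#' smallest score among rejected bases) together with the constrained set
#' `score >= t*`. Negative (acceleration) scores are never called.
#' Alternatively a fixed score threshold can be applied directly.
#'
#' @param track a `ScoreTrack`.
#' @param q FDR level in (0, 1).
#' @param fixed_threshold when non-`NULL`, skip BH and call every base with
#'   `score >= fixed_threshold` (inclusive, mirroring the "score >= 2.27"
#'   convention of genome-wide constraint tracks).
#' @return list with `result` (a `ThresholdResult`: `threshold`, `q`,
#'   `n_constrained`, `fraction`, `universe`) and `constrained` (a
#'   `ConstrainedSet`). When nothing is rejected the threshold is `Inf` and
#'   the set is empty.
#' @export
call_constrained_bases <- function(track, q = 0.05, fixed_threshold = NULL) {
  if (is.null(fixed_threshold) && (q <= 0 || q >= 1))
    stop("q must be in (0, 1)")
  U <- universe_size(track)
  if (U < 1) stop("track has no scored bases")

  if (is.null(fixed_threshold)) {
    s_all <- unlist(lapply(track$scores, function(s) s[!is.na(s)]),
                    use.names = FALSE)
    p <- ifelse(s_all > 0, 10^(-s_all), 1)
    padj <- p.adjust(p, method = "BH")
    rej <- padj <= q
    tstar <- if (any(rej)) min(s_all[rej]) else Inf
  } else {
    tstar <- fixed_threshold
  }

  ivs <- lapply(track$scores, function(s) {
    hit <- !is.na(s) & s >= tstar
    if (!any(hit)) return(.empty_mat())
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    cbind(start = starts[r$values], end = ends[r$values])
  })
  cs <- constrained_set(ivs)
  res <- structure(list(threshold = tstar, q = if (is.null(fixed_threshold))
    q else NA_real_, n_constrained = cs_total(cs),
    fraction = cs_total(cs) / U, universe = U), class = "ThresholdResult")
  list(result = res, constrained = cs)
}

#' @export
print.ThresholdResult <- function(x, ...) {
  cat(sprintf(
    "ThresholdResult: t* = %.4g, %.0f constrained bases (%.3f%% of %.0f)\n",
    x$threshold, x$n_constrained, 100 * x$fraction, x$universe))
  invisible(x)
}

#' Threshold a second score track to match a target genome fraction
#'
#' Finds the smallest score value `t*` such that the fraction of non-missing
#' bases with `score >= t*` does not exceed `target_fraction`; with ties the
#' achievable fraction closest to the target from below is taken. Used to
#' put a second conservation score (e.g. a phastCons-like posterior) on the
#' same genome-fraction footing as the primary constrained set.
#'
#' @param track a `ScoreTrack`.
#' @param target_fraction target fraction of the universe in (0, 1).
#' @return list with `result` (`ThresholdResult` carrying the realized
#'   fraction) and `constrained` (`ConstrainedSet`). A degenerate track where
#'   no threshold achieves a fraction below 1 yields an empty set with a
#'   warning.
#' @export
matched_fraction_threshold <- function(track, target_fraction) {
  stopifnot(target_fraction > 0, target_fraction < 1)
  s_all <- unlist(lapply(track$scores, function(s) s[!is.na(s)]),
                  use.names = FALSE)
  U <- length(s_all)
  vals <- sort(unique(s_all), decreasing = TRUE)
  n_ge <- cumsum(tabulate(match(s_all, vals), nbins = length(vals)))
  frac <- n_ge / U
  ok <- which(frac <= target_fraction)
  if (length(ok) == 0) {
    warning("no threshold achieves the target fraction; returning empty set")
    tstar <- Inf
  } else {
    tstar <- vals[max(ok)] # smallest value still within the target
  }
  call_fixed <- call_constrained_bases(track, fixed_threshold = tstar)
  call_fixed$result$q <- NA_real_
  call_fixed
}

#' Clustering of constrained bases: nearest-neighbor spacing statistics
#'
#' The observed statistic is the median, over constrained bases, of the
#' distance to the nearest other constrained base (adjacent bases have
#' distance 1). The null places the same number of bases uniformly at random
#' over the non-missing universe, `n_perm` times; the empirical p-value uses
#' the +1 correction `(1 + #\{null <= observed\}) / (n_perm + 1)` and tests
#' for clustering (small observed median).
#'
#' @param cs a `ConstrainedSet` with at least 2 bases.
#' @param track the `ScoreTrack` defining the universe.
#' @param n_perm number of null placements (>= 1).
#' @param seed seed for the null placements.
#' @return list with `observed` (median nearest-neighbor distance), `null`
#'   (numeric vector of null medians) and `p` (empirical p for clustering).
#' @export
spacing_statistics <- function(cs, track, n_perm = 100, seed = 1) {
  if (cs_total(cs) < 2) stop("need at least 2 constrained bases")
  stopifnot(n_perm >= 1)
  observed <- .median_nn_distance(lapply(names(cs$intervals), function(ct)
    cs_positions(cs, ct)))
  set.seed(seed)
  per <- lapply(track$scores, function(s) which(!is.na(s)) - 1L)
  sizes <- vapply(per, length, numeric(1))
  n_bases <- vapply(names(track$scores), function(ct) {
    m <- cs$intervals[[ct]]
    if (is.null(m)) 0 else sum(m[, 2] - m[, 1])
  }, numeric(1))
  null <- vapply(seq_len(n_perm), function(i) {
    pos <- lapply(seq_along(per), function(j) {
      if (n_bases[j] == 0) return(integer(0))
      sort(sample(per[[j]], n_bases[j]))
    })
    .median_nn_distance(pos)
  }, numeric(1))
  list(observed = observed, null = null,
       p = (1 + sum(null <= observed)) / (n_perm + 1))
}

# median over bases of distance to nearest other base; positions given per
# contig (sorted within contig; cross-contig distances are undefined)
.median_nn_distance <- function(pos_by_contig) {
  d <- unlist(lapply(pos_by_contig, function(p) {
    if (length(p) < 2) return(numeric(0))
    p <- sort(p)
    gaps <- diff(p)
    pmin(c(Inf, gaps), c(gaps, Inf))
  }), use.names = FALSE)
  median(d)
}
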