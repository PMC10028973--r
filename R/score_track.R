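# ScoreTrack: per-base signed conservation scores (signed -log10 p under
# neutrality; positive = conservation, negative = acceleration). Missing
# bases, i.e. bases outside the aligned universe, are NA.

#' Construct a per-base score track
#'
#' @param scores named list, one numeric vector per contig; `NA` marks bases
#'   with no score (outside the universe). Vector length is the contig length.
#' @return object of class `ScoreTrack`.
#' @export
score_track <- function(scores) {
  stopifnot(is.list(scores), length(names(scores)) == length(scores))
  for (ct in names(scores)) {
    s <- scores[[ct]]
    if (!is.numeric(s)) stop("scores for ", ct, " must be numeric")
    if (any(!is.finite(s) & !is.na(s)))
      stop("non-missing scores must be finite (contig ", ct, ")")
  }
  structure(list(scores = scores), class = "ScoreTrack")
}

#' @export
print.ScoreTrack <- function(x, ...) {
  cat(sprintf("ScoreTrack: %d contig(s), %.0f bases (%.0f scored)\n",
              length(x$scores), track_length(x), universe_size(x)))
  invisible(x)
}

#' Contig lengths and universe size of a track
#'
#' The universe is the set of non-missing (scored) bases; it is the
#' denominator of every genome-fraction statistic in the package.
#'
#' @param track a `ScoreTrack`.
#' @return numeric scalar.
#' @export
universe_size <- function(track) {
  sum(vapply(track$scores, function(s) sum(!is.na(s)), numeric(1)))
}

#' @rdname universe_size
#' @export
track_length <- function(track) {
  sum(vapply(track$scores, length, integer(1)))
}

#' @rdname universe_size
#' @export
track_contig_lengths <- function(track) {
  vapply(track$scores, length, integer(1))
}

#' Score lookup at base positions
#' @param track a `ScoreTrack`.
#' @param contig contig name.
#' @param positions 0-based positions.
#' @return numeric vector (`NA` for missing bases).
#' @export
track_score <- function(track, contig, positions) {
  s <- track$scores[[contig]]
  if (is.null(s)) stop("unknown contig: ", contig)
  if (any(positions < 0 | positions >= length(s)))
    stop("position out of bounds on ", contig)
  s[positions + 1]
}

#' Read a bedGraph/wig score file into a per-base track
#'
#' Interval records are expanded to per-base scores; bases covered by no
#' record are missing. Overlapping records with conflicting values are an
#' error (equal-valued overlap is tolerated).
#'
#' @param path bedGraph or wig file (format inferred by [rtracklayer::import]).
#' @param contig_lengths named integer vector of contig lengths.
#' @param format passed to [rtracklayer::import]; default `"bedGraph"`.
#' @return a `ScoreTrack`.
#' @export
read_score_track <- function(path, contig_lengths, format = "bedGraph") {
  if (file.size(path) == 0) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- rtracklayer::import(path, format = format)
  }
  scores <- lapply(setNames(names(contig_lengths), names(contig_lengths)),
                   function(ct) rep(NA_real_, contig_lengths[[ct]]))
  if (length(gr) > 0) {
    ct <- as.character(GenomicRanges::seqnames(gr))
    bad <- !(ct %in% names(contig_lengths))
    if (any(bad)) stop("record on undeclared contig: ", ct[which(bad)[1]])
    s0 <- IRanges::start(gr) - 1L
    e0 <- IRanges::end(gr)
    oob <- e0 > contig_lengths[ct] | s0 < 0
    if (any(oob)) {
      i <- which(oob)[1]
      stop(sprintf("interval out of bounds: %s:%d-%d", ct[i], s0[i], e0[i]))
    }
    val <- S4Vectors::mcols(gr)$score
    for (i in seq_along(gr)) {
      idx <- (s0[i] + 1):e0[i]
      prev <- scores[[ct[i]]][idx]
      clash <- !is.na(prev) & prev != val[i]
      if (any(clash)) {
        stop(sprintf(
          "overlapping intervals with conflicting values at %s:%d (%g vs %g)",
          ct[i], s0[i] + which(clash)[1] - 1L, prev[clash][1], val[i]))
      }
      scores[[ct[i]]][idx] <- val[i]
    }
  }
  score_track(scores)
}

#' Write a score track as bedGraph
#'
#' Runs of equal consecutive scores are collapsed into single records; missing
#' bases produce no record. Values are written with full double precision so a
#' write-then-read round trip reproduces scores exactly.
#'
#' @param track a `ScoreTrack`.
#' @param path output file.
#' @export
write_score_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ct in names(track$scores)) {
    s <- track$scores[[ct]]
    if (!any(!is.na(s))) next
    r <- rle(ifelse(is.na(s), "NA", sprintf("%.17g", s)))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths # 0-based starts
    keep <- r$values != "NA"
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", ct, starts[keep], ends[keep],
                         r$values[keep]), con)
    }
  }
  invisible(path)
}
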