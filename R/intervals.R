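# ConstrainedSet: sorted disjoint 0-based half-open intervals per contig,
# with O(log n) count / membership / nearest queries.

# -- coordinate bridges: internal matrices are 0-based half-open; IRanges is
#    1-based closed. Conversion happens only inside these two helpers.
.mat_to_ir <- function(m) IRanges::IRanges(start = m[, 1] + 1L, end = m[, 2])

.ir_to_mat <- function(ir) {
  cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

.empty_mat <- function() cbind(start = integer(0), end = integer(0))

.normalize_mat <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(.empty_mat())
  stopifnot(all(m[, 2] > m[, 1]))
  # reduce() merges overlapping and adjacent intervals -> canonical form
  .ir_to_mat(IRanges::reduce(.mat_to_ir(m)))
}

#' Build a constrained-base set from intervals
#'
#' A `ConstrainedSet` holds, per contig, sorted disjoint 0-based half-open
#' intervals of constrained bases. Construction normalizes the input:
#' intervals are sorted and overlapping or adjacent intervals are merged, so
#' two sets covering the same bases compare equal.
#'
#' @param intervals named list (by contig) of two-column matrices or
#'   data.frames with columns `start`, `end` (0-based half-open), or a single
#'   data.frame with columns `contig`, `start`, `end`.
#' @return an object of class `ConstrainedSet`.
#' @export
constrained_set <- function(intervals = list()) {
  if (is.data.frame(intervals)) {
    intervals <- split(as.matrix(intervals[, c("start", "end")]),
                       intervals$contig)
    intervals <- lapply(intervals, function(v) matrix(v, ncol = 2,
      dimnames = list(NULL, c("start", "end"))))
  }
  ivs <- lapply(intervals, function(m) {
    if (is.null(m) || NROW(m) == 0) return(.empty_mat())
    m <- as.matrix(as.data.frame(m)[, 1:2])
    storage.mode(m) <- "integer"
    colnames(m) <- c("start", "end")
    .normalize_mat(m)
  })
  structure(list(intervals = ivs,
                 total = sum(vapply(ivs, function(m)
                   sum(as.numeric(m[, 2] - m[, 1])), numeric(1)))),
            class = "ConstrainedSet")
}

#' Constrained set from individual base positions
#'
#' @param contig contig name (scalar) or vector parallel to `positions`.
#' @param positions integer vector of 0-based base positions.
#' @return a `ConstrainedSet` with maximal runs of consecutive positions
#'   merged into intervals.
#' @export
constrained_set_from_positions <- function(contig, positions) {
  df <- data.frame(contig = contig, pos = as.integer(positions))
  ivs <- lapply(split(df$pos, df$contig), function(p) {
    .ir_to_mat(IRanges::reduce(IRanges::IRanges(p + 1L, p + 1L)))
  })
  constrained_set(ivs)
}

#' @export
print.ConstrainedSet <- function(x, ...) {
  cat(sprintf("ConstrainedSet: %d contig(s), %d interval(s), %.0f bases\n",
              length(x$intervals),
              sum(vapply(x$intervals, nrow, integer(1))), x$total))
  invisible(x)
}

#' Total constrained bases in a set
#' @param cs a `ConstrainedSet`.
#' @return numeric scalar.
#' @export
cs_total <- function(cs) cs$total

#' Constrained base positions on one contig
#' @param cs a `ConstrainedSet`.
#' @param contig contig name.
#' @return integer vector of 0-based positions (sorted).
#' @export
cs_positions <- function(cs, contig) {
  m <- cs$intervals[[contig]]
  if (is.null(m) || nrow(m) == 0) return(integer(0))
  unlist(lapply(seq_len(nrow(m)), function(i) seq.int(m[i, 1], m[i, 2] - 1L)),
         use.names = FALSE)
}

# coverage function: number of constrained bases at positions < x, vectorized
.cs_cov <- function(m, x) {
  if (nrow(m) == 0) return(numeric(length(x)))
  cum <- cumsum(as.numeric(m[, 2] - m[, 1]))
  i <- findInterval(x, m[, 1] + 1) # number of intervals starting before x
  out <- numeric(length(x))
  nz <- i > 0
  out[nz] <- cum[i[nz]] - pmax(0, m[i[nz], 2] - x[nz])
  out
}

#' Count constrained bases overlapping intervals (vectorized)
#'
#' @param cs a `ConstrainedSet`.
#' @param contig contig name (scalar).
#' @param start,end 0-based half-open query coordinates (vectors).
#' @return numeric vector of constrained-base counts.
#' @export
cs_count <- function(cs, contig, start, end) {
  m <- cs$intervals[[contig]]
  if (is.null(m)) return(numeric(length(start))) # no intervals there
  .cs_cov(m, end) - .cs_cov(m, start)
}

#' Is each base constrained?
#' @inheritParams cs_count
#' @param positions 0-based positions.
#' @return logical vector.
#' @export
cs_member <- function(cs, contig, positions) {
  cs_count(cs, contig, positions, positions + 1) > 0
}

#' Count and nearest-distance query on a constrained set
#'
#' Returns the number of constrained bases inside a 0-based half-open query
#' interval, and the distance from the interval's start position to the
#' nearest constrained base on the contig (0 when that base is itself
#' constrained, `Inf` when the contig carries no constrained bases).
#'
#' @param cs a `ConstrainedSet`.
#' @param contig contig name.
#' @param start,end query interval, 0-based half-open; `end` defaults to
#'   `start + 1` (point query).
#' @return list with elements `count` and `nearest`.
#' @export
region_query <- function(cs, contig, start, end = start + 1) {
  if (!(contig %in% names(cs$intervals)) && length(cs$intervals) > 0)
    stop("unknown contig: ", contig)
  list(count = as.numeric(cs_count(cs, contig, start, end)),
       nearest = .cs_nearest(cs, contig, start))
}

# distance from a position to the nearest constrained base (Inf when the
# contig carries none); permissive about absent contigs
.cs_nearest <- function(cs, contig, q) {
  m <- cs$intervals[[contig]]
  if (is.null(m) || nrow(m) == 0) return(Inf)
  if (cs_member(cs, contig, q)) return(0)
  i <- findInterval(q, m[, 1]) # last interval with start <= q
  cand <- c(if (i >= 1) m[i, 2] - 1L, if (i < nrow(m)) m[i + 1L, 1])
  min(abs(q - cand))
}

# pairwise intersect / union sizes over shared contig universe
.cs_pair_sizes <- function(a, b) {
  contigs <- union(names(a$intervals), names(b$intervals))
  inter <- 0; uni <- 0
  for (ct in contigs) {
    ma <- a$intervals[[ct]]; mb <- b$intervals[[ct]]
    la <- if (is.null(ma)) 0 else sum(as.numeric(ma[, 2] - ma[, 1]))
    lb <- if (is.null(mb)) 0 else sum(as.numeric(mb[, 2] - mb[, 1]))
    ii <- if (is.null(ma) || is.null(mb)) 0 else
      sum(as.numeric(IRanges::width(IRanges::intersect(.mat_to_ir(ma),
                                                       .mat_to_ir(mb)))))
    inter <- inter + ii
    uni <- uni + la + lb - ii
  }
  c(intersection = inter, union = uni)
}

#' Jaccard index between two constrained-base sets
#'
#' Base-level Jaccard index |A intersect B| / |A union B|. Defined as 0 when
#' both sets are empty.
#'
#' @param a,b `ConstrainedSet` objects over the same contig universe.
#' @return numeric in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  sz <- .cs_pair_sizes(a, b)
  if (sz[["union"]] == 0) return(0)
  unname(sz[["intersection"]] / sz[["union"]])
}

# set operations used by downstream modules ---------------------------------

.cs_map <- function(a, b, fun) {
  contigs <- union(names(a$intervals), names(b$intervals))
  out <- lapply(setNames(contigs, contigs), function(ct) {
    ma <- a$intervals[[ct]]; mb <- b$intervals[[ct]]
    ia <- if (is.null(ma)) IRanges::IRanges() else .mat_to_ir(ma)
    ib <- if (is.null(mb)) IRanges::IRanges() else .mat_to_ir(mb)
    .ir_to_mat(fun(ia, ib))
  })
  constrained_set(out)
}

#' @rdname cs_setops
#' @export
cs_intersect <- function(a, b) .cs_map(a, b, IRanges::intersect)

#' Interval-set operations
#'
#' Base-level intersection, union and difference of two interval sets,
#' returned in canonical (normalized) form.
#'
#' @param a,b `ConstrainedSet` objects.
#' @return a `ConstrainedSet`.
#' @name cs_setops
#' @export
cs_union <- function(a, b) .cs_map(a, b, IRanges::union)

#' @rdname cs_setops
#' @export
cs_setdiff <- function(a, b) .cs_map(a, b, IRanges::setdiff)

#' Constrained set as a BED-like data.frame
#' @param cs a `ConstrainedSet`.
#' @return data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open).
#' @export
cs_to_df <- function(cs) {
  rows <- lapply(names(cs$intervals), function(ct) {
    m <- cs$intervals[[ct]]
    if (nrow(m) == 0) return(NULL)
    data.frame(contig = ct, start = m[, 1], end = m[, 2])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(contig = character(0), start = integer(0),
                               end = integer(0)) else out
}

#' Write a constrained set as BED3
#' @param cs a `ConstrainedSet`.
#' @param path output file.
#' @export
write_bed3 <- function(cs, path) {
  df <- cs_to_df(cs)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ file into a constrained set
#' @param path BED file (0-based half-open, no header; track/browser lines
#'   are skipped).
#' @return a `ConstrainedSet`.
#' @export
read_bed3 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                   start = IRanges::start(gr) - 1L, end = IRanges::end(gr))
  constrained_set(df)
}
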