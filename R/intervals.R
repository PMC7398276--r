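# Interval algebra on BED-style tables (chrom, start, end; 0-based half-open).
# All set operations go through GenomicRanges; these helpers centralise the
# 0-based <-> 1-based conversion so it happens in exactly one place.

#' Construct a BED-style interval table
#'
#' @param chrom character vector of chromosome names
#' @param start 0-based inclusive starts
#' @param end exclusive ends
#' @param ... further columns, recycled as in [data.table::data.table()]
#' @return a `data.table` with at least `chrom`, `start`, `end`
#' @export
bed <- function(chrom = character(), start = integer(), end = integer(), ...) {
  dt <- data.table(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end), ...)
  validate_bed(dt)
  dt
}

validate_bed <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) && any(x$start < 0 | x$start >= x$end))
    stop("invalid interval: need 0 <= start < end")
  invisible(x)
}

empty_bed <- function() data.table(chrom = character(),
                                   start = numeric(), end = numeric())

as_granges <- function(x) {
  validate_bed(x)
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

as_bed <- function(gr) {
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = as.numeric(GenomicRanges::start(gr)) - 1,
             end = as.numeric(GenomicRanges::end(gr)))
}

#' Merge intervals lying within `gap` bp of each other
#'
#' @param x BED table
#' @param gap maximum gap (bp) bridged by a merge; 0 merges only
#'   touching/overlapping intervals
#' @return merged BED table, sorted
#' @export
bed_reduce <- function(x, gap = 0) {
  if (!nrow(x)) return(empty_bed())
  as_bed(GenomicRanges::reduce(as_granges(x), min.gapwidth = gap + 1))
}

#' @export
bed_intersect <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(empty_bed())
  as_bed(suppressWarnings(GenomicRanges::intersect(as_granges(a), as_granges(b),
                                  ignore.strand = TRUE)))
}

#' @export
bed_setdiff <- function(a, b) {
  if (!nrow(a)) return(empty_bed())
  if (!nrow(b)) return(bed_reduce(a))
  as_bed(suppressWarnings(GenomicRanges::setdiff(as_granges(a), as_granges(b),
                                ignore.strand = TRUE)))
}

#' Does each interval of `x` overlap any interval of `targets`?
#' @export
bed_overlaps_any <- function(x, targets) {
  if (!nrow(x)) return(logical(0))
  if (!nrow(targets)) return(rep(FALSE, nrow(x)))
  suppressWarnings(
    GenomicRanges::countOverlaps(as_granges(x), as_granges(targets))) > 0
}

#' Total bases of `x` covered by `targets` (per interval of `x`)
#' @export
bed_overlap_bases <- function(x, targets) {
  if (!nrow(x)) return(numeric(0))
  out <- numeric(nrow(x))
  if (!nrow(targets)) return(out)
  gx <- as_granges(x)
  gt <- GenomicRanges::reduce(as_granges(targets))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gx, gt))
  if (length(hits)) {
    ov <- IRanges::pintersect(gx[S4Vectors::queryHits(hits)],
                              gt[S4Vectors::subjectHits(hits)])
    w <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
    out[as.integer(names(w))] <- as.numeric(w)
  }
  out
}

#' Base-level Jaccard index of two interval sets
#' @export
jaccard_bases <- function(a, b) {
  a <- bed_reduce(a); b <- bed_reduce(b)
  inter <- sum(bed_intersect(a, b)[, end - start])
  union <- sum(bed_reduce(rbind(a[, .(chrom, start, end)],
                                b[, .(chrom, start, end)]))[, end - start])
  if (union == 0) return(NA_real_)
  inter / union
}

# index of the interval in `x` containing each 1-based point, NA if none.
# `x` must be disjoint.
point_interval_index <- function(chrom, pos, x) {
  if (!nrow(x)) return(rep(NA_integer_, length(pos)))
  gp <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gp, as_granges(x), select = "first"))
  as.integer(hits)
}

#' Fraction of each planted interval covered by calls, and vice versa
#'
#' A planted feature counts as recovered when calls cover at least
#' `min_frac` of its bases; a call is a true positive when planted features
#' cover at least `min_frac` of it.
#'
#' @param calls,truth BED tables
#' @param min_frac minimum covered fraction (default 0.5)
#' @return list with `recall`, `precision`, per-interval covered fractions
#' @export
domain_recovery <- function(calls, truth, min_frac = 0.5) {
  tf <- if (nrow(truth)) bed_overlap_bases(truth, calls) / (truth$end - truth$start) else numeric(0)
  cf <- if (nrow(calls)) bed_overlap_bases(calls, truth) / (calls$end - calls$start) else numeric(0)
  list(recall = if (length(tf)) mean(tf >= min_frac) else NA_real_,
       precision = if (length(cf)) mean(cf >= min_frac) else NA_real_,
       truth_covered = tf, call_covered = cf)
}
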