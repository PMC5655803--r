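#' Construct an interval set
#'
#' An `interval_set` is a data frame of strand-aware genomic intervals on one
#' named genome, in 0-based half-open (BED) coordinates. It is the common
#' currency of every stage of the pipeline: deletions, repeats, peaks, exons,
#' promoters and alignment-block sides are all interval sets.
#'
#' @param chrom character vector of sequence names.
#' @param start,end integer vectors; 0-based half-open, `end > start`.
#' @param strand character vector in `+`, `-`, `.` (recycled).
#' @param label optional character vector of free-text labels (recycled).
#' @param genome single string naming the genome the coordinates live on.
#' @return A data frame of class `interval_set` with columns
#'   `chrom`, `start`, `end`, `strand`, `label` and a `genome` attribute.
#' @examples
#' x <- interval_set("chr1", c(0, 30), c(10, 40), genome = "L")
#' total_bp(x)
#' @export
interval_set <- function(chrom, start, end, strand = ".", label = NA_character_,
                         genome = "genome") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (length(start) != n || length(end) != n || length(chrom) != n)
    stop("chrom, start, end must have equal length (chrom may be scalar)")
  if (n > 0) {
    if (any(is.na(start)) || any(is.na(end))) stop("NA coordinates")
    if (any(start < 0)) stop("start must be >= 0")
    bad <- which(end <= start)
    if (length(bad))
      stop("end <= start at interval ", bad[1], " (", chrom[bad[1]], ":",
           start[bad[1]], "-", end[bad[1]], ")")
  }
  x <- data.frame(chrom = as.character(chrom), start = start, end = end,
                  strand = rep_len(as.character(strand), n),
                  label = rep_len(as.character(label), n),
                  stringsAsFactors = FALSE)
  attr(x, "genome") <- genome
  class(x) <- c("interval_set", "data.frame")
  x
}

#' @export
print.interval_set <- function(x, ...) {
  cat("interval_set on genome '", genome_of(x), "': ", nrow(x),
      " intervals, ", format(total_bp(x), big.mark = ","), " bp covered\n",
      sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Genome name of an interval or alignment object
#' @param x an `interval_set`.
#' @return The genome identifier string.
#' @export
genome_of <- function(x) attr(x, "genome")

## keep class/attr through subsetting
#' @export
`[.interval_set` <- function(x, i, j, ...) {
  g <- attr(x, "genome")
  out <- NextMethod()
  if (is.data.frame(out) && all(c("chrom", "start", "end") %in% names(out))) {
    attr(out, "genome") <- g
    class(out) <- c("interval_set", "data.frame")
  }
  out
}

as_interval_set <- function(df, genome) {
  interval_set(df$chrom, df$start, df$end,
               strand = if (is.null(df$strand)) "." else df$strand,
               label = if (is.null(df$label)) NA_character_ else df$label,
               genome = genome)
}

## conversions to/from Bioconductor ranges (1-based closed internally)
as_granges <- function(x) {
  if (nrow(x) == 0)
    return(GenomicRanges::GRanges())
  s <- x$strand
  s[!s %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(seqnames = x$chrom,
                         ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
                         strand = s)
}

from_granges <- function(gr, genome, label = NA_character_) {
  if (length(gr) == 0) return(interval_set(character(), numeric(), numeric(), genome = genome))
  s <- as.character(BiocGenerics::strand(gr))
  s[s == "*"] <- "."
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               BiocGenerics::start(gr) - 1, BiocGenerics::end(gr),
               strand = s, label = label, genome = genome)
}

#' Merge intervals, closing gaps up to a maximum size
#'
#' Unions all intervals whose gap is at most `max_gap` bp (the deletion
#' caller uses 10 bp, the merge distance applied to candidate deleted
#' regions). Strand is ignored; output is sorted and non-overlapping.
#'
#' @param x an `interval_set`.
#' @param max_gap non-negative integer; intervals separated by `<= max_gap`
#'   bp are joined. `0` unions overlapping/adjacent intervals only.
#' @return A sorted, non-overlapping `interval_set`.
#' @export
merge_intervals <- function(x, max_gap = 0) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  if (nrow(x) <= 1) return(sort_intervals(x))
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = max_gap + 1,
                              ignore.strand = TRUE)
  from_granges(BiocGenerics::sort(gr), genome_of(x))
}

sort_intervals <- function(x) {
  if (nrow(x) <= 1) return(x)
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

#' Total basepairs covered by an interval set
#' @param x an `interval_set`; overlaps are counted once (union semantics).
#' @return Numeric scalar, bp.
#' @export
total_bp <- function(x) {
  if (nrow(x) == 0) return(0)
  sum(as.numeric(BiocGenerics::width(GenomicRanges::reduce(as_granges(x), ignore.strand = TRUE))))
}

#' Fraction of each query interval covered by a set
#'
#' Covered bp of each interval in `a` by the union of `set`, divided by the
#' interval length. Used for the ">50% repeat overlap" and the ">25% assembly
#' gap" filters.
#'
#' @param a query `interval_set` (or single-row subset).
#' @param set covering `interval_set` on the same genome.
#' @return Numeric vector in `[0, 1]`, one value per row of `a`.
#' @export
overlap_fraction <- function(a, set) {
  if (nrow(a) == 0) return(numeric())
  idx <- coverage_index(set)
  covered_bp(idx, a$chrom, a$start, a$end) / (a$end - a$start)
}

## Prefix-sum coverage index: O(log m) covered-bp lookups, used in the
## randomization loop where building ranges objects per shuffle would dominate.
coverage_index <- function(set) {
  m <- merge_intervals(set, 0)
  split(m[c("start", "end")], m$chrom)
}

covered_bp <- function(idx, chrom, qstart, qend) {
  out <- numeric(length(chrom))
  for (cn in unique(chrom)) {
    iv <- idx[[cn]]
    sel <- which(chrom == cn)
    if (is.null(iv) || nrow(iv) == 0) next
    cum <- c(0, cumsum(iv$end - iv$start))
    F <- function(p) {
      i <- findInterval(p, iv$start)
      v <- cum[i + 1]
      inside <- i >= 1
      if (any(inside)) {
        ii <- i[inside]
        v[inside] <- cum[ii] + pmin(pmax(p[inside] - iv$start[ii], 0),
                                    iv$end[ii] - iv$start[ii])
      }
      v
    }
    out[sel] <- F(qend[sel]) - F(qstart[sel])
  }
  out
}

#' Subtract one interval set from another
#'
#' Returns the parts of `x` not covered by `y` (strand-blind). The deletion
#' caller uses this to find sequence aligned to the outgroup but not to the
#' sister subgenome.
#' @param x,y `interval_set`s on the same genome.
#' @return An `interval_set`.
#' @export
setdiff_intervals <- function(x, y) {
  if (nrow(x) == 0) return(x)
  if (nrow(y) == 0) return(merge_intervals(x, 0))
  gr <- harmonize(as_granges(x), as_granges(y))
  from_granges(BiocGenerics::sort(GenomicRanges::setdiff(gr[[1]], gr[[2]],
                                                         ignore.strand = TRUE)),
               genome_of(x))
}

## shared seqlevels so cross-set operations do not warn on disjoint chroms
harmonize <- function(gx, gy) {
  gx <- GenomicRanges::reduce(gx, ignore.strand = TRUE)
  gy <- GenomicRanges::reduce(gy, ignore.strand = TRUE)
  lv <- union(GenomeInfoDb::seqlevels(gx), GenomeInfoDb::seqlevels(gy))
  GenomeInfoDb::seqlevels(gx) <- lv
  GenomeInfoDb::seqlevels(gy) <- lv
  list(gx, gy)
}

#' Intersect two interval sets
#' @param x,y `interval_set`s on the same genome.
#' @return An `interval_set` covering the bp present in both unions.
#' @export
intersect_intervals <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0)
    return(interval_set(character(), numeric(), numeric(), genome = genome_of(x)))
  gr <- harmonize(as_granges(x), as_granges(y))
  from_granges(BiocGenerics::sort(GenomicRanges::intersect(gr[[1]], gr[[2]],
                                                           ignore.strand = TRUE)),
               genome_of(x))
}

## indices of rows in `a` overlapping any interval of `b` by >= min_bp
overlaps_any <- function(a, b, min_bp = 1) {
  if (nrow(a) == 0 || nrow(b) == 0) return(logical(nrow(a)))
  overlap_fraction(a, b) * (a$end - a$start) >= min_bp
}
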