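#' Construct an alignment set
#'
#' An `alignment_set` holds pairwise homology blocks between two named
#' genomes. Each block links an interval on genome A to an interval on
#' genome B with an identity fraction, a strand (orientation of B relative
#' to A) and a reciprocality flag. Blocks are consumed from a whole-genome
#' aligner; the package never computes them (except synthetically).
#'
#' @param blocks data frame with columns `a_chrom`, `a_start`, `a_end`,
#'   `b_chrom`, `b_start`, `b_end`, `strand`, `identity`, `reciprocal`.
#'   Coordinates are 0-based half-open on the forward strand of each genome.
#' @param genome_a,genome_b genome identifiers for the two sides.
#' @return A data frame of class `alignment_set` with attributes
#'   `genome_a` and `genome_b`.
#' @export
alignment_set <- function(blocks, genome_a, genome_b) {
  need <- c("a_chrom", "a_start", "a_end", "b_chrom", "b_start", "b_end",
            "strand", "identity", "reciprocal")
  miss <- setdiff(need, names(blocks))
  if (length(miss)) stop("missing block columns: ", paste(miss, collapse = ", "))
  blocks <- as.data.frame(blocks)[need]
  if (nrow(blocks)) {
    if (any(blocks$a_end <= blocks$a_start) || any(blocks$b_end <= blocks$b_start))
      stop("zero- or negative-length block interval")
    if (any(blocks$identity < 0 | blocks$identity > 1))
      stop("identity outside [0,1]")
    if (!all(blocks$strand %in% c("+", "-"))) stop("block strand must be + or -")
  }
  attr(blocks, "genome_a") <- genome_a
  attr(blocks, "genome_b") <- genome_b
  class(blocks) <- c("alignment_set", "data.frame")
  blocks
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("alignment_set ", attr(x, "genome_a"), " <-> ", attr(x, "genome_b"),
      ": ", nrow(x), " blocks (", sum(x$reciprocal), " reciprocal)\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' @export
`[.alignment_set` <- function(x, i, j, ...) {
  ga <- attr(x, "genome_a"); gb <- attr(x, "genome_b")
  out <- NextMethod()
  if (is.data.frame(out) && all(c("a_start", "b_start") %in% names(out))) {
    attr(out, "genome_a") <- ga
    attr(out, "genome_b") <- gb
    class(out) <- c("alignment_set", "data.frame")
  }
  out
}

aln_side <- function(aln, genome) {
  if (genome == attr(aln, "genome_a")) "a"
  else if (genome == attr(aln, "genome_b")) "b"
  else stop("genome '", genome, "' is not part of this alignment (",
            attr(aln, "genome_a"), ", ", attr(aln, "genome_b"), ")")
}

#' Block footprints on one genome of an alignment set
#'
#' @param aln an `alignment_set`.
#' @param genome which side to extract.
#' @param reciprocal_only keep only blocks flagged reciprocal.
#' @return An `interval_set` of the block intervals on `genome`.
#' @export
blocks_on <- function(aln, genome, reciprocal_only = FALSE) {
  side <- aln_side(aln, genome)
  b <- as.data.frame(aln)
  if (reciprocal_only) b <- b[b$reciprocal, , drop = FALSE]
  pre <- paste0(side, "_")
  interval_set(b[[paste0(pre, "chrom")]], b[[paste0(pre, "start")]],
               b[[paste0(pre, "end")]], genome = genome)
}

#' Project intervals through an alignment onto the other genome
#'
#' Each query interval is clipped to every overlapping block and mapped
#' proportionally by offset within the block. Projection through a
#' minus-strand block reverses orientation but reports the target interval
#' in forward coordinates. An empty result is valid (nothing aligned).
#'
#' @param x `interval_set` on one of the two aligned genomes.
#' @param aln an `alignment_set`.
#' @param target genome identifier of the destination side.
#' @param reciprocal_only use only reciprocal blocks.
#' @return An `interval_set` on `target`; labels carry the query label (or
#'   `chrom:start-end`) so fragments can be traced back.
#' @export
project_intervals <- function(x, aln, target, reciprocal_only = FALSE) {
  tside <- aln_side(aln, target)
  qside <- if (tside == "a") "b" else "a"
  qgen <- attr(aln, paste0("genome_", qside))
  if (!is.null(genome_of(x)) && genome_of(x) != qgen)
    stop("query intervals are on '", genome_of(x), "', expected '", qgen, "'")
  b <- as.data.frame(aln)
  if (reciprocal_only) b <- b[b$reciprocal, , drop = FALSE]
  out <- vector("list", nrow(x))
  if (nrow(x) == 0 || nrow(b) == 0)
    return(interval_set(character(), numeric(), numeric(), genome = target))
  qc <- b[[paste0(qside, "_chrom")]]; qs <- b[[paste0(qside, "_start")]]
  qe <- b[[paste0(qside, "_end")]]
  tc <- b[[paste0(tside, "_chrom")]]; ts <- b[[paste0(tside, "_start")]]
  te <- b[[paste0(tside, "_end")]]
  for (i in seq_len(nrow(x))) {
    hit <- which(qc == x$chrom[i] & qs < x$end[i] & qe > x$start[i])
    if (!length(hit)) next
    cs <- pmax(x$start[i], qs[hit]); ce <- pmin(x$end[i], qe[hit])
    r <- (te[hit] - ts[hit]) / (qe[hit] - qs[hit])
    plus <- b$strand[hit] == "+"
    os <- ifelse(plus, ts[hit] + round((cs - qs[hit]) * r),
                        ts[hit] + round((qe[hit] - ce) * r))
    oe <- ifelse(plus, ts[hit] + round((ce - qs[hit]) * r),
                        ts[hit] + round((qe[hit] - cs) * r))
    keep <- oe > os
    if (!any(keep)) next
    lab <- if (is.na(x$label[i]))
      paste0(x$chrom[i], ":", x$start[i], "-", x$end[i]) else x$label[i]
    out[[i]] <- data.frame(chrom = tc[hit][keep], start = os[keep], end = oe[keep],
                           strand = ".", label = lab, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(interval_set(character(), numeric(), numeric(), genome = target))
  df <- do.call(rbind, out)
  sort_intervals(as_interval_set(df, target))
}
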