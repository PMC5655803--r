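## Deletion calling from three pairwise alignment sets.
##
## A deletion "from" genome Y is evidenced on the retained genome X as a
## region that reciprocally aligns to the outgroup but not to Y, whose
## 500-bp flanks both align reciprocally to Y, and whose residual inter-flank
## gap on Y is small: at most 4 kb and at least three times shorter than the
## retained span.

#' Candidate deleted-region footprints on one subgenome
#'
#' Regions of `subgenome` covered by reciprocal blocks to the outgroup with
#' zero reciprocal coverage to the sister subgenome, merged within
#' `merge_gap` bp, minus candidates overlapping assembly gaps (N-runs of at
#' least `min_nrun` bp) for more than `gap_overlap_max` of their length.
#'
#' @param aln_sister `alignment_set` between the two subgenomes.
#' @param aln_outgroup `alignment_set` between `subgenome` and the outgroup.
#' @param subgenome genome identifier of the retained side.
#' @param merge_gap merge distance, bp.
#' @param genome optional `DNAStringSet` of `subgenome` for N-run filtering;
#'   `NULL` skips the filter.
#' @param gap_overlap_max maximum tolerated N-run overlap fraction.
#' @param min_nrun minimum N-run length treated as an assembly gap.
#' @return An `interval_set` of candidates; attribute `n_gap_filtered`
#'   counts candidates removed by the N-run filter.
#' @export
candidate_regions <- function(aln_sister, aln_outgroup, subgenome,
                              merge_gap = 10, genome = NULL,
                              gap_overlap_max = 0.25, min_nrun = 10) {
  if (merge_gap < 0) stop("merge_gap must be >= 0")
  cov_t <- blocks_on(aln_outgroup, subgenome, reciprocal_only = TRUE)
  cov_s <- blocks_on(aln_sister, subgenome, reciprocal_only = TRUE)
  cand <- merge_intervals(setdiff_intervals(cov_t, cov_s), merge_gap)
  n_filtered <- 0
  if (!is.null(genome) && nrow(cand)) {
    nr <- n_runs(genome, min_nrun, genome_id = genome_of(cand))
    if (nrow(nr)) {
      frac <- overlap_fraction(cand, nr)
      n_filtered <- sum(frac > gap_overlap_max)
      cand <- cand[frac <= gap_overlap_max, , drop = FALSE]
    }
  }
  attr(cand, "n_gap_filtered") <- n_filtered
  cand
}

## maximal N-runs of length >= min_len as an interval set
n_runs <- function(genome, min_len = 10, genome_id = "genome") {
  rows <- list()
  for (nm in names(genome)) {
    m <- gregexpr(sprintf("N{%d,}", min_len), as.character(genome[[nm]]))[[1]]
    if (m[1] == -1) next
    rows[[length(rows) + 1]] <- data.frame(
      chrom = nm, start = as.numeric(m) - 1,
      end = as.numeric(m) - 1 + attr(m, "match.length"))
  }
  if (!length(rows))
    return(interval_set(character(), numeric(), numeric(), genome = genome_id))
  df <- do.call(rbind, rows)
  interval_set(df$chrom, df$start, df$end, genome = genome_id)
}

#' Call deletions from candidate regions
#'
#' For each candidate on the retained genome, both `flank`-bp flanks must
#' contain at least one reciprocal block to the sister subgenome overlapping
#' the flank by `min_flank_overlap` bp. The residual gap between the
#' sister-side projections of the two flank anchors is measured; a call is
#' emitted iff `size_gap <= max_gap` and
#' `size_retained >= min_ratio * size_gap`. The flank anchor is the block
#' nearest the candidate on each side (ties broken by the longer block).
#'
#' @param candidates `interval_set` from [candidate_regions()].
#' @param aln_sister `alignment_set` between the two subgenomes.
#' @param flank flank width, bp.
#' @param max_gap maximum residual sister-side gap, bp.
#' @param min_ratio minimum retained-to-gap size ratio.
#' @param min_flank_overlap minimum block-flank overlap, bp.
#' @return A data frame of class `deletion_calls`: `side` (e.g. `"LdS"` =
#'   deleted from S, retained on L), retained coordinates, sister gap
#'   coordinates, sizes and flank anchors. Attribute `dropped` tabulates
#'   rejection reasons.
#' @export
call_deletions <- function(candidates, aln_sister, flank = 500,
                           max_gap = 4000, min_ratio = 3,
                           min_flank_overlap = 50) {
  retained <- genome_of(candidates)
  side_ret <- aln_side(aln_sister, retained)
  deleted <- attr(aln_sister, if (side_ret == "a") "genome_b" else "genome_a")
  b <- as.data.frame(aln_sister)
  b <- b[b$reciprocal, , drop = FALSE]
  pre_r <- paste0(side_ret, "_")
  pre_d <- paste0(if (side_ret == "a") "b" else "a", "_")
  rc <- b[[paste0(pre_r, "chrom")]]; rs <- b[[paste0(pre_r, "start")]]
  re <- b[[paste0(pre_r, "end")]]
  dc <- b[[paste0(pre_d, "chrom")]]; ds <- b[[paste0(pre_d, "start")]]
  de <- b[[paste0(pre_d, "end")]]
  dropped <- c(no_left_flank = 0, no_right_flank = 0, cross_chrom = 0,
               inverted = 0, gap_too_large = 0, ratio_too_small = 0)
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    cs <- candidates$start[i]; ce <- candidates$end[i]
    cn <- candidates$chrom[i]
    lf0 <- max(0, cs - flank)
    on_chrom <- which(rc == cn)
    ov_l <- pmin(re[on_chrom], cs) - pmax(rs[on_chrom], lf0)
    left <- on_chrom[ov_l >= min_flank_overlap]
    if (!length(left)) { dropped["no_left_flank"] <- dropped["no_left_flank"] + 1; next }
    ov_r <- pmin(re[on_chrom], ce + flank) - pmax(rs[on_chrom], ce)
    right <- on_chrom[ov_r >= min_flank_overlap]
    if (!length(right)) { dropped["no_right_flank"] <- dropped["no_right_flank"] + 1; next }
    ## nearest block each side; ties -> longer block
    lsel <- left[order(-re[left], -(re[left] - rs[left]))][1]
    rsel <- right[order(rs[right], -(re[right] - rs[right]))][1]
    if (dc[lsel] != dc[rsel] || b$strand[lsel] != "+" || b$strand[rsel] != "+") {
      dropped["cross_chrom"] <- dropped["cross_chrom"] + 1; next
    }
    gap_s <- de[lsel]; gap_e <- ds[rsel]
    if (gap_e < gap_s) { dropped["inverted"] <- dropped["inverted"] + 1; next }
    size_gap <- gap_e - gap_s
    size_ret <- ce - cs
    if (size_gap > max_gap) { dropped["gap_too_large"] <- dropped["gap_too_large"] + 1; next }
    if (size_ret < min_ratio * size_gap) {
      dropped["ratio_too_small"] <- dropped["ratio_too_small"] + 1; next
    }
    out[[length(out) + 1]] <- data.frame(
      side = paste0(retained, "d", deleted),
      retained_chrom = cn, retained_start = cs, retained_end = ce,
      size_retained = size_ret,
      gap_chrom = dc[lsel], gap_start = gap_s, gap_end = gap_e,
      size_gap = size_gap,
      left_anchor_start = rs[lsel], left_anchor_end = re[lsel],
      right_anchor_start = rs[rsel], right_anchor_end = re[rsel],
      stringsAsFactors = FALSE)
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(side = character(), retained_chrom = character(),
               retained_start = numeric(), retained_end = numeric(),
               size_retained = numeric(), gap_chrom = character(),
               gap_start = numeric(), gap_end = numeric(), size_gap = numeric(),
               left_anchor_start = numeric(), left_anchor_end = numeric(),
               right_anchor_start = numeric(), right_anchor_end = numeric(),
               stringsAsFactors = FALSE)
  attr(calls, "retained_genome") <- retained
  attr(calls, "deleted_genome") <- deleted
  attr(calls, "dropped") <- dropped
  class(calls) <- c("deletion_calls", "data.frame")
  calls
}

#' @export
print.deletion_calls <- function(x, ...) {
  cat("deletion_calls: ", nrow(x), " calls (retained on ",
      attr(x, "retained_genome"), ", deleted from ",
      attr(x, "deleted_genome"), ")\n", sep = "")
  dr <- attr(x, "dropped")
  if (!is.null(dr) && sum(dr) > 0)
    cat("dropped candidates:",
        paste(names(dr)[dr > 0], dr[dr > 0], sep = "=", collapse = ", "), "\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Retained regions of a call set as an interval set
#' @param calls a `deletion_calls` data frame.
#' @return An `interval_set` on the retained genome.
#' @export
retained_regions <- function(calls) {
  interval_set(calls$retained_chrom, calls$retained_start, calls$retained_end,
               label = calls$side, genome = attr(calls, "retained_genome"))
}

#' Deletion size spectrum and per-bin side ratio
#'
#' Bins deletion sizes (retained-side span) into log-spaced bins and reports
#' per-side counts and the count ratio between the two sides per bin
#' (`Inf` with a flag where the denominator side is empty).
#'
#' @param calls either a single `deletion_calls` frame carrying one side, or
#'   a list of two from the two subgenomes (rbind-ed).
#' @param n_bins number of log-spaced bins.
#' @param numerator,denominator side labels for the ratio; defaults to the
#'   two sides present sorted alphabetically (e.g. LdS / SdL).
#' @return list: `bins` data frame (`lo`, `hi`, per-side counts, `ratio`,
#'   `ratio_defined`), `overall_ratio`.
#' @export
deletion_size_spectrum <- function(calls, n_bins = 8, numerator = NULL,
                                   denominator = NULL) {
  if (is.list(calls) && !is.data.frame(calls))
    calls <- do.call(rbind, lapply(calls, as.data.frame))
  if (nrow(calls) == 0) stop("no calls")
  sides <- sort(unique(calls$side))
  if (is.null(numerator)) numerator <- sides[1]
  if (is.null(denominator)) denominator <- sides[length(sides)]
  sz <- calls$size_retained
  brk <- exp(seq(log(max(1, min(sz))), log(max(sz) + 1), length.out = n_bins + 1))
  brk[1] <- min(sz); brk[n_bins + 1] <- max(sz) + 1
  bin <- cut(sz, brk, right = FALSE, include.lowest = TRUE)
  tab <- table(bin, factor(calls$side, levels = sides))
  num <- as.numeric(tab[, numerator]); den <- as.numeric(tab[, denominator])
  bins <- data.frame(lo = brk[-(n_bins + 1)], hi = brk[-1])
  for (s in sides) bins[[s]] <- as.numeric(tab[, s])
  bins$ratio <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, NA_real_))
  bins$ratio_defined <- den > 0
  n_num <- sum(calls$side == numerator); n_den <- sum(calls$side == denominator)
  list(bins = bins,
       overall_ratio = if (n_den > 0) n_num / n_den else Inf,
       sides = c(numerator = numerator, denominator = denominator))
}
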