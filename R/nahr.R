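## Non-allelic homologous recombination signature: retained regions overlap
## long repeats, and their flanks resemble each other.

#' Repeat length enrichment in retained regions
#'
#' Collects lengths of repeat elements overlapping the retained regions of
#' called deletions and compares them with repeat elements overlapping
#' length-matched random regions (same count, chromosome and sizes, drawn by
#' per-chromosome shuffling). Reports the mean length ratio and a
#' Mann-Whitney p on the two length samples.
#'
#' @param retained `interval_set` of retained regions ([retained_regions()]).
#' @param repeats `interval_set` of annotated repeat elements on the same
#'   genome.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param n_random random region sets to pool (1 matches the region count).
#' @param seed optional integer seed.
#' @return list: `mean_length_retained`, `mean_length_random`, `ratio`,
#'   `mann_whitney_p`, sample sizes; `ratio` is `NA` with `flag` set when
#'   either sample is empty.
#' @export
repeat_length_ratio <- function(retained, repeats, chrom_sizes, n_random = 1,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(retained) == 0) stop("empty retained set")
  lens_at <- function(regions) {
    hit <- overlaps_any(repeats, regions, min_bp = 1)
    (repeats$end - repeats$start)[hit]
  }
  obs <- lens_at(retained)
  rnd <- unlist(lapply(seq_len(n_random), function(i)
    lens_at(shuffle_within_chromosome(retained, chrom_sizes))))
  if (!length(obs) || !length(rnd))
    return(list(mean_length_retained = NA_real_, mean_length_random = NA_real_,
                ratio = NA_real_, mann_whitney_p = NA_real_,
                n_retained = length(obs), n_random = length(rnd),
                flag = "no overlapping repeats in one of the samples"))
  mw <- mann_whitney_u(obs, rnd)
  list(mean_length_retained = mean(obs), mean_length_random = mean(rnd),
       ratio = mean(obs) / mean(rnd), mann_whitney_p = mw$p,
       n_retained = length(obs), n_random = length(rnd), flag = NA_character_)
}

#' Global alignment identity of two DNA sequences
#'
#' Needleman-Wunsch global alignment (affine gaps) with pinned default
#' scoring; identity = matching columns / alignment columns. Identity values
#' are scoring-dependent, so the scoring is part of the result metadata.
#'
#' @param seq_a,seq_b non-empty DNA strings (IUPAC `N` allowed).
#' @param match,mismatch,gap_open,gap_extend scoring (penalties negative).
#' @return identity fraction in `[0, 1]` with attribute `scoring`.
#' @export
global_align_identity <- function(seq_a, seq_b, match = 1, mismatch = -1,
                                  gap_open = -2, gap_extend = -1) {
  if (!nchar(seq_a) || !nchar(seq_b)) stop("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(seq_a)), Biostrings::DNAString(toupper(seq_b)),
    type = "global", substitutionMatrix = mat,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  out <- sum(pa == sa & pa != "-") / length(pa)
  attr(out, "scoring") <- c(match = match, mismatch = mismatch,
                            gap_open = gap_open, gap_extend = gap_extend)
  out
}

#' Mutual similarity of retained-region flanks
#'
#' For each retained region, globally aligns its left and right `flank`-bp
#' flanks against each other and records the identity; the sample is
#' compared (Mann-Whitney) with identities of random same-chromosome flank
#' pairs of the same size. Under the NAHR model the recombining homologous
#' repeats sit in these flanks, so deletion-associated regions score higher
#' than random pairs. Pass `mode = "each-vs-random"` to instead align each
#' region's left flank against a random window.
#'
#' @param retained `interval_set` of retained regions.
#' @param genome `DNAStringSet` of the retained genome.
#' @param flank flank width, bp.
#' @param n_random_pairs random pairs to sample (default: one per region).
#' @param seed optional integer seed.
#' @param mode `"left-vs-right"` (default) or `"each-vs-random"`.
#' @param max_n_fraction flanks with more than this fraction of N are
#'   skipped (and counted).
#' @return list: `similarity` and `random` identity samples,
#'   `mann_whitney_p`, `n_skipped` (edge-clipped or N-rich regions).
#' @export
flank_similarity <- function(retained, genome, flank = 1000,
                             n_random_pairs = NULL, seed = NULL,
                             mode = c("left-vs-right", "each-vs-random"),
                             max_n_fraction = 0.5) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  sizes <- setNames(nchar(as.character(genome)), names(genome))
  getseq <- function(chrom, s, e) substr(as.character(genome[[chrom]]), s + 1, e)
  frac_n <- function(s) {
    n <- nchar(s)
    if (n == 0) return(1)
    (n - nchar(gsub("N", "", s, fixed = TRUE))) / n
  }
  rand_window <- function(chrom) {
    s <- floor(stats::runif(1) * (sizes[[chrom]] - flank))
    getseq(chrom, s, s + flank)
  }
  sim <- numeric(0); n_skip <- 0
  for (i in seq_len(nrow(retained))) {
    chrom <- retained$chrom[i]
    s <- retained$start[i]; e <- retained$end[i]
    if (s - flank < 0 || e + flank > sizes[[chrom]]) { n_skip <- n_skip + 1; next }
    lf <- getseq(chrom, s - flank, s); rf <- getseq(chrom, e, e + flank)
    if (frac_n(lf) > max_n_fraction || frac_n(rf) > max_n_fraction) {
      n_skip <- n_skip + 1; next
    }
    other <- if (mode == "left-vs-right") rf else rand_window(chrom)
    sim <- c(sim, as.numeric(global_align_identity(lf, other)))
  }
  if (is.null(n_random_pairs)) n_random_pairs <- max(length(sim), 10)
  chroms_pool <- retained$chrom[retained$chrom %in% names(sizes)]
  rnd <- vapply(seq_len(n_random_pairs), function(i) {
    chrom <- sample(chroms_pool, 1)
    as.numeric(global_align_identity(rand_window(chrom), rand_window(chrom)))
  }, numeric(1))
  if (!length(sim)) stop("no usable retained regions (all skipped)")
  mw <- mann_whitney_u(sim, rnd)
  list(similarity = sim, random = rnd, mann_whitney_p = mw$p,
       n_skipped = n_skip, mode = mode)
}
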