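## Regulatory-landscape statistics: peak conservation through alignment,
## subgenome-specific peaks, annotation enrichment, active-transcription
## thresholding, repeat density, and the enhancer-proximity expression test.

#' Peak conservation through a whole-genome alignment
#'
#' A reference peak is conserved when its projection onto the target genome
#' overlaps at least one target peak by `min_overlap_bp`.
#'
#' @param ref_peaks `interval_set` of reference peaks.
#' @param aln `alignment_set` between the two genomes.
#' @param target_peaks `interval_set` of peaks on the target genome.
#' @param min_overlap_bp minimum projected overlap, bp.
#' @return list: `fraction`, logical `conserved` per reference peak.
#' @export
peak_conservation <- function(ref_peaks, aln, target_peaks, min_overlap_bp = 1) {
  target <- genome_of(target_peaks)
  conserved <- vapply(seq_len(nrow(ref_peaks)), function(i) {
    proj <- project_intervals(ref_peaks[i, , drop = FALSE], aln, target)
    if (nrow(proj) == 0) return(FALSE)
    total_bp(intersect_intervals(proj, target_peaks)) >= min_overlap_bp
  }, logical(1))
  list(fraction = mean(conserved), conserved = conserved)
}

#' Subgenome-specific peaks
#'
#' Peaks lacking any sequence-level conservation: at most `max_aligned_bp`
#' of the peak aligns to the sister subgenome and to the outgroup (default
#' 0, the strict reading of "lacking any conservation").
#'
#' @param peaks `interval_set` of peaks on one subgenome.
#' @param aln_sister,aln_outgroup `alignment_set`s from that subgenome.
#' @param max_aligned_bp tolerated aligned bp per peak.
#' @return the specific subset of `peaks`.
#' @export
subgenome_specific_peaks <- function(peaks, aln_sister, aln_outgroup,
                                     max_aligned_bp = 0) {
  g <- genome_of(peaks)
  bp_s <- overlap_fraction(peaks, blocks_on(aln_sister, g)) * (peaks$end - peaks$start)
  bp_o <- overlap_fraction(peaks, blocks_on(aln_outgroup, g)) * (peaks$end - peaks$start)
  peaks[bp_s <= max_aligned_bp & bp_o <= max_aligned_bp, , drop = FALSE]
}

#' Annotation enrichment of a peak subset
#'
#' For each annotation, counts peaks overlapping it by more than
#' `min_overlap` of the peak length, in the subset (`k` of `n`) and in all
#' peaks (`K` of `N`); fold = `(k/n)/(K/N)`, p = hypergeometric upper tail
#' with all peaks as population, prevalence = `k/n`. The full table is
#' returned with a `pass` column applying the three thresholds.
#'
#' @param subset `interval_set` of the peak subset (must be non-empty).
#' @param all_peaks `interval_set` of the full peak population.
#' @param annotations named list of `interval_set`s (repeat families, motif
#'   hits, ...).
#' @param min_overlap peak-overlap fraction threshold (strict `>`).
#' @param p_max,fold_min,prevalence_min reporting thresholds.
#' @return data frame: `annotation`, `k`, `n`, `K`, `N`, `fold`,
#'   `prevalence`, `p`, `pass`.
#' @export
annotation_enrichment <- function(subset, all_peaks, annotations,
                                  min_overlap = 0.5, p_max = 1e-4,
                                  fold_min = 2, prevalence_min = 0.15) {
  if (nrow(subset) == 0) stop("empty peak subset")
  n <- nrow(subset); N <- nrow(all_peaks)
  rows <- lapply(names(annotations), function(nm) {
    ann <- annotations[[nm]]
    k <- sum(overlap_fraction(subset, ann) > min_overlap)
    K <- sum(overlap_fraction(all_peaks, ann) > min_overlap)
    fold <- if (K > 0) (k / n) / (K / N) else ifelse(k > 0, Inf, NA_real_)
    p <- if (K > 0) hypergeometric_tail(k, K, n, N) else 1
    data.frame(annotation = nm, k = k, n = n, K = K, N = N, fold = fold,
               prevalence = k / n, p = p,
               pass = is.finite(fold) && fold >= fold_min && p <= p_max &&
                 (k / n) >= prevalence_min,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Repeat (or any annotation) frequency per megabase
#'
#' @param annotation `interval_set` of elements.
#' @param genome_size_bp genome (or subgenome) size in bp.
#' @return elements per Mb.
#' @export
repeats_per_megabase <- function(annotation, genome_size_bp) {
  if (genome_size_bp <= 0) stop("genome size must be positive")
  nrow(annotation) / (genome_size_bp / 1e6)
}

#' Active-transcription thresholds from background signal
#'
#' Per mark, threshold = mean + 2 SD of the signal over random background
#' regions; a region is actively transcribed when it reaches the threshold
#' for every mark independently (boundary values pass).
#'
#' @param background named list (one element per mark, e.g. `H3K36me3`,
#'   `RNAPII`) of numeric background values (RPKM over random regions).
#' @return named numeric thresholds.
#' @export
active_transcription_threshold <- function(background) {
  vapply(background, function(v) {
    if (length(v) < 2) stop("need >= 2 background values per mark")
    mean(v) + 2 * stats::sd(v)
  }, numeric(1))
}

#' @rdname active_transcription_threshold
#' @param signal data frame or matrix of per-region signal, columns named
#'   like the thresholds.
#' @param thresholds output of [active_transcription_threshold()].
#' @return logical vector: actively transcribed per region.
#' @export
is_actively_transcribed <- function(signal, thresholds) {
  signal <- as.data.frame(signal)
  miss <- setdiff(names(thresholds), names(signal))
  if (length(miss)) stop("signal lacks marks: ", paste(miss, collapse = ", "))
  ok <- rep(TRUE, nrow(signal))
  for (mk in names(thresholds)) ok <- ok & signal[[mk]] >= thresholds[[mk]]
  ok
}

#' Strand-aware transcription start sites
#'
#' @param genes `interval_set` of gene bodies with strand and `label` =
#'   gene id.
#' @return `interval_set` of 1-bp TSS intervals (start for `+`, `end - 1`
#'   for `-`).
#' @export
tss_points <- function(genes) {
  pos <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  interval_set(genes$chrom, pos, pos + 1, strand = genes$strand,
               label = genes$label, genome = genome_of(genes))
}

#' Expression shift of genes near enhancers
#'
#' Partitions genes by TSS-to-nearest-enhancer distance (`<= distance`,
#' boundary inclusive) and compares log2 TPM between the two groups by
#' Mann-Whitney.
#'
#' @param enhancers `interval_set` of enhancer peaks.
#' @param tss `interval_set` of 1-bp TSS intervals with `label` = gene id
#'   (see [tss_points()]).
#' @param expression data frame `gene_id`, `tpm`.
#' @param distance proximity cutoff, bp.
#' @return list: `n_near`, `n_far`, `median_tpm_near`, `median_tpm_far`,
#'   `U`, `p`.
#' @export
proximity_expression_test <- function(enhancers, tss, expression,
                                      distance = 5000) {
  ex <- setNames(expression$tpm, expression$gene_id)
  have <- tss$label %in% names(ex)
  tss <- tss[have, , drop = FALSE]
  if (!nrow(tss)) stop("no TSS with expression data")
  near <- logical(nrow(tss))
  for (cn in unique(tss$chrom)) {
    e <- enhancers[enhancers$chrom == cn, , drop = FALSE]
    sel <- which(tss$chrom == cn)
    if (!nrow(e)) next
    for (i in sel) {
      p <- tss$start[i]
      d <- pmax(0, pmax(e$start - (p + 1), p - e$end) + 1)
      d[p >= e$start & p < e$end] <- 0
      near[i] <- min(d) <= distance
    }
  }
  tpm <- ex[tss$label]
  if (!any(near) || all(near))
    stop("empty proximity group (near = ", sum(near), ", far = ",
         sum(!near), ")")
  mw <- mann_whitney_u(log2(tpm[near] + 0.01), log2(tpm[!near] + 0.01))
  list(n_near = sum(near), n_far = sum(!near),
       median_tpm_near = stats::median(tpm[near]),
       median_tpm_far = stats::median(tpm[!near]), U = mw$U, p = mw$p)
}
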