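## Pseudogene feature classification, dating per gene triangle, nonsense
## (protein-truncating) variant annotation, and protein-complex retention.

## premature stops of one gapped row, frame anchored to alignment columns
## (a downstream frameshift does not shift the reading used here)
aligned_premature_stops <- function(gapped) {
  cods <- split_into_codons(gapped)
  idx <- codon_index(cods)
  last_aligned <- max(which(!is.na(idx)), 0)
  stops <- which(!is.na(idx) & codon_aa(CODONS[pmax(idx, 1)]) == "*")
  stops[stops < last_aligned] - 1
}

ungapped_len <- function(s) nchar(gsub("-", "", s, fixed = TRUE))

#' Pseudogene features of both copies of one gene triangle
#'
#' Evaluates the four (non-exclusive) feature classes per subgenome copy:
#' `premature_stop` (in-frame stop before the last aligned codon, frame
#' anchored to the codon alignment), `frameshift` (a gap run in that copy
#' with length not a multiple of 3), `truncated_50` (ungapped CDS shorter
#' than half of both the homeolog and the outgroup ortholog; homeolog only,
#' flagged, when the ortholog is absent), and `promoter_loss_75` (at least
#' 75% of the homeolog's promoter is unaligned to this subgenome or its
#' projection falls in called deletions).
#'
#' @param aln named gapped triplet (outgroup + the two copies).
#' @param promoters optional named list per subgenome of promoter
#'   `GenomeInterval` rows (1-row `interval_set`), e.g. from
#'   [promoter_of()]; `NULL` disables the promoter feature.
#' @param aln_sister optional `alignment_set` between the subgenomes
#'   (needed for promoter projection).
#' @param deletions optional named list per subgenome of deletion-footprint
#'   `interval_set`s on that subgenome.
#' @param outgroup,a,b taxon names in `aln`.
#' @return data frame with one row per copy (`copy` = taxon name) and
#'   logical feature columns.
#' @export
classify_pseudogene_features <- function(aln, promoters = NULL,
                                         aln_sister = NULL, deletions = NULL,
                                         outgroup = "T", a = "L", b = "S") {
  lens <- vapply(aln, ungapped_len, numeric(1))
  has_out <- outgroup %in% names(aln) && lens[[outgroup]] > 0
  rows <- list()
  for (copy in c(a, b)) {
    sister <- if (copy == a) b else a
    stops <- aligned_premature_stops(aln[[copy]])
    fs <- detect_frameshift(aln[[copy]], aln[[sister]])
    fs <- fs[fs$seq == "a", , drop = FALSE]
    trunc <- lens[[copy]] < 0.5 * lens[[sister]] &&
      (!has_out || lens[[copy]] < 0.5 * lens[[outgroup]])
    prom_lost <- FALSE
    if (!is.null(promoters) && !is.null(promoters[[sister]]) &&
        !is.null(aln_sister)) {
      prom_lost <- promoter_loss_fraction(promoters[[sister]], aln_sister,
                                          copy, deletions[[copy]]) >= 0.75
    }
    rows[[copy]] <- data.frame(
      copy = copy, premature_stop = length(stops) > 0,
      frameshift = nrow(fs) > 0, truncated_50 = trunc,
      promoter_loss_75 = prom_lost,
      truncation_vs_homeolog_only = trunc && !has_out,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Fraction of a homeolog promoter lost on the other subgenome
#'
#' A promoter basepair counts as lost when it is unaligned to the target
#' subgenome or its projection falls inside the supplied deletion
#' footprints.
#'
#' @param promoter 1-row `interval_set` on the sister subgenome.
#' @param aln_sister `alignment_set` between the subgenomes.
#' @param target genome identifier of the copy under test.
#' @param deletions optional `interval_set` of deletion footprints on
#'   `target`.
#' @return lost fraction in `[0, 1]`.
#' @export
promoter_loss_fraction <- function(promoter, aln_sister, target,
                                   deletions = NULL) {
  len <- sum(promoter$end - promoter$start)
  aligned <- intersect_intervals(promoter,
                                 blocks_on(aln_sister, genome_of(promoter),
                                           reciprocal_only = TRUE))
  aligned_bp <- total_bp(aligned)
  lost <- len - aligned_bp
  if (!is.null(deletions) && nrow(deletions) && aligned_bp > 0) {
    proj <- project_intervals(aligned, aln_sister, target, reciprocal_only = TRUE)
    lost <- lost + total_bp(intersect_intervals(proj, deletions))
  }
  min(1, lost / len)
}

#' Promoter interval of a gene
#'
#' The H3K4me3 peak overlapping the gene's transcription start site when one
#' exists, otherwise TSS +/- `fallback` bp.
#'
#' @param tss 1-row `interval_set` holding the TSS point (see
#'   [tss_points()]).
#' @param peaks `interval_set` of H3K4me3 peaks on the same genome.
#' @param fallback half-width of the fallback promoter, bp.
#' @return 1-row `interval_set`.
#' @export
promoter_of <- function(tss, peaks, fallback = 500) {
  if (nrow(peaks)) {
    hit <- which(peaks$chrom == tss$chrom[1] & peaks$start <= tss$start[1] &
                 peaks$end > tss$start[1])
    if (length(hit))
      return(peaks[hit[1], , drop = FALSE])
  }
  interval_set(tss$chrom[1], max(0, tss$start[1] - fallback),
               tss$start[1] + fallback, genome = genome_of(tss))
}

#' Likely pseudogenes by feature plus expression criterion
#'
#' A copy is called when it carries at least one pseudogene feature and its
#' expression is at least `fold` times lower than its homeolog's, with the
#' homeolog expressed (TPM >= `floor`). `mode = "strict"` additionally
#' requires the candidate itself to be unexpressed (TPM < `floor`), the
#' definition used for date histograms.
#'
#' @param features data frame with columns `gene_id`, `copy` and the
#'   logical feature columns of [classify_pseudogene_features()].
#' @param expression data frame `gene_id`, `tpm` where ids are
#'   `<gene>.<copy>`.
#' @param fold minimum homeolog/candidate expression ratio.
#' @param floor TPM at or above which a gene counts as expressed.
#' @param mode `"relative"` or `"strict"`.
#' @return the subset of `features` rows called, with `tpm` and
#'   `tpm_homeolog` attached; attribute `n_no_expression` counts gene pairs
#'   skipped for missing expression data.
#' @export
call_likely_pseudogenes <- function(features, expression, fold = 10,
                                    floor = 1, mode = c("relative", "strict")) {
  mode <- match.arg(mode)
  feat_cols <- c("premature_stop", "frameshift", "truncated_50", "promoter_loss_75")
  ex <- setNames(expression$tpm, expression$gene_id)
  ## copy suffixes come from the expression table (the features frame may
  ## only carry one side)
  copies <- unique(sub(".*\\.", "", expression$gene_id))
  skipped <- 0
  keep <- logical(nrow(features))
  tpm <- tpm_h <- rep(NA_real_, nrow(features))
  for (i in seq_len(nrow(features))) {
    sister <- setdiff(copies, features$copy[i])[1]
    id <- paste0(features$gene_id[i], ".", features$copy[i])
    idh <- paste0(features$gene_id[i], ".", sister)
    if (!(id %in% names(ex)) || !(idh %in% names(ex))) { skipped <- skipped + 1; next }
    tpm[i] <- ex[[id]]; tpm_h[i] <- ex[[idh]]
    has_feat <- any(as.logical(features[i, feat_cols]))
    expr_ok <- tpm_h[i] >= floor &&
      (if (mode == "strict") tpm[i] < floor else tpm[i] < tpm_h[i] / fold)
    keep[i] <- has_feat && expr_ok
  }
  out <- features[keep, , drop = FALSE]
  out$tpm <- tpm[keep]; out$tpm_homeolog <- tpm_h[keep]
  attr(out, "n_no_expression") <- skipped
  out
}

#' Non-overlapping pseudogene cause classes
#'
#' Deterministic partition of the feature sets: deletion-linked features
#' (`truncated_50`, `promoter_loss_75`) dominate; a single point feature
#' yields its own class; anything else is `multiple`.
#'
#' @param features data frame (or 1-row subset) with the four logical
#'   feature columns; every row must have at least one feature.
#' @param priority `"deletion"` (default) or `"none"` (pure
#'   single/multiple partition).
#' @return character vector of classes: `deletion-driven`, `stop-only`,
#'   `frameshift-only`, `multiple`.
#' @export
exclusive_class <- function(features, priority = c("deletion", "none")) {
  priority <- match.arg(priority)
  fm <- as.matrix(features[c("premature_stop", "frameshift", "truncated_50",
                             "promoter_loss_75")])
  if (any(rowSums(fm) == 0)) stop("every row must have at least one feature")
  vapply(seq_len(nrow(fm)), function(i) {
    f <- fm[i, ]
    if (priority == "deletion" && (f["truncated_50"] || f["promoter_loss_75"]))
      return("deletion-driven")
    if (sum(f) > 1) return("multiple")
    c("stop-only", "frameshift-only", "deletion-driven",
      "deletion-driven")[which(f)]
  }, "")
}

## genome coordinate (0-based) of coding position j for a multi-part CDS
cds_genome_coord <- function(parts, strand, j) {
  widths <- parts$end - parts$start
  cum <- c(0, cumsum(widths))
  L <- sum(widths)
  jf <- if (strand == "+") j else L - 1 - j
  k <- findInterval(jf, cum, rightmost.closed = FALSE)
  parts$start[k] + (jf - cum[k])
}

#' Annotate nonsense (premature-stop) variants
#'
#' For each SNP passing the depth filters that falls inside an annotated
#' CDS, substitutes the alternate allele in the coding frame (strand-aware)
#' and flags the variant when the new codon is a stop strictly before the
#' terminal codon.
#'
#' @param variants data frame from [read_vcf_min()].
#' @param cds `interval_set` of CDS parts with `label` = gene id and strand
#'   set.
#' @param genome `DNAStringSet` of the genome the variants are called on.
#' @param min_dp,min_alt depth filters (at least tenfold coverage with at
#'   least four alternate observations).
#' @return list: `records` (per passing nonsense variant: gene, position,
#'   codon change, depth), `per_gene` (gene_id, has_nonsense),
#'   `n_ref_mismatch` (records skipped because REF disagreed with the
#'   genome), `n_coding_snps` (depth-passing SNPs inside CDS).
#' @export
annotate_nonsense <- function(variants, cds, genome, min_dp = 10, min_alt = 4) {
  v <- variants[!is.na(variants$dp) & variants$dp >= min_dp &
                !is.na(variants$alt_reads) & variants$alt_reads >= min_alt &
                nchar(variants$ref) == 1 & nchar(variants$alt) == 1, , drop = FALSE]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  genes <- unique(cds$label)
  per_gene <- setNames(rep(FALSE, length(genes)), genes)
  records <- list(); n_mismatch <- 0; n_coding <- 0
  parts_by_gene <- split(seq_len(nrow(cds)), cds$label)
  for (gid in genes) {
    parts <- as.data.frame(cds[parts_by_gene[[gid]], , drop = FALSE])
    parts <- parts[order(parts$start), , drop = FALSE]
    strand <- parts$strand[1]; chrom <- parts$chrom[1]
    vv <- v[v$chrom == chrom, , drop = FALSE]
    if (!nrow(vv)) next
    inside <- rep(FALSE, nrow(vv))
    for (k in seq_len(nrow(parts)))
      inside <- inside | (vv$pos0 >= parts$start[k] & vv$pos0 < parts$end[k])
    vv <- vv[inside, , drop = FALSE]
    if (!nrow(vv)) next
    n_coding <- n_coding + nrow(vv)
    segs <- vapply(seq_len(nrow(parts)), function(k)
      substr(as.character(genome[[chrom]]), parts$start[k] + 1, parts$end[k]), "")
    fseq <- paste(segs, collapse = "")
    cseq <- if (strand == "+") fseq else revcomp(fseq)
    L <- nchar(cseq); ncod <- L %/% 3
    widths <- parts$end - parts$start
    cum <- c(0, cumsum(widths))
    for (r in seq_len(nrow(vv))) {
      pos <- vv$pos0[r]
      k <- max(which(parts$start <= pos))
      jf <- cum[k] + (pos - parts$start[k])
      j <- if (strand == "+") jf else L - 1 - jf
      ref_cod <- substr(cseq, j + 1, j + 1)
      ref_gen <- if (strand == "+") vv$ref[r] else comp[[vv$ref[r]]]
      if (ref_cod != ref_gen) { n_mismatch <- n_mismatch + 1; next }
      alt_cod <- if (strand == "+") vv$alt[r] else comp[[vv$alt[r]]]
      ci <- j %/% 3
      if (ci >= ncod) next
      codon <- substr(cseq, ci * 3 + 1, ci * 3 + 3)
      mut <- codon
      substr(mut, j %% 3 + 1, j %% 3 + 1) <- alt_cod
      if (!is.na(codon_index(mut)) && codon_aa(mut) == "*" && ci < ncod - 1) {
        per_gene[[gid]] <- TRUE
        records[[length(records) + 1]] <- data.frame(
          gene_id = gid, chrom = chrom, pos0 = pos, codon_index = ci,
          codon_ref = codon, codon_alt = mut, consequence = "nonsense",
          depth = vv$dp[r], alt_reads = vv$alt_reads[r], stringsAsFactors = FALSE)
      }
    }
  }
  list(records = if (length(records)) do.call(rbind, records) else
         data.frame(gene_id = character(), chrom = character(), pos0 = numeric(),
                    codon_index = numeric(), codon_ref = character(),
                    codon_alt = character(), consequence = character(),
                    depth = numeric(), alt_reads = numeric()),
       per_gene = data.frame(gene_id = genes, has_nonsense = unname(per_gene),
                             stringsAsFactors = FALSE),
       n_ref_mismatch = n_mismatch, n_coding_snps = n_coding)
}

#' Loss-of-function summary across genomes
#'
#' Per-genome fraction of genes with at least one nonsense variant, the
#' nonsense-per-coding-SNP rate, and pairwise chi-squared comparisons of
#' both quantities.
#'
#' @param n_genes named vector: annotated genes per genome.
#' @param n_lof named vector: genes with >= 1 nonsense variant.
#' @param coding_snps optional named vector: depth-passing coding SNPs.
#' @param nonsense_snps optional named vector: nonsense SNP counts.
#' @return list: `table` (per-genome percentages/rates), `gene_tests` and
#'   `rate_tests` (pairwise chi-squared data frames).
#' @export
lof_summary <- function(n_genes, n_lof, coding_snps = NULL, nonsense_snps = NULL) {
  if (any(n_genes <= 0)) stop("zero gene totals")
  gs <- names(n_genes)
  tab <- data.frame(genome = gs, n_genes = as.numeric(n_genes),
                    n_lof = as.numeric(n_lof[gs]),
                    pct_lof = round(100 * as.numeric(n_lof[gs]) / as.numeric(n_genes), 2))
  if (!is.null(coding_snps)) {
    tab$coding_snps <- as.numeric(coding_snps[gs])
    tab$nonsense_snps <- as.numeric(nonsense_snps[gs])
    tab$nonsense_rate <- tab$nonsense_snps / tab$coding_snps
  }
  pairtests <- function(a_succ, a_tot) {
    rows <- list()
    cmb <- utils::combn(gs, 2)
    for (k in seq_len(ncol(cmb))) {
      g1 <- cmb[1, k]; g2 <- cmb[2, k]
      ct <- chi_squared_2x2(a_succ[[g1]], a_tot[[g1]] - a_succ[[g1]],
                            a_succ[[g2]], a_tot[[g2]] - a_succ[[g2]])
      rows[[k]] <- data.frame(genome_a = g1, genome_b = g2,
                              statistic = ct$statistic, p = ct$p)
    }
    do.call(rbind, rows)
  }
  out <- list(table = tab,
              gene_tests = pairtests(as.list(n_lof[gs]), as.list(n_genes[gs])))
  if (!is.null(coding_snps))
    out$rate_tests <- pairtests(as.list(nonsense_snps[gs]), as.list(coding_snps[gs]))
  out
}

#' Protein-complex (dimer) retention summary
#'
#' Classifies fully represented dimers by homeolog copy status and compares
#' the observed fraction of complexes where both members are single-copy
#' with the expectation under independent loss (`q^2`; `q` supplied or
#' estimated from the classified dimers as the member single-copy rate).
#'
#' @param dimers data frame `complex_id`, `gene_a`, `gene_b`.
#' @param status named vector gene -> `"dual"`, `"single"` or `"absent"`.
#' @param q optional genome-wide single-copy probability.
#' @return A `complex_summary` list: counts, `observed_fraction`,
#'   `expected_fraction`, `q`.
#' @export
complex_retention <- function(dimers, status, q = NULL) {
  st_a <- status[dimers$gene_a]; st_b <- status[dimers$gene_b]
  if (any(is.na(st_a)) || any(is.na(st_b)))
    stop("every dimer member needs a copy status")
  present <- st_a != "absent" & st_b != "absent"
  ns <- (st_a[present] == "single") + (st_b[present] == "single")
  complex_retention_counts(sum(ns == 0), sum(ns == 1), sum(ns == 2), q = q)
}

#' @rdname complex_retention
#' @param n_both_dual,n_one_single,n_both_single dimer counts by number of
#'   single-copy members (printed-count interface).
#' @export
complex_retention_counts <- function(n_both_dual, n_one_single, n_both_single,
                                     q = NULL) {
  n_total <- n_both_dual + n_one_single + n_both_single
  if (n_total == 0) stop("no fully represented complexes")
  if (is.null(q)) q <- (n_one_single + 2 * n_both_single) / (2 * n_total)
  structure(list(n_total = n_total, n_both_dual = n_both_dual,
                 n_one_single = n_one_single, n_both_single = n_both_single,
                 observed_fraction = n_both_single / n_total,
                 expected_fraction = q^2, q = q),
            class = "complex_summary")
}

#' @export
print.complex_summary <- function(x, ...) {
  cat(sprintf(paste0("%d fully represented dimers: %d dual/dual, %d one single,",
                     " %d both single\nobserved both-single %.1f%% vs %.1f%%",
                     " expected under independence (q = %.3f)\n"),
              x$n_total, x$n_both_dual, x$n_one_single, x$n_both_single,
              100 * x$observed_fraction, 100 * x$expected_fraction, x$q))
  invisible(x)
}
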