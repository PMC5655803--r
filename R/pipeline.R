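## Orchestration: per-gene triangle analysis and the end-to-end synthetic
## pipeline (deletions -> randomization enrichment -> NAHR -> rates/dating ->
## gene loss -> regulatory landscape), each stage writing its own table so
## every report number is traceable.

#' Analyze gene triangles: rates, features, dates
#'
#' For every gene, reconstructs the split ancestor, computes NG86 rates per
#' branch, evaluates the four pseudogene features for both copies, and dates
#' copies carrying at least one feature with the constrained/neutral mixture
#' model (optionally with a codon bootstrap CI).
#'
#' @param cds_aln named list (per gene) of named gapped triplets
#'   (`outgroup`, `a`, `b` taxa).
#' @param T_my branch time since the subgenome split, My.
#' @param outgroup,a,b taxon names (defaults `"T"`, `"L"`, `"S"`).
#' @param promoters optional list per gene of per-subgenome promoter
#'   intervals (see [classify_pseudogene_features()]).
#' @param aln_sister optional `alignment_set` between the subgenomes.
#' @param deletions optional named list per subgenome of deletion
#'   footprints.
#' @param n_boot bootstrap replicates for dated genes (0 = none).
#' @param seed optional integer seed (bootstrap only).
#' @return data frame, one row per gene copy: rates of its branch
#'   (`ka`, `ks`, `omega`), the functional-branch `omega_f`, the four
#'   feature flags, `t_loss` (+ CI columns when bootstrapped).
#' @export
analyze_gene_triangles <- function(cds_aln, T_my = 34, outgroup = "T",
                                   a = "L", b = "S", promoters = NULL,
                                   aln_sister = NULL, deletions = NULL,
                                   n_boot = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (gid in names(cds_aln)) {
    aln <- cds_aln[[gid]]
    tri <- gene_triangle_rates(aln, outgroup = outgroup, a = a, b = b)
    feats <- classify_pseudogene_features(
      aln, promoters = promoters[[gid]], aln_sister = aln_sister,
      deletions = deletions, outgroup = outgroup, a = a, b = b)
    for (copy in c(a, b)) {
      r <- if (copy == a) tri$a else tri$b
      rf <- if (copy == a) tri$b else tri$a
      f <- feats[feats$copy == copy, , drop = FALSE]
      has_feat <- any(as.logical(f[c("premature_stop", "frameshift",
                                     "truncated_50", "promoter_loss_75")]))
      t_loss <- ci_lo <- ci_hi <- NA_real_
      if (has_feat && !is.na(r$omega) && !is.na(rf$omega) && rf$omega < 1) {
        if (n_boot > 0) {
          bd <- bootstrap_date(aln, pseudo = copy, functional = if (copy == a) b else a,
                               outgroup = outgroup, T_my = T_my, n_boot = n_boot)
          t_loss <- bd$t_loss; ci_lo <- bd$ci_low; ci_hi <- bd$ci_high
        } else {
          t_loss <- date_pseudogene(r$omega, rf$omega, T_my)$t_loss
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gid, copy = copy, ka = r$Ka, ks = r$Ks, omega = r$omega,
        omega_f = rf$omega, premature_stop = f$premature_stop,
        frameshift = f$frameshift, truncated_50 = f$truncated_50,
        promoter_loss_75 = f$promoter_loss_75, t_loss = t_loss,
        ci_low = ci_lo, ci_high = ci_hi, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full pipeline on a simulated (or equivalently structured) system
#'
#' Executes deletion calling on both subgenomes, the randomization
#' enrichment test, the NAHR statistics, per-gene rates/features/dating,
#' the likely-pseudogene and nonsense-variant summaries, and the
#' regulatory-landscape statistics, writing one TSV/JSON per stage plus a
#' JSON report. Deterministic for a fixed seed.
#'
#' @param sim output of [simulate_system()] (or a compatible list).
#' @param out_dir report directory (created).
#' @param seed integer seed for all stochastic stages.
#' @param n_rand randomizations for the enrichment test.
#' @param n_boot bootstrap replicates for pseudogene dating (0 = off).
#' @param max_flank_regions cap on regions entering the flank-similarity
#'   alignment sample (rank tests need no more).
#' @param date_bin_my histogram bin width for pseudogene dates, My.
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(sim, out_dir, seed = 1, n_rand = 1000, n_boot = 0,
                         max_flank_regions = 100, date_bin_my = 2) {
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = seed)
  genome <- list(L = Biostrings::DNAStringSet(sim$genome_seq$L),
                 S = Biostrings::DNAStringSet(sim$genome_seq$S))

  ## -- deletions, both sides
  calls <- list()
  for (sub in c("L", "S")) {
    aln_out <- if (sub == "L") sim$aln$LT else sim$aln$ST
    cand <- candidate_regions(sim$aln$LS, aln_out, sub, genome = genome[[sub]])
    calls[[sub]] <- call_deletions(cand, sim$aln$LS)
  }
  all_calls <- rbind(as.data.frame(calls$L), as.data.frame(calls$S))
  utils::write.table(all_calls, file.path(out_dir, "deletions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  spec <- deletion_size_spectrum(all_calls)
  n_lds <- sum(all_calls$side == "LdS"); n_sdl <- sum(all_calls$side == "SdL")
  report$deletions <- list(
    n_calls = nrow(all_calls), n_LdS = n_lds, n_SdL = n_sdl,
    pct_LdS = round(100 * n_lds / max(1, nrow(all_calls)), 1),
    pct_SdL = round(100 * n_sdl / max(1, nrow(all_calls)), 1),
    overall_size_ratio = spec$overall_ratio)

  ## -- enrichment: homeolog-proxy feature classes per subgenome
  enr <- list()
  for (sub in c("L", "S")) {
    sister <- if (sub == "L") "S" else "L"
    dels <- retained_regions(calls[[sub]])
    cls <- list(
      Exonic = project_intervals(
        gff_cds(sim$gene_models[[sister]], sister), sim$aln$LS, sub),
      H3K4me3 = project_intervals(sim$h3k4me3[[sister]], sim$aln$LS, sub),
      p300 = project_intervals(sim$annotations[[sister]]$p300, sim$aln$LS, sub))
    enr[[sub]] <- deletion_enrichment(dels, cls, sim$chrom_sizes[[sub]],
                                      n_rand = n_rand)
  }
  enr_all <- rbind(cbind(genome = "L", as.data.frame(enr$L)),
                   cbind(genome = "S", as.data.frame(enr$S)))
  utils::write.table(enr_all, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cmp <- compare_subgenome_enrichment(enr$L, enr$S)
  utils::write.table(cmp, file.path(out_dir, "enrichment_L_vs_S.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$enrichment <- list(
    classes = unique(enr_all$class),
    genome_rows = enr_all[enr_all$chromosome == "all",
                          c("genome", "class", "log2_fold", "p", "q")])

  ## -- NAHR statistics per side
  report$nahr <- list()
  for (sub in c("L", "S")) {
    ret <- retained_regions(calls[[sub]])
    if (nrow(ret) == 0) next
    rl <- repeat_length_ratio(ret, sim$annotations[[sub]]$repeats,
                              sim$chrom_sizes[[sub]])
    sub_ret <- ret[ret$end - ret$start >= 200, , drop = FALSE]
    if (nrow(sub_ret) > max_flank_regions)
      sub_ret <- sub_ret[sample.int(nrow(sub_ret), max_flank_regions), , drop = FALSE]
    fs <- flank_similarity(sub_ret, genome[[sub]])
    report$nahr[[sub]] <- list(
      repeat_length_ratio = rl$ratio, repeat_length_p = rl$mann_whitney_p,
      flank_similarity_mean = mean(fs$similarity),
      flank_random_mean = mean(fs$random), flank_p = fs$mann_whitney_p)
  }

  ## -- gene triangles: rates, features, dating
  proms <- lapply(names(sim$cds_aln), function(gid) {
    out <- list()
    for (g in c("L", "S")) {
      pk <- sim$h3k4me3[[g]]
      hit <- which(!is.na(pk$label) & pk$label == paste0(gid, ".", g))
      if (length(hit)) out[[g]] <- pk[hit[1], , drop = FALSE]
    }
    out
  })
  names(proms) <- names(sim$cds_aln)
  tri <- analyze_gene_triangles(sim$cds_aln, promoters = proms,
                                aln_sister = sim$aln$LS, n_boot = n_boot)
  utils::write.table(tri, file.path(out_dir, "gene_triangles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  feats <- tri
  likely <- call_likely_pseudogenes(feats, sim$expression)
  utils::write.table(likely, file.path(out_dir, "likely_pseudogenes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dated <- likely$t_loss[!is.na(likely$t_loss)]
  hist_breaks <- seq(0, 34 + date_bin_my, by = date_bin_my)
  date_hist <- table(cut(pmin(dated, 34), hist_breaks, right = FALSE))
  report$pseudogenes <- list(
    n_likely = nrow(likely),
    n_likely_L = sum(likely$copy == "L"), n_likely_S = sum(likely$copy == "S"),
    date_histogram = as.list(setNames(as.numeric(date_hist), names(date_hist))),
    median_ks_L = stats::median(tri$ks[tri$copy == "L"], na.rm = TRUE),
    median_ks_S = stats::median(tri$ks[tri$copy == "S"], na.rm = TRUE))

  ## -- nonsense variants per genome
  vcf <- read_vcf_min(sim$files$vcf)
  lof_n <- c(); lof_genes <- c(); lof_coding <- c(); lof_nons <- c()
  for (g in c("L", "S", "T")) {
    cds <- gff_cds(sim$gene_models[[g]], g)
    ann <- annotate_nonsense(vcf, cds, Biostrings::DNAStringSet(sim$genome_seq[[g]]))
    lof_genes[g] <- length(unique(cds$label))
    lof_n[g] <- sum(ann$per_gene$has_nonsense)
    lof_coding[g] <- ann$n_coding_snps
    lof_nons[g] <- nrow(ann$records)
  }
  lof <- lof_summary(lof_genes, lof_n, lof_coding, lof_nons)
  utils::write.table(lof$table, file.path(out_dir, "lof_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$lof <- list(table = lof$table)

  ## -- regulatory landscape
  consv <- peak_conservation(sim$annotations$L$p300, sim$aln$LT,
                             sim$annotations$T$p300)
  specific <- subgenome_specific_peaks(sim$annotations$L$p300, sim$aln$LS,
                                       sim$aln$LT)
  kolo <- sim$annotations$L$repeats
  kolo <- kolo[!is.na(kolo$label) & kolo$label == "Kolobok", , drop = FALSE]
  enr_ann <- annotation_enrichment(specific, sim$annotations$L$p300,
                                   list(Kolobok = kolo))
  prox <- tryCatch(proximity_expression_test(
    specific, tss_points(gff_genes(sim$gene_models$L, "L")),
    sim$expression), error = function(e) list(error = conditionMessage(e)))
  report$regland <- list(
    p300_conserved_fraction = consv$fraction,
    n_specific_peaks = nrow(specific),
    kolo_enrichment = as.list(enr_ann[1, c("fold", "prevalence", "p", "pass")]),
    kolo_per_mb = list(
      L = repeats_per_megabase(kolo, sum(sim$chrom_sizes$L)),
      S = repeats_per_megabase(
        sim$annotations$S$repeats[!is.na(sim$annotations$S$repeats$label) &
          sim$annotations$S$repeats$label == "Kolobok", , drop = FALSE],
        sum(sim$chrom_sizes$S)),
      T = repeats_per_megabase(
        sim$annotations$T$repeats[!is.na(sim$annotations$T$repeats$label) &
          sim$annotations$T$repeats$label == "Kolobok", , drop = FALSE],
        sum(sim$chrom_sizes$T))),
    proximity = prox)

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE)
  invisible(report)
}

## interval sets from the generator's gene-model row tables
gff_cds <- function(rows, genome) {
  r <- rows[rows$type == "CDS", , drop = FALSE]
  sort_intervals(interval_set(r$chrom, r$start, r$end, strand = r$strand,
                              label = r$id, genome = genome))
}

gff_genes <- function(rows, genome) {
  r <- rows[rows$type == "gene", , drop = FALSE]
  sort_intervals(interval_set(r$chrom, r$start, r$end, strand = r$strand,
                              label = r$id, genome = genome))
}
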