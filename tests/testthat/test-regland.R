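identity_aln <- function(len = 10000, ga = "L", gb = "T") {
  alignment_set(data.frame(a_chrom = "cA", a_start = 0, a_end = len,
                           b_chrom = "cB", b_start = 0, b_end = len,
                           strand = "+", identity = 1, reciprocal = TRUE),
                ga, gb)
}

test_that("peak conservation needs aligned sequence plus a target peak", {
  aln <- identity_aln()
  ref <- interval_set("cA", c(100, 5000), c(400, 5300), genome = "L")
  tgt <- interval_set("cB", 100, 400, genome = "T")
  out <- peak_conservation(ref, aln, tgt)
  expect_equal(out$conserved, c(TRUE, FALSE))
  expect_equal(out$fraction, 0.5)
  ## identical peak sets on an identity alignment: fraction 1
  both <- peak_conservation(ref, aln,
                            interval_set("cB", c(100, 5000), c(400, 5300),
                                         genome = "T"))
  expect_equal(both$fraction, 1)
  ## a peak with no aligned sequence is never conserved
  off <- interval_set("cZ", 0, 300, genome = "L")
  expect_equal(peak_conservation(off, aln, tgt)$fraction, 0)
})

test_that("subgenome-specific peaks tolerate zero aligned bp by default", {
  aln_s <- identity_aln(ga = "L", gb = "S")
  aln_t <- identity_aln(ga = "L", gb = "T")
  peaks <- interval_set("cA", c(0, 20000), c(300, 20300), genome = "L")
  sp <- subgenome_specific_peaks(peaks, aln_s, aln_t)
  expect_equal(nrow(sp), 1)               # only the unaligned peak survives
  expect_equal(sp$start, 20000)
  ## 1 aligned bp is enough to disqualify under the strict default
  edge <- interval_set("cA", 9999, 10300, genome = "L")
  expect_equal(nrow(subgenome_specific_peaks(edge, aln_s, aln_t)), 0)
  expect_equal(nrow(subgenome_specific_peaks(edge, aln_s, aln_t,
                                             max_aligned_bp = 5)), 1)
})

test_that("annotation enrichment reproduces constructed counts", {
  set.seed(7)
  ## 100 peaks; annotation covers every subset peak and 3 of the others
  all_peaks <- interval_set("c", seq(0, 99000, by = 1000),
                            seq(0, 99000, by = 1000) + 300, genome = "L")
  subset <- all_peaks[1:10, , drop = FALSE]
  ann <- list(fam = interval_set("c", c(seq(0, 9000, by = 1000), c(50000, 60000, 70000)),
                                 c(seq(0, 9000, by = 1000), c(50000, 60000, 70000)) + 300,
                                 genome = "L"))
  out <- annotation_enrichment(subset, all_peaks, ann)
  expect_equal(out$k, 10)
  expect_equal(out$K, 13)
  expect_equal(out$fold, (10 / 10) / (13 / 100))
  expect_equal(out$prevalence, 1)
  expect_equal(out$p, hypergeometric_tail(10, 13, 10, 100))
  expect_true(out$pass)
  ## subset = all peaks: fold is exactly 1, never passing a 2x threshold
  out2 <- annotation_enrichment(all_peaks, all_peaks, ann)
  expect_equal(out2$fold, 1)
  expect_false(out2$pass)
  expect_error(annotation_enrichment(all_peaks[0, ], all_peaks, ann), "empty")
})

test_that("null subsets show no enrichment at the thresholds", {
  set.seed(9)
  all_peaks <- interval_set("c", seq(0, 199000, by = 2000),
                            seq(0, 199000, by = 2000) + 300, genome = "L")
  ann <- list(fam = all_peaks[sample.int(100, 30), , drop = FALSE])
  hits <- 0
  for (i in 1:40) {
    subset <- all_peaks[sample.int(100, 15), , drop = FALSE]
    out <- annotation_enrichment(subset, all_peaks, ann)
    hits <- hits + out$pass
  }
  expect_lte(hits, 1)
})

test_that("repeats per megabase is a plain rate", {
  ann <- interval_set("c", seq(0, 99), seq(0, 99) + 1, genome = "g")
  expect_equal(repeats_per_megabase(ann, 1e7), 10)
  expect_equal(repeats_per_megabase(ann[0, ], 1e7), 0)
  expect_error(repeats_per_megabase(ann, 0), "positive")
})

test_that("active-transcription thresholding is mean + 2 SD per mark, both required", {
  bg <- list(H3K36me3 = c(0.5, 1.5), RNAPII = c(1, 3))
  th <- active_transcription_threshold(bg)
  expect_equal(unname(th["H3K36me3"]), 1 + 2 * sd(c(0.5, 1.5)))
  sig <- data.frame(H3K36me3 = c(3, 3, 1), RNAPII = c(6, 1, 6))
  expect_equal(is_actively_transcribed(sig, th), c(TRUE, FALSE, FALSE))
  ## constant background: threshold = the constant, boundary passes
  thc <- active_transcription_threshold(list(m = c(2, 2, 2)))
  expect_equal(unname(thc), 2)
  expect_true(is_actively_transcribed(data.frame(m = 2), thc))
  ## scale equivariance of the labels
  th10 <- active_transcription_threshold(lapply(bg, `*`, 10))
  expect_equal(is_actively_transcribed(sig * 10, th10),
               is_actively_transcribed(sig, th))
  expect_error(active_transcription_threshold(list(m = 1)), ">= 2")
})

test_that("TSS extraction is strand-aware", {
  genes <- interval_set("c", c(100, 500), c(200, 700),
                        strand = c("+", "-"), label = c("g1", "g2"),
                        genome = "L")
  tss <- tss_points(genes)
  expect_equal(tss$start, c(100, 699))
  expect_equal(tss$end - tss$start, c(1, 1))
})

test_that("the proximity test includes the 5-kb boundary and needs both groups", {
  enh <- interval_set("c", 10000, 10500, genome = "L")
  genes <- interval_set("c", c(4999, 15500, 40000), c(5100, 15800, 40200),
                        strand = "+", label = c("gA", "gB", "gC"), genome = "L")
  tss <- tss_points(genes)
  expr <- data.frame(gene_id = c("gA", "gB", "gC"), tpm = c(50, 40, 1))
  ## gA TSS at 4999: distance to [10000,10500) is 5001 -> far;
  ## gB TSS at 15500: distance 15500 - 10500 + 1 = 5001 -> far... move it
  genes2 <- interval_set("c", c(5000, 15499, 40000), c(5100, 15800, 40200),
                         strand = "+", label = c("gA", "gB", "gC"), genome = "L")
  out <- proximity_expression_test(enh, tss_points(genes2), expr)
  expect_equal(out$n_near, 2)             # both sit exactly at 5000 bp
  expect_equal(out$n_far, 1)
  expect_error(proximity_expression_test(
    interval_set("c", 39000, 39500, genome = "L"),
    tss_points(genes2)[3, , drop = FALSE], expr), "group")
})

test_that("enhancers planted next to expressed genes shift the test", {
  set.seed(18)
  n <- 60
  pos <- seq(10000, by = 20000, length.out = n)
  genes <- interval_set(rep("c", n), pos, pos + 500, strand = "+",
                        label = sprintf("g%02d", 1:n), genome = "L")
  tpm <- 2^rnorm(n, 3, 1.5)
  top <- order(tpm, decreasing = TRUE)[1:15]
  enh <- interval_set(rep("c", 15), pos[top] - 3000, pos[top] - 2500,
                      genome = "L")
  out <- proximity_expression_test(enh, tss_points(genes),
                                   data.frame(gene_id = genes$label, tpm = tpm))
  expect_lt(out$p, 1e-4)
  expect_gt(out$median_tpm_near, out$median_tpm_far)
})
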