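## small constructed triangles for feature-level tests
triangle <- function(t, l, s) c(T = t, L = l, S = s)

test_that("feature classification applies the printed thresholds", {
  ## truncated_50: ungapped CDS must be < half of homeolog AND ortholog
  base <- strrep("ATGAAACCTGGT", 25)                # 300 bp, in frame
  tr <- paste0(substr(base, 1, 120), strrep("-", 180))  # 120 bp kept: 40%
  aln <- triangle(base, base, tr)
  f <- classify_pseudogene_features(aln)
  expect_true(f$truncated_50[f$copy == "S"])
  expect_false(f$truncated_50[f$copy == "L"])
  ## 55% kept is not truncated
  tr2 <- paste0(substr(base, 1, 165), strrep("-", 135))
  f2 <- classify_pseudogene_features(triangle(base, base, tr2))
  expect_false(f2$truncated_50[f2$copy == "S"])
  ## identical intact copies: all features false
  f3 <- classify_pseudogene_features(triangle(base, base, base))
  expect_false(any(as.matrix(f3[c("premature_stop", "frameshift",
                                  "truncated_50", "promoter_loss_75")])))
})

test_that("aligned-frame stops and frameshifts are separated", {
  base <- strrep("ATGAAACCTGGT", 10)
  ## substitute codon 4 (AAA -> TAA) in S only
  s <- base; substr(s, 10, 12) <- "TAA"
  f <- classify_pseudogene_features(triangle(base, base, s))
  expect_true(f$premature_stop[f$copy == "S"])
  expect_false(f$frameshift[f$copy == "S"])
  ## 1-bp gap: frameshift, and no stop is imputed from the shifted frame
  fs <- paste0(substr(base, 1, 30), "-", substr(base, 32, nchar(base)))
  f2 <- classify_pseudogene_features(triangle(base, base, fs))
  expect_true(f2$frameshift[f2$copy == "S"])
  expect_false(f2$premature_stop[f2$copy == "S"])
})

test_that("promoter loss uses the projected homeolog promoter", {
  ## L promoter [1000,2000); alignment covers only [1800,2000) on S side:
  ## 80% of the promoter is unaligned -> lost
  prom <- interval_set("cL", 1000, 2000, genome = "L")
  aln <- alignment_set(data.frame(
    a_chrom = "cL", a_start = 1800, a_end = 2600,
    b_chrom = "cS", b_start = 100, b_end = 900,
    strand = "+", identity = 1, reciprocal = TRUE), "L", "S")
  expect_equal(promoter_loss_fraction(prom, aln, "S"), 0.8)
  ## fully aligned promoter, nothing deleted: no loss
  aln2 <- alignment_set(data.frame(
    a_chrom = "cL", a_start = 0, a_end = 3000,
    b_chrom = "cS", b_start = 0, b_end = 3000,
    strand = "+", identity = 1, reciprocal = TRUE), "L", "S")
  expect_equal(promoter_loss_fraction(prom, aln2, "S"), 0)
  ## aligned but the projection falls in deletion footprints: lost again
  dels <- interval_set("cS", 1000, 2000, genome = "S")
  expect_equal(promoter_loss_fraction(prom, aln2, "S", dels), 1)
})

test_that("promoter_of prefers the peak overlapping the TSS", {
  tss <- interval_set("c", 5000, 5001, genome = "L")
  peaks <- interval_set("c", c(1000, 4800), c(1500, 5400), genome = "L")
  p <- promoter_of(tss, peaks)
  expect_equal(c(p$start, p$end), c(4800, 5400))
  p2 <- promoter_of(tss, peaks[1, , drop = FALSE])   # no overlap: fallback
  expect_equal(c(p2$start, p2$end), c(4500, 5500))
})

test_that("likely pseudogenes require a feature and the tenfold rule", {
  feats <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"), copy = "S",
    premature_stop = c(TRUE, TRUE, FALSE, TRUE),
    frameshift = FALSE, truncated_50 = FALSE, promoter_loss_75 = FALSE)
  expr <- data.frame(
    gene_id = c("g1.S", "g1.L", "g2.S", "g2.L", "g3.S", "g3.L", "g4.S", "g4.L"),
    tpm = c(0.1, 5, 4, 5, 0.1, 5, 0.2, 0.5))
  out <- call_likely_pseudogenes(feats, expr)
  expect_equal(out$gene_id, "g1")      # 50x lower, homeolog expressed
  ## g2 fails the ratio, g3 has no feature, g4's homeolog is not expressed
  strict <- call_likely_pseudogenes(feats, expr, mode = "strict")
  expect_equal(strict$gene_id, "g1")
  expr$tpm[1] <- 2                     # candidate expressed above floor
  expect_equal(nrow(call_likely_pseudogenes(feats, expr, mode = "strict")), 0)
})

test_that("exclusive classes partition deterministically", {
  f <- data.frame(premature_stop = c(TRUE, FALSE, TRUE, TRUE),
                  frameshift = c(FALSE, TRUE, TRUE, FALSE),
                  truncated_50 = c(FALSE, FALSE, TRUE, FALSE),
                  promoter_loss_75 = FALSE)
  expect_equal(exclusive_class(f),
               c("stop-only", "frameshift-only", "deletion-driven", "stop-only"))
  expect_equal(exclusive_class(f[3, , drop = FALSE], priority = "none"),
               "multiple")
  none <- f[1, ]; none[] <- FALSE
  expect_error(exclusive_class(none), "at least one feature")
})

test_that("nonsense annotation is strand-aware and depth-filtered", {
  ## plus-strand gene: codon AAA at genome [103,106)
  g <- paste0(strrep("G", 100), "ATGAAACCTTAA", strrep("G", 88))
  genome <- Biostrings::DNAStringSet(c(c1 = g))
  cds <- interval_set("c1", 100, 112, strand = "+", label = "gp", genome = "X")
  v <- data.frame(chrom = "c1", pos0 = 103, ref = "A", alt = "T",
                  dp = 20, alt_reads = 8)
  out <- annotate_nonsense(v, cds, genome)
  expect_equal(out$records$codon_alt, "TAA")
  expect_true(out$per_gene$has_nonsense[out$per_gene$gene_id == "gp"])
  ## same codon, third position: AAT (Asn), not nonsense
  v3 <- transform(v, pos0 = 105)
  expect_equal(nrow(annotate_nonsense(v3, cds, genome)$records), 0)
  ## depth filters drop the record entirely
  vlow <- transform(v, dp = 8)
  expect_equal(nrow(annotate_nonsense(vlow, cds, genome)$records), 0)
  ## REF mismatch is skipped and counted
  vbad <- transform(v, ref = "C")
  outb <- annotate_nonsense(vbad, cds, genome)
  expect_equal(outb$n_ref_mismatch, 1)
  ## minus-strand gene: genome carries revcomp(ATGAAACCTTAA)
  gm <- paste0(strrep("G", 100), "TTAAGGTTTCAT", strrep("G", 88))
  genomem <- Biostrings::DNAStringSet(c(c1 = gm))
  cdsm <- interval_set("c1", 100, 112, strand = "-", label = "gm", genome = "X")
  ## coding codon 2 pos 1 (A->T) sits at genome position 108, pairing T->A
  vm <- data.frame(chrom = "c1", pos0 = 108, ref = "T", alt = "A",
                   dp = 30, alt_reads = 10)
  outm <- annotate_nonsense(vm, cdsm, genomem)
  expect_equal(nrow(outm$records), 1)
  expect_equal(outm$records$codon_alt, "TAA")
})

test_that("nonsense calls agree with the mutate-and-translate oracle", {
  set.seed(33)
  n_checked <- 0
  for (rep in 1:40) {
    strand <- sample(c("+", "-"), 1)
    cds_seq <- random_cds(30)
    pad <- paste(sample(BASES, 50, TRUE), collapse = "")
    body <- if (strand == "+") cds_seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_seq)))
    g <- paste0(pad, body, pad)
    genome <- Biostrings::DNAStringSet(c(c = g))
    cds <- interval_set("c", 50, 50 + nchar(cds_seq), strand = strand,
                        label = "g1", genome = "X")
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (k in 1:5) {
      j <- sample.int(nchar(cds_seq) - 3, 1) + 2   # skip start, stay internal
      refc <- substr(cds_seq, j + 1, j + 1)
      altc <- sample(setdiff(BASES, refc), 1)
      gpos <- if (strand == "+") 50 + j else 50 + nchar(cds_seq) - 1 - j
      v <- data.frame(chrom = "c", pos0 = gpos,
                      ref = if (strand == "+") refc else comp[[refc]],
                      alt = if (strand == "+") altc else comp[[altc]],
                      dp = 20, alt_reads = 8)
      got <- nrow(annotate_nonsense(v, cds, genome)$records) > 0
      expect_equal(got, oracle_is_nonsense(cds_seq, j, altc),
                   info = sprintf("strand %s j %d %s>%s", strand, j, refc, altc))
      n_checked <- n_checked + 1
    }
  }
  expect_equal(n_checked, 200)
})

test_that("LOF summary reproduces the printed percentages", {
  out <- lof_summary(c(L = 23667, S = 16939, X = 26550),
                     c(L = 528, S = 367, X = 388))
  expect_equal(out$table$pct_lof, c(2.23, 2.17, 1.46))
  eq <- lof_summary(c(a = 1000, b = 1000), c(a = 50, b = 50))
  expect_equal(eq$gene_tests$p, 1)
  expect_error(lof_summary(c(a = 0), c(a = 0)), "zero")
})

test_that("complex retention matches the printed counts and closed forms", {
  cs <- complex_retention_counts(170, 124, 63)
  expect_equal(cs$n_total, 357)
  expect_equal(round(100 * cs$observed_fraction, 1), 17.6)
  expect_equal(cs$q, (124 + 2 * 63) / (2 * 357))
  expect_equal(cs$expected_fraction, cs$q^2)
  expect_equal(complex_retention_counts(10, 0, 0, q = 0.3)$expected_fraction, 0.09)
  ## the dimer interface classifies statuses, dropping absent members
  dimers <- data.frame(complex_id = c("c1", "c2", "c3", "c4"),
                       gene_a = c("a", "b", "c", "d"),
                       gene_b = c("e", "f", "g", "h"))
  status <- c(a = "dual", e = "dual", b = "dual", f = "single",
              c = "single", g = "single", d = "dual", h = "absent")
  out <- complex_retention(dimers, status)
  expect_equal(out$n_total, 3)
  expect_equal(out$n_both_single, 1)
  all_dual <- complex_retention(dimers[1, ], c(a = "dual", e = "dual"))
  expect_equal(all_dual$observed_fraction, 0)
  expect_equal(all_dual$expected_fraction, 0)
})
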