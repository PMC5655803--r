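## hand-built alignment sets for threshold-level tests
two_genome_aln <- function(rows, ga = "L", gb = "S") {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(a_chrom = r[[1]], a_start = r[[2]], a_end = r[[3]],
               b_chrom = r[[4]], b_start = r[[5]], b_end = r[[6]],
               strand = "+", identity = 1, reciprocal = isTRUE(r[[7]]),
               stringsAsFactors = FALSE)))
  alignment_set(df, ga, gb)
}

test_that("candidate regions are T-aligned minus sister-aligned, merged", {
  aln_lt <- two_genome_aln(list(list("cL", 0, 1000, "cT", 0, 1000, TRUE)),
                           "L", "T")
  ## sister alignment covers [0,400) and [606,1000): candidate = [400,606)
  ## minus the 6-bp mid-gap, i.e. two sub-segments 6 bp apart -> merged
  aln_ls <- two_genome_aln(list(list("cL", 0, 400, "cS", 0, 400, TRUE),
                                list("cL", 500, 506, "cS", 400, 406, TRUE),
                                list("cL", 606, 1000, "cS", 406, 800, TRUE)),
                           "L", "S")
  cand <- candidate_regions(aln_ls, aln_lt, "L", merge_gap = 10)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$start, cand$end), c(400, 606))
  ## region aligned to both T and S is never a candidate
  aln_ls_full <- two_genome_aln(list(list("cL", 0, 1000, "cS", 0, 1000, TRUE)),
                                "L", "S")
  expect_equal(nrow(candidate_regions(aln_ls_full, aln_lt, "L")), 0)
  ## non-reciprocal outgroup blocks do not count
  aln_lt_nr <- two_genome_aln(list(list("cL", 0, 1000, "cT", 0, 1000, FALSE)),
                              "L", "T")
  expect_equal(nrow(candidate_regions(aln_ls, aln_lt_nr, "L")), 0)
})

test_that("candidates overlapping assembly gaps beyond 25% are removed", {
  aln_lt <- two_genome_aln(list(list("cL", 0, 1000, "cT", 0, 1000, TRUE)),
                           "L", "T")
  aln_ls <- two_genome_aln(list(list("cL", 0, 400, "cS", 0, 400, TRUE),
                                list("cL", 600, 1000, "cS", 400, 800, TRUE)),
                           "L", "S")
  ## 200-bp candidate [400,600); implant a 70-bp N-run inside (35% > 25%)
  g <- strrep("A", 1000)
  substr(g, 451, 520) <- strrep("N", 70)
  genome <- Biostrings::DNAStringSet(c(cL = g))
  cand <- candidate_regions(aln_ls, aln_lt, "L", genome = genome)
  expect_equal(nrow(cand), 0)
  expect_equal(attr(cand, "n_gap_filtered"), 1)
  ## a 40-bp N-run (20%) passes
  g2 <- strrep("A", 1000)
  substr(g2, 451, 490) <- strrep("N", 40)
  cand2 <- candidate_regions(aln_ls, aln_lt, "L",
                             genome = Biostrings::DNAStringSet(c(cL = g2)))
  expect_equal(nrow(cand2), 1)
})

test_that("size filters apply exactly as stated", {
  aln_lt <- two_genome_aln(list(list("cL", 0, 10000, "cT", 0, 10000, TRUE)),
                           "L", "T")
  mk_ls <- function(gap) {
    ## L [4000,6000) unaligned to S; S resumes after a residual gap
    two_genome_aln(list(list("cL", 0, 4000, "cS", 0, 4000, TRUE),
                        list("cL", 6000, 10000, "cS", 4000 + gap, 8000 + gap, TRUE)),
                   "L", "S")
  }
  ## retained 2000, gap 100: 2000 >= 3*100 and 100 <= 4000 -> called
  calls <- call_deletions(candidate_regions(mk_ls(100), aln_lt, "L"), mk_ls(100))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$size_gap, 100)
  expect_equal(calls$size_retained, 2000)
  expect_equal(calls$side, "LdS")
  ## gap 900: 2000 < 3*900 -> rejected on the ratio
  calls2 <- call_deletions(candidate_regions(mk_ls(900), aln_lt, "L"), mk_ls(900))
  expect_equal(nrow(calls2), 0)
  expect_equal(unname(attr(calls2, "dropped")["ratio_too_small"]), 1)
  ## gap 4500 (> 4 kb) -> rejected even though ratio logic would differ
  calls3 <- call_deletions(candidate_regions(mk_ls(4500), aln_lt, "L"), mk_ls(4500))
  expect_equal(nrow(calls3), 0)
  expect_equal(unname(attr(calls3, "dropped")["gap_too_large"]), 1)
})

test_that("both flanks must align reciprocally to the sister", {
  aln_lt <- two_genome_aln(list(list("cL", 0, 10000, "cT", 0, 10000, TRUE)),
                           "L", "T")
  one_flank <- two_genome_aln(list(list("cL", 0, 4000, "cS", 0, 4000, TRUE)),
                              "L", "S")
  cand <- candidate_regions(one_flank, aln_lt, "L")
  cand <- cand[cand$start == 4000, , drop = FALSE]  # region right of the block
  calls <- call_deletions(cand, one_flank)
  expect_equal(nrow(calls), 0)
  expect_equal(unname(attr(calls, "dropped")["no_right_flank"]), 1)
})

test_that("implanted deletions are recovered with high precision and recall", {
  sim <- small_sim()
  truth <- sim$truth$deletions
  for (sub in c("L", "S")) {
    aln_out <- if (sub == "L") sim$aln$LT else sim$aln$ST
    cand <- candidate_regions(sim$aln$LS, aln_out, sub,
                              genome = Biostrings::DNAStringSet(sim$genome_seq[[sub]]))
    calls <- call_deletions(cand, sim$aln$LS)
    st <- recovery_stats(calls, truth)
    expect_gte(st$precision, 0.95)
    expect_gte(st$recall, 0.90)
    ## every emitted call satisfies both size constraints on the record
    expect_true(all(calls$size_gap <= 4000))
    expect_true(all(calls$size_retained >= 3 * calls$size_gap))
    ## side labels are uniform per retained genome
    expect_equal(unique(calls$side), if (sub == "L") "LdS" else "SdL")
  }
})

test_that("the size spectrum reports per-bin side ratios and degenerate bins", {
  calls <- data.frame(
    side = rep(c("LdS", "SdL"), c(10, 5)),
    size_retained = c(rep(100, 10), rep(100, 5)))
  sp <- deletion_size_spectrum(calls, n_bins = 1)
  expect_equal(sp$bins$ratio, 2)
  expect_equal(sp$overall_ratio, 2)
  only_l <- data.frame(side = rep("LdS", 4), size_retained = c(50, 60, 500, 600))
  sp2 <- deletion_size_spectrum(only_l, n_bins = 2)
  expect_true(all(!sp2$bins$ratio_defined | is.finite(sp2$bins$ratio)))
  expect_error(deletion_size_spectrum(calls[0, ]), "no calls")
})
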