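test_that("NG86 has the forced sign structure on simple pairs", {
  r <- ng86_ka_ks("ATGAAACCTGGTTTCGCTAGCAAGGACGAA",
                  "ATGAAACCTGGTTTCGCTAGCAAGGACGAA")
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_true(is.na(r$omega))
  ## one synonymous difference: Ka = 0, Ks > 0, omega = 0 is not defined
  ## (omega needs Ks > 0 and is then Ka/Ks = 0)
  r2 <- ng86_ka_ks("ATGAAACCTGGTTTCGCTAGCAAGGACGAA",
                   "ATGAAGCCTGGTTTCGCTAGCAAGGACGAA")
  expect_equal(r2$Ka, 0)
  expect_gt(r2$Ks, 0)
  expect_equal(r2$omega, 0)
  ## symmetry under sequence swap
  a <- "ATGAAACCTGGTTTCGCTAGCAAGGACGAA"
  b <- "ATGAACCCAGGTTTGGCTAGCATGGACGAA"
  expect_equal(ng86_ka_ks(a, b)[c("Ka", "Ks")], ng86_ka_ks(b, a)[c("Ka", "Ks")])
  expect_error(ng86_ka_ks("---", "---"), "no comparable codons")
})

test_that("NG86 equals the independent path-enumeration oracle", {
  ## spot-check here on random pairs; the exhaustive 2-difference sweep
  ## runs in the acceptance suite
  set.seed(2)
  sense <- CODS <- apply(expand.grid(BASES, BASES, BASES)[, 3:1], 1,
                         paste, collapse = "")
  sense <- CODS[vapply(CODS, function(c) GC[[c]] != "*", TRUE)]
  for (i in 1:25) {
    a <- paste(sample(sense, 5, TRUE), collapse = "")
    b <- paste(sample(sense, 5, TRUE), collapse = "")
    got <- ng86_ka_ks(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$Na, want$Na, tolerance = 1e-10)
    expect_equal(got$Ns, want$Ns, tolerance = 1e-10)
    expect_equal(got$La, want$La, tolerance = 1e-10)
    expect_equal(got$Ls, want$Ls, tolerance = 1e-10)
  }
})

test_that("fourfold-degenerate sites follow the genetic code", {
  expect_equal(as.numeric(fourfold_degenerate_sites("GGA")), 2)  # GGN = Gly
  expect_equal(length(fourfold_degenerate_sites("TTA")), 0)      # Leu/Phe split
  ## 9-codon toy gene, hand enumeration: 4D codons are GGx(Gly), CTx(Leu),
  ## GTx(Val), CCx(Pro), ACx(Thr), GCx(Ala), CGx(Arg), TCx(Ser)
  toy <- paste0("ATG", "GGA", "TTA", "CTG", "AAA", "GTC", "CCT", "TGG", "TCA")
  pos <- as.numeric(fourfold_degenerate_sites(toy))
  expect_equal(pos, c(3 * 1 + 2, 3 * 3 + 2, 3 * 5 + 2, 3 * 6 + 2, 3 * 8 + 2))
  ## internal stops are skipped and counted
  with_stop <- paste0("ATG", "TAA", "GGA")
  out <- fourfold_degenerate_sites(with_stop)
  expect_equal(attr(out, "skipped_stops"), 1)
})

test_that("site conservation matches the Jukes-Cantor identity expectation", {
  expect_equal(as.numeric(site_conservation("ACGT", "ACGT", 0:3)), 1)
  expect_equal(as.numeric(site_conservation("AAAA", "CCCC", 0:3)), 0)
  expect_error(site_conservation("ACGT", "ACGT", integer()), "empty")
  set.seed(6)
  n <- 20000; d <- 0.2                    # JC branch divergence
  anc <- sample(BASES, n, TRUE)
  ## simulate explicit JC: events at rate d per site, uniform new base
  evolve <- function(x, t) {
    k <- rpois(1, t * n)
    for (i in seq_len(k)) {
      p <- sample.int(n, 1)
      x[p] <- sample(setdiff(BASES, x[p]), 1)
    }
    x
  }
  a <- evolve(anc, d); b <- evolve(anc, d)
  obs <- as.numeric(site_conservation(paste(a, collapse = ""),
                                      paste(b, collapse = ""), 0:(n - 1)))
  expected <- 1 / 4 + 3 / 4 * exp(-4 / 3 * 2 * d)  # JC identity at distance 2d
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(obs - expected), 3 * se + 0.005)
})

test_that("the parsimony ancestor follows agreement then outgroup arbitration", {
  expect_equal(ancestral_at_split("G", "A", "A"), "A")  # ingroup agreement
  expect_equal(ancestral_at_split("G", "A", "G"), "G")  # outgroup arbitrates
  expect_equal(ancestral_at_split("C", "A", "G"), "N")  # three-way tie
  expect_equal(ancestral_at_split("-", "-", "-"), "-")
  ## accuracy under low divergence
  set.seed(11)
  n <- 3000
  anc <- sample(BASES, n, TRUE)
  evolve <- function(x, t) {
    k <- rpois(1, t * n)
    for (i in seq_len(k)) { p <- sample.int(n, 1); x[p] <- sample(setdiff(BASES, x[p]), 1) }
    x
  }
  l <- evolve(anc, 0.1); s <- evolve(anc, 0.1); o <- evolve(anc, 0.25)
  rec <- strsplit(ancestral_at_split(paste(o, collapse = ""),
                                     paste(l, collapse = ""),
                                     paste(s, collapse = "")), "")[[1]]
  ok <- rec != "N"
  expect_gt(mean(rec[ok] == anc[ok]), 0.95)
})

test_that("pseudogene dating inverts the mixture model", {
  expect_equal(date_pseudogene(0.2, 0.2, 34)$t_loss, 0)
  expect_equal(date_pseudogene(1, 0.2, 34)$t_loss, 34)
  expect_equal(date_pseudogene(0.6, 0.2, 34)$t_loss, 17)
  expect_equal(date_pseudogene(1.4, 0.2, 34)$t_loss, 34)   # clamped
  expect_true(date_pseudogene(0.6, 1, 34)$undatable)
  ## monotone non-decreasing in omega_obs
  ts <- vapply(seq(0.1, 1, by = 0.05), function(w)
    date_pseudogene(w, 0.1, 34)$t_loss, numeric(1))
  expect_true(all(diff(ts) >= 0))
})

test_that("the codon bootstrap is deterministic and degenerate on constants", {
  set.seed(3)
  anc <- random_cds(120)
  l <- evolve_cds(anc, 34, 0.2, rate = 0.0059)$seq
  s <- evolve_cds(anc, 34, 0.2, relaxation_time = 20, rate = 0.0059)$seq
  tt <- evolve_cds(anc, 62, 0.2, rate = 0.0059)$seq
  aln <- list(T = tt, L = l, S = s)
  b1 <- bootstrap_date(aln, pseudo = "S", functional = "L", outgroup = "T",
                       T_my = 34, n_boot = 100, seed = 7)
  b2 <- bootstrap_date(aln, pseudo = "S", functional = "L", outgroup = "T",
                       T_my = 34, n_boot = 100, seed = 7)
  expect_identical(b1[c("t_loss", "ci_low", "ci_high")],
                   b2[c("t_loss", "ci_low", "ci_high")])
  expect_true(b1$ci_low <= b1$t_loss && b1$t_loss <= b1$ci_high)
  ## zero-variation alignment: every replicate lacks synonymous signal
  zv <- list(T = anc, L = anc, S = anc)
  bz <- bootstrap_date(zv, n_boot = 20, seed = 1)
  expect_true(bz$undatable || bz$n_boot == 0)
  expect_true(attr(bz, "unreliable"))
  expect_error(bootstrap_date(list(T = "ATGTAA", L = "ATGTAA", S = "ATGTAA")),
               "10 aligned codons")
})

test_that("frameshift detection reports non-triplet gap runs individually", {
  expect_equal(nrow(detect_frameshift("ATGAAATTT", "ATG---TTT")), 0)
  fs <- detect_frameshift("ATG-AAATT", "ATGCAAATT")
  expect_equal(fs$seq, "a")
  expect_equal(fs$column, 3)
  two <- detect_frameshift(paste0("ATG-", strrep("A", 30), "--AATT"),
                           paste0("ATGC", strrep("A", 30), "CCAATT"))
  expect_equal(nrow(two), 2)
})

test_that("premature stops are in-frame and strictly internal", {
  expect_equal(as.numeric(detect_premature_stop("ATGTAATTT")), 1)
  expect_equal(length(detect_premature_stop("ATGAAATAA")), 0)
  out <- detect_premature_stop("ATGTAATT")   # ragged tail: longest prefix
  expect_equal(as.numeric(out), 1)
  expect_true(attr(out, "truncated"))
})
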