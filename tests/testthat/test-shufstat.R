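test_that("Mann-Whitney exact mode matches the printed example and symmetry", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)        # 2 of the 20 assignments are as extreme
  expect_equal(mann_whitney_u(c(1, 1, 1), c(1, 1))$p, 1)
  a <- c(3, 9, 2); b <- c(5, 1, 8, 4)
  expect_equal(mann_whitney_u(a, b)$p, mann_whitney_u(b, a)$p)
  expect_equal(mann_whitney_u(a, b)$U, length(a) * length(b) - mann_whitney_u(b, a)$U)
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("exact enumeration agrees with the oracle for all n, m <= 5", {
  set.seed(21)
  for (n in 1:5) for (m in 1:5) {
    x <- sample(1:6, n, replace = TRUE)     # ties included
    y <- sample(1:6, m, replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$p, oracle_mw_p(x, y),
                 info = sprintf("n=%d m=%d", n, m))
  }
})

test_that("the large-sample branch tracks the tie-corrected normal test", {
  set.seed(5)
  x <- rnorm(30); y <- rnorm(25) + 0.5
  mw <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(mw$U, unname(ref$statistic))
  expect_equal(mw$p, ref$p.value, tolerance = 1e-10)
})

test_that("chi-squared 2x2 matches the textbook formula and scales", {
  expect_equal(chi_squared_2x2(10, 10, 10, 10)$statistic, 0)
  expect_equal(chi_squared_2x2(10, 10, 10, 10)$p, 1)
  got <- chi_squared_2x2(20, 10, 10, 20)
  O <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(got$statistic, sum((O - E)^2 / E))
  expect_equal(chi_squared_2x2(40, 20, 20, 40)$statistic, 2 * got$statistic)
  expect_error(chi_squared_2x2(0, 0, 5, 5), "margin")
})

test_that("hypergeometric tail matches closed forms and normalizes", {
  expect_equal(hypergeometric_tail(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(hypergeometric_tail(0, 5, 5, 10), 1)
  probs <- vapply(0:5, function(k) dhyper(k, 5, 5, 5), numeric(1))
  tails <- vapply(0:5, function(k) hypergeometric_tail(k, 5, 5, 10), numeric(1))
  expect_equal(tails, rev(cumsum(rev(probs))))
  expect_error(hypergeometric_tail(6, 5, 5, 10), "inconsistent")
})

test_that("BH adjustment equals the hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.005, 0.04, 0.03, 0.8)
  expect_equal(bh_adjust(p), c(0.02, 0.04 * 4 / 3, 0.04 * 4 / 3, 0.8))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("shuffling preserves counts and lengths and respects bounds", {
  x <- interval_set(rep(c("c1", "c2"), c(30, 20)),
                    s <- sample(0:900, 50, TRUE), s + sample(1:90, 50, TRUE),
                    genome = "g")
  sizes <- c(c1 = 1000, c2 = 1000)
  sh <- shuffle_within_chromosome(x, sizes, seed = 3)
  expect_equal(table(sh$chrom), table(x$chrom))
  expect_equal(sort(sh$end - sh$start), sort(x$end - x$start))
  expect_true(all(sh$start >= 0 & sh$end <= sizes[sh$chrom]))
  sh2 <- shuffle_within_chromosome(x, sizes, seed = 3)
  expect_identical(sh, sh2)
  ## forced placement: interval exactly as long as its chromosome
  f <- shuffle_within_chromosome(interval_set("c1", 0, 1000, genome = "g"),
                                 sizes, seed = 1)
  expect_equal(c(f$start, f$end), c(0, 1000))
  expect_error(shuffle_within_chromosome(
    interval_set("c1", 0, 1001, genome = "g"), sizes), "longer")
})

test_that("enrichment is exactly zero-fold when the class covers everything", {
  sizes <- c(c1 = 10000)
  dels <- interval_set("c1", c(100, 5000), c(300, 5400), genome = "g")
  whole <- list(all = interval_set("c1", 0, 10000, genome = "g"))
  res <- deletion_enrichment(dels, whole, sizes, n_rand = 50, seed = 1)
  expect_true(all(res$log2_fold == 0))
  expect_true(all(res$degenerate))      # sd of a constant null is 0
  expect_true(all(res$p == 1))
  expect_true(all(res$q >= res$p))
})

test_that("a deletion-depleted class recovers its constructed fold", {
  ## exons occupy [0, 250000); deletions are placed only in [250000, 1e6):
  ## observed exon overlap 0 vs expected ~25% of deleted bp
  set.seed(8)
  sizes <- c(c1 = 1e6)
  exon <- list(Exonic = interval_set("c1", 0, 250000, genome = "g"))
  s <- 250000 + floor(runif(120) * (750000 - 500))
  dels <- interval_set(rep("c1", 120), s, s + 500, genome = "g")
  res <- deletion_enrichment(dels, exon, sizes, n_rand = 300, seed = 2)
  all_row <- res[res$chromosome == "all", ]
  expect_equal(all_row$observed_bp, 0)
  expect_lt(all_row$z, -5)
  expect_lt(all_row$p, 1e-6)
  expect_true(is.infinite(all_row$log2_fold) && all_row$log2_fold < 0)
})

test_that("per-chromosome folds feed the subgenome comparison", {
  set.seed(3)
  sizes <- c(c1 = 2e5, c2 = 2e5, c3 = 2e5, c4 = 2e5, c5 = 2e5)
  mkdels <- function() {
    ch <- sample(names(sizes), 60, TRUE)
    s <- floor(runif(60) * (sizes[ch] - 400))
    interval_set(ch, s, s + 400, genome = "g")
  }
  cls <- list(f = interval_set(rep(names(sizes), each = 3),
                               rep(c(0, 5e4, 1e5), 5),
                               rep(c(0, 5e4, 1e5), 5) + 8000, genome = "g"))
  rl <- deletion_enrichment(mkdels(), cls, sizes, n_rand = 100, seed = 4)
  rs <- deletion_enrichment(mkdels(), cls, sizes, n_rand = 100, seed = 5)
  cmp <- compare_subgenome_enrichment(rl, rs)
  expect_equal(nrow(cmp), 1)
  expect_true(cmp$p >= 0 && cmp$p <= 1)
})
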