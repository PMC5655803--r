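#' Mann-Whitney U test
#'
#' Rank-sum test with an exact-enumeration small-sample mode: when
#' `n + m <= 14` the two-sided p-value is computed by full enumeration of
#' all assignments of the pooled values (correct under ties), otherwise by
#' the normal approximation with tie correction. U counts pairs where an
#' `x` value exceeds a `y` value (ties count 1/2).
#'
#' @param x,y numeric samples, both non-empty.
#' @return list with `U`, `p` (two-sided) and `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p  # exact, 0.1
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  U <- u_stat(x, y)
  if (length(unique(c(x, y))) == 1)
    return(list(U = U, p = 1, method = "degenerate (all tied)"))
  if (n + m <= 14) {
    pool <- c(x, y)
    combs <- utils::combn(n + m, n)
    dev <- abs(apply(combs, 2, function(i) u_stat(pool[i], pool[-i])) - n * m / 2)
    p <- mean(dev >= abs(U - n * m / 2) - 1e-9)
    list(U = U, p = p, method = "exact enumeration")
  } else {
    r <- rank(c(x, y))
    ties <- table(r)
    mu <- n * m / 2
    sig2 <- n * m / 12 * ((n + m + 1) - sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
    if (sig2 <= 0) return(list(U = U, p = 1, method = "degenerate (all tied)"))
    z <- (U - mu) / sqrt(sig2)
    list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal approximation")
  }
}

u_stat <- function(x, y) {
  n <- length(x)
  sum(rank(c(x, y))[seq_len(n)]) - n * (n + 1) / 2
}

#' Pearson chi-squared test on a 2x2 table
#'
#' No continuity correction (df = 1), the form used for the
#' nonsense-variant rate comparisons between (sub)genomes.
#' @param a,b,c,d cell counts, row-wise.
#' @return list with `statistic` and `p`.
#' @export
chi_squared_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be >= 0")
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` when drawing `n` items from a population of `N` containing
#' `K` successes. Used for annotation enrichment of peak subsets.
#' @param k successes drawn; `K` successes in population; `n` draws;
#'   `N` population size.
#' @return upper-tail p-value.
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || n > N || K > N)
    stop("inconsistent hypergeometric counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return step-up adjusted q-values, input order preserved.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Shuffle intervals uniformly within their own chromosomes
#'
#' Length-preserving relocation, the null model of the deletion-enrichment
#' test (features stay on their chromosome, as with `bedtools shuffle
#' -chrom`). Shuffled intervals may overlap each other; pass
#' `allow_overlap = FALSE` for rejection sampling of a non-overlapping
#' placement.
#'
#' @param x an `interval_set`.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param seed optional integer seed (sets the RNG).
#' @param allow_overlap permit shuffled intervals to overlap (default).
#' @param max_tries rejection-sampling attempts when `allow_overlap = FALSE`.
#' @return An `interval_set` with identical per-chromosome interval counts
#'   and lengths.
#' @export
shuffle_within_chromosome <- function(x, chrom_sizes, seed = NULL,
                                      allow_overlap = TRUE, max_tries = 100) {
  if (!is.null(seed)) set.seed(seed)
  len <- x$end - x$start
  size <- chrom_sizes[x$chrom]
  if (any(is.na(size))) stop("chromosome missing from chrom_sizes: ",
                             x$chrom[which(is.na(size))[1]])
  if (any(len > size)) stop("interval longer than its chromosome")
  draw <- function() floor(stats::runif(nrow(x)) * (size - len + 1))
  s <- draw()
  if (!allow_overlap) {
    for (i in seq_len(max_tries)) {
      cand <- interval_set(x$chrom, s, s + len, genome = genome_of(x))
      gr <- as_granges(cand)
      if (!any(GenomicRanges::countOverlaps(gr, gr, ignore.strand = TRUE) > 1)) break
      s <- draw()
      if (i == max_tries) stop("could not place non-overlapping shuffle; chromosome too dense")
    }
  }
  interval_set(x$chrom, s, s + len, strand = x$strand, label = x$label,
               genome = genome_of(x))
}

#' Randomization test of deletion enrichment per feature class
#'
#' Compares the observed deleted basepairs overlapping each feature class
#' with the distribution over `n_rand` per-chromosome shuffles of the
#' deletions. Reports, per class and chromosome (plus a genome-wide `all`
#' row), the observed and expected bp, the log2 fold difference, the
#' z-score, a two-sided normal-tail p, and Benjamini-Hochberg q across all
#' reported tests. Enrichment direction is carried by the sign of
#' `log2_fold`.
#'
#' @param deletions `interval_set` of deletion footprints.
#' @param classes named list of `interval_set`s (feature classes, e.g.
#'   exonic/intronic/intergenic or peak footprints).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param n_rand number of randomizations.
#' @param seed optional integer seed.
#' @return data frame of class `enrichment_result` with columns `class`,
#'   `chromosome`, `observed_bp`, `expected_bp`, `sd_bp`, `log2_fold`, `z`,
#'   `p`, `q`, `degenerate`.
#' @export
deletion_enrichment <- function(deletions, classes, chrom_sizes,
                                n_rand = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(classes)) || any(!nzchar(names(classes))))
    stop("classes must be a named list")
  chroms <- names(chrom_sizes)
  dl <- split(seq_len(nrow(deletions)), factor(deletions$chrom, levels = chroms))
  len <- deletions$end - deletions$start
  idxs <- lapply(classes, coverage_index)

  obs <- obs_matrix(deletions$start, deletions$end, deletions$chrom, dl, idxs, chroms)
  rnd <- array(0, dim = c(n_rand, length(classes), length(chroms)),
               dimnames = list(NULL, names(classes), chroms))
  for (r in seq_len(n_rand)) {
    s <- floor(stats::runif(nrow(deletions)) * (chrom_sizes[deletions$chrom] - len + 1))
    rnd[r, , ] <- obs_matrix(s, s + len, deletions$chrom, dl, idxs, chroms)
  }
  rows <- list()
  for (ci in seq_along(classes)) {
    for (ch in c(chroms, "all")) {
      if (ch == "all") {
        o <- sum(obs[ci, ])
        null <- apply(rnd[, ci, , drop = FALSE], 1, sum)
      } else {
        o <- obs[ci, ch]; null <- rnd[, ci, ch]
      }
      e <- mean(null); s2 <- stats::sd(null)
      degen <- is.na(s2) || s2 == 0
      z <- if (degen) NA_real_ else (o - e) / s2
      p <- if (degen) (if (o == e) 1 else 0) else min(1, 2 * stats::pnorm(-abs(z)))
      rows[[length(rows) + 1]] <- data.frame(
        class = names(classes)[ci], chromosome = ch, observed_bp = o,
        expected_bp = e, sd_bp = ifelse(degen, 0, s2),
        log2_fold = log2(o / e), z = z, p = p, degenerate = degen,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

obs_matrix <- function(start, end, chrom, dl, idxs, chroms) {
  m <- matrix(0, nrow = length(idxs), ncol = length(chroms),
              dimnames = list(names(idxs), chroms))
  for (ci in seq_along(idxs)) {
    cov <- covered_bp(idxs[[ci]], chrom, start, end)
    for (ch in chroms) {
      ii <- dl[[ch]]
      if (length(ii)) m[ci, ch] <- sum(cov[ii])
    }
  }
  m
}

#' Compare per-chromosome enrichment folds between two genomes
#'
#' For each feature class present in both results, a Mann-Whitney U test on
#' the per-chromosome `log2_fold` values of the two genomes (the unit of
#' comparison is the chromosome).
#'
#' @param res_a,res_b `enrichment_result` data frames from
#'   [deletion_enrichment()] on the two genomes.
#' @return data frame `class`, `U`, `p`, `q`.
#' @export
compare_subgenome_enrichment <- function(res_a, res_b) {
  shared <- intersect(unique(res_a$class), unique(res_b$class))
  rows <- lapply(shared, function(cl) {
    xa <- res_a$log2_fold[res_a$class == cl & res_a$chromosome != "all"]
    xb <- res_b$log2_fold[res_b$class == cl & res_b$chromosome != "all"]
    xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
    if (!length(xa) || !length(xb))
      return(data.frame(class = cl, U = NA_real_, p = NA_real_))
    mw <- mann_whitney_u(xa, xb)
    data.frame(class = cl, U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p)
  out$q <- NA_real_
  out$q[ok] <- bh_adjust(out$p[ok])
  out
}
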