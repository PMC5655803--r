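## Codon-level evolution statistics: NG86 Ka/Ks, 4D sites, parsimony
## ancestor at the subgenome split, unitary-pseudogene dating, codon
## bootstrap, and the frameshift/premature-stop detectors.

.af_cache <- new.env(parent = emptyenv())

CODONS <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                            c("T", "C", "A", "G"), stringsAsFactors = FALSE)[, 3:1],
                1, paste, collapse = "")

codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

## NG86 conventions used throughout (documented in ?ng86_ka_ks):
##  - site fractions: changes creating a stop codon count as nonsynonymous
##  - multi-substitution codons: average over all minimal paths; paths through
##    stop codons are excluded unless every path is blocked
ng86_table <- function() {
  if (!is.null(.af_cache$ng86)) return(.af_cache$ng86)
  aa <- codon_aa(CODONS)
  sense <- aa != "*"
  nt <- c("T", "C", "A", "G")
  syn_sites <- numeric(64)
  for (i in seq_len(64)) {
    if (!sense[i]) next
    cod <- strsplit(CODONS[i], "")[[1]]
    s <- 0
    for (pos in 1:3) for (b in setdiff(nt, cod[pos])) {
      mut <- cod; mut[pos] <- b
      maa <- codon_aa(paste(mut, collapse = ""))
      if (maa == aa[i]) s <- s + 1 / 3
    }
    syn_sites[i] <- s
  }
  ## path-averaged substitution counts for every ordered codon pair
  syn_subs <- matrix(0, 64, 64); nonsyn_subs <- matrix(0, 64, 64)
  split_codons <- strsplit(CODONS, "")
  for (i in seq_len(64)) {
    if (!sense[i]) next
    for (j in seq_len(64)) {
      if (!sense[j] || i == j) next
      diffpos <- which(split_codons[[i]] != split_codons[[j]])
      k <- length(diffpos)
      ords <- if (k == 1) matrix(1) else if (k == 2) rbind(c(1, 2), c(2, 1)) else
        matrix(c(1,2,3, 1,3,2, 2,1,3, 2,3,1, 3,1,2, 3,2,1), ncol = 3, byrow = TRUE)
      paths <- list()
      for (r in seq_len(nrow(ords))) {
        cur <- split_codons[[i]]
        steps <- character(0); blocked <- FALSE; sy <- 0; ns <- 0
        for (p in diffpos[ords[r, ]]) {
          prev_aa <- codon_aa(paste(cur, collapse = ""))
          cur[p] <- split_codons[[j]][p]
          cur_codon <- paste(cur, collapse = "")
          cur_aa <- codon_aa(cur_codon)
          if (cur_aa == "*" && cur_codon != CODONS[j]) blocked <- TRUE
          if (cur_aa == prev_aa) sy <- sy + 1 else ns <- ns + 1
        }
        paths[[r]] <- c(sy = sy, ns = ns, blocked = as.numeric(blocked))
      }
      pm <- do.call(rbind, paths)
      use <- pm[, "blocked"] == 0
      if (!any(use)) use <- rep(TRUE, nrow(pm))
      syn_subs[i, j] <- mean(pm[use, "sy"])
      nonsyn_subs[i, j] <- mean(pm[use, "ns"])
    }
  }
  .af_cache$ng86 <- list(sense = sense, syn_sites = syn_sites,
                         syn_subs = syn_subs, nonsyn_subs = nonsyn_subs)
  .af_cache$ng86
}

## codon strings -> 1..64 index (NA for gap/ambiguity/non-ACGT)
codon_index <- function(codons) {
  match(chartr("U", "T", toupper(codons)), CODONS)
}

split_into_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n - 2, by = 3), seq(3, n, by = 3))
}

## per-codon NG86 contributions for two codon-index vectors; codons where
## either side is NA (gap/ambiguity) or a stop are excluded
ng86_percodon <- function(ia, ib) {
  tab <- ng86_table()
  ok <- !is.na(ia) & !is.na(ib) & tab$sense[ia] & tab$sense[ib]
  pair <- (ia - 1) * 64 + ib
  list(ok = ok,
       S = ifelse(ok, (tab$syn_sites[ia] + tab$syn_sites[ib]) / 2, 0),
       N = ifelse(ok, 3 - (tab$syn_sites[ia] + tab$syn_sites[ib]) / 2, 0),
       Sd = ifelse(ok, tab$syn_subs[pair], 0),
       Nd = ifelse(ok, tab$nonsyn_subs[pair], 0))
}

jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, ifelse(p <= 0, 0, -3 / 4 * log(1 - 4 * p / 3)))
}

rates_from_sums <- function(S, N, Sd, Nd, n_codons) {
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jc_correct(pS); Ka <- jc_correct(pN)
  omega <- if (!is.na(Ks) && Ks > 0 && !is.na(Ka)) Ka / Ks else NA_real_
  structure(list(Ka = Ka, Ks = Ks, omega = omega, Na = Nd, Ns = Sd,
                 La = N, Ls = S, n_codons = n_codons,
                 saturated = (!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)),
            class = "evolution_rates")
}

#' @export
print.evolution_rates <- function(x, ...) {
  cat(sprintf("NG86 rates over %d codons: Ka = %.4f, Ks = %.4f, Ka/Ks = %s\n",
              x$n_codons, x$Ka, x$Ks,
              if (is.na(x$omega)) "undefined" else sprintf("%.3f", x$omega)))
  invisible(x)
}

#' NG86 Ka/Ks for a pair of in-frame aligned coding sequences
#'
#' Nei-Gojobori (1986) counting with Jukes-Cantor correction. Synonymous and
#' nonsynonymous site fractions are averaged over both sequences; codons
#' differing at several positions are averaged over all minimal substitution
#' paths (paths through stop codons excluded unless all are). Changes that
#' create a stop codon count as nonsynonymous in the site calculation.
#' Codon columns containing a gap, an ambiguity character, or a stop codon
#' in either sequence are excluded.
#'
#' @param seq_a,seq_b equal-length aligned sequences (gaps `-` allowed),
#'   frame anchored at the first column, length divisible by 3.
#' @return An `evolution_rates` object: `Ka`, `Ks`, `omega` (`NA` when
#'   `Ks` is 0 or undefined), raw counts `Na`, `Ns`, site counts `La`, `Ls`,
#'   and a `saturated` flag when a proportion reaches the Jukes-Cantor
#'   singularity (p >= 0.75).
#' @examples
#' # one synonymous difference over ten codons: Ka = 0, Ks > 0
#' ng86_ka_ks("ATGAAACCTGGTTTCGCTAGCAAGGACGAA", "ATGAAGCCTGGTTTCGCTAGCAAGGACGAA")
#' @export
ng86_ka_ks <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("aligned sequences differ in length")
  if (nchar(seq_a) %% 3 != 0) stop("alignment length not divisible by 3")
  ia <- codon_index(split_into_codons(seq_a))
  ib <- codon_index(split_into_codons(seq_b))
  pc <- ng86_percodon(ia, ib)
  if (!any(pc$ok)) stop("no comparable codons")
  rates_from_sums(sum(pc$S), sum(pc$N), sum(pc$Sd), sum(pc$Nd), sum(pc$ok))
}

#' Fourfold-degenerate positions of a coding sequence
#'
#' Third positions of codons whose amino acid is invariant to all four
#' third-position nucleotides, the standard neutral proxy. Codons that are
#' stops are flagged and skipped.
#'
#' @param cds in-frame ungapped coding sequence, length divisible by 3.
#' @return 0-based positions within `cds`; attribute `skipped_stops` counts
#'   internal stop codons encountered.
#' @export
fourfold_degenerate_sites <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("length not divisible by 3")
  cods <- chartr("U", "T", toupper(split_into_codons(cds)))
  idx <- codon_index(cods)
  nt <- c("T", "C", "A", "G")
  is4d <- logical(length(cods))
  skipped <- 0
  for (i in seq_along(cods)) {
    if (is.na(idx[i])) next
    if (codon_aa(cods[i]) == "*") { skipped <- skipped + 1; next }
    pre <- substr(cods[i], 1, 2)
    aas <- codon_aa(paste0(pre, nt))
    is4d[i] <- length(unique(aas)) == 1
  }
  out <- (which(is4d) - 1) * 3 + 2
  attr(out, "skipped_stops") <- skipped
  out
}

#' Conservation at selected alignment positions
#'
#' Fraction of the given positions at which the two aligned sequences carry
#' identical, ungapped nucleotides; positions where either sequence is
#' gapped are excluded from the denominator (a deleted site is reported via
#' `n_used`).
#'
#' @param seq_a,seq_b equal-length aligned sequences.
#' @param positions 0-based alignment coordinates, non-empty.
#' @return Numeric fraction with attribute `n_used`.
#' @export
site_conservation <- function(seq_a, seq_b, positions) {
  if (!length(positions)) stop("empty position set")
  a <- strsplit(toupper(seq_a), "")[[1]][positions + 1]
  b <- strsplit(toupper(seq_b), "")[[1]][positions + 1]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no ungapped positions among those given")
  out <- mean(a[ok] == b[ok])
  attr(out, "n_used") <- sum(ok)
  out
}

#' Parsimony ancestral sequence at the subgenome split
#'
#' Per-column Fitch parsimony on the rooted triplet `((A, B), outgroup)`:
#' agreement of the two ingroup states wins; otherwise the outgroup
#' arbitrates; a three-way disagreement yields `N`, which downstream rate
#' counting excludes. Gaps are treated as a fifth state; an all-gap column
#' stays a gap.
#'
#' @param outgroup,a,b equal-length aligned sequences (outgroup and the two
#'   subgenome copies).
#' @return The ancestral sequence at the `a`/`b` split as a character string.
#' @export
ancestral_at_split <- function(outgroup, a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  co <- strsplit(toupper(outgroup), "")[[1]]
  if (length(unique(c(length(ca), length(cb), length(co)))) != 1)
    stop("aligned sequences differ in length")
  anc <- ifelse(ca == cb, ca,
         ifelse(co == ca, ca,
         ifelse(co == cb, cb, "N")))
  paste(anc, collapse = "")
}

#' Date the loss of selective constraint of a unitary pseudogene
#'
#' Under a piecewise-neutral model, a gene constrained at ratio
#' `omega_f` until it lost constraint `t` My ago and neutral afterwards
#' accumulates `Ka/Ks = (omega_f * (T - t) + t) / T` over a branch of `T`
#' My. Inverting gives `t = T * (omega_obs - omega_f) / (1 - omega_f)`,
#' clamped to `[0, T]`.
#'
#' @param omega_obs observed Ka/Ks on the pseudogene branch.
#' @param omega_f constrained (functional) Ka/Ks for the gene, `< 1`.
#' @param T_my total branch time since the subgenome split, My.
#' @return A `pseudogene_date` object (`t_loss`, `T`, `omega_obs`,
#'   `omega_f`; CI fields filled by [bootstrap_date()]).
#' @examples
#' date_pseudogene(0.6, 0.2, 34)  # t_loss = 17 My
#' @export
date_pseudogene <- function(omega_obs, omega_f, T_my) {
  if (is.na(omega_f) || omega_f < 0) stop("omega_f must be >= 0")
  if (omega_f >= 1)
    return(structure(list(t_loss = NA_real_, T = T_my, omega_obs = omega_obs,
                          omega_f = omega_f, ci_low = NA_real_, ci_high = NA_real_,
                          n_boot = 0, undatable = TRUE), class = "pseudogene_date"))
  t <- T_my * (omega_obs - omega_f) / (1 - omega_f)
  structure(list(t_loss = min(max(t, 0), T_my), T = T_my,
                 omega_obs = omega_obs, omega_f = omega_f,
                 ci_low = NA_real_, ci_high = NA_real_, n_boot = 0,
                 undatable = FALSE), class = "pseudogene_date")
}

#' @export
print.pseudogene_date <- function(x, ...) {
  if (x$undatable) { cat("undatable (omega_f >= 1)\n"); return(invisible(x)) }
  cat(sprintf("loss of constraint %.2f My ago (branch %.1f My; omega %.3f vs functional %.3f)",
              x$t_loss, x$T, x$omega_obs, x$omega_f))
  if (x$n_boot > 0)
    cat(sprintf("; bootstrap 95%% CI [%.2f, %.2f] (%d replicates)",
                x$ci_low, x$ci_high, x$n_boot))
  cat("\n")
  invisible(x)
}

#' Per-branch rates for a gene triangle
#'
#' Reconstructs the ancestor at the split of the two subgenome copies with
#' [ancestral_at_split()] and computes NG86 rates on the ancestor-to-copy
#' branches and the ancestor-to-outgroup path.
#'
#' @param aln named character vector of equal-length aligned sequences; must
#'   contain the `outgroup`, `a` and `b` taxa.
#' @param outgroup,a,b taxon names (defaults `"T"`, `"L"`, `"S"`).
#' @return list with `ancestor` plus `evolution_rates` for branches `a`,
#'   `b` and `outgroup`.
#' @export
gene_triangle_rates <- function(aln, outgroup = "T", a = "L", b = "S") {
  miss <- setdiff(c(outgroup, a, b), names(aln))
  if (length(miss)) stop("alignment lacks taxa: ", paste(miss, collapse = ", "))
  anc <- ancestral_at_split(aln[[outgroup]], aln[[a]], aln[[b]])
  list(ancestor = anc,
       a = ng86_ka_ks(anc, aln[[a]]),
       b = ng86_ka_ks(anc, aln[[b]]),
       outgroup = ng86_ka_ks(anc, aln[[outgroup]]))
}

#' Codon-resampling bootstrap of a pseudogene date
#'
#' Builds `n_boot` artificial alignments of the original codon length by
#' resampling aligned codon columns with replacement, recomputes the
#' ancestral sequence, the branch Ka/Ks values, and the loss date for each,
#' and attaches the 2.5/97.5 percentile interval to the point estimate from
#' the unresampled alignment. Replicates with zero or undefined synonymous
#' divergence on either branch are dropped; if more than half drop, the CI
#' is flagged unreliable.
#'
#' @param aln named character vector with `outgroup`, pseudogene and
#'   functional-copy taxa, codon-aligned.
#' @param pseudo name of the pseudogene taxon; `functional` its homeolog.
#' @param outgroup outgroup taxon name.
#' @param T_my branch time since the split, My.
#' @param n_boot bootstrap replicates.
#' @param seed optional integer seed.
#' @return A `pseudogene_date` with `ci_low`, `ci_high`, `n_boot` (kept
#'   replicates) and an `unreliable` attribute when >50% were dropped.
#' @export
bootstrap_date <- function(aln, pseudo = "S", functional = "L", outgroup = "T",
                           T_my = 34, n_boot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len <- nchar(aln[[1]])
  if (len %% 3 != 0) stop("alignment length not divisible by 3")
  n_cod <- len / 3
  if (n_cod < 10) stop("need at least 10 aligned codons")
  anc <- ancestral_at_split(aln[[outgroup]], aln[[functional]], aln[[pseudo]])
  ianc <- codon_index(split_into_codons(anc))
  ips <- codon_index(split_into_codons(aln[[pseudo]]))
  ifn <- codon_index(split_into_codons(aln[[functional]]))
  pc_ps <- ng86_percodon(ianc, ips)
  pc_fn <- ng86_percodon(ianc, ifn)
  date_from <- function(idx) {
    r_ps <- rates_from_sums(sum(pc_ps$S[idx]), sum(pc_ps$N[idx]),
                            sum(pc_ps$Sd[idx]), sum(pc_ps$Nd[idx]), sum(pc_ps$ok[idx]))
    r_fn <- rates_from_sums(sum(pc_fn$S[idx]), sum(pc_fn$N[idx]),
                            sum(pc_fn$Sd[idx]), sum(pc_fn$Nd[idx]), sum(pc_fn$ok[idx]))
    if (is.na(r_ps$omega) || is.na(r_fn$omega)) return(NA_real_)
    if (r_fn$omega >= 1) return(NA_real_)
    date_pseudogene(r_ps$omega, r_fn$omega, T_my)$t_loss
  }
  all_idx <- seq_len(n_cod)
  point <- date_from(all_idx)
  boots <- vapply(seq_len(n_boot), function(i)
    date_from(sample.int(n_cod, n_cod, replace = TRUE)), numeric(1))
  kept <- boots[!is.na(boots)]
  r_ps_full <- rates_from_sums(sum(pc_ps$S), sum(pc_ps$N), sum(pc_ps$Sd),
                               sum(pc_ps$Nd), sum(pc_ps$ok))
  r_fn_full <- rates_from_sums(sum(pc_fn$S), sum(pc_fn$N), sum(pc_fn$Sd),
                               sum(pc_fn$Nd), sum(pc_fn$ok))
  out <- structure(list(t_loss = point, T = T_my,
                        omega_obs = r_ps_full$omega, omega_f = r_fn_full$omega,
                        ci_low = if (length(kept)) unname(stats::quantile(kept, 0.025)) else NA_real_,
                        ci_high = if (length(kept)) unname(stats::quantile(kept, 0.975)) else NA_real_,
                        n_boot = length(kept),
                        undatable = is.na(point)), class = "pseudogene_date")
  attr(out, "unreliable") <- length(kept) < n_boot / 2
  out
}

#' Detect frameshifting gap runs in a pairwise codon alignment
#'
#' Any maximal gap run in either sequence whose length is not a multiple of
#' 3 is reported as one frameshift event; compensated shifts nearby are
#' still reported individually.
#'
#' @param seq_a,seq_b equal-length aligned sequences.
#' @return data frame `seq` (`"a"`/`"b"`), `column` (0-based alignment
#'   column of the run start), `length`.
#' @export
detect_frameshift <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("aligned sequences differ in length")
  runs <- function(s, tag) {
    r <- rle(strsplit(s, "")[[1]] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    gap <- which(r$values & r$lengths %% 3 != 0)
    if (!length(gap)) return(NULL)
    data.frame(seq = tag, column = starts[gap] - 1, length = r$lengths[gap],
               stringsAsFactors = FALSE)
  }
  out <- rbind(runs(seq_a, "a"), runs(seq_b, "b"))
  if (is.null(out)) data.frame(seq = character(), column = numeric(),
                               length = numeric()) else out
}

#' Detect premature stop codons
#'
#' In-frame stop codons strictly before the annotated terminal codon. The
#' frame is anchored at position 1; when the length is not a multiple of 3
#' the longest in-frame prefix is analyzed and flagged — the true terminal
#' codon then lies beyond the prefix, so a stop at the prefix's last codon
#' still counts as premature.
#'
#' @param cds ungapped coding sequence (terminal stop codon expected but not
#'   required).
#' @param ref_codons optional annotated codon count; stops at codon indices
#'   `< ref_codons - 1` (0-based) are premature.
#' @return 0-based codon indices of premature stops; attribute `truncated`
#'   marks a non-multiple-of-3 input.
#' @export
detect_premature_stop <- function(cds, ref_codons = NULL) {
  n <- nchar(cds)
  trunc <- n %% 3 != 0
  if (trunc) cds <- substr(cds, 1, n - n %% 3)
  cods <- split_into_codons(cds)
  idx <- codon_index(cods)
  is_stop <- !is.na(idx) & codon_aa(CODONS[idx]) == "*"
  prem <- which(is_stop)
  terminal <- if (!is.null(ref_codons)) ref_codons
    else if (trunc) length(cods) + 1 else length(cods)
  prem <- prem[prem < terminal]
  out <- prem - 1
  attr(out, "truncated") <- trunc
  out
}
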