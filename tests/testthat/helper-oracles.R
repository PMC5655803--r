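## Independent oracles used by the tests. They deliberately avoid the
## package's own counting code paths (lookup tables, rank formulas, DP
## reuse) so agreement is evidence, not tautology.

GC <- Biostrings::GENETIC_CODE
BASES <- c("A", "C", "G", "T")

## --- NG86 oracle: direct recursion over minimal substitution paths -------
oracle_codon_paths <- function(c1, c2) {
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(diffs)) return(list())
  orders <- if (length(diffs) == 1) list(diffs) else
    lapply(asplit(gtools_permutations(diffs), 1), as.numeric)
  paths <- list()
  for (ord in orders) {
    cur <- c1; steps <- character(0); blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      steps <- c(steps, if (GC[[cur]] == GC[[nxt]]) "syn" else "nonsyn")
      if (GC[[nxt]] == "*" && nxt != c2) blocked <- TRUE
      cur <- nxt
    }
    paths[[length(paths) + 1]] <- list(steps = steps, blocked = blocked)
  }
  paths
}

## all permutations of a vector (base R, no dependency)
gtools_permutations <- function(v) {
  if (length(v) == 1) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], gtools_permutations(v[-i])))
  out
}

oracle_codon_subs <- function(c1, c2) {
  paths <- oracle_codon_paths(c1, c2)
  if (!length(paths)) return(c(syn = 0, nonsyn = 0))
  ok <- Filter(function(p) !p$blocked, paths)
  if (!length(ok)) ok <- paths
  syn <- mean(vapply(ok, function(p) sum(p$steps == "syn"), numeric(1)))
  c(syn = syn, nonsyn = mean(vapply(ok, function(p)
    sum(p$steps == "nonsyn"), numeric(1))))
}

oracle_codon_sites <- function(cod) {
  s <- 0
  for (p in 1:3) for (b in setdiff(BASES, substr(cod, p, p))) {
    mut <- cod; substr(mut, p, p) <- b
    if (GC[[mut]] == GC[[cod]]) s <- s + 1 / 3
  }
  c(syn = s, nonsyn = 3 - s)
}

## full NG86 estimate computed independently (string-by-string)
oracle_ng86 <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a) - 2, 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b) - 2, 3), seq(3, nchar(seq_b), 3))
  S <- N <- Sd <- Nd <- 0
  for (i in seq_along(ca)) {
    if (grepl("[^ACGT]", ca[i]) || grepl("[^ACGT]", cb[i])) next
    if (GC[[ca[i]]] == "*" || GC[[cb[i]]] == "*") next
    sa <- oracle_codon_sites(ca[i]); sb <- oracle_codon_sites(cb[i])
    S <- S + (sa["syn"] + sb["syn"]) / 2
    N <- N + (sa["nonsyn"] + sb["nonsyn"]) / 2
    sub <- oracle_codon_subs(ca[i], cb[i])
    Sd <- Sd + sub["syn"]; Nd <- Nd + sub["nonsyn"]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else if (p <= 0) 0 else
    -3 / 4 * log(1 - 4 * p / 3)
  list(Ka = jc(unname(Nd / N)), Ks = jc(unname(Sd / S)),
       Na = unname(Nd), Ns = unname(Sd), La = unname(N), Ls = unname(S))
}

## --- Mann-Whitney enumeration oracle -------------------------------------
oracle_mw_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pool <- c(x, y)
  ustat <- function(a, b) {
    u <- 0
    for (ai in a) u <- u + sum(ai > b) + 0.5 * sum(ai == b)
    u
  }
  obs_dev <- abs(ustat(x, y) - n * m / 2)
  combs <- utils::combn(n + m, n)
  devs <- apply(combs, 2, function(i) abs(ustat(pool[i], pool[-i]) - n * m / 2))
  mean(devs >= obs_dev - 1e-9)
}

## --- Needleman-Wunsch oracle (affine approximated as linear per-column
## penalty with open cost; small inputs only) ------------------------------
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, open = 2, ext = 1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 1:n) X[i + 1, 1] <- -open - ext * i
  for (j in 1:m) Y[1, j + 1] <- -open - ext * j
  for (i in 1:n) for (j in 1:m) {
    sc <- if (ca[i] == cb[j]) match else mismatch
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sc
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## --- whole-CDS mutate-and-translate nonsense oracle -----------------------
oracle_is_nonsense <- function(cds, j, alt) {
  substr(cds, j + 1, j + 1) <- alt
  ncod <- nchar(cds) %/% 3
  aa <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1, ncod * 3)),
    if.fuzzy.codon = "solve")), "")[[1]]
  any(aa[-length(aa)] == "*")
}
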