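## Synthetic outgroup + two-subgenome system with a ground-truth ledger.
##
## Everything is laid out in a shared ancestral coordinate space per
## chromosome; each genome is the ancestor minus a set of removal segments
## (deletions, lineage-specific insertions seen from the other side), plus
## backbone substitutions and per-gene coding sequences evolved under a
## per-branch constraint model. Alignment blocks, annotations, variants and
## the truth ledger are all derived from the same layout, so they are exact
## by construction.

NT <- c("A", "C", "G", "T")

#' Configuration for the synthetic triplet-genome generator
#'
#' Defaults encode the study conditions the pipeline is meant to recover:
#' a 2:1 deletion bias against the S subgenome, a 34-My subgenome split with
#' hybridization at 17 My, neutral synonymous divergence near 0.2 per branch,
#' constrained genes at Ka/Ks ~ 0.2, homeolog expression correlation 0.6
#' with a small L bias, and a 40% conserved fraction of enhancer peaks.
#'
#' @param seed integer RNG seed; a fixed seed makes all outputs
#'   byte-identical across runs.
#' @param n_chroms,chrom_length chromosome count and length (bp).
#' @param n_genes homeologous gene triples across the genome.
#' @param cds_codons codons per coding sequence (incl. start/stop).
#' @param repeat_density fraction of each chromosome covered by background
#'   repeat elements.
#' @param n_deletions_L,n_deletions_S segments deleted from L (SdL) and
#'   from S (LdS).
#' @param deletion_size list `meanlog`, `sdlog`, `min`, `max` of the
#'   log-normal deletion size distribution (bp).
#' @param nahr_fraction fraction of deletions whose retained counterpart is
#'   flanked by a homologous repeat pair.
#' @param nahr_repeat_length length of the planted flanking repeats (bp).
#' @param t_split My since the speciation of the two subgenome ancestors
#'   (the `T` of pseudogene dating).
#' @param t_outgroup My since the outgroup split (must be `>= t_split`).
#' @param hybridization_time My since hybridization (annotation only).
#' @param neutral_rate substitutions/site/My at neutral sites.
#' @param omega_shape1,omega_shape2 Beta parameters of the functional
#'   Ka/Ks distribution across genes.
#' @param pseudogene_fraction fraction of gene pairs where one copy loses
#'   constraint.
#' @param pg_s_bias probability that the pseudogenized copy is the S one.
#' @param pg_causes named weights over implanted primary causes
#'   (`stop`, `frameshift`, `truncation`, `promoter`).
#' @param expr_meanlog2,expr_sdlog2 log2-TPM location and scale.
#' @param expr_correlation homeolog log-expression correlation.
#' @param expr_l_bias additive log2 bias of the L copy.
#' @param coding_snp_rate,nonsense_snp_rate polymorphic SNPs per coding kb
#'   (all coding; the subset engineered to create premature stops).
#' @param n_p300 p300 peaks per subgenome; `p300_conserved_fraction` of
#'   them have an outgroup counterpart, the rest sit in subgenome-specific
#'   sequence.
#' @param p300_conserved_fraction see above.
#' @param n_kolo standalone copies of the subgenome-restricted repeat
#'   family (present in L and S, absent from the outgroup).
#' @param backbone_divergence,outgroup_backbone_divergence substitution
#'   fraction applied to non-coding backbone per subgenome / outgroup.
#' @param n_runs_per_chrom assembly-gap (N-run) stretches per chromosome.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_chroms = 5, chrom_length = 2e6,
                       n_genes = 200, cds_codons = 300, repeat_density = 0.02,
                       n_deletions_L = 150, n_deletions_S = 300,
                       deletion_size = list(meanlog = log(500), sdlog = 0.8,
                                            min = 50, max = 3500),
                       nahr_fraction = 0.5, nahr_repeat_length = 1400,
                       t_split = 34, t_outgroup = 48, hybridization_time = 17,
                       neutral_rate = 0.0059,
                       omega_shape1 = 2, omega_shape2 = 8,
                       pseudogene_fraction = 0.15, pg_s_bias = 0.7,
                       pg_causes = c(stop = 0.3, frameshift = 0.25,
                                     truncation = 0.25, promoter = 0.2),
                       expr_meanlog2 = 3, expr_sdlog2 = 2,
                       expr_correlation = 0.6, expr_l_bias = 0.08,
                       coding_snp_rate = 2, nonsense_snp_rate = 0.3,
                       n_p300 = 120, p300_conserved_fraction = 0.4,
                       p300_specific_fraction = 0.2,
                       n_kolo = 50, backbone_divergence = 0.03,
                       outgroup_backbone_divergence = 0.08,
                       n_runs_per_chrom = 2) {
  cfg <- as.list(environment())
  fracs <- c(repeat_density = repeat_density, nahr_fraction = nahr_fraction,
             p300_specific_fraction = p300_specific_fraction,
             pseudogene_fraction = pseudogene_fraction, pg_s_bias = pg_s_bias,
             expr_correlation = expr_correlation,
             p300_conserved_fraction = p300_conserved_fraction)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0,1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  if (t_outgroup < t_split || t_split < hybridization_time || hybridization_time < 0)
    stop("need t_outgroup >= t_split >= hybridization_time >= 0")
  if (any(c(n_chroms, chrom_length, n_genes, cds_codons) <= 0))
    stop("sizes must be positive")
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) paste(sample(NT, n, replace = TRUE), collapse = "")

revcomp <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

## random in-frame CDS: ATG, sense codons, terminal TAA
random_cds <- function(n_codons) {
  sense <- CODONS[codon_aa(CODONS) != "*" & CODONS != "ATG"]
  paste(c("ATG", sample(sense, n_codons - 2, replace = TRUE), "TAA"),
        collapse = "")
}

#' Evolve a coding sequence under a piecewise constraint model
#'
#' Substitution proposals arrive as a Poisson process at `rate` per site per
#' My along a branch of `branch_time` My (Jukes-Cantor style: uniform site,
#' uniform alternative base). Synonymous proposals are always accepted;
#' nonsynonymous proposals are accepted with probability `omega` while the
#' gene is under constraint and always once constraint is lost
#' (`relaxation_time` My before present). Proposals creating a stop codon
#' are rejected under constraint and accepted when relaxed. Optional
#' relaxed-phase indels (length 1-3) model frameshifts.
#'
#' @param ancestral in-frame coding sequence, no internal stops.
#' @param branch_time branch length, My.
#' @param omega constrained nonsynonymous acceptance probability, `<= 1`.
#' @param relaxation_time My before present at which constraint was lost
#'   (`NULL` = never; must be `<= branch_time`).
#' @param rate neutral substitution rate, subs/site/My.
#' @param indel_rate relaxed-phase indel rate per site per My (default 0).
#' @param seed optional integer seed.
#' @return list: `seq` (descendant, ungapped), `aln` (two-row gapped
#'   alignment `ancestral`/`descendant`), `events` (data frame log of
#'   accepted changes: `time_mya`, `type`, `position`).
#' @export
evolve_cds <- function(ancestral, branch_time, omega, relaxation_time = NULL,
                       rate = 0.0059, indel_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (omega > 1) stop("omega > 1: constraint model assumes omega <= 1")
  L <- nchar(ancestral)
  if (L %% 3 != 0) stop("ancestral length must be divisible by 3")
  if (length(detect_premature_stop(ancestral))) stop("ancestral has internal stop")
  cur <- strsplit(ancestral, "")[[1]]
  events <- list()
  n_prop <- stats::rpois(1, rate * branch_time * L)
  times <- sort(stats::runif(n_prop, 0, branch_time), decreasing = TRUE)
  relax_at <- if (is.null(relaxation_time)) -1 else relaxation_time
  for (i in seq_len(n_prop)) {
    pos <- sample.int(L, 1)
    new <- sample(setdiff(NT, cur[pos]), 1)
    ci <- (pos - 1) %/% 3
    codon <- paste(cur[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
    mut <- cur; mut[pos] <- new
    codon2 <- paste(mut[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
    syn <- codon_aa(codon) == codon_aa(codon2)
    relaxed <- times[i] <= relax_at
    accept <- if (syn) TRUE
      else if (relaxed) TRUE
      else if (codon_aa(codon2) == "*") FALSE
      else stats::runif(1) < omega
    if (accept) {
      cur <- mut
      events[[length(events) + 1]] <- data.frame(
        time_mya = times[i], type = if (syn) "synonymous" else
          if (codon_aa(codon2) == "*") "stop" else "nonsynonymous",
        position = pos - 1)
    }
  }
  anc_gapped <- ancestral
  des_gapped <- paste(cur, collapse = "")
  if (indel_rate > 0 && relax_at > 0) {
    n_ind <- stats::rpois(1, indel_rate * relax_at * L)
    for (i in seq_len(n_ind)) {
      len <- sample(1:3, 1)
      pos <- sample.int(length(cur) - len, 1)
      cur <- cur[-(pos:(pos + len - 1))]
      events[[length(events) + 1]] <- data.frame(
        time_mya = stats::runif(1, 0, relax_at), type = "deletion",
        position = pos - 1)
      ## maintain gapped alignment
      dg <- strsplit(des_gapped, "")[[1]]
      unggap <- which(dg != "-")
      dg[unggap[pos:(pos + len - 1)]] <- "-"
      des_gapped <- paste(dg, collapse = "")
    }
  }
  list(seq = paste(cur, collapse = ""),
       aln = c(ancestral = anc_gapped, descendant = des_gapped),
       events = if (length(events)) do.call(rbind, events) else
         data.frame(time_mya = numeric(), type = character(), position = numeric()))
}

#' Simulate correlated homeolog expression
#'
#' Bivariate normal log2-TPM for the two copies of each gene with the given
#' correlation and an additive L bias.
#'
#' @param n gene pairs.
#' @param rho correlation of log2 TPM between homeologs.
#' @param meanlog2,sdlog2 marginal location/scale on the log2 scale.
#' @param l_bias additive log2 shift of the L copy.
#' @return data frame `tpm_l`, `tpm_s`.
#' @export
simulate_expression <- function(n, rho = 0.6, meanlog2 = 3, sdlog2 = 2,
                                l_bias = 0.08) {
  z1 <- stats::rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  data.frame(tpm_l = 2^(meanlog2 + l_bias + sdlog2 * z1),
             tpm_s = 2^(meanlog2 + sdlog2 * z2))
}

## ---- layout machinery -----------------------------------------------------

## map an ancestral coordinate to genome coordinates after removing segments
## `rem` (sorted, non-overlapping). Positions inside a removed segment map to
## the collapse point.
map_coord <- function(pos, rem) {
  if (is.null(rem) || nrow(rem) == 0) return(pos)
  cw <- c(0, cumsum(rem$end - rem$start))
  j <- findInterval(pos, rem$end)        # segments entirely at/before pos
  m <- findInterval(pos, rem$start)      # segments started at/before pos
  inside <- m > j
  out <- pos - cw[j + 1]
  if (any(inside)) out[inside] <- rem$start[m[inside]] - cw[m[inside]]
  out
}

## map a feature interval; returns NULL when (almost) nothing remains
map_feature <- function(start, end, rem, min_keep = 1) {
  s <- map_coord(start, rem); e <- map_coord(end, rem)
  if (e - s < min_keep) return(NULL)
  c(s, e)
}

mutate_chars <- function(ch, divergence) {
  n <- length(ch)
  k <- stats::rbinom(1, n, divergence)
  if (k == 0) return(ch)
  pos <- sample.int(n, k)
  ## shift each mutated base by 1-3 in A/C/G/T order: always a different base
  idx <- match(ch[pos], NT)
  idx[is.na(idx)] <- 1   # N or other: treat as A
  ch[pos] <- NT[(idx - 1 + sample.int(3, k, replace = TRUE)) %% 4 + 1]
  ch
}

mutate_string <- function(s, divergence)
  paste(mutate_chars(strsplit(s, "")[[1]], divergence), collapse = "")

## write sequence `txt` into char vector at 0-based half-open [start, end)
chv_write <- function(ch, start, txt) {
  v <- strsplit(txt, "")[[1]]
  ch[(start + 1):(start + length(v))] <- v
  ch
}

#' Simulate a full outgroup + two-subgenome system
#'
#' Writes genomes (FASTA), gene models (GFF3), repeats and peaks (BED),
#' per-gene codon alignments (FASTA), expression (TSV), variants (VCF),
#' pairwise alignment blocks (block-TSV) for L-T, S-T and L-S, a YAML
#' manifest, and a truth ledger (TSV per truth class). Deterministic for a
#' fixed seed. See [sim_config()] for the knobs.
#'
#' @param config a `sim_config`.
#' @param out_dir output directory (created).
#' @return Invisibly, a list: `config`, `dir`, `files` (named paths),
#'   `chrom_sizes` (per genome), `truth` (data frames: `deletions`,
#'   `relaxation`, `peaks`, `nonsense`, `expression`), `aln`
#'   (`alignment_set`s `LT`, `ST`, `LS`), `annotations` (interval sets),
#'   `cds_aln` (per-gene named gapped triplets), `expression` (long table).
#' @export
simulate_system <- function(config = sim_config(), out_dir) {
  set.seed(config$seed)
  nc <- config$n_chroms
  Lc <- config$chrom_length
  margin <- max(2000, 2 * config$nahr_repeat_length + 200); pad <- 3000

  ## -- per-gene assignments
  ng <- config$n_genes
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(ng)),
    chrom = rep_len(seq_len(nc), ng),
    strand = sample(c("+", "-"), ng, replace = TRUE),
    omega_f = stats::rbeta(ng, config$omega_shape1, config$omega_shape2),
    stringsAsFactors = FALSE)
  genes$pseudo <- stats::runif(ng) < config$pseudogene_fraction
  genes$pseudo_side <- ifelse(genes$pseudo,
                              ifelse(stats::runif(ng) < config$pg_s_bias, "S", "L"),
                              NA_character_)
  causes <- names(config$pg_causes)
  genes$cause <- ifelse(genes$pseudo,
                        sample(causes, ng, replace = TRUE,
                               prob = config$pg_causes), NA_character_)
  genes$relax_time <- ifelse(genes$pseudo,
                             stats::runif(ng, 0, config$t_split), NA_real_)

  ## -- element tables per chromosome (ancestral coordinates)
  cds_len <- config$cds_codons * 3
  spread <- function(n) { # distribute counts over chromosomes
    base <- rep(n %/% nc, nc); extra <- n %% nc
    if (extra) base[seq_len(extra)] <- base[seq_len(extra)] + 1
    base
  }
  del_sizes <- function(n) {
    d <- config$deletion_size
    pmin(pmax(round(stats::rlnorm(n, d$meanlog, d$sdlog)), d$min), d$max)
  }
  n_cons <- round(config$p300_conserved_fraction * config$n_p300)
  n_spec <- round(config$p300_specific_fraction * config$n_p300)
  n_div <- config$n_p300 - n_cons - n_spec
  counts <- list(del_S = spread(config$n_deletions_S),
                 del_L = spread(config$n_deletions_L),
                 peak_cons = spread(n_cons),
                 spec_L = spread(n_spec), spec_S = spread(n_spec),
                 div_L = spread(n_div), div_S = spread(n_div),
                 kolo = spread(config$n_kolo),
                 nrun = rep(config$n_runs_per_chrom, nc))
  n_bg <- spread(round(config$repeat_density * Lc * nc / 150))

  layout <- list(); truth_del <- list()
  for (ci in seq_len(nc)) {
    gidx <- which(genes$chrom == ci)
    el <- data.frame(type = character(), size = numeric(), ref = numeric())
    add <- function(el, type, sizes, ref = NA_real_)
      rbind(el, data.frame(type = type, size = sizes,
                           ref = rep_len(ref, length(sizes))))
    el <- add(el, "gene", rep(500 + cds_len, length(gidx)), gidx)
    el <- add(el, "del_S", del_sizes(counts$del_S[ci]))
    el <- add(el, "del_L", del_sizes(counts$del_L[ci]))
    el <- add(el, "peak_cons", rep(300, counts$peak_cons[ci]))
    el <- add(el, "spec_L", rep(800, counts$spec_L[ci]))
    el <- add(el, "spec_S", rep(800, counts$spec_S[ci]))
    el <- add(el, "div_L", rep(300, counts$div_L[ci]))
    el <- add(el, "div_S", rep(300, counts$div_S[ci]))
    el <- add(el, "kolo", rep(200, counts$kolo[ci]))
    el <- add(el, "nrun", rep(500, counts$nrun[ci]))
    el <- add(el, "bg", pmax(80, round(stats::rlnorm(n_bg[ci], log(150), 0.4))))
    el <- el[sample.int(nrow(el)), , drop = FALSE]
    k <- nrow(el)
    need <- 2 * pad + sum(el$size) + margin * (k - 1)
    if (need > Lc)
      stop("infeasible packing: chromosome ", ci, " needs ", need,
           " bp but has ", Lc)
    w <- stats::runif(k + 1); w <- w / sum(w)
    extra <- floor(w * (Lc - need))
    starts <- pad + cumsum(c(0, el$size[-k] + margin)) + cumsum(extra)[-(k + 1)]
    el$start <- starts; el$end <- starts + el$size
    layout[[ci]] <- el
  }

  ## NAHR flags for deletions
  for (ci in seq_len(nc)) {
    el <- layout[[ci]]
    isdel <- el$type %in% c("del_S", "del_L")
    el$nahr <- FALSE
    el$nahr[isdel] <- stats::runif(sum(isdel)) < config$nahr_fraction
    layout[[ci]] <- el
  }

  ## -- evolve gene triples
  out_branch <- 2 * config$t_outgroup - config$t_split
  anc_cds <- vapply(seq_len(ng), function(i) random_cds(config$cds_codons), "")
  ev <- function(i, side) {
    relax <- if (!is.na(genes$pseudo_side[i]) && genes$pseudo_side[i] == side)
      genes$relax_time[i] else NULL
    evolve_cds(anc_cds[i], config$t_split, genes$omega_f[i],
               relaxation_time = relax, rate = config$neutral_rate)
  }
  cds_T <- vapply(seq_len(ng), function(i)
    evolve_cds(anc_cds[i], out_branch, genes$omega_f[i],
               rate = config$neutral_rate)$seq, "")
  cds_L <- vapply(seq_len(ng), function(i) ev(i, "L")$seq, "")
  cds_S <- vapply(seq_len(ng), function(i) ev(i, "S")$seq, "")
  ## implant a guaranteed premature stop for cause == "stop"
  for (i in which(genes$pseudo & genes$cause == "stop")) {
    side <- genes$pseudo_side[i]
    s <- if (side == "L") cds_L[i] else cds_S[i]
    ci <- sample(seq(10, config$cds_codons - 10), 1)
    substr(s, ci * 3 + 1, ci * 3 + 3) <- "TAA"
    if (side == "L") cds_L[i] <- s else cds_S[i] <- s
  }

  ## -- removal segments per genome, gene-linked removals first
  rem <- list(T = vector("list", nc), L = vector("list", nc), S = vector("list", nc))
  seg <- function(start, end, kind, id = NA_character_, nahr = FALSE)
    data.frame(start = start, end = end, kind = kind, id = id, nahr = nahr,
               stringsAsFactors = FALSE)
  gene_pos <- list()   # per gene: chrom, el_start, promoter & cds anc coords, tss
  for (ci in seq_len(nc)) {
    el <- layout[[ci]]
    for (r in which(el$type == "gene")) {
      gi <- el$ref[r]; st <- genes$strand[gi]
      if (st == "+") {
        prom <- c(el$start[r], el$start[r] + 500)
        cds <- c(el$start[r] + 500, el$end[r])
      } else {
        cds <- c(el$start[r], el$start[r] + cds_len)
        prom <- c(el$start[r] + cds_len, el$end[r])
      }
      gene_pos[[genes$gene_id[gi]]] <- list(chrom = ci, prom = prom, cds = cds)
      if (genes$pseudo[gi]) {
        side <- genes$pseudo_side[gi]
        if (genes$cause[gi] == "truncation") {
          tl <- (round(0.6 * config$cds_codons)) * 3  # multiple of 3: no frameshift
          segm <- if (st == "+") seg(cds[2] - tl, cds[2], "truncation", genes$gene_id[gi])
                  else seg(cds[1], cds[1] + tl, "truncation", genes$gene_id[gi])
          rem[[side]][[ci]] <- rbind(rem[[side]][[ci]], segm)
        } else if (genes$cause[gi] == "frameshift") {
          off <- sample(seq(30, cds_len - 90, by = 3), 1)
          segm <- seg(cds[1] + off, cds[1] + off + 31, "frameshift", genes$gene_id[gi])
          rem[[side]][[ci]] <- rbind(rem[[side]][[ci]], segm)
        } else if (genes$cause[gi] == "promoter") {
          pl <- if (st == "+") c(prom[1] - 50, prom[1] + 450)
                else c(prom[1] + 50, prom[2] + 50)
          rem[[side]][[ci]] <- rbind(rem[[side]][[ci]],
                                     seg(pl[1], pl[2], "promoter", genes$gene_id[gi]))
        }
      }
    }
    for (r in which(el$type == "del_S"))
      rem$S[[ci]] <- rbind(rem$S[[ci]],
                           seg(el$start[r], el$end[r], "deletion", nahr = el$nahr[r]))
    for (r in which(el$type == "del_L"))
      rem$L[[ci]] <- rbind(rem$L[[ci]],
                           seg(el$start[r], el$end[r], "deletion", nahr = el$nahr[r]))
    for (r in which(el$type == "spec_L")) {  # L-specific: absent from S and T
      rem$S[[ci]] <- rbind(rem$S[[ci]], seg(el$start[r], el$end[r], "spec_L"))
      rem$T[[ci]] <- rbind(rem$T[[ci]], seg(el$start[r], el$end[r], "spec_L"))
    }
    for (r in which(el$type == "spec_S")) {
      rem$L[[ci]] <- rbind(rem$L[[ci]], seg(el$start[r], el$end[r], "spec_S"))
      rem$T[[ci]] <- rbind(rem$T[[ci]], seg(el$start[r], el$end[r], "spec_S"))
    }
    for (r in which(el$type == "kolo"))      # subgenome-restricted family
      rem$T[[ci]] <- rbind(rem$T[[ci]], seg(el$start[r], el$end[r], "kolo"))
  }
  for (g in names(rem)) for (ci in seq_len(nc)) {
    x <- rem[[g]][[ci]]
    if (!is.null(x)) rem[[g]][[ci]] <- x[order(x$start), , drop = FALSE]
  }

  ## -- ancestral sequences with element content
  chrom_name <- function(g, ci) paste0("chr", ci, g)
  kolo_cons <- random_dna(200)
  bg_cons <- random_dna(150)
  anc <- vector("list", nc)   # char vectors; strings are assembled once
  nahr_copies <- list()   # ancestral coords of planted repeat pairs
  for (ci in seq_len(nc)) {
    ch <- sample(NT, Lc, replace = TRUE)
    el <- layout[[ci]]
    for (r in seq_len(nrow(el))) {
      tp <- el$type[r]
      if (tp == "gene") {
        gi <- el$ref[r]
        cds <- gene_pos[[genes$gene_id[gi]]]$cds
        body <- if (genes$strand[gi] == "+") anc_cds[gi] else revcomp(anc_cds[gi])
        ch <- chv_write(ch, cds[1], body)
      } else if (tp == "kolo") {
        ch <- chv_write(ch, el$start[r], mutate_string(kolo_cons, 0.05))
      } else if (tp == "spec_L" || tp == "spec_S") {
        ch <- chv_write(ch, el$start[r] + 300, mutate_string(kolo_cons, 0.05))
      } else if (tp == "bg") {
        rep_seq <- mutate_string(substr(paste(rep(bg_cons, 20), collapse = ""),
                                        1, el$size[r]), 0.05)
        ch <- chv_write(ch, el$start[r], rep_seq)
      } else if (tp %in% c("del_S", "del_L") && el$nahr[r]) {
        ## copy straddles each deletion edge; with length >= 2*straddle + 1 kb
        ## both 1-kb flanks of the retained region expose the same copy
        ## interval, so their global alignment sees it without offset gaps
        cp <- random_dna(config$nahr_repeat_length)
        straddle <- max(50, floor((config$nahr_repeat_length - 1000) / 2))
        lft <- el$start[r] - config$nahr_repeat_length + straddle
        rgt <- el$end[r] - straddle
        ch <- chv_write(ch, lft, cp)
        ch <- chv_write(ch, rgt, cp)
        nahr_copies[[length(nahr_copies) + 1]] <-
          data.frame(chrom = ci, start = c(lft, rgt),
                     end = c(lft, rgt) + config$nahr_repeat_length)
      }
    }
    anc[[ci]] <- ch
  }

  ## -- genome sequences: backbone mutation, CDS splice, removals, N-runs
  cds_by_genome <- list(T = cds_T, L = cds_L, S = cds_S)
  div <- c(T = config$outgroup_backbone_divergence,
           L = config$backbone_divergence, S = config$backbone_divergence)
  genome_seq <- list()
  for (g in c("T", "L", "S")) {
    seqs <- character(nc)
    for (ci in seq_len(nc)) {
      ch <- mutate_chars(anc[[ci]], div[[g]])
      for (gi in which(genes$chrom == ci)) {
        cds <- gene_pos[[genes$gene_id[gi]]]$cds
        body <- cds_by_genome[[g]][gi]
        if (genes$strand[gi] == "-") body <- revcomp(body)
        ch <- chv_write(ch, cds[1], body)
      }
      rg <- rem[[g]][[ci]]
      if (!is.null(rg) && nrow(rg)) {
        keep <- rep(TRUE, Lc)
        for (k in seq_len(nrow(rg))) keep[(rg$start[k] + 1):rg$end[k]] <- FALSE
        ch <- ch[keep]
      }
      el <- layout[[ci]]
      for (r in which(el$type == "nrun")) {
        mp <- map_feature(el$start[r], el$end[r], rg)
        if (!is.null(mp)) ch[(mp[1] + 1):mp[2]] <- "N"
      }
      seqs[ci] <- paste(ch, collapse = "")
    }
    names(seqs) <- chrom_name(g, seq_len(nc))
    genome_seq[[g]] <- seqs
  }
  chrom_sizes <- lapply(genome_seq, nchar)

  ## -- alignment blocks per genome pair
  pair_blocks <- function(gx, gy, ident) {
    rows <- list()
    for (ci in seq_len(nc)) {
      cuts <- rbind(rem[[gx]][[ci]][c("start", "end")],
                    rem[[gy]][[ci]][c("start", "end")])
      if (is.null(cuts) || nrow(cuts) == 0) {
        segs <- data.frame(start = 0, end = Lc)
      } else {
        m <- merge_intervals(interval_set(rep("x", nrow(cuts)), cuts$start,
                                          cuts$end, genome = "anc"), 0)
        ks <- c(0, m$end); ke <- c(m$start, Lc)
        ok <- ke > ks
        segs <- data.frame(start = ks[ok], end = ke[ok])
      }
      rows[[ci]] <- data.frame(
        a_chrom = chrom_name(gx, ci),
        a_start = map_coord(segs$start, rem[[gx]][[ci]]),
        a_end = map_coord(segs$end, rem[[gx]][[ci]]),
        b_chrom = chrom_name(gy, ci),
        b_start = map_coord(segs$start, rem[[gy]][[ci]]),
        b_end = map_coord(segs$end, rem[[gy]][[ci]]),
        strand = "+", identity = ident, reciprocal = TRUE,
        stringsAsFactors = FALSE)
    }
    alignment_set(do.call(rbind, rows), gx, gy)
  }
  aln <- list(LT = pair_blocks("L", "T", 0.88),
              ST = pair_blocks("S", "T", 0.88),
              LS = pair_blocks("L", "S", 0.92))

  ## -- annotations in final coordinates
  map_iv <- function(g, ci, start, end, min_keep = 1)
    map_feature(start, end, rem[[g]][[ci]], min_keep)
  ann <- list()
  for (g in c("T", "L", "S")) {
    rows_rep <- list(); rows_peak <- list(); rows_spec <- list()
    for (ci in seq_len(nc)) {
      el <- layout[[ci]]
      take <- function(r, fam, min_keep = 50) {
        mp <- map_iv(g, ci, el$start[r], el$end[r], min_keep)
        if (is.null(mp)) return(NULL)
        data.frame(chrom = chrom_name(g, ci), start = mp[1], end = mp[2],
                   fam = fam, stringsAsFactors = FALSE)
      }
      for (r in which(el$type == "bg")) rows_rep[[length(rows_rep) + 1]] <- take(r, "bgRep")
      if (g != "T")
        for (r in which(el$type == "kolo")) rows_rep[[length(rows_rep) + 1]] <- take(r, "Kolobok")
      if (g == "L") for (r in which(el$type == "spec_L")) {
        mp <- map_iv(g, ci, el$start[r] + 300, el$start[r] + 500, 50)
        if (!is.null(mp))
          rows_rep[[length(rows_rep) + 1]] <- data.frame(chrom = chrom_name(g, ci),
            start = mp[1], end = mp[2], fam = "Kolobok")
      }
      if (g == "S") for (r in which(el$type == "spec_S")) {
        mp <- map_iv(g, ci, el$start[r] + 300, el$start[r] + 500, 50)
        if (!is.null(mp))
          rows_rep[[length(rows_rep) + 1]] <- data.frame(chrom = chrom_name(g, ci),
            start = mp[1], end = mp[2], fam = "Kolobok")
      }
      ## p300: conserved everywhere, specific on the owner only
      for (r in which(el$type == "peak_cons")) {
        mp <- map_iv(g, ci, el$start[r], el$end[r], 150)
        if (!is.null(mp))
          rows_peak[[length(rows_peak) + 1]] <- data.frame(chrom = chrom_name(g, ci),
            start = mp[1], end = mp[2], label = "conserved")
      }
      div_type <- paste0("div_", g)
      for (r in which(el$type == div_type)) {
        mp <- map_iv(g, ci, el$start[r], el$end[r], 150)
        if (!is.null(mp))
          rows_peak[[length(rows_peak) + 1]] <- data.frame(chrom = chrom_name(g, ci),
            start = mp[1], end = mp[2], label = "diverged")
      }
      spec_type <- paste0("spec_", g)
      for (r in which(el$type == spec_type)) {
        mp <- map_iv(g, ci, el$start[r] + 250, el$start[r] + 550, 150)
        if (!is.null(mp))
          rows_peak[[length(rows_peak) + 1]] <- data.frame(chrom = chrom_name(g, ci),
            start = mp[1], end = mp[2], label = "specific")
      }
    }
    ## planted NAHR repeat copies exist in every genome (ancestral)
    for (npc in nahr_copies) {
      for (k in seq_len(nrow(npc))) {
        mp <- map_iv(g, npc$chrom[k], npc$start[k], npc$end[k], 50)
        if (!is.null(mp))
          rows_rep[[length(rows_rep) + 1]] <- data.frame(
            chrom = chrom_name(g, npc$chrom[k]), start = mp[1], end = mp[2],
            fam = "nahrRep", stringsAsFactors = FALSE)
      }
    }
    rr <- do.call(rbind, rows_rep)
    rp <- do.call(rbind, rows_peak)
    ann[[g]] <- list(
      repeats = if (is.null(rr)) interval_set(character(), numeric(), numeric(), genome = g)
        else sort_intervals(interval_set(rr$chrom, rr$start, rr$end, label = rr$fam, genome = g)),
      p300 = if (is.null(rp)) interval_set(character(), numeric(), numeric(), genome = g)
        else sort_intervals(interval_set(rp$chrom, rp$start, rp$end, label = rp$label, genome = g)))
  }

  ## gene models + promoter (H3K4me3) peaks per genome
  gene_rows <- list(); h3k <- list()
  for (g in c("T", "L", "S")) {
    grows <- list(); prows <- list()
    for (gi in seq_len(ng)) {
      gp <- gene_pos[[genes$gene_id[gi]]]
      ci <- gp$chrom
      id <- paste0(genes$gene_id[gi], ".", g)
      rg <- rem[[g]][[ci]]
      ## CDS possibly split by an internal removal
      cds_parts <- list(data.frame(start = gp$cds[1], end = gp$cds[2]))
      if (!is.null(rg) && nrow(rg)) {
        hit <- rg[rg$start < gp$cds[2] & rg$end > gp$cds[1], , drop = FALSE]
        if (nrow(hit)) {
          ks <- c(gp$cds[1], hit$end); ke <- c(hit$start, gp$cds[2])
          ok <- ke > ks
          cds_parts <- list(data.frame(start = ks[ok], end = ke[ok]))
        }
      }
      parts <- cds_parts[[1]]
      mp <- lapply(seq_len(nrow(parts)), function(k)
        map_feature(parts$start[k], parts$end[k], rg))
      mp <- do.call(rbind, lapply(mp[!vapply(mp, is.null, TRUE)], function(v)
        data.frame(start = v[1], end = v[2])))
      if (is.null(mp) || nrow(mp) == 0) next
      grows[[length(grows) + 1]] <- data.frame(
        chrom = chrom_name(g, ci), start = min(mp$start), end = max(mp$end),
        strand = genes$strand[gi], id = id, type = "gene")
      for (k in seq_len(nrow(mp)))
        grows[[length(grows) + 1]] <- data.frame(
          chrom = chrom_name(g, ci), start = mp$start[k], end = mp$end[k],
          strand = genes$strand[gi], id = id, type = "CDS")
      ## promoter peak: only if >= 50% of the promoter survives
      pr <- gp$prom
      pmp <- map_feature(pr[1], pr[2], rg, min_keep = 250)
      if (!is.null(pmp))
        prows[[length(prows) + 1]] <- data.frame(
          chrom = chrom_name(g, ci), start = pmp[1], end = pmp[2], id = id)
    }
    gene_rows[[g]] <- do.call(rbind, grows)
    pdf <- do.call(rbind, prows)
    h3k[[g]] <- sort_intervals(interval_set(pdf$chrom, pdf$start, pdf$end,
                                            label = pdf$id, genome = g))
  }

  ## -- expression
  ex <- simulate_expression(ng, config$expr_correlation, config$expr_meanlog2,
                            config$expr_sdlog2, config$expr_l_bias)
  tpm_l <- ex$tpm_l; tpm_s <- ex$tpm_s
  ps_l <- genes$pseudo & genes$pseudo_side == "L"
  ps_s <- genes$pseudo & genes$pseudo_side == "S"
  tpm_l[ps_l] <- stats::runif(sum(ps_l), 0, 0.05)
  tpm_s[ps_s] <- stats::runif(sum(ps_s), 0, 0.05)
  expression <- data.frame(
    gene_id = c(paste0(genes$gene_id, ".L"), paste0(genes$gene_id, ".S")),
    tpm = round(c(tpm_l, tpm_s), 4), stringsAsFactors = FALSE)

  ## -- per-gene codon alignments (T/L/S), gaps where a copy lost sequence
  gap_mask <- function(gi, g, body) {
    gp <- gene_pos[[genes$gene_id[gi]]]
    rg <- rem[[g]][[gp$chrom]]
    ch <- strsplit(body, "")[[1]]
    if (!is.null(rg) && nrow(rg)) {
      hit <- rg[rg$start < gp$cds[2] & rg$end > gp$cds[1], , drop = FALSE]
      for (k in seq_len(nrow(hit))) {
        s <- max(hit$start[k], gp$cds[1]); e <- min(hit$end[k], gp$cds[2])
        if (genes$strand[gi] == "+") {
          ch[(s - gp$cds[1] + 1):(e - gp$cds[1])] <- "-"
        } else {
          ch[(gp$cds[2] - e + 1):(gp$cds[2] - s)] <- "-"
        }
      }
    }
    paste(ch, collapse = "")
  }
  cds_aln <- lapply(seq_len(ng), function(gi)
    c(T = gap_mask(gi, "T", cds_T[gi]),
      L = gap_mask(gi, "L", cds_L[gi]),
      S = gap_mask(gi, "S", cds_S[gi])))
  names(cds_aln) <- genes$gene_id

  ## -- variants (VCF) with an engineered nonsense subset
  vcf <- simulate_variants(genes, gene_rows, genome_seq, config)

  ## -- truth tables
  truth_del <- list()
  for (side in c("S", "L")) {
    keep_genome <- if (side == "S") "L" else "S"
    for (ci in seq_len(nc)) {
      rg <- rem[[side]][[ci]]
      if (is.null(rg) || !nrow(rg)) next
      own <- rg[rg$kind %in% c("deletion", "truncation", "frameshift", "promoter"), , drop = FALSE]
      if (!nrow(own)) next
      rk <- rem[[keep_genome]][[ci]]
      ms <- map_coord(own$start, rk); me <- map_coord(own$end, rk)
      truth_del[[length(truth_del) + 1]] <- data.frame(
        side = if (side == "S") "LdS" else "SdL",
        retained_genome = keep_genome,
        retained_chrom = chrom_name(keep_genome, ci),
        retained_start = ms, retained_end = me,
        gap_chrom = chrom_name(side, ci),
        gap_pos = map_coord(own$start, rg),
        size = own$end - own$start, nahr = own$nahr, kind = own$kind,
        gene_id = own$id, stringsAsFactors = FALSE)
    }
  }
  truth_del <- do.call(rbind, truth_del)

  truth_peaks <- do.call(rbind, lapply(c("T", "L", "S"), function(g) {
    p <- ann[[g]]$p300
    if (!nrow(p)) return(NULL)
    data.frame(genome = g, chrom = p$chrom, start = p$start, end = p$end,
               mark = "p300", label = p$label, stringsAsFactors = FALSE)
  }))
  truth_relax <- genes[genes$pseudo,
                       c("gene_id", "pseudo_side", "relax_time", "cause", "omega_f")]
  names(truth_relax)[2] <- "side"

  truth <- list(deletions = truth_del, relaxation = truth_relax,
                peaks = truth_peaks, nonsense = vcf$truth,
                expression = expression)

  ## -- write everything
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "cds_aln"), showWarnings = FALSE)
  files <- list()
  for (g in c("T", "L", "S")) {
    p <- file.path(out_dir, paste0(g, ".fa"))
    write_fasta(Biostrings::DNAStringSet(genome_seq[[g]]), p)
    files[[paste0("genome_", g)]] <- p
    p <- file.path(out_dir, paste0(g, ".gff3"))
    write_gff3(gene_rows[[g]], p)
    files[[paste0("genes_", g)]] <- p
    p <- file.path(out_dir, paste0(g, "_repeats.bed"))
    write_bed(ann[[g]]$repeats, p)
    files[[paste0("repeats_", g)]] <- p
    p <- file.path(out_dir, paste0(g, "_p300.bed"))
    write_bed(ann[[g]]$p300, p)
    files[[paste0("p300_", g)]] <- p
    p <- file.path(out_dir, paste0(g, "_h3k4me3.bed"))
    write_bed(h3k[[g]], p)
    files[[paste0("h3k4me3_", g)]] <- p
  }
  for (nm in names(aln)) {
    p <- file.path(out_dir, paste0("aln_", nm, ".tsv"))
    write_alignment_blocks(aln[[nm]], p)
    files[[paste0("aln_", nm)]] <- p
  }
  for (gi in seq_len(ng)) {
    fa <- Biostrings::DNAStringSet(cds_aln[[gi]])
    Biostrings::writeXStringSet(fa, file.path(out_dir, "cds_aln",
                                              paste0(genes$gene_id[gi], ".fa")))
  }
  files$cds_aln_dir <- file.path(out_dir, "cds_aln")
  files$expression <- file.path(out_dir, "expression.tsv")
  utils::write.table(expression, files$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files$vcf <- file.path(out_dir, "variants.vcf")
  write_vcf_min(vcf$records, files$vcf)
  for (nm in names(truth)) {
    p <- file.path(out_dir, paste0("truth_", nm, ".tsv"))
    utils::write.table(truth[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[paste0("truth_", nm)]] <- p
  }
  files$manifest <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(seed = config$seed,
                        genomes = c("T", "L", "S"),
                        chrom_sizes = lapply(chrom_sizes, as.list),
                        files = lapply(files, function(p)
                          sub(paste0("^", out_dir, "/?"), "", p))),
                   files$manifest)

  invisible(list(config = config, dir = out_dir, files = files,
                 chrom_sizes = chrom_sizes, truth = truth, aln = aln,
                 annotations = ann, h3k4me3 = h3k, genes = genes,
                 gene_models = gene_rows, cds_aln = cds_aln,
                 expression = expression, genome_seq = genome_seq))
}

write_gff3 <- function(rows, path) {
  con <- file(path, "w")
  writeLines("##gff-version 3", con)
  if (!is.null(rows) && nrow(rows)) {
    attrs <- ifelse(rows$type == "gene", paste0("ID=", rows$id),
                    paste0("Parent=", rows$id))
    writeLines(paste(rows$chrom, "synthio", rows$type, rows$start + 1, rows$end,
                     ".", rows$strand, ifelse(rows$type == "CDS", "0", "."),
                     attrs, sep = "\t"), con)
  }
  close(con)
  invisible(path)
}

write_vcf_min <- function(records, path) {
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample1"), con)
  if (!is.null(records) && nrow(records)) {
    records <- records[order(records$chrom, records$pos0), ]
    writeLines(paste(records$chrom, records$pos0 + 1, ".", records$ref,
                     records$alt, "100", "PASS", ".", "GT:DP:AD",
                     paste0("0/1:", records$dp, ":", records$dp - records$alt_reads,
                            ",", records$alt_reads), sep = "\t"), con)
  }
  close(con)
  invisible(path)
}

## per sense codon: which (position, alternative base) yields a stop codon
stop_site_table <- function() {
  if (!is.null(.af_cache$stop_sites)) return(.af_cache$stop_sites)
  tab <- list()
  for (cod in CODONS) {
    if (codon_aa(cod) == "*") next
    rows <- NULL
    for (p in 1:3) for (b in setdiff(NT, substr(cod, p, p))) {
      mut <- cod; substr(mut, p, p) <- b
      if (codon_aa(mut) == "*")
        rows <- rbind(rows, data.frame(pos = p, alt = b, stringsAsFactors = FALSE))
    }
    if (!is.null(rows)) tab[[cod]] <- rows
  }
  .af_cache$stop_sites <- tab
  tab
}

## engineered coding SNPs: a controlled nonsense subset plus benign coding SNPs
simulate_variants <- function(genes, gene_rows, genome_seq, config) {
  recs <- list(); truth <- list()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (g in c("L", "S", "T")) {
    rows <- gene_rows[[g]]
    if (is.null(rows)) next
    cds_rows <- rows[rows$type == "CDS", , drop = FALSE]
    for (id in unique(cds_rows$id)) {
      parts <- cds_rows[cds_rows$id == id, , drop = FALSE]
      parts <- parts[order(parts$start), , drop = FALSE]
      strand <- parts$strand[1]; chrom <- parts$chrom[1]
      segs <- mapply(function(s, e) substr(genome_seq[[g]][[chrom]], s + 1, e),
                     parts$start, parts$end)
      fseq <- paste(segs, collapse = "")
      cseq <- if (strand == "+") fseq else revcomp(fseq)
      L <- nchar(cseq)
      if (L < 30) next
      ## genome coordinate of coding position j (0-based)
      widths <- parts$end - parts$start
      cum <- c(0, cumsum(widths))
      gcoord <- function(j) {
        jf <- if (strand == "+") j else L - 1 - j  # position along forward concat
        k <- findInterval(jf, cum, rightmost.closed = FALSE)
        parts$start[k] + (jf - cum[k])
      }
      cods <- split_into_codons(cseq)
      ncod <- length(cods)
      ## sites where one substitution creates a premature stop (table lookup)
      s2s <- stop_site_table()
      cand <- list()
      for (ci in seq(2, ncod - 1)) {
        hits <- s2s[[cods[ci]]]
        if (is.null(hits)) next
        for (h in seq_len(nrow(hits)))
          cand[[length(cand) + 1]] <- c(j = (ci - 1) * 3 + hits$pos[h] - 1,
                                        alt = hits$alt[h])
      }
      kb <- L / 1000
      n_non <- stats::rpois(1, config$nonsense_snp_rate * kb)
      n_ben <- stats::rpois(1, config$coding_snp_rate * kb)
      if (n_non > 0 && length(cand)) {
        pick <- sample(length(cand), min(n_non, length(cand)))
        for (k in pick) {
          j <- as.numeric(cand[[k]]["j"]); altc <- cand[[k]]["alt"]
          refc <- substr(cseq, j + 1, j + 1)
          gpos <- gcoord(j)
          gref <- if (strand == "+") refc else comp[[refc]]
          galt <- if (strand == "+") altc else comp[[altc]]
          dp <- 10 + stats::rpois(1, 12)
          recs[[length(recs) + 1]] <- data.frame(chrom = chrom, pos0 = gpos,
            ref = gref, alt = unname(galt), dp = dp,
            alt_reads = 4 + stats::rbinom(1, dp - 4, 0.4), stringsAsFactors = FALSE)
          truth[[length(truth) + 1]] <- data.frame(genome = g, gene_id = id,
            chrom = chrom, pos0 = gpos, ref = gref, alt = unname(galt),
            codon_index = j %/% 3, stringsAsFactors = FALSE)
        }
      }
      if (n_ben > 0) {
        for (k in seq_len(n_ben)) {
          ## benign: synonymous or missense, never a stop
          for (try in 1:20) {
            j <- sample.int(L - 3, 1) + 2   # skip the start codon
            refc <- substr(cseq, j + 1, j + 1)
            altc <- sample(setdiff(NT, refc), 1)
            ci <- j %/% 3
            mut <- cods[ci + 1]
            substr(mut, j %% 3 + 1, j %% 3 + 1) <- altc
            if (codon_aa(cods[ci + 1]) != "*" && codon_aa(mut) != "*") break
          }
          gpos <- gcoord(j)
          dp <- 10 + stats::rpois(1, 12)
          recs[[length(recs) + 1]] <- data.frame(chrom = chrom, pos0 = gpos,
            ref = if (strand == "+") refc else comp[[refc]],
            alt = if (strand == "+") altc else unname(comp[[altc]]),
            dp = dp, alt_reads = 4 + stats::rbinom(1, dp - 4, 0.4),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  recs <- if (length(recs)) unique(do.call(rbind, recs)) else
    data.frame(chrom = character(), pos0 = numeric(), ref = character(),
               alt = character(), dp = numeric(), alt_reads = numeric())
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(genome = character(), gene_id = character(), chrom = character(),
               pos0 = numeric(), ref = character(), alt = character(),
               codon_index = numeric())
  list(records = recs, truth = truth)
}
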