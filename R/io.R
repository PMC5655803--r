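#' Read intervals from BED or GFF3
#'
#' BED is 0-based half-open and passes through unchanged; GFF3 is 1-based
#' closed on disk and the start is decremented on read so that everything
#' in memory shares the BED convention.
#'
#' @param path file path.
#' @param format `"bed"` or `"gff3"`.
#' @param genome genome identifier to attach.
#' @param feature for GFF3, keep only rows of this feature type
#'   (e.g. `"CDS"`); `NULL` keeps all.
#' @return An `interval_set`. For BED, column 4 becomes `label` and column 6
#'   `strand` when present; for GFF3 the `ID` (or `Parent`) attribute becomes
#'   `label`.
#' @export
read_intervals <- function(path, format = c("bed", "gff3"), genome = "genome",
                           feature = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
    if (!length(lines))
      return(interval_set(character(), numeric(), numeric(), genome = genome))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3))
      stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
    chrom <- vapply(parts, `[[`, "", 1)
    start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
    end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad)) stop("malformed BED line ", bad[1], ": non-numeric coordinate")
    bad <- which(end <= start | start < 0)
    if (length(bad)) stop("malformed BED line ", bad[1], ": end <= start or start < 0")
    label <- ifelse(nf >= 4, vapply(parts, function(p) if (length(p) >= 4) p[[4]] else NA_character_, ""), NA_character_)
    strand <- ifelse(nf >= 6, vapply(parts, function(p) if (length(p) >= 6) p[[6]] else ".", ""), ".")
    strand[!strand %in% c("+", "-")] <- "."
    interval_set(chrom, start, end, strand = strand, label = label, genome = genome)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    if (!is.null(feature)) gr <- gr[as.character(gr$type) %in% feature]
    lab <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
    if (!is.null(gr$Parent)) {
      par <- vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
      lab <- ifelse(is.na(lab) | lab == "", par, lab)
    }
    x <- from_granges(gr, genome, label = lab)
    if (nrow(x) && any(x$end <= x$start)) stop("GFF3 feature with end <= start after conversion")
    x
  }
}

#' Write an interval set as BED
#'
#' @param x an `interval_set`.
#' @param path output path. BED6 when any strand or label is set, else BED3.
#' @param extra optional data frame of additional columns (BED6+).
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra = NULL) {
  df <- data.frame(chrom = x$chrom, start = format(x$start, scientific = FALSE, trim = TRUE),
                   end = format(x$end, scientific = FALSE, trim = TRUE),
                   stringsAsFactors = FALSE)
  if (any(!is.na(x$label)) || any(x$strand != ".") || !is.null(extra)) {
    df$name <- ifelse(is.na(x$label), ".", x$label)
    df$score <- 0
    df$strand <- x$strand
  }
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read pairwise alignment blocks (block-TSV or MAF)
#'
#' The canonical interchange dialect is a 10-column headered TSV:
#' `a_genome a_chrom a_start a_end b_genome b_start_genome... identity`
#' (see Details). An optional 11th column `reciprocal` (0/1) declares
#' reciprocality; otherwise a block is flagged reciprocal when its mirrored
#' row (sides swapped) is present. A minimal MAF reader is provided for
#' interoperability; the first two `s` lines of each block are used and
#' identity is computed from the aligned text.
#'
#' @details Block-TSV columns: `a_genome, a_chrom, a_start, a_end, b_genome,
#'   b_chrom, b_start, b_end, strand, identity[, reciprocal]`. Coordinates
#'   0-based half-open, forward strand; `strand` is the orientation of side
#'   b relative to side a.
#' @param path file path.
#' @param dialect `"block_tsv"` or `"maf"`.
#' @param genomes optional character(2) declaring the expected genome pair;
#'   rows naming other genomes are an error.
#' @return An `alignment_set`; messages summarize self-contradictory
#'   (mutually overlapping) blocks, which are kept.
#' @export
read_alignment_blocks <- function(path, dialect = c("block_tsv", "maf"),
                                  genomes = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "maf") return(read_maf_blocks(path, genomes))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    if (is.null(genomes)) genomes <- c("a", "b")
    return(alignment_set(data.frame(a_chrom = character(), a_start = numeric(),
                                    a_end = numeric(), b_chrom = character(),
                                    b_start = numeric(), b_end = numeric(),
                                    strand = character(), identity = numeric(),
                                    reciprocal = logical()),
                         genomes[1], genomes[2]))
  }
  gpair <- unique(c(df$a_genome, df$b_genome))
  if (is.null(genomes)) {
    genomes <- c(df$a_genome[1], df$b_genome[1])
  } else if (!all(gpair %in% genomes)) {
    stop("unknown genome identifier(s): ",
         paste(setdiff(gpair, genomes), collapse = ", "))
  }
  ## canonicalize row orientation to (genomes[1] -> genomes[2])
  swap <- df$a_genome != genomes[1]
  if (any(swap)) {
    tmp <- df[swap, c("b_chrom", "b_start", "b_end")]
    df[swap, c("b_chrom", "b_start", "b_end")] <- df[swap, c("a_chrom", "a_start", "a_end")]
    df[swap, c("a_chrom", "a_start", "a_end")] <- tmp
  }
  key <- paste(df$a_chrom, df$a_start, df$a_end, df$b_chrom, df$b_start,
               df$b_end, df$strand)
  if ("reciprocal" %in% names(df)) {
    rec <- df$reciprocal %in% c(1, "1", TRUE, "TRUE")
  } else {
    both <- tapply(swap, key, function(z) any(z) && any(!z))
    rec <- as.vector(both[key])
  }
  keep <- !duplicated(key)
  blocks <- data.frame(a_chrom = df$a_chrom, a_start = df$a_start,
                       a_end = df$a_end, b_chrom = df$b_chrom,
                       b_start = df$b_start, b_end = df$b_end,
                       strand = df$strand, identity = df$identity,
                       reciprocal = rec, stringsAsFactors = FALSE)[keep, ]
  aln <- alignment_set(blocks, genomes[1], genomes[2])
  n_contra <- count_self_overlaps(aln)
  if (n_contra > 0)
    message(n_contra, " blocks overlap another block on the same genome side ",
            "(kept; downstream reciprocality filters apply)")
  aln
}

count_self_overlaps <- function(aln) {
  n <- 0
  for (side in c("a", "b")) {
    iv <- blocks_on(aln, attr(aln, paste0("genome_", side)))
    if (nrow(iv) < 2) next
    gr <- as_granges(iv)
    hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
    n <- n + (length(hits) - length(gr)) / 2
  }
  n
}

#' Write alignment blocks in the block-TSV dialect
#' @param aln an `alignment_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_blocks <- function(aln, path) {
  df <- data.frame(a_genome = attr(aln, "genome_a"), a_chrom = aln$a_chrom,
                   a_start = aln$a_start, a_end = aln$a_end,
                   b_genome = attr(aln, "genome_b"), b_chrom = aln$b_chrom,
                   b_start = aln$b_start, b_end = aln$b_end,
                   strand = aln$strand, identity = aln$identity,
                   reciprocal = as.integer(aln$reciprocal))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_maf_blocks <- function(path, genomes = NULL) {
  lines <- readLines(path)
  s_idx <- which(startsWith(lines, "s "))
  a_idx <- which(startsWith(lines, "a") & !startsWith(lines, "a_"))
  rows <- list()
  for (ai in seq_along(a_idx)) {
    lo <- a_idx[ai]
    hi <- if (ai < length(a_idx)) a_idx[ai + 1] else length(lines) + 1
    ss <- s_idx[s_idx > lo & s_idx < hi]
    if (length(ss) < 2) next
    p1 <- strsplit(trimws(lines[ss[1]]), "\\s+")[[1]]
    p2 <- strsplit(trimws(lines[ss[2]]), "\\s+")[[1]]
    parse_s <- function(p) {
      src <- strsplit(p[2], ".", fixed = TRUE)[[1]]
      start <- as.numeric(p[3]); size <- as.numeric(p[4])
      strand <- p[5]; src_size <- as.numeric(p[6])
      fstart <- if (strand == "-") src_size - start - size else start
      list(genome = src[1], chrom = paste(src[-1], collapse = "."),
           start = fstart, end = fstart + size, strand = strand, text = p[7])
    }
    q1 <- parse_s(p1); q2 <- parse_s(p2)
    c1 <- strsplit(toupper(q1$text), "")[[1]]
    c2 <- strsplit(toupper(q2$text), "")[[1]]
    ok <- c1 != "-" & c2 != "-"
    ident <- if (any(ok)) mean(c1[ok] == c2[ok]) else 0
    rows[[length(rows) + 1]] <- data.frame(
      a_genome = q1$genome, a_chrom = q1$chrom, a_start = q1$start, a_end = q1$end,
      b_genome = q2$genome, b_chrom = q2$chrom, b_start = q2$start, b_end = q2$end,
      strand = if (q1$strand == q2$strand) "+" else "-",
      identity = ident, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    if (is.null(genomes)) genomes <- c("a", "b")
    return(alignment_set(data.frame(a_chrom = character(), a_start = numeric(),
                                    a_end = numeric(), b_chrom = character(),
                                    b_start = numeric(), b_end = numeric(),
                                    strand = character(), identity = numeric(),
                                    reciprocal = logical()),
                         genomes[1], genomes[2]))
  }
  df <- do.call(rbind, rows)
  if (!is.null(genomes) && !all(unique(c(df$a_genome, df$b_genome)) %in% genomes))
    stop("unknown genome identifier in MAF")
  df$reciprocal <- TRUE  # MAF blocks come from a single symmetric alignment
  alignment_set(df[-match(c("a_genome", "b_genome"), names(df))],
                df$a_genome[1], df$b_genome[1])
}

#' Read an expression table
#' @param path TSV with columns `gene_id` and `tpm` (header required).
#' @return data frame `gene_id`, `tpm`.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "tpm") %in% names(df)))
    stop("expression table needs columns gene_id, tpm")
  df[c("gene_id", "tpm")]
}

#' Read a minimal single-sample VCF
#'
#' Accepts the VCF v4.2 subset used here: `CHROM POS ID REF ALT QUAL FILTER
#' INFO [FORMAT sample]` with per-sample `DP` (total depth) and `AD`
#' (ref,alt depths). Positions are converted to 0-based.
#'
#' @param path uncompressed VCF path.
#' @return data frame: `chrom`, `pos0`, `ref`, `alt`, `dp`, `alt_reads`.
#' @export
read_vcf_min <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  dp <- rep(NA_real_, nrow(fix)); ad_alt <- rep(NA_real_, nrow(fix))
  if (ncol(v@gt) >= 2) {
    dpm <- suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
    adm <- vcfR::extract.gt(v, "AD")
    if (!is.null(dpm)) dp <- as.numeric(dpm[, 1])
    if (!is.null(adm))
      ad_alt <- as.numeric(vapply(strsplit(adm[, 1], ","), function(z)
        if (length(z) >= 2) z[2] else NA_character_, ""))
  }
  data.frame(chrom = fix$CHROM, pos0 = as.numeric(fix$POS) - 1,
             ref = fix$REF, alt = fix$ALT, dp = dp, alt_reads = ad_alt,
             stringsAsFactors = FALSE)
}

#' Read gene models from GFF3
#'
#' Returns the gene-level intervals (strand-aware, `label` = gene ID) and
#' the CDS intervals (`label` = parent gene ID).
#' @param path GFF3 path.
#' @param genome genome identifier.
#' @return list with `interval_set`s `genes` and `cds`.
#' @export
read_gene_models <- function(path, genome = "genome") {
  list(genes = read_intervals(path, "gff3", genome, feature = "gene"),
       cds = read_intervals(path, "gff3", genome, feature = "CDS"))
}

read_fasta <- function(path) Biostrings::readDNAStringSet(path)

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 70)
  invisible(path)
}
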