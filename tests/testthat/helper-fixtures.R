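# Shared fixture builders: a small seeded simulation config and hand-built
# single/two-exon toy genes for exact, hand-worked ORF tests.

small_cfg <- function(seed = 42, ...) {
  args <- list(...)
  defaults <- list(n_genes = 6, cds_length_mean = 300, intergenic_length = 600,
                   assay_depth = 100, n_female_poly = 5, n_shared_poly = 3,
                   indel_rate = 0, seed = seed)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# Build a reference + annotation holding one gene with the given transcript
# CDS. For "-" strand the genomic insert is the reverse complement. An intron
# (sequence given) may split the CDS after `split_at` transcript bases.
toy_gene <- function(cds, strand = "+", pad = 30L, intron = NULL, split_at = NULL) {
  pad_seq <- function(n) paste(rep("C", n), collapse = "")
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  if (is.null(intron)) {
    construct <- cds
    piece_start <- 1L
    elens <- nchar(cds)
  } else {
    e1 <- substr(cds, 1L, split_at)
    e2 <- substr(cds, split_at + 1L, nchar(cds))
    construct <- paste0(e1, intron, e2)
    piece_start <- c(1L, nchar(e1) + nchar(intron) + 1L)
    elens <- c(nchar(e1), nchar(e2))
  }
  insert <- if (strand == "+") construct else revcomp(construct)
  reference <- stats::setNames(paste0(pad_seq(pad), insert, pad_seq(pad)), "chrT")
  gene_start <- pad + 1L
  gl <- nchar(construct)
  n_ex <- length(elens)
  rows <- lapply(seq_len(n_ex), function(k) {
    if (strand == "+") {
      s <- gene_start + piece_start[k] - 1L
      e <- s + elens[k] - 1L
    } else {
      e <- gene_start + gl - piece_start[k]
      s <- e - elens[k] + 1L
    }
    data.frame(gene_id = "gX", chrom = "chrT", strand = strand,
               start = s, end = e, exon_rank = k, phase = 0L)
  })
  annotation <- do.call(rbind, rows)
  attr(annotation, "genes") <- data.frame(
    gene_id = "gX", chrom = "chrT", strand = strand,
    start = gene_start, end = gene_start + gl - 1L, cds_length = nchar(cds))
  attr(annotation, "chrom") <- "chrT"
  attr(annotation, "seqlength") <- nchar(reference[[1L]])
  class(annotation) <- c("gene_models", "data.frame")
  list(reference = reference, annotation = annotation, gene_start = gene_start)
}

snp_row <- function(pos, ref, alt, chrom = "chrT") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             vclass = "SNP", stringsAsFactors = FALSE)
}

indel_row <- function(pos, ref, alt, chrom = "chrT") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             vclass = ifelse(nchar(ref) > nchar(alt), "DEL", "INS"),
             stringsAsFactors = FALSE)
}

# Exhaustive two-sided Fisher p for a 2x2 table via the hypergeometric mass
# function (independent of fisher.test's implementation path).
hyper_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0L, k - n):min(m, k)
  pr <- stats::dhyper(x, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  sum(pr[pr <= p0 * (1 + 1e-7)])
}

# brute-force oracle: a third position is silent iff every substitution there
# leaves the translation unchanged
oracle_silent_sites <- function(cds) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(cds) %/% 3
  out <- integer(0)
  for (k in seq_len(n)) {
    cod <- substr(cds, 3 * k - 2, 3 * k)
    if (!grepl("^[ACGT]{3}$", cod)) next
    aa <- gc[[cod]]
    if (aa == "*") next
    invariant <- TRUE
    for (b in setdiff(c("A", "C", "G", "T"), substr(cod, 3, 3))) {
      alt <- cod
      substr(alt, 3, 3) <- b
      if (gc[[alt]] != aa) { invariant <- FALSE; break }
    }
    if (invariant) out <- c(out, 3L * k)
  }
  out
}

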