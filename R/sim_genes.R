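#' Simulate a reference chromosome with valid gene models
#'
#' Generates a single reference (neo-X) chromosome containing \code{n_genes}
#' non-overlapping, strand-mixed genes separated by intergenic spacers. Every
#' CDS starts with ATG, ends with a single terminal stop codon, has no internal
#' in-frame stop and a length divisible by three. Exons are stored in
#' transcript (5' to 3') order with GFF-style phases.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements \code{reference} (named character vector of
#'   length 1), \code{annotation} (exon-level data frame of class
#'   \code{gene_models}; attributes \code{genes}, \code{chrom},
#'   \code{seqlength}) and \code{intergenic} (data frame of intergenic
#'   windows).
#' @export
simulate_gene_models <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chrom <- "neoX"
  sense <- sense_codons()

  pieces <- character(0)
  pos <- 0L
  exon_rows <- list()
  gene_rows <- list()
  inter_rows <- list()

  # rough capacity check: genes must fit alongside their spacers
  if (cfg$cds_length_mean < 180 || cfg$intergenic_length < 200) {
    stop("simulate_gene_models: impossible geometry", call. = FALSE)
  }

  for (i in seq_len(cfg$n_genes)) {
    gid <- sprintf("g%03d", i)

    sp_len <- max(200L, as.integer(round(stats::rnorm(1, cfg$intergenic_length,
                                                      cfg$intergenic_length * 0.1))))
    pieces <- c(pieces, random_dna(sp_len))
    inter_rows[[length(inter_rows) + 1L]] <- data.frame(
      window_id = sprintf("w%03d", i), chrom = chrom,
      start = pos + 1L, end = pos + sp_len)
    pos <- pos + sp_len

    n_cod <- max(60L, as.integer(round(stats::rnorm(1, cfg$cds_length_mean,
                                                    0.15 * cfg$cds_length_mean) / 3)))
    cds <- paste0("ATG",
                  paste(sample(sense, n_cod - 2L, replace = TRUE), collapse = ""),
                  sample(STOP_CODONS, 1L))
    cds_len <- 3L * n_cod

    n_ex <- cfg$n_exons_per_gene
    if (n_ex > 1L) {
      cuts <- round(cds_len * seq_len(n_ex - 1L) / n_ex +
                      stats::runif(n_ex - 1L, -15, 15))
      cuts <- pmin(pmax(as.integer(cuts), 30L), cds_len - 30L)
      cuts <- sort(unique(cuts))
      n_ex <- length(cuts) + 1L
    } else {
      cuts <- integer(0)
    }
    bounds <- c(0L, cuts, cds_len)
    exon_seqs <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
    intron_seqs <- if (n_ex > 1L) {
      vapply(seq_len(n_ex - 1L), function(k) random_dna(sample(60:200, 1L)), "")
    } else character(0)

    strand <- sample(c("+", "-"), 1L)
    construct <- exon_seqs[1L]
    tr_off <- nchar(exon_seqs[1L])    # offsets of exon pieces in the construct
    piece_start <- c(1L)
    for (k in seq_len(n_ex - 1L)) {
      construct <- paste0(construct, intron_seqs[k], exon_seqs[k + 1L])
      piece_start <- c(piece_start, nchar(construct) - nchar(exon_seqs[k + 1L]) + 1L)
    }
    gl <- nchar(construct)
    insert <- if (strand == "+") construct else revcomp(construct)
    gene_start <- pos + 1L
    pieces <- c(pieces, insert)
    pos <- pos + gl

    # genomic exon coordinates, rank = transcript order
    elens <- nchar(exon_seqs)
    cum <- c(0L, cumsum(elens))[seq_len(n_ex)]
    phases <- (3L - (cum %% 3L)) %% 3L
    for (k in seq_len(n_ex)) {
      if (strand == "+") {
        s <- gene_start + piece_start[k] - 1L
        e <- s + elens[k] - 1L
      } else {
        e <- gene_start + gl - piece_start[k]
        s <- e - elens[k] + 1L
      }
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        gene_id = gid, chrom = chrom, strand = strand,
        start = s, end = e, exon_rank = k, phase = phases[k])
    }
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene_id = gid, chrom = chrom, strand = strand,
      start = gene_start, end = gene_start + gl - 1L, cds_length = cds_len)
  }

  tail_len <- as.integer(cfg$intergenic_length)
  pieces <- c(pieces, random_dna(tail_len))
  inter_rows[[length(inter_rows) + 1L]] <- data.frame(
    window_id = sprintf("w%03d", cfg$n_genes + 1L), chrom = chrom,
    start = pos + 1L, end = pos + tail_len)
  pos <- pos + tail_len

  reference <- stats::setNames(paste(pieces, collapse = ""), chrom)
  annotation <- do.call(rbind, exon_rows)
  genes <- do.call(rbind, gene_rows)
  attr(annotation, "genes") <- genes
  attr(annotation, "chrom") <- chrom
  attr(annotation, "seqlength") <- pos
  class(annotation) <- c("gene_models", "data.frame")

  list(reference = reference,
       annotation = annotation,
       intergenic = do.call(rbind, inter_rows))
}

gene_table <- function(annotation) attr(annotation, "genes")

exons_of <- function(annotation, gene_id) {
  ex <- annotation[annotation$gene_id == gene_id, , drop = FALSE]
  if (nrow(ex) == 0L) stop("unknown gene id: ", gene_id, call. = FALSE)
  ex[order(ex$exon_rank), , drop = FALSE]
}

# Transcript position -> genomic position map (5'->3' transcript order).
cds_genomic_map <- function(annotation, gene_id) {
  ex <- exons_of(annotation, gene_id)
  unlist(lapply(seq_len(nrow(ex)), function(k) {
    if (ex$strand[k] == "+") seq.int(ex$start[k], ex$end[k])
    else seq.int(ex$end[k], ex$start[k])
  }), use.names = FALSE)
}

# Spliced, strand-oriented CDS of a gene on a reference sequence.
spliced_cds <- function(reference, annotation, gene_id) {
  ex <- exons_of(annotation, gene_id)
  seq <- unname(reference[1L])
  pieces <- substring(seq, ex$start, ex$end)
  if (ex$strand[1L] == "-") pieces <- vapply(pieces, revcomp, "", USE.NAMES = FALSE)
  paste(pieces, collapse = "")
}
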