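# Fixture bundle: run the full generator and write/read every pipeline input
# through the standard plain-text formats (FASTA, GFF3, VCF v4.2, TSV).
# Writers are minimal hand-rolled emitters of the package's own simulated
# data; readers go through Biostrings / rtracklayer / vcfR, so a write/read
# round trip is an independent check of the emitters.

#' Simulate a complete fixture bundle in memory
#'
#' Runs [simulate_gene_models()], [mutate_haplotype()],
#' [simulate_assay_counts()], [simulate_expression_tables()] and
#' [simulate_chip_coverage()] under one configuration.
#'
#' @param cfg A [sim_config()].
#' @return List of class \code{fixture_bundle}.
#' @export
simulate_bundle <- function(cfg) {
  gm <- simulate_gene_models(cfg)
  mh <- mutate_haplotype(gm$reference, gm$annotation, cfg)
  structure(list(
    cfg = cfg,
    reference = gm$reference,
    annotation = gm$annotation,
    intergenic = gm$intergenic,
    neo_y = mh$neo_y,
    truth = mh$truth,
    site_counts = simulate_assay_counts(mh$truth, cfg),
    expression = simulate_expression_tables(gm$annotation, gm$intergenic, cfg),
    chip = simulate_chip_coverage(gm$annotation, mh$truth, cfg)
  ), class = "fixture_bundle")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

write_vcf <- function(variants, path, sample_name, contig, contig_length) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, contig_length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t")
  ), con)
  if (nrow(variants)) {
    gt <- c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1", MISSING = "./.")[variants$gt]
    writeLines(paste(variants$chrom, variants$pos, ".", variants$ref,
                     variants$alt, format(variants$qual, trim = TRUE),
                     "PASS", ".", "GT:DP",
                     paste0(gt, ":", variants$depth), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a single-sample VCF into a variant-site table
#'
#' @param path VCF file (v4.x, GT required; DP used for depth when present).
#' @return Data frame \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{vclass}, \code{gt}, \code{qual}, \code{depth}.
#' @export
read_vcf <- function(path) {
  empty <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), vclass = character(0), gt = character(0),
                      qual = numeric(0), depth = integer(0))
  lines <- readLines(path)
  if (!any(!startsWith(lines, "#"))) return(empty)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(v, element = "GT")[, 1L]
  dp_raw <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[, 1L])
  gt <- rep("MISSING", length(gt_raw))
  gt[gt_raw %in% c("0/1", "1/0", "0|1", "1|0")] <- "HET"
  gt[gt_raw %in% c("1/1", "1|1")] <- "HOM_ALT"
  gt[gt_raw %in% c("0/0", "0|0")] <- "HOM_REF"
  ref <- unname(fix[, "REF"])
  alt <- unname(fix[, "ALT"])
  vclass <- ifelse(nchar(ref) == nchar(alt), "SNP",
                   ifelse(nchar(ref) > nchar(alt), "DEL", "INS"))
  data.frame(chrom = unname(fix[, "CHROM"]), pos = as.integer(fix[, "POS"]),
             ref = ref, alt = alt, vclass = vclass, gt = unname(gt),
             qual = as.numeric(fix[, "QUAL"]),
             depth = as.integer(dp_raw))
}

write_gff3 <- function(annotation, path, seqlength) {
  con <- file(path, "w")
  on.exit(close(con))
  chrom <- attr(annotation, "chrom")
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", chrom, seqlength)), con)
  genes <- gene_table(annotation)
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    writeLines(paste(chrom, "neosex", "gene", genes$start[i], genes$end[i], ".",
                     genes$strand[i], ".", sprintf("ID=%s", g), sep = "\t"), con)
    ex <- exons_of(annotation, g)
    for (k in seq_len(nrow(ex))) {
      writeLines(paste(chrom, "neosex", "CDS", ex$start[k], ex$end[k], ".",
                       ex$strand[k], ex$phase[k],
                       sprintf("ID=cds_%s_%d;Parent=%s", g, k, g), sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports \code{CDS} features (1-based inclusive, \code{phase} column) via
#' rtracklayer and rebuilds the exon-level annotation with transcript-order
#' exon ranks.
#'
#' @param path GFF3 file.
#' @return A \code{gene_models} data frame as from [simulate_gene_models()].
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  parent <- vapply(S4Vectors::mcols(cds)$Parent, function(p) as.character(p)[1L], "")
  df <- data.frame(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds),
    phase = as.integer(S4Vectors::mcols(cds)$phase)
  )
  parts <- split(df, df$gene_id)
  out <- do.call(rbind, lapply(parts, function(p) {
    p <- if (p$strand[1L] == "+") p[order(p$start), , drop = FALSE]
    else p[order(-p$start), , drop = FALSE]
    p$exon_rank <- seq_len(nrow(p))
    p
  }))
  out <- out[order(out$gene_id, out$exon_rank), , drop = FALSE]
  rownames(out) <- NULL
  genes <- do.call(rbind, lapply(split(out, out$gene_id), function(p) {
    data.frame(gene_id = p$gene_id[1L], chrom = p$chrom[1L],
               strand = p$strand[1L], start = min(p$start), end = max(p$end),
               cds_length = sum(p$end - p$start + 1L))
  }))
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  attr(out, "genes") <- genes
  attr(out, "chrom") <- out$chrom[1L]
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Write a fixture bundle to disk
#'
#' Emits reference FASTA, gene-model GFF3, male and female single-sample
#' VCFs (truth variants as male-heterozygous records; planted polymorphisms
#' per sex), TSV count tables and coverage tracks, and flat TSV truth files.
#' All files round-trip through the package readers without loss.
#'
#' @param bundle A [simulate_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2L) != 0L) {
    stop("write_fixture_bundle: cannot write to directory ", dir, call. = FALSE)
  }
  chrom <- names(bundle$reference)[1L]
  sl <- nchar(bundle$reference[[1L]])

  seqs <- Biostrings::DNAStringSet(c(bundle$reference[[1L]], bundle$neo_y[[1L]]))
  names(seqs) <- c(chrom, names(bundle$neo_y)[1L])
  Biostrings::writeXStringSet(seqs[1L], file.path(dir, "reference.fa"), width = 80L)
  Biostrings::writeXStringSet(seqs[2L], file.path(dir, "neo_y.fa"), width = 80L)

  write_gff3(bundle$annotation, file.path(dir, "genes.gff3"), sl)

  tv <- bundle$truth$true_variants
  poly <- bundle$truth$polymorphisms
  male <- rbind(
    data.frame(chrom = tv$chrom, pos = tv$pos, ref = tv$ref, alt = tv$alt,
               gt = tv$male_gt, qual = tv$qual, depth = tv$depth),
    data.frame(chrom = poly$chrom[poly$sex == "shared"],
               pos = poly$pos[poly$sex == "shared"],
               ref = poly$ref[poly$sex == "shared"],
               alt = poly$alt[poly$sex == "shared"],
               gt = rep("HET", sum(poly$sex == "shared")),
               qual = poly$qual[poly$sex == "shared"],
               depth = poly$depth[poly$sex == "shared"])
  )
  male <- male[order(male$pos), , drop = FALSE]
  female <- data.frame(chrom = poly$chrom, pos = poly$pos, ref = poly$ref,
                       alt = poly$alt, gt = rep("HET", nrow(poly)),
                       qual = poly$qual, depth = poly$depth)
  female <- female[order(female$pos), , drop = FALSE]
  write_vcf(male, file.path(dir, "male.vcf"), "male", chrom, sl)
  write_vcf(female, file.path(dir, "female.vcf"), "female", chrom, sl)

  write_tsv(bundle$site_counts, file.path(dir, "site_counts.tsv"))
  write_tsv(bundle$expression$counts, file.path(dir, "expression_counts.tsv"))
  write_tsv(data.frame(sample = names(bundle$expression$totals),
                       total = unname(bundle$expression$totals)),
            file.path(dir, "expression_totals.tsv"))
  write_tsv(bundle$chip$chip, file.path(dir, "chip_coverage.tsv"))
  write_tsv(bundle$chip$input, file.path(dir, "input_coverage.tsv"))
  write_tsv(bundle$intergenic, file.path(dir, "intergenic_windows.tsv"))

  write_tsv(tv, file.path(dir, "truth_variants.tsv"))
  write_tsv(poly, file.path(dir, "truth_polymorphisms.tsv"))
  write_tsv(data.frame(gene_id = names(bundle$truth$true_status),
                       status = unname(bundle$truth$true_status),
                       allelic_ratio = unname(
                         bundle$truth$true_allelic_ratio[names(bundle$truth$true_status)]),
                       group = unname(
                         bundle$truth$gene_groups[names(bundle$truth$true_status)])),
            file.path(dir, "truth_genes.tsv"))
  write_tsv(data.frame(group = names(bundle$truth$true_enrichment),
                       log2_level = unname(bundle$truth$true_enrichment)),
            file.path(dir, "truth_enrichment.tsv"))
  invisible(dir)
}

#' Read a fixture bundle back from disk
#'
#' @param dir Directory written by [write_fixture_bundle()].
#' @return List with the reference, annotation, male/female variant tables,
#'   count tables, coverage tracks and truth tables.
#' @export
read_fixture_bundle <- function(dir) {
  ref <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  reference <- stats::setNames(as.character(ref[1L]), names(ref)[1L])
  neoy <- Biostrings::readDNAStringSet(file.path(dir, "neo_y.fa"))
  expr_tot <- read_tsv(file.path(dir, "expression_totals.tsv"))
  truth_genes <- read_tsv(file.path(dir, "truth_genes.tsv"))
  truth_enr <- read_tsv(file.path(dir, "truth_enrichment.tsv"))
  list(
    reference = reference,
    neo_y = stats::setNames(as.character(neoy[1L]), names(neoy)[1L]),
    annotation = read_gff3(file.path(dir, "genes.gff3")),
    male_variants = read_vcf(file.path(dir, "male.vcf")),
    female_variants = read_vcf(file.path(dir, "female.vcf")),
    site_counts = read_tsv(file.path(dir, "site_counts.tsv")),
    expression = list(
      counts = read_tsv(file.path(dir, "expression_counts.tsv")),
      totals = stats::setNames(expr_tot$total, expr_tot$sample)
    ),
    chip = list(chip = read_tsv(file.path(dir, "chip_coverage.tsv")),
                input = read_tsv(file.path(dir, "input_coverage.tsv"))),
    intergenic = read_tsv(file.path(dir, "intergenic_windows.tsv")),
    truth = structure(list(
      true_variants = read_tsv(file.path(dir, "truth_variants.tsv")),
      polymorphisms = read_tsv(file.path(dir, "truth_polymorphisms.tsv")),
      true_status = stats::setNames(truth_genes$status, truth_genes$gene_id),
      true_allelic_ratio = stats::setNames(truth_genes$allelic_ratio,
                                           truth_genes$gene_id),
      true_enrichment = stats::setNames(truth_enr$log2_level, truth_enr$group),
      gene_groups = stats::setNames(truth_genes$group, truth_genes$gene_id),
      chrom = names(reference)[1L],
      seqlength = nchar(reference[[1L]])
    ), class = "truth_bundle")
  )
}
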