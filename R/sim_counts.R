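# Simulated count data: per-site allele counts for DNA/RNA/ChIP/input assays
# and per-feature expression counts forming two separable log-RPKM mixtures.

#' Simulate per-site allele counts for each assay
#'
#' At every informative site (male-specific SNP inside a gene), draws a
#' Poisson total depth per assay and splits it between the neo-X and neo-Y
#' alleles. DNA and input counts use the configured (default 1:1) DNA ratio;
#' RNA counts use each gene's true allelic ratio; ChIP counts additionally
#' apply the configured ChIP allelic ratio. Counts are beta-binomial when
#' \code{dispersion > 0}, binomial otherwise.
#'
#' @param truth A \code{truth_bundle} from [mutate_haplotype()].
#' @param cfg The [sim_config()].
#' @return Data frame \code{chrom}, \code{pos}, \code{gene_id}, \code{assay},
#'   \code{x_count}, \code{y_count}.
#' @export
simulate_assay_counts <- function(truth, cfg) {
  stopifnot(inherits(truth, "truth_bundle"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  tv <- truth$true_variants
  sites <- tv[tv$vclass == "SNP" & !is.na(tv$gene_id), , drop = FALSE]
  if (nrow(sites) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      gene_id = character(0), assay = character(0),
                      x_count = integer(0), y_count = integer(0)))
  }
  ratio_dna <- cfg$dna_ratio
  p_dna <- ratio_dna / (1 + ratio_dna)
  r_rna <- unname(truth$true_allelic_ratio[sites$gene_id])
  p_rna <- r_rna / (1 + r_rna)
  r_chip <- ratio_dna * cfg$chip_allelic_ratio
  p_chip <- r_chip / (1 + r_chip)

  out <- lapply(c("DNA", "RNA", "ChIP", "input"), function(a) {
    p <- switch(a, DNA = rep(p_dna, nrow(sites)), input = rep(p_dna, nrow(sites)),
                RNA = p_rna, ChIP = rep(p_chip, nrow(sites)))
    n <- stats::rpois(nrow(sites), cfg$assay_depth)
    x <- rbetabinom(nrow(sites), n, p, cfg$dispersion)
    data.frame(chrom = sites$chrom, pos = sites$pos, gene_id = sites$gene_id,
               assay = a, x_count = x, y_count = n - x)
  })
  out <- do.call(rbind, out)
  out[order(out$pos, out$assay), , drop = FALSE]
}

#' Simulate per-feature expression counts for four samples
#'
#' Draws true log10 RPKM values from a gene component and an intergenic
#' component (two separable normal mixtures on the log scale), converts them
#' to expected read counts given feature length and library size, and draws
#' Poisson counts per sample (male/female larva and adult).
#'
#' @param annotation Gene models from [simulate_gene_models()].
#' @param intergenic Intergenic window table from the same call.
#' @param cfg The [sim_config()].
#' @return List: \code{counts} (feature_id, feature_type, length_bp, sample,
#'   count) and \code{totals} (named mapped-read totals per sample).
#' @export
simulate_expression_tables <- function(annotation, intergenic, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  genes <- gene_table(annotation)
  if (nrow(genes) == 0L) stop("simulate_expression_tables: no genes", call. = FALSE)
  exon_len <- vapply(genes$gene_id, function(g) {
    ex <- exons_of(annotation, g)
    sum(ex$end - ex$start + 1L)
  }, integer(1))
  feats <- rbind(
    data.frame(feature_id = genes$gene_id, feature_type = "gene",
               length_bp = as.integer(exon_len)),
    data.frame(feature_id = intergenic$window_id, feature_type = "intergenic",
               length_bp = as.integer(intergenic$end - intergenic$start + 1L))
  )
  samples <- c("male_larva", "female_larva", "male_adult", "female_adult")
  mu_l10 <- ifelse(feats$feature_type == "gene",
                   cfg$gene_log10_rpkm_mean, cfg$intergenic_log10_rpkm_mean)
  counts <- do.call(rbind, lapply(samples, function(s) {
    l10 <- stats::rnorm(nrow(feats), mu_l10, cfg$log10_rpkm_sd)
    lambda <- 10^l10 * (feats$length_bp / 1000) * (cfg$library_size / 1e6)
    data.frame(feats, sample = s, count = stats::rpois(nrow(feats), lambda))
  }))
  totals <- stats::setNames(rep(cfg$library_size, length(samples)), samples)
  list(counts = counts, totals = totals)
}
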