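#' Simulation configuration for a neo-sex fixture bundle
#'
#' Collects every knob of the seeded generator that produces a synthetic
#' neo-X/neo-Y data set: gene-model geometry, the per-silent-site substitution
#' probability separating the two haplotypes, which genes receive degenerative
#' (premature-stop / frameshift) mutations, sequencing-style count depths and
#' overdispersion, expression mixture components, and ChIP enrichment levels.
#'
#' @param n_genes Number of genes to simulate (default 86, the size of the
#'   neo-sex linked gene set the pipeline is scaled to).
#' @param cds_length_mean Mean CDS length in bp (rounded to codons; default 1500).
#' @param n_exons_per_gene Exons per gene (default 2).
#' @param intergenic_length Mean intergenic spacer length in bp (default 4000,
#'   wide enough that 1.5 kb flanks of neighbouring genes do not collide).
#' @param silent_divergence_d Per-site substitution probability at 4-fold
#'   degenerate third codon positions (default 0.0084, i.e. 0.84\% silent
#'   divergence between the two haplotypes).
#' @param nonsyn_rate Per-site probability of a nonsynonymous (never
#'   stop-creating) substitution at other CDS positions (default 0).
#' @param indel_rate Intergenic/intronic indel events per kb (default 0.2).
#' @param pseudogene_targets Character vector of gene ids to receive
#'   degenerative mutations. If named, values must be one of
#'   \code{"PTC"}, \code{"FRAMESHIFT"}, \code{"PTC_AND_FRAMESHIFT"}; if
#'   unnamed, types are assigned round-robin in that order.
#' @param assay_depth Mean reads per informative site per assay (default 50).
#' @param allelic_ratio Expected neo-X : neo-Y RNA ratio, scalar or per-gene
#'   named vector (default 2, a moderate neo-X bias).
#' @param dispersion Beta-binomial overdispersion (intraclass correlation) for
#'   allele counts; 0 = plain binomial.
#' @param chip_gradient If \code{TRUE}, expected ChIP enrichment increases
#'   monotonically 5' to 3' within gene bodies (3'-biased binding).
#' @param seed Integer seed; mandatory, |seed| < 2^31 - 16.
#' @param n_female_poly Number of planted female-only heterozygous SNPs.
#' @param n_shared_poly Number of planted SNPs heterozygous in both sexes.
#' @param dna_ratio Neo-X : neo-Y ratio for DNA/input counts (mapping-bias
#'   skew; default 1, the unbiased expectation).
#' @param chip_allelic_ratio Neo-X : neo-Y ratio for ChIP counts (default 1).
#' @param gene_log10_rpkm_mean,intergenic_log10_rpkm_mean,log10_rpkm_sd
#'   Components of the two log10-RPKM expression mixtures (defaults 1.5, -0.5,
#'   0.5: separable gene and intergenic distributions).
#' @param library_size Mapped reads per expression sample (default 2e6).
#' @param enrichment_groups Named numeric vector: mean log2 ChIP/input level
#'   per gene group; genes are assigned to groups round-robin.
#' @param chip_depth Mean input reads per coverage bin (default 100).
#' @param chip_bin Coverage bin width in bp (default 50).
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_genes = 86,
                       cds_length_mean = 1500,
                       n_exons_per_gene = 2,
                       intergenic_length = 4000,
                       silent_divergence_d = 0.0084,
                       nonsyn_rate = 0,
                       indel_rate = 0.2,
                       pseudogene_targets = character(0),
                       assay_depth = 50,
                       allelic_ratio = 2,
                       dispersion = 0,
                       chip_gradient = FALSE,
                       seed,
                       n_female_poly = 30,
                       n_shared_poly = 10,
                       dna_ratio = 1,
                       chip_allelic_ratio = 1,
                       gene_log10_rpkm_mean = 1.5,
                       intergenic_log10_rpkm_mean = -0.5,
                       log10_rpkm_sd = 0.5,
                       library_size = 2e6,
                       enrichment_groups = c(target = 1, background = 0),
                       chip_depth = 100,
                       chip_bin = 50) {
  if (missing(seed)) stop("sim_config: 'seed' is mandatory", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != floor(seed) || abs(seed) >= 2^31 - 16) {
    stop("sim_config: 'seed' must be a single integer with |seed| < 2^31 - 16",
         call. = FALSE)
  }
  if (!is_count(n_genes) || n_genes < 1) {
    stop("sim_config: n_genes must be a count >= 1", call. = FALSE)
  }
  for (nm in c("silent_divergence_d", "nonsyn_rate", "dispersion")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("sim_config: %s must be a probability in [0, 1]", nm),
           call. = FALSE)
    }
  }
  if (indel_rate < 0) stop("sim_config: indel_rate must be >= 0", call. = FALSE)
  if (any(allelic_ratio <= 0)) stop("sim_config: allelic_ratio must be > 0", call. = FALSE)
  if (dna_ratio <= 0 || chip_allelic_ratio <= 0) {
    stop("sim_config: dna_ratio and chip_allelic_ratio must be > 0", call. = FALSE)
  }
  if (assay_depth < 0) stop("sim_config: assay_depth must be >= 0", call. = FALSE)
  if (cds_length_mean < 180) {
    stop("sim_config: cds_length_mean must be >= 180 bp (60 codons)", call. = FALSE)
  }
  if (!is_count(n_exons_per_gene) || n_exons_per_gene < 1) {
    stop("sim_config: n_exons_per_gene must be a count >= 1", call. = FALSE)
  }
  if (intergenic_length < 200) {
    stop("sim_config: intergenic_length must be >= 200 bp", call. = FALSE)
  }
  if (is.null(names(enrichment_groups)) || any(names(enrichment_groups) == "")) {
    stop("sim_config: enrichment_groups must be a fully named numeric vector",
         call. = FALSE)
  }
  pseudogene_targets <- normalize_targets(pseudogene_targets)
  cfg <- list(
    n_genes = as.integer(n_genes), cds_length_mean = cds_length_mean,
    n_exons_per_gene = as.integer(n_exons_per_gene),
    intergenic_length = intergenic_length,
    silent_divergence_d = silent_divergence_d, nonsyn_rate = nonsyn_rate,
    indel_rate = indel_rate, pseudogene_targets = pseudogene_targets,
    assay_depth = assay_depth, allelic_ratio = allelic_ratio,
    dispersion = dispersion, chip_gradient = isTRUE(chip_gradient),
    seed = as.integer(seed),
    n_female_poly = as.integer(n_female_poly),
    n_shared_poly = as.integer(n_shared_poly),
    dna_ratio = dna_ratio, chip_allelic_ratio = chip_allelic_ratio,
    gene_log10_rpkm_mean = gene_log10_rpkm_mean,
    intergenic_log10_rpkm_mean = intergenic_log10_rpkm_mean,
    log10_rpkm_sd = log10_rpkm_sd, library_size = library_size,
    enrichment_groups = enrichment_groups,
    chip_depth = chip_depth, chip_bin = as.integer(chip_bin)
  )
  class(cfg) <- "sim_config"
  cfg
}

ORF_STATUSES <- c("INTACT", "PTC", "FRAMESHIFT", "PTC_AND_FRAMESHIFT")

# Accepts an unnamed id vector (types cycled) or a named id -> type vector.
normalize_targets <- function(targets) {
  if (length(targets) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  types <- setdiff(ORF_STATUSES, "INTACT")
  if (is.null(names(targets))) {
    stats::setNames(rep_len(types, length(targets)), targets)
  } else {
    bad <- setdiff(unique(unname(targets)), types)
    if (length(bad)) {
      stop("pseudogene_targets types must be PTC, FRAMESHIFT or PTC_AND_FRAMESHIFT; got: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    stats::setNames(unname(targets), names(targets))
  }
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Neo-sex fixture simulation config\n")
  cat(sprintf("  genes: %d (mean CDS %.0f bp, %d exon(s)); intergenic %.0f bp\n",
              x$n_genes, x$cds_length_mean, x$n_exons_per_gene, x$intergenic_length))
  cat(sprintf("  silent divergence d = %.4g; nonsyn rate = %.3g; indels/kb = %.3g\n",
              x$silent_divergence_d, x$nonsyn_rate, x$indel_rate))
  cat(sprintf("  pseudogene targets: %d; assay depth %.0f; allelic ratio %s; dispersion %.3g\n",
              length(x$pseudogene_targets), x$assay_depth,
              paste(utils::head(unique(x$allelic_ratio), 3), collapse = ","),
              x$dispersion))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Study-scale default simulation configuration
#'
#' The fixture the pipeline uses by default: 86 neo-sex linked gene pairs with
#' degenerative mutations planted in 50 of them, 0.84\% silent divergence, a
#' 2-fold neo-X expression bias, and two ChIP enrichment groups.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A \code{sim_config}.
#' @export
default_sim_config <- function(seed, ...) {
  args <- list(...)
  if (is.null(args$pseudogene_targets)) {
    n <- args$n_genes %||% 86
    ntarg <- min(50L, as.integer(n))
    args$pseudogene_targets <- sprintf("g%03d", seq_len(ntarg))
  }
  do.call(sim_config, c(list(seed = seed), args))
}
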