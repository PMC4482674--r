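# Pipeline orchestration: simulate (or load) a fixture, classify variant
# sites, reconstruct the neo-Y, call ORF integrity, date the divergence, test
# allelic expression, and profile chromatin — with every threshold defaulted
# to its reference value and recorded in the report.

#' Pipeline configuration
#'
#' Thresholds default to the reference values used throughout: variant
#' quality 30 and depth 5, significance alpha 0.05, active-gene cutoff
#' fallback log10 RPKM 0.65, mutation rate 5e-9 per bp per generation, 10
#' generations per year, and 1.5 kb flanks.
#'
#' @param sim A [sim_config()] describing the fixture to simulate, or
#'   \code{NULL} when \code{fixture_dir} is given.
#' @param fixture_dir Optional directory holding a written fixture bundle.
#' @param outdir Optional output directory for TSV reports.
#' @param min_qual,min_depth Variant filters.
#' @param alpha Allelic-bias significance level on the raw Fisher p.
#' @param active_default Fallback active-transcription cutoff (log10 RPKM).
#' @param mu,gen_per_year Dating constants.
#' @param flank Flank in bp for enrichment and metagene profiles.
#' @param body_bins,flank_bins Metagene bin counts.
#' @param pseudocount Pseudocount for enrichment log-ratios.
#' @param expression_sample Sample used for activity calls (default
#'   \code{male_adult}).
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = NULL, fixture_dir = NULL, outdir = NULL,
                            min_qual = 30, min_depth = 5, alpha = 0.05,
                            active_default = 0.65, mu = 5e-9,
                            gen_per_year = 10, flank = 1500,
                            body_bins = 20L, flank_bins = 5L,
                            pseudocount = 0.5,
                            expression_sample = "male_adult") {
  if (is.null(sim) && is.null(fixture_dir)) {
    stop("pipeline_config: supply a sim_config or a fixture_dir", call. = FALSE)
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, fixture_dir = fixture_dir, outdir = outdir,
                 min_qual = min_qual, min_depth = min_depth, alpha = alpha,
                 active_default = active_default, mu = mu,
                 gen_per_year = gen_per_year, flank = flank,
                 body_bins = as.integer(body_bins),
                 flank_bins = as.integer(flank_bins),
                 pseudocount = pseudocount,
                 expression_sample = expression_sample),
            class = "pipeline_config")
}

#' Simulate a fixture bundle and write it to disk
#'
#' @param cfg A [sim_config()]; the default configuration (via
#'   [default_sim_config()]) is 86 genes with degenerative mutations planted
#'   in 50.
#' @param outdir Output directory.
#' @param quiet Suppress the truth summary printout.
#' @return The bundle, invisibly.
#' @export
make_fixture <- function(cfg, outdir, quiet = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  bundle <- simulate_bundle(cfg)
  write_fixture_bundle(bundle, outdir)
  if (!quiet) {
    st <- table(factor(bundle$truth$true_status, levels = ORF_STATUSES))
    cat(sprintf("Fixture written to %s\n", outdir))
    cat(sprintf("  genes: %d (%s)\n", length(bundle$truth$true_status),
                paste(sprintf("%s=%d", names(st), st), collapse = ", ")))
    cat(sprintf("  variants: %d (+%d polymorphisms)\n",
                nrow(bundle$truth$true_variants),
                nrow(bundle$truth$polymorphisms)))
  }
  invisible(bundle)
}

# Variant tables as the classifier expects them, from an in-memory bundle
# (truth variants -> male calls; polymorphisms -> per-sex calls).
bundle_variant_calls <- function(bundle) {
  tv <- bundle$truth$true_variants
  poly <- bundle$truth$polymorphisms
  male <- rbind(
    data.frame(chrom = tv$chrom, pos = tv$pos, ref = tv$ref, alt = tv$alt,
               vclass = tv$vclass, gt = tv$male_gt, qual = tv$qual,
               depth = tv$depth),
    data.frame(chrom = poly$chrom[poly$sex == "shared"],
               pos = poly$pos[poly$sex == "shared"],
               ref = poly$ref[poly$sex == "shared"],
               alt = poly$alt[poly$sex == "shared"],
               vclass = poly$vclass[poly$sex == "shared"],
               gt = rep("HET", sum(poly$sex == "shared")),
               qual = poly$qual[poly$sex == "shared"],
               depth = poly$depth[poly$sex == "shared"])
  )
  female <- data.frame(chrom = poly$chrom, pos = poly$pos, ref = poly$ref,
                       alt = poly$alt, vclass = poly$vclass,
                       gt = rep("HET", nrow(poly)),
                       qual = poly$qual, depth = poly$depth)
  list(male = male[order(male$pos), , drop = FALSE],
       female = female[order(female$pos), , drop = FALSE])
}

#' Run the full neo-sex analysis pipeline
#'
#' Simulates (or loads) a fixture, filters and classifies variant sites,
#' reconstructs the neo-Y, classifies ORF integrity per gene, estimates
#' silent divergence and the divergence date, runs the DNA-normalized allelic
#' Fisher tests, derives the active-gene cutoff and sex-bias ratios, and
#' profiles chromatin enrichment with metagene bound fractions and group
#' contrasts. All tables are written as TSVs when an output directory is
#' configured.
#'
#' @param config A [pipeline_config()].
#' @return List of class \code{neosex_report}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$fixture_dir)) {
    fx <- read_fixture_bundle(config$fixture_dir)
    calls <- list(male = fx$male_variants, female = fx$female_variants)
  } else {
    fx <- simulate_bundle(config$sim)
    calls <- bundle_variant_calls(fx)
  }
  annotation <- fx$annotation
  genes <- gene_table(annotation)
  reference <- fx$reference

  # --- variant classification and neo-Y reconstruction ---------------------
  mf <- filter_variants(calls$male, config$min_qual, config$min_depth)
  ff <- filter_variants(calls$female, config$min_qual, config$min_depth)
  cls <- classify_sites(mf$kept, ff$kept)
  ms <- cls$male_specific
  neoy <- build_neo_y(reference, ms)
  contamination <- if (nrow(ms) > 0) {
    estimate_polymorphism_contamination(nrow(ms), nrow(cls$female_het))
  } else NA_real_

  # --- ORF integrity --------------------------------------------------------
  orf_rows <- lapply(genes$gene_id, function(g) {
    ext <- genes[genes$gene_id == g, ]
    vg <- ms[ms$pos >= ext$start - 1L & ms$pos <= ext$end, , drop = FALSE]
    pr <- project_and_apply(g, reference, annotation, vg)
    if (pr$unresolvable) {
      return(data.frame(gene_id = g, status = NA_character_,
                        first_ptc_codon = NA_integer_,
                        truncation_fraction = NA_real_, frame_restored = NA,
                        start_lost = NA, unresolvable = TRUE))
    }
    st <- classify_orf(pr$x_cds, pr$y_cds, pr$variants_in_cds)
    data.frame(gene_id = g, status = st$status,
               first_ptc_codon = st$first_ptc_codon,
               truncation_fraction = st$truncation_fraction,
               frame_restored = st$frame_restored, start_lost = st$start_lost,
               unresolvable = FALSE)
  })
  orf_status <- do.call(rbind, orf_rows)
  orf_summary <- summarize_status(orf_status[!orf_status$unresolvable, ])

  # --- silent divergence and dating (SNP-only projection keeps alignment) ---
  div_rows <- lapply(genes$gene_id, function(g) {
    ext <- genes[genes$gene_id == g, ]
    vg <- ms[ms$pos >= ext$start & ms$pos <= ext$end & ms$vclass == "SNP", ,
             drop = FALSE]
    pr <- project_and_apply(g, reference, annotation, vg)
    dv <- silent_divergence(pr$x_cds, pr$y_cds, gene_id = g)
    kk <- ng86_kaks(pr$x_cds, pr$y_cds, gene_id = g)
    data.frame(gene_id = g, n_silent_sites = dv$n_silent_sites,
               n_silent_diffs = dv$n_silent_diffs, d = dv$d,
               usable = dv$usable, Ka = kk$Ka, Ks = kk$Ks, kaks = kk$ratio)
  })
  divergence <- do.call(rbind, div_rows)
  usable <- divergence[divergence$usable, , drop = FALSE]
  d_median <- stats::median(usable$d)
  d_pooled <- sum(usable$n_silent_diffs) / sum(usable$n_silent_sites)
  age <- estimate_age(d_median, mu = config$mu, gen_per_year = config$gen_per_year)

  # --- codon usage ----------------------------------------------------------
  ref_cds <- vapply(genes$gene_id, function(g) spliced_cds(reference, annotation, g), "")
  opt <- optimal_codons_from_usage(ref_cds)
  cu <- do.call(rbind, lapply(genes$gene_id, function(g) {
    s <- codon_usage(ref_cds[[g]], optimal_codons = opt, gene_id = g)
    data.frame(gene_id = g, Fop = s$Fop, CBI = s$CBI)
  }))

  # --- allelic expression ---------------------------------------------------
  agg <- aggregate_allele_counts(fx$site_counts)
  wide <- counts_wide(agg, assays = c("DNA", "RNA"))
  bias <- allelic_bias_test(wide, alpha = config$alpha)
  n_sig <- sum(bias$significant_xy_bias, na.rm = TRUE)
  n_testable <- sum(bias$testable)

  expr <- rpkm_table(fx$expression$counts, fx$expression$totals)
  es <- config$expression_sample
  sub <- expr[expr$sample == es, ]
  cut <- active_cutoff(log10(sub$rpkm[sub$feature_type == "gene"] + 1e-9),
                       log10(sub$rpkm[sub$feature_type == "intergenic"] + 1e-9),
                       default = config$active_default)
  gene_rpkm_m <- sub$rpkm[match(genes$gene_id, sub$feature_id)]
  active <- log10(gene_rpkm_m + 1e-9) >= cut$threshold
  names(active) <- genes$gene_id

  female_sample <- sub("^male", "female", es)
  subf <- expr[expr$sample == female_sample, ]
  gene_rpkm_f <- subf$rpkm[match(genes$gene_id, subf$feature_id)]
  x_frac <- with(bias, ifelse(rna_x + rna_y > 0, rna_x / (rna_x + rna_y), NA))
  x_frac <- x_frac[match(genes$gene_id, bias$gene_id)]
  sb <- sex_bias(genes$gene_id, gene_rpkm_m, gene_rpkm_f,
                 male_x_rpkm = gene_rpkm_m * x_frac,
                 male_y_rpkm = gene_rpkm_m * (1 - x_frac))
  corr <- tryCatch(
    correlate_bias(bias$log2_norm_ratio[match(genes$gene_id, bias$gene_id)],
                   sb$log2_male_female),
    error = function(e) list(rho = NA_real_, p_value = NA_real_,
                             n_used = 0L, n_dropped = NA_integer_))

  # --- chromatin ------------------------------------------------------------
  enr <- gene_enrichment(fx$chip$chip, fx$chip$input, genes,
                         flank = config$flank, pseudocount = config$pseudocount)
  grp <- fx$truth$gene_groups
  bin_enr <- gene_bin_enrichment(fx$chip$chip, fx$chip$input, genes,
                                 body_bins = config$body_bins,
                                 flank_bins = config$flank_bins,
                                 flank = config$flank,
                                 pseudocount = config$pseudocount)
  target <- names(fx$truth$true_enrichment)[which.max(fx$truth$true_enrichment)]
  bc <- tryCatch(bound_cutoff(bin_enr, grp, target), warning = function(w) {
    structure(list(mark = NA, threshold = 0, separable = FALSE,
                   method = "fallback_default"), class = "bound_cutoff")
  })
  prof_groups <- stats::setNames(
    paste0(unname(grp[genes$gene_id]), "_",
           ifelse(active[genes$gene_id], "active", "silent")),
    genes$gene_id)
  profile <- metagene_profile(bin_enr, bc, prof_groups)
  enr$group <- unname(grp[enr$gene_id])
  contrast_groups <- unique(enr$group)
  contrasts <- if (length(contrast_groups) >= 2) {
    utils::combn(contrast_groups, 2, simplify = FALSE)
  } else list()
  cmp <- if (length(contrasts)) {
    group_compare(data.frame(value = enr$log2_enrichment, group = enr$group),
                  contrasts)
  } else NULL
  ae <- tryCatch(allele_enrichment(agg, pseudocount = config$pseudocount),
                 error = function(e) NULL)

  report <- structure(list(
    config = config,
    site_classification_counts = cls$counts,
    n_male_specific = nrow(ms),
    n_female_het = nrow(cls$female_het),
    n_shared_het = nrow(cls$shared_het),
    contamination = contamination,
    neo_y_length = nchar(neoy$sequence),
    orf_status = orf_status,
    orf_summary = orf_summary,
    divergence = divergence,
    d_median = d_median,
    d_pooled = d_pooled,
    age = age,
    codon_usage = cu,
    allelic_bias = bias,
    n_significant_bias = n_sig,
    n_testable = n_testable,
    expression_cutoff = cut,
    active = active,
    sex_bias = sb,
    bias_sexbias_correlation = corr,
    enrichment = enr,
    allele_enrichment = ae,
    bound_cutoff = bc,
    metagene = profile,
    contrasts = cmp,
    truth = fx$truth
  ), class = "neosex_report")

  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$orf_status, file.path(dir, "orf_status.tsv"))
  write_tsv(report$orf_summary, file.path(dir, "orf_summary.tsv"))
  write_tsv(report$divergence, file.path(dir, "divergence.tsv"))
  write_tsv(report$codon_usage, file.path(dir, "codon_usage.tsv"))
  write_tsv(report$allelic_bias, file.path(dir, "allelic_bias.tsv"))
  write_tsv(report$sex_bias, file.path(dir, "sex_bias.tsv"))
  write_tsv(report$enrichment, file.path(dir, "enrichment.tsv"))
  if (!is.null(report$allele_enrichment)) {
    write_tsv(report$allele_enrichment, file.path(dir, "allele_enrichment.tsv"))
  }
  write_tsv(report$metagene, file.path(dir, "metagene.tsv"))
  if (!is.null(report$contrasts)) {
    write_tsv(report$contrasts, file.path(dir, "contrasts.tsv"))
  }
  summary <- data.frame(
    key = c("n_male_specific", "n_female_het", "n_shared_het",
            "polymorphism_contamination", "prop_nonfunctional",
            "d_median", "d_pooled", "t_generations", "t_years",
            "n_significant_bias", "n_testable", "active_cutoff",
            "bound_cutoff", "min_qual", "min_depth", "alpha", "mu",
            "gen_per_year", "flank", "seed"),
    value = c(report$n_male_specific, report$n_female_het, report$n_shared_het,
              report$contamination,
              report$orf_summary$prop_nonfunctional[1L],
              report$d_median, report$d_pooled,
              report$age$t_generations, report$age$t_years,
              report$n_significant_bias, report$n_testable,
              report$expression_cutoff$threshold,
              report$bound_cutoff$threshold,
              report$config$min_qual, report$config$min_depth,
              report$config$alpha, report$config$mu,
              report$config$gen_per_year, report$config$flank,
              if (!is.null(report$config$sim)) report$config$sim$seed else NA)
  )
  write_tsv(summary, file.path(dir, "summary.tsv"))
  invisible(dir)
}

#' @export
print.neosex_report <- function(x, ...) {
  cat("Neo-sex chromosome analysis report\n")
  cat(sprintf("  male-specific sites: %d; female-het: %d; shared-het: %d\n",
              x$n_male_specific, x$n_female_het, x$n_shared_het))
  cat(sprintf("  polymorphism contamination: %.2f%%\n", 100 * x$contamination))
  cat(sprintf("  non-functional neo-Y genes: %d / %d (%.1f%%)\n",
              x$orf_summary$n_nonfunctional[1L], x$orf_summary$n_total[1L],
              100 * x$orf_summary$prop_nonfunctional[1L]))
  cat(sprintf("  silent divergence: median %.4g, pooled %.4g\n",
              x$d_median, x$d_pooled))
  cat(sprintf("  age: %s generations (%s years at %g gen/yr)\n",
              format(round(x$age$t_generations), big.mark = ","),
              format(round(x$age$t_years), big.mark = ","),
              x$age$gen_per_year))
  cat(sprintf("  allelic bias: %d / %d testable genes significant (alpha = %g)\n",
              x$n_significant_bias, x$n_testable, x$config$alpha))
  cat(sprintf("  active cutoff: log10 RPKM %.3f (%s); bound cutoff: %.3f (%s)\n",
              x$expression_cutoff$threshold, x$expression_cutoff$method,
              x$bound_cutoff$threshold, x$bound_cutoff$method))
  invisible(x)
}
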