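# Allele-specific expression: aggregation of per-site allele counts,
# DNA-normalized Fisher exact testing, RPKM, the active-gene cutoff from the
# gene/intergenic density crossing, sex-bias ratios and rank correlations.

#' Aggregate per-site allele counts to genes
#'
#' Sums neo-X and neo-Y read counts over the informative (male-specific SNP)
#' sites of each gene, separately per assay, and records per-gene informative
#' site counts. Genes listed in the site-to-gene map but lacking sites are
#' returned flagged with zero sites.
#'
#' @param site_counts Data frame with \code{chrom}, \code{pos}, \code{assay},
#'   \code{x_count}, \code{y_count} and optionally \code{gene_id}.
#' @param site_to_gene Optional data frame \code{chrom}, \code{pos},
#'   \code{gene_id} used when \code{site_counts} lacks a \code{gene_id}
#'   column. A site mapping to more than one gene is an error.
#' @return Data frame: \code{gene_id}, \code{assay}, \code{x_count},
#'   \code{y_count}, \code{n_informative_sites}.
#' @export
aggregate_allele_counts <- function(site_counts, site_to_gene = NULL) {
  sc <- site_counts
  if (!("gene_id" %in% names(sc))) {
    if (is.null(site_to_gene)) {
      stop("aggregate_allele_counts: need gene_id column or site_to_gene map",
           call. = FALSE)
    }
    key <- paste(site_to_gene$chrom, site_to_gene$pos)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1L]
      stop("site maps to more than one gene: ", dup, call. = FALSE)
    }
    sc$gene_id <- site_to_gene$gene_id[match(paste(sc$chrom, sc$pos), key)]
  }
  sc <- sc[!is.na(sc$gene_id), , drop = FALSE]
  if (nrow(sc) == 0L) {
    return(data.frame(gene_id = character(0), assay = character(0),
                      x_count = numeric(0), y_count = numeric(0),
                      n_informative_sites = integer(0)))
  }
  agg <- stats::aggregate(cbind(x_count, y_count) ~ gene_id + assay, data = sc, FUN = sum)
  sites <- unique(sc[, c("gene_id", "chrom", "pos")])
  ns <- table(sites$gene_id)
  agg$n_informative_sites <- as.integer(ns[agg$gene_id])
  agg[order(agg$gene_id, agg$assay), , drop = FALSE]
}

#' DNA-normalized allelic expression bias test
#'
#' For each gene, tests whether the neo-X:neo-Y ratio of RNA-seq reads differs
#' from the same gene's DNA-seq ratio (expected 1:1 in males, so the DNA row
#' absorbs mapping bias) with a two-sided Fisher exact test on the 2x2 table
#' \code{[[dna_x, dna_y], [rna_x, rna_y]]}. The normalized effect size is
#' \code{log2((rna_x/rna_y) / (dna_x/dna_y))}; a pseudocount of 0.5 is added
#' to all four cells for the ratio only when some cell is zero (the exact test
#' always uses raw counts). Benjamini-Hochberg adjusted p-values are reported
#' alongside; the significance flag uses the raw p-value at \code{alpha}.
#' Genes with a zero DNA count on either allele are excluded (normalization
#' undefined); all-zero tables are flagged untestable.
#'
#' @param gene_counts Data frame with \code{gene_id}, \code{dna_x},
#'   \code{dna_y}, \code{rna_x}, \code{rna_y} (see [counts_wide()]).
#' @param alpha Raw-p significance threshold (default 0.05); a threshold >= 1
#'   marks every testable gene significant.
#' @return Data frame with odds ratio, p, BH-adjusted p,
#'   \code{log2_norm_ratio}, \code{significant_xy_bias}, \code{testable} and
#'   an exclusion \code{note}.
#' @export
allelic_bias_test <- function(gene_counts, alpha = 0.05) {
  gc <- gene_counts
  need <- c("gene_id", "dna_x", "dna_y", "rna_x", "rna_y")
  stopifnot(all(need %in% names(gc)))
  n <- nrow(gc)
  p <- or <- lr <- rep(NA_real_, n)
  testable <- rep(FALSE, n)
  note <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tab <- matrix(c(gc$dna_x[i], gc$dna_y[i], gc$rna_x[i], gc$rna_y[i]),
                  nrow = 2, byrow = TRUE)
    if (all(tab == 0)) { note[i] <- "all_zero"; next }
    if (tab[1, 1] == 0 || tab[1, 2] == 0) { note[i] <- "zero_dna"; next }
    testable[i] <- TRUE
    p[i] <- stats::fisher.test(tab)$p.value
    cells <- tab + if (any(tab == 0)) 0.5 else 0
    or[i] <- (cells[2, 1] / cells[2, 2]) / (cells[1, 1] / cells[1, 2])
    lr[i] <- log2(or[i])
  }
  padj <- rep(NA_real_, n)
  padj[testable] <- stats::p.adjust(p[testable], method = "BH")
  data.frame(gene_id = gc$gene_id,
             dna_x = gc$dna_x, dna_y = gc$dna_y,
             rna_x = gc$rna_x, rna_y = gc$rna_y,
             odds_ratio = or, p_value = p, p_adjusted = padj,
             log2_norm_ratio = lr,
             significant_xy_bias = testable & (p < alpha | alpha >= 1),
             testable = testable, note = note)
}

#' Reshape aggregated allele counts to one row per gene
#'
#' @param agg Output of [aggregate_allele_counts()].
#' @param assays Which assays to spread into columns.
#' @return Data frame with one row per gene and \code{<assay>_x} /
#'   \code{<assay>_y} columns (lower-case assay names).
#' @export
counts_wide <- function(agg, assays = c("DNA", "RNA")) {
  genes <- sort(unique(agg$gene_id))
  out <- data.frame(gene_id = genes)
  for (a in assays) {
    sub <- agg[agg$assay == a, , drop = FALSE]
    i <- match(genes, sub$gene_id)
    out[[paste0(tolower(a), "_x")]] <- ifelse(is.na(i), 0, sub$x_count[i])
    out[[paste0(tolower(a), "_y")]] <- ifelse(is.na(i), 0, sub$y_count[i])
  }
  ns <- agg[!duplicated(agg$gene_id), c("gene_id", "n_informative_sites")]
  out$n_informative_sites <- ns$n_informative_sites[match(genes, ns$gene_id)]
  out
}

#' Reads per kilobase per million mapped reads
#'
#' \code{rpkm = count / (length_bp / 1000) / (total / 1e6)}; invariant under
#' uniform scaling of all counts and the library total.
#'
#' @param counts Data frame with \code{feature_id}, \code{sample},
#'   \code{count}, \code{length_bp}.
#' @param totals Named numeric vector of mapped-read totals per sample (> 0).
#' @return Input with an \code{rpkm} column.
#' @export
rpkm_table <- function(counts, totals) {
  stopifnot(all(c("feature_id", "sample", "count", "length_bp") %in% names(counts)))
  if (any(counts$length_bp <= 0)) stop("rpkm_table: lengths must be > 0", call. = FALSE)
  tot <- totals[counts$sample]
  if (any(is.na(tot)) || any(tot <= 0)) {
    stop("rpkm_table: every sample needs a positive mapped-read total", call. = FALSE)
  }
  counts$rpkm <- counts$count / (counts$length_bp / 1000) / (tot / 1e6)
  counts
}

# Density-crossing machinery shared by the active-gene and bound/unbound
# cutoffs: Gaussian KDE with Silverman's rule-of-thumb bandwidth on a common
# grid; the cutoff is the smallest density-equality point between the two
# global modes.
density_crossing <- function(low_sample, high_sample, n_grid = 1024L) {
  rng <- range(c(low_sample, high_sample), finite = TRUE)
  pad <- 0.1 * diff(rng) + 1e-9
  d_lo <- stats::density(low_sample, bw = "nrd0", from = rng[1] - pad,
                         to = rng[2] + pad, n = n_grid)
  d_hi <- stats::density(high_sample, bw = "nrd0", from = rng[1] - pad,
                         to = rng[2] + pad, n = n_grid)
  x <- d_lo$x
  mode_lo <- x[which.max(d_lo$y)]
  mode_hi <- x[which.max(d_hi$y)]
  if (mode_hi <= mode_lo) return(NULL)
  between <- which(x > mode_lo & x < mode_hi)
  if (length(between) < 2L) return(NULL)
  diffd <- d_lo$y[between] - d_hi$y[between]
  flip <- which(diffd[-length(diffd)] > 0 & diffd[-1L] <= 0)
  if (!length(flip)) return(NULL)
  i <- between[flip[1L]]
  # linear interpolation of the equality point between grid nodes
  y1 <- d_lo$y[i] - d_hi$y[i]
  y2 <- d_lo$y[i + 1L] - d_hi$y[i + 1L]
  if (y1 == y2) x[i] else x[i] - y1 * (x[i + 1L] - x[i]) / (y2 - y1)
}

#' Active-transcription cutoff from gene vs intergenic expression densities
#'
#' Estimates the log10-RPKM value separating transcribed genes from
#' intergenic background as the crossing point of the two kernel density
#' estimates between their modes. Non-separable input (no crossing, or the
#' intergenic mode not below the gene mode) falls back to the configured
#' default with a warning.
#'
#' @param gene_log10_rpkm,intergenic_log10_rpkm Numeric samples (>= 10 each).
#' @param default Fallback threshold (default 0.65, the reference value for
#'   defining actively transcribed genes).
#' @return List of class \code{expression_cutoff}: \code{threshold},
#'   \code{separable}, \code{method}.
#' @export
active_cutoff <- function(gene_log10_rpkm, intergenic_log10_rpkm, default = 0.65) {
  g <- gene_log10_rpkm[is.finite(gene_log10_rpkm)]
  i <- intergenic_log10_rpkm[is.finite(intergenic_log10_rpkm)]
  if (length(g) < 10L || length(i) < 10L) {
    stop("active_cutoff: need at least 10 finite values in each set", call. = FALSE)
  }
  cx <- density_crossing(low_sample = i, high_sample = g)
  if (is.null(cx)) {
    warning("active_cutoff: distributions not separable; using default ",
            default, call. = FALSE)
    return(structure(list(threshold = default, separable = FALSE,
                          method = "fallback_default"),
                     class = "expression_cutoff"))
  }
  structure(list(threshold = cx, separable = TRUE, method = "kde_crossing"),
            class = "expression_cutoff")
}

#' Sex-bias expression ratios
#'
#' Computes per-gene log2 male/female expression ratios, using combined
#' neo-X + neo-Y expression in males versus (neo-X only) female expression,
#' plus per-allele male/female ratios when allele-resolved male RPKMs are
#' supplied. Genes with a fold difference below \code{fold} are labelled
#' unbiased. A pseudocount is applied to zero values only.
#'
#' @param gene_id Gene identifiers.
#' @param male_rpkm_combined,female_rpkm Paired per-gene RPKM vectors.
#' @param male_x_rpkm,male_y_rpkm Optional allele-resolved male RPKMs.
#' @param fold Unbiased band: fold difference < \code{fold} (default 1.5).
#' @param pseudocount Replacement applied to zero values (default 0.01 RPKM).
#' @return Data frame with log2 ratios and a \code{bias_class}.
#' @export
sex_bias <- function(gene_id, male_rpkm_combined, female_rpkm,
                     male_x_rpkm = NULL, male_y_rpkm = NULL,
                     fold = 1.5, pseudocount = 0.01) {
  pc <- function(v) ifelse(v == 0, pseudocount, v)
  m <- pc(male_rpkm_combined)
  f <- pc(female_rpkm)
  lr <- log2(m / f)
  cls <- ifelse(abs(lr) < log2(fold), "unbiased",
                ifelse(lr > 0, "male_biased", "female_biased"))
  out <- data.frame(gene_id = gene_id, male_rpkm = male_rpkm_combined,
                    female_rpkm = female_rpkm, log2_male_female = lr,
                    bias_class = cls)
  if (!is.null(male_x_rpkm)) out$x_over_female <- pc(male_x_rpkm) / f
  if (!is.null(male_y_rpkm)) out$y_over_female <- pc(male_y_rpkm) / f
  out
}

#' Spearman rank correlation between two per-gene measures
#'
#' @param vec_a,vec_b Paired numeric vectors; incomplete pairs are dropped
#'   (and counted); fewer than 5 complete pairs is an error.
#' @return List: \code{rho}, \code{p_value}, \code{n_used}, \code{n_dropped}.
#' @export
correlate_bias <- function(vec_a, vec_b) {
  stopifnot(length(vec_a) == length(vec_b))
  ok <- is.finite(vec_a) & is.finite(vec_b)
  if (sum(ok) < 5L) {
    stop("correlate_bias: need at least 5 complete pairs", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(vec_a[ok], vec_b[ok],
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_used = sum(ok), n_dropped = sum(!ok))
}
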