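# Chromatin profiling: per-gene and per-allele log2 ChIP/input enrichment,
# bound/unbound cutoffs from density crossings of bin-level enrichment,
# scaled metagene bound-fraction profiles, and group contrasts.
#
# Coverage tracks are BED-like data frames (chrom, start, end, count) with
# 0-based half-open intervals; counts are fractionally allocated when a
# requested range cuts a bin.

track_total <- function(track) sum(track$count)

# Sum of track counts over a 1-based inclusive range, fractional at the edges.
track_range_sum <- function(track, start1, end1) {
  s0 <- start1 - 1L
  e0 <- end1
  sel <- track$end > s0 & track$start < e0
  if (!any(sel)) return(0)
  tr <- track[sel, , drop = FALSE]
  frac <- (pmin(tr$end, e0) - pmax(tr$start, s0)) / (tr$end - tr$start)
  sum(tr$count * frac)
}

log2_enrichment <- function(chip_count, input_count, chip_total, input_total,
                            pseudocount = 0.5) {
  log2(((chip_count + pseudocount) / chip_total) /
         ((input_count + pseudocount) / input_total))
}

#' Per-gene ChIP enrichment over gene body plus flanks
#'
#' Sums ChIP and input coverage over each gene body extended by \code{flank}
#' bp on both sides (truncated at sequence ends, with truncation recorded)
#' and reports the total-normalized log2 ChIP/input ratio with a pseudocount.
#'
#' @param chip,input Coverage tracks (0-based half-open bins with counts).
#' @param genes Data frame with \code{gene_id}, \code{start}, \code{end}
#'   (1-based inclusive extents).
#' @param flank Flank size in bp (default 1500).
#' @param pseudocount Reads added to each region count (default 0.5).
#' @param seqlength Sequence length; defaults to the track extent.
#' @return Data frame of class \code{enrichment_records}.
#' @export
gene_enrichment <- function(chip, input, genes, flank = 1500,
                            pseudocount = 0.5, seqlength = NULL) {
  ct <- track_total(chip)
  it <- track_total(input)
  if (ct <= 0 || it <= 0) {
    stop("gene_enrichment: chip and input totals must be > 0", call. = FALSE)
  }
  sl <- seqlength %||% max(chip$end, input$end)
  if (any(genes$start < 1L) || any(genes$end > sl)) {
    stop("gene_enrichment: gene extent outside coverage track", call. = FALSE)
  }
  s <- pmax(1L, genes$start - flank)
  e <- pmin(sl, genes$end + flank)
  cc <- vapply(seq_len(nrow(genes)), function(i) track_range_sum(chip, s[i], e[i]),
               numeric(1))
  ic <- vapply(seq_len(nrow(genes)), function(i) track_range_sum(input, s[i], e[i]),
               numeric(1))
  out <- data.frame(gene_id = genes$gene_id,
                    chip_count = cc, input_count = ic,
                    chip_total = ct, input_total = it,
                    log2_enrichment = log2_enrichment(cc, ic, ct, it, pseudocount),
                    flank_truncated = (genes$start - flank < 1L) |
                      (genes$end + flank > sl))
  class(out) <- c("enrichment_records", "data.frame")
  out
}

#' Allele-resolved ChIP enrichment from informative-site counts
#'
#' Computes per-gene, per-allele log2 enrichment from allele-assigned ChIP
#' reads normalized against allele-assigned input reads (no additional DNA
#' correction is applied, since the input control already absorbs it). Totals
#' are taken over both alleles, so a genuine allelic ChIP excess is retained.
#' Genes with zero input reads on an allele are excluded and reported.
#'
#' @param agg Aggregated allele counts ([aggregate_allele_counts()]) holding
#'   \code{ChIP} and \code{input} assays.
#' @param pseudocount Reads added to each count (default 0.5).
#' @return Data frame \code{gene_id}, \code{allele} ("neoX"/"neoY"),
#'   \code{log2_enrichment}; excluded genes in attribute \code{excluded}.
#' @export
allele_enrichment <- function(agg, pseudocount = 0.5) {
  w <- counts_wide(agg, assays = c("ChIP", "input"))
  ct <- sum(w$chip_x + w$chip_y)
  it <- sum(w$input_x + w$input_y)
  if (ct <= 0 || it <= 0) {
    stop("allele_enrichment: no ChIP or input reads", call. = FALSE)
  }
  excl <- w$gene_id[w$input_x == 0 | w$input_y == 0]
  keep <- !(w$gene_id %in% excl)
  w <- w[keep, , drop = FALSE]
  out <- rbind(
    data.frame(gene_id = w$gene_id, allele = "neoX",
               log2_enrichment = log2_enrichment(w$chip_x, w$input_x, ct, it,
                                                 pseudocount)),
    data.frame(gene_id = w$gene_id, allele = "neoY",
               log2_enrichment = log2_enrichment(w$chip_y, w$input_y, ct, it,
                                                 pseudocount))
  )
  out <- out[order(out$gene_id, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excl
  out
}

# Strand-oriented per-gene bin boundaries: flank_bins fixed-width bins
# upstream, body_bins equal-fraction bins over the gene, flank_bins
# downstream. Returns a data frame of (bin_index, bin_type, start, end).
gene_bins <- function(start, end, strand, body_bins, flank_bins, flank, seqlength) {
  fb_w <- flank / flank_bins
  up <- cbind(start - 1 - flank + fb_w * (seq_len(flank_bins) - 1),
              start - 1 - flank + fb_w * seq_len(flank_bins))
  body_edges <- start - 1 + (end - start + 1) * (0:body_bins) / body_bins
  body <- cbind(body_edges[-(body_bins + 1)], body_edges[-1])
  down <- cbind(end + fb_w * (seq_len(flank_bins) - 1), end + fb_w * seq_len(flank_bins))
  m <- rbind(up, body, down)
  type <- c(rep("upstream", flank_bins), rep("body", body_bins),
            rep("downstream", flank_bins))
  if (strand == "-") {
    m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    type <- rev(type)
    type[type == "upstream"] <- "tmp"
    type[type == "downstream"] <- "upstream"
    type[type == "tmp"] <- "downstream"
  }
  s <- pmax(0, m[, 1])
  e <- pmin(seqlength, m[, 2])
  data.frame(bin_index = seq_len(nrow(m)), bin_type = type,
             start = pmin(s, e), end = pmax(s, e))
}

#' Per-gene, per-bin log2 enrichment (metagene substrate)
#'
#' Maps every gene body to \code{body_bins} equal-fraction bins plus
#' fixed-width flank bins, strand-oriented so bin 1 is the 5' flank end, and
#' computes total-normalized log2 ChIP/input enrichment per bin. Genes
#' shorter than \code{body_bins} bases are excluded and reported in the
#' \code{excluded} attribute.
#'
#' @inheritParams gene_enrichment
#' @param genes Data frame with \code{gene_id}, \code{start}, \code{end},
#'   \code{strand}.
#' @param body_bins Number of scaled gene-body bins (default 20).
#' @param flank_bins Bins per 1.5 kb flank (default 5).
#' @return Data frame \code{gene_id}, \code{bin_index}, \code{bin_type},
#'   \code{enrichment}.
#' @export
gene_bin_enrichment <- function(chip, input, genes, body_bins = 20L,
                                flank_bins = 5L, flank = 1500,
                                pseudocount = 0.5, seqlength = NULL) {
  ct <- track_total(chip)
  it <- track_total(input)
  sl <- seqlength %||% max(chip$end, input$end)
  short <- genes$gene_id[(genes$end - genes$start + 1L) < body_bins]
  keep <- !(genes$gene_id %in% short)
  rows <- lapply(which(keep), function(i) {
    b <- gene_bins(genes$start[i], genes$end[i], genes$strand[i],
                   body_bins, flank_bins, flank, sl)
    cc <- vapply(seq_len(nrow(b)),
                 function(k) track_range_sum(chip, b$start[k] + 1, b$end[k]),
                 numeric(1))
    ic <- vapply(seq_len(nrow(b)),
                 function(k) track_range_sum(input, b$start[k] + 1, b$end[k]),
                 numeric(1))
    data.frame(gene_id = genes$gene_id[i], bin_index = b$bin_index,
               bin_type = b$bin_type,
               enrichment = log2_enrichment(cc, ic, ct, it, pseudocount))
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- short
  out
}

#' Bound/unbound cutoff from bin-enrichment distributions
#'
#' Chooses the threshold separating the bin-level enrichment distribution of
#' a target gene group from the background groups as the density-crossing
#' point between the pooled distributions (same machinery as
#' [active_cutoff()]). Deterministic given identical input; non-separable
#' distributions fall back to the configured default with a warning.
#'
#' @param bin_enrichment Output of [gene_bin_enrichment()].
#' @param groups Named vector gene_id -> group label.
#' @param target_group Group whose enrichment should sit above the cutoff.
#' @param default Fallback threshold (default 0).
#' @param min_bins Minimum bins required per side (default 50).
#' @param mark Optional mark name carried through.
#' @return List of class \code{bound_cutoff}: \code{mark}, \code{threshold},
#'   \code{separable}, \code{method}.
#' @export
bound_cutoff <- function(bin_enrichment, groups, target_group, default = 0,
                         min_bins = 50L, mark = NA_character_) {
  grp <- unname(groups[bin_enrichment$gene_id])
  tgt <- bin_enrichment$enrichment[grp == target_group]
  bkg <- bin_enrichment$enrichment[grp != target_group & !is.na(grp)]
  if (length(tgt) < min_bins || length(bkg) < min_bins) {
    stop("bound_cutoff: need at least ", min_bins, " bins per side", call. = FALSE)
  }
  cx <- density_crossing(low_sample = bkg, high_sample = tgt)
  if (is.null(cx)) {
    warning("bound_cutoff: distributions not separable; using default ",
            default, call. = FALSE)
    return(structure(list(mark = mark, threshold = default, separable = FALSE,
                          method = "fallback_default"), class = "bound_cutoff"))
  }
  structure(list(mark = mark, threshold = cx, separable = TRUE,
                 method = "kde_crossing"), class = "bound_cutoff")
}

#' Metagene bound-fraction profiles per gene group
#'
#' For each group (e.g. chromosome x expression status), the fraction of
#' genes whose bin enrichment is at or above the bound cutoff, per scaled
#' gene-body bin and fixed-width flank bin, oriented 5' to 3'.
#'
#' @param bin_enrichment Output of [gene_bin_enrichment()].
#' @param cutoff A [bound_cutoff()] result or a plain numeric threshold.
#' @param groups Named vector gene_id -> group label.
#' @return Data frame \code{group}, \code{bin_index}, \code{bin_type},
#'   \code{bound_fraction}, \code{n_genes}.
#' @export
metagene_profile <- function(bin_enrichment, cutoff, groups) {
  thr <- if (inherits(cutoff, "bound_cutoff")) cutoff$threshold else cutoff
  be <- bin_enrichment
  be$group <- unname(groups[be$gene_id])
  be <- be[!is.na(be$group), , drop = FALSE]
  be$bound <- be$enrichment >= thr
  agg <- stats::aggregate(bound ~ group + bin_index + bin_type, data = be, FUN = mean)
  ngene <- stats::aggregate(gene_id ~ group, data = unique(be[, c("gene_id", "group")]),
                            FUN = length)
  names(agg)[names(agg) == "bound"] <- "bound_fraction"
  agg$n_genes <- ngene$gene_id[match(agg$group, ngene$group)]
  agg <- agg[order(agg$group, agg$bin_index), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Compare enrichment between gene groups (Wilcoxon rank-sum)
#'
#' Reports group medians and a two-sided Wilcoxon rank-sum p-value for each
#' requested contrast. Contrasts with a missing or too-small group are
#' skipped with a note.
#'
#' @param values Data frame with \code{value} and \code{group}.
#' @param contrasts List of 2-vectors \code{c(group_a, group_b)}.
#' @param min_n Minimum group size (default 3).
#' @return Data frame: one row per contrast with medians, delta and p-value.
#' @export
group_compare <- function(values, contrasts, min_n = 3L) {
  do.call(rbind, lapply(contrasts, function(ct) {
    a <- values$value[values$group == ct[1L]]
    b <- values$value[values$group == ct[2L]]
    if (length(a) < min_n || length(b) < min_n) {
      return(data.frame(group1 = ct[1L], group2 = ct[2L],
                        n1 = length(a), n2 = length(b),
                        median1 = NA_real_, median2 = NA_real_,
                        delta = NA_real_, p_value = NA_real_,
                        note = "skipped_small_group"))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
    data.frame(group1 = ct[1L], group2 = ct[2L], n1 = length(a), n2 = length(b),
               median1 = stats::median(a), median2 = stats::median(b),
               delta = stats::median(a) - stats::median(b),
               p_value = wt$p.value, note = NA_character_)
  }))
}
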