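# Simulated ChIP and input coverage tracks. Input coverage is uniform in
# expectation; ChIP coverage is scaled per gene group by the configured true
# log2 enrichment over the gene body plus flanks, optionally with a
# 3'-increasing gradient inside the gene body.

#' Simulate binned ChIP and input coverage tracks
#'
#' Input counts per bin are Poisson with a uniform mean; ChIP counts are
#' Poisson with the mean multiplied by \code{2^level} inside each gene's body
#' and 1.5 kb flanks, where \code{level} is the gene group's true enrichment.
#' With \code{cfg$chip_gradient}, the in-body level ramps linearly from
#' \code{0.5 * level} at the 5' end to \code{1.5 * level} at the 3' end
#' (strand-aware), so the expected enrichment increases monotonically towards
#' the 3' end while averaging \code{level}.
#'
#' @param annotation Gene models from [simulate_gene_models()].
#' @param truth A \code{truth_bundle} (provides group levels and assignments).
#' @param cfg The [sim_config()].
#' @param flank Flank width over which the group level applies (default 1500).
#' @return List with \code{chip} and \code{input} coverage tracks
#'   (0-based half-open \code{chrom}, \code{start}, \code{end}, \code{count}).
#' @export
simulate_chip_coverage <- function(annotation, truth, cfg, flank = 1500) {
  stopifnot(inherits(truth, "truth_bundle"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 4L)
  sl <- attr(annotation, "seqlength")
  chrom <- attr(annotation, "chrom")
  w <- cfg$chip_bin
  starts <- seq.int(0L, sl - 1L, by = w)
  ends <- pmin(starts + w, sl)
  mid <- (starts + ends) / 2
  lvl <- numeric(length(starts))

  genes <- gene_table(annotation)
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    level <- unname(truth$true_enrichment[truth$gene_groups[g]])
    gs <- genes$start[i]; ge <- genes$end[i]
    span <- mid >= gs - 1 - flank & mid < ge + flank
    lvl[span] <- level
    if (cfg$chip_gradient && level != 0) {
      body <- mid >= gs - 1 & mid < ge
      f <- (mid[body] - (gs - 1)) / (ge - gs + 1)
      if (genes$strand[i] == "-") f <- 1 - f
      lvl[body] <- level * (0.5 + f)
    }
  }
  frac <- (ends - starts) / w
  input_count <- stats::rpois(length(starts), cfg$chip_depth * frac)
  chip_count <- stats::rpois(length(starts), cfg$chip_depth * 2^lvl * frac)
  list(
    chip = data.frame(chrom = chrom, start = starts, end = ends, count = chip_count),
    input = data.frame(chrom = chrom, start = starts, end = ends, count = input_count)
  )
}
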