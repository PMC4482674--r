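# Enrichment records, allele-resolved enrichment, bound cutoffs, metagene
# bound-fraction profiles and group contrasts.

flat_track <- function(n_bins, width = 50, count = 100, chrom = "chrT") {
  data.frame(chrom = chrom, start = (seq_len(n_bins) - 1) * width,
             end = seq_len(n_bins) * width, count = count)
}

# genes placed >= 1.5 kb from both sequence ends so flanks are never truncated
two_genes <- function(len = 400, gap = 2000, strand2 = "+") {
  data.frame(gene_id = c("gA", "gB"),
             start = c(2001, 2001 + len + gap),
             end = c(2000 + len, 2000 + len + gap + len),
             strand = c("+", strand2))
}

test_that("identical tracks give zero enrichment and global scaling cancels", {
  tr <- flat_track(200)
  genes <- two_genes()
  e0 <- gene_enrichment(tr, tr, genes, seqlength = 10000)
  expect_true(all(e0$log2_enrichment == 0))

  tr2 <- transform(tr, count = count * 2)
  e1 <- gene_enrichment(tr2, tr, genes, seqlength = 10000)
  expect_true(all(abs(e1$log2_enrichment) < 0.01))

  expect_error(gene_enrichment(tr, tr, data.frame(gene_id = "g", start = 1,
                                                  end = 99999, strand = "+")),
               "outside")
})

test_that("allele enrichment keeps a genuine allelic ChIP excess and reports exclusions", {
  agg <- rbind(
    data.frame(gene_id = sprintf("g%d", 1:20), assay = "ChIP",
               x_count = 100, y_count = 200, n_informative_sites = 3L),
    data.frame(gene_id = sprintf("g%d", 1:20), assay = "input",
               x_count = 100, y_count = 100, n_informative_sites = 3L)
  )
  ae <- allele_enrichment(agg)
  dy <- ae$log2_enrichment[ae$allele == "neoY"] -
    ae$log2_enrichment[ae$allele == "neoX"]
  expect_true(all(abs(dy - 1) < 0.02))

  agg0 <- rbind(agg, data.frame(gene_id = "gz", assay = c("ChIP", "input"),
                                x_count = c(10, 0), y_count = c(10, 10),
                                n_informative_sites = 1L))
  ae2 <- allele_enrichment(agg0)
  expect_identical(attr(ae2, "excluded"), "gz")
  expect_false("gz" %in% ae2$gene_id)

  # equal splits -> equal enrichment for the two alleles
  agg_eq <- transform(agg, y_count = x_count)
  ae3 <- allele_enrichment(agg_eq)
  expect_equal(ae3$log2_enrichment[ae3$allele == "neoX"],
               ae3$log2_enrichment[ae3$allele == "neoY"])
})

test_that("bound cutoff separates shifted groups, is order-invariant, and falls back", {
  set.seed(15)
  be <- data.frame(gene_id = rep(sprintf("g%d", 1:20), each = 10),
                   bin_index = rep(1:10, 20), bin_type = "body",
                   enrichment = c(rnorm(100, 2, 0.5), rnorm(100, 0, 0.5)))
  groups <- stats::setNames(rep(c("target", "bg"), each = 10), sprintf("g%d", 1:20))
  bc <- bound_cutoff(be, groups, "target")
  expect_true(bc$separable)
  expect_gt(bc$threshold, 0)
  expect_lt(bc$threshold, 2)

  be_perm <- be[sample(nrow(be)), ]
  bc2 <- bound_cutoff(be_perm, groups, "target")
  expect_equal(bc2$threshold, bc$threshold)

  be_same <- transform(be, enrichment = rnorm(200, 1, 0.5))
  expect_warning(bc3 <- bound_cutoff(be_same, groups, "target", default = 0.25),
                 "default")
  expect_equal(bc3$threshold, 0.25)

  expect_error(bound_cutoff(be[1:60, ], groups, "target"), "bins per side")
})

test_that("uniform enrichment above the cutoff gives bound fraction one everywhere", {
  # total normalization cancels a globally uniform chip/input ratio, so the
  # uniform enrichment level is 0; any cutoff below it is exceeded everywhere
  chip <- flat_track(400, count = 400)
  input <- flat_track(400, count = 100)
  genes <- two_genes()
  be <- gene_bin_enrichment(chip, input, genes, seqlength = 20000)
  prof <- metagene_profile(be, cutoff = -0.5,
                           groups = c(gA = "all", gB = "all"))
  expect_true(all(prof$bound_fraction == 1))
  expect_equal(unique(prof$n_genes), 2L)
})

test_that("metagene profiles are strand-symmetric for mirrored 3' signal", {
  # two equal-length genes; signal occupies the 3' half of each gene,
  # which is the right half for the + gene and the left half for the - gene
  genes <- two_genes(len = 400, strand2 = "-")
  w <- 50
  n_bins <- 200
  base <- flat_track(n_bins, width = w, count = 100)
  chip <- base
  hi <- function(a, b) which(base$start >= a & base$end <= b)
  chip$count[hi(2200, 2400)] <- 800                      # gA 3' half (+)
  chip$count[hi(4400, 4600)] <- 800                      # gB 3' half (-)
  be <- gene_bin_enrichment(chip, base, genes, seqlength = n_bins * w)
  pa <- be[be$gene_id == "gA", ]
  pb <- be[be$gene_id == "gB", ]
  expect_equal(pa$bin_type, pb$bin_type)
  expect_equal(pa$enrichment, pb$enrichment, tolerance = 1e-9)

  prof <- metagene_profile(be, cutoff = 1, groups = c(gA = "plus", gB = "minus"))
  expect_equal(prof$bound_fraction[prof$group == "plus"],
               prof$bound_fraction[prof$group == "minus"])
})

test_that("genes shorter than the bin count are excluded and reported", {
  chip <- flat_track(100)
  genes <- rbind(two_genes(),
                 data.frame(gene_id = "tiny", start = 4001, end = 4010,
                            strand = "+"))
  be <- gene_bin_enrichment(chip, chip, genes, body_bins = 20, seqlength = 5000)
  expect_identical(attr(be, "excluded"), "tiny")
  expect_false("tiny" %in% be$gene_id)
})

test_that("group contrasts report medians and Wilcoxon p-values, skipping small groups", {
  set.seed(16)
  vals <- data.frame(value = c(rnorm(50, 0), rnorm(50, 2)),
                     group = rep(c("a", "b"), each = 50))
  cmp <- group_compare(vals, list(c("b", "a")))
  expect_lt(cmp$p_value, 0.001)
  expect_gt(cmp$delta, 1)

  same <- data.frame(value = rep(rnorm(30), 2), group = rep(c("a", "b"), each = 30))
  cmp2 <- group_compare(same, list(c("a", "b")))
  expect_gt(cmp2$p_value, 0.9)

  cmp3 <- group_compare(vals, list(c("a", "missing")))
  expect_identical(cmp3$note, "skipped_small_group")
})
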