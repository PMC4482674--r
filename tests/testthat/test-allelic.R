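# Allelic aggregation, DNA-normalized Fisher testing, RPKM, the activity
# cutoff, sex-bias ratios and rank correlation.

test_that("site counts aggregate to genes with conservation of totals", {
  sc <- data.frame(chrom = "c", pos = c(10, 20, 10, 20, 30),
                   gene_id = c("g1", "g1", "g1", "g1", "g2"),
                   assay = c("RNA", "RNA", "DNA", "DNA", "RNA"),
                   x_count = c(10, 20, 5, 6, 7), y_count = c(5, 15, 5, 6, 3))
  agg <- aggregate_allele_counts(sc)
  g1rna <- agg[agg$gene_id == "g1" & agg$assay == "RNA", ]
  expect_equal(g1rna$x_count, 30)
  expect_equal(g1rna$y_count, 20)
  expect_equal(g1rna$n_informative_sites, 2L)
  expect_equal(sum(agg$x_count), sum(sc$x_count))
  expect_equal(sum(agg$y_count), sum(sc$y_count))

  # mapping table route and the ambiguous-site error
  sc2 <- sc[, setdiff(names(sc), "gene_id")]
  map <- data.frame(chrom = "c", pos = c(10, 20, 30), gene_id = c("g1", "g1", "g2"))
  agg2 <- aggregate_allele_counts(sc2, map)
  expect_equal(sum(agg2$x_count), sum(sc$x_count))
  bad <- rbind(map, data.frame(chrom = "c", pos = 10, gene_id = "g2"))
  expect_error(aggregate_allele_counts(sc2, bad), "more than one")
})

test_that("the allelic bias test matches the hypergeometric oracle and its defined ratios", {
  gc <- data.frame(gene_id = c("null", "biased", "allzero", "zerodna"),
                   dna_x = c(50, 50, 0, 0), dna_y = c(50, 50, 0, 40),
                   rna_x = c(50, 80, 0, 30), rna_y = c(50, 20, 0, 30))
  res <- allelic_bias_test(gc)
  expect_equal(res$odds_ratio[1], 1)
  expect_equal(res$p_value[1], 1)
  expect_equal(res$log2_norm_ratio[1], 0)

  expect_equal(res$odds_ratio[2], 4)
  expect_equal(res$p_value[2], hyper_fisher_p(50, 50, 80, 20), tolerance = 1e-10)

  expect_false(res$testable[3]); expect_identical(res$note[3], "all_zero")
  expect_false(res$testable[4]); expect_identical(res$note[4], "zero_dna")

  # pseudocount only enters the ratio when a cell is zero
  gc2 <- data.frame(gene_id = "g", dna_x = 50, dna_y = 50, rna_x = 40, rna_y = 0)
  res2 <- allelic_bias_test(gc2)
  expect_equal(res2$odds_ratio, (40.5 / 0.5) / (50.5 / 50.5))
  expect_equal(res2$log2_norm_ratio, log2(res2$odds_ratio))

  # BH adjustment is monotone in p and bounded by 1
  expect_true(all(res$p_adjusted[res$testable] >= res$p_value[res$testable] - 1e-12))
})

test_that("log2 normalized ratio is zero exactly when the odds ratio is one", {
  set.seed(5)
  for (i in 1:20) {
    dx <- sample(10:80, 1); dy <- sample(10:80, 1)
    k <- sample(1:4, 1)
    res <- allelic_bias_test(data.frame(gene_id = "g", dna_x = dx, dna_y = dy,
                                        rna_x = k * dx, rna_y = k * dy))
    expect_equal(res$odds_ratio, 1)
    expect_equal(res$log2_norm_ratio, 0)
  }
})

test_that("RPKM follows its closed form and scale invariance", {
  cts <- data.frame(feature_id = c("a", "b"), sample = "s",
                    count = c(100, 0), length_bp = c(1000, 500))
  r <- rpkm_table(cts, c(s = 1e6))
  expect_equal(r$rpkm, c(100, 0))
  r2 <- rpkm_table(transform(cts, count = count * 2), c(s = 2e6))
  expect_equal(r2$rpkm, r$rpkm)
  expect_error(rpkm_table(cts, c(s = 0)), "positive")
  expect_error(rpkm_table(transform(cts, length_bp = 0), c(s = 1e6)), "lengths")
})

test_that("the activity cutoff sits between separable components and falls back otherwise", {
  set.seed(8)
  g <- rnorm(400, 1.5, 0.5)
  i <- rnorm(400, -0.5, 0.5)
  cut <- active_cutoff(g, i)
  expect_true(cut$separable)
  expect_gt(cut$threshold, -0.5)
  expect_lt(cut$threshold, 1.5)
  # equal weights and sds -> analytic equal-density point at the midpoint 0.5
  expect_lt(abs(cut$threshold - 0.5), 0.3)

  # translation equivariance
  cut2 <- active_cutoff(g + 1, i + 1)
  expect_lt(abs(cut2$threshold - (cut$threshold + 1)), 0.02)

  # identical distributions -> warning and the reference default 0.65
  expect_warning(cut3 <- active_cutoff(g, g), "default")
  expect_false(cut3$separable)
  expect_equal(cut3$threshold, 0.65)

  expect_error(active_cutoff(g[1:5], i), "at least 10")
})

test_that("sex-bias ratios classify fold changes and expose per-allele ratios", {
  sb <- sex_bias(c("a", "b", "c"),
                 male_rpkm_combined = c(1, 2, 1),
                 female_rpkm = c(1, 1, 4),
                 male_x_rpkm = c(0.5, 1.5, 0.5),
                 male_y_rpkm = c(0.5, 0.5, 0.5))
  expect_equal(sb$log2_male_female, c(0, 1, -2))
  expect_identical(sb$bias_class, c("unbiased", "male_biased", "female_biased"))
  expect_equal(sb$x_over_female, c(0.5, 1.5, 0.125))

  # two neo-X copies in females vs one in males at equal per-copy output:
  # the male neo-X allele runs at half the female level
  set.seed(9)
  f <- 2 * rlnorm(50, 0, 0.1)
  sb2 <- sex_bias(sprintf("g%d", 1:50), f / 2 + 0, f, male_x_rpkm = f / 4 * 2)
  expect_lt(abs(median(sb2$x_over_female) - 0.5), 0.05)
})

test_that("rank correlation handles monotone, reversed and incomplete input", {
  x <- 1:20
  expect_equal(correlate_bias(x, x * 2)$rho, 1)
  expect_equal(correlate_bias(x, rev(x))$rho, -1)
  r <- correlate_bias(c(x, NA), c(x * 2, 1))
  expect_equal(r$n_used, 20L)
  expect_equal(r$n_dropped, 1L)
  expect_error(correlate_bias(1:4, 1:4), "at least 5")
})
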