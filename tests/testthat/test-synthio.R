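# Generator: gene-model validity, seeded determinism, mutation planting,
# count models, expression mixtures, coverage tracks, fixture round trips.

test_that("gene models are deterministic per seed, differ across seeds, and are valid ORFs", {
  cfg <- small_cfg(seed = 1)
  gm1 <- simulate_gene_models(cfg)
  gm2 <- simulate_gene_models(cfg)
  expect_identical(gm1, gm2)

  gm3 <- simulate_gene_models(small_cfg(seed = 2))
  expect_false(identical(gm1$reference, gm3$reference))

  genes <- attr(gm1$annotation, "genes")
  expect_equal(nrow(genes), 6L)
  for (g in genes$gene_id) {
    cds <- neosex:::spliced_cds(gm1$reference, gm1$annotation, g)
    expect_identical(substr(cds, 1, 3), "ATG")
    expect_equal(nchar(cds) %% 3, 0)
    aa <- neosex:::translate_cds(cds)
    expect_equal(sum(aa == "*"), 1)
    expect_identical(aa[length(aa)], "*")
  }
  # genes non-overlapping and disjoint from intergenic windows
  o <- order(genes$start)
  expect_true(all(genes$start[o][-1] > genes$end[o][-nrow(genes)]))
  for (i in seq_len(nrow(gm1$intergenic))) {
    w <- gm1$intergenic[i, ]
    expect_false(any(genes$start <= w$end & genes$end >= w$start))
  }
})

test_that("single-gene config yields one CDS whose translation stops exactly once, at the end", {
  cfg <- small_cfg(seed = 5, n_genes = 1)
  gm <- simulate_gene_models(cfg)
  cds <- neosex:::spliced_cds(gm$reference, gm$annotation, "g001")
  aa <- neosex:::translate_cds(cds)
  expect_equal(which(aa == "*"), length(aa))
})

test_that("zero divergence and no targets leave the haplotype untouched", {
  cfg <- small_cfg(seed = 3, silent_divergence_d = 0, n_female_poly = 0,
                   n_shared_poly = 0)
  gm <- simulate_gene_models(cfg)
  mh <- mutate_haplotype(gm$reference, gm$annotation, cfg)
  expect_identical(mh$neo_y[[1]], gm$reference[[1]])
  expect_equal(nrow(mh$truth$true_variants), 0L)
  expect_true(all(mh$truth$true_status == "INTACT"))
})

test_that("planted silent substitution counts sit in the binomial envelope", {
  d <- 0.02
  cfg <- small_cfg(seed = 9, n_genes = 20, cds_length_mean = 900,
                   silent_divergence_d = d, n_female_poly = 0, n_shared_poly = 0)
  gm <- simulate_gene_models(cfg)
  mh <- mutate_haplotype(gm$reference, gm$annotation, cfg)
  G <- sum(vapply(attr(gm$annotation, "genes")$gene_id, function(g) {
    length(silent_sites(neosex:::spliced_cds(gm$reference, gm$annotation, g)))
  }, numeric(1)))
  n_silent <- sum(mh$truth$true_variants$category == "silent")
  expect_lt(abs(n_silent - G * d), 3 * sqrt(G * d * (1 - d)))
})

test_that("pseudogene targets receive exactly their planted degeneration class", {
  targets <- c(g001 = "PTC", g002 = "FRAMESHIFT", g004 = "PTC_AND_FRAMESHIFT")
  cfg <- small_cfg(seed = 12, pseudogene_targets = targets)
  gm <- simulate_gene_models(cfg)
  mh <- mutate_haplotype(gm$reference, gm$annotation, cfg)
  st <- mh$truth$true_status
  expect_identical(st[["g001"]], "PTC")
  expect_identical(st[["g002"]], "FRAMESHIFT")
  expect_identical(st[["g004"]], "PTC_AND_FRAMESHIFT")
  expect_true(all(st[c("g003", "g005", "g006")] == "INTACT"))

  cfg_bad <- small_cfg(seed = 12, pseudogene_targets = c("nope"))
  expect_error(mutate_haplotype(gm$reference, gm$annotation, cfg_bad), "nope")
})

test_that("assay counts follow the configured allelic ratios", {
  cfg <- small_cfg(seed = 21, n_genes = 10, cds_length_mean = 900,
                   silent_divergence_d = 0.05, assay_depth = 1000,
                   allelic_ratio = 3, n_female_poly = 0, n_shared_poly = 0)
  gm <- simulate_gene_models(cfg)
  mh <- mutate_haplotype(gm$reference, gm$annotation, cfg)
  sc <- simulate_assay_counts(mh$truth, cfg)
  expect_true(all(sc$x_count >= 0 & sc$y_count >= 0))

  dna <- sc[sc$assay == "DNA", ]
  p_dna <- sum(dna$x_count) / sum(dna$x_count + dna$y_count)
  se <- sqrt(0.25 / sum(dna$x_count + dna$y_count))
  expect_lt(abs(p_dna - 0.5), 3 * se)

  rna <- sc[sc$assay == "RNA", ]
  p_rna <- sum(rna$x_count) / sum(rna$x_count + rna$y_count)
  se_r <- sqrt(0.75 * 0.25 / sum(rna$x_count + rna$y_count))
  expect_lt(abs(p_rna - 0.75), 3 * se_r)
})

test_that("zero assay depth yields all-zero counts", {
  cfg <- small_cfg(seed = 22, silent_divergence_d = 0.05, assay_depth = 0)
  gm <- simulate_gene_models(cfg)
  mh <- mutate_haplotype(gm$reference, gm$annotation, cfg)
  sc <- simulate_assay_counts(mh$truth, cfg)
  expect_true(all(sc$x_count == 0 & sc$y_count == 0))
})

test_that("expression tables form separable mixtures with RPKM invariant to library size", {
  cfg <- small_cfg(seed = 31, n_genes = 40, cds_length_mean = 600,
                   intergenic_length = 1500)
  gm <- simulate_gene_models(cfg)
  ex <- simulate_expression_tables(gm$annotation, gm$intergenic, cfg)
  rp <- rpkm_table(ex$counts, ex$totals)
  sub <- rp[rp$sample == "male_adult", ]
  cut <- active_cutoff(log10(sub$rpkm[sub$feature_type == "gene"] + 1e-9),
                       log10(sub$rpkm[sub$feature_type == "intergenic"] + 1e-9))
  expect_true(cut$separable)
  expect_gt(cut$threshold, cfg$intergenic_log10_rpkm_mean)
  expect_lt(cut$threshold, cfg$gene_log10_rpkm_mean)

  cfg2 <- small_cfg(seed = 31, n_genes = 40, cds_length_mean = 600,
                    intergenic_length = 1500, library_size = 2 * cfg$library_size)
  ex2 <- simulate_expression_tables(gm$annotation, gm$intergenic, cfg2)
  rp2 <- rpkm_table(ex2$counts, ex2$totals)
  m1 <- median(rp$rpkm[rp$feature_type == "gene"])
  m2 <- median(rp2$rpkm[rp2$feature_type == "gene"])
  expect_lt(abs(log2(m1 / m2)), 0.3)
})

test_that("coverage tracks carry the planted group enrichment and gradient", {
  # null: all groups at 0 -> per-gene enrichment centred on 0
  cfg0 <- small_cfg(seed = 41, n_genes = 30, cds_length_mean = 600,
                    intergenic_length = 4000,
                    enrichment_groups = c(genes = 0), chip_depth = 200)
  gm0 <- simulate_gene_models(cfg0)
  mh0 <- mutate_haplotype(gm0$reference, gm0$annotation, cfg0)
  cv0 <- simulate_chip_coverage(gm0$annotation, mh0$truth, cfg0)
  enr0 <- gene_enrichment(cv0$chip, cv0$input, attr(gm0$annotation, "genes"),
                          seqlength = attr(gm0$annotation, "seqlength"))
  expect_lt(abs(median(enr0$log2_enrichment)), 0.1)

  # two groups split by one log2 unit
  cfg1 <- small_cfg(seed = 42, n_genes = 40, cds_length_mean = 600,
                    intergenic_length = 4000,
                    enrichment_groups = c(target = 1, background = 0),
                    chip_depth = 200)
  gm1 <- simulate_gene_models(cfg1)
  mh1 <- mutate_haplotype(gm1$reference, gm1$annotation, cfg1)
  cv1 <- simulate_chip_coverage(gm1$annotation, mh1$truth, cfg1)
  enr1 <- gene_enrichment(cv1$chip, cv1$input, attr(gm1$annotation, "genes"),
                          seqlength = attr(gm1$annotation, "seqlength"))
  grp <- mh1$truth$gene_groups[enr1$gene_id]
  dmed <- median(enr1$log2_enrichment[grp == "target"]) -
    median(enr1$log2_enrichment[grp == "background"])
  expect_lt(abs(dmed - 1), 0.15)

  # gradient: bin means increase 5' -> 3'
  cfgg <- small_cfg(seed = 43, n_genes = 40, cds_length_mean = 1000,
                    intergenic_length = 4000, chip_gradient = TRUE,
                    enrichment_groups = c(genes = 2), chip_depth = 200)
  gmg <- simulate_gene_models(cfgg)
  mhg <- mutate_haplotype(gmg$reference, gmg$annotation, cfgg)
  cvg <- simulate_chip_coverage(gmg$annotation, mhg$truth, cfgg)
  be <- gene_bin_enrichment(cvg$chip, cvg$input, attr(gmg$annotation, "genes"),
                            seqlength = attr(gmg$annotation, "seqlength"))
  body <- be[be$bin_type == "body", ]
  bm <- aggregate(enrichment ~ bin_index, data = body, FUN = mean)
  fit <- lm(enrichment ~ bin_index, data = bm)
  expect_gt(coef(fit)[["bin_index"]], 0)
})

test_that("fixture bundles are byte-identical per seed and round-trip through the readers", {
  cfg <- small_cfg(seed = 51, silent_divergence_d = 0.03,
                   pseudogene_targets = c("g001", "g002"))
  b1 <- simulate_bundle(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_bundle(b1, d1)
  write_fixture_bundle(simulate_bundle(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }

  fx <- read_fixture_bundle(d1)
  tv <- b1$truth$true_variants
  shared <- b1$truth$polymorphisms[b1$truth$polymorphisms$sex == "shared", ]
  expect_setequal(paste(fx$male_variants$pos, fx$male_variants$ref, fx$male_variants$alt),
                  c(paste(tv$pos, tv$ref, tv$alt),
                    paste(shared$pos, shared$ref, shared$alt)))
  k1 <- with(b1$annotation, paste(gene_id, start, end, strand, exon_rank))
  k2 <- with(fx$annotation, paste(gene_id, start, end, strand, exon_rank))
  expect_setequal(k1, k2)
  expect_identical(fx$reference[[1]], b1$reference[[1]])
  expect_identical(fx$neo_y[[1]], b1$neo_y[[1]])
})

test_that("an all-quiet simulation writes valid headers with zero variant records", {
  cfg <- small_cfg(seed = 52, silent_divergence_d = 0, n_female_poly = 0,
                   n_shared_poly = 0)
  b <- simulate_bundle(cfg)
  d <- withr::local_tempdir()
  write_fixture_bundle(b, d)
  mv <- read_vcf(file.path(d, "male.vcf"))
  expect_equal(nrow(mv), 0L)
  expect_true(any(grepl("^##fileformat=VCF", readLines(file.path(d, "male.vcf")))))
})

test_that("configuration validation rejects bad inputs", {
  expect_error(sim_config(n_genes = 0, seed = 1), "n_genes")
  expect_error(sim_config(seed = 1, silent_divergence_d = 1.5), "probability")
  expect_error(sim_config(n_genes = 5), "seed")
  expect_error(sim_config(seed = 1, pseudogene_targets = c(g001 = "BAD")), "PTC")
})
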