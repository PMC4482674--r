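# ORF-integrity classification on hand-built toy genes with manually derived
# expected coding sequences and statuses.

test_that("a gene without variants yields identical alleles and INTACT status", {
  cds <- "ATGAAACCCGGGTTTTAA"
  toy <- toy_gene(cds)
  pr <- project_and_apply("gX", toy$reference, toy$annotation,
                          data.frame()[0, ])
  expect_identical(pr$y_cds, pr$x_cds)
  st <- classify_orf(pr$x_cds, pr$y_cds, pr$variants_in_cds)
  expect_identical(st$status, "INTACT")
})

test_that("intronic variants do not alter the coding sequence", {
  cds <- "ATGAAACCCGGGTTTTAA"
  toy <- toy_gene(cds, intron = "GTTTTTTTAG", split_at = 9L)
  # intron occupies genomic pad+10 .. pad+19
  v <- snp_row(toy$gene_start + 12L, "T", "A")
  pr <- project_and_apply("gX", toy$reference, toy$annotation, v)
  expect_identical(pr$y_cds, cds)
  expect_equal(nrow(pr$variants_in_cds), 0L)
})

test_that("minus-strand genes apply reverse-complemented alleles at the right transcript position", {
  cds <- "ATGGGCTGCTTTTAA"
  toy <- toy_gene(cds, strand = "-")
  L <- nchar(cds)
  t <- 6L                                     # transcript position to change
  gpos <- toy$gene_start + (L - t)            # genomic position on the + strand
  # transcript base C -> T means reference-forward G -> A at gpos
  expect_identical(substr(toy$reference[[1]], gpos, gpos), "G")
  pr <- project_and_apply("gX", toy$reference, toy$annotation,
                          snp_row(gpos, "G", "A"))
  expected <- cds
  substr(expected, t, t) <- "T"
  expect_identical(pr$y_cds, expected)
})

test_that("a single substitution to a stop codon is called PTC with the retained fraction", {
  # 10 codons; codon 5 (TAC) -> TAA by one substitution
  cds <- paste0("ATG", "AAA", "CCC", "GGG", "TAC", "TTT", "CAT", "GAA", "CGA", "TAA")
  toy <- toy_gene(cds)
  gpos <- toy$gene_start + 14L                 # CDS position 15: third base of codon 5
  pr <- project_and_apply("gX", toy$reference, toy$annotation,
                          snp_row(gpos, "C", "A"))
  st <- classify_orf(pr$x_cds, pr$y_cds, pr$variants_in_cds)
  expect_identical(st$status, "PTC")
  expect_equal(st$first_ptc_codon, 5L)
  expect_equal(st$truncation_fraction, 0.4)
})

test_that("frameshifting insertions are classified with and without a shifted-frame stop", {
  cds <- "ATGAAACCCGGGTTTTAA"
  toy <- toy_gene(cds)

  # +1 insertion in codon 3; shifted tail has no stop -> FRAMESHIFT only
  g7 <- toy$gene_start + 6L
  v1 <- indel_row(g7, substr(cds, 7, 7), paste0(substr(cds, 7, 7), "A"))
  pr1 <- project_and_apply("gX", toy$reference, toy$annotation, v1)
  expect_identical(pr1$y_cds, "ATGAAACACCGGGTTTTAA")
  st1 <- classify_orf(pr1$x_cds, pr1$y_cds, pr1$variants_in_cds)
  expect_identical(st1$status, "FRAMESHIFT")
  expect_false(st1$frame_restored)

  # +1 insertion whose shifted frame reads TGA immediately -> PTC too
  cds2 <- "ATGGAATTTTAA"
  toy2 <- toy_gene(cds2)
  g3 <- toy2$gene_start + 2L
  v2 <- indel_row(g3, "G", "GT")
  pr2 <- project_and_apply("gX", toy2$reference, toy2$annotation, v2)
  expect_identical(pr2$y_cds, "ATGTGAATTTTAA")
  st2 <- classify_orf(pr2$x_cds, pr2$y_cds, pr2$variants_in_cds)
  expect_identical(st2$status, "PTC_AND_FRAMESHIFT")
  expect_equal(st2$first_ptc_codon, 2L)
  expect_equal(st2$truncation_fraction, 0.25)
})

test_that("in-frame indels that only move the terminal stop stay INTACT", {
  cds <- "ATGAAACCCTAA"
  toy <- toy_gene(cds)
  # delete codon 2 (AAA): anchor at CDS pos 3
  g3 <- toy$gene_start + 2L
  v <- indel_row(g3, substr(cds, 3, 6), substr(cds, 3, 3))
  pr <- project_and_apply("gX", toy$reference, toy$annotation, v)
  expect_identical(pr$y_cds, "ATGCCCTAA")
  st <- classify_orf(pr$x_cds, pr$y_cds, pr$variants_in_cds)
  expect_identical(st$status, "INTACT")
})

test_that("compensating +1/-1 indels restore the frame but remain FRAMESHIFT", {
  cds <- "ATGAAACCCGGGTTTTAA"
  toy <- toy_gene(cds)
  v <- rbind(
    indel_row(toy$gene_start + 6L, substr(cds, 7, 7),
              paste0(substr(cds, 7, 7), "A")),          # +1 after CDS pos 7
    indel_row(toy$gene_start + 8L, substr(cds, 9, 10),
              substr(cds, 9, 9))                         # -1: deletes CDS pos 10
  )
  pr <- project_and_apply("gX", toy$reference, toy$annotation, v)
  expect_identical(pr$y_cds, "ATGAAACACCGGTTTTAA")
  st <- classify_orf(pr$x_cds, pr$y_cds, pr$variants_in_cds)
  expect_identical(st$status, "FRAMESHIFT")
  expect_true(st$frame_restored)
  expect_equal(length(st$frameshift_positions), 2L)
})

test_that("an indel spanning an exon boundary flags the gene unresolvable", {
  cds <- "ATGAAACCCGGGTTTTAA"
  toy <- toy_gene(cds, intron = "GTAAAAATAG", split_at = 9L)
  # deletion starting in exon 1 and reaching into the intron
  g8 <- toy$gene_start + 7L
  v <- indel_row(g8, substr(toy$reference[[1]], g8, g8 + 3L),
                 substr(toy$reference[[1]], g8, g8))
  pr <- project_and_apply("gX", toy$reference, toy$annotation, v)
  expect_true(pr$unresolvable)
})

test_that("start-codon loss is flagged separately, not folded into PTC", {
  cds <- "ATGAAACCCTAA"
  toy <- toy_gene(cds)
  pr <- project_and_apply("gX", toy$reference, toy$annotation,
                          snp_row(toy$gene_start, "A", "G"))
  st <- classify_orf(pr$x_cds, pr$y_cds, pr$variants_in_cds)
  expect_true(st$start_lost)
  expect_identical(st$status, "INTACT")
})

test_that("status summaries count categories and the non-functional proportion", {
  st <- data.frame(gene_id = sprintf("g%02d", 1:10),
                   status = c(rep("INTACT", 5), rep("PTC", 2),
                              rep("FRAMESHIFT", 2), "PTC_AND_FRAMESHIFT"))
  sm <- summarize_status(st)
  expect_equal(sm$n_total, 10)
  expect_equal(sm$n_nonfunctional, 5)
  expect_equal(sm$prop_nonfunctional, 0.5)

  empty <- summarize_status(st[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("classification matches planted truth on a simulated fixture", {
  cfg <- small_cfg(seed = 71, n_genes = 12, silent_divergence_d = 0.03,
                   nonsyn_rate = 0.003,
                   pseudogene_targets = sprintf("g%03d", 1:7))
  gm <- simulate_gene_models(cfg)
  mh <- mutate_haplotype(gm$reference, gm$annotation, cfg)
  genes <- attr(gm$annotation, "genes")
  for (g in genes$gene_id) {
    ext <- genes[genes$gene_id == g, ]
    tv <- mh$truth$true_variants
    vg <- tv[tv$pos >= ext$start - 1 & tv$pos <= ext$end, ]
    pr <- project_and_apply(g, gm$reference, gm$annotation, vg)
    st <- classify_orf(pr$x_cds, pr$y_cds, pr$variants_in_cds)
    expect_identical(st$status, mh$truth$true_status[[g]], label = g)
  }
})
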