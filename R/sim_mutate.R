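# Haplotype mutagenesis: derive a neo-Y sequence from the simulated neo-X
# reference by planting silent substitutions at 4-fold degenerate sites,
# optional nonsynonymous substitutions, degenerative mutations (premature stop
# codons, frameshifting indels) in designated target genes, and neutral
# intergenic/intronic indels. Every introduced variant is recorded in
# reference coordinates with its planted category, so downstream recovery can
# be checked against an exact ground truth.

# Left-alignment + detectability context for planted indels (VCF anchor form):
# the indel must not be shiftable one base left, and the first changed base
# must mismatch the reference continuation so an exhaustive pairwise scan
# recovers the exact planted representation.
indel_context_ok <- function(refseq, pos, ref, alt) {
  n <- nchar(refseq)
  if (pos < 2L) return(FALSE)
  if (nchar(ref) > nchar(alt)) {          # deletion
    s <- pos + 1L
    e <- pos + nchar(ref) - 1L
    if (e + 1L > n) return(FALSE)
    substr(refseq, pos, pos) != substr(refseq, e, e) &&
      substr(refseq, s, s) != substr(refseq, e + 1L, e + 1L)
  } else {                                # insertion
    w <- substr(alt, 2L, nchar(alt))
    lw <- nchar(w)
    if (pos + 1L > n) return(FALSE)
    substr(w, 1L, 1L) != substr(refseq, pos + 1L, pos + 1L) &&
      substr(w, lw, lw) != substr(refseq, pos, pos)
  }
}

span_within_exon <- function(exons, lo, hi, margin = 3L) {
  any(exons$start + margin <= lo & hi <= exons$end - margin)
}

# Convert a transcript-space indel (after/at transcript position t) into a
# genomic VCF-style record. Returns NULL when the indel would not sit
# contiguously inside one exon.
transcript_indel_to_genomic <- function(refseq, map, strand, t, kind, len, ins_seq = NULL) {
  dir <- if (strand == "+") 1L else -1L
  if (kind == "DEL") {
    if (t + len - 1L > length(map)) return(NULL)
    if (map[t + len - 1L] != map[t] + dir * (len - 1L)) return(NULL)
    span <- sort(c(map[t], map[t + len - 1L]))
    a <- span[1L] - 1L
    if (a < 1L) return(NULL)
    list(pos = a,
         ref = substr(refseq, a, span[2L]),
         alt = substr(refseq, a, a),
         vclass = "DEL", span = c(a, span[2L]))
  } else {                                # INS after transcript position t
    if (t + 1L > length(map)) return(NULL)
    if (map[t + 1L] != map[t] + dir) return(NULL)
    a <- min(map[t], map[t + 1L])
    w <- if (strand == "+") ins_seq else revcomp(ins_seq)
    list(pos = a,
         ref = substr(refseq, a, a),
         alt = paste0(substr(refseq, a, a), w),
         vclass = "INS", span = c(a, a + 1L))
  }
}

apply_transcript_indel <- function(cds, t, kind, len, ins_seq = NULL) {
  if (kind == "DEL") {
    paste0(substr(cds, 1L, t - 1L), substr(cds, t + len, nchar(cds)))
  } else {
    paste0(substr(cds, 1L, t), ins_seq, substr(cds, t + 1L, nchar(cds)))
  }
}

first_stop_codon <- function(cds) {
  cod <- split_codons(cds)
  hit <- which(cod %in% STOP_CODONS)
  if (length(hit)) hit[1L] else NA_integer_
}

variant_row <- function(chrom, pos, ref, alt, vclass, gene_id, category) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             vclass = vclass, gene_id = gene_id, category = category,
             stringsAsFactors = FALSE)
}

#' Mutate the reference into a neo-Y haplotype with recorded ground truth
#'
#' Plants silent substitutions at 4-fold degenerate third codon positions with
#' per-site probability \code{cfg$silent_divergence_d}, optional
#' nonsynonymous (never stop-creating) substitutions, degenerative mutations in
#' the genes named in \code{cfg$pseudogene_targets}, and neutral
#' intergenic/intronic indels. Target genes receive exactly the degeneration
#' class they were assigned: a premature stop codon is created by a single
#' substitution in the middle third of the CDS, and a frameshifting indel is
#' placed near the 3' end and rejection-sampled so the shifted tail frame
#' introduces no premature stop of its own.
#'
#' @param reference Named character vector of length 1 (the neo-X sequence).
#' @param annotation Gene models from [simulate_gene_models()].
#' @param cfg The [sim_config()] used to build the models.
#' @return A list with \code{neo_y} (named sequence), \code{truth} (class
#'   \code{truth_bundle}: \code{true_variants}, \code{polymorphisms},
#'   \code{true_status}, \code{true_allelic_ratio}, \code{true_enrichment},
#'   \code{gene_groups}) and \code{map} (reference-to-neo-Y coordinate map).
#' @export
mutate_haplotype <- function(reference, annotation, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  refseq <- unname(reference[1L])
  chrom <- names(reference)[1L]
  genes <- gene_table(annotation)

  targets <- cfg$pseudogene_targets
  unknown <- setdiff(names(targets), genes$gene_id)
  if (length(unknown)) {
    stop("pseudogene target id(s) not in annotation: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  vars <- list()
  status <- stats::setNames(rep("INTACT", nrow(genes)), genes$gene_id)

  for (gi in seq_len(nrow(genes))) {
    gid <- genes$gene_id[gi]
    strand <- genes$strand[gi]
    ex <- exons_of(annotation, gid)
    map <- cds_genomic_map(annotation, gid)
    cds <- spliced_cds(reference, annotation, gid)
    L <- nchar(cds)
    ncod <- L %/% 3L
    work <- cds
    blocked_t <- integer(0)   # transcript positions no substitution may touch
    fs_cut <- L + 1L          # nothing planted at transcript pos >= fs_cut - 1
    type <- if (gid %in% names(targets)) targets[[gid]] else NA_character_

    plant_snp <- function(t, newb) {
      oldb <- substr(work, t, t)
      g <- map[t]
      gref <- if (strand == "+") oldb else comp_base(oldb)
      galt <- if (strand == "+") newb else comp_base(newb)
      stopifnot(substr(refseq, g, g) == gref)
      list(row = variant_row(chrom, g, gref, galt, "SNP", gid, NA_character_),
           t = t)
    }

    if (!is.na(type) && type %in% c("PTC", "PTC_AND_FRAMESHIFT")) {
      lo <- max(2L, floor(ncod * 0.3))
      hi <- max(lo, floor(ncod * 0.6))
      planted <- FALSE
      for (k in sample(seq.int(lo, hi))) {
        cod <- substr(work, 3L * k - 2L, 3L * k)
        hits <- list()
        for (p in 1:3) for (b in setdiff(DNA_BASES, substr(cod, p, p))) {
          nc <- substr_set(cod, p, b)
          substr(nc, p, p) <- b
          if (nc %in% STOP_CODONS) hits[[length(hits) + 1L]] <- list(p = p, b = b)
        }
        if (length(hits)) {
          h <- hits[[sample.int(length(hits), 1L)]]
          t <- 3L * (k - 1L) + h$p
          sv <- plant_snp(t, h$b)
          sv$row$category <- "ptc"
          vars[[length(vars) + 1L]] <- sv$row
          work <- substr_set(work, t, h$b)
          blocked_t <- c(blocked_t, (3L * k - 2L):(3L * k))
          ptc_codon <- k
          planted <- TRUE
          break
        }
      }
      if (!planted) stop("could not plant a PTC in gene ", gid, call. = FALSE)
    } else ptc_codon <- NA_integer_

    if (!is.na(type) && type %in% c("FRAMESHIFT", "PTC_AND_FRAMESHIFT")) {
      w_lo <- max(4L, ncod - 15L, if (!is.na(ptc_codon)) ptc_codon + 2L else 0L)
      w_hi <- ncod - 2L
      if (w_lo > w_hi) w_lo <- w_hi
      ok <- FALSE
      for (try in seq_len(400L)) {
        k <- sample(seq.int(w_lo, w_hi), 1L)
        t <- 3L * (k - 1L) + sample.int(3L, 1L)
        kind <- sample(c("INS", "DEL"), 1L)
        len <- sample(1:2, 1L)
        ins_seq <- if (kind == "INS") random_dna(len) else NULL
        if (kind == "DEL" && t + len - 1L > L - 3L) next
        gv <- transcript_indel_to_genomic(refseq, map, strand, t, kind, len, ins_seq)
        if (is.null(gv)) next
        if (!span_within_exon(ex, gv$span[1L], gv$span[2L])) next
        if (!indel_context_ok(refseq, gv$pos, gv$ref, gv$alt)) next
        if (type == "FRAMESHIFT") {
          # shifted tail frame must introduce no premature stop
          cand <- apply_transcript_indel(work, t, kind, len, ins_seq)
          fs <- first_stop_codon(cand)
          if (!is.na(fs) && fs < ncod) next
        }
        vars[[length(vars) + 1L]] <- variant_row(chrom, gv$pos, gv$ref, gv$alt,
                                                 gv$vclass, gid, "frameshift")
        fs_cut <- t
        ok <- TRUE
        break
      }
      if (!ok) stop("could not plant a clean frameshift in gene ", gid, call. = FALSE)
    }

    if (!is.na(type)) status[[gid]] <- type

    # silent substitutions at 4-fold degenerate third positions
    if (cfg$silent_divergence_d > 0) {
      ss <- silent_sites(work)
      ss <- ss[ss < fs_cut - 1L & !(ss %in% blocked_t)]
      hit <- ss[stats::runif(length(ss)) < cfg$silent_divergence_d]
      for (t in hit) {
        newb <- sample(setdiff(DNA_BASES, substr(work, t, t)), 1L)
        sv <- plant_snp(t, newb)
        sv$row$category <- "silent"
        vars[[length(vars) + 1L]] <- sv$row
        work <- substr_set(work, t, newb)
      }
    }

    # nonsynonymous, never stop-creating substitutions elsewhere in the CDS
    if (cfg$nonsyn_rate > 0) {
      used_t <- c(blocked_t, silent_sites(cds))
      cand <- setdiff(seq.int(4L, min(L - 3L, fs_cut - 2L)), used_t)
      sel <- cand[stats::runif(length(cand)) < cfg$nonsyn_rate]
      for (t in sel) {
        k <- (t - 1L) %/% 3L + 1L
        cod <- substr(work, 3L * k - 2L, 3L * k)
        p <- t - 3L * (k - 1L)
        aa0 <- translate_codons(cod)
        for (b in sample(setdiff(DNA_BASES, substr(cod, p, p)))) {
          nc <- substr_set(cod, p, b)
          aa1 <- translate_codons(nc)
          if (aa1 != "*" && aa1 != aa0) {
            sv <- plant_snp(t, b)
            sv$row$category <- "nonsyn"
            vars[[length(vars) + 1L]] <- sv$row
            work <- substr_set(work, t, b)
            break
          }
        }
      }
    }
  }

  # neutral indels outside exons (intergenic + intronic)
  if (cfg$indel_rate > 0) {
    exonic <- logical(nchar(refseq))
    for (r in seq_len(nrow(annotation))) {
      exonic[annotation$start[r]:annotation$end[r]] <- TRUE
    }
    # keep clear of exon edges so CDS projection is unaffected
    pad <- 10L
    for (r in seq_len(nrow(annotation))) {
      lo <- max(1L, annotation$start[r] - pad)
      hi <- min(nchar(refseq), annotation$end[r] + pad)
      exonic[lo:hi] <- TRUE
    }
    free <- which(!exonic)
    free <- free[free > 60L & free < nchar(refseq) - 60L]
    n_indel <- stats::rpois(1L, cfg$indel_rate * length(free) / 1000)
    placed <- integer(0)
    tries <- 0L
    while (n_indel > 0L && tries < n_indel * 50L) {
      tries <- tries + 1L
      a <- sample(free, 1L)
      if (length(placed) && min(abs(placed - a)) < 40L) next
      kind <- sample(c("INS", "DEL"), 1L)
      len <- sample(1:3, 1L)
      if (kind == "DEL") {
        ref <- substr(refseq, a, a + len)
        alt <- substr(refseq, a, a)
        if (any(exonic[a:(a + len + 1L)])) next
      } else {
        ref <- substr(refseq, a, a)
        alt <- paste0(ref, random_dna(len))
      }
      if (!indel_context_ok(refseq, a, ref, alt)) next
      vars[[length(vars) + 1L]] <- variant_row(chrom, a, ref, alt, kind,
                                               NA_character_, "intergenic_indel")
      placed <- c(placed, a)
      n_indel <- n_indel - 1L
    }
  }

  tv <- if (length(vars)) do.call(rbind, vars) else
    variant_row(character(0), integer(0), character(0), character(0),
                character(0), character(0), character(0))
  tv <- tv[order(tv$pos), , drop = FALSE]
  rownames(tv) <- NULL
  if (nrow(tv)) {
    tv$male_gt <- "HET"
    tv$female_gt <- "HOM_REF"
    tv$qual <- round(stats::runif(nrow(tv), 100, 3000), 1)
    tv$depth <- stats::rpois(nrow(tv), 30) + 5L
  } else {
    tv$male_gt <- character(0); tv$female_gt <- character(0)
    tv$qual <- numeric(0); tv$depth <- integer(0)
  }

  # segregating polymorphisms: female-only and shared heterozygous SNPs
  poly <- list()
  n_poly <- cfg$n_female_poly + cfg$n_shared_poly
  if (n_poly > 0L) {
    taken <- unique(unlist(lapply(seq_len(nrow(tv)), function(i) {
      tv$pos[i] + seq.int(-2L, nchar(tv$ref[i]) + 1L)
    })))
    cand <- setdiff(sample.int(nchar(refseq) - 4L, min(6L * n_poly, nchar(refseq) - 4L)) + 2L,
                    taken)
    cand <- cand[seq_len(min(length(cand), n_poly))]
    if (length(cand) < n_poly) {
      stop("could not place the requested polymorphic sites", call. = FALSE)
    }
    sex <- c(rep("female", cfg$n_female_poly), rep("shared", cfg$n_shared_poly))
    for (i in seq_along(cand)) {
      p <- cand[i]
      rb <- substr(refseq, p, p)
      ab <- sample(setdiff(DNA_BASES, rb), 1L)
      poly[[i]] <- data.frame(chrom = chrom, pos = p, ref = rb, alt = ab,
                              vclass = "SNP", sex = sex[i],
                              qual = round(stats::runif(1, 100, 3000), 1),
                              depth = stats::rpois(1, 30) + 5L,
                              stringsAsFactors = FALSE)
    }
  }
  pdf <- if (length(poly)) do.call(rbind, poly) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), vclass = character(0), sex = character(0),
               qual = numeric(0), depth = integer(0))
  pdf <- pdf[order(pdf$pos), , drop = FALSE]
  rownames(pdf) <- NULL

  ny <- build_neo_y(reference, tv)

  ratios <- cfg$allelic_ratio
  if (is.null(names(ratios))) {
    ratios <- stats::setNames(rep_len(ratios, nrow(genes)), genes$gene_id)
  }
  groups <- stats::setNames(rep_len(names(cfg$enrichment_groups), nrow(genes)),
                            genes$gene_id)

  truth <- structure(list(
    true_variants = tv,
    polymorphisms = pdf,
    true_status = status,
    true_allelic_ratio = ratios,
    true_enrichment = cfg$enrichment_groups,
    gene_groups = groups,
    chrom = chrom,
    seqlength = nchar(refseq)
  ), class = "truth_bundle")

  list(neo_y = stats::setNames(ny$sequence, "neoY"), truth = truth, map = ny$map)
}

#' Plant a random, exactly recoverable variant set on a sequence
#'
#' Utility for round-trip testing of [build_neo_y()] and
#' [recover_variants()]: samples well-spaced SNPs and short indels whose
#' placement is rejection-sampled to be left-aligned and unambiguous, so
#' exhaustive pairwise comparison of the two sequences recovers exactly this
#' set.
#'
#' @param reference Named character vector of length 1.
#' @param n Number of variants to plant.
#' @param seed Integer seed.
#' @param p_indel Probability a variant is an indel rather than a SNP.
#' @param max_len Maximum indel length in bp.
#' @param min_spacing Minimum distance between variant anchors.
#' @return Data frame with \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{vclass}.
#' @export
simulate_variant_set <- function(reference, n, seed, p_indel = 0.4,
                                 max_len = 3L, min_spacing = 30L) {
  set.seed(seed)
  refseq <- unname(reference[1L])
  chrom <- names(reference)[1L]
  ln <- nchar(refseq)
  rows <- list()
  placed <- integer(0)
  tries <- 0L
  while (length(rows) < n && tries < n * 100L) {
    tries <- tries + 1L
    a <- sample.int(ln - max_len - 60L, 1L) + 20L
    if (length(placed) && min(abs(placed - a)) < min_spacing) next
    if (stats::runif(1) < p_indel) {
      kind <- sample(c("INS", "DEL"), 1L)
      len <- sample.int(max_len, 1L)
      if (kind == "DEL") {
        ref <- substr(refseq, a, a + len)
        alt <- substr(refseq, a, a)
      } else {
        ref <- substr(refseq, a, a)
        alt <- paste0(ref, random_dna(len))
      }
      if (!indel_context_ok(refseq, a, ref, alt)) next
      rows[[length(rows) + 1L]] <- variant_row(chrom, a, ref, alt, kind,
                                               NA_character_, "random")
    } else {
      rb <- substr(refseq, a, a)
      ab <- sample(setdiff(DNA_BASES, rb), 1L)
      rows[[length(rows) + 1L]] <- variant_row(chrom, a, rb, ab, "SNP",
                                               NA_character_, "random")
    }
    placed <- c(placed, a)
  }
  if (length(rows) < n) stop("could not place ", n, " spaced variants", call. = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("chrom", "pos", "ref", "alt", "vclass")]
}
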