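# Variant-site handling: quality/depth filtering, classification of sites into
# fixed neo-X/neo-Y differences versus polymorphism, reconstruction of the
# neo-Y sequence from male-specific variants, exhaustive pairwise variant
# recovery, and the polymorphism-contamination estimate.

GT_LEVELS <- c("HOM_REF", "HET", "HOM_ALT", "MISSING")

variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

#' Filter variant sites on quality and depth
#'
#' Keeps sites with \code{qual >= min_qual} and \code{depth >= min_depth}
#' (defaults 30 and 5: sites with Quality < 30 or Depth < 5 are discarded, so
#' the boundary values are kept). Filtered records carry a reason.
#'
#' @param sites Data frame with at least \code{qual} and \code{depth}.
#' @param min_qual,min_depth Inclusive keep thresholds.
#' @return List with \code{kept} and \code{filtered_out} (the latter with a
#'   \code{reason} column); the two partition the input.
#' @export
filter_variants <- function(sites, min_qual = 30, min_depth = 5) {
  if (min_qual < 0 || min_depth < 0) {
    stop("filter_variants: thresholds must be non-negative", call. = FALSE)
  }
  stopifnot(all(c("qual", "depth") %in% names(sites)))
  low_q <- sites$qual < min_qual
  low_d <- sites$depth < min_depth
  drop <- low_q | low_d
  reason <- character(nrow(sites))
  reason[low_q] <- "quality"
  reason[low_d] <- "depth"
  reason[low_q & low_d] <- "quality+depth"
  out <- sites[drop, , drop = FALSE]
  if (nrow(out)) out$reason <- reason[drop] else out$reason <- character(0)
  list(kept = sites[!drop, , drop = FALSE], filtered_out = out)
}

#' Optional per-sex quantile-based quality re-calibration threshold
#'
#' Second-round filtering cutoff chosen as a quantile of the observed quality
#' distribution of one sex's calls, for use when male and female samples were
#' sequenced at different coverage. Disabled by default in the pipeline.
#'
#' @param quals Numeric vector of variant qualities for one sex.
#' @param quantile Which quantile to use as the new cutoff (default 0.05).
#' @return A single quality threshold.
#' @export
quality_recalibration_cutoff <- function(quals, quantile = 0.05) {
  stopifnot(length(quals) > 0, quantile >= 0, quantile <= 1)
  unname(stats::quantile(quals, quantile, names = FALSE))
}

#' Classify sites into male-specific, female-het, shared-het
#'
#' Sites heterozygous in the male but not in the female are the putative fixed
#' neo-X/neo-Y differences (\code{male_specific}); sites heterozygous in both
#' sexes are shared polymorphism and excluded from divergence; female-only
#' heterozygous sites estimate segregating polymorphism. Sites heterozygous in
#' neither sex are set aside with a reason. A site absent from one sex's call
#' set is taken as homozygous reference in that sex.
#'
#' @param male_kept,female_kept Filtered variant data frames (columns
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{gt}).
#' @return List of class \code{site_classification}: data frames
#'   \code{male_specific}, \code{female_het}, \code{shared_het},
#'   \code{filtered_out}, and a per-chromosome \code{counts} table.
#' @export
classify_sites <- function(male_kept, female_kept) {
  for (nm in c("male_kept", "female_kept")) {
    df <- get(nm)
    k <- variant_key(df)
    if (anyDuplicated(k)) {
      stop("duplicate variant record in ", nm, ": ",
           k[duplicated(k)][1L], call. = FALSE)
    }
  }
  mk <- variant_key(male_kept)
  fk <- variant_key(female_kept)
  all_keys <- union(mk, fk)
  m_gt <- stats::setNames(rep("HOM_REF", length(all_keys)), all_keys)
  f_gt <- m_gt
  m_gt[mk] <- male_kept$gt
  f_gt[fk] <- female_kept$gt

  base <- rbind(
    male_kept[, c("chrom", "pos", "ref", "alt")],
    female_kept[!(fk %in% mk), c("chrom", "pos", "ref", "alt")]
  )
  key <- variant_key(base)
  base <- base[match(all_keys, key), , drop = FALSE]
  rownames(base) <- NULL
  base$vclass <- ifelse(nchar(base$ref) == nchar(base$alt), "SNP",
                        ifelse(nchar(base$ref) > nchar(base$alt), "DEL", "INS"))
  base$male_gt <- unname(m_gt)
  base$female_gt <- unname(f_gt)

  m_het <- base$male_gt == "HET"
  f_het <- base$female_gt == "HET"
  res <- list(
    male_specific = base[m_het & !f_het, , drop = FALSE],
    female_het = base[f_het & !m_het, , drop = FALSE],
    shared_het = base[m_het & f_het, , drop = FALSE],
    filtered_out = base[!m_het & !f_het, , drop = FALSE]
  )
  if (nrow(res$filtered_out)) res$filtered_out$reason <- "not_heterozygous"
  else res$filtered_out$reason <- character(0)
  counts <- do.call(rbind, lapply(names(res), function(s) {
    df <- res[[s]]
    if (!nrow(df)) return(NULL)
    agg <- stats::aggregate(list(n = df$pos), by = list(chrom = df$chrom), FUN = length)
    agg$set <- s
    agg
  }))
  res$counts <- counts
  class(res) <- "site_classification"
  res
}

#' Reconstruct the neo-Y sequence from male-specific variants
#'
#' Applies the putative fixed neo-X/neo-Y differences to the reference (neo-X)
#' sequence: SNPs substitute in place, insertions and deletions shift all
#' downstream coordinates. Indels use the VCF anchor-base convention. Variants
#' must be sorted and non-overlapping and their \code{ref} alleles must match
#' the reference; violations are errors naming the site.
#'
#' @param reference Named character vector of length 1.
#' @param variants Data frame with \code{pos}, \code{ref}, \code{alt} (and
#'   optionally \code{vclass}).
#' @return Object of class \code{neo_y}: \code{sequence} (character),
#'   \code{map} (integer vector: reference position -> neo-Y position, NA for
#'   deleted bases).
#' @export
build_neo_y <- function(reference, variants) {
  refseq <- unname(reference[1L])
  n <- nchar(refseq)
  if (is.null(variants) || nrow(variants) == 0L) {
    out <- list(sequence = refseq, map = seq_len(n))
    class(out) <- "neo_y"
    return(out)
  }
  v <- variants[order(variants$pos), , drop = FALSE]
  spans_end <- v$pos + nchar(v$ref) - 1L
  if (any(v$pos < 1L) || any(spans_end > n)) {
    stop("variant outside reference bounds at pos ",
         v$pos[which(v$pos < 1L | spans_end > n)][1L], call. = FALSE)
  }
  if (nrow(v) > 1L && any(v$pos[-1L] <= spans_end[-nrow(v)])) {
    i <- which(v$pos[-1L] <= spans_end[-nrow(v)])[1L] + 1L
    stop("overlapping variants at pos ", v$pos[i], call. = FALSE)
  }
  obs <- substring(refseq, v$pos, spans_end)
  if (any(obs != v$ref)) {
    i <- which(obs != v$ref)[1L]
    stop(sprintf("ref allele mismatch at pos %d: expected '%s', reference has '%s'",
                 v$pos[i], v$ref[i], obs[i]), call. = FALSE)
  }

  map <- integer(n)
  pieces <- character(2L * nrow(v) + 1L)
  pi <- 0L
  ref_cursor <- 1L   # next unconsumed reference position
  y_cursor <- 0L     # length of output emitted so far
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]
    e <- spans_end[i]
    if (p > ref_cursor) {
      seg <- substr(refseq, ref_cursor, p - 1L)
      pi <- pi + 1L; pieces[pi] <- seg
      map[ref_cursor:(p - 1L)] <- y_cursor + seq_len(p - ref_cursor)
      y_cursor <- y_cursor + nchar(seg)
    }
    pi <- pi + 1L; pieces[pi] <- v$alt[i]
    lr <- nchar(v$ref[i]); la <- nchar(v$alt[i])
    if (lr == la) {                     # SNP / same-length substitution
      map[p:e] <- y_cursor + seq_len(lr)
    } else if (lr > la) {               # deletion: anchor maps, rest NA
      map[p] <- y_cursor + 1L
      map[(p + 1L):e] <- NA_integer_
    } else {                            # insertion: anchor maps
      map[p] <- y_cursor + 1L
    }
    y_cursor <- y_cursor + la
    ref_cursor <- e + 1L
  }
  if (ref_cursor <= n) {
    seg <- substr(refseq, ref_cursor, n)
    pi <- pi + 1L; pieces[pi] <- seg
    map[ref_cursor:n] <- y_cursor + seq_len(n - ref_cursor + 1L)
  }
  out <- list(sequence = paste(pieces[seq_len(pi)], collapse = ""), map = map)
  class(out) <- "neo_y"
  out
}

#' Project a reference interval onto neo-Y coordinates
#'
#' @param neo_y A [build_neo_y()] result.
#' @param start,end 1-based inclusive reference interval.
#' @return Integer vector \code{c(start, end)} in neo-Y coordinates (nearest
#'   surviving bases for deleted endpoints).
#' @export
project_interval <- function(neo_y, start, end) {
  map <- neo_y$map
  stopifnot(start >= 1, end <= length(map), start <= end)
  s <- map[start:end]
  s <- s[!is.na(s)]
  if (!length(s)) stop("interval entirely deleted on neo-Y", call. = FALSE)
  c(min(s), max(s))
}

#' Recover variants by exhaustive comparison of two sequences
#'
#' Independent desk-scale analogue of variant calling: scans the reference and
#' a derived sequence with two cursors, classifying each mismatch as a SNP or
#' a short indel by requiring an exact downstream anchor match. Calls are
#' emitted in left-aligned VCF anchor convention, so a variant set planted in
#' unambiguous sequence context is recovered exactly.
#'
#' @param reference,derived Named character vectors of length 1.
#' @param anchor Anchor length in bp used to confirm a candidate event.
#' @param max_indel Maximum indel length considered.
#' @return Data frame with \code{pos}, \code{ref}, \code{alt}, \code{vclass}.
#' @export
recover_variants <- function(reference, derived, anchor = 20L, max_indel = 10L) {
  r <- unname(reference[1L])
  d <- unname(derived[1L])
  nr <- nchar(r); nd <- nchar(d)
  rows <- list()
  i <- 1L; j <- 1L
  same_ahead <- function(s1, p1, s2, p2, k) {
    n1 <- nchar(s1); n2 <- nchar(s2)
    k <- min(k, n1 - p1 + 1L, n2 - p2 + 1L)
    if (k <= 0L) return(TRUE)
    substr(s1, p1, p1 + k - 1L) == substr(s2, p2, p2 + k - 1L)
  }
  while (i <= nr && j <= nd) {
    if (substr(r, i, i) == substr(d, j, j)) { i <- i + 1L; j <- j + 1L; next }
    if (same_ahead(r, i + 1L, d, j + 1L, anchor)) {   # SNP
      rows[[length(rows) + 1L]] <- data.frame(
        pos = i, ref = substr(r, i, i), alt = substr(d, j, j),
        vclass = "SNP", stringsAsFactors = FALSE)
      i <- i + 1L; j <- j + 1L
      next
    }
    resolved <- FALSE
    for (L in seq_len(max_indel)) {
      if (i + L <= nr + 1L && same_ahead(r, i + L, d, j, anchor)) {
        # deletion of r[i..i+L-1]
        rows[[length(rows) + 1L]] <- data.frame(
          pos = i - 1L, ref = substr(r, i - 1L, i + L - 1L),
          alt = substr(r, i - 1L, i - 1L), vclass = "DEL",
          stringsAsFactors = FALSE)
        i <- i + L
        resolved <- TRUE
        break
      }
      if (j + L <= nd + 1L && same_ahead(r, i, d, j + L, anchor)) {
        # insertion of d[j..j+L-1]
        rows[[length(rows) + 1L]] <- data.frame(
          pos = i - 1L, ref = substr(r, i - 1L, i - 1L),
          alt = paste0(substr(r, i - 1L, i - 1L), substr(d, j, j + L - 1L)),
          vclass = "INS", stringsAsFactors = FALSE)
        j <- j + L
        resolved <- TRUE
        break
      }
    }
    if (!resolved) {                                  # fall back: call a SNP
      rows[[length(rows) + 1L]] <- data.frame(
        pos = i, ref = substr(r, i, i), alt = substr(d, j, j),
        vclass = "SNP", stringsAsFactors = FALSE)
      i <- i + 1L; j <- j + 1L
    }
  }
  if (!length(rows)) {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), vclass = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of divergence sites attributable to segregating polymorphism
#'
#' Female-heterozygous sites measure segregating polymorphism; since only half
#' of the polymorphic sites carried by the sequenced line are expected to look
#' male-specific, the contamination fraction of the putative fixed divergence
#' set is estimated as \code{(n_female_het / 2) / n_male_specific}.
#'
#' @param n_male_specific Count of putative fixed neo-X/neo-Y sites (> 0).
#' @param n_female_het Count of female-heterozygous sites.
#' @return The estimated contaminating fraction.
#' @export
estimate_polymorphism_contamination <- function(n_male_specific, n_female_het) {
  if (!is_count(n_male_specific) || n_male_specific <= 0) {
    stop("n_male_specific must be a positive count", call. = FALSE)
  }
  if (!is_count(n_female_het)) {
    stop("n_female_het must be a non-negative count", call. = FALSE)
  }
  (n_female_het / 2) / n_male_specific
}
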