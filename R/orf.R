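# ORF-integrity calling: project male-specific variants onto CDS models,
# derive the neo-Y coding sequence per gene, and classify each gene as intact
# or degenerate (premature termination codon and/or frameshift).

#' Project variants onto a gene's CDS and derive both allelic coding sequences
#'
#' Splices the strand-oriented reference CDS (neo-X allele) and applies the
#' supplied variants to obtain the neo-Y allele. Variants outside exons leave
#' the CDS untouched; an indel whose changed bases straddle an exon boundary
#' flags the gene unresolvable rather than being silently truncated.
#'
#' @param gene_id Gene identifier present in \code{annotation}.
#' @param reference Named character vector of length 1.
#' @param annotation Gene models (exon-level data frame).
#' @param variants Data frame with \code{pos}, \code{ref}, \code{alt},
#'   \code{vclass}; non-overlapping.
#' @return List: \code{gene_id}, \code{x_cds}, \code{y_cds},
#'   \code{variants_in_cds} (applied variants with \code{indel_len}),
#'   \code{unresolvable}, \code{reason}.
#' @export
project_and_apply <- function(gene_id, reference, annotation, variants) {
  ex <- exons_of(annotation, gene_id)
  strand <- ex$strand[1L]
  refseq <- unname(reference[1L])
  x_cds <- spliced_cds(reference, annotation, gene_id)

  if (is.null(variants) || nrow(variants) == 0L) {
    return(list(gene_id = gene_id, x_cds = x_cds, y_cds = x_cds,
                variants_in_cds = empty_cds_variants(),
                unresolvable = FALSE, reason = NA_character_))
  }
  v <- variants[order(variants$pos), , drop = FALSE]
  v_end <- v$pos + nchar(v$ref) - 1L

  pieces <- character(nrow(ex))
  applied <- list()
  for (k in seq_len(nrow(ex))) {
    s <- ex$start[k]; e <- ex$end[k]
    seg <- substr(refseq, s, e)
    # changed bases of each variant: SNP -> pos; DEL -> pos+1..end; INS -> gap pos/pos+1
    for (i in rev(seq_len(nrow(v)))) {
      lr <- nchar(v$ref[i]); la <- nchar(v$alt[i])
      if (lr == 1L && la == 1L) {                       # SNP
        if (v$pos[i] >= s && v$pos[i] <= e) {
          loc <- v$pos[i] - s + 1L
          seg <- substr_set(seg, loc, v$alt[i])
          applied[[length(applied) + 1L]] <- cbind(v[i, , drop = FALSE],
                                                   indel_len = 0L)
        }
      } else if (lr > la) {                             # deletion
        ds <- v$pos[i] + 1L; de <- v_end[i]
        if (de < s || ds > e) next
        if (ds < s || de > e) {
          return(unresolvable_result(gene_id, x_cds, "indel spans exon boundary"))
        }
        seg <- paste0(substr(seg, 1L, ds - s), substr(seg, de - s + 2L, e - s + 1L))
        applied[[length(applied) + 1L]] <- cbind(v[i, , drop = FALSE],
                                                 indel_len = la - lr)
      } else {                                          # insertion after pos
        # inserted bases land between pos and pos+1: inside this exon only
        # when the anchor lies at s..e-1 (an anchor at the exon edge puts the
        # new bases into the flanking intron/intergenic gap)
        if (v$pos[i] < s || v$pos[i] > e - 1L) next
        loc <- v$pos[i] - s + 1L
        seg <- paste0(substr(seg, 1L, loc), substr(v$alt[i], 2L, la),
                      substr(seg, loc + 1L, e - s + 1L))
        applied[[length(applied) + 1L]] <- cbind(v[i, , drop = FALSE],
                                                 indel_len = la - lr)
      }
    }
    pieces[k] <- seg
  }
  if (strand == "-") pieces <- vapply(pieces, revcomp, "", USE.NAMES = FALSE)
  y_cds <- paste(pieces, collapse = "")
  vic <- if (length(applied)) do.call(rbind, applied) else empty_cds_variants()
  vic <- vic[order(vic$pos), , drop = FALSE]
  rownames(vic) <- NULL
  list(gene_id = gene_id, x_cds = x_cds, y_cds = y_cds,
       variants_in_cds = vic, unresolvable = FALSE, reason = NA_character_)
}

empty_cds_variants <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), vclass = character(0), indel_len = integer(0))
}

unresolvable_result <- function(gene_id, x_cds, reason) {
  list(gene_id = gene_id, x_cds = x_cds, y_cds = NA_character_,
       variants_in_cds = empty_cds_variants(), unresolvable = TRUE,
       reason = reason)
}

#' Classify a gene's neo-Y allele as intact or degenerate
#'
#' A gene is \code{FRAMESHIFT} if at least one coding indel has length not
#' divisible by three; it is \code{PTC} if translation of the neo-Y CDS (in
#' the frame as shifted by any upstream indel) reaches a stop codon strictly
#' before the expected terminal codon (the reference terminal codon index,
#' adjusted by the net length of in-frame indels, so a 3n indel that merely
#' moves the original stop is not a premature stop). Both together give
#' \code{PTC_AND_FRAMESHIFT}. A premature stop is called at any position; the
#' retained fraction of the reference protein
#' (\code{truncation_fraction = (first stop codon index - 1) / reference codon
#' count}) lets stricter definitions be applied downstream. Frame restoration
#' by compensating indels (net length divisible by three) and loss of the
#' start codon are reported as separate flags, not folded into the status.
#'
#' @param x_cds Reference (neo-X) CDS; a valid ORF.
#' @param y_cds Neo-Y CDS with variants applied.
#' @param variants_in_cds Applied variants with an \code{indel_len} column.
#' @return List of class \code{orf_status}: \code{status},
#'   \code{first_ptc_codon}, \code{truncation_fraction},
#'   \code{frameshift_positions}, \code{frame_restored}, \code{start_lost}.
#' @export
classify_orf <- function(x_cds, y_cds, variants_in_cds = empty_cds_variants()) {
  if (is.na(y_cds) || nchar(y_cds) == 0L) {
    stop("classify_orf: empty neo-Y CDS", call. = FALSE)
  }
  ref_codons <- nchar(x_cds) %/% 3L
  ilen <- variants_in_cds$indel_len
  fs_idx <- which(ilen != 0L & (ilen %% 3L) != 0L)
  has_fs <- length(fs_idx) > 0L
  frame_restored <- has_fs && (sum(ilen[fs_idx]) %% 3L == 0L)

  # in-frame indels move the (unchanged) terminal stop to a new codon index;
  # a stop is premature only if it falls before that expected terminal codon
  net <- if (length(ilen)) sum(ilen) else 0L
  expected_terminal <- if (net %% 3L == 0L) ref_codons + net %/% 3L else ref_codons
  fs1 <- first_stop_codon(y_cds)
  has_ptc <- !is.na(fs1) && fs1 < expected_terminal
  status <- if (has_ptc && has_fs) "PTC_AND_FRAMESHIFT"
  else if (has_ptc) "PTC"
  else if (has_fs) "FRAMESHIFT"
  else "INTACT"

  structure(list(
    status = status,
    first_ptc_codon = if (has_ptc) fs1 else NA_integer_,
    truncation_fraction = if (has_ptc) (fs1 - 1L) / ref_codons else NA_real_,
    frameshift_positions = variants_in_cds$pos[fs_idx],
    frame_restored = frame_restored,
    start_lost = substr(y_cds, 1L, 3L) != "ATG"
  ), class = "orf_status")
}

#' @export
print.orf_status <- function(x, ...) {
  cat(sprintf("ORF status: %s", x$status))
  if (!is.na(x$first_ptc_codon)) {
    cat(sprintf(" (first stop at codon %d, %.0f%% of protein retained)",
                x$first_ptc_codon, 100 * x$truncation_fraction))
  }
  if (x$frame_restored) cat(" [frame restored downstream]")
  if (x$start_lost) cat(" [start codon lost]")
  cat("\n")
  invisible(x)
}

#' Summarize ORF statuses per chromosome
#'
#' @param statuses Data frame with \code{gene_id} and \code{status}.
#' @param chromosome_map Optional named vector gene_id -> chromosome; genes
#'   without an entry (or with \code{NULL} map) are pooled as "all".
#' @return Data frame with per-chromosome counts of every category and the
#'   proportion of putative non-functional genes.
#' @export
summarize_status <- function(statuses, chromosome_map = NULL) {
  if (is.null(statuses) || nrow(statuses) == 0L) {
    return(data.frame(chrom = character(0), n_total = integer(0),
                      n_intact = integer(0), n_ptc = integer(0),
                      n_frameshift = integer(0), n_ptc_and_frameshift = integer(0),
                      n_nonfunctional = integer(0),
                      prop_nonfunctional = numeric(0)))
  }
  chrom <- if (is.null(chromosome_map)) rep("all", nrow(statuses))
  else unname(chromosome_map[statuses$gene_id])
  chrom[is.na(chrom)] <- "all"
  sp <- split(statuses, chrom)
  out <- do.call(rbind, lapply(names(sp), function(cn) {
    df <- sp[[cn]]
    tab <- table(factor(df$status, levels = ORF_STATUSES))
    nonfunc <- sum(tab[c("PTC", "FRAMESHIFT", "PTC_AND_FRAMESHIFT")])
    data.frame(chrom = cn,
               n_total = nrow(df),
               n_intact = unname(tab["INTACT"]),
               n_ptc = unname(tab["PTC"]),
               n_frameshift = unname(tab["FRAMESHIFT"]),
               n_ptc_and_frameshift = unname(tab["PTC_AND_FRAMESHIFT"]),
               n_nonfunctional = nonfunc,
               prop_nonfunctional = nonfunc / nrow(df))
  }))
  rownames(out) <- NULL
  out
}
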