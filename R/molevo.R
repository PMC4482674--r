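# Molecular evolution statistics: 4-fold degenerate ("silent") site
# identification, pairwise silent divergence, divergence dating, NG86
# pairwise Ka/Ks with Jukes-Cantor correction, and codon usage bias
# (Fop, CBI, CAI).

#' Positions of 4-fold degenerate third codon positions
#'
#' Returns the CDS positions (third positions of codons) whose encoded amino
#' acid is invariant to any third-position substitution under the standard
#' nuclear code. Codons containing ambiguous bases are excluded and counted in
#' the \code{n_ambiguous} attribute; stop codons are never 4-fold degenerate,
#' so the terminal codon is naturally excluded.
#'
#' @param cds Coding sequence, length divisible by three.
#' @return Integer vector of CDS positions (attribute \code{n_ambiguous}).
#' @export
silent_sites <- function(cds) {
  if (nchar(cds) %% 3L != 0L) {
    stop("silent_sites: CDS length must be divisible by 3", call. = FALSE)
  }
  cod <- split_codons(toupper(cds))
  ambiguous <- !grepl("^[ACGT]{3}$", cod)
  ff <- substr(cod, 1L, 2L) %in% fourfold_prefixes() & !ambiguous
  out <- 3L * which(ff)
  attr(out, "n_ambiguous") <- sum(ambiguous)
  out
}

#' Pairwise silent-site divergence between two aligned CDSs
#'
#' Divergence is counted only at third codon positions that are 4-fold
#' degenerate in \emph{both} sequences: d = differing such positions / all
#' such positions. Codons containing ambiguous bases are excluded. Sequences
#' must be equal length (codons affected by indels are to be excluded before
#' calling).
#'
#' @param x_cds,y_cds Aligned equal-length CDSs.
#' @param gene_id Optional identifier carried through to the result.
#' @return List of class \code{divergence_estimate}: \code{gene_id},
#'   \code{n_silent_sites}, \code{n_silent_diffs}, \code{d}, \code{usable},
#'   \code{method}.
#' @export
silent_divergence <- function(x_cds, y_cds, gene_id = NA_character_) {
  if (nchar(x_cds) != nchar(y_cds)) {
    stop("silent_divergence: sequences must be equal length", call. = FALSE)
  }
  sx <- silent_sites(x_cds)
  sy <- silent_sites(y_cds)
  sites <- intersect(sx, sy)
  n <- length(sites)
  if (n == 0L) {
    return(structure(list(gene_id = gene_id, n_silent_sites = 0L,
                          n_silent_diffs = 0L, d = NA_real_, usable = FALSE,
                          method = "FOURFOLD"), class = "divergence_estimate"))
  }
  xb <- substring(x_cds, sites, sites)
  yb <- substring(y_cds, sites, sites)
  k <- sum(xb != yb)
  structure(list(gene_id = gene_id, n_silent_sites = n, n_silent_diffs = k,
                 d = k / n, usable = TRUE, method = "FOURFOLD"),
            class = "divergence_estimate")
}

#' Date the neo-X/neo-Y split from silent divergence
#'
#' Under neutrality the silent divergence between the two haplotypes accrues
#' at twice the mutation rate, so the time since recombination stopped is
#' \code{t_generations = d / (2 * mu)} with \code{mu} in mutations per bp per
#' generation; \code{t_years = t_generations / gen_per_year}. Defaults are a
#' Drosophila mutation rate of 5e-9 per bp per generation and 10 generations
#' per year. Both time scales are reported because shorthand accounts often
#' quote the generations figure in years.
#'
#' @param d_median Median pairwise silent divergence (proportion, >= 0).
#' @param mu Mutation rate per bp per generation (> 0).
#' @param gen_per_year Generations per year (> 0).
#' @return Object of class \code{age_estimate}.
#' @export
estimate_age <- function(d_median, mu = 5e-9, gen_per_year = 10) {
  if (!is.numeric(mu) || mu <= 0) stop("estimate_age: mu must be > 0", call. = FALSE)
  if (!is.numeric(d_median) || d_median < 0) {
    stop("estimate_age: d_median must be >= 0", call. = FALSE)
  }
  if (gen_per_year <= 0) stop("estimate_age: gen_per_year must be > 0", call. = FALSE)
  t_gen <- d_median / (2 * mu)
  structure(list(d_median = d_median, mu = mu, gen_per_year = gen_per_year,
                 t_generations = t_gen, t_years = t_gen / gen_per_year),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("Silent-site divergence dating\n  d (median): %.4g;  mu = %.3g /bp/gen;  %g gen/yr\n",
              x$d_median, x$mu, x$gen_per_year))
  cat(sprintf("  t = d/(2*mu) = %s generations = %s years\n",
              format(round(x$t_generations), big.mark = ","),
              format(round(x$t_years), big.mark = ",")))
  invisible(x)
}

# --- NG86 -------------------------------------------------------------------

# Fraction of one-step changes at each codon position that are synonymous;
# changes producing stop codons count as nonsynonymous.
ng86_codon_sites <- function(codon) {
  gc <- genetic_code()
  aa <- gc[[codon]]
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(DNA_BASES, substr(codon, p, p))) {
      nc <- substr_set(codon, p, b)
      if (!is.na(gc[nc]) && gc[[nc]] == aa) s <- s + 1 / 3
    }
  }
  s
}

ng86_sites_table <- function() {
  if (is.null(.pkg_cache$ng86_sites)) {
    sc <- sense_codons()
    .pkg_cache$ng86_sites <- stats::setNames(
      vapply(sc, ng86_codon_sites, numeric(1)), sc)
  }
  .pkg_cache$ng86_sites
}

# Average synonymous / nonsynonymous differences between two codons over all
# mutational pathways; pathways through stop codons are excluded when any
# stop-free pathway exists.
ng86_codon_diffs <- function(c1, c2) {
  gc <- genetic_code()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  paths <- if (nd == 1L) list(pos) else {
    perms <- if (nd == 2L) list(pos, rev(pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(i) pos[i])
    }
    perms
  }
  eval_path <- function(order) {
    cur <- c1
    sd <- 0; ndif <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- substr_set(cur, p, substr(c2, p, p))
      if (gc[[nxt]] == "*") blocked <- TRUE
      if (gc[[cur]] != "*" && gc[[nxt]] != "*" && gc[[nxt]] == gc[[cur]]) {
        sd <- sd + 1
      } else {
        ndif <- ndif + 1
      }
      cur <- nxt
    }
    list(sd = sd, nd = ndif, blocked = blocked)
  }
  res <- lapply(paths, eval_path)
  ok <- !vapply(res, `[[`, logical(1), "blocked")
  if (any(ok)) res <- res[ok]
  c(sd = mean(vapply(res, `[[`, numeric(1), "sd")),
    nd = mean(vapply(res, `[[`, numeric(1), "nd")))
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) counting method
#'
#' Counts fractional synonymous and nonsynonymous sites per codon (changes to
#' stop codons treated as nonsynonymous), averages observed differences over
#' all mutational pathways for multi-hit codons (pathways through stop codons
#' excluded when avoidable), and applies the Jukes-Cantor multiple-hit
#' correction. When a raw proportion reaches the JC ceiling (p >= 0.75) the
#' uncorrected proportion is reported and flagged. Codon pairs containing a
#' stop or ambiguous base are excluded. This is a pairwise desk-scale
#' statistic, not a likelihood branch model.
#'
#' @param x_cds,y_cds Aligned, equal-length, indel-free CDSs.
#' @param gene_id Optional identifier.
#' @return List of class \code{kaks_estimate}: \code{Ka}, \code{Ks},
#'   \code{ratio} (NA when Ks = 0), \code{syn_sites}, \code{nonsyn_sites},
#'   \code{jc_failed}.
#' @export
ng86_kaks <- function(x_cds, y_cds, gene_id = NA_character_) {
  if (nchar(x_cds) != nchar(y_cds)) {
    stop("ng86_kaks: sequences must be equal length", call. = FALSE)
  }
  cx <- split_codons(toupper(x_cds))
  cy <- split_codons(toupper(y_cds))
  keep <- grepl("^[ACGT]{3}$", cx) & grepl("^[ACGT]{3}$", cy) &
    !(cx %in% STOP_CODONS) & !(cy %in% STOP_CODONS)
  cx <- cx[keep]; cy <- cy[keep]
  st <- ng86_sites_table()
  S <- sum((st[cx] + st[cy]) / 2)
  N <- 3 * length(cx) - S
  sd_tot <- 0; nd_tot <- 0
  for (i in which(cx != cy)) {
    d <- ng86_codon_diffs(cx[i], cy[i])
    sd_tot <- sd_tot + d[["sd"]]
    nd_tot <- nd_tot + d[["nd"]]
  }
  ps <- if (S > 0) sd_tot / S else NA_real_
  pn <- if (N > 0) nd_tot / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(list(d = NA_real_, failed = FALSE))
    if (p >= 0.75) return(list(d = p, failed = TRUE))
    list(d = -3 / 4 * log(1 - 4 * p / 3), failed = FALSE)
  }
  ks <- jc(ps); ka <- jc(pn)
  structure(list(
    gene_id = gene_id,
    Ka = ka$d, Ks = ks$d,
    ratio = if (!is.na(ks$d) && ks$d > 0 && !is.na(ka$d)) ka$d / ks$d else NA_real_,
    syn_sites = S, nonsyn_sites = N,
    n_codons = length(cx),
    jc_failed = ka$failed || ks$failed
  ), class = "kaks_estimate")
}

# --- codon usage ------------------------------------------------------------

#' Codon usage bias statistics: Fop, CBI and CAI
#'
#' \code{Fop} is the fraction of optimal codons among synonymously variable
#' codons (amino acids with a single codon, and stop codons, are excluded).
#' \code{CBI = (Nopt - Nrand) / (Ntot - Nrand)} where \code{Nrand} is the
#' optimal-codon count expected under uniform synonymous usage, computed over
#' codons of amino acids that have at least one designated optimal codon.
#' \code{CAI} is the geometric mean of relative adaptiveness weights over
#' codons present in the weight table.
#'
#' @param cds Coding sequence (terminal stop codon, if present, is ignored).
#' @param optimal_codons Character vector of optimal codons (e.g. derived with
#'   [optimal_codons_from_usage()]); \code{NULL} makes Fop/CBI unavailable.
#' @param cai_weights Optional named numeric vector codon -> weight in (0, 1].
#' @param gene_id Optional identifier.
#' @return List of class \code{codon_usage_stats}: \code{Fop}, \code{CBI},
#'   \code{CAI} (NA when not computable).
#' @export
codon_usage <- function(cds, optimal_codons = NULL, cai_weights = NULL,
                        gene_id = NA_character_) {
  cod <- split_codons(toupper(cds))
  cod <- cod[grepl("^[ACGT]{3}$", cod) & !(cod %in% STOP_CODONS)]
  gc <- genetic_code()
  aa <- unname(gc[cod])
  fam_size <- table(gc[gc != "*"])          # codons per amino acid
  multi <- names(fam_size)[fam_size > 1]

  Fop <- CBI <- NA_real_
  if (!is.null(optimal_codons) && length(optimal_codons)) {
    optimal_codons <- toupper(optimal_codons)
    variable <- aa %in% multi
    n_var <- sum(variable)
    if (n_var > 0L) {
      Fop <- sum(cod[variable] %in% optimal_codons) / n_var
    }
    opt_aa <- unique(unname(gc[optimal_codons]))
    scope <- aa %in% intersect(opt_aa, multi)
    n_tot <- sum(scope)
    if (n_tot > 0L) {
      opt_per_aa <- table(factor(unname(gc[optimal_codons]), levels = opt_aa))
      n_opt <- sum(cod[scope] %in% optimal_codons)
      n_rand <- sum(vapply(intersect(opt_aa, multi), function(a) {
        sum(aa == a) * opt_per_aa[[a]] / fam_size[[a]]
      }, numeric(1)))
      if (n_tot - n_rand != 0) CBI <- (n_opt - n_rand) / (n_tot - n_rand)
    }
  }

  CAI <- NA_real_
  if (!is.null(cai_weights)) {
    w <- cai_weights[cod]
    w <- w[!is.na(w) & w > 0]
    if (length(w)) CAI <- exp(mean(log(w)))
  }

  structure(list(gene_id = gene_id, Fop = Fop, CBI = CBI, CAI = CAI,
                 n_codons = length(cod)),
            class = "codon_usage_stats")
}

#' Derive an optimal-codon table from a set of coding sequences
#'
#' The optimal codon of each synonymously variable amino acid is taken as the
#' most frequent codon in the pooled usage of the supplied sequences (a usage
#' table of highly expressed genes is the usual input).
#'
#' @param cds_list Character vector/list of CDSs.
#' @return Character vector of optimal codons (named by amino acid).
#' @export
optimal_codons_from_usage <- function(cds_list) {
  cod <- unlist(lapply(cds_list, split_codons), use.names = FALSE)
  cod <- cod[grepl("^[ACGT]{3}$", cod) & !(cod %in% STOP_CODONS)]
  gc <- genetic_code()
  fam_size <- table(gc[gc != "*"])
  counts <- table(cod)
  out <- c()
  for (a in names(fam_size)[fam_size > 1]) {
    members <- names(gc)[gc == a]
    cnt <- stats::setNames(rep(0L, length(members)), members)
    seen <- intersect(members, names(counts))
    cnt[seen] <- as.integer(counts[seen])
    out[a] <- names(cnt)[which.max(cnt)]
  }
  out
}
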