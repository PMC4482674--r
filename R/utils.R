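# Shared low-level helpers: genetic code access, codon splitting, reverse
# complement, random sequence, overdispersed counts. All sequence work is on
# plain upper-case character strings; 1-based inclusive coordinates.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

.pkg_cache <- new.env(parent = emptyenv())

genetic_code <- function() Biostrings::GENETIC_CODE

sense_codons <- function() {
  if (is.null(.pkg_cache$sense)) {
    gc <- genetic_code()
    .pkg_cache$sense <- names(gc)[gc != "*"]
  }
  .pkg_cache$sense
}

# Dinucleotide prefixes whose codon family is 4-fold degenerate at position 3.
fourfold_prefixes <- function() {
  if (is.null(.pkg_cache$fourfold)) {
    gc <- genetic_code()
    pre <- unique(substr(names(gc), 1L, 2L))
    ok <- vapply(pre, function(p) {
      aa <- gc[paste0(p, DNA_BASES)]
      length(unique(aa)) == 1L && !any(aa == "*")
    }, logical(1))
    .pkg_cache$fourfold <- pre[ok]
  }
  .pkg_cache$fourfold
}

split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  i <- seq_len(n)
  substring(seq, 3L * (i - 1L) + 1L, 3L * i)
}

# Translate codons; codons with ambiguous bases become "X".
translate_codons <- function(codons) {
  aa <- unname(genetic_code()[codons])
  aa[is.na(aa)] <- "X"
  aa
}

translate_cds <- function(seq) translate_codons(split_codons(seq))

comp_base <- function(b) chartr("ACGT", "TGCA", b)

revcomp <- function(seq) {
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

`substr_set` <- function(x, start, value) {
  substr(x, start, start + nchar(value) - 1L) <- value
  x
}

# Beta-binomial draws; rho = 0 collapses to binomial. rho parameterizes the
# intraclass correlation of the beta mixing distribution.
rbetabinom <- function(n, size, prob, rho = 0) {
  if (rho <= 0) return(stats::rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  p <- stats::rbeta(n, a, b)
  stats::rbinom(n, size, p)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
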