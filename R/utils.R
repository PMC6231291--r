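# Internal helpers shared across modules.

#' Extract the gene family from an IMGT-style gene label
#'
#' Strips allele (`*01`), gene-member (`-1`) and alternate-name (`/`)
#' suffixes so that e.g. `"TRBV5-1*01"` and `"TRBV5-6*02"` both map to the
#' subfamily `"TRBV5"` used for spectratype grouping and family-level
#' database matching.
#'
#' @param x character vector of gene labels.
#' @return character vector of family labels; `NA` input stays `NA`.
#' @examples
#' gene_family(c("TRBV5-1*01", "TRBV12-3/12-4", "TRBJ2-7"))
#' @export
gene_family <- function(x) {
  out <- sub("[-/*].*$", "", trimws(as.character(x)))
  out[!nzchar(out)] <- NA_character_
  out
}

#' Translate in-frame CDR3 junction nucleotide sequences
#'
#' Junctions whose length is not a multiple of 3 (out-of-frame
#' rearrangements) translate to `NA`.
#'
#' @param nt character vector of nucleotide junction sequences.
#' @return character vector of amino-acid sequences (may contain `*` for
#'   stop codons); `NA` where out of frame or input `NA`.
#' @export
translate_junction <- function(nt) {
  nt <- as.character(nt)
  out <- rep(NA_character_, length(nt))
  ok <- !is.na(nt) & nzchar(nt) & nchar(nt) %% 3L == 0L
  if (any(ok)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(nt[ok]),
                                no.init.codon = TRUE)
    out[ok] <- as.character(aa)
  }
  out
}

# Deterministic child-seed derivation: a fixed integer hash of the master
# seed and stream indices, so replicate draws are reproducible regardless of
# evaluation order. Arithmetic in double, reduced mod 2^31 - 2 to stay a
# valid 32-bit seed.
derive_seed <- function(master_seed, ...) {
  idx <- c(...)
  h <- as.double(master_seed) %% 2147483647
  for (k in seq_along(idx)) {
    h <- (h * 48271 + as.double(idx[k]) * 16807 + k) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Greatest common divisor of a vector of positive integers.
gcd_vec <- function(x) {
  g2 <- function(a, b) if (b == 0) a else Recall(b, a %% b)
  Reduce(g2, as.integer(x))
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
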