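# Diversity statistics over clonotype abundance distributions.

#' Gini coefficient of a clonotype abundance vector
#'
#' Inequality of the clone-size distribution: twice the area between the
#' 45-degree line and the Lorenz curve of cumulative clonotype share
#' against cumulative abundance share. Computed with the discrete
#' estimator
#' \deqn{G = \frac{\sum_i (2i - n - 1)\, x_{(i)}}{n \sum_i x_i}}
#' over counts sorted ascending, without small-sample correction, so a
#' vector of identical counts returns exactly 0 and values approach 1 as
#' the sample tends toward oligoclonality.
#'
#' A single-clonotype vector returns 0 with attribute `degenerate = TRUE`:
#' inequality between clonotypes is undefined for one clonotype, and the
#' flag prevents reading that 0 as "maximally even".
#'
#' @param abundances positive numeric vector, one abundance per clonotype.
#' @return Gini coefficient in `[0, 1)`; attribute `degenerate` is `TRUE`
#'   for length-1 input.
#' @examples
#' gini_coefficient(c(5, 5, 5, 5)) # 0: completely equal
#' gini_coefficient(c(1, 9))       # 0.4
#' @export
gini_coefficient <- function(abundances) {
  x <- as.numeric(abundances)
  if (length(x) == 0L) stop("empty abundance vector", call. = FALSE)
  if (any(!is.finite(x) | x <= 0))
    stop("abundances must be positive and finite", call. = FALSE)
  n <- length(x)
  if (n == 1L) return(structure(0, degenerate = TRUE))
  xs <- sort(x)
  i <- seq_len(n)
  sum((2 * i - n - 1) * xs) / (n * sum(xs))
}

#' Shannon entropy of a clonotype abundance vector
#'
#' \eqn{H(X) = -\sum_i p(x_i) \log_b p(x_i)} with \eqn{p(x_i)} the
#' proportional abundance of clonotype \eqn{i}; base \eqn{b = 2} by
#' default, so the result is in bits. The \eqn{0 \log 0} limit is taken
#' as 0.
#'
#' @param abundances positive numeric vector.
#' @param base logarithm base, > 1.
#' @return entropy, between 0 (monoclonal) and `log(n, base)` (all
#'   clonotypes equally abundant).
#' @examples
#' shannon_entropy(c(1, 1, 1, 1)) # 2 bits
#' shannon_entropy(c(1, 1, 2))    # 1.5 bits
#' @export
shannon_entropy <- function(abundances, base = 2) {
  x <- as.numeric(abundances)
  if (length(x) == 0L) stop("empty abundance vector", call. = FALSE)
  if (any(!is.finite(x) | x <= 0))
    stop("abundances must be positive and finite", call. = FALSE)
  if (!is.numeric(base) || length(base) != 1L || base <= 1)
    stop("`base` must be a number > 1", call. = FALSE)
  p <- x / sum(x)
  -sum(p * log(p, base = base))
}

#' Diversity summary of a repertoire sample
#'
#' Gini coefficient, Shannon entropy (bits), richness, read total and the
#' cumulative frequency captured by the top-k most abundant clonotypes
#' (ties broken as in [top_clonotypes()]).
#'
#' @param sample a [repertoire_sample()].
#' @param top_k integer vector of k values, default 20.
#' @return object of class `diversity_summary`: list with `sample_id`,
#'   `gini`, `shannon_bits`, `richness`, `total_reads`, `top_k_fraction`
#'   (named numeric, one entry per k) and `degenerate` (TRUE for a
#'   monoclonal sample).
#' @export
diversity_summary <- function(sample, top_k = 20L) {
  stopifnot(inherits(sample, "repertoire_sample"))
  top_k <- sort(unique(as.integer(top_k)))
  if (length(top_k) == 0L || any(top_k < 1L))
    stop("`top_k` must be positive integers", call. = FALSE)
  counts <- sample$clonotypes$count
  g <- gini_coefficient(counts)
  frac <- vapply(top_k, function(k) {
    tc <- top_clonotypes(sample, n = k)
    sum(tc$frequency)
  }, numeric(1))
  structure(
    list(
      sample_id = sample$sample_id,
      gini = as.numeric(g),
      shannon_bits = shannon_entropy(counts, base = 2),
      richness = length(counts),
      total_reads = sample$total_reads,
      top_k_fraction = stats::setNames(frac, top_k),
      degenerate = isTRUE(attr(g, "degenerate"))
    ),
    class = "diversity_summary"
  )
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat("<diversity_summary> ", x$sample_id, "\n", sep = "")
  cat(sprintf("  Gini %.4f%s   Shannon %.3f bits   richness %d   reads %d\n",
              x$gini, if (x$degenerate) " (degenerate)" else "",
              x$shannon_bits, x$richness, x$total_reads))
  for (k in names(x$top_k_fraction))
    cat(sprintf("  top-%s clonotypes: %.1f%% of reads\n",
                k, 100 * x$top_k_fraction[[k]]))
  invisible(x)
}
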