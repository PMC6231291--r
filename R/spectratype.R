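# Virtual spectratypes: CDR3-length profiles per TRBV family reconstructed
# from sequence data, Gaussian-shape scoring, and the three-group clinical
# classification (Abnormal / Almost_normal / Normal).

#' Spectratype classification thresholds
#'
#' The clinical convention scores a repertoire on (a) the median number of
#' peaks per TRBV family and (b) the fraction of families whose length
#' profile is approximately Gaussian. The defaults encode common clinical
#' spectratyping practice (>= 8 peaks per family and a predominantly
#' Gaussian profile for a complex, "Normal" repertoire; <= 5 peaks or a
#' mostly non-Gaussian profile for "Abnormal"); they are explicit
#' package choices, configurable per site.
#'
#' @param t_peaks median peaks per family at or above which (with a
#'   Gaussian fraction at or above `t_frac`) a repertoire is Normal.
#' @param t_gauss minimum [gaussianness_score()] for a family to count as
#'   Gaussian.
#' @param t_frac minimum fraction of Gaussian families for Normal.
#' @param t_peaks_low median peaks at or below which a repertoire is
#'   Abnormal.
#' @param t_frac_low Gaussian-family fraction at or below which a
#'   repertoire is Abnormal.
#' @return object of class `spectratype_thresholds`.
#' @export
spectratype_thresholds <- function(t_peaks = 8, t_gauss = 0.8,
                                   t_frac = 0.75, t_peaks_low = 5,
                                   t_frac_low = 0.4) {
  structure(list(t_peaks = t_peaks, t_gauss = t_gauss, t_frac = t_frac,
                 t_peaks_low = t_peaks_low, t_frac_low = t_frac_low),
            class = "spectratype_thresholds")
}

#' CDR3-length distribution of a repertoire, overall and per V family
#'
#' Reconstructs a virtual spectratype: the histogram of nucleotide CDR3
#' (junction) lengths weighted by clonotype read frequency, split by TRBV
#' family ([gene_family()] of `v_call`; unresolvable calls are binned
#' under `"unassigned"`). A peak is a length bin whose frequency exceeds
#' `peak_floor` times the family's total frequency. In-frame repertoires
#' show the classical 3-nt peak spacing.
#'
#' @param sample a [repertoire_sample()].
#' @param by_family split by V family (default) or return the aggregate
#'   histogram only.
#' @param peak_floor fraction of the family total above which a bin counts
#'   as a peak (default 0.01).
#' @param weight `"reads"` (frequency-weighted, default) or
#'   `"clonotypes"` (each unique clonotype weighted equally).
#' @return object of class `spectratype_profile`: list with `sample_id`,
#'   `aggregate_histogram` (named numeric: frequency by nt length),
#'   `families` (per-family list: `v_family`, `length_histogram`,
#'   `total_freq`, `peak_count`, `gaussian_score`, `degenerate`),
#'   `median_peaks`, `n_gaussian_families` is filled by
#'   [classify_spectratype()].
#' @export
cdr3_length_distribution <- function(sample, by_family = TRUE,
                                     peak_floor = 0.01,
                                     weight = c("reads", "clonotypes")) {
  stopifnot(inherits(sample, "repertoire_sample"))
  weight <- match.arg(weight)
  cl <- sample$clonotypes
  w <- if (weight == "reads") cl$count / sample$total_reads
       else rep(1 / nrow(cl), nrow(cl))
  len <- nchar(cl$cdr3_nt)

  hist_of <- function(lengths, weights) {
    h <- vapply(split(weights, lengths), sum, numeric(1))
    h[order(as.integer(names(h)))]
  }
  aggregate <- hist_of(len, w)

  families <- list()
  if (by_family) {
    fam <- gene_family(cl$v_call)
    fam[is.na(fam)] <- "unassigned"
    if (any(fam == "unassigned"))
      message(sum(fam == "unassigned"),
              " clonotype(s) with unresolvable v_call binned as 'unassigned'")
    for (f in sort(unique(fam))) {
      sel <- fam == f
      h <- hist_of(len[sel], w[sel])
      tot <- sum(h)
      peaks <- sum(h > peak_floor * tot)
      gs <- gaussianness_score(h)
      families[[f]] <- list(v_family = f, length_histogram = h,
                            total_freq = tot, peak_count = as.integer(peaks),
                            gaussian_score = as.numeric(gs),
                            degenerate = isTRUE(attr(gs, "degenerate")))
    }
  }
  structure(
    list(sample_id = sample$sample_id,
         aggregate_histogram = aggregate,
         families = families,
         median_peaks = if (length(families))
           stats::median(vapply(families, `[[`, integer(1), "peak_count"))
           else NA_real_,
         classification = NA_character_),
    class = "spectratype_profile"
  )
}

#' Gaussian-shape score of a CDR3 length histogram
#'
#' Fits a Gaussian by the frequency-weighted mean and standard deviation
#' of the lengths, discretizes it on the histogram's own length lattice
#' (step = greatest common divisor of the observed length spacings, so
#' in-frame 3-nt combs are compared comb-to-comb), and scores
#' `1 - L1/2` where L1 is the total variation distance between the
#' normalized observed and fitted histograms. Identical shapes score 1,
#' disjoint shapes 0. A single-bin (or zero-spread) histogram has no
#' defined shape: score 0 with attribute `degenerate = TRUE`.
#'
#' @param histogram named numeric vector: names are nt lengths, values
#'   non-negative frequencies (any positive total).
#' @return score in `[0, 1]`.
#' @export
gaussianness_score <- function(histogram) {
  if (length(histogram) == 0L) stop("empty histogram", call. = FALSE)
  lens <- suppressWarnings(as.numeric(names(histogram)))
  if (any(is.na(lens))) stop("histogram names must be numeric lengths",
                             call. = FALSE)
  w <- as.numeric(histogram)
  if (any(w < 0) || sum(w) <= 0)
    stop("histogram values must be non-negative with positive sum",
         call. = FALSE)
  keep <- w > 0
  lens <- lens[keep]; w <- w[keep]
  if (length(lens) == 1L) return(structure(0, degenerate = TRUE))
  p <- w / sum(w)
  mu <- sum(p * lens)
  sigma <- sqrt(sum(p * (lens - mu)^2))
  if (sigma == 0) return(structure(0, degenerate = TRUE))
  step <- gcd_vec(diff(sort(lens)))
  grid <- seq(min(lens), max(lens), by = step)
  obs <- stats::setNames(numeric(length(grid)), grid)
  obs[as.character(lens)] <- p
  fit <- stats::dnorm(grid, mean = mu, sd = sigma)
  fit <- fit / sum(fit)
  1 - sum(abs(obs - fit)) / 2
}

#' Classify a spectratype profile into the three clinical groups
#'
#' Normal iff the median per-family peak count is at least
#' `t_peaks` *and* the fraction of families with
#' `gaussian_score >= t_gauss` is at least `t_frac`; Abnormal iff the
#' median peak count is at most `t_peaks_low` *or* the Gaussian fraction
#' is at most `t_frac_low`; otherwise Almost_normal. Comparisons are
#' inclusive, so a profile exactly at the Normal thresholds is Normal.
#'
#' @param profile a [cdr3_length_distribution()] profile with at least one
#'   family.
#' @param thresholds a [spectratype_thresholds()].
#' @return the profile with `classification`, `median_peaks`,
#'   `gaussian_fraction` and `n_gaussian_families` filled in.
#' @export
classify_spectratype <- function(profile,
                                 thresholds = spectratype_thresholds()) {
  stopifnot(inherits(profile, "spectratype_profile"),
            inherits(thresholds, "spectratype_thresholds"))
  if (length(profile$families) == 0L)
    stop("profile has no V families (was by_family = FALSE?)", call. = FALSE)
  peaks <- vapply(profile$families, `[[`, integer(1), "peak_count")
  scores <- vapply(profile$families, `[[`, numeric(1), "gaussian_score")
  med <- stats::median(peaks)
  n_gauss <- sum(scores >= thresholds$t_gauss)
  frac <- n_gauss / length(scores)
  cls <- if (med >= thresholds$t_peaks && frac >= thresholds$t_frac) {
    "Normal"
  } else if (med <= thresholds$t_peaks_low || frac <= thresholds$t_frac_low) {
    "Abnormal"
  } else {
    "Almost_normal"
  }
  profile$median_peaks <- med
  profile$n_gaussian_families <- as.integer(n_gauss)
  profile$gaussian_fraction <- frac
  profile$classification <- cls
  profile
}

#' @export
print.spectratype_profile <- function(x, ...) {
  cat("<spectratype_profile> ", x$sample_id, ": ",
      length(x$families), " V families, ",
      length(x$aggregate_histogram), " length bins\n", sep = "")
  if (!is.na(x$classification))
    cat("  classification: ", x$classification,
        sprintf(" (median peaks %.1f, Gaussian fraction %.2f)",
                x$median_peaks, x$gaussian_fraction), "\n", sep = "")
  invisible(x)
}
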