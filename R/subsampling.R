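# Replicate rarefaction, the minimum representative subsampling depth
# algorithm, and the cohort-level common-depth optimization.

#' Rarefaction configuration
#'
#' @param percent_grid strictly increasing integer grid of subsampling
#'   percentages within 1..100; the minimum-depth algorithm requires the
#'   full `1:100` grid.
#' @param replicates independent subsamples per depth (default 30).
#' @param gradient_threshold decline-gradient threshold marking
#'   greater-than-linear depreciation of the normalized Gini coefficient;
#'   with depth expressed as a fraction in \[0,1\] a linear decline from
#'   (0,0) to (1,1) has gradient 1, so the default 1.1 flags depths where
#'   the decline is at least 10% steeper than linear.
#' @param master_seed integer seed from which every replicate draw derives
#'   its own child seed, making curves reproducible independent of
#'   evaluation order.
#' @return object of class `rarefaction_config`.
#' @export
rarefaction_config <- function(percent_grid = 1:100,
                               replicates = 30L,
                               gradient_threshold = 1.1,
                               master_seed = 1L) {
  percent_grid <- as.integer(percent_grid)
  if (length(percent_grid) == 0L || any(is.na(percent_grid)) ||
      any(percent_grid < 1L) || any(percent_grid > 100L) ||
      any(diff(percent_grid) <= 0L))
    stop("`percent_grid` must be strictly increasing integers in 1..100",
         call. = FALSE)
  if (!is_count_scalar(replicates))
    stop("`replicates` must be a positive integer", call. = FALSE)
  if (!is.numeric(gradient_threshold) || length(gradient_threshold) != 1L)
    stop("`gradient_threshold` must be a number", call. = FALSE)
  structure(list(percent_grid = percent_grid,
                 replicates = as.integer(replicates),
                 gradient_threshold = as.numeric(gradient_threshold),
                 master_seed = as.integer(master_seed)),
            class = "rarefaction_config")
}

#' Subsample reads from a repertoire without replacement
#'
#' Draws `depth` reads from the sample's read population (each clonotype
#' contributing `count` indistinguishable reads) — a multivariate
#' hypergeometric draw. Clonotypes drawn zero times are dropped; returned
#' counts sum to `depth` exactly. Subsampling at full depth returns the
#' sample unchanged. No extrapolation: `depth` beyond `total_reads` is an
#' error.
#'
#' @param sample a [repertoire_sample()].
#' @param depth number of reads to draw, `1 <= depth <= total_reads`.
#' @param seed integer seed for the draw (the caller's RNG state is left
#'   untouched).
#' @return a [repertoire_sample()] with the rarefied counts.
#' @export
subsample_reads <- function(sample, depth, seed = 1L) {
  stopifnot(inherits(sample, "repertoire_sample"))
  if (!is_count_scalar(depth))
    stop("`depth` must be a positive integer", call. = FALSE)
  depth <- as.integer(depth)
  if (depth > sample$total_reads)
    stop("depth (", depth, ") exceeds total reads (", sample$total_reads,
         "); no extrapolation", call. = FALSE)
  if (depth == sample$total_reads) return(sample)
  counts <- with_seed(seed, mvhyper_draw(sample$clonotypes$count, depth))
  keep <- counts > 0L
  out <- sample
  out$clonotypes <- sample$clonotypes[keep, , drop = FALSE]
  out$clonotypes$count <- counts[keep]
  rownames(out$clonotypes) <- NULL
  out$total_reads <- depth
  out
}

# Depth in reads for a given percent of the total (grid convention:
# nearest read, floor at 1).
percent_to_depth <- function(percent, total_reads) {
  pmax(1L, as.integer(round(percent / 100 * total_reads)))
}

#' Replicate rarefaction curve of normalized diversity
#'
#' For each percent p on the grid the sample is subsampled to
#' `round(p/100 * total_reads)` reads (at least 1), `replicates` times
#' independently; the Gini coefficient and Shannon entropy of each
#' subsample are normalized to their full-depth (100%) values, and the
#' replicate mean and standard error (sd/sqrt(replicates)) recorded. At
#' 100% the subsample is the sample itself, so both normalized means are
#' exactly 1 with zero SE.
#'
#' A sample whose full-depth Gini or Shannon is 0 (e.g. monoclonal) has no
#' meaningful normalization; the curve is flagged degenerate and the
#' affected metric reported as `NA`.
#'
#' @param sample a [repertoire_sample()] with `total_reads >= 100` (so 1%
#'   is at least one read).
#' @param config a [rarefaction_config()].
#' @return object of class `rarefaction_curve`: list with `sample_id`,
#'   `total_reads`, `degenerate`, full-depth `gini_full` / `shannon_full`,
#'   and `curve`, a data.frame with columns `percent`, `depth`,
#'   `mean_norm_gini`, `se_norm_gini`, `mean_norm_shannon`,
#'   `se_norm_shannon`.
#' @export
rarefaction_curve <- function(sample, config = rarefaction_config()) {
  stopifnot(inherits(sample, "repertoire_sample"),
            inherits(config, "rarefaction_config"))
  if (sample$total_reads < 100L)
    stop("rarefaction needs total_reads >= 100", call. = FALSE)
  counts <- sample$clonotypes$count
  g_full <- as.numeric(gini_coefficient(counts))
  h_full <- shannon_entropy(counts)
  degenerate <- g_full == 0 || h_full == 0

  grid <- config$percent_grid
  R <- config$replicates
  res <- matrix(NA_real_, nrow = length(grid), ncol = 4L,
                dimnames = list(NULL, c("mean_norm_gini", "se_norm_gini",
                                        "mean_norm_shannon", "se_norm_shannon")))
  depths <- percent_to_depth(grid, sample$total_reads)
  if (degenerate) {
    return(structure(
      list(sample_id = sample$sample_id, total_reads = sample$total_reads,
           gini_full = g_full, shannon_full = h_full, degenerate = TRUE,
           curve = data.frame(percent = grid, depth = depths, res)),
      class = "rarefaction_curve"
    ))
  }
  for (k in seq_along(grid)) {
    p <- grid[k]
    if (depths[k] == sample$total_reads) {
      res[k, ] <- c(1, 0, 1, 0)
      next
    }
    g <- h <- numeric(R)
    for (r in seq_len(R)) {
      seed_kr <- derive_seed(config$master_seed, p, r)
      sub_counts <- with_seed(seed_kr, mvhyper_draw(counts, depths[k]))
      sub_counts <- sub_counts[sub_counts > 0L]
      g[r] <- as.numeric(gini_coefficient(sub_counts))
      h[r] <- shannon_entropy(sub_counts)
    }
    se <- function(v) stats::sd(v) / sqrt(R)
    res[k, ] <- c(mean(g) / g_full, se(g) / g_full,
                  mean(h) / h_full, se(h) / h_full)
  }

  structure(
    list(sample_id = sample$sample_id,
         total_reads = sample$total_reads,
         gini_full = g_full,
         shannon_full = h_full,
         degenerate = degenerate,
         curve = data.frame(percent = grid, depth = depths, res)),
    class = "rarefaction_curve"
  )
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat("<rarefaction_curve> ", x$sample_id, ": ", nrow(x$curve),
      " depths, total ", x$total_reads, " reads",
      if (x$degenerate) "  [degenerate]", "\n", sep = "")
  invisible(x)
}

# Decompose a sorted integer vector into maximal runs of consecutive
# integers.
consecutive_runs <- function(x) {
  if (length(x) == 0L) return(list())
  x <- sort(unique(as.integer(x)))
  grp <- cumsum(c(1L, diff(x) != 1L))
  unname(split(x, grp))
}

#' Minimum representative subsampling depth of a sample
#'
#' Scans the replicate-mean normalized Gini rarefaction curve for depths
#' where its decline toward low depth is steeper than linear. With depth
#' expressed as a fraction, the forward-difference gradient at percent p is
#' `(g(p+1) - g(p)) / 0.01`; percents where it exceeds
#' `config$gradient_threshold` qualify. Qualifying percents are grouped
#' into maximal runs of consecutive integers; the run containing the
#' smallest percents (order statistic 1) marks where low-frequency
#' clonotypes collapse into the top clones, and the minimum representative
#' percent is that run's largest element plus one (a run ending at 20%
#' yields 21%). If no gradient exceeds the threshold the sample is
#' representative at any depth and the minimum percent is 1.
#'
#' @param curve a [rarefaction_curve()] over the full 1..100 grid,
#'   non-degenerate.
#' @param config the [rarefaction_config()] holding the gradient
#'   threshold.
#' @return object of class `min_depth_result`: list with `sample_id`,
#'   `total_reads`, `qualifying_percents`, `runs`, `selected_run`,
#'   `min_percent` and `min_depth_reads = ceiling(min_percent/100 *
#'   total_reads)` capped at `total_reads`.
#' @export
minimum_representative_depth <- function(curve,
                                         config = rarefaction_config()) {
  stopifnot(inherits(curve, "rarefaction_curve"),
            inherits(config, "rarefaction_config"))
  if (curve$degenerate)
    stop("degenerate rarefaction curve (full-depth Gini or Shannon is 0); ",
         "exclude this sample or handle it separately", call. = FALSE)
  grid <- curve$curve$percent
  if (!identical(as.integer(grid), 1:100))
    stop("minimum_representative_depth requires the full 1..100 percent grid",
         call. = FALSE)
  g <- curve$curve$mean_norm_gini
  gradient <- (g[-1] - g[-length(g)]) / 0.01   # at percents 1..99
  qualifying <- grid[-length(grid)][gradient > config$gradient_threshold]
  runs <- consecutive_runs(qualifying)
  if (length(runs) == 0L) {
    selected <- integer(0)
    min_percent <- 1L
  } else {
    first_members <- vapply(runs, min, integer(1))
    selected <- runs[[which.min(first_members)]]
    min_percent <- max(selected) + 1L
  }
  min_depth <- min(as.integer(ceiling(min_percent / 100 * curve$total_reads)),
                   curve$total_reads)
  structure(
    list(sample_id = curve$sample_id,
         total_reads = curve$total_reads,
         qualifying_percents = as.integer(qualifying),
         runs = runs,
         selected_run = selected,
         min_percent = as.integer(min_percent),
         min_depth_reads = min_depth),
    class = "min_depth_result"
  )
}

#' @export
print.min_depth_result <- function(x, ...) {
  fmt_run <- function(r) paste0(min(r), "-", max(r))
  cat("<min_depth_result> ", x$sample_id, "\n", sep = "")
  cat("  qualifying runs: ",
      if (length(x$runs)) paste(vapply(x$runs, fmt_run, character(1)),
                                collapse = "; ") else "(none)", "\n", sep = "")
  cat("  minimum representative depth: ", x$min_percent, "% = ",
      x$min_depth_reads, " of ", x$total_reads, " reads\n", sep = "")
  invisible(x)
}

#' Cohort-level common subsampling depth
#'
#' Chooses the common depth D (in reads) that maximizes the number of
#' samples whose interval `[min_depth_reads, total_reads]` contains D —
#' i.e. samples that are both representative at D and deep enough to be
#' rarefied to it. The inclusion count only changes at interval endpoints,
#' so the search is restricted to the candidate set of all endpoints; ties
#' are broken toward the largest D (more reads retained per included
#' sample).
#'
#' @param results list of [minimum_representative_depth()] results (each
#'   carrying `min_depth_reads` and `total_reads`).
#' @return object of class `cohort_depth_result`: list with
#'   `common_depth_reads`, `included_sample_ids`, `excluded_sample_ids`
#'   and `n_included`.
#' @export
cohort_common_depth <- function(results) {
  if (inherits(results, "min_depth_result")) results <- list(results)
  if (length(results) == 0L) stop("empty cohort", call. = FALSE)
  lo <- vapply(results, function(r) as.numeric(r$min_depth_reads), numeric(1))
  hi <- vapply(results, function(r) as.numeric(r$total_reads), numeric(1))
  ids <- vapply(results, function(r) as.character(r$sample_id), character(1))
  if (any(lo > hi)) stop("min_depth_reads exceeds total_reads", call. = FALSE)
  candidates <- sort(unique(c(lo, hi)))
  n_inc <- vapply(candidates, function(d) sum(lo <= d & d <= hi), numeric(1))
  best <- max(n_inc)
  D <- max(candidates[n_inc == best])   # tie-break: largest depth
  included <- lo <= D & D <= hi
  structure(
    list(common_depth_reads = as.integer(D),
         included_sample_ids = ids[included],
         excluded_sample_ids = ids[!included],
         n_included = as.integer(sum(included))),
    class = "cohort_depth_result"
  )
}

#' @export
print.cohort_depth_result <- function(x, ...) {
  cat("<cohort_depth_result> common depth ", x$common_depth_reads,
      " reads; ", x$n_included, " sample(s) included",
      if (length(x$excluded_sample_ids))
        paste0("; excluded: ",
               paste(x$excluded_sample_ids, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}
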