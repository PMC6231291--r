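# Fixture builders and independent oracles shared across the suite.

# 61 sense codons (no stops), fixed order.
codons61 <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

# Deterministic distinct in-frame junction for clone i: C + 2 indexed
# codons + F.
toy_junction <- function(i) {
  stopifnot(all(i >= 1 & i <= 61^2))
  a <- ((i - 1) %/% 61) + 1
  b <- ((i - 1) %% 61) + 1
  paste0("TGC", codons61[a], codons61[b], "TTC")
}

# Build a validated sample from a count vector; clonotypes distinct by
# construction with in-frame junctions.
toy_sample <- function(counts, v_call = NULL, j_call = NULL, ...) {
  n <- length(counts)
  if (is.null(v_call)) v_call <- rep("TRBV5-1*01", n)
  if (is.null(j_call)) j_call <- rep("TRBJ2-1*01", n)
  cl <- data.frame(v_call = v_call, j_call = j_call,
                   cdr3_nt = toy_junction(seq_len(n)),
                   count = counts, stringsAsFactors = FALSE)
  repertoire_sample(cl, ...)
}

# --- independent oracles -------------------------------------------------

# Gini via the Lorenz-curve trapezoid rule: twice the area between the
# 45-degree line and the cumulative-share polyline.
gini_lorenz_oracle <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  P <- c(0, seq_len(n) / n)
  L <- c(0, cumsum(xs) / sum(xs))
  area <- sum(diff(P) * (L[-1] + L[-length(L)]) / 2)
  2 * (0.5 - area)
}

shannon_direct_oracle <- function(x, base = 2) {
  p <- x / sum(x)
  -sum(p * log(p) / log(base))
}

# Brute-force minimum-representative-depth: scan percents, group runs by
# linear scan, select the run with the smallest member, +1 rule.
mindepth_oracle <- function(mean_norm_gini, threshold = 1.1) {
  qual <- integer(0)
  for (p in 1:99) {
    grad <- (mean_norm_gini[p + 1] - mean_norm_gini[p]) / 0.01
    if (grad > threshold) qual <- c(qual, p)
  }
  if (!length(qual)) return(1L)
  runs <- list()
  cur <- qual[1]
  if (length(qual) > 1) for (q in qual[-1]) {
    if (q == cur[length(cur)] + 1L) cur <- c(cur, q)
    else { runs[[length(runs) + 1L]] <- cur; cur <- q }
  }
  runs[[length(runs) + 1L]] <- cur
  lowest <- runs[[which.min(vapply(runs, function(r) r[1], integer(1)))]]
  max(lowest) + 1L
}

# Wrap a mean-normalized-Gini vector (percents 1..100) as a curve object.
fake_curve <- function(g, total_reads = 10000L, sample_id = "synthetic") {
  structure(list(sample_id = sample_id, total_reads = total_reads,
                 gini_full = 0.5, shannon_full = 10, degenerate = FALSE,
                 curve = data.frame(percent = 1:100,
                                    depth = pmax(1L, round(1:100 / 100 * total_reads)),
                                    mean_norm_gini = g,
                                    se_norm_gini = 0,
                                    mean_norm_shannon = g,
                                    se_norm_shannon = 0)),
            class = "rarefaction_curve")
}

# Exhaustive cohort-depth search over every integer depth in range.
cohort_depth_oracle <- function(lo, hi) {
  best_n <- -1L; best_d <- NA_integer_
  for (d in seq(min(lo), max(hi))) {
    nn <- sum(lo <= d & d <= hi)
    if (nn > best_n || (nn == best_n && d > best_d)) {
      best_n <- nn; best_d <- d
    }
  }
  list(depth = best_d, n = best_n)
}

fake_mindepth <- function(id, lo, hi) {
  structure(list(sample_id = id, total_reads = as.integer(hi),
                 qualifying_percents = integer(0), runs = list(),
                 selected_run = integer(0), min_percent = 1L,
                 min_depth_reads = as.integer(lo)),
            class = "min_depth_result")
}

# Random mean-normalized-Gini curves: positive increments so the curve
# declines toward low depth, scattered above/below the gradient threshold.
random_gini_curve <- function() {
  inc <- stats::runif(99, 0, 0.025)
  flat <- stats::runif(99) < 0.4
  inc[flat] <- stats::runif(sum(flat), 0, 0.010)
  g <- c(0, cumsum(inc))
  g / max(g)
}

# Distinct in-frame junction of a given nt length (multiple of 3, >= 9):
# C flank + indexed middle codons + F flank.
junction_len <- function(len_nt, i) {
  stopifnot(len_nt %% 3 == 0, len_nt >= 9)
  m <- len_nt / 3 - 2
  idx <- i - 1
  mids <- character(m)
  for (k in seq_len(m)) {
    mids[k] <- codons61[(idx %% 61) + 1]
    idx <- idx %/% 61
  }
  paste0("TGC", paste(mids, collapse = ""), "TTC")
}

# Sample with prescribed junction lengths, counts and V calls.
spectra_sample <- function(lengths_nt, counts, v_call = NULL, ...) {
  n <- length(lengths_nt)
  if (is.null(v_call)) v_call <- rep("TRBV5-1*01", n)
  cl <- data.frame(
    v_call = v_call, j_call = rep("TRBJ2-1*01", n),
    cdr3_nt = vapply(seq_len(n), function(i) junction_len(lengths_nt[i], i),
                     character(1)),
    count = counts, stringsAsFactors = FALSE)
  repertoire_sample(cl, ...)
}
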