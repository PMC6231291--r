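# Synthetic repertoire generator: clone-size distributions spanning the
# control-cord to post-transplant clonally-expanded range, per-family CDR3
# length models (Gaussian vs spiked), and longitudinal reconstitution
# series with persistent expanded clones.

.trbv_families <- paste0("TRBV", c(2, 4, 5, 6, 7, 9, 10, 11, 12, 13, 14, 15,
                                   18, 19, 20, 24, 25, 27, 28, 29, 30))
.trbj_genes <- c(paste0("TRBJ1-", 1:6), paste0("TRBJ2-", 1:7))

# Sense-strand codons excluding stops; first/last codon fixed to the
# conserved Cys...Phe junction flanks.
.codons <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

#' CDR3-length models for the simulator
#'
#' `normal_profile()` draws in-frame junction lengths from a Gaussian over
#' codon counts (nt length = 3 x codons), the shape of a polyclonal
#' "Normal" spectratype family; `spike_profile()` concentrates mass on a
#' few fixed lengths, the oligoclonal "Abnormal" shape.
#'
#' @param mean_nt mean junction length in nucleotides (multiple of 3 for
#'   in-frame sequences; default 45 nt = 15 aa).
#' @param sd_nt standard deviation in nucleotides.
#' @param lengths,weights spike positions (nt, multiples of 3) and their
#'   probabilities.
#' @return length-model specification used in [simulation_params()].
#' @export
normal_profile <- function(mean_nt = 45, sd_nt = 6) {
  if (mean_nt %% 3 != 0)
    stop("mean_nt must be a multiple of 3 for in-frame junctions",
         call. = FALSE)
  structure(list(kind = "normal", mean_nt = mean_nt, sd_nt = sd_nt),
            class = "cdr3_length_model")
}

#' @rdname normal_profile
#' @export
spike_profile <- function(lengths, weights = NULL) {
  if (any(lengths %% 3 != 0))
    stop("spike lengths must be multiples of 3 for in-frame junctions",
         call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / length(lengths), length(lengths))
  if (length(weights) != length(lengths) || any(weights < 0))
    stop("weights must be non-negative, one per length", call. = FALSE)
  structure(list(kind = "spike", lengths = as.integer(lengths),
                 weights = weights / sum(weights)),
            class = "cdr3_length_model")
}

#' Parameters for simulating a single repertoire
#'
#' The generator draws expected clone sizes for `baseline_richness`
#' baseline clones from `baseline_distribution`, adds `n_expanded`
#' expanded clones holding fixed repertoire fractions
#' (`expansion_fractions`), then samples `total_reads` reads multinomially
#' over the expected frequencies, so counts sum to `total_reads` exactly.
#' Each clone gets a V gene family and J gene from the weight vectors and
#' a random in-frame CDR3 (conserved C...F flanks, no stop codons) whose
#' length follows the family's length model.
#'
#' The defaults emulate a control-cord beta-chain repertoire: a large
#' polyclonal baseline with near-even clone sizes (geometric with success
#' probability 0.9, closed-form Gini (1-q)/(2-q) ~ 0.09 before sampling
#' noise) and no clonal expansions. At the default depth the *observed*
#' count Gini also carries multinomial noise of roughly 1/sqrt(pi *
#' reads-per-clone), so these defaults land near Gini 0.18 and Shannon
#' 12.5 bits — inside the control-cord band (Gini below 0.2, Shannon
#' above 12 bits). Post-transplant oligoclonal repertoires are obtained
#' by adding expanded clones and/or spiked length models.
#'
#' @param baseline_richness number of baseline clones.
#' @param baseline_distribution `list(kind = "geometric", prob = q)` or
#'   `list(kind = "lognormal", meanlog = m, sdlog = s)` over expected
#'   clone sizes (`sdlog = 0` gives an equal-abundance baseline).
#' @param n_expanded number of expanded clones.
#' @param expansion_fractions repertoire fraction per expanded clone,
#'   summing to < 1; recycled to `n_expanded`.
#' @param v_family_weights named probability vector over TRBV family
#'   labels (default uniform over 21 families).
#' @param j_weights named probability vector over TRBJ genes (default
#'   uniform over the 13 genes).
#' @param cdr3_length_model a single [normal_profile()] / [spike_profile()]
#'   applied to every family, or a named list keyed by family.
#' @param total_reads reads to draw (default 1.5e5).
#' @param seed integer seed; identical params + seed give an identical
#'   table.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(baseline_richness = 6000L,
                              baseline_distribution = list(kind = "geometric",
                                                           prob = 0.9),
                              n_expanded = 0L,
                              expansion_fractions = numeric(0),
                              v_family_weights = NULL,
                              j_weights = NULL,
                              cdr3_length_model = normal_profile(),
                              total_reads = 150000L,
                              seed = 1L) {
  if (!is_count_scalar(baseline_richness))
    stop("baseline_richness must be a positive integer", call. = FALSE)
  if (!is.list(baseline_distribution) ||
      !baseline_distribution$kind %in% c("geometric", "lognormal"))
    stop("baseline_distribution must be geometric or lognormal",
         call. = FALSE)
  n_expanded <- as.integer(n_expanded)
  if (n_expanded > 0L) {
    expansion_fractions <- rep_len(expansion_fractions, n_expanded)
    if (any(expansion_fractions <= 0) || sum(expansion_fractions) >= 1)
      stop("expansion_fractions must be in (0,1) and sum to < 1",
           call. = FALSE)
  } else {
    expansion_fractions <- numeric(0)
  }
  if (is.null(v_family_weights))
    v_family_weights <- stats::setNames(
      rep(1 / length(.trbv_families), length(.trbv_families)),
      .trbv_families)
  if (is.null(j_weights))
    j_weights <- stats::setNames(
      rep(1 / length(.trbj_genes), length(.trbj_genes)), .trbj_genes)
  for (w in list(v_family_weights, j_weights))
    if (is.null(names(w)) || abs(sum(w) - 1) > 1e-9 || any(w < 0))
      stop("gene weights must be named, non-negative, summing to 1",
           call. = FALSE)
  if (inherits(cdr3_length_model, "cdr3_length_model"))
    cdr3_length_model <- stats::setNames(
      rep(list(cdr3_length_model), length(v_family_weights)),
      names(v_family_weights))
  if (!is_count_scalar(total_reads))
    stop("total_reads must be a positive integer", call. = FALSE)
  structure(list(baseline_richness = as.integer(baseline_richness),
                 baseline_distribution = baseline_distribution,
                 n_expanded = n_expanded,
                 expansion_fractions = expansion_fractions,
                 v_family_weights = v_family_weights,
                 j_weights = j_weights,
                 cdr3_length_model = cdr3_length_model,
                 total_reads = as.integer(total_reads),
                 seed = as.integer(seed)),
            class = "simulation_params")
}

# Draw n random in-frame CDR3 nt sequences with C...F flanks and lengths
# (in codons) from the given per-clone codon counts.
random_cdr3 <- function(n_codons) {
  n_mid <- pmax(n_codons - 2L, 0L)
  mids <- sample(.codons, sum(n_mid), replace = TRUE)
  grp <- rep.int(seq_along(n_mid), n_mid)
  mid_str <- character(length(n_mid))
  if (length(mids)) {
    agg <- vapply(split(mids, factor(grp, levels = seq_along(n_mid))),
                  paste0, character(1), collapse = "")
    mid_str <- as.character(agg)
  }
  paste0("TGC", mid_str, "TTC")
}

draw_lengths <- function(model, n) {
  if (model$kind == "normal") {
    codons <- round(stats::rnorm(n, model$mean_nt / 3, model$sd_nt / 3))
    pmin(pmax(codons, 4L), 35L)
  } else {
    model$lengths[sample.int(length(model$lengths), n, replace = TRUE,
                             prob = model$weights)] / 3L
  }
}

#' Simulate a repertoire sample
#'
#' See [simulation_params()] for the generative model. Deterministic under
#' `params$seed`; the caller's RNG state is untouched.
#'
#' @param params a [simulation_params()].
#' @param sample_id,patient_id,month_post_tx,group metadata for the
#'   returned sample.
#' @param expanded_identities optional data.frame (`v_call`, `j_call`,
#'   `cdr3_nt`, `cdr3_aa`) fixing the identities of the first expanded
#'   clones — used by [simulate_reconstitution_series()] to carry
#'   persistent clones between timepoints.
#' @return a validated [repertoire_sample()]; attribute `truth` records
#'   the expanded-clone identities and fractions.
#' @export
simulate_repertoire <- function(params, sample_id = "sim",
                                patient_id = NA_character_,
                                month_post_tx = NA_real_,
                                group = "patient",
                                expanded_identities = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, {
    nb <- params$baseline_richness
    ne <- params$n_expanded
    bd <- params$baseline_distribution
    sizes <- switch(bd$kind,
      geometric = stats::rgeom(nb, prob = bd$prob) + 1,
      lognormal = stats::rlnorm(nb, meanlog = bd$meanlog, sdlog = bd$sdlog))
    exp_mass <- sum(params$expansion_fractions)
    freq <- c(sizes / sum(sizes) * (1 - exp_mass), params$expansion_fractions)

    n <- nb + ne
    fams <- sample(names(params$v_family_weights), n, replace = TRUE,
                   prob = params$v_family_weights)
    # concrete gene-level call within the family, so family extraction is
    # exercised downstream
    v_call <- paste0(fams, "-1*01")
    j_call <- sample(names(params$j_weights), n, replace = TRUE,
                     prob = params$j_weights)
    codons <- integer(n)
    for (f in unique(fams)) {
      sel <- fams == f
      model <- params$cdr3_length_model[[f]]
      if (is.null(model)) model <- normal_profile()
      codons[sel] <- draw_lengths(model, sum(sel))
    }
    cdr3_nt <- random_cdr3(codons)
    if (!is.null(expanded_identities) && ne > 0L) {
      m <- min(nrow(expanded_identities), ne)
      idx <- nb + seq_len(m)
      v_call[idx] <- expanded_identities$v_call[seq_len(m)]
      j_call[idx] <- expanded_identities$j_call[seq_len(m)]
      cdr3_nt[idx] <- expanded_identities$cdr3_nt[seq_len(m)]
    }
    # regenerate any colliding keys so clonotypes are distinct by
    # construction; injected expanded identities are never rewritten
    protected <- rep(FALSE, n)
    if (!is.null(expanded_identities) && ne > 0L)
      protected[nb + seq_len(min(nrow(expanded_identities), ne))] <- TRUE
    repeat {
      key <- paste(v_call, j_call, cdr3_nt, sep = "\r")
      ord <- order(!protected, seq_len(n))   # keep protected copy of a key
      regen <- ord[duplicated(key[ord])]
      regen <- regen[!protected[regen]]
      if (!length(regen)) break
      cdr3_nt[regen] <- random_cdr3(codons[regen])
    }
    counts <- as.integer(stats::rmultinom(1, params$total_reads, freq))
    keep <- counts > 0L
    cl <- data.frame(v_call = v_call[keep], j_call = j_call[keep],
                     cdr3_nt = cdr3_nt[keep],
                     cdr3_aa = translate_junction(cdr3_nt[keep]),
                     count = counts[keep], stringsAsFactors = FALSE)
    truth <- data.frame(v_call = v_call, j_call = j_call, cdr3_nt = cdr3_nt,
                        expanded = seq_len(n) > nb,
                        expected_fraction = freq,
                        stringsAsFactors = FALSE)[seq_len(n) > nb, ,
                                                  drop = FALSE]
    out <- repertoire_sample(cl, sample_id = sample_id,
                             patient_id = patient_id,
                             month_post_tx = month_post_tx, group = group,
                             check_translation = FALSE)
    attr(out, "truth") <- truth
    out
  })
}

#' Calibrate expansion mass to a target Gini coefficient
#'
#' Monotone bisection over the total expanded-clone mass: larger expansion
#' mass gives a more unequal repertoire. Each candidate mass is scored by
#' the mean observed Gini of `n_seeds` simulated repertoires. Multinomial
#' sampling noise sets a Gini floor even with zero expansion; a target at
#' or below the floor returns zero expansion mass when the floor is within
#' `tol` of the target and errors (reporting the achievable bracket)
#' otherwise.
#'
#' @param target_gini target in `[0, 0.9]`.
#' @param template a [simulation_params()]; its `n_expanded` (or 10 when
#'   zero) expanded clones receive equal shares of the searched mass.
#' @param tol acceptable |mean Gini - target| (default 0.05).
#' @param n_seeds simulations averaged per candidate (default 10).
#' @param max_iter bisection iterations (default 12).
#' @return calibrated [simulation_params()] with attributes
#'   `achieved_gini` and `expansion_mass`.
#' @export
calibrate_to_target_gini <- function(target_gini, template,
                                     tol = 0.05, n_seeds = 10L,
                                     max_iter = 12L) {
  stopifnot(inherits(template, "simulation_params"))
  if (!is.numeric(target_gini) || target_gini < 0 || target_gini > 0.9)
    stop("target_gini must be in [0, 0.9]", call. = FALSE)
  ne <- if (template$n_expanded > 0L) template$n_expanded else 10L
  mass_max <- 0.95
  params_at <- function(mass) {
    p <- template
    if (mass <= 0) {
      p$n_expanded <- 0L
      p$expansion_fractions <- numeric(0)
    } else {
      p$n_expanded <- ne
      p$expansion_fractions <- rep(mass / ne, ne)
    }
    p
  }
  mean_gini <- function(mass) {
    p <- params_at(mass)
    mean(vapply(seq_len(n_seeds), function(s) {
      p$seed <- derive_seed(template$seed, s)
      smp <- simulate_repertoire(p)
      as.numeric(gini_coefficient(smp$clonotypes$count))
    }, numeric(1)))
  }
  g_lo <- mean_gini(0)
  if (target_gini <= g_lo) {
    if (g_lo - target_gini <= tol) {
      out <- params_at(0)
      attr(out, "achieved_gini") <- g_lo
      attr(out, "expansion_mass") <- 0
      return(out)
    }
    stop(sprintf(paste0("target Gini %.3f unreachable: sampling-noise floor ",
                        "of this template is %.3f"), target_gini, g_lo),
         call. = FALSE)
  }
  g_hi <- mean_gini(mass_max)
  if (target_gini > g_hi + tol)
    stop(sprintf(paste0("target Gini %.3f unreachable: achievable range of ",
                        "this template is [%.3f, %.3f]"),
         target_gini, g_lo, g_hi), call. = FALSE)
  lo <- 0; hi <- mass_max
  g_mid <- g_hi; mid <- mass_max
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    g_mid <- mean_gini(mid)
    if (abs(g_mid - target_gini) <= tol / 2) break
    if (g_mid < target_gini) lo <- mid else hi <- mid
  }
  out <- params_at(mid)
  attr(out, "achieved_gini") <- g_mid
  attr(out, "expansion_mass") <- mid
  out
}

#' Parameters for a longitudinal reconstitution series
#'
#' @param months strictly increasing sampling months (at least 2).
#' @param initial [simulation_params()] at the first month (typically
#'   oligoclonal: low richness, high expansion mass).
#' @param final [simulation_params()] at the last month (diverse).
#' @param persistence_fraction probability that an expanded clone at one
#'   timepoint is carried (same V/J/CDR3 identity) to the next.
#' @param seed master seed for the series.
#' @return object of class `reconstitution_params`.
#' @export
reconstitution_params <- function(months, initial, final,
                                  persistence_fraction = 0.5, seed = 1L) {
  months <- as.numeric(months)
  if (length(months) < 2L || any(diff(months) <= 0))
    stop("months must be >= 2 strictly increasing values", call. = FALSE)
  stopifnot(inherits(initial, "simulation_params"),
            inherits(final, "simulation_params"))
  if (persistence_fraction < 0 || persistence_fraction > 1)
    stop("persistence_fraction must be in [0, 1]", call. = FALSE)
  structure(list(months = months, initial = initial, final = final,
                 persistence_fraction = persistence_fraction,
                 seed = as.integer(seed)),
            class = "reconstitution_params")
}

#' Simulate a longitudinal reconstitution series
#'
#' One sample per month. Baseline richness and total expansion mass follow
#' a monotone linear schedule from the initial (oligoclonal) to the final
#' (diverse) parameters, emulating the post-transplant trend toward
#' normality; the number of expanded clones stays at the initial value
#' while their fractions shrink. Each expanded clone is carried to the
#' next month with probability `persistence_fraction` (identical
#' V/J/CDR3), otherwise replaced by a fresh clone, giving ground truth for
#' persistence-tracking tests.
#'
#' @param params a [reconstitution_params()].
#' @param patient_id patient identifier stamped on every sample.
#' @return list of [repertoire_sample()], one per month, ordered by month;
#'   attribute `truth` is a data.frame of expanded-clone identities per
#'   month with a `carried` flag.
#' @export
simulate_reconstitution_series <- function(params, patient_id = "P1") {
  stopifnot(inherits(params, "reconstitution_params"))
  months <- params$months
  tt <- length(months)
  ne <- max(params$initial$n_expanded, 1L)
  mass_ini <- sum(params$initial$expansion_fractions)
  mass_fin <- sum(params$final$expansion_fractions)
  rich_ini <- params$initial$baseline_richness
  rich_fin <- params$final$baseline_richness

  samples <- vector("list", tt)
  truth <- list()
  prev_ids <- NULL
  for (k in seq_len(tt)) {
    w <- (k - 1) / (tt - 1)
    mass_k <- mass_ini * (1 - w) + mass_fin * w
    rich_k <- as.integer(round(rich_ini * (1 - w) + rich_fin * w))
    p <- params$initial
    p$baseline_richness <- rich_k
    if (mass_k > 0) {
      p$n_expanded <- ne
      p$expansion_fractions <- rep(mass_k / ne, ne)
    } else {
      p$n_expanded <- 0L
      p$expansion_fractions <- numeric(0)
    }
    p$seed <- derive_seed(params$seed, k)

    carried <- rep(FALSE, if (mass_k > 0) ne else 0L)
    ident <- NULL
    if (!is.null(prev_ids) && mass_k > 0) {
      carried <- with_seed(derive_seed(params$seed, k, 777L),
                           stats::runif(ne) < params$persistence_fraction)
      ident <- prev_ids
      # non-carried slots get fresh identities inside the simulator
      ident[!carried, c("v_call", "j_call", "cdr3_nt")] <- NA
      ident <- ident[carried, , drop = FALSE]
      if (!nrow(ident)) ident <- NULL
    }
    smp <- simulate_repertoire(
      p, sample_id = sprintf("%s_m%g", patient_id, months[k]),
      patient_id = patient_id, month_post_tx = months[k],
      expanded_identities = ident
    )
    tr <- attr(smp, "truth")
    if (nrow(tr)) {
      tr$month <- months[k]
      tr$carried <- FALSE
      if (!is.null(ident) && nrow(ident))
        tr$carried[seq_len(nrow(ident))] <- TRUE
      truth[[k]] <- tr
    }
    prev_ids <- tr[, c("v_call", "j_call", "cdr3_nt"), drop = FALSE]
    if (!nrow(prev_ids)) prev_ids <- NULL
    samples[[k]] <- smp
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else NULL
  attr(samples, "truth") <- truth_df
  samples
}
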