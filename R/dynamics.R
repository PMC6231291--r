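# Longitudinal clonotype tracking and VDJdb-based antigen annotation.

#' Most abundant clonotypes of a sample
#'
#' Sorted by count descending; ties broken deterministically by
#' `(cdr3_nt, v_call, j_call)` lexicographic ascending.
#'
#' @param sample a [repertoire_sample()].
#' @param n maximum number of clonotypes to return (default 20).
#' @return data.frame with columns `v_call`, `j_call`, `cdr3_nt`,
#'   `cdr3_aa`, `count`, `frequency`, at most `n` rows.
#' @export
top_clonotypes <- function(sample, n = 20L) {
  stopifnot(inherits(sample, "repertoire_sample"))
  if (!is_count_scalar(n)) stop("`n` must be a positive integer",
                                call. = FALSE)
  cl <- sample$clonotypes
  ord <- order(-cl$count, cl$cdr3_nt, cl$v_call, cl$j_call, method = "radix")
  take <- ord[seq_len(min(as.integer(n), nrow(cl)))]
  out <- cl[take, c("v_call", "j_call", "cdr3_nt", "cdr3_aa", "count"),
            drop = FALSE]
  out$frequency <- out$count / sample$total_reads
  rownames(out) <- NULL
  out
}

clonotype_key <- function(df) {
  paste(df$v_call, df$j_call, df$cdr3_nt, sep = "\r")
}

#' Track abundant clonotypes across a patient's longitudinal samples
#'
#' Takes the union of each timepoint's top-`n` clonotypes (by exact
#' nucleotide identity) and reports every tracked clonotype's frequency at
#' every timepoint where it is detected at all — including timepoints
#' where it sits outside the top `n`. A clonotype detected at two or more
#' timepoints is flagged persistent. Input order is irrelevant: samples
#' are ordered by `month_post_tx`.
#'
#' @param samples list of [repertoire_sample()] for one patient and chain,
#'   with distinct `month_post_tx`.
#' @param n per-timepoint top-clonotype cutoff (default 20).
#' @return object of class `clonotype_trajectories`: long-format
#'   data.frame with columns `v_call`, `j_call`, `cdr3_nt`, `month`,
#'   `frequency`, `persistent`; one row per (tracked clonotype, timepoint
#'   detected).
#' @export
track_clonotypes <- function(samples, n = 20L) {
  if (inherits(samples, "repertoire_sample")) samples <- list(samples)
  if (length(samples) < 2L)
    stop("need at least 2 timepoints to track clonotypes", call. = FALSE)
  ok <- vapply(samples, inherits, logical(1), "repertoire_sample")
  if (!all(ok)) stop("`samples` must be repertoire_sample objects",
                     call. = FALSE)
  patients <- unique(vapply(samples, `[[`, character(1), "patient_id"))
  chains <- unique(vapply(samples, `[[`, character(1), "chain"))
  if (length(patients) != 1L)
    stop("samples span multiple patients: ",
         paste(patients, collapse = ", "), call. = FALSE)
  if (length(chains) != 1L)
    stop("samples span multiple chains: ",
         paste(chains, collapse = ", "), call. = FALSE)
  months <- vapply(samples, `[[`, numeric(1), "month_post_tx")
  if (anyNA(months) || anyDuplicated(months))
    stop("samples must have distinct, non-missing month_post_tx",
         call. = FALSE)
  samples <- samples[order(months)]
  months <- sort(months)

  tracked <- unique(unlist(lapply(samples, function(s)
    clonotype_key(top_clonotypes(s, n = n)))))
  rows <- list()
  for (k in seq_along(samples)) {
    cl <- samples[[k]]$clonotypes
    key <- clonotype_key(cl)
    hit <- match(tracked, key)
    det <- !is.na(hit)
    if (!any(det)) next
    rows[[k]] <- data.frame(
      v_call = cl$v_call[hit[det]],
      j_call = cl$j_call[hit[det]],
      cdr3_nt = cl$cdr3_nt[hit[det]],
      month = months[k],
      frequency = cl$count[hit[det]] / samples[[k]]$total_reads,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  key <- paste(out$v_call, out$j_call, out$cdr3_nt, sep = "\r")
  n_points <- table(key)
  out$persistent <- as.integer(n_points[key]) >= 2L
  out <- out[order(key, out$month, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("clonotype_trajectories", "data.frame")
  out
}

#' Annotate a repertoire against a VDJdb-format table
#'
#' Matches each in-frame clonotype's amino-acid CDR3 exactly against the
#' database. Under policy `"cdr3_aa+v"` (default) the V gene families
#' must also agree ([gene_family()] of both calls; database records
#' without a V call cannot match). Policy `"cdr3_aa"` matches on the
#' CDR3 alone — more permissive, and the mode in which spurious "public"
#' annotations (e.g. HIV-1 hits in seronegative patients) surface.
#'
#' Per species, the antigen binding potential is the summed read
#' frequency of the distinct clonotypes matching that species — each
#' clonotype counted once per species however many epitopes it hits; a
#' clonotype matching several species contributes its full frequency to
#' each, so potentials are bounded by 1 per species but do not sum to 1
#' across species.
#'
#' @param sample a [repertoire_sample()] whose clonotypes carry `cdr3_aa`.
#' @param db data.frame from [read_vdjdb_table()].
#' @param match_policy `"cdr3_aa+v"` or `"cdr3_aa"`.
#' @return object of class `annotation_result`: list with `hits`
#'   (data.frame: clonotype key columns, `frequency`, `epitope`,
#'   `antigen_species`, `match_level`), `binding_potential` (named
#'   numeric per species), `n_skipped` (clonotypes without `cdr3_aa`).
#' @export
annotate_vdjdb <- function(sample, db,
                           match_policy = c("cdr3_aa+v", "cdr3_aa")) {
  stopifnot(inherits(sample, "repertoire_sample"))
  match_policy <- match.arg(match_policy)
  if (!is.data.frame(db) || nrow(db) == 0L)
    stop("empty annotation database", call. = FALSE)
  cl <- sample$clonotypes
  skipped <- is.na(cl$cdr3_aa)
  if (any(skipped))
    message(sum(skipped),
            " clonotype(s) without amino-acid CDR3 skipped in annotation")
  cl <- cl[!skipped, , drop = FALSE]

  hits <- data.frame(v_call = character(0), j_call = character(0),
                     cdr3_nt = character(0), cdr3_aa = character(0),
                     frequency = numeric(0), epitope = character(0),
                     antigen_species = character(0),
                     match_level = character(0), stringsAsFactors = FALSE)
  if (nrow(cl)) {
    cl_idx <- data.frame(cdr3_aa = cl$cdr3_aa, .ci = seq_len(nrow(cl)),
                         stringsAsFactors = FALSE)
    db_idx <- data.frame(cdr3_aa = db$cdr3_aa, .di = seq_len(nrow(db)),
                         stringsAsFactors = FALSE)
    joined <- merge(cl_idx, db_idx, by = "cdr3_aa")
    if (nrow(joined)) {
      ci <- joined$.ci; di <- joined$.di
      if (match_policy == "cdr3_aa+v") {
        fam_cl <- gene_family(cl$v_call[ci])
        fam_db <- gene_family(db$v_call[di])
        keep <- !is.na(fam_db) & !is.na(fam_cl) & fam_cl == fam_db
        ci <- ci[keep]; di <- di[keep]
      }
      if (length(ci)) {
        hits <- data.frame(
          v_call = cl$v_call[ci], j_call = cl$j_call[ci],
          cdr3_nt = cl$cdr3_nt[ci], cdr3_aa = cl$cdr3_aa[ci],
          frequency = cl$count[ci] / sample$total_reads,
          epitope = db$epitope[di],
          antigen_species = db$antigen_species[di],
          match_level = match_policy, stringsAsFactors = FALSE
        )
        ord <- order(-hits$frequency, hits$antigen_species, hits$cdr3_aa,
                     method = "radix")
        hits <- hits[ord, , drop = FALSE]
        rownames(hits) <- NULL
      }
    }
  }
  potential <- numeric(0)
  if (nrow(hits)) {
    key <- paste(hits$v_call, hits$j_call, hits$cdr3_nt, sep = "\r")
    once <- !duplicated(paste(key, hits$antigen_species, sep = "\r"))
    potential <- vapply(split(hits$frequency[once],
                              hits$antigen_species[once]), sum, numeric(1))
    potential <- potential[order(names(potential))]
  }
  structure(
    list(sample_id = sample$sample_id, hits = hits,
         binding_potential = potential,
         n_skipped = as.integer(sum(skipped)),
         match_policy = match_policy),
    class = "annotation_result"
  )
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("<annotation_result> ", x$sample_id, " (policy ", x$match_policy,
      "): ", nrow(x$hits), " hit(s)",
      if (x$n_skipped) paste0(", ", x$n_skipped, " clonotype(s) skipped"),
      "\n", sep = "")
  for (sp in names(x$binding_potential))
    cat(sprintf("  %s: binding potential %.4f (%.2f%% of reads)\n",
                sp, x$binding_potential[[sp]],
                100 * x$binding_potential[[sp]]))
  invisible(x)
}
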