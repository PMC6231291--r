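#' Construct a validated repertoire sample
#'
#' A repertoire sample is a table of UMI-corrected clonotypes plus sample
#' metadata. A clonotype is a unique rearrangement keyed by
#' `(v_call, j_call, cdr3_nt)` (plus V/J deletion counts when the input
#' dialect carries them) with a positive integer abundance `count` — one
#' count per UMI-corrected read. Duplicate keys are merged by summing
#' counts; zero-count rows are dropped with a warning; negative or
#' non-integer counts are an error.
#'
#' @param clonotypes data.frame with columns `v_call`, `j_call`, `cdr3_nt`,
#'   `count`, optionally `cdr3_aa` (NA where out of frame), `v_del`,
#'   `j_del`.
#' @param sample_id,patient_id sample and patient identifiers.
#' @param month_post_tx months after transplant (`NA` for controls).
#' @param chain `"beta"` (default) or `"alpha"`.
#' @param group `"patient"`, `"control_cord"` or `"control_adult"`.
#' @param spectratype_class optional clinical spectratype label
#'   (`"Abnormal"`, `"Almost_normal"`, `"Normal"`).
#' @param gvhd_grade optional integer 0-4.
#' @param check_translation verify that `cdr3_aa`, where present on an
#'   in-frame junction, equals the translation of `cdr3_nt`.
#' @return object of class `repertoire_sample`: list with the validated
#'   clonotype data.frame (`$clonotypes`), `$total_reads` and the metadata
#'   fields.
#' @seealso [read_clonotype_table()], [diversity_summary()]
#' @export
repertoire_sample <- function(clonotypes,
                              sample_id = "sample",
                              patient_id = NA_character_,
                              month_post_tx = NA_real_,
                              chain = c("beta", "alpha"),
                              group = c("patient", "control_cord", "control_adult"),
                              spectratype_class = NA_character_,
                              gvhd_grade = NA_integer_,
                              check_translation = TRUE) {
  chain <- match.arg(chain)
  group <- match.arg(group)
  if (!is.data.frame(clonotypes))
    stop("`clonotypes` must be a data.frame", call. = FALSE)
  required <- c("v_call", "j_call", "cdr3_nt", "count")
  missing_cols <- setdiff(required, names(clonotypes))
  if (length(missing_cols))
    stop("clonotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(clonotypes) == 0L)
    stop("no clonotypes: table is empty", call. = FALSE)

  cl <- data.frame(
    v_call  = as.character(clonotypes$v_call),
    j_call  = as.character(clonotypes$j_call),
    cdr3_nt = as.character(clonotypes$cdr3_nt),
    cdr3_aa = if ("cdr3_aa" %in% names(clonotypes))
      as.character(clonotypes$cdr3_aa) else NA_character_,
    v_del   = if ("v_del" %in% names(clonotypes))
      as.integer(clonotypes$v_del) else NA_integer_,
    j_del   = if ("j_del" %in% names(clonotypes))
      as.integer(clonotypes$j_del) else NA_integer_,
    count   = clonotypes$count,
    stringsAsFactors = FALSE
  )
  cl$cdr3_aa[!is.na(cl$cdr3_aa) & !nzchar(cl$cdr3_aa)] <- NA_character_

  if (any(is.na(cl$cdr3_nt) | !nzchar(cl$cdr3_nt)))
    stop("empty cdr3_nt in row(s): ",
         paste(which(is.na(cl$cdr3_nt) | !nzchar(cl$cdr3_nt)), collapse = ", "),
         call. = FALSE)
  bad <- !is.finite(cl$count) | cl$count < 0 | cl$count != floor(cl$count)
  if (any(bad))
    stop("non-integer or negative count in row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  zero <- cl$count == 0
  if (any(zero)) {
    warning(sum(zero), " zero-count row(s) dropped", call. = FALSE)
    cl <- cl[!zero, , drop = FALSE]
  }
  if (nrow(cl) == 0L)
    stop("no clonotypes: all rows had zero counts", call. = FALSE)
  cl$count <- as.integer(cl$count)

  if (check_translation) {
    inframe <- !is.na(cl$cdr3_aa) & nchar(cl$cdr3_nt) %% 3L == 0L
    if (any(inframe)) {
      expect <- translate_junction(cl$cdr3_nt[inframe])
      mism <- which(expect != cl$cdr3_aa[inframe])
      if (length(mism))
        stop("cdr3_aa does not match translation of cdr3_nt in row(s): ",
             paste(which(inframe)[mism], collapse = ", "), call. = FALSE)
    }
  }

  # merge duplicate clonotype keys (deletions are part of the key where set)
  key <- paste(cl$v_call, cl$j_call, cl$cdr3_nt,
               ifelse(is.na(cl$v_del), "", cl$v_del),
               ifelse(is.na(cl$j_del), "", cl$j_del), sep = "\r")
  if (anyDuplicated(key)) {
    counts <- vapply(split(cl$count, key), sum, numeric(1))
    first <- !duplicated(key)
    cl <- cl[first, , drop = FALSE]
    cl$count <- as.integer(counts[key[first]])
  }
  ord <- order(cl$v_call, cl$j_call, cl$cdr3_nt, method = "radix")
  cl <- cl[ord, , drop = FALSE]
  rownames(cl) <- NULL

  structure(
    list(
      sample_id = as.character(sample_id),
      patient_id = as.character(patient_id),
      month_post_tx = as.numeric(month_post_tx),
      chain = chain,
      group = group,
      spectratype_class = as.character(spectratype_class),
      gvhd_grade = as.integer(gvhd_grade),
      clonotypes = cl,
      total_reads = sum(cl$count)
    ),
    class = "repertoire_sample"
  )
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat("<repertoire_sample> ", x$sample_id,
      if (!is.na(x$patient_id)) paste0(" (patient ", x$patient_id, ")"), "\n",
      sep = "")
  cat("  chain: ", x$chain, "   group: ", x$group,
      if (!is.na(x$month_post_tx))
        paste0("   month post-Tx: ", x$month_post_tx), "\n", sep = "")
  cat("  clonotypes: ", nrow(x$clonotypes),
      "   total UMI-corrected reads: ", x$total_reads, "\n", sep = "")
  invisible(x)
}

#' Clonotype frequencies of a sample
#'
#' @param sample a `repertoire_sample`.
#' @return numeric vector `count / total_reads`, one entry per clonotype,
#'   summing to 1.
#' @export
clonotype_frequencies <- function(sample) {
  stopifnot(inherits(sample, "repertoire_sample"))
  sample$clonotypes$count / sample$total_reads
}
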