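# Readers and writers for the two clonotype-table dialects the pipeline
# consumes (AIRR rearrangement TSV; Decombinator-style frequency CSV) and
# for VDJdb-format annotation tables.

.airr_cols <- c("v_call", "j_call", "junction", "junction_aa", "duplicate_count")

#' Read a clonotype abundance table
#'
#' Supported dialects:
#' \describe{
#'   \item{`airr`}{AIRR rearrangement TSV with at least the columns
#'     `v_call`, `j_call`, `junction` (nucleotide), `junction_aa`,
#'     `duplicate_count` (UMI-corrected abundance).}
#'   \item{`decombinator_freq`}{comma-separated five-field classifier
#'     output plus a count: V index or name, J index or name, number of V
#'     deletions, number of J deletions, insert sequence, count. An
#'     optional two-column `gene_map` table (index, IMGT name) resolves
#'     numeric tag indices to gene names; unresolved numeric indices are
#'     labelled `V<i>` / `J<i>`. This dialect does not carry the full
#'     junction sequence, so the insert is stored as `cdr3_nt` and the
#'     deletion counts join the clonotype identity key; amino-acid-level
#'     analyses (spectratype, database annotation) need junction-bearing
#'     input.}
#' }
#' Duplicate clonotype keys are merged by summing counts and zero-count
#' rows dropped with a warning (see [repertoire_sample()]).
#'
#' @param path input file.
#' @param dialect `"airr"` or `"decombinator_freq"`.
#' @param gene_map optional path to a tab- or comma-separated two-column
#'   file mapping Decombinator tag indices to gene names.
#' @param ... metadata fields passed to [repertoire_sample()]
#'   (`sample_id`, `patient_id`, `month_post_tx`, ...). `sample_id`
#'   defaults to the file name without extension.
#' @return a validated [repertoire_sample()].
#' @export
read_clonotype_table <- function(path,
                                 dialect = c("airr", "decombinator_freq"),
                                 gene_map = NULL, ...) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- list(...)
  if (is.null(meta$sample_id))
    meta$sample_id <- sub("\\.[^.]*$", "", basename(path))

  if (dialect == "airr") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE, na.strings = c("NA", ""))
    missing_cols <- setdiff(.airr_cols, names(tab))
    if (length(missing_cols))
      stop("AIRR table ", path, " lacks mandatory column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    if (nrow(tab) == 0L) stop("no clonotypes in ", path, call. = FALSE)
    cl <- data.frame(v_call = tab$v_call, j_call = tab$j_call,
                     cdr3_nt = tab$junction, cdr3_aa = tab$junction_aa,
                     count = tab$duplicate_count, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                           na.strings = character())
    if (ncol(tab) != 6L)
      stop("decombinator_freq table ", path, " must have 6 fields, found ",
           ncol(tab), call. = FALSE)
    if (nrow(tab) == 0L) stop("no clonotypes in ", path, call. = FALSE)
    names(tab) <- c("v", "j", "v_del", "j_del", "insert", "count")
    map <- NULL
    if (!is.null(gene_map)) {
      map <- utils::read.table(gene_map, header = FALSE, sep = "",
                               stringsAsFactors = FALSE,
                               col.names = c("index", "name"))
    }
    resolve <- function(idx, prefix) {
      idx <- trimws(as.character(idx))
      out <- idx
      numeric_like <- grepl("^[0-9]+$", idx)
      if (!is.null(map)) {
        hit <- match(idx, as.character(map$index))
        out[!is.na(hit)] <- map$name[hit[!is.na(hit)]]
        numeric_like <- numeric_like & is.na(hit)
      }
      out[numeric_like] <- paste0(prefix, idx[numeric_like])
      out
    }
    cl <- data.frame(v_call = resolve(tab$v, "V"),
                     j_call = resolve(tab$j, "J"),
                     cdr3_nt = trimws(tab$insert),
                     v_del = tab$v_del, j_del = tab$j_del,
                     count = tab$count, stringsAsFactors = FALSE)
  }
  do.call(repertoire_sample, c(list(clonotypes = cl), meta))
}

#' Write a clonotype abundance table
#'
#' Re-reading the written file reproduces the sample's clonotype multiset
#' and counts exactly. Absent amino-acid junctions are emitted as empty
#' fields; absent deletion counts as 0.
#'
#' @param sample a validated [repertoire_sample()].
#' @param path output file.
#' @param dialect `"airr"` or `"decombinator_freq"` (see
#'   [read_clonotype_table()]).
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(sample, path,
                                  dialect = c("airr", "decombinator_freq")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(sample, "repertoire_sample"))
  cl <- sample$clonotypes
  if (nrow(cl) == 0L) stop("refusing to write a sample with no clonotypes",
                           call. = FALSE)
  if (dialect == "airr") {
    out <- data.frame(
      v_call = cl$v_call, j_call = cl$j_call,
      junction = cl$cdr3_nt,
      junction_aa = ifelse(is.na(cl$cdr3_aa), "", cl$cdr3_aa),
      duplicate_count = cl$count, stringsAsFactors = FALSE
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    out <- data.frame(
      v = cl$v_call, j = cl$j_call,
      v_del = ifelse(is.na(cl$v_del), 0L, cl$v_del),
      j_del = ifelse(is.na(cl$j_del), 0L, cl$j_del),
      insert = cl$cdr3_nt, count = cl$count, stringsAsFactors = FALSE
    )
    utils::write.table(out, path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a VDJdb-format annotation table
#'
#' Expects a TSV with at least the columns `cdr3` and `antigen.species`;
#' `v.segm`, `j.segm` and `antigen.epitope` are used when present. Rows
#' with an empty CDR3 are dropped (with a message); duplicate CDR3s are
#' retained — the same sequence may be annotated to several epitopes or
#' species.
#'
#' @param path VDJdb export TSV.
#' @return data.frame with columns `cdr3_aa`, `v_call`, `j_call`,
#'   `epitope`, `antigen_species`.
#' @export
read_vdjdb_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("NA", ""))
  need <- c("cdr3", "antigen.species")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("VDJdb table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  grab <- function(col) if (col %in% names(tab))
    as.character(tab[[col]]) else rep(NA_character_, nrow(tab))
  db <- data.frame(
    cdr3_aa = as.character(tab$cdr3),
    v_call = grab("v.segm"),
    j_call = grab("j.segm"),
    epitope = grab("antigen.epitope"),
    antigen_species = as.character(tab$`antigen.species`),
    stringsAsFactors = FALSE
  )
  empty <- is.na(db$cdr3_aa) | !nzchar(db$cdr3_aa)
  if (any(empty)) {
    message(sum(empty), " VDJdb record(s) with empty CDR3 dropped")
    db <- db[!empty, , drop = FALSE]
  }
  bad_sp <- is.na(db$antigen_species) | !nzchar(db$antigen_species)
  if (any(bad_sp)) {
    message(sum(bad_sp), " VDJdb record(s) with empty antigen species dropped")
    db <- db[!bad_sp, , drop = FALSE]
  }
  rownames(db) <- NULL
  db
}
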