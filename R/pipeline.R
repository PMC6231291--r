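# One-command cohort analysis: per-sample rarefaction and minimum depth,
# cohort common depth, rarefied diversity, spectratypes, optional VDJdb
# annotation, per-patient trajectories, all written as TSV reports.

#' Cohort analysis configuration
#'
#' Samples come either from a manifest data.frame (`path`, `dialect` plus
#' metadata columns `sample_id`, `patient_id`, `month_post_tx`, `group`,
#' `spectratype_class`, `gvhd_grade`) or directly as a list of
#' [repertoire_sample()] objects.
#'
#' @param manifest data.frame describing input files (or `NULL`).
#' @param samples list of `repertoire_sample` (or `NULL`).
#' @param out_dir output directory for the TSV reports.
#' @param rarefaction a [rarefaction_config()]; its `master_seed` is
#'   overridden by `master_seed`.
#' @param spectra_thresholds a [spectratype_thresholds()].
#' @param vdjdb_path optional VDJdb-format TSV enabling annotation.
#' @param match_policy annotation policy, see [annotate_vdjdb()].
#' @param top_n top-clonotype cutoff for trajectories.
#' @param master_seed master seed for all subsampling.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(manifest = NULL, samples = NULL,
                          out_dir = ".",
                          rarefaction = rarefaction_config(),
                          spectra_thresholds = spectratype_thresholds(),
                          vdjdb_path = NULL,
                          match_policy = c("cdr3_aa+v", "cdr3_aa"),
                          top_n = 20L,
                          master_seed = 1L) {
  match_policy <- match.arg(match_policy)
  if (is.null(manifest) && is.null(samples))
    stop("provide a manifest or a list of samples", call. = FALSE)
  if (!is.null(manifest)) {
    if (!all(c("path", "dialect") %in% names(manifest)))
      stop("manifest needs columns `path` and `dialect`", call. = FALSE)
    missing_files <- manifest$path[!file.exists(manifest$path)]
    if (length(missing_files))
      stop("manifest path(s) not found: ",
           paste(missing_files, collapse = ", "), call. = FALSE)
  }
  rarefaction$master_seed <- as.integer(master_seed)
  structure(list(manifest = manifest, samples = samples, out_dir = out_dir,
                 rarefaction = rarefaction,
                 spectra_thresholds = spectra_thresholds,
                 vdjdb_path = vdjdb_path, match_policy = match_policy,
                 top_n = as.integer(top_n),
                 master_seed = as.integer(master_seed)),
            class = "cohort_config")
}

load_cohort_samples <- function(config) {
  samples <- config$samples
  if (!is.null(config$manifest)) {
    m <- config$manifest
    get_col <- function(col, default) if (col %in% names(m)) m[[col]]
      else rep(default, nrow(m))
    loaded <- lapply(seq_len(nrow(m)), function(i)
      read_clonotype_table(
        m$path[i], dialect = m$dialect[i],
        sample_id = get_col("sample_id", NA)[i],
        patient_id = get_col("patient_id", NA_character_)[i],
        month_post_tx = get_col("month_post_tx", NA_real_)[i],
        group = get_col("group", "patient")[i],
        spectratype_class = get_col("spectratype_class", NA_character_)[i],
        gvhd_grade = get_col("gvhd_grade", NA_integer_)[i]))
    samples <- c(samples, loaded)
  }
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  samples
}

#' Run the full cohort analysis
#'
#' Stages: (1) replicate rarefaction and minimum representative depth per
#' sample; (2) cohort common depth; (3) rarefaction of every included
#' sample to the common depth (samples whose total reads fall below it
#' are excluded and listed); (4) diversity summaries at the common depth;
#' (5) virtual spectratype profiles and classification (full depth);
#' (6) VDJdb annotation when a database is configured; (7) per-patient
#' clonotype trajectories for patients with two or more timepoints.
#' Per-sample failures (e.g. degenerate monoclonal samples) are recorded
#' and the remaining samples processed.
#'
#' Writes `diversity.tsv`, `mindepth.tsv`, `cohort_depth.tsv`,
#' `spectratype.tsv`, `trajectories.tsv`, `annotation.tsv` (when
#' configured) and `run.log` to `config$out_dir`; reruns with the same
#' configuration and seed produce byte-identical files.
#'
#' @param config a [cohort_config()].
#' @return invisibly, a list with the report data.frames (`diversity`,
#'   `mindepth`, `cohort_depth`, `spectratype`, `trajectories`,
#'   `annotation`), the per-sample `failures`, and `cohort` (the
#'   [cohort_common_depth()] result).
#' @export
run_cohort_analysis <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  samples <- load_cohort_samples(config)
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  failures <- list()
  note_failure <- function(id, stage, e) {
    failures[[length(failures) + 1L]] <<-
      data.frame(sample_id = id, stage = stage,
                 message = conditionMessage(e), stringsAsFactors = FALSE)
    NULL
  }

  # (1) rarefaction + min depth
  mindepths <- list()
  for (s in samples) {
    md <- tryCatch({
      curve <- rarefaction_curve(s, config$rarefaction)
      minimum_representative_depth(curve, config$rarefaction)
    }, error = function(e) note_failure(s$sample_id, "mindepth", e))
    if (!is.null(md)) mindepths[[s$sample_id]] <- md
  }
  if (!length(mindepths))
    stop("no sample produced a usable rarefaction curve", call. = FALSE)
  mindepth_df <- do.call(rbind, lapply(mindepths, function(r) {
    fmt_runs <- if (length(r$runs))
      paste(vapply(r$runs, function(x) paste0(min(x), "-", max(x)),
                   character(1)), collapse = ";") else ""
    data.frame(sample_id = r$sample_id, total_reads = r$total_reads,
               qualifying_runs = fmt_runs, min_percent = r$min_percent,
               min_depth_reads = r$min_depth_reads, stringsAsFactors = FALSE)
  }))
  rownames(mindepth_df) <- NULL

  # (2) cohort depth
  cohort <- cohort_common_depth(unname(mindepths))
  depth <- cohort$common_depth_reads
  cohort_df <- data.frame(
    common_depth_reads = depth, n_included = cohort$n_included,
    included = paste(cohort$included_sample_ids, collapse = ";"),
    excluded = paste(cohort$excluded_sample_ids, collapse = ";"),
    stringsAsFactors = FALSE)

  # (3)+(4) rarefy to common depth, diversity there
  diversity_rows <- list()
  analysed <- names(mindepths)[names(mindepths) %in%
                                 cohort$included_sample_ids]
  by_id <- stats::setNames(samples,
                           vapply(samples, `[[`, character(1), "sample_id"))
  for (id in analysed) {
    row <- tryCatch({
      rarefied <- subsample_reads(by_id[[id]], depth,
                                  seed = derive_seed(config$master_seed,
                                                     match(id, names(by_id))))
      d <- diversity_summary(rarefied, top_k = config$top_n)
      data.frame(sample_id = id,
                 patient_id = by_id[[id]]$patient_id,
                 month_post_tx = by_id[[id]]$month_post_tx,
                 group = by_id[[id]]$group,
                 depth_reads = depth,
                 gini = d$gini, shannon_bits = d$shannon_bits,
                 richness = d$richness,
                 top_k = config$top_n,
                 top_k_fraction = unname(d$top_k_fraction[1]),
                 stringsAsFactors = FALSE)
    }, error = function(e) note_failure(id, "diversity", e))
    if (!is.null(row)) diversity_rows[[id]] <- row
  }
  diversity_df <- do.call(rbind, diversity_rows)
  rownames(diversity_df) <- NULL

  # (5) spectratypes at full depth
  spectra_rows <- list()
  for (s in samples) {
    row <- tryCatch({
      prof <- classify_spectratype(cdr3_length_distribution(s),
                                   config$spectra_thresholds)
      data.frame(sample_id = s$sample_id,
                 classification = prof$classification,
                 median_peaks = prof$median_peaks,
                 gaussian_fraction = prof$gaussian_fraction,
                 n_families = length(prof$families),
                 clinical_class = s$spectratype_class,
                 stringsAsFactors = FALSE)
    }, error = function(e) note_failure(s$sample_id, "spectratype", e))
    if (!is.null(row)) spectra_rows[[s$sample_id]] <- row
  }
  spectratype_df <- do.call(rbind, spectra_rows)
  rownames(spectratype_df) <- NULL

  # (6) annotation
  annotation_df <- NULL
  if (!is.null(config$vdjdb_path)) {
    db <- read_vdjdb_table(config$vdjdb_path)
    ann_rows <- list()
    for (s in samples) {
      row <- tryCatch({
        a <- annotate_vdjdb(s, db, match_policy = config$match_policy)
        if (length(a$binding_potential))
          data.frame(sample_id = s$sample_id,
                     antigen_species = names(a$binding_potential),
                     binding_potential = unname(a$binding_potential),
                     stringsAsFactors = FALSE)
        else NULL
      }, error = function(e) note_failure(s$sample_id, "annotation", e))
      if (!is.null(row)) ann_rows[[s$sample_id]] <- row
    }
    annotation_df <- do.call(rbind, ann_rows)
    if (!is.null(annotation_df)) rownames(annotation_df) <- NULL
  }

  # (7) trajectories per patient with >= 2 timepoints
  traj_rows <- list()
  pats <- vapply(samples, `[[`, character(1), "patient_id")
  for (p in unique(pats[!is.na(pats)])) {
    grp <- samples[pats %in% p]
    months <- vapply(grp, `[[`, numeric(1), "month_post_tx")
    grp <- grp[!is.na(months)]
    if (length(grp) < 2L) next
    row <- tryCatch({
      tr <- track_clonotypes(grp, n = config$top_n)
      cbind(patient_id = p, as.data.frame(tr), stringsAsFactors = FALSE)
    }, error = function(e) note_failure(p, "trajectories", e))
    if (!is.null(row)) traj_rows[[p]] <- row
  }
  trajectories_df <- do.call(rbind, traj_rows)
  if (!is.null(trajectories_df)) rownames(trajectories_df) <- NULL

  write_tsv <- function(df, name) {
    if (is.null(df)) df <- data.frame()
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  write_tsv(diversity_df, "diversity.tsv")
  write_tsv(mindepth_df, "mindepth.tsv")
  write_tsv(cohort_df, "cohort_depth.tsv")
  write_tsv(spectratype_df, "spectratype.tsv")
  write_tsv(trajectories_df, "trajectories.tsv")
  if (!is.null(config$vdjdb_path)) write_tsv(annotation_df, "annotation.tsv")

  failures_df <- if (length(failures)) do.call(rbind, failures) else NULL
  log_lines <- c(
    paste0("tcrrecon cohort analysis (package version ",
           as.character(utils::packageVersion("tcrrecon")), ")"),
    paste0("master_seed\t", config$master_seed),
    paste0("replicates\t", config$rarefaction$replicates),
    paste0("gradient_threshold\t", config$rarefaction$gradient_threshold),
    paste0("match_policy\t", config$match_policy),
    paste0("n_samples\t", length(samples)),
    paste0("common_depth_reads\t", depth),
    paste0("excluded\t", paste(cohort$excluded_sample_ids, collapse = ";")),
    if (!is.null(failures_df))
      paste0("failure\t", failures_df$sample_id, "\t", failures_df$stage,
             "\t", failures_df$message)
  )
  writeLines(log_lines, file.path(config$out_dir, "run.log"))

  out <- list(diversity = diversity_df, mindepth = mindepth_df,
              cohort_depth = cohort_df, cohort = cohort,
              spectratype = spectratype_df,
              trajectories = trajectories_df, annotation = annotation_df,
              failures = failures_df)
  if (!is.null(failures_df))
    warning(nrow(failures_df), " per-sample failure(s); see run.log",
            call. = FALSE)
  invisible(out)
}
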