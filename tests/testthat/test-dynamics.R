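vdjdb_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(cdr3_aa = r[[1]], v_call = r[[2]], j_call = NA_character_,
               epitope = r[[3]], antigen_species = r[[4]],
               stringsAsFactors = FALSE)))
}

test_that("top clonotypes rank by count with lexicographic tie-break", {
  s <- toy_sample(c(5, 3, 3))
  top <- top_clonotypes(s, n = 2)
  expect_equal(top$count, c(5L, 3L))
  tied <- s$clonotypes[s$clonotypes$count == 3, ]
  expect_equal(top$cdr3_nt[2], min(tied$cdr3_nt))
  expect_equal(nrow(top_clonotypes(s, n = 50)), 3)
  expect_lte(sum(top_clonotypes(s, n = 3)$frequency), 1)
  expect_error(top_clonotypes(s, n = 0), "positive")
})

make_timepoint <- function(counts, month, patient = "P1", ids = NULL) {
  n <- length(counts)
  if (is.null(ids)) ids <- seq_len(n)
  cl <- data.frame(v_call = "TRBV5-1*01", j_call = "TRBJ2-1*01",
                   cdr3_nt = toy_junction(ids), count = counts,
                   stringsAsFactors = FALSE)
  repertoire_sample(cl, sample_id = paste0(patient, "_m", month),
                    patient_id = patient, month_post_tx = month)
}

test_that("tracking unions top-n sets and looks up all detections", {
  # clone 1 abundant at both months; clone 2 only at month 1; clone 3
  # top at month 3 but also detected (low) at month 1
  s1 <- make_timepoint(c(50, 40, 2, 1), 1, ids = 1:4)
  s3 <- make_timepoint(c(60, 30, 5), 3, ids = c(1, 3, 5))
  tr <- track_clonotypes(list(s1, s3), n = 2)
  key1 <- toy_junction(1); key2 <- toy_junction(2); key3 <- toy_junction(3)

  t1 <- tr[tr$cdr3_nt == key1, ]
  expect_equal(sort(t1$month), c(1, 3))
  expect_true(all(t1$persistent))

  t2 <- tr[tr$cdr3_nt == key2, ]
  expect_equal(t2$month, 1)
  expect_false(any(t2$persistent))

  # union-then-lookup: clone 3 outside month-1 top-2 still gets its
  # month-1 frequency
  t3 <- tr[tr$cdr3_nt == key3, ]
  expect_equal(sort(t3$month), c(1, 3))
  expect_equal(t3$frequency[t3$month == 1], 2 / 93)
  expect_true(all(t3$persistent))

  # every reported frequency equals the raw-table frequency
  for (i in seq_len(nrow(tr))) {
    src <- if (tr$month[i] == 1) s1 else s3
    raw <- src$clonotypes$count[src$clonotypes$cdr3_nt == tr$cdr3_nt[i]]
    expect_equal(tr$frequency[i], raw / src$total_reads)
  }
})

test_that("tracking is invariant to input order and validates metadata", {
  s1 <- make_timepoint(c(9, 5, 3), 1)
  s2 <- make_timepoint(c(2, 8, 4), 6)
  s3 <- make_timepoint(c(1, 1, 30), 12)
  a <- track_clonotypes(list(s1, s2, s3), n = 2)
  b <- track_clonotypes(list(s3, s1, s2), n = 2)
  expect_identical(a, b)

  other <- make_timepoint(c(5, 5), 3, patient = "P2")
  expect_error(track_clonotypes(list(s1, other)), "patients")
  dup <- make_timepoint(c(5, 5), 1)
  expect_error(track_clonotypes(list(s1, dup)), "distinct")
  expect_error(track_clonotypes(list(s1)), "2 timepoints")
  chain_mix <- make_timepoint(c(5, 5), 6)
  chain_mix$chain <- "alpha"
  expect_error(track_clonotypes(list(s1, chain_mix)), "chains")
})

test_that("annotation sums matched frequencies into binding potential", {
  s <- toy_sample(c(2, 49, 49), v_call = rep("TRBV5-1*01", 3))
  s$clonotypes$cdr3_aa <- translate_junction(s$clonotypes$cdr3_nt)
  aa <- s$clonotypes$cdr3_aa[s$clonotypes$count == 2]
  db <- vdjdb_df(list(aa, "TRBV5-1*01", "NLVPMVATV", "CMV"))
  res <- annotate_vdjdb(s, db)
  expect_equal(unname(res$binding_potential["CMV"]), 0.02)
  expect_equal(nrow(res$hits), 1)

  none <- vdjdb_df(list("CASSNOMATCHF", "TRBV5-1*01", "X", "CMV"))
  res0 <- annotate_vdjdb(s, none)
  expect_equal(nrow(res0$hits), 0)
  expect_length(res0$binding_potential, 0)
})

test_that("a clonotype counts once per species but fully for each species", {
  s <- toy_sample(c(1, 19), v_call = rep("TRBV5-1*01", 2))
  s$clonotypes$cdr3_aa <- translate_junction(s$clonotypes$cdr3_nt)
  aa <- s$clonotypes$cdr3_aa[s$clonotypes$count == 1]
  db <- vdjdb_df(
    list(aa, "TRBV5-1*01", "epitope_one", "CMV"),
    list(aa, "TRBV5-1*01", "epitope_two", "CMV"),
    list(aa, "TRBV5-1*01", "epitope_three", "EBV"))
  res <- annotate_vdjdb(s, db)
  expect_equal(nrow(res$hits), 3)           # every epitope hit reported
  expect_equal(unname(res$binding_potential["CMV"]), 0.05)  # counted once
  expect_equal(unname(res$binding_potential["EBV"]), 0.05)  # full freq again
  expect_true(all(res$binding_potential <= 1))
})

test_that("V-family matching policy gates hits; CDR3-only is permissive", {
  s <- toy_sample(c(1, 9), v_call = c("TRBV5-1*01", "TRBV9*01"))
  s$clonotypes$cdr3_aa <- translate_junction(s$clonotypes$cdr3_nt)
  aa <- s$clonotypes$cdr3_aa[1]
  db <- vdjdb_df(list(aa, "TRBV12-3*01", "pep", "HIV-1"))
  strict <- annotate_vdjdb(s, db, match_policy = "cdr3_aa+v")
  expect_equal(nrow(strict$hits), 0)
  loose <- annotate_vdjdb(s, db, match_policy = "cdr3_aa")
  expect_equal(nrow(loose$hits), 1)
  expect_equal(loose$hits$match_level, "cdr3_aa")

  # same family, different allele/member: matches under the strict policy
  db2 <- vdjdb_df(list(aa, "TRBV5-6*02", "pep", "CMV"))
  expect_equal(nrow(annotate_vdjdb(s, db2)$hits), 1)
})

test_that("clonotypes without amino-acid CDR3 are skipped, not fatal", {
  s <- toy_sample(c(3, 7))
  s$clonotypes$cdr3_aa <- NA_character_
  db <- vdjdb_df(list("CASSF", "TRBV5-1*01", "pep", "CMV"))
  expect_message(res <- annotate_vdjdb(s, db), "skipped")
  expect_equal(res$n_skipped, 2L)
  expect_equal(nrow(res$hits), 0)
  expect_error(annotate_vdjdb(s, db[0, ]), "empty")
})
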