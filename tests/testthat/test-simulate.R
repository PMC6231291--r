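test_that("simulated tables validate, hit the read total and are seeded", {
  p <- simulation_params(baseline_richness = 300, total_reads = 5000,
                         seed = 42)
  s1 <- simulate_repertoire(p)
  expect_s3_class(s1, "repertoire_sample")
  expect_equal(sum(s1$clonotypes$count), 5000)
  expect_true(all(nchar(s1$clonotypes$cdr3_nt) %% 3 == 0))
  expect_identical(s1$clonotypes$cdr3_aa,
                   translate_junction(s1$clonotypes$cdr3_nt))
  expect_false(any(grepl("\\*", s1$clonotypes$cdr3_aa)))  # no stop codons

  s2 <- simulate_repertoire(p)
  expect_identical(s1$clonotypes, s2$clonotypes)
  # byte-identical when written
  f1 <- tempfile(); f2 <- tempfile()
  write_clonotype_table(s1, f1, "airr")
  write_clonotype_table(s2, f2, "airr")
  expect_identical(readLines(f1), readLines(f2))

  s3 <- simulate_repertoire(simulation_params(baseline_richness = 300,
                                              total_reads = 5000, seed = 43))
  expect_false(identical(s1$clonotypes, s3$clonotypes))
})

test_that("an expanded clone holds its prescribed repertoire fraction", {
  p <- simulation_params(baseline_richness = 2000, n_expanded = 1,
                         expansion_fractions = 0.5,
                         total_reads = 50000, seed = 7)
  s <- simulate_repertoire(p)
  top1 <- top_clonotypes(s, n = 1)
  se <- sqrt(0.5 * 0.5 / 50000)
  expect_lt(abs(top1$frequency - 0.5), 4 * se)
})

test_that("control-like defaults land in the control diversity band", {
  g <- h <- numeric(5)
  for (i in 1:5) {
    p <- simulation_params(seed = 500 + i)
    s <- simulate_repertoire(p)
    g[i] <- as.numeric(gini_coefficient(s$clonotypes$count))
    h[i] <- shannon_entropy(s$clonotypes$count)
  }
  expect_lt(mean(g), 0.2)
  expect_gt(mean(h), 12)
})

test_that("spiked length models concentrate junction lengths", {
  p <- simulation_params(baseline_richness = 200,
                         cdr3_length_model = spike_profile(c(39, 45),
                                                           c(0.7, 0.3)),
                         total_reads = 4000, seed = 11)
  s <- simulate_repertoire(p)
  expect_setequal(unique(nchar(s$clonotypes$cdr3_nt)), c(39, 45))
  expect_error(spike_profile(c(40, 45)), "multiples of 3")
  expect_error(normal_profile(mean_nt = 44), "multiple of 3")
})

test_that("calibration recovers an equal-abundance target with zero mass", {
  template <- simulation_params(
    baseline_richness = 500,
    baseline_distribution = list(kind = "lognormal", meanlog = 0, sdlog = 0),
    total_reads = 100000, seed = 1)
  cal <- calibrate_to_target_gini(0, template, n_seeds = 4)
  expect_equal(attr(cal, "expansion_mass"), 0)
  expect_equal(cal$n_expanded, 0L)
  expect_lte(attr(cal, "achieved_gini"), 0.05)
})

test_that("calibration is monotone and reports unreachable targets", {
  template <- simulation_params(baseline_richness = 800,
                                total_reads = 30000, seed = 5)
  lo <- calibrate_to_target_gini(0.4, template, n_seeds = 3)
  hi <- calibrate_to_target_gini(0.7, template, n_seeds = 3)
  expect_gte(attr(hi, "expansion_mass"), attr(lo, "expansion_mass"))
  expect_lt(abs(attr(lo, "achieved_gini") - 0.4), 0.05)
  expect_lt(abs(attr(hi, "achieved_gini") - 0.7), 0.05)
  expect_error(calibrate_to_target_gini(0.05,
    simulation_params(baseline_richness = 2000, total_reads = 4000,
                      seed = 2), n_seeds = 3),
    "unreachable")
})

test_that("reconstitution series carries expanded clones per persistence", {
  base_initial <- simulation_params(
    baseline_richness = 150,
    baseline_distribution = list(kind = "lognormal", meanlog = 0, sdlog = 1),
    n_expanded = 5, expansion_fractions = rep(0.08, 5),
    total_reads = 4000, seed = 1)
  base_final <- simulation_params(baseline_richness = 900,
                                  n_expanded = 5,
                                  expansion_fractions = rep(0.01, 5),
                                  total_reads = 4000, seed = 1)

  keys_of <- function(s) {
    tr <- attr(s, "truth")
    paste(tr$v_call, tr$j_call, tr$cdr3_nt)
  }

  full <- simulate_reconstitution_series(
    reconstitution_params(c(1, 3, 6), base_initial, base_final,
                          persistence_fraction = 1, seed = 9))
  for (k in 1:2) {
    kt <- keys_of(full[[k]]); kt1 <- keys_of(full[[k + 1]])
    expect_true(all(kt %in% kt1))
    # carried clones really are present in the next month's table
    expect_true(all(attr(full[[k]], "truth")$cdr3_nt %in%
                      full[[k + 1]]$clonotypes$cdr3_nt))
  }

  none <- simulate_reconstitution_series(
    reconstitution_params(c(1, 3, 6), base_initial, base_final,
                          persistence_fraction = 0, seed = 9))
  for (k in 1:2)
    expect_length(intersect(keys_of(none[[k]]), keys_of(none[[k + 1]])), 0)

  expect_error(reconstitution_params(1, base_initial, base_final),
               ">= 2")
})

test_that("a monotone schedule drives Gini down over the series", {
  initial <- simulation_params(
    baseline_richness = 150,
    baseline_distribution = list(kind = "lognormal", meanlog = 0, sdlog = 1),
    n_expanded = 5, expansion_fractions = rep(0.1, 5),
    total_reads = 6000, seed = 1)
  final <- simulation_params(baseline_richness = 1500,
                             total_reads = 6000, seed = 1)
  series <- simulate_reconstitution_series(
    reconstitution_params(c(1, 2, 6, 12), initial, final,
                          persistence_fraction = 0.5, seed = 17))
  g <- vapply(series, function(s)
    as.numeric(gini_coefficient(s$clonotypes$count)), numeric(1))
  expect_true(all(diff(g) < 0.05))   # non-increasing within sampling noise
  months <- vapply(series, `[[`, numeric(1), "month_post_tx")
  expect_equal(months, c(1, 2, 6, 12))
})
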