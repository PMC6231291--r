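test_that("full-depth subsampling is the identity", {
  s <- toy_sample(c(4, 9, 2, 5))
  expect_identical(subsample_reads(s, s$total_reads, seed = 1), s)
})

test_that("monoclonal subsampling returns the clone at the requested depth", {
  s <- toy_sample(50)
  sub <- subsample_reads(s, 7, seed = 3)
  expect_equal(nrow(sub$clonotypes), 1)
  expect_equal(sub$clonotypes$count, 7L)
  expect_equal(sub$total_reads, 7)
})

test_that("subsampled counts sum to depth and never exceed originals", {
  s <- toy_sample(c(10, 3, 7, 1, 30))
  for (depth in c(1, 5, 25, 50)) {
    sub <- subsample_reads(s, depth, seed = depth)
    expect_equal(sub$total_reads, depth)
    expect_equal(sum(sub$clonotypes$count), depth)
    orig <- s$clonotypes$count[match(sub$clonotypes$cdr3_nt,
                                     s$clonotypes$cdr3_nt)]
    expect_true(all(sub$clonotypes$count <= orig))
  }
  expect_error(subsample_reads(s, s$total_reads + 1), "extrapolation")
  expect_error(subsample_reads(s, 0), "positive integer")
})

test_that("draws follow the multivariate hypergeometric law on a toy sample", {
  # counts {A:2, B:2}, depth 2: of the C(4,2)=6 equally likely draws,
  # 4 give {A:1,B:1}, 1 gives {A:2}, 1 gives {B:2}
  s <- toy_sample(c(2, 2))
  n_rep <- 20000
  split_11 <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    sub <- subsample_reads(s, 2, seed = r)
    split_11[r] <- nrow(sub$clonotypes) == 2
  }
  p_hat <- mean(split_11)
  se <- sqrt(2 / 3 * 1 / 3 / n_rep)
  expect_lt(abs(p_hat - 2 / 3), 3 * se)
})

test_that("expected clonotype counts match the hypergeometric closed form", {
  s <- toy_sample(c(3, 2, 1))
  depth <- 3
  n_rep <- 20000
  acc <- numeric(3)
  for (r in seq_len(n_rep)) {
    sub <- subsample_reads(s, depth, seed = 100000 + r)
    cnt <- sub$clonotypes$count[match(s$clonotypes$cdr3_nt,
                                      sub$clonotypes$cdr3_nt)]
    cnt[is.na(cnt)] <- 0
    acc <- acc + cnt
  }
  emp <- acc / n_rep
  expected <- depth * s$clonotypes$count / s$total_reads
  # per-clone MC standard error bound from hypergeometric variance
  v <- depth * (s$clonotypes$count / 6) * (1 - s$clonotypes$count / 6) *
    (6 - depth) / 5
  expect_true(all(abs(emp - expected) < 3 * sqrt(v / n_rep)))
})

test_that("rarefaction curve is normalized, seeded and flagged", {
  s <- toy_sample(c(60, 30, 20, 10, 40, 90, 25, 35, 15, 75))
  cfg <- rarefaction_config(percent_grid = c(10, 50, 100), replicates = 8,
                            master_seed = 11)
  rc <- rarefaction_curve(s, cfg)
  expect_false(rc$degenerate)
  at100 <- rc$curve[rc$curve$percent == 100, ]
  expect_equal(at100$mean_norm_gini, 1)
  expect_equal(at100$se_norm_gini, 0)
  expect_equal(at100$mean_norm_shannon, 1)
  # determinism under the master seed
  rc2 <- rarefaction_curve(s, cfg)
  expect_identical(rc$curve, rc2$curve)
  # a different seed changes the replicate draws
  rc3 <- rarefaction_curve(s, rarefaction_config(percent_grid = c(10, 50, 100),
                                                 replicates = 8,
                                                 master_seed = 12))
  expect_false(identical(rc$curve$mean_norm_gini, rc3$curve$mean_norm_gini))

  mono <- toy_sample(500)
  expect_true(rarefaction_curve(mono, cfg)$degenerate)
  expect_error(rarefaction_curve(toy_sample(c(20, 30)), cfg), ">= 100")
})

test_that("mean normalized Gini declines toward low depth on heavy tails", {
  p <- simulation_params(baseline_richness = 600, n_expanded = 5,
                         expansion_fractions = rep(0.08, 5),
                         total_reads = 4000, seed = 21)
  s <- simulate_repertoire(p)
  cfg <- rarefaction_config(percent_grid = seq(10, 100, 10),
                            replicates = 12, master_seed = 5)
  rc <- rarefaction_curve(s, cfg)
  cur <- rc$curve
  # decline regime: below ~60% depth the loss of rare clonotypes drives
  # the normalized Gini down monotonically
  low <- cur[cur$percent <= 60, ]
  for (k in seq_len(nrow(low) - 1)) {
    tol <- 2 * (low$se_norm_gini[k] + low$se_norm_gini[k + 1])
    expect_lte(low$mean_norm_gini[k], low$mean_norm_gini[k + 1] + tol)
  }
  # near full depth the curve may overshoot 1 slightly (small-sample
  # upward bias of the subsampled Gini) but stays within a few percent
  expect_true(all(cur$mean_norm_gini <= 1.03))
  expect_lt(cur$mean_norm_gini[1], 0.9)
})

test_that("minimum depth follows the lowest qualifying run plus one", {
  # gradient > 1.1 exactly over percents 15..20, nothing else
  g <- cumsum(c(0, rep(0.005, 99)))
  g[16:21] <- g[15] + cumsum(rep(0.02, 6))   # percents 15..20 steep
  g[22:100] <- g[21] + cumsum(rep(0.005, 79))
  md <- minimum_representative_depth(fake_curve(g), rarefaction_config())
  expect_equal(md$qualifying_percents, 15:20)
  expect_equal(md$min_percent, 21L)
  expect_equal(md$min_depth_reads, ceiling(0.21 * md$total_reads))
  expect_equal(md$min_percent, mindepth_oracle(g))
})

test_that("runs partition qualifying percents; lowest run is selected", {
  g <- cumsum(c(0, rep(0.002, 99)))
  steep <- c(3, 4, 5, 40, 41)
  for (p in steep) g[(p + 1):100] <- g[(p + 1):100] + 0.03
  md <- minimum_representative_depth(fake_curve(g), rarefaction_config())
  expect_equal(md$qualifying_percents, steep)
  expect_equal(lapply(md$runs, as.integer), list(3:5, 40:41))
  expect_equal(md$selected_run, 3:5)
  expect_equal(md$min_percent, 6L)
  expect_equal(sort(unlist(md$runs)), md$qualifying_percents)
})

test_that("no qualifying gradient means representative at any depth", {
  g <- seq(0, 1, length.out = 100)       # exactly linear decline
  md <- minimum_representative_depth(fake_curve(g), rarefaction_config())
  expect_length(md$qualifying_percents, 0)
  expect_equal(md$min_percent, 1L)
  expect_equal(md$min_depth_reads, ceiling(0.01 * md$total_reads))
})

test_that("degenerate curves are rejected with guidance", {
  mono <- toy_sample(500)
  rc <- rarefaction_curve(mono, rarefaction_config(master_seed = 2))
  expect_error(minimum_representative_depth(rc, rarefaction_config()),
               "degenerate")
})

test_that("cohort depth maximizes inclusion with largest-depth tie-break", {
  res <- list(fake_mindepth("s1", 5000, 50000),
              fake_mindepth("s2", 12000, 30000),
              fake_mindepth("s3", 8000, 9000))
  cd <- cohort_common_depth(res)
  expect_equal(cd$common_depth_reads, 30000L)
  expect_setequal(cd$included_sample_ids, c("s1", "s2"))
  expect_setequal(cd$excluded_sample_ids, "s3")

  same <- list(fake_mindepth("a", 100, 900), fake_mindepth("b", 100, 900))
  expect_equal(cohort_common_depth(same)$common_depth_reads, 900L)

  single <- cohort_common_depth(list(fake_mindepth("one", 10, 480)))
  expect_equal(single$common_depth_reads, 480L)
  expect_error(cohort_common_depth(list()), "empty")
})

test_that("cohort optimizer agrees with exhaustive integer search", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(2:10, 1)
    lo <- sample(1:5000, n, replace = TRUE)
    hi <- lo + sample(0:5000, n, replace = TRUE)
    res <- lapply(seq_len(n), function(i)
      fake_mindepth(paste0("s", i), lo[i], hi[i]))
    cd <- cohort_common_depth(res)
    oracle <- cohort_depth_oracle(lo, hi)
    expect_equal(cd$common_depth_reads, oracle$depth)
    expect_equal(cd$n_included, oracle$n)
  }
})
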