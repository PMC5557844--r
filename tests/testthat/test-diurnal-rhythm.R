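two_day_hours <- rep(seq(0, 22, 2), 2)
two_day_times <- (rep(1:2, each = 12) - 1) * 24 + two_day_hours

test_that("phase windows partition the twelve even sampling hours", {
  w <- phase_windows()
  expect_setequal(unlist(w), seq(0, 22, 2))
  expect_equal(anyDuplicated(unlist(w)), 0L)
  # midnight wraps across 0
  expect_true(all(c(22, 0, 2) %in% w$midnight))
  bad <- w; bad$midday <- c(bad$midday, 6)
  expect_error(assign_phase(rnorm(24), two_day_hours, bad),
               class = "dielcross_argument_error")
})

test_that("cosinor rhythmicity score matches its analytic extremes", {
  y <- cos(2 * pi * (two_day_times - 5) / 24)
  expect_equal(rhythmicity_score(y, two_day_times), 1.0)
  expect_equal(rhythmicity_score(rep(3.2, 24), two_day_times), 0)
  # white-noise null: E[R2] ~ 2/(n-1)
  set.seed(4)
  n <- 48
  tt <- seq(0, 2 * 24 - 1, length.out = n)
  r2 <- replicate(400, rhythmicity_score(rnorm(n), tt))
  expect_lt(abs(mean(r2) - 2 / (n - 1)), 0.015)
  # preconditions
  expect_error(rhythmicity_score(1:5, 1:5),
               class = "dielcross_argument_error")
  expect_error(rhythmicity_score(rnorm(12), seq(0, 22, 2)),
               class = "dielcross_argument_error")
})

test_that("phase assignment finds the analytic peak window and obeys the tie rule", {
  peak_cases <- list(c(12, "midday"), c(5, "predawn"), c(19, "lateday"),
                     c(0, "midnight"))
  for (case in peak_cases) {
    y <- cos(2 * pi * (two_day_hours - as.numeric(case[1])) / 24)
    expect_equal(assign_phase(y, two_day_hours)$phase, case[2])
  }
  # equal means everywhere: fixed tie order predawn > midday > ...
  tie <- assign_phase(rep(1, 24), two_day_hours)
  expect_equal(tie$phase, "predawn")
  expect_equal(names(tie$window_means),
               c("predawn", "midday", "lateday", "midnight"))
  # affine invariance: y -> a*y + b with a > 0 keeps the phase
  y <- cos(2 * pi * (two_day_hours - 14) / 24) + rnorm(24, 0, 0.1)
  expect_equal(assign_phase(3 * y + 10, two_day_hours)$phase,
               assign_phase(y, two_day_hours)$phase)
})

test_that("diurnal clustering groups phase-shifted genes by shape", {
  cfg <- sim_config(n_genes = 60, n_stages = 2, noise_sd = 0.1, seed = 6)
  # two synthetic phase groups five hours apart
  hours <- rep(seq(0, 22, 2), 2 * 2)
  stage <- rep(1:2, each = 24)
  md <- data.frame(sample_id = sprintf("s%03d", seq_along(hours)),
                   series_id = "d", stress_type = "none",
                   condition = "mock",
                   replicate = rep(rep(1:2, each = 12), 2),
                   stage = stage, day = rep(rep(1:2, each = 12), 2),
                   hour = hours, stringsAsFactors = FALSE)
  peaks <- rep(c(6, 11), each = 30)
  vals <- t(vapply(seq_along(peaks), function(i)
    8 + cos(2 * pi * (hours - peaks[i]) / 24) + rnorm(length(hours), 0, 0.1),
    numeric(length(hours))))
  dimnames(vals) <- list(sprintf("g%02d", seq_along(peaks)), md$sample_id)
  em <- expression_matrix(vals, "log2")
  km <- cluster_diurnal(em, k = 2, seed = 3)
  expect_equal(length(unique(km$assignments[1:30])), 1L)
  expect_equal(length(unique(km$assignments[31:60])), 1L)
  expect_false(km$assignments[1] == km$assignments[31])
  # duplicated genes co-cluster
  em_dup <- expression_matrix(rbind(vals, dup = vals[1, , drop = FALSE][1, ]),
                              "log2")
  rownames(em_dup$values)[61] <- "dup"
  km_dup <- cluster_diurnal(em_dup, k = 2, seed = 3)
  expect_equal(unname(km_dup$assignments["dup"]),
               unname(km_dup$assignments["g01"]))
})

test_that("call_diurnal recovers planted rhythmicity and phase", {
  cfg <- sim_config(n_genes = 800, amplitude = 1, noise_sd = 0.25,
                    frac_rhythmic = 0.5, seed = 19)
  sim <- generate_diurnal_course(cfg)
  calls <- call_diurnal(log2_normalize(sim$matrix), sim$metadata,
                        k = 7, seed = 19, r2_threshold = 0.3)
  expect_equal(length(unique(calls$cluster)), 7L)
  truth <- sim$truth[match(calls$gene_id, sim$truth$gene_id), ]
  sens <- mean(calls$rhythmic[truth$true_rhythmic])
  spec <- mean(!calls$rhythmic[!truth$true_rhythmic])
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
  both <- truth$true_rhythmic & calls$rhythmic
  acc <- mean(calls$phase[both] == truth$true_phase[both])
  expect_gte(acc, 0.85)
  # rhythmic genes carry a phase, arrhythmic genes do not
  expect_true(all(!is.na(calls$phase[calls$rhythmic])))
  expect_true(all(is.na(calls$phase[!calls$rhythmic])))
})

test_that("flat genes are not called rhythmic", {
  cfg <- sim_config(n_genes = 300, frac_rhythmic = 0, amplitude = 0,
                    noise_sd = 0.25, seed = 29)
  sim <- generate_diurnal_course(cfg)
  calls <- call_diurnal(log2_normalize(sim$matrix), sim$metadata,
                        k = 4, seed = 29, r2_threshold = 0.3)
  expect_lte(mean(calls$rhythmic), 0.02)
})

test_that("phase recovery is invariant to a constant shift of one stage", {
  cfg <- sim_config(n_genes = 80, frac_rhythmic = 1, noise_sd = 0.1,
                    n_stages = 3, seed = 31)
  sim <- generate_diurnal_course(cfg)
  em <- log2_normalize(sim$matrix)
  calls <- call_diurnal(em, sim$metadata, k = 4, seed = 31)
  shifted <- em$values
  stage1 <- sim$metadata$sample_id[sim$metadata$stage == 1]
  shifted[, stage1] <- shifted[, stage1] + 0.5
  calls_sh <- call_diurnal(expression_matrix(shifted, "log2"),
                           sim$metadata, k = 4, seed = 31)
  expect_equal(calls_sh$phase, calls$phase)
})

test_that("crosstalk summary reproduces the reported arithmetic", {
  # the printed counts: 712 up (403 diurnal), 761 down (363 diurnal)
  labels <- data.frame(
    gene_id = sprintf("g%04d", 1:1500),
    drought_class = c(rep("up", 712), rep("down", 761), rep("none", 27)),
    stringsAsFactors = FALSE)
  calls <- data.frame(
    gene_id = labels$gene_id,
    rhythmic = c(rep(TRUE, 403), rep(FALSE, 712 - 403),
                 rep(TRUE, 363), rep(FALSE, 761 - 363),
                 rep(FALSE, 27)),
    phase = NA_character_, stringsAsFactors = FALSE)
  calls$phase[calls$rhythmic] <- rep(c("predawn", "midday"),
                                     length.out = sum(calls$rhythmic))
  s <- crosstalk_summary(labels, calls)
  expect_equal(s$up$pct_diurnal, 56.6)
  expect_equal(s$down$pct_diurnal, 47.7)
  expect_equal(s$n_diurnal_total, 766)
  expect_lte(s$up$n_diurnal, s$up$n)
  expect_equal(s$up$n + s$down$n + 27, nrow(labels))
  expect_equal(sum(s$up$phase_pct), 100, tolerance = 0.05)

  # zero-diurnal direction reports 0; empty direction reports NA
  calls0 <- calls; calls0$rhythmic <- FALSE; calls0$phase <- NA_character_
  s0 <- crosstalk_summary(labels, calls0)
  expect_equal(s0$up$pct_diurnal, 0)
  labels_noup <- labels[labels$drought_class != "up", ]
  s_na <- crosstalk_summary(labels_noup,
                            calls[match(labels_noup$gene_id, calls$gene_id), ])
  expect_true(is.na(s_na$up$pct_diurnal))
})
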