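test_that("stress generator dimensions and metadata bookkeeping are exact", {
  cfg <- sim_config(n_genes = 100, n_series = 9, replicates_per_series = 2,
                    seed = 3)
  sim <- generate_stress_series(cfg)
  expect_equal(dim(sim$matrix$values), c(100L, 36L))  # 9 series x 2 reps x 2 conditions
  expect_equal(sim$matrix$scale, "linear")
  expect_true(all(sim$matrix$values > 0))
  expect_equal(nrow(sim$metadata), 36L)
  expect_setequal(sim$metadata$sample_id, colnames(sim$matrix$values))
  expect_equal(sum(sim$metadata$stress_type == "drought"), 24L)  # 6 of 9 series
})

test_that("generators are byte-identical under the same config and seed", {
  cfg <- sim_config(n_genes = 50, seed = 11)
  expect_identical(generate_stress_series(cfg), generate_stress_series(cfg))
  expect_identical(generate_diurnal_course(cfg), generate_diurnal_course(cfg))
  expect_identical(generate_annotations(cfg, n_terms = 10),
                   generate_annotations(cfg, n_terms = 10))
  expect_identical(generate_interactions(cfg, 3, 10),
                   generate_interactions(cfg, 3, 10))
  cfg2 <- sim_config(n_genes = 50, seed = 12)
  expect_false(identical(generate_stress_series(cfg)$matrix$values,
                         generate_stress_series(cfg2)$matrix$values))
})

test_that("planted drought effects are recovered on the log2 fold-change scale", {
  cfg <- sim_config(n_genes = 1000, frac_up = 0.2, frac_down = 0.2,
                    effect_size = 2, noise_sd = 0.25, seed = 42)
  sim <- generate_stress_series(cfg)
  fcp <- fold_change(log2_normalize(sim$matrix), sim$metadata)
  dr <- fcp$pairs$stress_type == "drought"
  up <- sim$truth$true_drought_class == "up"
  mean_up <- mean(fcp$log2fc[up, dr])
  expect_lt(abs(mean_up - 2), 0.05)
  none <- sim$truth$true_drought_class == "none"
  expect_lt(abs(mean(fcp$log2fc[none, dr])), 0.05)
})

test_that("truth table is internally consistent and marginally calibrated", {
  cfg <- sim_config(n_genes = 4000, frac_up = 0.25, frac_down = 0.15,
                    frac_rhythmic = 0.4, seed = 5)
  sim <- generate_diurnal_course(cfg)
  tt <- sim$truth
  # phase present iff rhythmic; peak hour inside the named window span
  expect_identical(is.na(tt$true_phase), !tt$true_rhythmic)
  expect_identical(is.na(tt$true_peak_hour), !tt$true_rhythmic)
  spans <- list(predawn = c(4, 6), midday = c(8, 16), lateday = c(18, 20),
                midnight = c(22, 26))
  for (i in which(tt$true_rhythmic)) {
    sp <- spans[[tt$true_phase[i]]]
    h <- tt$true_peak_hour[i]
    if (h < sp[1]) h <- h + 24  # midnight wrap
    expect_true(h >= sp[1] && h <= sp[2])
  }
  # binomial calibration at 3 sigma
  for (frac_pair in list(c(mean(tt$true_drought_class == "up"), 0.25),
                         c(mean(tt$true_drought_class == "down"), 0.15),
                         c(mean(tt$true_rhythmic), 0.4))) {
    tol <- 3 * sqrt(frac_pair[2] * (1 - frac_pair[2]) / nrow(tt))
    expect_lt(abs(frac_pair[1] - frac_pair[2]), tol)
  }
})

test_that("diurnal course has the expected design and degenerate behaviour", {
  cfg <- sim_config(n_genes = 40, n_stages = 9, seed = 2)
  sim <- generate_diurnal_course(cfg)
  expect_equal(ncol(sim$matrix$values), 216L)  # 12 hours x 2 days x 9 stages
  expect_setequal(unique(sim$metadata$hour), seq(0, 22, 2))

  # amplitude 0 for all genes: per-gene variance ~ noise_sd^2 (+ stage
  # spread); with one stage and no stage effect it is noise alone
  cfg0 <- sim_config(n_genes = 400, frac_rhythmic = 0, amplitude = 0,
                     n_stages = 1, stage_sd = 0, noise_sd = 0.3, seed = 8)
  sim0 <- generate_diurnal_course(cfg0)
  v <- apply(log2(sim0$matrix$values), 1, var)
  expect_lt(abs(mean(v) - 0.09), 0.01)

  # noiseless cosine peaking at 5 h peaks at a flanking sampled hour
  cfg5 <- sim_config(n_genes = 5, frac_rhythmic = 1, noise_sd = 0,
                     n_stages = 1, stage_sd = 0, seed = 13)
  sim5 <- generate_diurnal_course(cfg5)
  tt <- sim5$truth
  x <- log2(sim5$matrix$values)
  hours <- sim5$metadata$hour
  for (i in seq_len(nrow(tt))) {
    peak_hour <- hours[which.max(x[i, ])]
    lo <- 2 * floor(tt$true_peak_hour[i] / 2)
    expect_true(peak_hour %in% c(lo %% 24, (lo + 2) %% 24))
  }
})

test_that("generator configuration errors are raised", {
  expect_error(sim_config(n_genes = 0), class = "dielcross_config_error")
  expect_error(sim_config(frac_up = 0.7, frac_down = 0.5),
               class = "dielcross_config_error")
  expect_error(sim_config(frac_up = -0.1), class = "dielcross_config_error")
  expect_error(sim_config(phase_mix = c(predawn = 1, midday = 1,
                                        lateday = 0, midnight = 0)),
               class = "dielcross_config_error")
  expect_error(sim_config(noise_sd = -1), class = "dielcross_config_error")
  cfg <- sim_config(n_genes = 20, seed = 1)
  expect_error(generate_annotations(cfg, n_terms = 0),
               class = "dielcross_config_error")
  expect_error(generate_annotations(cfg, n_terms = 5,
                                    planted_term_fold = 0.5),
               class = "dielcross_config_error")
  # infeasible planted fold: membership probability would exceed 1
  big <- sim_config(n_genes = 200, frac_up = 0.5, frac_rhythmic = 1,
                    seed = 1)
  expect_error(generate_annotations(big, n_terms = 2,
                                    planted_term_fold = 50,
                                    term_size_range = c(180, 180)),
               class = "dielcross_config_error")
})

test_that("annotation generator plants a null term at fold ~ 1", {
  cfg <- sim_config(n_genes = 3000, seed = 21)
  ann <- generate_annotations(cfg, n_terms = 20, planted_term_fold = 1,
                              term_size_range = c(200, 500))
  truth <- generate_diurnal_course(cfg)$truth
  target <- truth$gene_id[truth$true_drought_class == "up" &
                            truth$true_rhythmic]
  res <- enrich(target, ann, background = truth$gene_id, min_term_size = 2)
  planted <- attr(ann, "planted_terms")
  folds <- res$fold[res$term_id %in% planted]
  expect_true(all(abs(folds - 1) < 0.5))
})

test_that("interaction generator yields valid confidences and planted correlation", {
  cfg <- sim_config(seed = 30)
  gi <- generate_interactions(cfg, n_pathway_genes = 11, n_partners = 69,
                              planted_pcc = 0.9, frac_planted = 0.5)
  expect_equal(nrow(gi$interactions), 69L)
  expect_true(all(gi$interactions$confidence > 0 &
                    gi$interactions$confidence <= 1))
  expect_false(any(gi$interactions$gene_a == gi$interactions$gene_b))
  vals <- log2(gi$expression$values)
  pcc <- vapply(seq_len(nrow(gi$truth)), function(i)
    cor(vals[gi$truth$gene_a[i], ], vals[gi$truth$gene_b[i], ]),
    numeric(1))
  expect_true(all(pcc[gi$truth$planted] > 0.5))
  expect_lt(mean(abs(pcc[!gi$truth$planted])), 0.4)
})

test_that("simulation tables round-trip through the TSV writers", {
  cfg <- sim_config(n_genes = 12, n_series = 2, seed = 9)
  sim <- generate_stress_series(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir, "toy")
  em2 <- read_expression_matrix(paths["matrix"], "linear")
  expect_equal(em2$values, sim$matrix$values, tolerance = 1e-9)
  ann <- generate_annotations(cfg, n_terms = 5, planted_term_fold = 1,
                              term_size_range = c(2, 5))
  p <- file.path(dir, "ann.tsv")
  write_annotations(ann, p)
  expect_true(any(grepl("term_size_range", readLines(p))))
})
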