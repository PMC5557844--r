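# Synthetic-data module: stress series and diurnal courses with planted
# ground truth, emulating the statistical structure of the meta-expression
# compendium (nine Affymetrix stress series with paired stress/MOCK
# replicates) and a field-grown diurnal leaf course sampled every 2 h for
# 2 days across nine developmental stages.

PHASE_SPANS <- list(predawn = c(4, 6), midday = c(8, 16),
                    lateday = c(18, 20), midnight = c(22, 26))

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators with validated
#' defaults. Defaults mirror the study conditions the pipeline is meant
#' for: nine stress series (six drought), a log2 effect of 2 for planted
#' drought genes, cosine diurnal signals of log2 amplitude 1 with peaks in
#' four clock windows mixed roughly as reported for drought-upregulated
#' genes, nine developmental stages, and log2 noise of 0.25.
#'
#' @param n_genes Number of genes.
#' @param n_series Number of stress series (default 9).
#' @param replicates_per_series Stress/MOCK replicate pairs per series;
#'   scalar or one value per series (default 2).
#' @param frac_up,frac_down Fractions of genes with a planted drought
#'   effect (up / down); must sum to at most 1.
#' @param effect_size Planted drought effect in log2-fold units
#'   (default 2).
#' @param frac_rhythmic Fraction of genes with a planted diurnal signal.
#' @param amplitude Cosine half-range in log2 units (default 1).
#' @param phase_mix Probabilities over the four peak windows (predawn,
#'   midday, lateday, midnight); must sum to 1.
#' @param n_stages Developmental stages in the diurnal course (default 9).
#' @param noise_sd Measurement noise, log2 units (default 0.25).
#' @param baseline_mean,baseline_sd Per-gene baseline expression, log2
#'   units.
#' @param stage_sd Spread of additive per-gene stage offsets, log2 units
#'   (default 0.5), mimicking vegetative-versus-reproductive level shifts.
#' @param seed Integer seed; the same configuration and seed reproduce
#'   every generator output exactly.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000, n_series = 9,
                       replicates_per_series = 2, frac_up = 0.2,
                       frac_down = 0.2, effect_size = 2,
                       frac_rhythmic = 0.5, amplitude = 1,
                       phase_mix = c(predawn = 0.35, midday = 0.30,
                                     lateday = 0.17, midnight = 0.18),
                       n_stages = 9, noise_sd = 0.25, baseline_mean = 8,
                       baseline_sd = 1.5, stage_sd = 0.5, seed = 1) {
  err <- "dielcross_config_error"
  dc_assert(is_count(n_genes), "n_genes must be a positive integer",
            class = err)
  dc_assert(is_count(n_series), "n_series must be a positive integer",
            class = err)
  dc_assert(is.numeric(replicates_per_series) &&
              length(replicates_per_series) %in% c(1L, n_series) &&
              all(replicates_per_series >= 1),
            "replicates_per_series must be a positive scalar or one value per series",
            class = err)
  for (f in list(frac_up = frac_up, frac_down = frac_down,
                 frac_rhythmic = frac_rhythmic))
    dc_assert(is_fraction(f), "fractions must lie in [0, 1]", class = err)
  dc_assert(frac_up + frac_down <= 1, "frac_up + frac_down must be <= 1",
            class = err)
  dc_assert(length(phase_mix) == 4L &&
              setequal(names(phase_mix), PHASE_ORDER) &&
              all(phase_mix >= 0) && abs(sum(phase_mix) - 1) < 1e-8,
            "phase_mix needs the four named windows and must sum to 1",
            class = err)
  dc_assert(is_count(n_stages), "n_stages must be a positive integer",
            class = err)
  dc_assert(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0",
            class = err)
  dc_assert(is.numeric(amplitude) && amplitude >= 0,
            "amplitude must be >= 0", class = err)
  dc_assert(is.numeric(baseline_sd) && baseline_sd >= 0 &&
              is.numeric(stage_sd) && stage_sd >= 0,
            "spread parameters must be >= 0", class = err)
  structure(list(
    n_genes = as.integer(n_genes), n_series = as.integer(n_series),
    replicates_per_series = rep(as.integer(replicates_per_series),
                                length.out = n_series),
    frac_up = frac_up, frac_down = frac_down, effect_size = effect_size,
    frac_rhythmic = frac_rhythmic, amplitude = amplitude,
    phase_mix = phase_mix[PHASE_ORDER], n_stages = as.integer(n_stages),
    noise_sd = noise_sd, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, stage_sd = stage_sd,
    seed = as.integer(seed)), class = "sim_config")
}

gene_names <- function(n) sprintf("gene_%0*d", nchar(n), seq_len(n))

# Ground truth shared by the stress and diurnal generators: drawn from the
# configuration seed alone, so both datasets agree on which genes are
# drought-responsive and which are rhythmic.
draw_truth <- function(config) {
  with_seed(config$seed, {
    n <- config$n_genes
    cls <- sample(c("up", "down", "none"), n, replace = TRUE,
                  prob = c(config$frac_up, config$frac_down,
                           1 - config$frac_up - config$frac_down))
    rhythmic <- stats::runif(n) < config$frac_rhythmic
    phase <- rep(NA_character_, n)
    peak <- rep(NA_real_, n)
    nr <- sum(rhythmic)
    if (nr > 0) {
      ph <- sample(PHASE_ORDER, nr, replace = TRUE, prob = config$phase_mix)
      spans <- do.call(rbind, PHASE_SPANS[ph])
      peak_h <- stats::runif(nr, spans[, 1], spans[, 2]) %% 24
      phase[rhythmic] <- ph
      peak[rhythmic] <- peak_h
    }
    data.frame(gene_id = gene_names(n), true_drought_class = cls,
               true_rhythmic = rhythmic, true_phase = phase,
               true_peak_hour = peak, stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic stress-series compendium
#'
#' Emulates a multi-series stress compendium with paired stress/MOCK
#' replicates: by default nine series of which six are drought (the rest
#' cold, heat, submergence, carrying no planted drought effect). Each
#' gene's linear intensity is `2^(baseline + effect * is_stress + noise)`
#' where the planted effect applies only in drought series to truth-up
#' (positive) and truth-down (negative) genes.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (linear-scale `expr_matrix`), `metadata`
#'   (sample table), `truth` (per-gene ground truth).
#' @export
generate_stress_series <- function(config) {
  dc_assert(inherits(config, "sim_config"), "`config` must be a sim_config",
            class = "dielcross_config_error")
  truth <- draw_truth(config)
  n <- config$n_genes
  # six of nine default series are drought; the remainder cycle through
  # the other abiotic stresses
  n_drought <- max(1L, ceiling(config$n_series * 2 / 3))
  types <- c(rep("drought", n_drought),
             rep(c("cold", "heat", "submergence"),
                 length.out = config$n_series - n_drought))
  effect <- ifelse(truth$true_drought_class == "up", config$effect_size,
                   ifelse(truth$true_drought_class == "down",
                          -config$effect_size, 0))
  md <- do.call(rbind, lapply(seq_len(config$n_series), function(s) {
    reps <- config$replicates_per_series[s]
    expand <- expand.grid(replicate = seq_len(reps),
                          condition = c("stress", "mock"),
                          stringsAsFactors = FALSE)
    data.frame(sample_id = sprintf("series%d_%s_r%d", s, expand$condition,
                                   expand$replicate),
               series_id = sprintf("series%d", s),
               stress_type = types[s], condition = expand$condition,
               replicate = expand$replicate, stage = NA_integer_,
               day = NA_integer_, hour = NA_integer_,
               stringsAsFactors = FALSE)
  }))
  vals <- with_seed(config$seed + 1L, {
    baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
    log2val <- matrix(baseline, n, nrow(md))
    is_stress <- md$condition == "stress" & md$stress_type == "drought"
    log2val[, is_stress] <- log2val[, is_stress] + effect
    log2val + matrix(stats::rnorm(n * nrow(md), 0, config$noise_sd),
                     n, nrow(md))
  })
  dimnames(vals) <- list(truth$gene_id, md$sample_id)
  list(matrix = expression_matrix(2^vals, "linear"), metadata = md,
       truth = truth)
}

#' Generate a synthetic diurnal time-course
#'
#' One sample per even clock hour (0, 2, ..., 22), per day (two days), per
#' developmental stage. Rhythmic genes follow
#' `baseline + stage_offset + amplitude * cos(2 pi (t - peak) / 24) +
#' noise` with the peak hour drawn inside the gene's true phase window;
#' arrhythmic genes have amplitude zero. Output intensities are on the
#' linear scale.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (linear `expr_matrix`, `24 * n_stages`
#'   samples), `metadata`, `truth`.
#' @export
generate_diurnal_course <- function(config) {
  dc_assert(inherits(config, "sim_config"), "`config` must be a sim_config",
            class = "dielcross_config_error")
  truth <- draw_truth(config)
  n <- config$n_genes
  md <- expand.grid(hour = seq(0, 22, by = 2), day = 1:2,
                    stage = seq_len(config$n_stages))
  md <- data.frame(
    sample_id = sprintf("stage%02d_day%d_h%02d", md$stage, md$day, md$hour),
    series_id = "diurnal_course", stress_type = "none", condition = "mock",
    replicate = md$day, stage = md$stage, day = md$day, hour = md$hour,
    stringsAsFactors = FALSE)
  amp <- ifelse(truth$true_rhythmic, config$amplitude, 0)
  peak <- ifelse(truth$true_rhythmic, truth$true_peak_hour, 0)
  vals <- with_seed(config$seed + 2L, {
    baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
    stage_off <- matrix(stats::rnorm(n * config$n_stages, 0,
                                     config$stage_sd),
                        n, config$n_stages)
    cosine <- outer(seq_len(n), seq_len(nrow(md)), function(i, j)
      amp[i] * cos(2 * pi * (md$hour[j] - peak[i]) / 24))
    baseline + stage_off[, md$stage] + cosine +
      matrix(stats::rnorm(n * nrow(md), 0, config$noise_sd), n, nrow(md))
  })
  dimnames(vals) <- list(truth$gene_id, md$sample_id)
  list(matrix = expression_matrix(2^vals, "linear"), metadata = md,
       truth = truth)
}

#' Generate a synthetic gene-to-term annotation table
#'
#' Stand-in for a GO-style annotation file. Background term sizes are
#' drawn log-uniformly from `term_size_range`; the first `n_planted`
#' terms are planted so that genes in the target set (truth-up and
#' rhythmic) carry the term at `planted_term_fold` times the rate of
#' other genes, with the out-of-set rate deflated to preserve the
#' expected term size.
#'
#' @param config A [sim_config()].
#' @param n_terms Number of terms (>= 1).
#' @param planted_term_fold Rate ratio planted for the designated terms
#'   (>= 1; 1 means no enrichment).
#' @param n_planted How many terms are planted (default
#'   `min(3, n_terms)`).
#' @param term_size_range Expected term-size range the log-uniform draw
#'   uses; default 10 to `n_genes / 5`.
#' @return A data frame of `(gene_id, term_id)` pairs with attributes
#'   `planted_terms`, `planted_term_fold`, `term_size_range`, and
#'   `term_sizes` (the drawn expected sizes).
#' @export
generate_annotations <- function(config, n_terms = 50, planted_term_fold = 5,
                                 n_planted = min(3L, n_terms),
                                 term_size_range = NULL) {
  dc_assert(inherits(config, "sim_config"), "`config` must be a sim_config",
            class = "dielcross_config_error")
  dc_assert(is_count(n_terms), "n_terms must be >= 1",
            class = "dielcross_config_error")
  dc_assert(is.numeric(planted_term_fold) && planted_term_fold >= 1,
            "planted_term_fold must be >= 1",
            class = "dielcross_config_error")
  dc_assert(is_count(n_planted, min = 0L) && n_planted <= n_terms,
            "n_planted must be between 0 and n_terms",
            class = "dielcross_config_error")
  truth <- draw_truth(config)
  N <- config$n_genes
  term_size_range <- term_size_range %||% c(10, max(10, floor(N / 5)))
  target <- truth$true_drought_class == "up" & truth$true_rhythmic
  n_t <- sum(target)
  with_seed(config$seed + 3L, {
    sizes <- round(exp(stats::runif(n_terms, log(term_size_range[1]),
                                    log(term_size_range[2]))))
    sizes <- pmin(pmax(sizes, 1), N)
    term_ids <- sprintf("TERM:%04d", seq_len(n_terms))
    planted <- seq_len(n_planted)
    pairs <- vector("list", n_terms)
    for (j in seq_len(n_terms)) {
      if (j %in% planted && planted_term_fold > 1 && n_t > 0) {
        p_out <- sizes[j] / (N + (planted_term_fold - 1) * n_t)
        p_in <- planted_term_fold * p_out
        if (p_in > 1)
          dc_stop("planted fold %g infeasible for term size %d (target set %d of %d genes)",
                  planted_term_fold, sizes[j], n_t, N,
                  class = "dielcross_config_error")
        p <- ifelse(target, p_in, p_out)
      } else {
        p <- rep(sizes[j] / N, N)
      }
      member <- stats::runif(N) < p
      if (any(member))
        pairs[[j]] <- data.frame(gene_id = truth$gene_id[member],
                                 term_id = term_ids[j],
                                 stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, pairs)
    rownames(ann) <- NULL
    attr(ann, "planted_terms") <- term_ids[planted]
    attr(ann, "planted_term_fold") <- planted_term_fold
    attr(ann, "term_size_range") <- term_size_range
    attr(ann, "term_sizes") <- stats::setNames(sizes, term_ids)
    ann
  })
}

#' Generate a synthetic pathway interaction table
#'
#' Stand-in for interolog-confidence interaction records plus the
#' anatomical-style expression matrix used to score edges by Pearson
#' correlation. Each partner gene is attached to one pathway gene;
#' a `frac_planted` subset of edges is planted with correlated linear
#' profiles at `planted_pcc` (recorded in the truth table), the rest are
#' independent.
#'
#' @param config A [sim_config()] (supplies the seed).
#' @param n_pathway_genes Number of pathway member genes (>= 1).
#' @param n_partners Number of interaction partners / edge records
#'   (>= 1).
#' @param n_samples Columns of the companion expression matrix
#'   (default 24, anatomical-panel sized).
#' @param planted_pcc Target correlation for planted edges (default 0.9).
#' @param frac_planted Fraction of edges planted as correlated.
#' @return List with `interactions` (`gene_a`, `gene_b`, `confidence` in
#'   (0, 1]), `expression` (linear `expr_matrix` over the edge
#'   endpoints), `truth` (per-edge planted flag and target PCC).
#' @export
generate_interactions <- function(config, n_pathway_genes = 11,
                                  n_partners = 69, n_samples = 24,
                                  planted_pcc = 0.9, frac_planted = 0.5) {
  dc_assert(inherits(config, "sim_config"), "`config` must be a sim_config",
            class = "dielcross_config_error")
  dc_assert(is_count(n_pathway_genes) && is_count(n_partners),
            "counts must be >= 1", class = "dielcross_config_error")
  dc_assert(is_count(n_samples, min = 3L), "n_samples must be >= 3",
            class = "dielcross_config_error")
  dc_assert(is.numeric(planted_pcc) && abs(planted_pcc) < 1,
            "planted_pcc must lie in (-1, 1)",
            class = "dielcross_config_error")
  dc_assert(is_fraction(frac_planted), "frac_planted must lie in [0, 1]",
            class = "dielcross_config_error")
  with_seed(config$seed + 4L, {
    pw <- sprintf("pathway_%02d", seq_len(n_pathway_genes))
    partners <- sprintf("partner_%03d", seq_len(n_partners))
    anchor <- pw[(seq_len(n_partners) - 1L) %% n_pathway_genes + 1L]
    confidence <- stats::runif(n_partners, 0.05, 1)
    planted <- stats::runif(n_partners) < frac_planted
    interactions <- data.frame(gene_a = anchor, gene_b = partners,
                               confidence = confidence,
                               stringsAsFactors = FALSE)
    base <- matrix(stats::rnorm(n_pathway_genes * n_samples), n_pathway_genes,
                   dimnames = list(pw, NULL))
    part_prof <- matrix(NA_real_, n_partners, n_samples,
                        dimnames = list(partners, NULL))
    for (i in seq_len(n_partners)) {
      eps <- stats::rnorm(n_samples)
      a <- base[anchor[i], ]
      part_prof[i, ] <- if (planted[i]) {
        planted_pcc * scale(a)[, 1] + sqrt(1 - planted_pcc^2) * eps
      } else eps
    }
    prof <- rbind(base, part_prof)
    log2val <- 8 + 1.5 * prof
    colnames(log2val) <- sprintf("anatomy_%02d", seq_len(n_samples))
    truth <- data.frame(gene_a = anchor, gene_b = partners,
                        planted = planted,
                        target_pcc = ifelse(planted, planted_pcc, NA_real_),
                        stringsAsFactors = FALSE)
    list(interactions = interactions,
         expression = expression_matrix(2^log2val, "linear"),
         truth = truth)
  })
}

#' Write generator outputs to a directory
#'
#' Writes the expression matrix, metadata and truth tables of a
#' [generate_stress_series()] / [generate_diurnal_course()] result as TSV.
#'
#' @param sim A generator result list.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Paths of written files, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, paste0(prefix, "_matrix.tsv")),
    metadata = file.path(dir, paste0(prefix, "_metadata.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  write_expression_matrix(sim$matrix, paths["matrix"])
  write_tsv(sim$metadata, paths["metadata"])
  write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}

#' Write an annotation table to TSV
#'
#' Header comment lines record the planted terms, the planted rate ratio
#' and the log-uniform term-size range used.
#'
#' @param ann Result of [generate_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  rng <- attr(ann, "term_size_range")
  write_tsv(ann, path, comment = c(
    sprintf("planted_terms: %s",
            paste(attr(ann, "planted_terms"), collapse = ",")),
    sprintf("planted_term_fold: %g", attr(ann, "planted_term_fold")),
    sprintf("term_size_range: log-uniform [%g, %g]", rng[1], rng[2])))
}
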