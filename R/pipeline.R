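# End-to-end orchestration: simulate -> normalize -> classify ->
# call diurnal -> crosstalk -> enrich -> network, from one structured
# config, with a log and a checksummed run manifest.

PIPELINE_STAGES <- c("simulate", "fold_change", "classify", "diurnal",
                     "crosstalk", "enrich", "network")

default_run_config <- function() {
  list(
    seed = 1,
    stages = PIPELINE_STAGES,
    sim = list(),  # sim_config() overrides
    classify = list(k = 10, up_threshold = 1, down_threshold = 1),
    diurnal = list(k = 7, r2_threshold = 0.3),
    enrich = list(n_terms = 40, planted_term_fold = 10, min_fold = 2,
                  alpha = 0.05, term_size_range = NULL),
    network = list(n_pathway_genes = 11, n_partners = 69,
                   pcc_threshold = 0.5))
}

#' Load and validate a pipeline run configuration
#'
#' Accepts a YAML file path or a plain list; missing entries fall back to
#' package defaults. The configuration carries the seed, the enabled
#' stages, the [sim_config()] overrides, and per-stage parameters.
#'
#' @param config Path to a YAML file, or a list.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(config = list()) {
  if (is.character(config)) {
    dc_assert(file.exists(config), "config file not found: %s", config,
              class = "dielcross_config_error")
    config <- yaml::read_yaml(config)
  }
  dc_assert(is.list(config), "`config` must be a list or a YAML path",
            class = "dielcross_config_error")
  out <- utils::modifyList(default_run_config(), config)
  bad <- setdiff(out$stages, PIPELINE_STAGES)
  if (length(bad))
    dc_stop("unknown stage(s): %s", paste(bad, collapse = ", "),
            class = "dielcross_config_error")
  out$sim$seed <- out$sim$seed %||% out$seed
  class(out) <- "run_config"
  out
}

#' Run the crosstalk pipeline
#'
#' Executes the enabled stages in dependency order on synthetic data
#' generated from the configuration, writing every intermediate table, a
#' log, and a manifest (package version, seeds, parameters, output
#' checksums) into `out_dir`. A rerun with an identical configuration
#' reproduces identical output tables. A stage failure aborts with the
#' failing stage named; outputs of completed stages are retained.
#'
#' @param config A `run_config`, list, or YAML path
#'   (see [load_run_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else
    load_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    writeLines(msg, log_con)
    message(msg)
  }
  enabled <- function(st) st %in% cfg$stages
  state <- list(out_dir = out_dir)
  outputs <- character(0)
  need <- function(obj, stage, upstream) {
    if (is.null(obj))
      dc_stop("stage '%s' needs the '%s' stage (disabled and no cached input)",
              stage, upstream, class = "dielcross_config_error")
    obj
  }
  run_stage <- function(stage, fn) {
    if (!enabled(stage)) {
      say("stage %s: skipped", stage)
      return(invisible(NULL))
    }
    say("stage %s: running", stage)
    tryCatch(fn(), error = function(e) {
      dc_stop("stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }

  sim_cfg <- do.call(sim_config, cfg$sim)

  run_stage("simulate", function() {
    state$stress <<- generate_stress_series(sim_cfg)
    state$diurnal_sim <<- generate_diurnal_course(sim_cfg)
    outputs <<- c(outputs,
                  write_simulation(state$stress, out_dir, "stress"),
                  write_simulation(state$diurnal_sim, out_dir, "diurnal"))
    say("  %d genes, %d stress samples, %d diurnal samples",
        sim_cfg$n_genes, ncol(state$stress$matrix$values),
        ncol(state$diurnal_sim$matrix$values))
  })

  run_stage("fold_change", function() {
    st <- need(state$stress, "fold_change", "simulate")
    lm2 <- log2_normalize(st$matrix)
    state$fcp <<- fold_change(lm2, st$metadata)
    p <- file.path(out_dir, "fold_changes.tsv")
    write_fold_changes(state$fcp, p)
    outputs <<- c(outputs, p)
  })

  run_stage("classify", function() {
    fcp <- need(state$fcp, "classify", "fold_change")
    state$labels <<- classify_drought(
      fcp, k = cfg$classify$k, seed = cfg$seed,
      up_threshold = cfg$classify$up_threshold,
      down_threshold = cfg$classify$down_threshold)
    p <- file.path(out_dir, "response_labels.tsv")
    write_tsv(state$labels, p)
    outputs <<- c(outputs, p)
    cnt <- response_counts(state$labels)
    say("  %d up, %d down, %d unresponsive", cnt["n_up"], cnt["n_down"],
        cnt["n_none"])
  })

  run_stage("diurnal", function() {
    ds <- need(state$diurnal_sim, "diurnal", "simulate")
    lm2 <- log2_normalize(ds$matrix)
    state$calls <<- call_diurnal(lm2, ds$metadata, k = cfg$diurnal$k,
                                 seed = cfg$seed,
                                 r2_threshold = cfg$diurnal$r2_threshold)
    p <- file.path(out_dir, "diurnal_calls.tsv")
    write_tsv(as.data.frame(state$calls), p)
    outputs <<- c(outputs, p)
    say("  %d/%d genes called rhythmic", sum(state$calls$rhythmic),
        nrow(state$calls))
  })

  run_stage("crosstalk", function() {
    labels <- need(state$labels, "crosstalk", "classify")
    calls <- need(state$calls, "crosstalk", "diurnal")
    state$crosstalk <<- crosstalk_summary(labels, calls)
    p <- file.path(out_dir, "crosstalk_summary.tsv")
    write_crosstalk_summary(state$crosstalk, p)
    outputs <<- c(outputs, p)
    say("  up: %s%% diurnal; down: %s%% diurnal",
        format(state$crosstalk$up$pct_diurnal),
        format(state$crosstalk$down$pct_diurnal))
  })

  run_stage("enrich", function() {
    labels <- need(state$labels, "enrich", "classify")
    calls <- need(state$calls, "enrich", "diurnal")
    ann <- generate_annotations(sim_cfg, n_terms = cfg$enrich$n_terms,
                                planted_term_fold = cfg$enrich$planted_term_fold,
                                term_size_range = cfg$enrich$term_size_range)
    pa <- file.path(out_dir, "annotations.tsv")
    write_annotations(ann, pa)
    rhythmic_ids <- calls$gene_id[calls$rhythmic]
    query <- intersect(labels$gene_id[labels$drought_class == "up"],
                       rhythmic_ids)
    state$enrichment <<- enrich(query, ann,
                                background = labels$gene_id,
                                min_fold = cfg$enrich$min_fold,
                                alpha = cfg$enrich$alpha)
    p <- file.path(out_dir, "enrichment.tsv")
    write_tsv(state$enrichment, p)
    outputs <<- c(outputs, pa, p)
    say("  %d terms tested, %d pass", nrow(state$enrichment),
        sum(state$enrichment$passes))
  })

  run_stage("network", function() {
    gi <- generate_interactions(sim_cfg,
                                n_pathway_genes = cfg$network$n_pathway_genes,
                                n_partners = cfg$network$n_partners)
    net <- build_network(unique(gi$interactions$gene_a), gi$interactions,
                         expression = gi$expression,
                         labels = state$labels, calls = state$calls,
                         pcc_threshold = cfg$network$pcc_threshold)
    state$network <<- net
    outputs <<- c(outputs,
                  export_network(net, out_dir, "sif"),
                  export_network(net, out_dir, "graphml"))
    say("  %d nodes, %d edges (%d high-PCC)", nrow(net$nodes),
        nrow(net$edges), sum(net$edges$high_pcc))
  })

  manifest <- list(
    package = "dielcross",
    version = as.character(utils::packageVersion("dielcross")),
    seed = cfg$seed,
    stages = cfg$stages,
    parameters = cfg[c("sim", "classify", "diurnal", "enrich", "network")],
    outputs = as.list(tools::md5sum(sort(unname(outputs)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("wrote manifest with %d output file(s)", length(outputs))
  invisible(c(state, list(manifest = manifest)))
}

#' Validate pipeline inputs for consistency
#'
#' Reporting operation: checks matrix/metadata agreement, clock-hour
#' validity, phase-window coverage, and annotation/query containment, and
#' returns a machine-readable issue table (empty when everything is
#' consistent) instead of raising errors.
#'
#' @param em Optional `expr_matrix`.
#' @param metadata Optional sample-metadata table.
#' @param annotations Optional annotation table (`gene_id`, `term_id`).
#' @param query Optional query gene set.
#' @param windows Phase windows to check coverage against.
#' @return Data frame with columns `code` and `message`, one row per
#'   detected issue.
#' @export
validate_inputs <- function(em = NULL, metadata = NULL, annotations = NULL,
                            query = NULL, windows = phase_windows()) {
  issues <- list()
  add <- function(code, fmt, ...)
    issues[[length(issues) + 1L]] <<- data.frame(
      code = code, message = sprintf(fmt, ...), stringsAsFactors = FALSE)
  if (!is.null(em) && !is.null(metadata)) {
    miss <- setdiff(sample_ids(em), metadata$sample_id)
    if (length(miss))
      add("missing_metadata", "%d sample(s) lack metadata: %s",
          length(miss), paste(utils::head(miss, 5L), collapse = ", "))
    extra <- setdiff(metadata$sample_id, sample_ids(em))
    if (length(extra))
      add("orphan_metadata", "%d metadata row(s) match no sample",
          length(extra))
  }
  if (!is.null(metadata) && "hour" %in% names(metadata)) {
    h <- metadata$hour[!is.na(metadata$hour)]
    bad <- h[h %% 2 != 0 | h < 0 | h > 22]
    if (length(bad))
      add("bad_hour", "invalid clock hour(s): %s",
          paste(unique(bad), collapse = ", "))
    good <- setdiff(h, bad)
    uncovered <- setdiff(unique(good %% 24), unlist(windows))
    if (length(uncovered))
      add("uncovered_hour", "hour(s) outside every phase window: %s",
          paste(uncovered, collapse = ", "))
  }
  if (!is.null(annotations) && !is.null(em)) {
    out <- setdiff(unique(annotations$gene_id), gene_ids(em))
    if (length(out))
      add("annotation_outside_background",
          "%d annotated gene(s) absent from the matrix", length(out))
  }
  if (!is.null(query)) {
    bg <- if (!is.null(em)) gene_ids(em) else
      unique(annotations$gene_id %||% character(0))
    out <- setdiff(query, bg)
    if (length(out))
      add("query_outside_background",
          "%d query gene(s) absent from the background", length(out))
  }
  if (length(issues) == 0L)
    return(data.frame(code = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
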