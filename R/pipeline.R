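# The umbrella pipeline: simulate (optional) -> migration-call ->
# secretome-screen -> association screen -> candidate selection ->
# signature scoring, with a run manifest and per-stage staleness
# skipping. All randomness flows from the config seed; no stage reads
# the clock or ambient entropy for data generation.

#' Pipeline configuration
#'
#' Analysis thresholds with the defaults the method prescribes.
#'
#' @param seed master seed for the simulation stage.
#' @param ratio_cutoff donor-QC boundary (default 2.5).
#' @param sd_multiplier induction SD multiplier (default 2).
#' @param alpha significance threshold (default 0.05).
#' @param majority_threshold presence-contrast majority (default 0.5).
#' @param fdr_family `"per_subset"` or `"global"`.
#' @param donor_pooling `"mean"` or `"separate"`.
#' @param anchor_subset selection anchor (default `"cDC1"`).
#' @param lod_policy below-LOD substitution (`"lod"` or `"half_lod"`).
#'
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ratio_cutoff = 2.5,
                            sd_multiplier = 2, alpha = 0.05,
                            majority_threshold = 0.5,
                            fdr_family = c("per_subset", "global"),
                            donor_pooling = c("mean", "separate"),
                            anchor_subset = "cDC1",
                            lod_policy = c("lod", "half_lod")) {
  if (alpha <= 0 || alpha > 1) stop("config error: alpha outside (0, 1]")
  if (ratio_cutoff < 0) stop("config error: negative ratio_cutoff")
  if (sd_multiplier < 0) stop("config error: negative sd_multiplier")
  if (majority_threshold < 0 || majority_threshold >= 1)
    stop("config error: majority_threshold outside [0, 1)")
  structure(list(seed = as.integer(seed), ratio_cutoff = ratio_cutoff,
                 sd_multiplier = sd_multiplier, alpha = alpha,
                 majority_threshold = majority_threshold,
                 fdr_family = match.arg(fdr_family),
                 donor_pooling = match.arg(donor_pooling),
                 anchor_subset = anchor_subset,
                 lod_policy = match.arg(lod_policy)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are a config error; omitted keys take the
#' [pipeline_config()] defaults.
#'
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("config error in ", path, ": unknown key(s) ",
         paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write simulated datasets to a directory
#'
#' Materializes one simulation as the pipeline's on-disk inputs:
#' `wells.csv`, `meta.csv`, `npx.csv`, `lod.csv`, `expr.csv`,
#' `labels.csv`, `signatures.gmt`, `composites.tsv` and `truth.json`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
simulate_to_dir <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sec <- simulate_secretome(config)
  mig <- simulate_migration(config, sec$truth)
  expr <- simulate_expression(config)
  p <- function(f) file.path(out_dir, f)
  .write_table(mig$wells, p("wells.csv"))
  .write_table(mig$meta, p("meta.csv"))
  write_npx(sec$secretome, p("npx.csv"), p("lod.csv"))
  write_expression(expr$values, p("expr.csv"))
  .write_table(data.frame(sample_id = names(expr$labels),
                          label = unname(expr$labels),
                          stringsAsFactors = FALSE), p("labels.csv"))
  write_gmt(expr$signatures, p("signatures.gmt"))
  write_tsv(expr$composites, p("composites.tsv"))
  truth <- list(
    planted_chemokines = sec$truth$planted,
    protein_classes = as.list(sec$truth$classes),
    stromal_activity = as.list(sec$truth$stromal_activity),
    shifted_signatures = expr$truth$shifted,
    flat_signatures = expr$truth$flat,
    seed = config$seed)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

.stage_fresh <- function(out_file, in_files) {
  file.exists(out_file) &&
    all(file.exists(in_files)) &&
    file.mtime(out_file) >= max(file.mtime(in_files))
}

#' Run the full analysis pipeline on a data directory
#'
#' Stages: migration-call -> secretome presence contrast -> association
#' screen -> candidate selection -> signature scoring and response
#' comparison. Each stage writes a TSV under `out_dir` and is skipped
#' when its output is newer than all of its inputs (`force = TRUE`
#' reruns everything). A `manifest.json` records package version,
#' configuration and input hashes.
#'
#' @param data_dir directory holding the input files (the
#'   [simulate_to_dir()] layout).
#' @param out_dir result directory (created if absent).
#' @param config a [pipeline_config()].
#' @param force rerun stages even when outputs are fresh.
#' @param quiet suppress per-stage messages.
#'
#' @return Invisibly, a list with the in-memory stage results: `calls`,
#'   `contrasts`, `associations`, `selection`, `scores`,
#'   `response_tests`.
#' @export
run_pipeline <- function(data_dir, out_dir, config = pipeline_config(),
                         force = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ip <- function(f) file.path(data_dir, f)
  op <- function(f) file.path(out_dir, f)
  say <- function(...) if (!quiet) message(...)

  # stage 1: migration calls
  calls_f <- op("migration_calls.tsv")
  if (force || !.stage_fresh(calls_f, c(ip("wells.csv"), ip("meta.csv")))) {
    say("stage migration-call")
    wells <- read_wells(ip("wells.csv"))
    meta <- read_attractant_meta(ip("meta.csv"))
    calls <- summarize_experiment(wells, meta,
                                  ratio_cutoff = config$ratio_cutoff,
                                  sd_mult = config$sd_multiplier,
                                  donor_pooling = config$donor_pooling)
    write_tsv(calls, calls_f)
  } else {
    say("stage migration-call: up to date")
    calls <- read_tsv(calls_f)
  }

  # stage 2: presence contrast
  contrast_f <- op("presence_contrast.tsv")
  sec <- read_npx(ip("npx.csv"), ip("lod.csv"))
  if (force || !.stage_fresh(contrast_f, c(ip("npx.csv"), ip("lod.csv")))) {
    say("stage secretome-screen")
    contrasts <- presence_contrast(
      sec, majority_threshold = config$majority_threshold)
    write_tsv(contrasts, contrast_f)
  } else {
    say("stage secretome-screen: up to date")
    contrasts <- read_tsv(contrast_f)
  }

  # stage 3: association screen
  assoc_f <- op("associations.tsv")
  if (force || !.stage_fresh(assoc_f, c(calls_f, ip("npx.csv")))) {
    say("stage screen")
    mig <- migration_count_matrix(calls)
    associations <- screen_associations(
      mig, sec, alpha = config$alpha, fdr_family = config$fdr_family,
      lod_policy = config$lod_policy)
    write_tsv(associations, assoc_f)
  } else {
    say("stage screen: up to date")
    associations <- read_tsv(assoc_f)
  }

  # stage 4: candidate selection
  cand_f <- op("candidates.tsv")
  say("stage select")
  selection <- select_candidates(associations, contrasts,
                                 anchor_subset = config$anchor_subset)
  write_tsv(data.frame(protein = selection$candidates,
                       stringsAsFactors = FALSE), cand_f)

  # stage 5: signature scoring + response comparison
  scores_f <- op("signature_scores.tsv")
  resp_f <- op("signature_response.tsv")
  expr_in <- c(ip("expr.csv"), ip("signatures.gmt"), ip("composites.tsv"),
               ip("labels.csv"))
  if (all(file.exists(expr_in))) {
    if (force || !.stage_fresh(resp_f, expr_in)) {
      say("stage signature-score")
      values <- read_expression(ip("expr.csv"))
      sigs <- resolve_signatures(read_gmt(ip("signatures.gmt")),
                                 read_tsv(ip("composites.tsv")))
      labels <- read_labels(ip("labels.csv"))
      scores <- score_signatures(values, sigs)
      response_tests <- compare_response(scores, labels)
      write_tsv(scores, scores_f)
      write_tsv(response_tests, resp_f)
    } else {
      say("stage signature-score: up to date")
      scores <- read_tsv(scores_f)
      response_tests <- read_tsv(resp_f)
    }
  } else {
    scores <- NULL
    response_tests <- NULL
  }

  manifest <- list(
    package = "chemoscreen",
    version = as.character(utils::packageVersion("chemoscreen")),
    config = unclass(config),
    inputs = basename(Sys.glob(file.path(data_dir, "*"))))
  jsonlite::write_json(manifest, op("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(calls = calls, contrasts = contrasts,
                 associations = associations, selection = selection,
                 scores = scores, response_tests = response_tests))
}
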