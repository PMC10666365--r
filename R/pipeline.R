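#' Run the full network-to-intervention pipeline
#'
#' Orchestrates the stages in order: read inputs, enumerate three-node
#' feedback loops, compute topology, featurize and score motifs under
#' every weighting scenario, select the top-k per scenario, assemble the
#' core network (motif union + receptors + markers), infer the calibrated
#' Boolean model, and run the perturbation screens. Fails fast naming the
#' stage on any error; writes result tables and a reproducibility
#' manifest to `outdir`.
#'
#' @param config Either a named list or a path to a YAML file with
#'   entries `network` (SIF path), `fc` (TSV path), `annotations` (TSV
#'   path), `receptors` (character vector or path to a one-id-per-line
#'   file), optional `markers` (4 ids, [emt_markers()] order), optional
#'   `scenarios` (YAML/JSON path; default bundled grid), optional
#'   `top_k` (default 10), optional `max_intervention_size` (default 1).
#' @param outdir Output directory, created if needed.
#' @return Invisibly, a list with every stage's in-memory result
#'   (`motifs`, `ranking`, `selection`, `core`, `model`, `calibration`,
#'   `screen`, `robustness`, `minimal`, `manifest`).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  need <- c("network", "fc", "annotations", "receptors")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop("config is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (f in c("network", "fc", "annotations")) {
    if (!file.exists(config[[f]])) {
      stop("input file not found (", f, "): ", config[[f]], call. = FALSE)
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  receptors <- config$receptors
  if (length(receptors) == 1L && file.exists(receptors)) {
    receptors <- readLines(receptors, warn = FALSE)
    receptors <- receptors[nzchar(trimws(receptors))]
  }
  markers <- if (is.null(config$markers)) emt_markers() else
    validate_markers(config$markers)
  top_k <- config$top_k %||% 10

  full <- stage("load", read_signed_network(config$network))
  fc <- stage("load", read_fold_changes(config$fc))
  annot <- stage("load", read_annotations(config$annotations))
  scenarios <- stage("load", read_weight_scenarios(config$scenarios))

  motifs <- stage("motifs", enumerate_feedback_loops(full))
  message("motifs: ", nrow(motifs), " three-node feedback loops")
  topo <- stage("topology", compute_topology(full))
  features <- stage("rank", featurize_motifs(motifs, topo, annot, fc))
  ranking <- stage("rank", score_motifs(features, scenarios))
  selection <- stage("rank", select_top_motifs(ranking, k = top_k))
  message("rank: ", length(selection$unique_motifs),
          " unique motifs from ", nrow(selection$selected), " selections")

  core <- stage("core", assemble_core(
    motifs[motifs$motif_id %in% selection$unique_motifs, ],
    full, receptors, markers))
  message("core: ", nrow(core$nodes), " nodes, ", nrow(core$edges),
          " edges")

  model <- stage("model", infer_gates(core, fc))
  message("model: ",
          sum(model$calibration$status == "unresolved"),
          " unresolved gate(s)")
  calibration <- stage("model", validate_calibration(model, fc))

  screen <- stage("screen", single_screen(model))
  robust <- stage("screen", robustness_analysis(model))
  minimal <- stage("screen", find_minimal_interventions(
    model, max_size = config$max_intervention_size %||% 1))
  message("screen: ", nrow(screen), " single interventions; fragile: ",
          paste(robust$fragile_nodes, collapse = ", "))

  w <- function(x, name) readr::write_tsv(x, file.path(outdir, name))
  w(motifs, "motifs.tsv")
  w(ranking, "ranking.tsv")
  w(selection$selected, "selected_motifs.tsv")
  write_signed_network(core, file.path(outdir, "core.sif"))
  jsonlite::write_json(
    stats::setNames(as.list(core$layers$layer), core$layers$id),
    file.path(outdir, "layers.json"), auto_unbox = TRUE)
  write_boolean_model(model, file.path(outdir, "model.bnet"))
  w(model$calibration, "gate_report.tsv")
  w(calibration, "calibration.tsv")
  w(screen, "screen_single.tsv")
  w(robust$details, "robustness.tsv")
  w(minimal, "minimal_interventions.tsv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("melanocore")),
    config = config,
    input_md5 = as.list(tools::md5sum(
      vapply(c("network", "fc", "annotations"), function(f)
        config[[f]], ""))),
    counts = list(
      motifs = nrow(motifs), unique_selected =
        length(selection$unique_motifs),
      core_nodes = nrow(core$nodes), core_edges = nrow(core$edges),
      unresolved_gates = sum(model$calibration$status == "unresolved"),
      screen_rows = nrow(screen)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(motifs = motifs, ranking = ranking,
                 selection = selection, core = core, model = model,
                 calibration = calibration, screen = screen,
                 robustness = robust, minimal = minimal,
                 manifest = manifest))
}
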