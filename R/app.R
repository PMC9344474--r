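# Orchestration: configuration handling and the two top-level pipelines
# (block-library building and whole-structure prediction), mirroring the
# command-line interface in inst/cli/dnahydro.

#' Run configuration
#'
#' Assembles the effective configuration from defaults and overrides.
#' Unknown keys are rejected; the effective configuration is attached to
#' results so runs are reproducible.
#'
#' @param ... overrides, or a single list/YAML file path via `config`.
#' @param config optional list of overrides or path to a YAML file.
#' @return list of class `dnahydro_config` with entries `curation`,
#'   `association`, `density`, `classifier_mode`, `allow_unreliable`,
#'   `use_symmetry`, `model_number`.
#' @export
run_config <- function(..., config = NULL) {
  overrides <- list(...)
  if (!is.null(config)) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    overrides <- utils::modifyList(config, overrides)
  }
  defaults <- list(
    curation = list(), association = list(), density = list(),
    classifier_mode = "lookup", allow_unreliable = FALSE,
    use_symmetry = TRUE, model_number = 1L)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, overrides)
  cfg$curation <- do.call(curation_params, cfg$curation)
  cfg$association <- do.call(assoc_params, cfg$association)
  cfg$density <- do.call(density_params, cfg$density)
  structure(cfg, class = "dnahydro_config")
}

#' Build a hydrated-block library from structures
#'
#' Executes the corpus half of the workflow: read structures, curate chains
#' (when a chain table is supplied or derivable), split into steps, classify,
#' associate waters at the association cutoff (including symmetry mates when
#' available and enabled), and assemble one hydrated block per
#' conformer/sequence combination.
#'
#' @param structure_paths character vector of PDB/mmCIF files.
#' @param classifier a `dnahydro_classifier` (assignment or centroid table)
#'   or path to its TSV.
#' @param out_dir optional directory; the library and summary are written
#'   there.
#' @param config a `dnahydro_config`.
#' @param curate apply the curation filters to chains before extraction
#'   (skipped when FALSE, e.g. for pre-curated synthetic corpora).
#' @return list with `library` (a `dnahydro_library`), `summary`
#'   (data.frame), `chain_table` and `config`.
#' @export
run_build_blocks <- function(structure_paths, classifier, out_dir = NULL,
                             config = run_config(), curate = TRUE) {
  if (length(structure_paths) == 0L) stop("empty input structure list")
  missing <- structure_paths[!file.exists(structure_paths)]
  if (length(missing) > 0L) stop("input not readable: ", missing[1L])
  if (is.character(classifier)) classifier <- read_classifier_table(classifier)

  models <- lapply(structure_paths, read_structure,
                   model_number = config$model_number)
  entries <- list()
  hydrated <- list()
  n_chains <- 0L
  for (m in models) {
    expansion <- NULL
    if (config$use_symmetry && !is.null(m$cell) && !is.null(m$symops)) {
      expansion <- expand_symmetry(m, config$association$d_assoc, "waters")
    }
    waters <- extract_waters(m, expansion)
    chains <- unique(m$atoms$chain_id[!m$atoms$is_water &
                                        is_dna_residue(m$atoms$residue_name)])
    for (ch in chains) {
      res <- residues_from_model(m, ch)
      if (length(res) == 0L) next
      n_chains <- n_chains + 1L
      wpn <- waters_per_nucleotide(m, ch, expansion,
                                   config$curation$water_contact_cutoff)
      entries[[length(entries) + 1L]] <- chain_table(
        m$structure_id, ch, m$resolution %||% NA_real_,
        paste(vapply(res, `[[`, character(1L), "one_letter"), collapse = ""),
        wpn)
      steps <- extract_steps(res, source = list(structure_id = m$structure_id,
                                                chain_id = ch))
      for (s in steps) {
        s$ntc <- assign_ntc(s, classifier)
        hydrated[[length(hydrated) + 1L]] <- list(
          step = s, waters = associate_waters(s, waters, config$association),
          key = paste(m$structure_id, ch))
      }
    }
  }
  if (n_chains == 0L) stop("no DNA chains found in the input structures")
  entries <- do.call(rbind, entries)

  if (curate) {
    reps <- curate_chains(entries, config$curation)
    keep_keys <- paste(reps$structure_id, reps$chain_id)
    hydrated <- Filter(function(h) h$key %in% keep_keys, hydrated)
    if (length(hydrated) == 0L) {
      att <- attr(reps, "attrition")
      stop("no chains pass the curation filters (input ", att[["input"]],
           ", after filters ", att[["filtered"]], ")")
    }
  }
  hydrated <- lapply(hydrated, function(h) h[c("step", "waters")])
  library <- build_block_library(hydrated, params = config$association)
  summary <- library_summary(library)
  if (!is.null(out_dir)) {
    save_block_library(library, out_dir)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    write_chain_table(entries, file.path(out_dir, "chains.csv"))
  }
  list(library = library, summary = summary, chain_table = entries,
       config = config)
}

#' Predict hydration for a target structure file
#'
#' Runs the prediction half of the workflow and optionally the evaluation
#' against the target's own crystallographic waters (including symmetry
#' mates when cell information is present and symmetry is enabled).
#'
#' @param target_path PDB/mmCIF file of the target DNA structure.
#' @param library a `dnahydro_library` or path to a saved library directory.
#' @param classifier a `dnahydro_classifier` or TSV path.
#' @param out_dir optional output directory: writes base/backbone MRC maps,
#'   a hydration-site PDB and TSV, and (with evaluation) a JSON report and
#'   TSV histogram.
#' @param config a `dnahydro_config`.
#' @param evaluate compare predicted sites with the target's waters.
#' @return list with `prediction` (`dnahydro_prediction`), `evaluation`
#'   (`dnahydro_evaluation` or NULL) and `config`.
#' @export
run_predict <- function(target_path, library, classifier, out_dir = NULL,
                        config = run_config(), evaluate = FALSE) {
  if (is.character(library)) library <- load_block_library(library)
  if (is.character(classifier)) classifier <- read_classifier_table(classifier)
  target <- read_structure(target_path, model_number = config$model_number)
  prediction <- predict_hydration(
    target, library, classifier, dparams = config$density,
    aparams = config$association,
    allow_unreliable = config$allow_unreliable)
  evaluation <- NULL
  if (evaluate) {
    expansion <- NULL
    if (config$use_symmetry && !is.null(target$cell) &&
        !is.null(target$symops)) {
      expansion <- expand_symmetry(target, config$association$d_assoc, "waters")
    }
    observed <- extract_waters(target, expansion)
    evaluation <- evaluate_prediction(prediction, observed)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_density_map(prediction$base_grid,
                      file.path(out_dir, "base_density.mrc"))
    write_density_map(prediction$backbone_grid,
                      file.path(out_dir, "backbone_density.mrc"))
    sites <- predicted_sites(prediction)
    write_hydration_sites(sites, file.path(out_dir, "hydration_sites.pdb"))
    utils::write.table(sites, file.path(out_dir, "hydration_sites.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(prediction$per_step_log,
                       file.path(out_dir, "step_log.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(evaluation)) {
      jsonlite::write_json(
        list(frac_within_1A = as.list(evaluation$frac_within_1A),
             n_sites = nrow(evaluation$distances)),
        file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
      utils::write.table(evaluation$histogram,
                         file.path(out_dir, "evaluation_histogram.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  list(prediction = prediction, evaluation = evaluation, config = config)
}
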