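# End-to-end triage funnel:
#   generate/ingest -> label -> descriptors -> remove_useless -> select ->
#   tune FN cost -> CV evaluation -> out-of-fold prediction -> consensus ->
#   SMARTS filters -> Lipinski -> fragment enrichment
# with a JSON manifest for reproducibility.

#' Build and validate a pipeline run configuration
#'
#' @param synthetic a [librarySpec()] for a generated library, or `NULL`
#'   when reading files.
#' @param smiles_path,assay_path input files (`SMILES<TAB>id` and
#'   `compound_id,percent_inhibition` CSV); ignored when `synthetic` given.
#' @param out_dir output directory (created if missing).
#' @param families learner families to train.
#' @param fp_ceiling false-positive-rate ceiling for cost tuning.
#' @param folds CV folds (>= 2).
#' @param seed integer seed (mandatory).
#' @param select run CFS best-first descriptor selection (default TRUE).
#' @param filter_paths optional named character vector of filter files;
#'   default bundled sets.
#' @param dictionary_path optional fragment dictionary file; default bundled.
#' @param consensus_before_filters apply SMARTS filters to the consensus
#'   active set (TRUE, default) or to each model's actives before consensus.
#' @return validated config (list, class `triageConfig`).
#' @export
runConfig <- function(synthetic = NULL, smiles_path = NULL, assay_path = NULL,
                      out_dir = tempfile("triage_run_"),
                      families = c("naive_bayes", "random_forest",
                                   "svm_smo_like"),
                      fp_ceiling = 0.2, folds = 5, seed,
                      select = TRUE, filter_paths = NULL,
                      dictionary_path = NULL,
                      consensus_before_filters = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  if (folds < 2) stop("folds must be >= 2")
  if (!(fp_ceiling > 0 && fp_ceiling < 1)) stop("fp_ceiling must be in (0,1)")
  families <- match.arg(families, .learnerFamilies, several.ok = TRUE)
  if (is.null(synthetic)) {
    if (is.null(smiles_path) || is.null(assay_path))
      stop("either a synthetic librarySpec or smiles_path + assay_path")
    for (p in c(smiles_path, assay_path, filter_paths, dictionary_path))
      if (!file.exists(p)) stop("input file does not exist: ", p)
  } else stopifnot(inherits(synthetic, "librarySpec"))
  structure(list(synthetic = synthetic, smiles_path = smiles_path,
                 assay_path = assay_path, out_dir = out_dir,
                 families = families, fp_ceiling = fp_ceiling,
                 folds = folds, seed = as.integer(seed), select = select,
                 filter_paths = filter_paths,
                 dictionary_path = dictionary_path,
                 consensus_before_filters = consensus_before_filters),
            class = "triageConfig")
}

#' Read a pipeline configuration from JSON
#'
#' Recognised keys mirror [runConfig()]; a `"synthetic"` object holds the
#' [librarySpec()] fields (`n_compounds`, `active_fraction`,
#' `enriched_fragments` as name->multiplier map, `noise_sd`, `seed`).
#' @param path JSON file.
#' @return validated config.
#' @export
readRunConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- NULL
  if (!is.null(j$synthetic)) {
    s <- j$synthetic
    syn <- librarySpec(n_compounds = s$n_compounds,
                       active_fraction = s$active_fraction %||% 0.0025,
                       enriched_fragments = unlist(s$enriched_fragments %||%
                                                     list()),
                       noise_sd = s$noise_sd %||% 5,
                       seed = s$seed %||% j$seed)
  }
  runConfig(synthetic = syn, smiles_path = j$smiles_path,
            assay_path = j$assay_path,
            out_dir = j$out_dir %||% tempfile("triage_run_"),
            families = j$families %||% .learnerFamilies,
            fp_ceiling = j$fp_ceiling %||% 0.2, folds = j$folds %||% 5,
            seed = j$seed, select = j$select %||% TRUE,
            filter_paths = j$filter_paths, dictionary_path = j$dictionary_path,
            consensus_before_filters = j$consensus_before_filters %||% TRUE)
}

#' Run the full triage pipeline
#'
#' Executes the funnel stages in order, writes per-stage outputs and a
#' manifest (`manifest.json`: seed, input hashes, per-stage counts, chosen
#' costs) into the run directory. Re-running an identical config reproduces
#' identical outputs.
#'
#' @param config a [runConfig()].
#' @return invisibly, a list with the run directory, the manifest, and the
#'   main in-memory results (models, confusion matrices, consensus ids,
#'   filter report, enrichment table).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "triageConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("BioassayTriage")),
                   stages = list())

  # ingest / generate
  if (!is.null(config$synthetic)) {
    lib <- generateLibrary(config$synthetic)
    compounds <- lib$compounds; assay <- lib$assay
    manifest$input <- list(type = "synthetic",
                           spec = config$synthetic[setdiff(names(config$synthetic),
                                                           "enriched_fragments")],
                           enriched_fragments = as.list(config$synthetic$enriched_fragments))
  } else {
    compounds <- readSmilesFile(config$smiles_path)
    assay <- readAssayCsv(config$assay_path)
    assay <- assay[match(compounds@ids, assay$compound_id), ]
    manifest$input <- list(type = "files",
                           smiles_md5 = unname(tools::md5sum(config$smiles_path)),
                           assay_md5 = unname(tools::md5sum(config$assay_path)))
  }
  writeSmilesFile(compounds, out("library.smi"))
  manifest$stages$compounds <- length(compounds)

  # label
  lab <- writeLabeledAssay(assay, out("assay_labeled.csv"))
  labels <- lab$activity_class
  manifest$stages$actives <- sum(labels == "active")
  manifest$stages$inactives <- sum(labels == "inactive")

  # descriptors + redundancy removal
  table <- descriptorTable(compounds)
  manifest$stages$descriptors <- dim(table)[2]
  table2 <- removeUseless(table)
  manifest$stages$descriptors_informative <- dim(table2)[2]
  writeDescriptorCsv(table2, out("descriptors.csv"))

  # selection
  if (config$select) {
    sel <- bestFirstSearch(table2, labels)
    selected <- sel$subset
    if (length(selected) == 0) selected <- descriptorSchema(table2)$name
    writeSelectedDescriptors(selected, out("selected_descriptors.txt"))
    modelTable <- table2[, selected]
    manifest$stages$descriptors_selected <- length(selected)
  } else modelTable <- table2

  # cost tuning + CV evaluation + out-of-fold predictions
  tuned <- list(); cms <- list(); activeSets <- list(); aucs <- list()
  for (fam in config$families) {
    tn <- tuneFnCost(fam, modelTable, labels, fp_ceiling = config$fp_ceiling,
                     folds = config$folds, seed = config$seed)
    cv <- crossValidate(fam, modelTable, labels, folds = config$folds,
                        seed = config$seed, costFn = tn$c_fn)
    tuned[[fam]] <- tn
    cms[[fam]] <- cv$pooled
    activeSets[[fam]] <- compounds@ids[cv$classes == "active"]
    roc <- rocAuc(labels, cv$scores)
    aucs[[fam]] <- roc$auc
    utils::write.csv(roc$points, out(paste0("roc_", fam, ".csv")),
                     row.names = FALSE)
  }
  writeMetricTable(cms, out("metrics.tsv"))
  manifest$stages$c_fn <- lapply(tuned, `[[`, "c_fn")
  manifest$stages$cv_fp_rate <- lapply(tuned, `[[`, "fp_rate")
  manifest$stages$auc <- aucs
  manifest$stages$predicted_active <- lapply(activeSets, length)

  # consensus then structural filtering (or the reverse)
  filterSets <- if (is.null(config$filter_paths)) defaultFilterSets()
    else lapply(config$filter_paths, readFilterSet)
  if (config$consensus_before_filters) {
    consensus <- consensusActives(activeSets)
    filtered <- applyFilters(compounds[consensus], filterSets)
    passIds <- filtered$passOverall
  } else {
    perModel <- lapply(activeSets, function(ids)
      applyFilters(compounds[ids], filterSets)$passOverall)
    consensus <- consensusActives(perModel)
    filtered <- applyFilters(compounds[consensus], filterSets)
    passIds <- filtered$passOverall
  }
  writeLines(consensus, out("consensus_actives.txt"))
  writeFilterReport(filtered, out("filter_report.csv"),
                    out("filter_summary.json"))
  manifest$stages$consensus_active <- length(consensus)
  manifest$stages$smarts_pass <- length(passIds)

  # Lipinski on the surviving candidates
  lip <- if (length(passIds)) lipinskiCompounds(compounds[passIds])
    else data.frame()
  if (nrow(lip)) utils::write.csv(lip, out("lipinski.csv"), row.names = FALSE)
  manifest$stages$lipinski_pass <- if (nrow(lip)) sum(lip$pass) else 0L
  finalIds <- if (nrow(lip)) lip$compound_id[lip$pass] else character(0)
  if (length(finalIds))
    writeSmilesFile(compounds[finalIds], out("candidates.smi"))

  # fragment enrichment over the assay classes
  dict <- if (is.null(config$dictionary_path)) defaultFragmentDictionary()
    else readFragmentDictionary(config$dictionary_path)
  enrich <- enrichmentTable(compounds, labels, dict)
  writeEnrichmentCsv(enrich, out("enrichment.csv"))
  manifest$stages$enriched_fragments <- nrow(enrich)

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(dir = config$out_dir, manifest = manifest, tuned = tuned,
                 confusion = cms, auc = aucs, consensus = consensus,
                 smartsPass = passIds, lipinski = lip, enrichment = enrich,
                 labels = labels, compounds = compounds))
}
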