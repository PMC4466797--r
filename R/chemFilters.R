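# SMARTS structural-alert filtering and the Lipinski drug-likeness check.

#' Read a SMARTS filter file
#'
#' Plain text, one `name<TAB>SMARTS` pair per line, `#` comments allowed.
#' Every pattern must compile; a non-compiling SMARTS is a configuration
#' error naming the pattern.
#'
#' @param path file path.
#' @param name filter-set name; defaults to the file name without extension.
#' @return a [FilterSet-class].
#' @export
readFilterSet <- function(path, name = NULL) {
  tab <- readTsvFile(path, c("name", "smarts"))
  fs <- new("FilterSet", name = name %||% sub("\\.[^.]*$", "", basename(path)),
            patternNames = tab$name, smarts = tab$smarts)
  invisible(compileDictionary(fs@smarts, paste0(fs@name, ":", fs@patternNames)))
  fs
}

#' The bundled structural-alert filter sets
#'
#' Small demonstration subsets of five alert families in common virtual-
#' screening use (PAINS, Glaxo, Oprea, Pfizer-LINT and ALARM-NMR style).
#' They cover the canonical reactive/interference chemotypes of each family
#' but are not the full proprietary lists; load those with [readFilterSet()]
#' if you have them.
#'
#' @return named list of [FilterSet-class] objects.
#' @export
defaultFilterSets <- function() {
  dir <- system.file("extdata", "filters", package = "BioassayTriage",
                     mustWork = TRUE)
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  sets <- lapply(files, readFilterSet)
  stats::setNames(sets, vapply(sets, function(s) s@name, character(1)))
}

#' Apply structural-alert filter sets
#'
#' A compound fails a set if at least one of the set's patterns matches as a
#' substructure; it passes overall only if it matches no pattern in any set.
#' Per-set fail percentages are computed over all input compounds (so they
#' can sum to more than 100% across sets).
#'
#' @param compounds a [CompoundSet-class].
#' @param filterSets list of [FilterSet-class]; default the bundled sets.
#' @return list with `perCompound` (logical matrix compounds x sets, TRUE =
#'   fails that set), `passOverall` (character vector of passing ids),
#'   `setSummary` (data.frame `set`, `n_fail`, `pct_fail`).
#' @export
applyFilters <- function(compounds, filterSets = defaultFilterSets()) {
  stopifnot(is(compounds, "CompoundSet"), length(filterSets) >= 1)
  fails <- vapply(filterSets, function(fs) {
    m <- matchPatternMatrix(compounds, fs@smarts,
                            make.unique(fs@patternNames))
    rowSums(m) > 0
  }, logical(length(compounds)))
  fails <- matrix(fails, nrow = length(compounds),
                  dimnames = list(compounds@ids,
                                  vapply(filterSets, function(s) s@name,
                                         character(1))))
  n <- length(compounds)
  summary <- data.frame(set = colnames(fails),
                        n_fail = colSums(fails),
                        pct_fail = 100 * colSums(fails) / n,
                        row.names = NULL)
  list(perCompound = fails,
       passOverall = compounds@ids[rowSums(fails) == 0],
       setSummary = summary)
}

#' Lipinski rule-of-five check
#'
#' Violations: molecular weight > 500 g/mol, H-bond donors > 5, H-bond
#' acceptors > 10, logP > 5 (strict inequalities). Passes with zero
#' violations. Fractional acceptor counts are allowed.
#'
#' @param mw molecular weight (g/mol).
#' @param hbd H-bond donor count.
#' @param hba H-bond acceptor count (may be fractional).
#' @param logp estimated logP.
#' @return list with `pass` (logical) and `violations` (character vector).
#' @examples
#' lipinski(390.52, 2, 3.5, 3.93)
#' @export
lipinski <- function(mw, hbd, hba, logp) {
  stopifnot(is.finite(mw), is.finite(hbd), is.finite(hba), is.finite(logp))
  v <- c(if (mw > 500) "mw > 500",
         if (hbd > 5) "hbd > 5",
         if (hba > 10) "hba > 10",
         if (logp > 5) "logp > 5")
  list(pass = length(v) == 0, violations = v %||% character(0))
}

#' Lipinski check for a CompoundSet
#'
#' Uses the package's own property descriptors (mw, hbd, hba, logp).
#' @param compounds a [CompoundSet-class].
#' @return data.frame `compound_id`, `mw`, `hbd`, `hba`, `logp`, `pass`,
#'   `n_violations`.
#' @export
lipinskiCompounds <- function(compounds) {
  pr <- propertyDescriptors(compounds)
  res <- lapply(seq_len(nrow(pr)), function(i)
    lipinski(pr[i, "mw"], pr[i, "hbd"], pr[i, "hba"], pr[i, "logp"]))
  data.frame(compound_id = compounds@ids,
             mw = pr[, "mw"], hbd = pr[, "hbd"], hba = pr[, "hba"],
             logp = pr[, "logp"],
             pass = vapply(res, `[[`, logical(1), "pass"),
             n_violations = vapply(res, function(r) length(r$violations),
                                   integer(1)),
             row.names = NULL)
}

#' Write a filter report (CSV + JSON)
#' @param report result of [applyFilters()].
#' @param csvPath per-compound CSV path.
#' @param jsonPath per-set summary JSON path.
#' @export
writeFilterReport <- function(report, csvPath, jsonPath) {
  df <- data.frame(compound_id = rownames(report$perCompound),
                   report$perCompound,
                   pass_overall = rownames(report$perCompound) %in%
                     report$passOverall, row.names = NULL)
  utils::write.csv(df, csvPath, row.names = FALSE)
  jsonlite::write_json(report$setSummary, jsonPath, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
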