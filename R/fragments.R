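# Substructure-fragment fingerprints and class-frequency enrichment.

#' Read a fragment dictionary file
#'
#' File format: tab-separated `fragment_id<TAB>name<TAB>SMARTS`, `#` comment
#' lines allowed. A SMARTS field may contain several patterns joined by
#' `" && "`; such an entry matches a molecule only if every component pattern
#' matches somewhere in it (used e.g. for salts, where the cation and anion
#' live on different components and a single SMARTS cannot span them).
#'
#' @param path file path.
#' @return a [FragmentDictionary-class].
#' @export
readFragmentDictionary <- function(path) {
  tab <- readTsvFile(path, c("fragment_id", "name", "smarts"))
  dict <- new("FragmentDictionary", ids = tab$fragment_id,
              fragmentNames = tab$name, smarts = tab$smarts)
  checkDictionary(dict)
  dict
}

#' The bundled fragment dictionary
#'
#' A ~40-entry named-fragment dictionary (SubFP-style) covering common organic
#' functional groups, including Nitrate, Carboxylic acid, Michael acceptor,
#' Alkene, Anion, Salt and Vinylogous ester.
#'
#' @return a [FragmentDictionary-class].
#' @export
defaultFragmentDictionary <- function() {
  if (is.null(.obEnv$defaultDict)) {
    path <- system.file("extdata", "fragment_dictionary.tsv",
                        package = "BioassayTriage", mustWork = TRUE)
    .obEnv$defaultDict <- readFragmentDictionary(path)
  }
  .obEnv$defaultDict
}

# Compile every (possibly &&-joined) SMARTS entry; error on non-compiling
# patterns, naming them.
compileDictionary <- function(smarts, names) {
  lapply(seq_along(smarts), function(i) {
    parts <- trimws(strsplit(smarts[i], "&&", fixed = TRUE)[[1]])
    pats <- lapply(parts, obCompileSmarts)
    bad <- vapply(pats, is.null, logical(1))
    if (any(bad))
      stop("SMARTS does not compile for '", names[i], "': ",
           paste(parts[bad], collapse = " ; "))
    pats
  })
}

checkDictionary <- function(dict) {
  invisible(compileDictionary(dict@smarts, dict@fragmentNames))
}

# Presence matrix of &&-joined patterns over molecules (compounds x patterns).
matchPatternMatrix <- function(compounds, smarts, patternNames) {
  pats <- compileDictionary(smarts, patternNames)
  m <- vapply(pats, function(plist) {
    vapply(compounds@mols, function(mol) {
      all(vapply(plist, function(p) obMatchCount(p, mol) > 0L, logical(1)))
    }, logical(1))
  }, logical(length(compounds@mols)))
  m <- matrix(as.integer(m), nrow = length(compounds@mols),
              dimnames = list(compounds@ids, patternNames))
  m
}

#' Substructure fingerprint over a fragment dictionary
#'
#' @param compounds a [CompoundSet-class].
#' @param dictionary a [FragmentDictionary-class]; default the bundled one.
#' @return binary integer matrix, compounds x fragments (columns named by
#'   fragment id).
#' @examples
#' cs <- parseCompounds(c(aceticAcid = "CC(=O)O"))
#' fp <- fragmentFingerprint(cs)
#' fp[, "FR009"]  # carboxylic acid bit
#' @export
fragmentFingerprint <- function(compounds, dictionary = defaultFragmentDictionary()) {
  stopifnot(is(compounds, "CompoundSet"), is(dictionary, "FragmentDictionary"))
  matchPatternMatrix(compounds, dictionary@smarts, dictionary@ids)
}

#' Class frequency of a fragment
#'
#' The enrichment ratio
#' `(n_fragment_class * n_total) / (n_fragment_total * n_class)`:
#' 1 means the fragment is distributed across the class as in the whole
#' library, values above 1 mean over-representation in that class.
#'
#' @param nFragmentClass compounds of the class containing the fragment.
#' @param nClass class size.
#' @param nFragmentTotal compounds (any class) containing the fragment.
#' @param nTotal total compounds.
#' @return the ratio, or `NA_real_` when the fragment is absent from the data
#'   or the class is empty (undefined, reported as absent).
#' @examples
#' fragmentFrequency(5, 5, 5, 100)  # fragment exclusive to a 5-member class
#' @export
fragmentFrequency <- function(nFragmentClass, nClass, nFragmentTotal, nTotal) {
  if (nFragmentTotal <= 0 || nClass <= 0) return(NA_real_)
  stopifnot(nFragmentClass <= min(nClass, nFragmentTotal), nTotal >= nClass)
  (nFragmentClass * nTotal) / (nFragmentTotal * nClass)
}

#' Fragment enrichment between actives and inactives
#'
#' For every dictionary fragment: presence counts, the class frequency in the
#' active and the inactive class, and a two-sided Fisher exact p-value on the
#' 2x2 (fragment presence x class) table. Only fragments with `p < alpha` are
#' returned, sorted by active-class frequency (descending); use `alpha = Inf`
#' to keep every fragment.
#'
#' @param compounds a [CompoundSet-class].
#' @param labels `"active"`/`"inactive"` per compound.
#' @param dictionary a [FragmentDictionary-class].
#' @param alpha significance cutoff (default 0.01). Use `Inf` to disable.
#' @param adjust p-value adjustment: `"none"` (default) or `"BH"`
#'   (Benjamini-Hochberg); the cutoff is applied to the adjusted value.
#' @param fingerprint optional precomputed [fragmentFingerprint()] matrix.
#' @return data.frame with columns `fragment_id`, `name`,
#'   `n_fragment_active`, `n_fragment_inactive`, `n_fragment_total`,
#'   `n_active`, `n_inactive`, `n_total`, `freq_active`, `freq_inactive`,
#'   `p_value`.
#' @export
enrichmentTable <- function(compounds, labels,
                            dictionary = defaultFragmentDictionary(),
                            alpha = 0.01, adjust = c("none", "BH"),
                            fingerprint = NULL) {
  adjust <- match.arg(adjust)
  labels <- normalizeLabels(labels)
  stopifnot(length(labels) == length(compounds))
  nA <- sum(labels == "active"); nI <- sum(labels == "inactive")
  if (nA == 0 || nI == 0) stop("both classes must be non-empty")
  fp <- fingerprint %||% fragmentFingerprint(compounds, dictionary)
  n <- nrow(fp)
  stats <- lapply(seq_len(ncol(fp)), function(j) {
    inA <- sum(fp[labels == "active", j])
    inI <- sum(fp[labels == "inactive", j])
    tot <- inA + inI
    p <- stats::fisher.test(matrix(c(inA, nA - inA, inI, nI - inI), 2))$p.value
    data.frame(fragment_id = dictionary@ids[j],
               name = dictionary@fragmentNames[j],
               n_fragment_active = inA, n_fragment_inactive = inI,
               n_fragment_total = tot, n_active = nA, n_inactive = nI,
               n_total = n,
               freq_active = fragmentFrequency(inA, nA, tot, n),
               freq_inactive = fragmentFrequency(inI, nI, tot, n),
               p_value = p)
  })
  out <- do.call(rbind, stats)
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out <- out[!is.na(out$p_value) & out$p_value < alpha, , drop = FALSE]
  out <- out[order(-ifelse(is.na(out$freq_active), -Inf, out$freq_active),
                   out$fragment_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment report as CSV
#' @param table result of [enrichmentTable()].
#' @param path output file.
#' @export
writeEnrichmentCsv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
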