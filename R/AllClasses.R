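#' @import methods
NULL

#' CompoundSet: a set of small molecules
#'
#' Holds compound identifiers, their SMILES strings and parsed molecule
#' handles. Construct with [parseCompounds()]; the molecule handles are
#' session-local external pointers and are rebuilt on demand, so a
#' `CompoundSet` should be treated as an in-memory working object (persist the
#' SMILES, not the object).
#'
#' @slot ids character vector of unique compound identifiers.
#' @slot smiles character vector of SMILES, parallel to `ids`.
#' @slot mols list of OpenBabel molecule handles, parallel to `ids`.
#' @exportClass CompoundSet
setClass("CompoundSet",
  representation(ids = "character", smiles = "character", mols = "list"),
  validity = function(object) {
    if (length(object@ids) != length(object@smiles))
      return("ids and smiles must have equal length")
    if (length(object@mols) != length(object@ids))
      return("mols must be parallel to ids")
    if (anyDuplicated(object@ids)) return("compound ids must be unique")
    TRUE
  })

#' DescriptorTable: compound-by-descriptor numeric matrix with a typed schema
#'
#' @slot compoundIds character vector, one id per row.
#' @slot schema data.frame with columns `name`, `family`
#'   (pharmacophore/burden/property/fragment) and `dtype` (binary/continuous),
#'   one row per descriptor column.
#' @slot values numeric matrix, rows parallel to `compoundIds`, columns to
#'   `schema$name`.
#' @exportClass DescriptorTable
setClass("DescriptorTable",
  representation(compoundIds = "character", schema = "data.frame",
                 values = "matrix"),
  validity = function(object) {
    if (nrow(object@values) != length(object@compoundIds))
      return("row count must match compoundIds")
    if (ncol(object@values) != nrow(object@schema))
      return("column count must match schema rows")
    if (!all(c("name", "family", "dtype") %in% names(object@schema)))
      return("schema needs columns name, family, dtype")
    if (anyDuplicated(object@schema$name))
      return("duplicate descriptor names")
    if (!all(object@schema$dtype %in% c("binary", "continuous")))
      return("dtype must be binary or continuous")
    TRUE
  })

#' ConfusionMatrix: 2x2 classification counts
#'
#' @slot tp,tn,fp,fn non-negative integer counts.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(tp = "numeric", tn = "numeric", fp = "numeric",
                 fn = "numeric"),
  validity = function(object) {
    v <- c(object@tp, object@tn, object@fp, object@fn)
    if (any(v < 0) || any(v != round(v))) return("counts must be non-negative integers")
    TRUE
  })

#' CostModel: a fitted cost-sensitive classifier
#'
#' @slot family one of `"naive_bayes"`, `"random_forest"`, `"svm_smo_like"`.
#' @slot costFn false-negative cost (false-positive cost is fixed at 1).
#' @slot fit opaque fitted state (family-specific).
#' @slot schema training descriptor schema (data.frame as in
#'   [DescriptorTable-class]).
#' @slot seed integer seed used at fit time.
#' @exportClass CostModel
setClass("CostModel",
  representation(family = "character", costFn = "numeric", fit = "list",
                 schema = "data.frame", seed = "integer"),
  validity = function(object) {
    if (!object@family %in% c("naive_bayes", "random_forest", "svm_smo_like"))
      return("unknown learner family")
    if (object@costFn < 1) return("costFn must be >= 1")
    TRUE
  })

#' FilterSet: a named set of SMARTS structural alerts
#'
#' @slot name filter-set name (e.g. `"PAINS"`).
#' @slot patternNames names of the individual patterns.
#' @slot smarts SMARTS strings, parallel to `patternNames`.
#' @exportClass FilterSet
setClass("FilterSet",
  representation(name = "character", patternNames = "character",
                 smarts = "character"),
  validity = function(object) {
    if (length(object@patternNames) != length(object@smarts))
      return("patternNames and smarts must be parallel")
    if (anyDuplicated(object@patternNames))
      return("pattern names must be unique within a set")
    TRUE
  })

#' FragmentDictionary: named substructure SMARTS patterns
#'
#' @slot ids fragment identifiers (unique).
#' @slot fragmentNames human-readable fragment names.
#' @slot smarts SMARTS strings, parallel to `ids`.
#' @exportClass FragmentDictionary
setClass("FragmentDictionary",
  representation(ids = "character", fragmentNames = "character",
                 smarts = "character"),
  validity = function(object) {
    if (anyDuplicated(object@ids)) return("fragment ids must be unique")
    if (length(object@ids) != length(object@smarts) ||
        length(object@ids) != length(object@fragmentNames))
      return("ids, fragmentNames and smarts must be parallel")
    TRUE
  })

# ---- generics ----

#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))
#' @export
setGeneric("compoundSmiles", function(x) standardGeneric("compoundSmiles"))
#' @export
setGeneric("descriptorSchema", function(x) standardGeneric("descriptorSchema"))
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))

#' @describeIn CompoundSet-class compound identifiers.
#' @param x object.
#' @export
setMethod("compoundIds", "CompoundSet", function(x) x@ids)
#' @describeIn CompoundSet-class SMILES strings, named by compound id.
#' @export
setMethod("compoundSmiles", "CompoundSet",
          function(x) stats::setNames(x@smiles, x@ids))
#' @describeIn CompoundSet-class number of compounds.
#' @export
setMethod("length", "CompoundSet", function(x) length(x@ids))

#' @describeIn CompoundSet-class subset by index, logical mask or compound id.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("CompoundSet", ids = x@ids[i], smiles = x@smiles[i], mols = x@mols[i])
})

setMethod("show", "CompoundSet", function(object) {
  cat("CompoundSet with", length(object@ids), "compounds\n")
  n <- min(3L, length(object@ids))
  if (n > 0)
    cat(paste0("  ", object@ids[seq_len(n)], ": ",
               object@smiles[seq_len(n)], collapse = "\n"), "\n")
  if (length(object@ids) > n) cat("  ...\n")
})

#' @describeIn DescriptorTable-class row ids.
#' @param x object.
#' @export
setMethod("compoundIds", "DescriptorTable", function(x) x@compoundIds)
#' @describeIn DescriptorTable-class descriptor schema (name/family/dtype).
#' @export
setMethod("descriptorSchema", "DescriptorTable", function(x) x@schema)
#' @describeIn DescriptorTable-class numeric value matrix (rows = compounds).
#' @export
setMethod("descriptorValues", "DescriptorTable", function(x) {
  v <- x@values
  dimnames(v) <- list(x@compoundIds, x@schema$name)
  v
})
#' @describeIn DescriptorTable-class rows and columns.
#' @export
setMethod("dim", "DescriptorTable", function(x) dim(x@values))

#' @describeIn DescriptorTable-class subset rows (`i`) and/or descriptor
#'   columns (`j`, by index or name).
#' @param i,j row / column index.
#' @param ...,drop ignored.
#' @export
setMethod("[", "DescriptorTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x@compoundIds)
  if (missing(j)) j <- seq_len(nrow(x@schema))
  if (is.character(j)) {
    jj <- match(j, x@schema$name)
    if (anyNA(jj)) stop("unknown descriptor column(s): ",
                        paste(j[is.na(jj)], collapse = ", "))
    j <- jj
  }
  new("DescriptorTable", compoundIds = x@compoundIds[i],
      schema = x@schema[j, , drop = FALSE],
      values = x@values[i, j, drop = FALSE])
})

setMethod("show", "DescriptorTable", function(object) {
  fam <- table(object@schema$family)
  cat("DescriptorTable:", length(object@compoundIds), "compounds x",
      nrow(object@schema), "descriptors\n  families:",
      paste(names(fam), fam, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix  TP:", object@tp, " TN:", object@tn,
      " FP:", object@fp, " FN:", object@fn, "\n")
})

setMethod("show", "CostModel", function(object) {
  cat("CostModel<", object@family, ">  FN cost:", object@costFn,
      " descriptors:", nrow(object@schema), "\n")
})

setMethod("show", "FilterSet", function(object) {
  cat("FilterSet", object@name, "with", length(object@smarts), "patterns\n")
})

setMethod("show", "FragmentDictionary", function(object) {
  cat("FragmentDictionary with", length(object@ids), "fragments\n")
})

#' Construct a ConfusionMatrix
#'
#' @param tp,tn,fp,fn non-negative integer counts of true positives, true
#'   negatives, false positives and false negatives.
#' @return a [ConfusionMatrix-class] object.
#' @examples
#' confusionMatrix(tp = 9, tn = 90, fp = 10, fn = 1)
#' @export
confusionMatrix <- function(tp, tn, fp, fn) {
  new("ConfusionMatrix", tp = as.numeric(tp), tn = as.numeric(tn),
      fp = as.numeric(fp), fn = as.numeric(fn))
}

#' Counts of a ConfusionMatrix as a named vector
#' @param cm a [ConfusionMatrix-class].
#' @return named numeric vector `c(tp, tn, fp, fn)`.
#' @export
confusionCounts <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  c(tp = cm@tp, tn = cm@tn, fp = cm@fp, fn = cm@fn)
}

#' Parse compounds from SMILES
#'
#' Structures that OpenBabel cannot parse are dropped with a warning naming
#' the offending ids (record-level failure, not a hard error).
#'
#' @param smiles character vector of SMILES.
#' @param ids compound identifiers; defaults to `names(smiles)` or
#'   `cmpd_1..n`.
#' @return a [CompoundSet-class].
#' @examples
#' cs <- parseCompounds(c(benzene = "c1ccccc1", ethanol = "CCO"))
#' length(cs)
#' @export
parseCompounds <- function(smiles, ids = NULL) {
  if (is.null(ids)) {
    ids <- names(smiles)
    if (is.null(ids)) ids <- paste0("cmpd_", seq_along(smiles))
  }
  stopifnot(length(ids) == length(smiles))
  mols <- obParseSmiles(smiles)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad))
    warning("dropped ", sum(bad), " unparseable structure(s): ",
            paste(ids[bad], collapse = ", "))
  new("CompoundSet", ids = as.character(ids[!bad]),
      smiles = as.character(smiles[!bad]), mols = mols[!bad])
}

#' Rebuild molecule handles of a CompoundSet
#'
#' Molecule handles are session-local; call this after loading a saved
#' object whose handles are stale.
#' @param x a [CompoundSet-class].
#' @return the same set with fresh handles.
#' @export
rebuildMols <- function(x) {
  stopifnot(is(x, "CompoundSet"))
  x@mols <- obParseSmiles(x@smiles)
  x
}
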