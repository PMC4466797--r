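# Activity labelling and descriptor redundancy removal.

#' Label assay activity at the 40% inhibition threshold
#'
#' A compound showing at least 40% inhibition at the assay concentration is
#' labelled `active` with activity score 20; everything else (including
#' negative readouts) is `inactive` with score 0. The threshold comparison is
#' inclusive.
#'
#' @param percent_inhibition numeric vector of % inhibition readouts.
#' @param compound_id optional ids used in error messages for invalid
#'   readouts.
#' @return data.frame with columns `activity_class` (`"active"`/`"inactive"`)
#'   and `activity_score` (20/0).
#' @examples
#' labelActivity(c(40, 39.999, -5))
#' @export
labelActivity <- function(percent_inhibition, compound_id = NULL) {
  x <- percent_inhibition
  bad <- !is.finite(suppressWarnings(as.numeric(x)))
  if (any(bad)) {
    ids <- if (!is.null(compound_id)) compound_id[bad] else which(bad)
    stop("missing or non-numeric inhibition readout for: ",
         paste(ids, collapse = ", "))
  }
  x <- as.numeric(x)
  active <- x >= 40
  data.frame(activity_class = ifelse(active, "active", "inactive"),
             activity_score = ifelse(active, 20L, 0L))
}

#' Read an assay CSV (`compound_id,percent_inhibition`)
#' @param path input file.
#' @return data.frame with the two columns.
#' @export
readAssayCsv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "percent_inhibition")
  if (!all(need %in% names(tab)))
    stop("assay CSV must have columns: ", paste(need, collapse = ", "))
  tab[, need]
}

#' Write a labelled assay CSV
#'
#' Adds `activity_class` and `activity_score` columns to the assay table.
#' @param assay data.frame with `compound_id` and `percent_inhibition`.
#' @param path output file.
#' @return the labelled data.frame, invisibly.
#' @export
writeLabeledAssay <- function(assay, path) {
  lab <- cbind(assay, labelActivity(assay$percent_inhibition, assay$compound_id))
  utils::write.csv(lab, path, row.names = FALSE)
  invisible(lab)
}

#' Drop constant and near-constant descriptor columns
#'
#' A column is dropped when its single most common value occurs in more than
#' `max_identical_fraction` of rows; constant columns are the special case
#' fraction = 1. Surviving columns keep their original order; rows are
#' untouched.
#'
#' @param table a [DescriptorTable-class].
#' @param max_identical_fraction threshold in (0, 1]; default 0.99.
#' @return the filtered [DescriptorTable-class].
#' @export
removeUseless <- function(table, max_identical_fraction = 0.99) {
  stopifnot(is(table, "DescriptorTable"))
  if (nrow(table@values) == 0) stop("table has no rows")
  if (!(max_identical_fraction > 0 && max_identical_fraction <= 1))
    stop("max_identical_fraction must be in (0, 1]")
  n <- nrow(table@values)
  topFrac <- apply(table@values, 2, function(col) {
    max(tabulate(match(col, unique(col)))) / n
  })
  keep <- which(topFrac <= max_identical_fraction)
  if (length(keep) == 0) stop("no informative descriptors survive the filter")
  table[, keep]
}
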