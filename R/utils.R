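# Small shared helpers.

# Evaluate an expression under a fixed RNG seed, restoring caller RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed; stays inside 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + 12345L * as.numeric(k)) %% 2147483647)
}

# Read a tab-separated bundled data file, skipping '#' comment lines.
readPackageTsv <- function(file, colNames) {
  path <- system.file("extdata", file, package = "BioassayTriage", mustWork = TRUE)
  readTsvFile(path, colNames)
}

readTsvFile <- function(path, colNames) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, lapply(parts, function(p) {
    length(p) <- length(colNames)
    p
  })), stringsAsFactors = FALSE)
  names(out) <- colNames
  out[is.na(out)] <- ""
  out
}

# Standardize activity labels to a character vector in {"active","inactive"}.
normalizeLabels <- function(labels) {
  labels <- as.character(labels)
  bad <- !labels %in% c("active", "inactive")
  if (any(bad)) stop("labels must be 'active' or 'inactive'; found: ",
                     paste(unique(labels[bad]), collapse = ", "))
  labels
}

`%||%` <- function(a, b) if (is.null(a)) b else a
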