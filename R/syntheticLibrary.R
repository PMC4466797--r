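# Synthetic imbalanced bioassay libraries with planted, substructure-driven
# activity signal.
#
# Structures are assembled from a bundled grammar of ~20 drug-like scaffolds
# and ~35 substituents (guaranteeing chemical validity and known fragment
# content), a latent activity propensity is raised for compounds carrying the
# enriched fragments, and the continuous inhibition readout is
# 100*sigmoid(propensity) + Gaussian noise, clipped to [-20, 120], so the 40%
# labelling rule induces the two classes with tunable overlap.

loadGrammar <- function() {
  if (is.null(.obEnv$grammar)) {
    sc <- readPackageTsv("scaffolds.tsv", c("name", "template"))
    su <- readPackageTsv("substituents.tsv", c("name", "smiles", "counterion"))
    .obEnv$grammar <- list(scaffolds = sc, substituents = su)
  }
  .obEnv$grammar
}

#' Specification of a synthetic compound library
#'
#' @param n_compounds number of compounds to generate (>= 1).
#' @param active_fraction target fraction of actives under the 40% rule,
#'   in (0, 1). The default 0.0025 mirrors the severe imbalance of real
#'   single-concentration phosphatase screens (~1 active per 400 compounds).
#' @param enriched_fragments named numeric vector: names are fragment names
#'   from the bundled dictionary (see [defaultFragmentDictionary()]), values
#'   are activity odds multipliers (>= 1) applied to carriers.
#' @param noise_sd Gaussian readout noise, in inhibition percentage points
#'   (default 5).
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @param latent_sd standard deviation of the per-compound latent propensity
#'   heterogeneity on the logit scale (default 2); gives compounds with the
#'   same structure class different intrinsic potencies.
#' @param base_logit optional fixed baseline propensity (logit scale). When
#'   `NA` (default) the baseline is calibrated so the expected realized
#'   active fraction equals `active_fraction`; setting it disables
#'   calibration (e.g. `-Inf` forces a signal-free library).
#' @return a `librarySpec` list.
#' @export
librarySpec <- function(n_compounds, active_fraction = 0.0025,
                        enriched_fragments = numeric(0), noise_sd = 5,
                        seed = 1L, latent_sd = 2, base_logit = NA_real_) {
  if (!is.numeric(n_compounds) || n_compounds < 1)
    stop("n_compounds must be a positive integer")
  n_compounds <- as.integer(n_compounds)
  if (!(active_fraction > 0 && active_fraction < 1))
    stop("active_fraction must be in (0, 1)")
  if (active_fraction * n_compounds < 1)
    stop("active_fraction * n_compounds must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(enriched_fragments)) {
    if (is.null(names(enriched_fragments)) || any(!nzchar(names(enriched_fragments))))
      stop("enriched_fragments must be a named numeric vector")
    if (any(enriched_fragments < 1))
      stop("enrichment odds multipliers must be >= 1")
    dict <- defaultFragmentDictionary()
    unknown <- setdiff(names(enriched_fragments), dict@fragmentNames)
    if (length(unknown))
      stop("unknown fragment name(s): ", paste(unknown, collapse = ", "))
  }
  structure(list(n_compounds = n_compounds, active_fraction = active_fraction,
                 enriched_fragments = enriched_fragments, noise_sd = noise_sd,
                 seed = as.integer(seed), latent_sd = latent_sd,
                 base_logit = base_logit),
            class = "librarySpec")
}

# Assemble one SMILES from scaffold template + substituent rows.
fillTemplate <- function(template, subs) {
  out <- template
  for (k in seq_along(subs)) {
    slot <- paste0("{R", k, "}")
    s <- subs[[k]]$smiles
    if (nzchar(s)) {
      out <- sub(slot, s, out, fixed = TRUE)
    } else {
      out <- sub(paste0("(", slot, ")"), "", out, fixed = TRUE)
      out <- sub(slot, "", out, fixed = TRUE)
    }
  }
  ions <- unique(vapply(subs, function(x) x$counterion, character(1)))
  ions <- ions[nzchar(ions)]
  if (length(ions)) out <- paste(c(out, ions), collapse = ".")
  out
}

templateSlots <- function(template) {
  if (grepl("{R2}", template, fixed = TRUE)) 2L else 1L
}

# Expected active fraction given per-compound propensities and readout noise.
expectedActiveFraction <- function(propensity, noise_sd) {
  thr <- 40
  mu <- 100 * stats::plogis(propensity)
  if (noise_sd > 0) mean(stats::pnorm((mu - thr) / noise_sd))
  else mean(mu >= thr)
}

# Calibrate the baseline logit so the expected active fraction hits target.
calibrateBaseline <- function(offsets, noise_sd, target) {
  f <- function(mu0) expectedActiveFraction(mu0 + offsets, noise_sd) - target
  if (noise_sd > 0) {
    if (f(-60) >= 0 || f(60) <= 0) {
      warning("target active_fraction unreachable at this noise level; ",
              "baseline clamped")
      return(if (f(-60) >= 0) -60 else 60)
    }
    stats::uniroot(f, c(-60, 60), tol = 1e-9)$root
  } else {
    # noiseless readout: place the baseline so that exactly round(n*target)
    # compounds clear the 40% threshold
    thr <- stats::qlogis(0.4)
    k <- max(1L, round(length(offsets) * target))
    s <- sort(offsets, decreasing = TRUE)
    cut <- if (k < length(s)) (s[k] + s[k + 1]) / 2 else s[length(s)] - 1
    thr - cut
  }
}

#' Generate a synthetic bioassay library
#'
#' Deterministic for a fixed seed. Every structure is assembled from the
#' bundled scaffold/substituent grammar (and therefore parses); compounds
#' carrying the fragments named in `spec$enriched_fragments` get their latent
#' activity propensity raised by `log(multiplier)` per fragment, so those
#' fragments end up over-represented among labelled actives.
#'
#' @param spec a [librarySpec()].
#' @return list with elements `compounds` (a [CompoundSet-class]), `assay`
#'   (data.frame `compound_id`, `percent_inhibition`), `base_logit` (the
#'   calibrated baseline) and `spec`.
#' @examples
#' lib <- generateLibrary(librarySpec(200, active_fraction = 0.05, seed = 7))
#' head(lib$assay)
#' @export
generateLibrary <- function(spec) {
  stopifnot(inherits(spec, "librarySpec"))
  g <- loadGrammar()
  n <- spec$n_compounds
  withSeed(spec$seed, {
    scIdx <- sample.int(nrow(g$scaffolds), n, replace = TRUE)
    smiles <- character(n)
    for (i in seq_len(n)) {
      tpl <- g$scaffolds$template[scIdx[i]]
      nslot <- templateSlots(tpl)
      subIdx <- sample.int(nrow(g$substituents), nslot, replace = TRUE)
      subs <- lapply(subIdx, function(j) as.list(g$substituents[j, ]))
      smiles[i] <- fillTemplate(tpl, subs)
    }
    ids <- sprintf("lib_%06d", seq_len(n))
    compounds <- parseCompounds(smiles, ids)
    if (length(compounds) != n)
      stop("internal error: grammar produced unparseable structures")

    offsets <- numeric(n)
    if (length(spec$enriched_fragments)) {
      dict <- defaultFragmentDictionary()
      idx <- match(names(spec$enriched_fragments), dict@fragmentNames)
      sub <- new("FragmentDictionary", ids = dict@ids[idx],
                 fragmentNames = dict@fragmentNames[idx],
                 smarts = dict@smarts[idx])
      carry <- fragmentFingerprint(compounds, sub)
      offsets <- as.numeric(carry %*% log(spec$enriched_fragments))
    }
    latent <- if (spec$latent_sd > 0) stats::rnorm(n, 0, spec$latent_sd) else numeric(n)
    offsets <- offsets + latent

    base <- spec$base_logit
    if (is.na(base))
      base <- calibrateBaseline(offsets, spec$noise_sd, spec$active_fraction)
    propensity <- base + offsets
    inhibition <- 100 * stats::plogis(propensity)
    if (spec$noise_sd > 0)
      inhibition <- inhibition + stats::rnorm(n, 0, spec$noise_sd)
    inhibition <- pmin(pmax(inhibition, -20), 120)

    list(compounds = compounds,
         assay = data.frame(compound_id = ids,
                            percent_inhibition = inhibition),
         base_logit = base, spec = spec)
  })
}

#' Write compounds as a SMILES file (`SMILES<TAB>id`, one per line)
#' @param compounds a [CompoundSet-class].
#' @param path output file.
#' @export
writeSmilesFile <- function(compounds, path) {
  writeLines(paste(compounds@smiles, compounds@ids, sep = "\t"), path)
  invisible(path)
}

#' Read a SMILES file written by [writeSmilesFile()]
#' @param path input file.
#' @return a [CompoundSet-class].
#' @export
readSmilesFile <- function(path) {
  tab <- readTsvFile(path, c("smiles", "id"))
  parseCompounds(tab$smiles, tab$id)
}

#' Write compounds as SDF
#' @param compounds a [CompoundSet-class].
#' @param path output file.
#' @export
writeSdfFile <- function(compounds, path) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(compounds@smiles, compounds@ids)))
  ChemmineR::write.SDF(sdf, path)
  invisible(path)
}

#' Write an assay table as CSV (`compound_id,percent_inhibition`)
#' @param assay data.frame with `compound_id` and `percent_inhibition`.
#' @param path output file.
#' @export
writeAssayCsv <- function(assay, path) {
  utils::write.csv(assay[, c("compound_id", "percent_inhibition")], path,
                   row.names = FALSE)
  invisible(path)
}
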