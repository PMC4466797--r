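# 2D molecular descriptors in three families:
#   - 147 binary pharmacophore-pair fingerprint bits,
#   - 24 Burden-eigenvalue (BCUT-style) descriptors,
#   - 8 property descriptors.
# 179 columns in total before redundancy removal.

loadElements <- function() {
  if (is.null(.obEnv$elements)) {
    tab <- readPackageTsv("elements.tsv",
                          c("symbol", "atomic_number", "mass", "polarizability"))
    .obEnv$elements <- data.frame(
      Z = as.integer(tab$atomic_number),
      mass = as.numeric(tab$mass),
      polarizability = as.numeric(tab$polarizability),
      row.names = tab$symbol)
  }
  .obEnv$elements
}

pharmacophoreFeatureNames <- c("donor", "acceptor", "aromatic",
                               "hydrophobic", "positive", "negative")

loadFeaturePatterns <- function() {
  if (is.null(.obEnv$featPats)) {
    tab <- readPackageTsv("pharmacophore_features.tsv", c("feature", "smarts"))
    stopifnot(identical(tab$feature, pharmacophoreFeatureNames))
    pats <- lapply(tab$smarts, obCompileSmarts)
    if (any(vapply(pats, is.null, logical(1))))
      stop("bundled feature SMARTS failed to compile")
    names(pats) <- tab$feature
    .obEnv$featPats <- pats
  }
  .obEnv$featPats
}

# Distance bins for feature pairs (topological bond-count distance).
.ppBins <- list(c(1, 2), c(3, 4), c(5, 6), c(7, Inf))
.ppBinLabels <- c("d1_2", "d3_4", "d5_6", "d7p")
.ppCountMax <- 10L

#' Schema of the 147-bit pharmacophore-pair fingerprint
#'
#' The fingerprint uses six chemical features assigned by bundled SMARTS
#' definitions (H-bond donor, H-bond acceptor, aromatic ring atom,
#' hydrophobic atom, positive centre, negative centre). Bits, in fixed order:
#' 21 unordered feature pairs x 4 topological distance bins
#' (1-2, 3-4, 5-6, 7+ bonds) = 84 pair bits; 6 features x 10 cumulative count
#' thresholds (>=1 .. >=10 feature atoms) = 60 count bits; and 3 composite
#' bits (donor & acceptor both present, any charged centre, aromatic &
#' hydrophobic both present). 147 bits in total.
#'
#' @return character vector of the 147 bit names.
#' @export
pharmacophoreSchema <- function() {
  feats <- pharmacophoreFeatureNames
  pairBits <- character(0)
  for (i in seq_along(feats)) for (j in i:length(feats))
    pairBits <- c(pairBits, paste0("pp_", feats[i], "_", feats[j], "_", .ppBinLabels))
  countBits <- as.vector(t(outer(feats, seq_len(.ppCountMax),
                                 function(f, k) paste0("ct_", f, "_ge", k))))
  c(pairBits, countBits,
    c("cx_donor_acceptor", "cx_any_charge", "cx_aromatic_hydrophobic"))
}

# Atom-level feature incidence: list of integer atom-index vectors by feature.
atomFeatures <- function(mol) {
  pats <- loadFeaturePatterns()
  lapply(pats, function(p) {
    hits <- obMatchAtoms(p, mol)
    if (length(hits) == 0) integer(0) else sort(unique(unlist(hits)))
  })
}

# Topological (bond-count) distance matrix from a molecule graph.
topoDistances <- function(graph) {
  n <- graph$nAtoms
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(graph$bonds) > 0)
    g <- igraph::add_edges(g, rbind(graph$bonds$from, graph$bonds$to))
  igraph::distances(g)
}

ppBitsForMol <- function(feats, dmat) {
  fn <- pharmacophoreFeatureNames
  nf <- length(fn)
  bits <- integer(0)
  for (i in seq_len(nf)) for (j in i:nf) {
    ai <- feats[[i]]; aj <- feats[[j]]
    present <- rep(0L, length(.ppBins))
    if (length(ai) && length(aj)) {
      d <- dmat[ai, aj, drop = FALSE]
      d <- d[is.finite(d) & d >= 1]
      if (length(d))
        present <- vapply(.ppBins, function(b) as.integer(any(d >= b[1] & d <= b[2])),
                          integer(1))
    }
    bits <- c(bits, present)
  }
  counts <- vapply(feats, length, integer(1))
  countBits <- as.vector(t(outer(counts, seq_len(.ppCountMax), ">=")))
  composites <- c(counts["donor"] > 0 && counts["acceptor"] > 0,
                  counts["positive"] > 0 || counts["negative"] > 0,
                  counts["aromatic"] > 0 && counts["hydrophobic"] > 0)
  c(bits, as.integer(countBits), as.integer(composites))
}

#' Pharmacophore-pair fingerprints
#'
#' @param compounds a [CompoundSet-class].
#' @return binary integer matrix (compounds x 147 bits); column names from
#'   [pharmacophoreSchema()].
#' @examples
#' fp <- pharmacophoreFingerprint(parseCompounds(c(benzene = "c1ccccc1")))
#' fp[, "pp_aromatic_aromatic_d1_2"]
#' @export
pharmacophoreFingerprint <- function(compounds) {
  stopifnot(is(compounds, "CompoundSet"))
  schema <- pharmacophoreSchema()
  rows <- lapply(compounds@mols, function(mol) {
    g <- obMolGraph(mol)
    ppBitsForMol(atomFeatures(mol), topoDistances(g))
  })
  matrix(unlist(rows), nrow = length(compounds@mols), byrow = TRUE,
         dimnames = list(compounds@ids, schema))
}

# ---- Burden eigenvalue descriptors ----

.burdenWeightings <- c("mass", "charge", "polarizability")

#' Names of the 24 Burden-eigenvalue descriptors
#'
#' For each atomic-property weighting (atomic mass, Gasteiger partial charge,
#' atomic polarizability) the 4 largest (`hi1..hi4`, descending) and
#' 4 smallest (`lo1..lo4`, ascending) eigenvalues of the Burden matrix.
#' @return character vector of 24 names.
#' @export
burdenSchema <- function() {
  as.vector(t(outer(.burdenWeightings, c(paste0("hi", 1:4), paste0("lo", 1:4)),
                    function(w, s) paste0("bcut_", w, "_", s))))
}

# Eigenvalues of the Burden matrix for one connected component.
# Diagonal: atomic property. Off-diagonal: 0.1 * bond order for bonded pairs
# (aromatic bonds count as order 1.5), 0.001 for non-bonded pairs within the
# component. Components are independent blocks.
burdenComponentEigen <- function(diagVals, bonds, memberIdx) {
  k <- length(memberIdx)
  if (k == 1) return(diagVals[memberIdx])
  B <- matrix(0.001, k, k)
  diag(B) <- diagVals[memberIdx]
  if (nrow(bonds) > 0) {
    pos <- match(seq_along(diagVals), memberIdx)
    for (r in seq_len(nrow(bonds))) {
      i <- pos[bonds$from[r]]; j <- pos[bonds$to[r]]
      if (!is.na(i) && !is.na(j)) {
        ord <- if (bonds$aromatic[r]) 1.5 else bonds$order[r]
        B[i, j] <- B[j, i] <- 0.1 * ord
      }
    }
  }
  eigen(B, symmetric = TRUE, only.values = TRUE)$values
}

extremeEigen <- function(ev) {
  ev <- sort(ev, decreasing = TRUE)
  n <- length(ev)
  hi <- ev[pmin(1:4, n)]
  lo <- rev(ev)[pmin(1:4, n)]
  c(hi, lo)
}

burdenForMol <- function(graph) {
  el <- loadElements()
  midx <- match(graph$Z, el$Z)
  if (anyNA(midx))
    stop("element with atomic number ",
         paste(unique(graph$Z[is.na(midx)]), collapse = ","),
         " missing from the bundled element table")
  if (graph$nAtoms == 1)
    warning("single-atom molecule: Burden eigenvalue replicated into all slots")
  comp <- connectedComponents(graph)
  out <- numeric(0)
  for (w in .burdenWeightings) {
    diagVals <- switch(w,
      mass = el$mass[midx],
      charge = graph$partialCharge,
      polarizability = el$polarizability[midx])
    ev <- unlist(lapply(comp, function(members)
      burdenComponentEigen(diagVals, graph$bonds, members)))
    out <- c(out, extremeEigen(ev))
  }
  out
}

connectedComponents <- function(graph) {
  g <- igraph::make_empty_graph(graph$nAtoms, directed = FALSE)
  if (nrow(graph$bonds) > 0)
    g <- igraph::add_edges(g, rbind(graph$bonds$from, graph$bonds$to))
  m <- igraph::components(g)$membership
  split(seq_len(graph$nAtoms), m)
}

#' Burden (BCUT-style) eigenvalue descriptors
#'
#' @param compounds a [CompoundSet-class].
#' @return numeric matrix (compounds x 24); columns per [burdenSchema()].
#' @export
burdenDescriptors <- function(compounds) {
  stopifnot(is(compounds, "CompoundSet"))
  rows <- lapply(compounds@mols, function(mol) burdenForMol(obMolGraph(mol)))
  matrix(unlist(rows), nrow = length(compounds@mols), byrow = TRUE,
         dimnames = list(compounds@ids, burdenSchema()))
}

# ---- property descriptors ----

#' Names of the 8 property descriptors
#'
#' `mw` molecular weight (g/mol); `logp` estimated octanol-water partition
#' coefficient; `hbd`/`hba` H-bond donor/acceptor atom counts (bundled SMARTS
#' definitions, counting heavy atoms, not hydrogens); `rotatable_bonds`
#' acyclic single bonds between heavy atoms (terminal rotors included);
#' `tpsa` topological polar surface area (A^2); `heavy_atoms` non-hydrogen
#' atom count; `formal_charge` net formal charge.
#' @return character vector of 8 names.
#' @export
propertySchema <- function() {
  c("mw", "logp", "hbd", "hba", "rotatable_bonds", "tpsa", "heavy_atoms",
    "formal_charge")
}

countRotatable <- function(graph) {
  b <- graph$bonds
  if (nrow(b) == 0) return(0L)
  sum(b$order == 1 & !b$aromatic & !b$inRing)
}

#' Property descriptors
#'
#' @param compounds a [CompoundSet-class].
#' @return numeric matrix (compounds x 8); columns per [propertySchema()].
#' @examples
#' propertyDescriptors(parseCompounds(c(water = "O")))
#' @export
propertyDescriptors <- function(compounds) {
  stopifnot(is(compounds, "CompoundSet"))
  pats <- loadFeaturePatterns()
  lp <- obLogpTpsa(compounds@mols)
  rows <- lapply(seq_along(compounds@mols), function(i) {
    mol <- compounds@mols[[i]]
    g <- obMolGraph(mol)
    feats <- atomFeatures(mol)
    c(mw = obMolWeight(mol), logp = lp$logp[i],
      hbd = length(feats$donor), hba = length(feats$acceptor),
      rotatable_bonds = countRotatable(g), tpsa = lp$tpsa[i],
      heavy_atoms = g$nAtoms, formal_charge = obTotalCharge(mol))
  })
  matrix(unlist(rows), nrow = length(compounds@mols), byrow = TRUE,
         dimnames = list(compounds@ids, propertySchema()))
}

#' Full 179-column descriptor table
#'
#' Concatenates the three families (147 pharmacophore bits + 24 Burden
#' eigenvalues + 8 properties) into a [DescriptorTable-class]. A pure
#' function of the structures: permuting the input permutes the rows
#' identically.
#'
#' @param compounds a [CompoundSet-class].
#' @return a [DescriptorTable-class].
#' @export
descriptorTable <- function(compounds) {
  pp <- pharmacophoreFingerprint(compounds)
  bd <- burdenDescriptors(compounds)
  pr <- propertyDescriptors(compounds)
  schema <- data.frame(
    name = c(colnames(pp), colnames(bd), colnames(pr)),
    family = c(rep("pharmacophore", ncol(pp)), rep("burden", ncol(bd)),
               rep("property", ncol(pr))),
    dtype = c(rep("binary", ncol(pp)), rep("continuous", ncol(bd)),
              rep("continuous", ncol(pr))))
  new("DescriptorTable", compoundIds = compounds@ids, schema = schema,
      values = unname(cbind(pp, bd, pr)))
}

#' Write a DescriptorTable as CSV
#'
#' The header encodes the typed schema as `name:family:dtype` per column,
#' with the compound id in the first column.
#' @param table a [DescriptorTable-class].
#' @param path output file.
#' @export
writeDescriptorCsv <- function(table, path) {
  hdr <- c("compound_id",
           paste(table@schema$name, table@schema$family, table@schema$dtype,
                 sep = ":"))
  df <- cbind(data.frame(compound_id = table@compoundIds), as.data.frame(table@values))
  names(df) <- hdr
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a DescriptorTable written by [writeDescriptorCsv()]
#' @param path input file.
#' @return a [DescriptorTable-class].
#' @export
readDescriptorCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  hdr <- names(df)[-1]
  parts <- do.call(rbind, strsplit(hdr, ":", fixed = TRUE))
  new("DescriptorTable", compoundIds = as.character(df[[1]]),
      schema = data.frame(name = parts[, 1], family = parts[, 2],
                          dtype = parts[, 3]),
      values = unname(as.matrix(df[, -1, drop = FALSE])))
}
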