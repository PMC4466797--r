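test_that("the descriptor schema has the documented shape", {
  expect_length(pharmacophoreSchema(), 147)
  expect_length(burdenSchema(), 24)
  expect_length(propertySchema(), 8)
  tab <- testDescriptors()
  expect_identical(dim(tab)[2], 179L)
  sch <- descriptorSchema(tab)
  expect_identical(as.integer(table(sch$family)[c("pharmacophore", "burden", "property")]),
                   c(147L, 24L, 8L))
  # pharmacophore columns are strictly binary
  pp <- descriptorValues(tab)[, sch$family == "pharmacophore"]
  expect_true(all(pp %in% c(0, 1)))
})

test_that("benzene sets aromatic-pair bits and no donor bits", {
  pp <- pharmacophoreFingerprint(probeCompounds())
  expect_identical(pp["benzene", "pp_aromatic_aromatic_d1_2"], 1L)
  expect_identical(pp["benzene", "pp_aromatic_aromatic_d3_4"], 1L)
  donorBits <- grep("donor", colnames(pp), value = TRUE)
  expect_true(all(pp["benzene", donorBits] == 0))
  expect_true(all(pp["methane", ] == 0))
  # determinism for duplicated input
  dup <- parseCompounds(c(e1 = "CCO", e2 = "CCO"))
  fpd <- pharmacophoreFingerprint(dup)
  expect_identical(unname(fpd[1, ]), unname(fpd[2, ]))
})

test_that("ethane Burden eigenvalues match the 2x2 closed form", {
  # probe set includes single-atom molecules whose replication warning is
  # exercised in its own test below
  bd <- suppressWarnings(burdenDescriptors(probeCompounds()))
  # mass weighting: eigen([[12.011, 0.1], [0.1, 12.011]]) = 12.111, 11.911
  expect_equal(unname(bd["ethane", "bcut_mass_hi1"]), 12.111, tolerance = 1e-9)
  expect_equal(unname(bd["ethane", "bcut_mass_lo1"]), 11.911, tolerance = 1e-9)
})

test_that("largest eigenvalue slots dominate smallest slots per weighting", {
  tl <- testLibrary()
  bd <- burdenDescriptors(tl$lib$compounds[1:40])
  for (w in c("mass", "charge", "polarizability"))
    expect_true(all(bd[, paste0("bcut_", w, "_hi1")] >=
                      bd[, paste0("bcut_", w, "_lo1")] - 1e-12))
})

test_that("disconnected structures give the union of per-block eigenvalues", {
  cs <- probeCompounds()["acetateSalt"]
  g <- BioassayTriage:::obMolGraph(cs@mols[[1]])
  el <- BioassayTriage:::loadElements()
  diagVals <- el$mass[match(g$Z, el$Z)]
  # brute-force: full block matrix over all atoms with cross-component zeros
  comp <- BioassayTriage:::connectedComponents(g)
  full <- matrix(0, g$nAtoms, g$nAtoms)
  for (members in comp) {
    for (i in members) for (j in members) if (i != j) full[i, j] <- 0.001
  }
  diag(full) <- diagVals
  for (r in seq_len(nrow(g$bonds))) {
    i <- g$bonds$from[r]; j <- g$bonds$to[r]
    ord <- if (g$bonds$aromatic[r]) 1.5 else g$bonds$order[r]
    full[i, j] <- full[j, i] <- 0.1 * ord
  }
  evFull <- sort(eigen(full, symmetric = TRUE, only.values = TRUE)$values)
  evBlocks <- sort(unlist(lapply(comp, function(m)
    BioassayTriage:::burdenComponentEigen(diagVals, g$bonds, m))))
  expect_equal(unname(evBlocks), unname(evFull), tolerance = 1e-10)
})

test_that("single-atom molecules replicate their eigenvalue with a warning", {
  cs <- probeCompounds()["methane"]
  expect_warning(bd <- burdenDescriptors(cs), "single-atom")
  expect_true(all(bd[1, grep("mass", colnames(bd))] == 12.011))
})

test_that("property descriptors match hand values on probe molecules", {
  pr <- propertyDescriptors(probeCompounds())
  expect_equal(unname(pr["water", "mw"]), 18.02, tolerance = 0.01)
  expect_identical(unname(pr["water", "hbd"]), 1)
  expect_identical(unname(pr["water", "heavy_atoms"]), 1)
  expect_identical(unname(pr["benzene", c("hbd", "hba", "rotatable_bonds")]),
                   c(0, 0, 0))
  expect_identical(unname(pr["propane", "heavy_atoms"]),
                   unname(pr["cyclopropane", "heavy_atoms"]))
  expect_false(pr["propane", "rotatable_bonds"] ==
                 pr["cyclopropane", "rotatable_bonds"])
  expect_identical(unname(pr["acetateSalt", "formal_charge"]), 0)
})

test_that("descriptor generation commutes with row permutation", {
  tl <- testLibrary()
  cs <- tl$lib$compounds[1:20]
  perm <- c(5:1, 20:6)
  t1 <- descriptorTable(cs)
  t2 <- descriptorTable(cs[perm])
  expect_identical(compoundIds(t2), compoundIds(t1)[perm])
  expect_equal(descriptorValues(t2), descriptorValues(t1)[perm, ],
               tolerance = 1e-12)
})

test_that("descriptor CSV round-trips schema and values", {
  tab <- testDescriptors()[1:10, ]
  path <- tempfile(fileext = ".csv")
  writeDescriptorCsv(tab, path)
  back <- readDescriptorCsv(path)
  expect_identical(descriptorSchema(back), descriptorSchema(tab))
  expect_equal(descriptorValues(back), descriptorValues(tab),
               tolerance = 1e-9)
})
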