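# Structure and ligand I/O.

test_that("a minimal hand-written PDB parses to atoms and residues", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(miniPDBLines(), path)
  m <- parseStructure(path)
  expect_s4_class(m, "StructureModel")
  expect_equal(nAtoms(m), 4)
  expect_equal(nResidues(m), 1)
  expect_equal(atoms(m)$element, c("N", "C", "C", "O"))
  expect_equal(atoms(m)$x, c(1, 2, 3, 3.5))
})

test_that("alternate locations resolve to the highest occupancy", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 20.00           N",
    "ATOM      2  CA AALA A   1       2.000   2.500   3.000  0.60 20.00           C",
    "ATOM      3  CA BALA A   1       9.000   9.000   9.000  0.40 20.00           C",
    "END"), path)
  m <- parseStructure(path)
  expect_equal(nAtoms(m), 2)
  ca <- atoms(m)[atoms(m)$name == "CA", ]
  expect_equal(ca$x, 2)  # altloc A, occupancy 0.6, wins
})

test_that("hydrogens and waters are excluded, mmCIF parses too", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 20.00           N",
    "ATOM      2  H   ALA A   1       1.500   2.000   3.000  1.00 20.00           H",
    "HETATM    3  O   HOH A 101       8.000   8.000   8.000  1.00 30.00           O",
    "END"), path)
  m <- parseStructure(path)
  expect_equal(nAtoms(m), 1)

  cif <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_toy", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 1.0 2.0 3.0 1.00 90.0 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.0 2.5 3.0 1.00 90.0 ? 1 ALA A CA 1"),
    cif)
  mc <- parseStructure(cif)
  expect_equal(nAtoms(mc), 2)
  expect_equal(nResidues(mc), 1)
})

test_that("parse errors are informative", {
  expect_error(parseStructure(tempfile()), "not found")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(parseStructure(empty), "empty|parse")
})

test_that("write -> parse round trip preserves geometry", {
  m <- makeCavityStructure(cavitySpec(seed = 5, plantedLigand = "PLM"))
  path <- withr::local_tempfile(fileext = ".pdb")
  writeStructurePDB(m, path)
  m2 <- parseStructure(path, modelKind = "predicted")
  expect_equal(nAtoms(m2), nAtoms(m))
  expect_equal(nResidues(m2), nResidues(m))
  expect_equal(atoms(m2)$x, atoms(m)$x, tolerance = 1e-3)
  expect_equal(atoms(m2)$y, atoms(m)$y, tolerance = 1e-3)
  expect_equal(atoms(m2)$z, atoms(m)$z, tolerance = 1e-3)
})

test_that("standalone ligand extraction honours the covalent cutoff", {
  m <- makeCavityStructure(cavitySpec(seed = 7, plantedLigand = "CLR"))
  ligs <- extractStandaloneLigands(m, lipidLigandCodes())
  expect_length(ligs, 1)
  expect_equal(compId(ligs[[1]]), "CLR")
  # center of mass = unweighted mean of planted heavy atoms
  la <- atoms(ligs[[1]])
  expect_equal(centerOfMass(ligs[[1]]),
               unname(colMeans(as.matrix(la[, c("x", "y", "z")]))))

  # a MYR carbon 1.5 A from a polymer atom marks the ligand covalent
  poly <- tetrahedronCoords(6)
  a <- rbind(
    data.frame(serial = 1:4, name = "CA", element = "C", resid = "ALA",
               chain = "A", resno = 1:4, x = poly[, 1], y = poly[, 2],
               z = poly[, 3], b = 20, hetero = FALSE),
    data.frame(serial = 5, name = "C1", element = "C", resid = "MYR",
               chain = "A", resno = 10,
               x = poly[1, 1] + 1.5, y = poly[1, 2], z = poly[1, 3],
               b = 20, hetero = TRUE))
  mc <- StructureModel(a, sourceId = "cov")
  expect_length(extractStandaloneLigands(mc, "MYR"), 0)
  # at 3 A the same ligand is standalone
  a$x[5] <- poly[1, 1] + 3
  expect_length(extractStandaloneLigands(StructureModel(a), "MYR"), 1)
})

test_that("ligand burial counts distinct residues inside the radius", {
  ring <- function(n, r) {
    th <- 2 * pi * seq_len(n) / n
    cbind(r * cos(th), r * sin(th), 0)
  }
  buildCase <- function(nRes) {
    a <- rbind(
      data.frame(serial = seq_len(nRes), name = "CA", element = "C",
                 resid = "ALA", chain = "A", resno = seq_len(nRes),
                 x = ring(nRes, 5)[, 1], y = ring(nRes, 5)[, 2],
                 z = ring(nRes, 5)[, 3], b = 20, hetero = FALSE),
      data.frame(serial = nRes + 1, name = "C1", element = "C",
                 resid = "CLR", chain = "A", resno = 500,
                 x = 0, y = 0, z = 0, b = 20, hetero = TRUE))
    m <- StructureModel(a)
    list(m = m, lig = extractStandaloneLigands(m, "CLR")[[1]])
  }
  b12 <- buildCase(12)
  expect_true(isBuriedLigand(b12$m, b12$lig))
  b9 <- buildCase(9)
  expect_false(isBuriedLigand(b9$m, b9$lig))
  # no residues at all
  b0 <- b12
  expect_false(isBuriedLigand(
    StructureModel(atoms(b12$m)[atoms(b12$m)$hetero, , drop = FALSE]),
    b12$lig))
  # monotone in radius: buried at r stays buried at r' > r
  for (r in c(6, 8, 12))
    if (isBuriedLigand(b12$m, b12$lig, radius = r))
      expect_true(isBuriedLigand(b12$m, b12$lig, radius = r + 2))
})

test_that("N-terminal trimming removes the right residues and composes", {
  m <- makeCavityStructure(cavitySpec(nShellAtoms = 120, seed = 3))
  expect_equal(nResidues(m), 120)
  t22 <- trimNTerminal(m, 22)
  expect_equal(nResidues(t22), 98)
  expect_equal(polymerResidues(t22)$resno[1], 23)
  expect_identical(trimNTerminal(m, 0), m)
  # composition: trim k then j == trim k + j
  expect_equal(atoms(trimNTerminal(t22, 10)),
               atoms(trimNTerminal(m, 32)))
  expect_error(trimNTerminal(m, 120), "invalid cut")
})

test_that("mean pLDDT averages per-residue confidence", {
  m90 <- makeCavityStructure(cavitySpec(seed = 1, plddt = 90))
  expect_equal(meanPlddt(m90), 90)
  half <- makeCavityStructure(cavitySpec(nShellAtoms = 40, seed = 1,
                                         plddt = rep(c(60, 80), 20)))
  expect_equal(meanPlddt(half), 70)
  set.seed(42)
  v <- runif(60, 40, 100)
  mr <- makeCavityStructure(cavitySpec(seed = 2, plddt = v))
  expect_equal(meanPlddt(mr), mean(v))
  expect_error(
    meanPlddt(makeCavityStructure(cavitySpec(seed = 1),
                                  modelKind = "experimental")),
    "predicted")
})

test_that("signal-peptide tables read as named cut sites", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tcut_site", "P1\t22", "P2\t0"), path)
  sp <- readSignalPeptides(path)
  expect_equal(sp, c(P1 = 22L, P2 = 0L))
})
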