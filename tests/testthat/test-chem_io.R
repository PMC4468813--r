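test_that("SD reading recovers atoms, heavy counts and coordinates", {
  p1 <- withr::local_tempfile(fileext = ".sdf")
  write_fixture_sdf(p1, "methane_core", "C", matrix(0, 1, 3))
  lig <- read_ligand(p1)
  expect_equal(length(lig$elements), 1L)
  expect_equal(n_heavy_atoms(lig), 1L)
  expect_equal(unname(ligand_coords(lig)), matrix(0, 1, 3))

  p2 <- withr::local_tempfile(fileext = ".sdf")
  fixture_ethanol(p2)
  eth <- read_ligand(p2)
  expect_equal(length(eth$elements), 9L)
  expect_equal(n_heavy_atoms(eth), 3L)
  expect_equal(eth$name, "ethanol")
  # coordinate precision to the format's 4 decimals
  expect_equal(unname(ligand_coords(eth)[2, 1]), 1.512, tolerance = 1e-9)
})

test_that("write/read round trip preserves coordinates to 4 decimals", {
  lig <- synth_ligand(50, seed = 101)
  p <- withr::local_tempfile(fileext = ".sdf")
  write_ligand(lig, p)
  back <- read_ligand(p)
  expect_equal(back$elements, lig$elements)
  expect_lt(max(abs(ligand_coords(back) - ligand_coords(lig))), 1e-4 + 1e-12)

  # multi-conformer round trip
  xyz <- ligand_coords(lig, heavy_only = FALSE)
  multi <- ligand_structure(lig$name, lig$elements,
                            list(xyz, random_reorientation(xyz, seed = 5)))
  write_ligand(multi, p)
  back2 <- read_ligand(p)
  expect_equal(length(back2$conformers), 2L)
  expect_lt(max(abs(back2$conformers[[2]] - multi$conformers[[2]])), 1e-4 + 1e-12)
})

test_that("degenerate ligand inputs are rejected", {
  expect_error(ligand_structure("none", character(0),
                                matrix(numeric(0), 0, 3)), "at least one atom")
  expect_error(ligand_structure("bad", "C", matrix(c(1, 2, NA), 1, 3)),
               "non-finite")
  # conformer atom-count mismatch
  expect_error(ligand_structure("mix", c("C", "C"),
                                list(matrix(0, 2, 3), matrix(0, 3, 3))),
               "conformer 2")
  # multi-record SD file whose blocks disagree is not a conformer set
  p <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(fixture_sdf_text("a", "C", matrix(0, 1, 3)),
               fixture_sdf_text("b", c("C", "O"), matrix(0, 2, 3))), p)
  expect_error(read_ligand(p), "block 2")
})

test_that("SD reader agrees with an independent SDF parser", {
  sdf <- system.file("extdata", "nadp_conformer_generated.sdf",
                     package = "dockboxr")
  lig <- read_ligand(sdf)
  ref <- suppressWarnings(ChemmineR::read.SDFset(sdf))
  ab <- ChemmineR::atomblock(ref[[1]])
  expect_equal(nrow(ab), length(lig$elements))
  expect_equal(unname(ab[, 1:3]),
               unname(ligand_coords(lig, heavy_only = FALSE)),
               tolerance = 1e-9)
  expect_equal(sub("_.*$", "", rownames(ab)), lig$elements)
  expect_equal(n_heavy_atoms(lig), 48L)   # NADP heavy-atom count
})

test_that("PDB reading populates chains/residues and separates HETATM ligands", {
  p <- withr::local_tempfile(fileext = ".pdb")
  het <- matrix(c(10, 0, 0, 11.2, 0, 0, 10.6, 1.1, 0), 3, 3, byrow = TRUE)
  write_fixture_pdb(p, n_res = 2, het_xyz = het)
  prot <- read_protein(p)
  expect_equal(n_residues(prot), 2L)   # HETATM group not a protein residue
  lig <- extract_bound_ligand(prot, "LIG")
  expect_s3_class(lig, "ligand_structure")
  expect_equal(n_heavy_atoms(lig), 3L)
  expect_equal(unname(ligand_coords(lig)), unname(het), tolerance = 1e-9)
  expect_error(extract_bound_ligand(prot, "XYZ"), "no HETATM")
})

test_that("malformed or empty PDB input errors rather than silently zeroing", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), p)
  expect_error(read_protein(p))
  bad <- pdb_atom_line(1, "CA", "GLY", "A", 1, c(0, 0, 0))
  substr(bad, 31, 38) <- "  abcdef"   # corrupt the x field
  writeLines(c(bad, "END"), p)
  expect_error(read_protein(p), "malformed|parse")
})

test_that("PDBQT coordinate extraction ignores torsion-tree records", {
  xyz <- matrix(c(1.5, 0, 0, 0, 2.25, 0, 0, 0, -3.125), 3, 3, byrow = TRUE)
  p1 <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(fixture_pdbqt_lines(xyz), p1)
  plain <- read_pdbqt_coordinates(p1)
  expect_equal(n_heavy_atoms(plain), 3L)
  expect_equal(unname(ligand_coords(plain)), unname(xyz), tolerance = 1e-9)

  p2 <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(fixture_pdbqt_lines(xyz, with_branches = TRUE), p2)
  branched <- read_pdbqt_coordinates(p2)
  expect_equal(ligand_coords(branched), ligand_coords(plain))

  # hydrogens flagged from AutoDock types, not counted heavy
  p3 <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(fixture_pdbqt_lines(xyz, types = c("C", "HD", "OA")), p3)
  expect_equal(n_heavy_atoms(read_pdbqt_coordinates(p3)), 2L)

  writeLines("REMARK no atoms", p3)
  expect_error(read_pdbqt_coordinates(p3), "no ATOM")
})

test_that("PDBQT and SD renderings of the same pose agree", {
  lig <- synth_ligand(10, seed = 77)
  xyz <- round(ligand_coords(lig), 3)
  sdf <- withr::local_tempfile(fileext = ".sdf")
  write_fixture_sdf(sdf, "pose", lig$elements, xyz)
  pq <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(fixture_pdbqt_lines(xyz), pq)
  expect_equal(ligand_coords(read_pdbqt_coordinates(pq)),
               ligand_coords(read_ligand(sdf)), tolerance = 1e-3)
})

test_that("ligand curation applies the 6-100 heavy-atom window inclusively", {
  mk <- function(n) synth_ligand(n, seed = n)
  r5 <- curate_ligand(mk(5))
  expect_false(r5$passed)
  expect_equal(r5$reasons, "heavy_atom_min")
  expect_true(curate_ligand(mk(6))$passed)
  expect_true(curate_ligand(mk(100))$passed)
  r101 <- curate_ligand(mk(101))
  expect_false(r101$passed)
  expect_equal(r101$reasons, "heavy_atom_max")
  # every count inside the window passes
  for (n in c(7, 25, 50, 99)) expect_true(curate_ligand(mk(n))$passed)
  # covalent attachment fails regardless of size
  rc <- curate_ligand(mk(20), covalent = TRUE)
  expect_false(rc$passed)
  expect_equal(rc$reasons, "covalent")
  # hydrogens never counted heavy
  withH <- ligand_structure("h6", c(rep("C", 6), rep("H", 99)),
                            matrix(rnorm(105 * 3), 105, 3))
  expect_true(curate_ligand(withH)$passed)
})

test_that("protein curation applies the 50-600 residue window inclusively", {
  mkprot <- function(n) {
    protein_structure(data.frame(
      type = "ATOM", chain = "A", resno = seq_len(n), resid = "GLY",
      elety = "CA", elesy = "C", x = seq_len(n) * 3.8, y = 0, z = 0,
      stringsAsFactors = FALSE))
  }
  expect_false(curate_protein(mkprot(49))$passed)
  expect_true(curate_protein(mkprot(50))$passed)
  expect_true(curate_protein(mkprot(600))$passed)
  expect_false(curate_protein(mkprot(601))$passed)
  expect_equal(curate_protein(mkprot(49))$reasons, "residue_min")
  # a structure with only HETATM records has zero protein residues
  het_only <- protein_structure(data.frame(
    type = "HETATM", chain = "A", resno = 900, resid = "LIG",
    elety = "C1", elesy = "C", x = 0, y = 0, z = 0, stringsAsFactors = FALSE))
  expect_false(curate_protein(het_only)$passed)
})
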