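# Tiny in-code structure fixtures (built at test time; nothing stored).

# V2000 molblock text written independently of the package's writer, so the
# reader and writer are not tested against each other alone.
fixture_sdf_text <- function(name, elements, xyz) {
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   xyz[, 1], xyz[, 2], xyz[, 3], elements)
  c(name, "  fixture", "",
    sprintf("%3d  0  0  0  0  0  0  0  0  0999 V2000", nrow(xyz)),
    atoms, "M  END", "$$$$")
}

write_fixture_sdf <- function(path, name, elements, xyz) {
  writeLines(fixture_sdf_text(name, elements, xyz), path)
  path
}

# Ethanol heavy atoms + hydrogens (idealised coordinates)
fixture_ethanol <- function(path) {
  el <- c("C", "C", "O", "H", "H", "H", "H", "H", "H")
  xyz <- matrix(c(0.000, 0.000, 0.000,
                  1.512, 0.000, 0.000,
                  2.031, 1.317, 0.000,
                  -0.37, 1.02, 0.00,
                  -0.37, -0.51, 0.88,
                  -0.37, -0.51, -0.88,
                  1.88, -0.52, 0.88,
                  1.88, -0.52, -0.88,
                  2.99, 1.25, 0.00), ncol = 3, byrow = TRUE)
  write_fixture_sdf(path, "ethanol", el, xyz)
}

pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                          record = "ATOM", element = substr(trimws(name), 1, 1)) {
  # strict v3 columns: name 13-16, resName 18-20, chain 22, resSeq 23-26,
  # x/y/z 31-54, element 77-78
  sprintf("%-6s%5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, name, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], element)
}

# A small synthetic protein: n_res glycine-like residues along x, plus an
# optional HETATM ligand group.
write_fixture_pdb <- function(path, n_res = 2, het_xyz = NULL,
                              het_resname = "LIG") {
  lines <- character(0)
  serial <- 0L
  for (r in seq_len(n_res)) {
    for (at in c("N", "CA", "C")) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, at, "GLY", "A", r,
                                      c(3 * r + serial * 0.1, 0, 0)))
    }
  }
  if (!is.null(het_xyz)) {
    for (i in seq_len(nrow(het_xyz))) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, paste0("C", i), het_resname,
                                      "A", 900, het_xyz[i, ],
                                      record = "HETATM", element = "C"))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# PDBQT pose text (torsion-tree records optional)
fixture_pdbqt_lines <- function(xyz, types = rep("C", nrow(xyz)),
                                with_branches = FALSE) {
  atom <- function(i) sprintf(
    "ATOM  %5d  C%-2d LIG A   1    %8.3f%8.3f%8.3f  0.00  0.00    +0.000 %-2s",
    i, i, xyz[i, 1], xyz[i, 2], xyz[i, 3], types[i])
  body <- vapply(seq_len(nrow(xyz)), atom, character(1))
  if (with_branches) {
    c("ROOT", body[1], "ENDROOT", "BRANCH 1 2", body[-1],
      "ENDBRANCH 1 2", "TORSDOF 1")
  } else body
}
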