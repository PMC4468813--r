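#' Ligand structure container
#'
#' A named small molecule: one atom list (element symbols) shared by one or
#' more conformers (coordinate sets in Angstrom). Atoms other than hydrogen
#' are flagged heavy; size descriptors and docking boxes are computed over
#' heavy atoms only.
#'
#' @param name molecule name.
#' @param elements character vector of element symbols, one per atom.
#' @param coords an n x 3 numeric matrix (single conformer) or a list of such
#'   matrices (multi-conformer); all conformers share \code{elements} and the
#'   atom order.
#' @return An object of class \code{ligand_structure} with components
#'   \code{name}, \code{elements}, \code{is_heavy} and \code{conformers}
#'   (a list of n x 3 matrices; the first is the designated low-energy
#'   conformer).
#' @examples
#' lig <- ligand_structure("ethene", c("C", "C"),
#'                         matrix(c(0, 0, 0, 1.33, 0, 0), 2, 3, byrow = TRUE))
#' n_heavy_atoms(lig)
#' @export
ligand_structure <- function(name, elements, coords) {
  elements <- as.character(elements)
  if (length(elements) < 1L) stop("ligand must have at least one atom")
  if (is.matrix(coords) || is.data.frame(coords)) coords <- list(coords)
  if (!is.list(coords) || length(coords) < 1L)
    stop("coords must be a matrix or a non-empty list of matrices")
  conformers <- lapply(coords, as_coord_matrix, what = "ligand coordinates")
  for (i in seq_along(conformers)) {
    if (nrow(conformers[[i]]) != length(elements))
      stop("conformer ", i, " has ", nrow(conformers[[i]]),
           " atoms; expected ", length(elements))
    dimnames(conformers[[i]]) <- list(NULL, c("x", "y", "z"))
  }
  structure(list(name = as.character(name)[1L],
                 elements = elements,
                 is_heavy = toupper(elements) != "H",
                 conformers = conformers),
            class = "ligand_structure")
}

#' @export
print.ligand_structure <- function(x, ...) {
  cat("ligand_structure:", x$name, "\n")
  cat("  atoms:", length(x$elements), "(", sum(x$is_heavy), "heavy )\n")
  cat("  conformers:", length(x$conformers), "\n")
  invisible(x)
}

#' @rdname ligand_structure
#' @param ligand a \code{ligand_structure}.
#' @export
n_heavy_atoms <- function(ligand) {
  stopifnot(inherits(ligand, "ligand_structure"))
  sum(ligand$is_heavy)
}

#' Heavy-atom coordinates of one conformer
#'
#' @param ligand a \code{ligand_structure}.
#' @param conformer conformer index (1 = designated low-energy conformer).
#' @param heavy_only drop hydrogens (default \code{TRUE}).
#' @return n x 3 coordinate matrix in Angstrom.
#' @export
ligand_coords <- function(ligand, conformer = 1L, heavy_only = TRUE) {
  stopifnot(inherits(ligand, "ligand_structure"))
  if (conformer < 1L || conformer > length(ligand$conformers))
    stop("no conformer ", conformer, " (ligand has ",
         length(ligand$conformers), ")")
  xyz <- ligand$conformers[[conformer]]
  if (heavy_only) xyz <- xyz[ligand$is_heavy, , drop = FALSE]
  xyz
}

#' Read a ligand from an SD file
#'
#' Reads a V2000 SD file using strict fixed-width molblock columns
#' (coordinates in columns 1-30 of each atom line, element symbol in 32-34),
#' so the format's 4-decimal coordinate precision is preserved exactly.
#' When the file holds several molecule blocks they are interpreted as
#' conformers of the same molecule and must agree in atom count and element
#' order; the first block is the designated low-energy conformer.
#'
#' @param path path to an SD file.
#' @return A [ligand_structure].
#' @export
read_ligand <- function(path) {
  blocks <- read_molblocks(path)
  first <- blocks[[1L]]
  name <- if (nzchar(first$name)) first$name
          else tools::file_path_sans_ext(basename(path))
  if (length(blocks) > 1L) {
    for (i in 2:length(blocks)) {
      if (!identical(blocks[[i]]$elements, first$elements))
        stop("molecule block ", i, " in ", path,
             " does not match block 1 in atoms; multi-record SD files are",
             " read as conformer sets of a single molecule")
    }
  }
  ligand_structure(name, first$elements, lapply(blocks, `[[`, "xyz"))
}

# Split an SD file into V2000 molblocks and parse each; parse failures name
# the molecule index.
read_molblocks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  if (length(ends) == 0L) { starts <- 1L; ends <- length(lines) + 1L }
  blocks <- vector("list", length(starts))
  kept <- logical(length(starts))
  for (m in seq_along(starts)) {
    blk <- lines[starts[m]:(ends[m] - 1L)]
    blk <- blk[cumsum(nzchar(trimws(blk)) | seq_along(blk) <= 4) > 0]
    if (!any(nzchar(trimws(blk)))) next   # trailing empty record
    if (length(blk) < 5L)
      stop("truncated molecule block ", m, " in ", path)
    n_atoms <- suppressWarnings(as.integer(substr(blk[4L], 1L, 3L)))
    if (is.na(n_atoms) || n_atoms < 1L)
      stop("unreadable counts line in molecule ", m, " of ", path)
    if (length(blk) < 4L + n_atoms)
      stop("truncated atom block in molecule ", m, " of ", path)
    at <- blk[5:(4L + n_atoms)]
    xyz <- cbind(suppressWarnings(as.numeric(substr(at, 1L, 10L))),
                 suppressWarnings(as.numeric(substr(at, 11L, 20L))),
                 suppressWarnings(as.numeric(substr(at, 21L, 30L))))
    if (!all(is.finite(xyz)))
      stop("non-numeric coordinates in molecule ", m, " of ", path)
    elements <- trimws(substr(at, 32L, 34L))
    if (!all(nzchar(elements)))
      stop("missing element symbols in molecule ", m, " of ", path)
    blocks[[m]] <- list(name = trimws(blk[1L]), elements = elements, xyz = xyz)
    kept[m] <- TRUE
  }
  blocks <- blocks[kept]
  if (length(blocks) < 1L) stop("no molecule blocks in ", path)
  blocks
}

# V2000 molblock text for one conformer (coordinates-only; no bond table).
format_molblock <- function(ligand, conformer) {
  xyz <- ligand$conformers[[conformer]]
  n <- nrow(xyz)
  if (n > 999L) stop("V2000 molblock limited to 999 atoms")
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   xyz[, 1], xyz[, 2], xyz[, 3], ligand$elements)
  c(ligand$name, "  dockboxr", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L),
    atoms, "M  END", "$$$$")
}

#' Write a ligand to an SD file
#'
#' Emits one V2000 molecule block per conformer (coordinates and element
#' symbols; no bond table). Coordinates are written in the format's fixed
#' 4-decimal fields, so \code{read_ligand(write_ligand(x))} reproduces
#' coordinates to 1e-4 Angstrom.
#'
#' @param ligand a [ligand_structure].
#' @param path output path.
#' @param conformers indices of the conformers to write (default: all).
#' @return \code{path}, invisibly.
#' @export
write_ligand <- function(ligand, path, conformers = NULL) {
  stopifnot(inherits(ligand, "ligand_structure"))
  if (length(ligand$elements) < 1L) stop("refusing to write a ligand with no atoms")
  if (is.null(conformers)) conformers <- seq_along(ligand$conformers)
  lines <- unlist(lapply(conformers, function(i) format_molblock(ligand, i)))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Protein structure container
#'
#' Thin atom-table representation of a protein: one row per atom with chain,
#' residue number and name, atom name, element symbol, Cartesian coordinates
#' (Angstrom), and the record type (ATOM / HETATM). Residue counts used by
#' the curation filter run over ATOM records (the polypeptide).
#'
#' @param atoms data frame with columns \code{type}, \code{chain},
#'   \code{resno}, \code{resid}, \code{elety}, \code{elesy}, \code{x},
#'   \code{y}, \code{z}.
#' @return An object of class \code{protein_structure}.
#' @export
protein_structure <- function(atoms) {
  need <- c("type", "chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("protein atom table contains non-finite coordinates")
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE)),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure:", nrow(x$atoms), "atoms,",
      n_residues(x), "protein residues\n")
  invisible(x)
}

#' @rdname protein_structure
#' @param protein a \code{protein_structure}.
#' @export
n_residues <- function(protein) {
  stopifnot(inherits(protein, "protein_structure"))
  a <- protein$atoms[protein$atoms$type == "ATOM", , drop = FALSE]
  length(unique(paste(a$chain, a$resno)))
}

#' Read a protein from a PDB file
#'
#' Parses ATOM/HETATM records via \pkg{bio3d}. Files with malformed
#' coordinate fields or no coordinate records raise an error rather than
#' returning silent zeros.
#'
#' @param path path to a PDB file.
#' @return A [protein_structure].
#' @export
read_protein <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path)),
                  error = function(e) stop("cannot parse PDB ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) < 1L) stop("no ATOM/HETATM records in ", path)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("malformed coordinate columns in ", path)
  elesy <- at$elesy
  blank <- is.na(elesy) | !nzchar(trimws(elesy))
  # PDB dialect tolerance: fall back to the leading letter of the atom name
  elesy[blank] <- sub("^[0-9 ]*([A-Za-z]).*$", "\\1", at$elety[blank])
  protein_structure(data.frame(type = at$type, chain = at$chain,
                               resno = at$resno, resid = at$resid,
                               elety = at$elety, elesy = trimws(elesy),
                               x = at$x, y = at$y, z = at$z,
                               stringsAsFactors = FALSE))
}

#' Extract a bound ligand from a protein's HETATM records
#'
#' @param protein a [protein_structure].
#' @param resname HETATM residue name of the ligand (e.g. \code{"NAP"}).
#' @return A [ligand_structure] with one conformer (the bound pose).
#' @export
extract_bound_ligand <- function(protein, resname) {
  stopifnot(inherits(protein, "protein_structure"))
  sel <- protein$atoms$type == "HETATM" & protein$atoms$resid == resname
  if (!any(sel)) stop("no HETATM records with residue name ", resname)
  a <- protein$atoms[sel, , drop = FALSE]
  ligand_structure(resname, a$elesy, as.matrix(a[, c("x", "y", "z")]))
}

#' Extract heavy-atom coordinates from a PDBQT file
#'
#' Reads only the ATOM/HETATM coordinate lines of a PDBQT file (a docked
#' pose, typically); ROOT/BRANCH/TORSDOF and other torsion-tree records are
#' ignored. Partial charges and AutoDock atom types are not interpreted
#' beyond flagging hydrogens (types H, HD, HS).
#'
#' @param path path to a PDBQT file.
#' @return A [ligand_structure] with one conformer.
#' @export
read_pdbqt_coordinates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(rec) < 1L) stop("no ATOM/HETATM coordinate lines in ", path)
  num <- function(s) suppressWarnings(as.numeric(trimws(s)))
  x <- num(substr(rec, 31, 38)); y <- num(substr(rec, 39, 46))
  z <- num(substr(rec, 47, 54))
  if (any(is.na(x) | is.na(y) | is.na(z)))
    stop("malformed coordinate fields in ", path)
  adtype <- trimws(substr(rec, 78, 79))
  none <- !nzchar(adtype)
  adtype[none] <- sub("^[0-9]*([A-Za-z]).*$", "\\1",
                      trimws(substr(rec[none], 13, 16)))
  element <- ifelse(toupper(adtype) %in% c("H", "HD", "HS"), "H",
                    sub("^([A-Za-z]).*$", "\\1", adtype))
  ligand_structure(tools::file_path_sans_ext(basename(path)),
                   element, cbind(x, y, z))
}

#' Dataset-curation filters for ligands and proteins
#'
#' Benchmark-style curation rules: a ligand passes when it is non-covalently
#' bound and has 6 to 100 heavy atoms (bounds inclusive); a protein passes
#' when its polypeptide length is 50 to 600 residues (inclusive). Covalent
#' attachment is an input flag taken from database annotation, never inferred
#' from geometry.
#'
#' @param ligand a [ligand_structure].
#' @param covalent is the ligand covalently bound to its target?
#' @return A \code{curation_report}: list with \code{id}, \code{passed} and
#'   \code{reasons} (names of the failed rules; empty iff passed).
#' @examples
#' lig <- ligand_structure("tiny", rep("C", 5), matrix(rnorm(15), 5, 3))
#' curate_ligand(lig)$reasons   # "heavy_atom_min"
#' @export
curate_ligand <- function(ligand, covalent = FALSE) {
  stopifnot(inherits(ligand, "ligand_structure"), is.logical(covalent))
  n <- n_heavy_atoms(ligand)
  reasons <- character(0)
  if (n < 6L) reasons <- c(reasons, "heavy_atom_min")
  if (n > 100L) reasons <- c(reasons, "heavy_atom_max")
  if (isTRUE(covalent)) reasons <- c(reasons, "covalent")
  curation_report(ligand$name, reasons)
}

#' @rdname curate_ligand
#' @param protein a [protein_structure].
#' @export
curate_protein <- function(protein) {
  stopifnot(inherits(protein, "protein_structure"))
  n <- n_residues(protein)
  reasons <- character(0)
  if (n < 50L) reasons <- c(reasons, "residue_min")
  if (n > 600L) reasons <- c(reasons, "residue_max")
  curation_report("protein", reasons)
}

curation_report <- function(id, reasons) {
  structure(list(id = id, passed = length(reasons) == 0L, reasons = reasons),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("curation_report [", x$id, "]: ",
      if (x$passed) "PASS" else paste("FAIL:", paste(x$reasons, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}
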