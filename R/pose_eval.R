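#' Heavy-atom RMSD between two poses (no superposition)
#'
#' Root-mean-square deviation over heavy atoms between two conformers of the
#' same molecule, compared in a fixed frame (the receptor frame): no
#' superposition is applied, because a docked pose's placement error is part
#' of the deviation being measured. Correspondence is positional (atom i to
#' atom i); no symmetry correction is attempted, so highly symmetric ligands
#' may overestimate RMSD.
#'
#' @param pose_a,pose_b n x 3 heavy-atom coordinate matrices, or
#'   [ligand_structure]s (hydrogens dropped; designated conformer used).
#' @return RMSD in Angstrom.
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' heavy_atom_rmsd(a, a + rep(c(3, 0, 0), each = 10))  # 3
#' @export
heavy_atom_rmsd <- function(pose_a, pose_b) {
  a <- resolve_heavy_coords(pose_a)
  b <- resolve_heavy_coords(pose_b)
  if (nrow(a) != nrow(b))
    stop("heavy-atom count mismatch: ", nrow(a), " vs ", nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

#' Protein-ligand contact sets
#'
#' Contacts are defined by a heavy-atom distance cutoff (default 4.5
#' Angstrom, configurable): an approximation to surface-complementarity
#' contact programs, exposed as a parameter so it can be calibrated against
#' them. \code{specific_contacts} returns atom-pair granularity (one member
#' per protein-atom/ligand-atom pair within the cutoff);
#' \code{binding_residues} returns residue granularity (a residue is a
#' member when any of its heavy atoms is within the cutoff of any ligand
#' heavy atom — all atoms of a residue are equivalent).
#'
#' @param protein a [protein_structure]; its ATOM-record heavy atoms are
#'   used.
#' @param ligand_pose n x 3 heavy-atom matrix or [ligand_structure].
#' @param cutoff contact distance cutoff in Angstrom (closed ball: distance
#'   <= cutoff).
#' @return A \code{contact_set}: list with \code{granularity}
#'   (\code{"atom_pair"} or \code{"residue"}), \code{members} (character
#'   keys), \code{cutoff}.
#' @export
specific_contacts <- function(protein, ligand_pose, cutoff = 4.5) {
  pa <- protein_heavy_atoms(protein)
  lig <- resolve_heavy_coords(ligand_pose)
  d2 <- cross_dist2(as.matrix(pa[, c("x", "y", "z")]), lig)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  members <- if (nrow(hit)) paste0(pa$atom_key[hit[, 1]], "|L", hit[, 2])
             else character(0)
  contact_set("atom_pair", members, cutoff)
}

#' @rdname specific_contacts
#' @export
binding_residues <- function(protein, ligand_pose, cutoff = 4.5) {
  pa <- protein_heavy_atoms(protein)
  lig <- resolve_heavy_coords(ligand_pose)
  d2 <- cross_dist2(as.matrix(pa[, c("x", "y", "z")]), lig)
  close_atom <- apply(d2 <= cutoff^2, 1, any)
  contact_set("residue", unique(pa$res_key[close_atom]), cutoff)
}

protein_heavy_atoms <- function(protein) {
  stopifnot(inherits(protein, "protein_structure"))
  a <- protein$atoms
  a <- a[a$type == "ATOM" & toupper(a$elesy) != "H", , drop = FALSE]
  if (nrow(a) < 1L) stop("protein has no heavy ATOM records")
  a$res_key <- paste0(a$chain, ":", a$resno)
  a$atom_key <- paste0(a$res_key, ":", trimws(a$elety))
  a
}

# squared distances, rows of A x rows of B
cross_dist2 <- function(A, B) {
  outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
}

contact_set <- function(granularity, members, cutoff) {
  stopifnot(granularity %in% c("atom_pair", "residue"), cutoff > 0)
  structure(list(granularity = granularity,
                 members = unique(as.character(members)),
                 cutoff = cutoff),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat("contact_set [", x$granularity, ", cutoff ", x$cutoff, " A]: ",
      length(x$members), " members\n", sep = "")
  invisible(x)
}

#' Fraction of native contacts recovered by a predicted pose
#'
#' \code{|native intersect predicted| / |native|}, for two contact sets of
#' the same granularity and cutoff. An empty native set leaves the fraction
#' undefined and is an error.
#'
#' @param native,predicted \code{contact_set}s from [specific_contacts] or
#'   [binding_residues].
#' @return Fraction in [0, 1].
#' @export
fraction_recovered <- function(native, predicted) {
  stopifnot(inherits(native, "contact_set"), inherits(predicted, "contact_set"))
  if (native$granularity != predicted$granularity)
    stop("granularity mismatch: ", native$granularity, " vs ",
         predicted$granularity)
  if (!isTRUE(all.equal(native$cutoff, predicted$cutoff)))
    stop("cutoff mismatch: ", native$cutoff, " vs ", predicted$cutoff)
  if (length(native$members) == 0L)
    stop("native contact set is empty; fraction undefined")
  length(intersect(native$members, predicted$members)) / length(native$members)
}

#' Evaluate a predicted pose against the native complex
#'
#' Convenience wrapper computing the three pose-accuracy readouts at once:
#' heavy-atom RMSD, fraction of recovered binding residues, and fraction of
#' recovered specific (atom-pair) contacts.
#'
#' @param protein a [protein_structure].
#' @param native_pose,predicted_pose heavy-atom coordinate matrices or
#'   [ligand_structure]s.
#' @param cutoff contact cutoff in Angstrom.
#' @return List of class \code{pose_accuracy}: \code{rmsd},
#'   \code{frac_binding_residues}, \code{frac_specific_contacts}.
#' @export
pose_accuracy <- function(protein, native_pose, predicted_pose, cutoff = 4.5) {
  nat_res <- binding_residues(protein, native_pose, cutoff)
  nat_atm <- specific_contacts(protein, native_pose, cutoff)
  structure(list(
    rmsd = heavy_atom_rmsd(native_pose, predicted_pose),
    frac_binding_residues =
      fraction_recovered(nat_res, binding_residues(protein, predicted_pose, cutoff)),
    frac_specific_contacts =
      fraction_recovered(nat_atm, specific_contacts(protein, predicted_pose, cutoff))),
    class = "pose_accuracy")
}
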