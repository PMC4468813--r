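# Accept either a bare n x 3 matrix or a ligand_structure conformer; bare
# matrices are taken to be heavy atoms already.
resolve_heavy_coords <- function(x, conformer = 1L) {
  if (inherits(x, "ligand_structure")) {
    xyz <- ligand_coords(x, conformer, heavy_only = TRUE)
    if (nrow(xyz) < 1L) stop("ligand has no heavy atoms")
    xyz
  } else as_coord_matrix(x)
}

#' Geometric center of a point set
#'
#' Unweighted arithmetic mean per axis — the center used both for the radius
#' of gyration and for defining an experimental binding site as the center of
#' the bound ligand.
#'
#' @param coords n x 3 matrix of Cartesian coordinates (Angstrom).
#' @return Numeric length-3 vector.
#' @export
geometric_center <- function(coords) {
  colMeans(as_coord_matrix(coords))
}

#' Ligand radius of gyration
#'
#' Root-mean-square distance of the heavy atoms from their geometric center:
#' \deqn{R_g = \sqrt{\frac{1}{N}\sum_{k=1}^{N} |r_k - r_{center}|^2}}
#' with N the heavy-atom count. Hydrogens are excluded and no mass weighting
#' is applied (the center is geometric, not a center of mass). Rg is the size
#' descriptor driving the optimized docking box.
#'
#' @param ligand a [ligand_structure] (hydrogens dropped automatically) or a
#'   bare n x 3 heavy-atom coordinate matrix.
#' @param conformer conformer index when a ligand is supplied.
#' @return Rg in Angstrom (scalar, >= 0).
#' @examples
#' radius_of_gyration(matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE))  # 1.0
#' @export
radius_of_gyration <- function(ligand, conformer = 1L) {
  xyz <- resolve_heavy_coords(ligand, conformer)
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Single-conformer versus rotamer-ensemble radius of gyration
#'
#' Computes Rg for the designated low-energy conformer (conformer 1) and the
#' mean and standard deviation of Rg over a rotamer ensemble. The ensemble is
#' taken from the ligand's stored conformers; alternatively a
#' \code{rotamer_hook} (e.g. wrapping an external rotamer generator such as
#' Open Babel's obrotamer) can supply \code{n_rotamers} coordinate sets.
#'
#' @param ligand a [ligand_structure].
#' @param rotamer_hook optional \code{function(ligand, n)} returning a list
#'   of n x 3 coordinate matrices over the same atom list.
#' @param n_rotamers ensemble size requested from the hook (default 100).
#' @return List of class \code{rg_summary}: \code{rg_single}, \code{rg_mean},
#'   \code{rg_sd}, \code{n_rotamers}.
#' @export
rg_ensemble_summary <- function(ligand, rotamer_hook = NULL, n_rotamers = 100L) {
  stopifnot(inherits(ligand, "ligand_structure"))
  rg_single <- radius_of_gyration(ligand, 1L)
  if (!is.null(rotamer_hook)) {
    rots <- rotamer_hook(ligand, n_rotamers)
    rgs <- vapply(rots, function(m) radius_of_gyration(
      ligand_structure(ligand$name, ligand$elements, m)), numeric(1))
  } else if (length(ligand$conformers) > 1L) {
    rgs <- vapply(seq_along(ligand$conformers),
                  function(i) radius_of_gyration(ligand, i), numeric(1))
  } else {
    rgs <- rg_single
  }
  structure(list(rg_single = rg_single,
                 rg_mean = mean(rgs),
                 rg_sd = if (length(rgs) > 1L) stats::sd(rgs) else 0,
                 n_rotamers = length(rgs)),
            class = "rg_summary")
}

#' @export
print.rg_summary <- function(x, ...) {
  cat(sprintf("Rg (single conformer): %.3f A\n", x$rg_single))
  cat(sprintf("Rg (ensemble of %d):   %.3f +/- %.3f A\n",
              x$n_rotamers, x$rg_mean, x$rg_sd))
  invisible(x)
}

# Haar-uniform random rotation matrix via the uniform-unit-quaternion
# construction: with u1,u2,u3 ~ U(0,1),
#   q = (sqrt(1-u1) sin 2*pi*u2, sqrt(1-u1) cos 2*pi*u2,
#        sqrt(u1)   sin 2*pi*u3, sqrt(u1)   cos 2*pi*u3)
# is uniform on S^3, hence the induced rotation is uniform over SO(3).
random_rotation_matrix <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

rotate_about_center <- function(xyz, R, center = colMeans(xyz)) {
  shifted <- sweep(xyz, 2, center)
  out <- shifted %*% t(R)
  sweep(out, 2, center, `+`)
}

#' Randomly reorient a conformer
#'
#' Applies a rotation drawn uniformly over all 3-D rotations, about the
#' conformer's geometric center. Used before docking into predicted pockets
#' so the engine receives no orientational information about the native pose
#' ("the ligand is randomly spun around all axes"). A rigid motion: all
#' interatomic distances (and hence Rg) are preserved.
#'
#' @param coords n x 3 conformer coordinate matrix, or a [ligand_structure]
#'   (all conformers rotated jointly about the designated conformer's heavy
#'   atom center is \emph{not} done; each call rotates one matrix).
#' @param seed integer; the same seed reproduces the same rotation.
#' @return Rotated coordinate matrix of the same shape.
#' @export
random_reorientation <- function(coords, seed = NULL) {
  xyz <- as_coord_matrix(coords)
  R <- with_seed(seed, random_rotation_matrix())
  out <- rotate_about_center(xyz, R)
  dimnames(out) <- dimnames(xyz)
  out
}

#' Pocket center specification
#'
#' @param center numeric length-3 pocket center (Angstrom).
#' @param source \code{"experimental"} (geometric center of the bound ligand)
#'   or \code{"predicted"} (e.g. a binding-site prediction method).
#' @return Object of class \code{pocket_spec}.
#' @export
pocket_spec <- function(center, source = c("experimental", "predicted")) {
  center <- as.numeric(center)
  if (length(center) != 3L || !all(is.finite(center)))
    stop("pocket center must be 3 finite coordinates")
  structure(list(center = center, source = match.arg(source)),
            class = "pocket_spec")
}

#' @export
print.pocket_spec <- function(x, ...) {
  cat(sprintf("pocket_spec (%s): %.3f %.3f %.3f\n", x$source,
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

as_pocket_center <- function(pocket) {
  if (inherits(pocket, "pocket_spec")) pocket$center
  else {
    p <- as.numeric(pocket)
    if (length(p) != 3L || !all(is.finite(p))) stop("invalid pocket center")
    p
  }
}

#' Read pocket centers from a delimited table
#'
#' Expects a header line and columns \code{id}, \code{x}, \code{y}, \code{z},
#' \code{source} (experimental | predicted).
#'
#' @param path path to a whitespace- or tab-delimited text file.
#' @return Named list of [pocket_spec] objects.
#' @export
read_pocket_centers <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "z", "source")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("pocket table missing columns: ",
                         paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i)
    pocket_spec(c(tab$x[i], tab$y[i], tab$z[i]), tab$source[i]))
  names(out) <- tab$id
  out
}

#' Translate a conformer so its center sits on a pocket center
#'
#' Rigid translation moving the heavy-atom geometric center onto the pocket
#' center; internal geometry (and Rg) is unchanged. Idempotent.
#'
#' @param coords n x 3 conformer matrix (all rows treated as heavy atoms) or
#'   a [ligand_structure], whose designated conformer is recentered using its
#'   heavy-atom center (hydrogens ride along).
#' @param pocket a [pocket_spec] or numeric length-3 center.
#' @param conformer conformer index when a ligand is supplied.
#' @return Same type as \code{coords}, recentered.
#' @export
recenter_to_pocket <- function(coords, pocket, conformer = 1L) {
  target <- as_pocket_center(pocket)
  if (inherits(coords, "ligand_structure")) {
    heavy <- ligand_coords(coords, conformer, heavy_only = TRUE)
    shift <- target - colMeans(heavy)
    coords$conformers[[conformer]] <-
      sweep(coords$conformers[[conformer]], 2, shift, `+`)
    return(coords)
  }
  xyz <- as_coord_matrix(coords)
  sweep(xyz, 2, target - colMeans(xyz), `+`)
}

#' Was a pocket prediction successful?
#'
#' A predicted binding site counts as successful when its center lies within
#' 8 Angstrom of the experimental pocket center (strictly below; a distance
#' of exactly 8 fails).
#'
#' @param predicted,experimental [pocket_spec] objects or length-3 centers.
#' @param threshold success threshold in Angstrom (default 8).
#' @return Logical scalar.
#' @export
pocket_prediction_success <- function(predicted, experimental, threshold = 8) {
  d <- sqrt(sum((as_pocket_center(predicted) - as_pocket_center(experimental))^2))
  d < threshold
}
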