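# The optimized protocol is stored as the Rg-to-edge ratio; the printed
# multiplier 2.857 = 1 / 0.35 is derived from it, never rounded twice.
OPTIMAL_RG_RATIO <- 0.35

#' Axis-aligned docking search space
#'
#' @param center numeric length-3 box center (Angstrom).
#' @param size numeric length-3 edge lengths (Angstrom), all > 0.
#' @param protocol how the box was constructed: \code{"default"} (Vina-style
#'   bounding-box protocol; every edge >= 22.5 Angstrom), \code{"optimized"}
#'   (cubic, edge = Rg / 0.35) or \code{"sweep"} (cubic grid member).
#' @return Object of class \code{docking_box}.
#' @export
docking_box <- function(center, size, protocol = c("sweep", "default", "optimized")) {
  protocol <- match.arg(protocol)
  center <- as.numeric(center); size <- as.numeric(size)
  if (length(size) == 1L) size <- rep(size, 3L)
  if (length(center) != 3L || !all(is.finite(center)))
    stop("box center must be 3 finite coordinates")
  if (length(size) != 3L || !all(is.finite(size)) || any(size <= 0))
    stop("box sizes must be 3 positive numbers")
  if (protocol == "optimized" && diff(range(size)) > 1e-9)
    stop("optimized boxes are cubic")
  if (protocol == "default" && min(size) < 22.5 - 1e-9)
    stop("default-protocol boxes have every edge >= 22.5 Angstrom")
  structure(list(center = center, size = size, protocol = protocol),
            class = "docking_box")
}

#' @export
print.docking_box <- function(x, ...) {
  cat(sprintf("docking_box [%s]\n  center: %8.3f %8.3f %8.3f\n  size:   %8.3f %8.3f %8.3f\n",
              x$protocol, x$center[1], x$center[2], x$center[3],
              x$size[1], x$size[2], x$size[3]))
  invisible(x)
}

#' Default-protocol docking box (Vina emulation)
#'
#' Emulates the stock box construction: start from the axis-aligned bounding
#' box of the bound ligand's heavy atoms; grow each dimension by 10 Angstrom
#' (5 per side, symmetric); then, independently per dimension, pick one of
#' the two directions at random and extend that side by a further 5 Angstrom
#' (shifting the center by +/- 2.5); finally any dimension still below
#' 22.5 Angstrom is expanded symmetrically about its current center to
#' exactly 22.5. Edge lengths are therefore seed-independent
#' (\code{max(extent + 15, 22.5)} per axis); only the center depends on the
#' seed. Coin flips are drawn in x, y, z order.
#'
#' @param bound_ligand_coords heavy-atom coordinates of the bound ligand
#'   (n x 3 matrix) or a [ligand_structure].
#' @param seed integer seed for the three direction coins.
#' @return A [docking_box] with protocol \code{"default"}.
#' @examples
#' default_box(matrix(0, 1, 3), seed = 1)$size   # 22.5 22.5 22.5
#' @export
default_box <- function(bound_ligand_coords, seed = NULL) {
  xyz <- resolve_heavy_coords(bound_ligand_coords)
  lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
  size <- (hi - lo) + 10
  center <- (hi + lo) / 2
  flip <- with_seed(seed, stats::runif(3) < 0.5)
  size <- size + 5
  center <- center + ifelse(flip, 2.5, -2.5)
  size <- pmax(size, 22.5)  # symmetric floor expansion: center unchanged
  docking_box(center, size, "default")
}

#' Optimized docking box from the ligand radius of gyration
#'
#' A cubic search space sized to the docking compound: edge length
#' Rg / 0.35 = 2.857 x Rg, centered exactly on the binding-pocket center.
#' This is the box size at which pose-prediction accuracy peaks in
#' edge-sweep experiments, and it requires no bound-ligand coordinates —
#' only the query compound's Rg and a pocket center (experimental or
#' predicted).
#'
#' @param rg ligand radius of gyration in Angstrom (> 0); see
#'   [radius_of_gyration].
#' @param pocket a [pocket_spec] or numeric length-3 pocket center.
#' @return A [docking_box] with protocol \code{"optimized"}.
#' @examples
#' optimized_box(1.0, c(0, 0, 0))$size       # 2.857 2.857 2.857
#' optimized_box(6.61, c(0, 0, 0))$size[1]   # 18.89 (case-study scale)
#' @export
optimized_box <- function(rg, pocket) {
  if (!is.numeric(rg) || length(rg) != 1L || !is.finite(rg) || rg <= 0)
    stop("rg must be a single positive number")
  docking_box(as_pocket_center(pocket), rep(rg / OPTIMAL_RG_RATIO, 3L),
              "optimized")
}

#' Sweep-protocol grid of cubic boxes
#'
#' @param edge_min,edge_max,edge_step grid of cube edge lengths in Angstrom;
#'   the default 2 to 36 in steps of 2 gives 18 boxes.
#' @return Object of class \code{sweep_spec}.
#' @export
sweep_spec <- function(edge_min = 2, edge_max = 36, edge_step = 2) {
  if (edge_min <= 0 || edge_step <= 0 || edge_min > edge_max)
    stop("need 0 < edge_min <= edge_max and edge_step > 0")
  structure(list(edge_min = edge_min, edge_max = edge_max,
                 edge_step = edge_step), class = "sweep_spec")
}

#' @rdname sweep_spec
#' @param pocket a [pocket_spec] or numeric length-3 center shared by all
#'   boxes.
#' @param spec a \code{sweep_spec}.
#' @return \code{sweep_boxes}: list of cubic [docking_box] objects centered
#'   on the pocket, edges increasing.
#' @export
sweep_boxes <- function(pocket, spec = sweep_spec()) {
  stopifnot(inherits(spec, "sweep_spec"))
  center <- as_pocket_center(pocket)
  edges <- seq(spec$edge_min, spec$edge_max, by = spec$edge_step)
  lapply(edges, function(e) docking_box(center, rep(e, 3L), "sweep"))
}

#' Relative box size (Rg-to-edge ratio)
#'
#' The dimensionless ratio of the ligand radius of gyration to the cubic box
#' edge — the x-axis of box-size sweep curves. Defined for cubic boxes only.
#'
#' @param rg ligand radius of gyration (Angstrom).
#' @param box a cubic [docking_box].
#' @return \code{rg / edge}.
#' @export
relative_box_size <- function(rg, box) {
  stopifnot(inherits(box, "docking_box"))
  if (diff(range(box$size)) > 1e-9)
    stop("relative box size is defined for cubic boxes only")
  rg / box$size[1]
}

#' @rdname relative_box_size
#' @return \code{box_volume}: the box volume in cubic Angstrom.
#' @export
box_volume <- function(box) {
  stopifnot(inherits(box, "docking_box"))
  prod(box$size)
}

#' Write / parse a Vina-style docking configuration file
#'
#' Emits \code{key = value} lines (receptor, ligand, center_x/y/z,
#' size_x/y/z, plus optional passthrough keys such as exhaustiveness) with
#' 3-decimal fixed-point coordinates; \code{read_docking_config} recovers the
#' box to 1e-3 Angstrom.
#'
#' @param box a [docking_box].
#' @param receptor_path,ligand_path paths recorded in the config.
#' @param out_path output file path.
#' @param extra named list/vector of extra key-value pairs to pass through.
#' @return \code{out_path}, invisibly.
#' @export
write_docking_config <- function(box, receptor_path, ligand_path, out_path,
                                 extra = NULL) {
  stopifnot(inherits(box, "docking_box"))
  lines <- c(paste("receptor =", receptor_path),
             paste("ligand =", ligand_path),
             sprintf("center_%s = %.3f", c("x", "y", "z"), box$center),
             sprintf("size_%s = %.3f", c("x", "y", "z"), box$size))
  if (!is.null(extra))
    lines <- c(lines, paste(names(extra), "=", unlist(extra)))
  tryCatch(writeLines(lines, out_path),
           error = function(e) stop("cannot write ", out_path, ": ",
                                    conditionMessage(e)))
  invisible(out_path)
}

#' @rdname write_docking_config
#' @param path a config file written by \code{write_docking_config} (or by
#'   hand in the same key = value dialect).
#' @return \code{read_docking_config}: list with \code{box} (a
#'   [docking_box], protocol tagged \code{"sweep"} since the file does not
#'   record provenance), \code{receptor}, \code{ligand} and \code{extra}.
#' @export
read_docking_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  key <- trimws(sub("=.*$", "", lines))
  val <- trimws(sub("^[^=]*=", "", lines))
  kv <- stats::setNames(as.list(val), key)
  need <- c(paste0("center_", c("x", "y", "z")), paste0("size_", c("x", "y", "z")))
  if (!all(need %in% key)) stop("config missing box keys in ", path)
  center <- as.numeric(unlist(kv[paste0("center_", c("x", "y", "z"))]))
  size <- as.numeric(unlist(kv[paste0("size_", c("x", "y", "z"))]))
  list(box = docking_box(center, size, "sweep"),
       receptor = kv[["receptor"]], ligand = kv[["ligand"]],
       extra = kv[setdiff(key, c(need, "receptor", "ligand"))])
}
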