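#' Synthetic ligand: self-avoiding random-walk chain
#'
#' Generates a toy ligand as a fixed-step self-avoiding chain of heavy
#' (carbon) atoms: each atom is placed one bond length from the previous one
#' in a random direction, rejecting placements within 80\% of the bond
#' length of any earlier atom. The chain statistics give Rg growing with the
#' heavy-atom count, which is the only property the fixtures need.
#'
#' @param n_heavy number of heavy atoms (1 to 200).
#' @param bond_length step length in Angstrom (default 1.5, a typical C-C
#'   bond).
#' @param seed integer; same seed, same chain.
#' @return A [ligand_structure] of \code{n_heavy} carbons, one conformer.
#' @export
synth_ligand <- function(n_heavy, bond_length = 1.5, seed = NULL) {
  if (n_heavy < 1L || n_heavy > 200L) stop("n_heavy must be in 1..200")
  xyz <- with_seed(seed, {
    for (restart in 1:25) {
      pts <- matrix(0, n_heavy, 3)
      ok <- TRUE
      if (n_heavy > 1L) for (i in 2:n_heavy) {
        placed <- FALSE
        for (try in 1:100) {
          dir <- stats::rnorm(3)
          cand <- pts[i - 1, ] + bond_length * dir / sqrt(sum(dir^2))
          d <- sqrt(rowSums(sweep(pts[seq_len(i - 1), , drop = FALSE], 2, cand)^2))
          if (all(d >= 0.8 * bond_length - 1e-9)) {
            pts[i, ] <- cand; placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) stop("could not place a self-avoiding chain of ", n_heavy,
                  " atoms after bounded retries")
    pts
  })
  ligand_structure(sprintf("synth%03d", n_heavy), rep("C", n_heavy), xyz)
}

#' Synthetic protein-ligand complex with a planted pocket
#'
#' Builds a mock complex for exercising the docking-evaluation machinery:
#' the synthetic ligand's native pose is centered on a planted pocket
#' center, and the receptor is a shell of single-atom pseudo-residues: half
#' are anchored 3.5 Angstrom radially outward from individual native ligand
#' atoms (guaranteeing native protein-ligand contacts at the default 4.5
#' Angstrom cutoff), the rest lie on a random outer shell 3.5 Angstrom
#' beyond the ligand's outermost atom. Deliberately non-physical:
#' single-atom residues suffice for contact-set logic.
#'
#' @param n_heavy ligand heavy-atom count.
#' @param seed integer master seed for this complex.
#' @param n_shell number of pseudo-residues in the receptor shell.
#' @param pocket_center planted pocket center (default origin).
#' @return List of class \code{mock_complex}: \code{receptor}
#'   ([protein_structure]), \code{ligand} ([ligand_structure]),
#'   \code{native_pose} (heavy-atom matrix), \code{pocket} ([pocket_spec]).
#' @export
synth_complex <- function(n_heavy = 12L, seed = NULL, n_shell = 40L,
                          pocket_center = c(0, 0, 0)) {
  lig <- synth_ligand(n_heavy, seed = derive_seed(if (is.null(seed)) 0 else seed, 1L))
  native <- recenter_to_pocket(ligand_coords(lig), pocket_center)
  r_max <- max(sqrt(rowSums(sweep(native, 2, pocket_center)^2)))
  shell_r <- r_max + 3.5
  shell <- with_seed(derive_seed(if (is.null(seed)) 0 else seed, 2L), {
    n_anchor <- min(nrow(native), ceiling(n_shell / 2))
    anchor_at <- sample(nrow(native), n_anchor)
    anchored <- t(vapply(anchor_at, function(i) {
      v <- native[i, ] - pocket_center
      nv <- sqrt(sum(v^2))
      u <- if (nv < 1e-8) { d <- stats::rnorm(3); d / sqrt(sum(d^2)) } else v / nv
      native[i, ] + 3.5 * u
    }, numeric(3)))
    n_rand <- n_shell - n_anchor
    m <- matrix(stats::rnorm(3 * n_rand), n_rand, 3)
    m <- m / sqrt(rowSums(m^2))
    rbind(anchored, sweep(m * shell_r, 2, pocket_center, `+`))
  })
  receptor <- protein_structure(data.frame(
    type = "ATOM", chain = "A", resno = seq_len(n_shell), resid = "PSD",
    elety = "CA", elesy = "C",
    x = shell[, 1], y = shell[, 2], z = shell[, 3],
    stringsAsFactors = FALSE))
  structure(list(receptor = receptor, ligand = lig, native_pose = native,
                 pocket = pocket_spec(pocket_center, "experimental")),
            class = "mock_complex")
}

#' Mock docking backend
#'
#' A stand-in docking engine whose only purpose is to exercise the sweep and
#' evaluation machinery while reproducing the two qualitative failure modes
#' of box-size selection. It samples rigid placements of the ligand inside
#' the box: a uniform random orientation, then a center drawn uniformly over
#' the centers at which that orientation fits entirely inside the box. An
#' orientation that cannot fit is rejected — so a box too small to contain
#' the ligand in its native orientation makes the correct mode unreachable
#' and forces distorted placements (sampling failure), and a box too small
#' for any orientation returns nothing. Each accepted placement is scored by
#' its RMSD to the native pose plus Gaussian noise whose magnitude grows
#' with the box edge — so overly generous boxes rank wrong poses first
#' (scoring failure). The score is explicitly non-physical.
#'
#' @param complex a \code{mock_complex} from [synth_complex].
#' @param box a [docking_box].
#' @param seed integer seed; fixed seed gives an identical pose list.
#' @param n_samples placements attempted (default 50).
#' @param noise_coef score noise standard deviation per Angstrom of box edge
#'   (default 0.08).
#' @param noise_floor optional baseline score noise standard deviation in
#'   Angstrom, added to the edge-proportional term (default 0).
#' @return List of class \code{mock_poses}, sorted by score (best first);
#'   each element has \code{coords} (heavy-atom matrix, center inside the
#'   box) and \code{score}. Length 0 when no placement fits in the box.
#' @export
mock_dock <- function(complex, box, seed = NULL, n_samples = 50L,
                      noise_coef = 0.08, noise_floor = 0) {
  stopifnot(inherits(complex, "mock_complex"), inherits(box, "docking_box"))
  native <- complex$native_pose
  lo <- box$center - box$size / 2
  hi <- box$center + box$size / 2
  edge <- mean(box$size)
  native0 <- sweep(native, 2, colMeans(native))
  n_at <- nrow(native0)
  ns <- as.integer(n_samples)
  poses <- with_seed(seed, {
    # one batched draw per quantity: rotation quaternion components, center
    # fractions, score noise
    u <- matrix(stats::runif(3L * ns), ns, 3L)
    ctru <- matrix(stats::runif(3L * ns), ns, 3L)
    noise <- stats::rnorm(ns, 0, noise_floor + noise_coef * edge)
    # Haar-uniform rotations from uniform unit quaternions, all at once
    qx <- sqrt(1 - u[, 1]) * sin(2 * pi * u[, 2])
    qy <- sqrt(1 - u[, 1]) * cos(2 * pi * u[, 2])
    qz <- sqrt(u[, 1]) * sin(2 * pi * u[, 3])
    qw <- sqrt(u[, 1]) * cos(2 * pi * u[, 3])
    tr <- matrix(0, 3L, 3L * ns)   # columns 3i-2..3i hold t(R_i)
    tr[, seq(1L, 3L * ns, by = 3L)] <-
      rbind(1 - 2 * (qy^2 + qz^2), 2 * (qx * qy - qz * qw), 2 * (qx * qz + qy * qw))
    tr[, seq(2L, 3L * ns, by = 3L)] <-
      rbind(2 * (qx * qy + qz * qw), 1 - 2 * (qx^2 + qz^2), 2 * (qy * qz - qx * qw))
    tr[, seq(3L, 3L * ns, by = 3L)] <-
      rbind(2 * (qx * qz - qy * qw), 2 * (qy * qz + qx * qw), 1 - 2 * (qx^2 + qy^2))
    cand_all <- native0 %*% tr     # rotated copies, centered at the origin
    cmin <- matrix(Reduce(pmin, asplit(cand_all, 1L)), ns, 3L, byrow = TRUE)
    cmax <- matrix(Reduce(pmax, asplit(cand_all, 1L)), ns, 3L, byrow = TRUE)
    # feasible centers for orientation i: [lo - cmin_i, hi - cmax_i]
    clo <- rep(lo, each = ns) - cmin
    chi <- rep(hi, each = ns) - cmax
    fits <- rowSums(chi < clo) == 0          # orientation can fit at all
    ctr <- clo + ctru * (chi - clo)
    out <- vector("list", sum(fits))
    k <- 0L
    for (i in which(fits)) {
      cand <- cand_all[, (3L * i - 2L):(3L * i), drop = FALSE] +
        rep(ctr[i, ], each = n_at)
      k <- k + 1L
      out[[k]] <- list(coords = cand,
                       score = sqrt(mean(rowSums((cand - native)^2))) + noise[i])
    }
    out
  })
  if (length(poses))
    poses <- poses[order(vapply(poses, `[[`, numeric(1), "score"))]
  structure(poses, class = "mock_poses")
}

#' Box-edge sweep over a set of complexes
#'
#' Runs the box-size sweep experiment: for each complex and each cubic box
#' edge in the sweep grid, dock with the backend, evaluate the top pose
#' against the native complex (RMSD, binding-residue recovery, specific
#' contact recovery), express the box by its relative size (Rg / edge), bin
#' the points by relative size, and average each metric per bin. Backend
#' failures (no pose fits the box) are recorded per point and excluded from
#' the bin means, never fatal.
#'
#' @param complexes list of \code{mock_complex} objects.
#' @param spec a [sweep_spec].
#' @param backend callable \code{(complex, box, seed) -> ranked poses};
#'   default [mock_dock].
#' @param seed master seed; per-(complex, edge) seeds are derived from it
#'   deterministically, so sub-sweeps are reproducible in isolation.
#' @param cutoff contact cutoff in Angstrom.
#' @param bin_width relative-box-size bin width (default 0.05).
#' @return A \code{sweep_curve}: data frame with one row per ratio bin,
#'   columns \code{ratio} (mean Rg/edge within the bin), \code{mean_rmsd},
#'   \code{mean_frac_residues}, \code{mean_frac_contacts}, \code{n_points},
#'   \code{n_failed}; ratios strictly increasing. The per-point table is
#'   attached as \code{attr(, "points")}.
#' @export
run_ratio_sweep <- function(complexes, spec = sweep_spec(),
                            backend = mock_dock, seed = 1L, cutoff = 4.5,
                            bin_width = 0.05) {
  stopifnot(length(complexes) >= 1L)
  rows <- list()
  counter <- 0L
  for (ci in seq_along(complexes)) {
    cx <- complexes[[ci]]
    rg <- radius_of_gyration(cx$ligand)
    boxes <- sweep_boxes(cx$pocket, spec)
    for (b in boxes) {
      counter <- counter + 1L
      ratio <- relative_box_size(rg, b)
      poses <- backend(cx, b, seed = derive_seed(seed, counter))
      if (length(poses) == 0L) {
        rows[[counter]] <- data.frame(complex = ci, edge = b$size[1],
                                      ratio = ratio, rmsd = NA_real_,
                                      frac_residues = NA_real_,
                                      frac_contacts = NA_real_, failed = TRUE)
        next
      }
      acc <- pose_accuracy(cx$receptor, cx$native_pose, poses[[1]]$coords,
                           cutoff = cutoff)
      rows[[counter]] <- data.frame(complex = ci, edge = b$size[1],
                                    ratio = ratio, rmsd = acc$rmsd,
                                    frac_residues = acc$frac_binding_residues,
                                    frac_contacts = acc$frac_specific_contacts,
                                    failed = FALSE)
    }
  }
  pts <- do.call(rbind, rows)
  bin <- floor(pts$ratio / bin_width)
  ok <- !pts$failed
  agg <- lapply(split(seq_len(nrow(pts)), bin), function(ii) {
    jj <- ii[ok[ii]]
    data.frame(ratio = mean(pts$ratio[ii]),
               mean_rmsd = if (length(jj)) mean(pts$rmsd[jj]) else NA_real_,
               mean_frac_residues = if (length(jj)) mean(pts$frac_residues[jj]) else NA_real_,
               mean_frac_contacts = if (length(jj)) mean(pts$frac_contacts[jj]) else NA_real_,
               n_points = length(jj), n_failed = length(ii) - length(jj))
  })
  curve <- do.call(rbind, agg)
  curve <- curve[order(curve$ratio), , drop = FALSE]
  rownames(curve) <- NULL
  class(curve) <- c("sweep_curve", "data.frame")
  attr(curve, "points") <- pts
  curve
}

#' Locate the optimum of a box-size sweep curve, failure-aware
#'
#' Finds the relative box size at which each accuracy metric of a
#' [run_ratio_sweep] curve is best. Ratio bins where every docking attempt
#' failed (the box could not contain the ligand) enter the search as
#' worst-case outcomes — an unreachable native pose has unbounded RMSD and
#' recovers no contacts — rather than being dropped, so the sampling-failure
#' limb of the curve counts against small boxes. A metric's optimum is
#' \emph{interior} when it falls strictly between the first and last ratio
#' bin of the full sweep grid.
#'
#' @param curve a \code{sweep_curve} from [run_ratio_sweep].
#' @return Data frame with one row per metric (\code{rmsd},
#'   \code{frac_residues}, \code{frac_contacts}): the optimal \code{ratio}
#'   and whether the optimum is \code{interior}.
#' @export
sweep_optimum <- function(curve) {
  stopifnot(inherits(curve, "sweep_curve"))
  v <- curve$mean_rmsd
  v[is.na(v)] <- Inf                       # all-failed bin: native unreachable
  fr <- curve$mean_frac_residues; fr[is.na(fr)] <- 0   # failure recovers nothing
  fc <- curve$mean_frac_contacts; fc[is.na(fc)] <- 0
  idx <- c(rmsd = which.min(v), frac_residues = which.max(fr),
           frac_contacts = which.max(fc))
  data.frame(metric = names(idx), ratio = curve$ratio[idx],
             interior = idx > 1L & idx < nrow(curve),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Synthetic ranked library with planted active/decoy separation
#'
#' Draws docking scores from two Normal models — one for actives, one for
#' decoys — mimicking the pooled score distributions seen in affinity
#' benchmarks (defaults: actives N(-8.70, sd), decoys N(-7.85, sd),
#' sd = 2.1), then ranks ascending. Lower scores mean stronger predicted
#' binding, so a more negative active mean plants real enrichment.
#'
#' @param n_actives,n_decoys class sizes (>= 1).
#' @param mean_active,mean_decoy class score means.
#' @param sd common score standard deviation (> 0).
#' @param seed integer seed.
#' @return A [ranked_library].
#' @export
synth_ranked_library <- function(n_actives, n_decoys, mean_active = -8.70,
                                 mean_decoy = -7.85, sd = 2.1, seed = NULL) {
  if (n_actives < 1L || n_decoys < 1L) stop("need at least one of each class")
  if (sd <= 0) stop("sd must be positive")
  scores <- with_seed(seed, c(stats::rnorm(n_actives, mean_active, sd),
                              stats::rnorm(n_decoys, mean_decoy, sd)))
  ranked_library(c(sprintf("ACT%05d", seq_len(n_actives)),
                   sprintf("DEC%05d", seq_len(n_decoys))),
                 scores,
                 c(rep("active", n_actives), rep("decoy", n_decoys)))
}

# Larger is better for enrichment-style metrics; ACT-50% is a cost.
METRIC_HIGHER_BETTER <- c(ef_1pct = TRUE, ef_10pct = TRUE, bedroc20 = TRUE,
                          auc = TRUE, act50 = FALSE)

#' Paired comparison of two docking protocols
#'
#' Compares per-target ranking metrics between two protocols (e.g. default
#' vs optimized box): per metric, the mean and standard deviation in each
#' arm, the Wilcoxon signed-rank two-sided p-value on the paired
#' differences, and the fraction of targets where the optimized arm beats
#' the default (ties count 1/2; "beats" respects each metric's direction —
#' higher is better except for ACT-50\%, where lower is better).
#'
#' @param default_reports,optimized_reports data frames of per-target metric
#'   rows (as produced by [metric_report]), equal length, paired by row.
#' @return Data frame of class \code{protocol_comparison}: one row per
#'   metric with \code{mean_default}, \code{sd_default},
#'   \code{mean_optimized}, \code{sd_optimized}, \code{p_wilcoxon}
#'   (\code{NA} with note \code{"no difference"} when all pairs tie) and
#'   \code{win_fraction}.
#' @export
compare_protocols <- function(default_reports, optimized_reports) {
  d <- as.data.frame(default_reports)
  o <- as.data.frame(optimized_reports)
  if (nrow(d) != nrow(o))
    stop("paired lists differ in length: ", nrow(d), " vs ", nrow(o))
  metrics <- intersect(names(METRIC_HIGHER_BETTER), intersect(names(d), names(o)))
  if (!length(metrics)) stop("no shared metric columns")
  out <- lapply(metrics, function(m) {
    diffs <- o[[m]] - d[[m]]
    p <- tryCatch(wilcoxon_signed_rank(diffs)$p, error = function(e) NA_real_)
    better <- if (METRIC_HIGHER_BETTER[[m]]) diffs > 0 else diffs < 0
    win <- (sum(better) + 0.5 * sum(diffs == 0)) / length(diffs)
    data.frame(metric = m,
               mean_default = mean(d[[m]]), sd_default = stats::sd(d[[m]]),
               mean_optimized = mean(o[[m]]), sd_optimized = stats::sd(o[[m]]),
               p_wilcoxon = p,
               note = if (is.na(p)) "no difference" else "",
               win_fraction = win,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("protocol_comparison", "data.frame")
  res
}
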