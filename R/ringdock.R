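#' Ring symmetry axis
#'
#' Detects the symmetry axis of a ring-shaped (disc-like) oligomer as the
#' eigenvector of the coordinate gyration tensor with the smallest
#' eigenvalue, sign-fixed toward positive z (then positive x). Flat rings
#' make this well-posed; near-spherical atom clouds are rejected.
#'
#' @param s an \code{iqa_structure} with at least 3 chains.
#' @return list with unit \code{axis} (length-3) and \code{center}
#'   (centroid).
#' @export
ring_axis <- function(s) {
  if (n_chains(s) < 3)
    stop_iqa("iqa_needs_ring", "ring axis detection requires >= 3 chains")
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  center <- colMeans(xyz)
  gyr <- crossprod(sweep(xyz, 2, center)) / nrow(xyz)
  eg <- eigen(gyr, symmetric = TRUE)
  lam <- rev(eg$values)            # ascending
  if ((lam[2] - lam[1]) / lam[3] < 0.1)
    stop_iqa("iqa_ambiguous_axis",
             "gyration tensor nearly degenerate; no unique ring axis")
  axis <- eg$vectors[, 3]
  if (axis[3] < 0 || (axis[3] == 0 && axis[1] < 0)) axis <- -axis
  list(axis = axis / sqrt(sum(axis^2)), center = center)
}

# Canonicalize a ring: axis -> +z, centroid -> origin.
canonical_ring <- function(s) {
  ax <- ring_axis(s)
  R <- rotation_between(ax$axis, c(0, 0, 1))
  transform_structure(s, R = R, t = -as.vector(R %*% ax$center))
}

#' Enumerate coaxial two-ring docking poses
#'
#' Aligns both rings on a common (z) axis and enumerates rigid arrangements
#' of ring B above ring A over a grid of axial offsets (descending in
#' \code{trans_step} decrements from the first-contact separation, the
#' largest grid offset at which any cross-ring atom pair is within contact
#' range) and axial rotations (in \code{rot_step} increments over
#' \code{[0, 360/symmetry_order)}; the cyclic symmetry of B makes the rest of
#' the circle redundant). The offset scan stops before the first offset at
#' which every rotation violates the clash rule, so the pose count is exactly
#' n_offsets x n_rotations. Each pose records its clash fraction: among
#' cross-ring atom pairs within contact range, the fraction closer than
#' \code{clash_ratio} times the sum of their radii (normalizing by in-range
#' pairs keeps the gate independent of ring size).
#'
#' @param ringA,ringB ring-shaped \code{iqa_structure} objects with radii.
#' @param trans_step axial translation step in Angstrom (default 1).
#' @param rot_step rotation step in degrees (default 2).
#' @param symmetry_order cyclic symmetry order of ring B; default: its chain
#'   count.
#' @param probe probe radius defining contact range
#'   (\code{r_i + r_j + 2 probe}).
#' @param clash_ratio pair-clash distance ratio (default 0.6).
#' @param clash_frac_max maximum tolerated clash fraction (default 0.001).
#' @return An object of class \code{iqa_pose_set}: data.frame with columns
#'   \code{offset}, \code{rotation}, \code{clash_fraction}, \code{score}
#'   (NA until scored); canonicalized rings, grid and clash parameters are
#'   kept as attributes. Empty (with a warning) if the rings never reach
#'   contact range.
#' @export
enumerate_poses <- function(ringA, ringB, trans_step = 1, rot_step = 2,
                            symmetry_order = NULL, probe = 1.4,
                            clash_ratio = 0.6, clash_frac_max = 0.001) {
  A <- canonical_ring(ringA)
  B <- canonical_ring(ringB)
  if (is.null(symmetry_order)) symmetry_order <- n_chains(ringB)
  n_rot <- max(1L, floor((360 / symmetry_order - 1e-9) / rot_step) + 1L)
  rotations <- (seq_len(n_rot) - 1L) * rot_step

  axyz <- as.matrix(A$atoms[, c("x", "y", "z")])
  bxyz <- as.matrix(B$atoms[, c("x", "y", "z")])
  ra <- A$atoms$radius; rb <- B$atoms$radius
  contact_rng <- outer(ra, rb, "+") + 2 * probe
  clash_rng2 <- (clash_ratio * outer(ra, rb, "+"))^2

  # per rotation: xy-plane distances and base z differences
  rot_geo <- lapply(rotations, function(th) {
    Rz <- rotation_matrix(c(0, 0, 1), th * pi / 180)
    bx <- bxyz %*% t(Rz)
    d2xy <- outer(axyz[, 1]^2 + axyz[, 2]^2, bx[, 1]^2 + bx[, 2]^2, "+") -
      2 * (axyz[, 1:2] %*% t(bx[, 1:2]))
    list(d2xy = d2xy, dz = outer(axyz[, 3], bx[, 3], "-"))
  })
  # first-contact separation: largest grid offset (multiple of trans_step)
  # at which any cross pair comes within contact range for any rotation
  zmax <- -Inf
  for (g in rot_geo) {
    reach <- contact_rng^2 - g$d2xy
    ok <- reach > 0
    if (any(ok))
      zmax <- max(zmax, max(g$dz[ok] + sqrt(reach[ok])))
  }
  empty <- structure(data.frame(offset = numeric(0), rotation = numeric(0),
                                clash_fraction = numeric(0),
                                score = numeric(0)),
                     class = c("iqa_pose_set", "data.frame"),
                     ringA = A, ringB = B, symmetry_order = symmetry_order,
                     probe = probe, clash_frac_max = clash_frac_max)
  if (!is.finite(zmax)) {
    warning("rings never reach contact range; no poses", call. = FALSE)
    return(empty)
  }
  z0 <- floor(zmax / trans_step) * trans_step
  offsets <- numeric(0)
  rows <- list()
  z <- z0
  repeat {
    cf <- vapply(rot_geo, function(g) {
      d2 <- g$d2xy + (g$dz - z)^2
      # denominator: pairs within contact range, so the gate is independent
      # of system size (an all-pairs denominator grows quadratically and
      # makes any fixed fraction arbitrarily lenient on large rings)
      sum(d2 < clash_rng2) / max(1, sum(d2 < contact_rng^2))
    }, 1)
    if (all(cf > clash_frac_max) || z < -z0) break
    offsets <- c(offsets, z)
    rows[[length(rows) + 1L]] <- data.frame(offset = z, rotation = rotations,
                                            clash_fraction = cf,
                                            score = NA_real_)
    z <- z - trans_step
  }
  if (!length(rows)) {
    warning("all offsets clash; no poses", call. = FALSE)
    return(empty)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("iqa_pose_set", "data.frame"),
            ringA = A, ringB = B, symmetry_order = symmetry_order,
            probe = probe, clash_frac_max = clash_frac_max)
}

#' Materialize one pose as a merged structure
#'
#' Applies a pose's rotation and axial offset to ring B and merges it with
#' ring A (B's chains relabelled). The returned structure carries the
#' \code{"chain_groups"} attribute separating the two rings.
#'
#' @param poses an \code{iqa_pose_set}.
#' @param index row index of the pose.
#' @return an \code{iqa_structure}.
#' @export
pose_structure <- function(poses, index) {
  A <- attr(poses, "ringA"); B <- attr(poses, "ringB")
  th <- poses$rotation[index] * pi / 180
  Bt <- transform_structure(B, R = rotation_matrix(c(0, 0, 1), th),
                            t = c(0, 0, poses$offset[index]))
  merge_structures(A, Bt, relabel = TRUE)
}

#' Score and rank docking poses
#'
#' Scores every clash-passing pose by its cross-ring interface pseudo-energy
#' (contacts between any chain of ring A and any chain of ring B) and ranks
#' ascending, most favorable first. Poses failing the clash rule are
#' excluded before scoring; poses with no cross-ring contacts score 0 and
#' therefore rank behind any pose with favorable (negative) contacts.
#'
#' @param poses an \code{iqa_pose_set}.
#' @param p an \code{iqa_potential}.
#' @param n_samples,seed contact-map parameters used per pose.
#' @return the pose set restricted to scored poses, sorted by ascending
#'   \code{score}.
#' @export
score_poses <- function(poses, p, n_samples = 256, seed = 1) {
  keep <- which(poses$clash_fraction <= attr(poses, "clash_frac_max"))
  probe <- attr(poses, "probe")
  scores <- rep(NA_real_, nrow(poses))
  for (k in keep) {
    s <- pose_structure(poses, k)
    grp <- attr(s, "chain_groups")
    cm <- compute_contact_map(s, probe = probe, n_samples = n_samples,
                              seed = seed)
    side <- ifelse(s$atoms$chain %in% grp$a, "A", "B")
    scores[k] <- interface_energy(cm, s, p, groups = side)
  }
  out <- poses[keep, , drop = FALSE]
  out$score <- scores[keep]
  out <- out[order(out$score), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(poses), ringA = attr(poses, "ringA"),
            ringB = attr(poses, "ringB"),
            symmetry_order = attr(poses, "symmetry_order"),
            probe = probe, clash_frac_max = attr(poses, "clash_frac_max"))
}

#' @export
print.iqa_pose_set <- function(x, ...) {
  cat(sprintf("iqa_pose_set: %d poses, offsets %s, %d rotations%s\n",
              nrow(x),
              if (nrow(x)) sprintf("%.1f..%.1f A", max(x$offset),
                                   min(x$offset)) else "-",
              length(unique(x$rotation)),
              if (all(is.na(x$score))) "" else
                sprintf(", best score %.1f", min(x$score, na.rm = TRUE))))
  invisible(x)
}
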