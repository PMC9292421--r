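#' Synthetic structure fixtures
#'
#' The fixture generators build idealized multi-chain assemblies on which the
#' whole scoring pipeline can be exercised with known ground truth. Subunits
#' are idealized poly-alanine alpha-helices (rise 1.5 Angstrom per residue,
#' 100 degrees of twist per residue) carrying backbone atoms N, CA, C, O plus
#' CB -- enough atoms for realistic contact maps at small scale.
#'
#' @name fixtures
NULL

# Idealized helix chain along local +x, centered at the origin.
# Returns an atom data.frame (radius unset).
helix_atoms <- function(len, chain = "A", helix_radius = 2.3) {
  stopifnot(len >= 1)
  pos <- function(u) {
    th <- u * 100 * pi / 180
    cbind(1.5 * u, helix_radius * cos(th), helix_radius * sin(th))
  }
  radial <- function(u, amount) {
    th <- u * 100 * pi / 180
    cbind(0, cos(th), sin(th)) * amount
  }
  u <- seq_len(len) - 1
  ca <- pos(u)
  nn <- pos(u - 0.35)
  cc <- pos(u + 0.35)
  oo <- cc + radial(u + 0.35, 1.23)
  cb <- ca + radial(u, 1.53)
  per <- function(m, name, el) data.frame(chain = chain, resno = rep(u + 1L),
                                          resid = "ALA", elety = name,
                                          elesy = el, x = m[, 1], y = m[, 2],
                                          z = m[, 3], stringsAsFactors = FALSE)
  a <- rbind(per(nn, "N", "N"), per(ca, "CA", "C"), per(cc, "C", "C"),
             per(oo, "O", "O"), per(cb, "CB", "C"))
  a <- a[order(a$resno, match(a$elety, c("N", "CA", "C", "O", "CB"))), ]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  a[, c("x", "y", "z")] <- sweep(xyz, 2, colMeans(xyz))
  rownames(a) <- NULL
  a
}

#' Idealized two-chain complex
#'
#' Two parallel idealized helices (chains A and B) with axes along x,
#' separated along y. The default separation of 9.5 Angstrom puts the helix
#' surfaces in van der Waals contact, giving a realistic dimer interface.
#'
#' @param len_a,len_b residues per chain.
#' @param separation axis-to-axis distance in Angstrom.
#' @param seed integer seed; reserved for forward compatibility (the geometry
#'   is deterministic).
#' @return an \code{iqa_structure} with radii assigned.
#' @export
make_dimer <- function(len_a = 20, len_b = len_a, separation = 9.5, seed = 1) {
  a <- helix_atoms(len_a, "A")
  b <- helix_atoms(len_b, "B")
  b$y <- b$y + separation
  assign_radii(iqa_structure(rbind(a, b)))
}

#' Cyclic (Cn) ring assembly fixture
#'
#' Builds a flat Cn-symmetric ring of idealized helical subunits, one chain
#' per subunit, symmetry axis along z. Each subunit's helix axis lies along
#' the local polygon tangent, so the assembly is ring-shaped (disc-like) and
#' its gyration-tensor minor axis is z by construction. The default ring
#' radius leaves a small tangential gap between consecutive subunits so that
#' neighboring chains are in contact without steric overlap.
#'
#' @param n_subunits number of chains (>= 3).
#' @param subunit_len residues per subunit.
#' @param ring_radius ring radius in Angstrom; default
#'   \code{1.08 * n_subunits * 1.5 * subunit_len / (2*pi)}.
#' @param seed integer seed; reserved (construction is deterministic --
#'   seeded jitter would break the exact Cn symmetry the fixture guarantees).
#' @return an \code{iqa_structure} with radii assigned; chains are labelled
#'   A, B, C, ... in ring order.
#' @export
make_ring <- function(n_subunits, subunit_len, ring_radius = NULL, seed = 1) {
  if (n_subunits < 3) stop_iqa("iqa_geometry", "need at least 3 subunits")
  L <- 1.5 * subunit_len
  if (is.null(ring_radius)) ring_radius <- 1.08 * n_subunits * L / (2 * pi)
  chord <- 2 * ring_radius * sin(pi / n_subunits)
  if (chord < 0.7 * L)
    stop_iqa("iqa_geometry",
             "ring_radius %.1f places subunit centroids too close (chord %.1f < 0.7 x length %.1f)",
             ring_radius, chord, L)
  if (n_subunits > 52) stop_iqa("iqa_geometry", "too many subunits to label")
  labels <- c(LETTERS, letters)
  parts <- vector("list", n_subunits)
  base <- helix_atoms(subunit_len, "A")
  bxyz <- as.matrix(base[, c("x", "y", "z")])
  for (k in seq_len(n_subunits)) {
    phi <- 2 * pi * (k - 1) / n_subunits
    tang <- c(-sin(phi), cos(phi), 0)   # local x -> polygon tangent
    radl <- c(cos(phi), sin(phi), 0)    # local y -> outward radial
    zax <- c(0, 0, 1)
    M <- cbind(tang, radl, zax)
    xyz <- bxyz %*% t(M)
    xyz <- xyz + matrix(ring_radius * radl, nrow(xyz), 3, byrow = TRUE)
    p <- base
    p$chain <- labels[k]
    p[, c("x", "y", "z")] <- xyz
    parts[[k]] <- p
  }
  assign_radii(iqa_structure(do.call(rbind, parts)))
}

#' Rigid-body decoy ensemble with known interface similarity
#'
#' Generates \code{n} decoys of a multimeric target by applying, per decoy, a
#' random rigid transform (rotation up to \code{max_rot} degrees about a
#' random axis through the chain centroid, then translation up to
#' \code{max_shift} Angstrom in a random direction) to one randomly chosen
#' chain, followed by i.i.d. Gaussian coordinate noise on all atoms. The
#' ground-truth quality of each decoy is its interface CAD-score against the
#' unperturbed target, recomputed from contact maps.
#'
#' @param target multimeric \code{iqa_structure} with radii assigned.
#' @param n number of decoys.
#' @param max_shift maximum translation, Angstrom.
#' @param max_rot maximum rotation, degrees.
#' @param noise_sigma per-coordinate Gaussian noise sd, Angstrom.
#' @param seed integer seed controlling all randomness in the ensemble.
#' @param probe,n_samples contact-map parameters used for the ground-truth
#'   interface CAD-scores.
#' @return An object of class \code{iqa_decoy_set}: list with \code{target},
#'   \code{decoys} (list of structures, in generation order), numeric
#'   \code{true_similarity} in [0,1], and \code{seed}.
#' @export
make_decoys <- function(target, n, max_shift = 5, max_rot = 30,
                        noise_sigma = 0.2, seed = 1,
                        probe = 1.4, n_samples = 512) {
  if (n_chains(target) < 2)
    stop_iqa("iqa_needs_multimer", "decoy generation requires >= 2 chains")
  tgt_rcm <- aggregate_residues(
    compute_contact_map(target, probe = probe, n_samples = n_samples,
                        seed = seed), target)
  chains <- unique(target$atoms$chain)
  decoys <- vector("list", n)
  sims <- numeric(n)
  with_local_seed(seed, {
    for (d in seq_len(n)) {
      ch <- sample(chains, 1)
      dec <- target
      idx <- dec$atoms$chain == ch
      xyz <- as.matrix(dec$atoms[idx, c("x", "y", "z")])
      cen <- colMeans(xyz)
      axis <- stats::rnorm(3)
      axis <- axis / sqrt(sum(axis^2))
      ang <- stats::runif(1, 0, max_rot) * pi / 180
      R <- rotation_matrix(axis, ang)
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      shift <- dir * stats::runif(1, 0, max_shift)
      xyz <- sweep(xyz, 2, cen) %*% t(R) +
        matrix(cen + shift, nrow(xyz), 3, byrow = TRUE)
      dec$atoms$x[idx] <- xyz[, 1]
      dec$atoms$y[idx] <- xyz[, 2]
      dec$atoms$z[idx] <- xyz[, 3]
      if (noise_sigma > 0) {
        m <- nrow(dec$atoms)
        dec$atoms$x <- dec$atoms$x + stats::rnorm(m, 0, noise_sigma)
        dec$atoms$y <- dec$atoms$y + stats::rnorm(m, 0, noise_sigma)
        dec$atoms$z <- dec$atoms$z + stats::rnorm(m, 0, noise_sigma)
      }
      decoys[[d]] <- dec
    }
  })
  for (d in seq_len(n)) {
    dec_rcm <- aggregate_residues(
      compute_contact_map(decoys[[d]], probe = probe, n_samples = n_samples,
                          seed = seed), decoys[[d]])
    sims[d] <- tryCatch(cad_interface(tgt_rcm, dec_rcm),
                        iqa_undefined_score = function(e) 0)
  }
  structure(list(target = target, decoys = decoys, true_similarity = sims,
                 seed = seed),
            class = "iqa_decoy_set")
}

#' Graded decoy ladder
#'
#' Combines several \code{\link{make_decoys}} calls into one ensemble
#' spanning a ladder of perturbation levels, from near-native to fully
#' disrupted -- the shape of a typical docking-model pool in which a
#' selection method must find the near-native solutions.
#'
#' @param target multimeric \code{iqa_structure} with radii assigned.
#' @param n_per_level decoys per ladder level.
#' @param levels data.frame with columns \code{shift} (max translation,
#'   Angstrom), \code{rot} (max rotation, degrees) and \code{noise}
#'   (coordinate noise sd, Angstrom); one row per level.
#' @param seed integer seed.
#' @param probe,n_samples contact-map parameters for ground-truth scoring.
#' @return an \code{iqa_decoy_set} (decoys ordered by level, then index).
#' @export
make_decoy_ladder <- function(target, n_per_level = 2,
                              levels = data.frame(
                                shift = c(0, 1, 2, 4, 8),
                                rot = c(0, 8, 16, 32, 64),
                                noise = c(0.02, 0.1, 0.2, 0.4, 0.8)),
                              seed = 1, probe = 1.4, n_samples = 512) {
  sets <- lapply(seq_len(nrow(levels)), function(L) {
    make_decoys(target, n_per_level, max_shift = levels$shift[L],
                max_rot = levels$rot[L], noise_sigma = levels$noise[L],
                seed = seed + 1000L * L, probe = probe,
                n_samples = n_samples)
  })
  structure(list(target = target,
                 decoys = do.call(c, lapply(sets, `[[`, "decoys")),
                 true_similarity = do.call(c, lapply(sets, `[[`,
                                                     "true_similarity")),
                 seed = seed),
            class = "iqa_decoy_set")
}

#' @export
print.iqa_decoy_set <- function(x, ...) {
  cat(sprintf("iqa_decoy_set: %d decoys, true interface CAD %.2f-%.2f (seed %d)\n",
              length(x$decoys), min(x$true_similarity),
              max(x$true_similarity), x$seed))
  invisible(x)
}
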