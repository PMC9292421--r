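#' Tessellation-style inter-atomic contact areas
#'
#' Contact areas between atoms are defined on the additively-weighted (power)
#' diagram of the probe-expanded atomic spheres: the contact between atoms i
#' and j is the area of the radical-plane face separating their power cells,
#' clipped to both expanded spheres, and the solvent-exposed area of an atom
#' is the part of its expanded sphere surface belonging to its own cell.
#' These areas are estimated by deterministic ray casting: for every atom a
#' low-discrepancy Fibonacci lattice of directions is traced from the center;
#' each ray either crosses the nearest power-plane face (contributing the
#' exact surface-element Jacobian \eqn{t^2/|u \cdot n|} to that neighbor's
#' face area) or reaches the expanded sphere (contributing to solvent area).
#' The estimator converges to the analytic face area; for two equal spheres
#' of radius r at center distance d it converges to the radical-disc area
#' \eqn{\pi (r^2 - d^2/4)}. The reported contact area is the mean of the two
#' directed estimates.
#'
#' @param s an \code{iqa_structure} with radii assigned.
#' @param probe probe (solvent) radius in Angstrom added to every atomic
#'   radius; default 1.4 (water probe convention).
#' @param n_samples rays per atom (>= 64); default 1024.
#' @param seed integer seed; only the global orientation of the direction
#'   lattice is randomized, so results are reproducible per seed.
#' @return An object of class \code{iqa_contact_map}: list with
#'   \code{contacts} (data.frame \code{i}, \code{j}, \code{area} with
#'   \code{i < j}, areas in Angstrom^2), \code{solvent} (per-atom areas),
#'   \code{probe}, \code{n_samples}, \code{seed}, \code{n_atoms}.
#' @export
compute_contact_map <- function(s, probe = 1.4, n_samples = 1024, seed = 1) {
  a <- s$atoms
  if (anyNA(a$radius))
    stop_iqa("iqa_missing_radius", "assign radii before computing contacts")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop_iqa("iqa_geometry", "non-finite coordinates")
  if (n_samples < 64) stop_iqa("iqa_geometry", "n_samples must be >= 64")
  n <- nrow(xyz)
  R <- a$radius + probe
  U <- fibonacci_directions(n_samples, seed)

  # neighbor lists: pairs with center distance < r_i + r_j + 2*probe
  nbrs <- neighbor_list(xyz, a$radius, probe)

  dir_area <- vector("list", n)   # per atom: named vector of directed areas
  solvent <- numeric(n)
  four_pi <- 4 * pi
  for (i in seq_len(n)) {
    nb <- nbrs[[i]]
    Ri <- R[i]
    if (length(nb) == 0L) {
      solvent[i] <- four_pi * Ri^2
      next
    }
    delta <- xyz[nb, , drop = FALSE] -
      matrix(xyz[i, ], length(nb), 3, byrow = TRUE)
    d2 <- rowSums(delta^2)
    b <- (d2 + Ri^2 - R[nb]^2) / 2     # ray hits plane j at t = b / (u.delta)
    D <- U %*% t(delta)                # n_samples x m
    Tm <- matrix(b, n_samples, length(nb), byrow = TRUE) / D
    Tm[D <= 0] <- Inf
    # b <= 0 with u.delta > 0 means the ray starts beyond plane j: the whole
    # ray lies outside atom i's power cell (buried direction, no area)
    bneg <- which(b <= 0)
    buried <- if (length(bneg))
      rowSums(D[, bneg, drop = FALSE] > 0) > 0 else
      rep(FALSE, n_samples)
    if (length(bneg)) Tm[, bneg] <- Inf
    jstar <- max.col(-Tm, ties.method = "first")
    sel <- cbind(seq_len(n_samples), jstar)
    tmin <- Tm[sel]
    hit <- !buried & tmin < Ri
    solvent[i] <- four_pi * Ri^2 * sum(!buried & tmin >= Ri) / n_samples
    if (any(hit)) {
      # ratio estimator: the unclipped face toward j is a radical-plane disc
      # of exact area pi (Ri^2 - h^2); sampling estimates only the fraction
      # of that disc surviving clipping by the other neighbors' planes.
      # Shared surface-element weights in numerator and denominator cancel
      # most lattice aliasing.
      W <- Tm * Tm * matrix(sqrt(d2), n_samples, length(nb), byrow = TRUE) / D
      W[!is.finite(W) | Tm >= Ri | Tm <= 0 | D <= 0] <- 0
      den <- colSums(W)
      wsel <- W[sel]
      wsel[!hit] <- 0
      num <- rowsum(wsel, jstar)
      jidx <- as.integer(rownames(num))
      h2 <- b[jidx]^2 / d2[jidx]
      full <- pi * pmax(0, Ri^2 - h2)
      v <- ifelse(den[jidx] > 0, full * num[, 1] / den[jidx], 0)
      keep <- v > 0
      if (any(keep)) {
        nm <- as.character(nb[jidx])
        v <- v[keep]
        names(v) <- nm[keep]
        dir_area[[i]] <- v
      }
    }
  }

  # symmetrize: area(i,j) = mean of the two directed estimates
  keys <- character(0); vals <- numeric(0)
  ii <- integer(0); jj <- integer(0)
  up <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    v <- dir_area[[i]]
    if (is.null(v)) next
    js <- as.integer(names(v))
    for (k in seq_along(js)) {
      j <- js[k]
      key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
      prev <- up[[key]]
      up[[key]] <- if (is.null(prev)) c(v[[k]], 1) else
        c(prev[1] + v[[k]], prev[2] + 1)
    }
  }
  ks <- ls(up)
  if (length(ks)) {
    parts <- strsplit(ks, "_", fixed = TRUE)
    ii <- vapply(parts, function(p) as.integer(p[1]), 1L)
    jj <- vapply(parts, function(p) as.integer(p[2]), 1L)
    # mean of the two directed estimates (a one-sided estimate is halved)
    vals <- vapply(ks, function(k) up[[k]][1] / 2, 1)
    ord <- order(ii, jj)
    ii <- ii[ord]; jj <- jj[ord]; vals <- unname(vals[ord])
    keep <- vals > 0
    ii <- ii[keep]; jj <- jj[keep]; vals <- vals[keep]
  }
  structure(list(contacts = data.frame(i = ii, j = jj, area = vals),
                 solvent = solvent, probe = probe, n_samples = n_samples,
                 seed = seed, n_atoms = n),
            class = "iqa_contact_map")
}

#' @export
print.iqa_contact_map <- function(x, ...) {
  cat(sprintf(
    "iqa_contact_map: %d atoms, %d contacts (%.1f A^2), solvent %.1f A^2\n",
    x$n_atoms, nrow(x$contacts), sum(x$contacts$area), sum(x$solvent)))
  invisible(x)
}

# Fibonacci sphere lattice of n unit directions, rotated by a seeded random
# global orientation (low discrepancy, reproducible).
fibonacci_directions <- function(n, seed = 1) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  phi <- 2 * pi * k * (sqrt(5) - 1) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  U <- cbind(r * cos(phi), r * sin(phi), z)
  Rm <- with_local_seed(seed, {
    ax <- stats::rnorm(3)
    rotation_matrix(ax / sqrt(sum(ax^2)), stats::runif(1, 0, 2 * pi))
  })
  U %*% t(Rm)
}

# Neighbor lists under the exact support cutoff r_i + r_j + 2*probe.
neighbor_list <- function(xyz, radius, probe) {
  n <- nrow(xyz)
  out <- vector("list", n)
  if (n == 1L) return(out)
  block <- max(1L, floor(2e6 / n))
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(n, start + block - 1L)
    d2 <- outer(rowSums(xyz[rows, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[rows, , drop = FALSE] %*% t(xyz)
    cut2 <- outer(radius[rows], radius, "+")
    cut2 <- (cut2 + 2 * probe)^2
    hit <- d2 < cut2
    for (q in seq_along(rows)) {
      i <- rows[q]
      nb <- which(hit[q, ])
      out[[i]] <- nb[nb != i]
    }
  }
  out
}

#' Aggregate an atomic contact map to residue level
#'
#' Residue-pair contact area is the sum of the constituent atom-pair areas;
#' intra-residue contacts are excluded; pairs whose chains differ are flagged
#' inter-chain. Per-residue solvent area is the sum over the residue's atoms.
#'
#' @param cm an \code{iqa_contact_map} computed from \code{s}.
#' @param s the \code{iqa_structure} the map was computed from.
#' @return An object of class \code{iqa_residue_map}: list with
#'   \code{contacts} (data.frame \code{res1}, \code{res2}, \code{area},
#'   \code{interchain}; residue keys are \code{"chain:resno"} with
#'   \code{res1 < res2} lexicographically) and \code{solvent} (data.frame
#'   \code{res}, \code{area}).
#' @export
aggregate_residues <- function(cm, s) {
  if (cm$n_atoms != nrow(s$atoms))
    stop_iqa("iqa_consistency", "contact map and structure atom counts differ")
  rk <- residue_keys(s)
  ct <- cm$contacts
  res_solv <- rowsum(cm$solvent, rk)
  solvent <- data.frame(res = rownames(res_solv), area = res_solv[, 1],
                        stringsAsFactors = FALSE)
  rownames(solvent) <- NULL
  if (nrow(ct) == 0L) {
    contacts <- data.frame(res1 = character(0), res2 = character(0),
                           area = numeric(0), interchain = logical(0))
  } else {
    r1 <- rk[ct$i]; r2 <- rk[ct$j]
    keep <- r1 != r2
    r1 <- r1[keep]; r2 <- r2[keep]; area <- ct$area[keep]
    swap <- r1 > r2
    tmp <- r1[swap]; r1[swap] <- r2[swap]; r2[swap] <- tmp
    key <- paste(r1, r2, sep = "|")
    acc <- rowsum(area, key)
    parts <- strsplit(rownames(acc), "|", fixed = TRUE)
    res1 <- vapply(parts, `[`, "", 1)
    res2 <- vapply(parts, `[`, "", 2)
    ch <- function(r) sub(":.*$", "", r)
    contacts <- data.frame(res1 = res1, res2 = res2, area = acc[, 1],
                           interchain = ch(res1) != ch(res2),
                           stringsAsFactors = FALSE)
    contacts <- contacts[order(contacts$res1, contacts$res2), ]
    rownames(contacts) <- NULL
  }
  structure(list(contacts = contacts, solvent = solvent),
            class = "iqa_residue_map")
}

#' @export
print.iqa_residue_map <- function(x, ...) {
  cat(sprintf(
    "iqa_residue_map: %d residue pairs (%d inter-chain), %.1f A^2 total\n",
    nrow(x$contacts), sum(x$contacts$interchain), sum(x$contacts$area)))
  invisible(x)
}

#' Restrict a residue contact map to inter-chain pairs
#'
#' Keeps only residue pairs whose members belong to different chains (the
#' interface); per-residue solvent areas are dropped. Idempotent.
#'
#' @param rcm an \code{iqa_residue_map}.
#' @return an \code{iqa_residue_map} containing only inter-chain pairs.
#' @export
interchain_subset <- function(rcm) {
  ct <- rcm$contacts[rcm$contacts$interchain, , drop = FALSE]
  rownames(ct) <- NULL
  structure(list(contacts = ct,
                 solvent = data.frame(res = character(0), area = numeric(0))),
            class = "iqa_residue_map")
}

#' Serialize a contact map to a tab-separated file
#'
#' Writes one row per atom-atom contact (chain, residue and atom name of both
#' partners plus the area) and one row per atom's solvent area with partner
#' \code{"solvent"}.
#'
#' @param cm an \code{iqa_contact_map} computed from \code{s}.
#' @param s the source \code{iqa_structure}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_contact_map <- function(cm, s, path) {
  a <- s$atoms
  ct <- cm$contacts
  rows <- data.frame(chain1 = a$chain[ct$i], res1 = a$resno[ct$i],
                     atom1 = a$elety[ct$i], chain2 = a$chain[ct$j],
                     res2 = a$resno[ct$j], atom2 = a$elety[ct$j],
                     area = ct$area)
  sv <- which(cm$solvent > 0)
  solv <- data.frame(chain1 = a$chain[sv], res1 = a$resno[sv],
                     atom1 = a$elety[sv], chain2 = "solvent", res2 = NA,
                     atom2 = "solvent", area = cm$solvent[sv])
  utils::write.table(rbind(rows, solv), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
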