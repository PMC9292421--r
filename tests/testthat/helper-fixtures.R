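# Shared fixtures and independent oracles. Expensive objects are cached so a
# test run computes each once.

iqa_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(iqa_cache[[name]])) iqa_cache[[name]] <- force(expr)
  iqa_cache[[name]]
}

fix_dimer <- function() cached("dimer", make_dimer(20))

fix_dimer_rcm <- function() cached("dimer_rcm", {
  d <- fix_dimer()
  aggregate_residues(compute_contact_map(d, n_samples = 256, seed = 1), d)
})

fix_potential <- function() cached("potential", {
  derive_potential(list(fix_dimer(), make_dimer(14)), n_samples = 192,
                   seed = 3)
})

# dimer with chain B spun 180 degrees in place about the inter-centroid (y)
# axis: the same residues face the interface but the cross-chain pairings
# reverse
fix_spun_dimer <- function() cached("spun_dimer", {
  d <- fix_dimer()
  idx <- d$atoms$chain == "B"
  xyz <- as.matrix(d$atoms[idx, c("x", "y", "z")])
  cen <- colMeans(xyz)
  R <- diag(c(-1, 1, -1))   # 180 deg about y
  xyz <- sweep(xyz, 2, cen) %*% R + matrix(cen, nrow(xyz), 3, byrow = TRUE)
  d$atoms$x[idx] <- xyz[, 1]
  d$atoms$y[idx] <- xyz[, 2]
  d$atoms$z[idx] <- xyz[, 3]
  d
})

# two-atom / few-atom ad-hoc structures
ball_structure <- function(xyz, radius, chain = NULL, resno = NULL) {
  n <- nrow(xyz)
  if (is.null(chain)) chain <- rep("A", n)
  if (is.null(resno)) resno <- seq_len(n)
  s <- iqa_structure(data.frame(chain = chain, resno = as.integer(resno),
                                resid = "ALA", elety = paste0("X", seq_len(n)),
                                elesy = "C", x = xyz[, 1], y = xyz[, 2],
                                z = xyz[, 3], stringsAsFactors = FALSE))
  s$atoms$radius <- radius
  s
}

# Independent contact-area oracle: Monte-Carlo sampling ON each candidate
# radical plane (a different scheme from the package's ray casting). For the
# pair (i,j) the face is sampled over the radical-plane disc clipped to both
# probe-expanded spheres, keeping points power-closest to i and j among all
# atoms.
oracle_contact_areas <- function(s, probe = 0, n_pts = 40000, seed = 99) {
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  R <- a$radius + probe
  n <- nrow(xyz)
  out <- list()
  set.seed(seed)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dvec <- xyz[j, ] - xyz[i, ]
    d <- sqrt(sum(dvec^2))
    if (d >= R[i] + R[j]) next
    # radical plane: distance from i along dvec
    h <- (d^2 + R[i]^2 - R[j]^2) / (2 * d)
    rho2 <- R[i]^2 - h^2
    if (rho2 <= 0) next
    rho <- sqrt(rho2)
    nrm <- dvec / d
    perp1 <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp1 <- perp1 - sum(perp1 * nrm) * nrm
    perp1 <- perp1 / sqrt(sum(perp1^2))
    perp2 <- c(nrm[2] * perp1[3] - nrm[3] * perp1[2],
               nrm[3] * perp1[1] - nrm[1] * perp1[3],
               nrm[1] * perp1[2] - nrm[2] * perp1[1])
    cen <- xyz[i, ] + h * nrm
    rr <- rho * sqrt(stats::runif(n_pts))
    th <- stats::runif(n_pts, 0, 2 * pi)
    pts <- cbind(cen[1] + rr * cos(th) * perp1[1] + rr * sin(th) * perp2[1],
                 cen[2] + rr * cos(th) * perp1[2] + rr * sin(th) * perp2[2],
                 cen[3] + rr * cos(th) * perp1[3] + rr * sin(th) * perp2[3])
    # power distance to every atom; keep points whose two smallest are i, j
    pd <- sapply(seq_len(n), function(k) {
      rowSums(sweep(pts, 2, xyz[k, ])^2) - R[k]^2
    })
    pdij <- pd[, i]  # equals pd[,j] on the radical plane
    inside <- pdij < 0
    others <- setdiff(seq_len(n), c(i, j))
    ok <- inside
    for (k in others) ok <- ok & (pd[, k] >= pdij)
    area <- pi * rho2 * mean(ok)
    if (area > 0) out[[paste(i, j)]] <- area
  }
  out
}

# Interface CAD between two ring-stack complexes, maximized over cyclic
# relabelings of the second ring's (interchangeable) chains.
cyclic_best_interface_cad <- function(native_rcm, model_rcm,
                                      native_b, model_b) {
  n <- length(model_b)
  stopifnot(length(native_b) == n)
  best <- 0
  for (shift in 0:(n - 1)) {
    mp <- stats::setNames(native_b[(seq_len(n) + shift - 1) %% n + 1],
                          model_b)
    fixed <- setdiff(unique(sub(":.*", "", model_rcm$contacts$res1)),
                     model_b)
    fixed <- union(fixed,
                   setdiff(unique(sub(":.*", "", model_rcm$contacts$res2)),
                           model_b))
    mp <- c(mp, stats::setNames(fixed, fixed))
    sc <- tryCatch(
      cad_interface(native_rcm, interqa:::remap_chains(model_rcm, mp)),
      iqa_undefined_score = function(e) 0)
    best <- max(best, sc)
  }
  best
}

# brute-force CAD-score: explicit loops over all target pairs
brute_cad <- function(tpairs, mpairs) {
  num <- 0; den <- 0
  for (k in names(tpairs)) {
    m <- if (k %in% names(mpairs)) mpairs[[k]] else 0
    num <- num + abs(tpairs[[k]] - m)
    den <- den + tpairs[[k]]
  }
  1 - min(1, num / den)
}

# random sparse residue contact map over two chains
random_rcm <- function(n_res, seed, p_edge = 0.2) {
  set.seed(seed)
  res <- paste0(sample(c("A", "B"), n_res, replace = TRUE), ":",
                seq_len(n_res))
  ct <- data.frame(res1 = character(0), res2 = character(0),
                   area = numeric(0), interchain = logical(0))
  for (i in seq_len(n_res - 1)) for (j in (i + 1):n_res) {
    if (stats::runif(1) < p_edge) {
      r1 <- min(res[i], res[j]); r2 <- max(res[i], res[j])
      ct <- rbind(ct, data.frame(
        res1 = r1, res2 = r2, area = stats::runif(1, 0.1, 20),
        interchain = sub(":.*", "", r1) != sub(":.*", "", r2)))
    }
  }
  structure(list(contacts = ct,
                 solvent = data.frame(res = res, area = stats::runif(n_res))),
            class = "iqa_residue_map")
}

# residue map from explicit pair list: list of c(res1, res2, area)
rcm_from_pairs <- function(...) {
  rows <- list(...)
  ct <- do.call(rbind, lapply(rows, function(r) {
    r1 <- min(r[[1]], r[[2]]); r2 <- max(r[[1]], r[[2]])
    data.frame(res1 = r1, res2 = r2, area = as.numeric(r[[3]]),
               interchain = sub(":.*", "", r1) != sub(":.*", "", r2),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ct)) ct <- data.frame(res1 = character(0), res2 = character(0),
                                    area = numeric(0), interchain = logical(0))
  structure(list(contacts = ct,
                 solvent = data.frame(res = character(0), area = numeric(0))),
            class = "iqa_residue_map")
}

ms <- function(id, gd, ie, gl = NA_real_) model_scores(id, gd, ie, gl)

# minimal PDB text fixture writer
write_pdb_lines <- function(lines, path) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          elesy = substr(name, 1, 1), type = "ATOM",
                          occ = 1.0, alt = "") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          alt, resid, chain, resno, x, y, z, occ, 0, elesy)
}
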