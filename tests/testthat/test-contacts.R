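test_that("two equal balls reproduce the analytic bridge area", {
  s <- ball_structure(rbind(c(0, 0, 0), c(2, 0, 0)), radius = 2)
  cm <- compute_contact_map(s, probe = 0, n_samples = 4096, seed = 1)
  exact <- 3 * pi    # radical-plane disc, pi (r^2 - d^2/4)
  expect_equal(nrow(cm$contacts), 1)
  expect_lt(abs(cm$contacts$area - exact) / exact, 0.03)
  # independent oracle with a different sampling scheme agrees
  oracle <- oracle_contact_areas(s, probe = 0, n_pts = 40000)
  expect_lt(abs(oracle[["1 2"]] - exact) / exact, 0.03)
})

test_that("an isolated ball is fully solvent exposed", {
  s <- ball_structure(matrix(c(0, 0, 0), 1), radius = 1.7)
  cm <- compute_contact_map(s, probe = 1.4, n_samples = 256)
  expect_equal(nrow(cm$contacts), 0)
  expect_equal(cm$solvent, 4 * pi * 3.1^2, tolerance = 1e-10)
})

test_that("equilateral three-ball systems give equal pairwise areas", {
  a <- 2.5
  xyz <- rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0))
  s <- ball_structure(xyz, radius = 1.8)
  cm <- compute_contact_map(s, probe = 0.5, n_samples = 2048, seed = 4)
  expect_equal(nrow(cm$contacts), 3)
  expect_lt(diff(range(cm$contacts$area)) / mean(cm$contacts$area), 0.05)
})

test_that("estimator agrees with the plane-sampling oracle on small systems", {
  set.seed(17)
  for (rep in 1:3) {
    n <- sample(6:12, 1)
    xyz <- matrix(stats::rnorm(3 * n, sd = 2.2), n, 3)
    s <- ball_structure(xyz, radius = stats::runif(n, 1.4, 2.0))
    cm <- compute_contact_map(s, probe = 0.4, n_samples = 4096, seed = rep)
    oracle <- oracle_contact_areas(s, probe = 0.4, n_pts = 30000,
                                   seed = 100 + rep)
    got <- stats::setNames(cm$contacts$area,
                           paste(cm$contacts$i, cm$contacts$j))
    for (k in names(oracle)) {
      if (oracle[[k]] < 1) next    # slivers: relative tolerance meaningless
      expect_lt(abs(got[[k]] - oracle[[k]]) / oracle[[k]], 0.05)
    }
  }
})

test_that("estimator converges as the sample count grows", {
  # quadrupling the sample count moves most faces by well under 5%; the
  # worst movers are the half-clipped discs between deeply overlapping
  # bonded atoms, which stay under 20%
  d <- make_dimer(8)
  a1 <- compute_contact_map(d, n_samples = 1024, seed = 2)
  a2 <- compute_contact_map(d, n_samples = 4096, seed = 2)
  k1 <- paste(a1$contacts$i, a1$contacts$j)
  k2 <- paste(a2$contacts$i, a2$contacts$j)
  common <- intersect(k1, k2)
  v1 <- a1$contacts$area[match(common, k1)]
  v2 <- a2$contacts$area[match(common, k2)]
  rel <- abs(v1 - v2) / pmax(v2, 1)
  expect_lt(stats::median(rel), 0.05)
  expect_lt(stats::quantile(rel, 0.95), 0.15)
  expect_lt(max(rel), 0.25)
  expect_lt(abs(sum(a1$contacts$area) - sum(a2$contacts$area)) /
              sum(a2$contacts$area), 0.01)
})

test_that("areas scale as the square of a global dilation", {
  s <- ball_structure(rbind(c(0, 0, 0), c(2.5, 0.5, 0), c(1, 2.2, 1)),
                      radius = c(1.7, 1.6, 1.9))
  cm1 <- compute_contact_map(s, probe = 1.0, n_samples = 2048, seed = 5)
  s2 <- s
  s2$atoms[, c("x", "y", "z")] <- s$atoms[, c("x", "y", "z")] * 2
  s2$atoms$radius <- s$atoms$radius * 2
  cm2 <- compute_contact_map(s2, probe = 2.0, n_samples = 2048, seed = 5)
  expect_equal(paste(cm2$contacts$i, cm2$contacts$j),
               paste(cm1$contacts$i, cm1$contacts$j))
  expect_equal(cm2$contacts$area, 4 * cm1$contacts$area, tolerance = 0.02)
  expect_equal(cm2$solvent, 4 * cm1$solvent, tolerance = 0.02)
})

test_that("areas are invariant under rigid motion", {
  d <- make_dimer(6)
  cm1 <- compute_contact_map(d, n_samples = 2048, seed = 8)
  R <- interqa:::rotation_matrix(c(1, 2, 0.5), 1.1)
  d2 <- transform_structure(d, R = R, t = c(5, -3, 11))
  cm2 <- compute_contact_map(d2, n_samples = 2048, seed = 8)
  k1 <- paste(cm1$contacts$i, cm1$contacts$j)
  k2 <- paste(cm2$contacts$i, cm2$contacts$j)
  common <- intersect(k1, k2)
  expect_gt(length(common), 0.95 * max(length(k1), length(k2)))
  v1 <- cm1$contacts$area[match(common, k1)]
  v2 <- cm2$contacts$area[match(common, k2)]
  rel <- abs(v1 - v2) / pmax(v1, 1)
  expect_lt(stats::median(rel), 0.05)
  expect_lt(stats::quantile(rel, 0.95), 0.15)
  expect_lt(abs(sum(cm1$contacts$area) - sum(cm2$contacts$area)) /
              sum(cm1$contacts$area), 0.01)
})

test_that("missing radii and bad coordinates are rejected", {
  s <- iqa_structure(data.frame(chain = "A", resno = 1:2, resid = "ALA",
                                elety = c("CA", "CB"), elesy = "C",
                                x = c(0, 2), y = 0, z = 0))
  expect_error(compute_contact_map(s), class = "iqa_missing_radius")
  s$atoms$radius <- 1.7
  s$atoms$x[1] <- NaN
  expect_error(compute_contact_map(s), class = "iqa_geometry")
})

test_that("residue aggregation conserves area and flags inter-chain pairs", {
  d <- fix_dimer()
  cm <- compute_contact_map(d, n_samples = 256, seed = 1)
  rcm <- fix_dimer_rcm()
  rk <- interqa:::residue_keys(d)
  inter_res_atom <- rk[cm$contacts$i] != rk[cm$contacts$j]
  expect_equal(sum(rcm$contacts$area), sum(cm$contacts$area[inter_res_atom]),
               tolerance = 1e-6)
  expect_equal(sum(rcm$solvent$area), sum(cm$solvent), tolerance = 1e-6)
  cross_atom <- d$atoms$chain[cm$contacts$i] != d$atoms$chain[cm$contacts$j]
  expect_equal(sum(rcm$contacts$area[rcm$contacts$interchain]),
               sum(cm$contacts$area[cross_atom]), tolerance = 1e-6)
})

test_that("a hand-built two-residue map aggregates by direct summation", {
  # 4 atoms, 2 residues; atoms 1,2 in res 1 and 3,4 in res 2
  s <- ball_structure(rbind(c(0, 0, 0), c(3.2, 0, 0), c(0, 3.2, 0),
                            c(3.2, 3.2, 0)),
                      radius = 1.8, resno = c(1, 1, 2, 2))
  cm <- compute_contact_map(s, probe = 0.2, n_samples = 512, seed = 3)
  rcm <- aggregate_residues(cm, s)
  # expected: sum of the atom-level areas crossing the residue boundary
  rk <- interqa:::residue_keys(s)
  cross <- rk[cm$contacts$i] != rk[cm$contacts$j]
  expect_equal(nrow(rcm$contacts), 1)
  expect_equal(rcm$contacts$area, sum(cm$contacts$area[cross]),
               tolerance = 1e-9)
  expect_false(any(rcm$contacts$interchain))
})

test_that("inter-chain subsetting is correct and idempotent", {
  rcm <- fix_dimer_rcm()
  sub <- interchain_subset(rcm)
  expect_true(all(sub$contacts$interchain))
  expect_equal(nrow(sub$solvent), 0)
  expect_identical(interchain_subset(sub)$contacts, sub$contacts)
  # single chain: empty interface
  mono <- iqa_structure(fix_dimer()$atoms[fix_dimer()$atoms$chain == "A", ])
  mono$atoms$radius <- fix_dimer()$atoms$radius[fix_dimer()$atoms$chain == "A"]
  mrcm <- aggregate_residues(compute_contact_map(mono, n_samples = 128), mono)
  expect_equal(nrow(interchain_subset(mrcm)$contacts), 0)
})

test_that("contact maps serialize to the tab-separated layout", {
  d <- make_dimer(4)
  cm <- compute_contact_map(d, n_samples = 128)
  p <- tempfile(fileext = ".tsv")
  write_contact_map(cm, d, p)
  tab <- read.delim(p)
  expect_true(all(c("chain1", "res1", "atom1", "chain2", "res2", "atom2",
                    "area") %in% names(tab)))
  expect_equal(sum(tab$chain2 == "solvent"), sum(cm$solvent > 0))
  expect_equal(sum(tab$area[tab$chain2 != "solvent"]), sum(cm$contacts$area))
})
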