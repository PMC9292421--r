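test_that("atom typing covers the vocabulary and falls back by element", {
  expect_equal(atom_type("CA", "C"), "CA")
  expect_equal(atom_type("CB", "C"), "CB")
  expect_equal(atom_type(c("N", "C", "O", "OXT"), c("N", "C", "O", "O")),
               c("backbone-N", "backbone-C", "backbone-O", "backbone-O"))
  expect_equal(atom_type("SG", "S"), "S")
  expect_equal(atom_type(c("OD1", "ND2", "CG"), c("O", "N", "C")),
               c("sidechain-O", "sidechain-N", "sidechain-C"))
  expect_warning(ty <- atom_type("X1", "P"), "sidechain-C")
  expect_equal(ty, "sidechain-C")
})

test_that("log-odds energies vanish when observed equals expected", {
  # counts built to satisfy the independence model exactly:
  # O(a,b) = 2 T p_a p_b, O(a,a) = T p_a^2
  types <- atom_type_vocabulary()
  p <- c(0.3, 0.2, 0.1, 0.1, 0.1, 0.05, 0.05, 0.04, 0.03, 0.03)
  total <- 5000
  O <- 2 * total * outer(p, p)
  diag(O) <- total * p^2
  dimnames(O) <- list(types, types)
  pot <- interqa:::potential_from_counts(O, pseudocount = 0.5)
  expect_true(all(abs(pot) < 0.05))
})

test_that("unobserved pairs get finite positive energies and symmetry holds", {
  d <- fix_dimer()
  pot <- fix_potential()
  expect_true(all(is.finite(pot)))
  expect_equal(unclass(pot), t(unclass(pot)))
  # a pair with positive expected mass but zero observed area is repulsive
  types <- atom_type_vocabulary()
  p <- c(0.3, 0.2, 0.1, 0.1, 0.1, 0.05, 0.05, 0.04, 0.03, 0.03)
  O <- 2 * 5000 * outer(p, p); diag(O) <- 5000 * p^2
  dimnames(O) <- list(types, types)
  O[1, 2] <- O[2, 1] <- 0
  pz <- interqa:::potential_from_counts(O, pseudocount = 0.5)
  expect_gt(pz[1, 2], 0)
  expect_true(is.finite(pz[1, 2]))
  # zero-mass types (no sulfur in poly-alanine) stay neutral, not infinite
  expect_equal(pot["S", "S"], 0)
  expect_error(derive_potential(list()), class = "iqa_insufficient_data")
})

test_that("pseudo-energy is linear, decomposable and matches a hand sum", {
  # 3 atoms with hand-set contact and solvent areas
  s <- ball_structure(rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0)), radius = 1.8)
  cm <- structure(list(contacts = data.frame(i = c(1L, 2L), j = c(2L, 3L),
                                             area = c(2, 3)),
                       solvent = c(10, 5, 8), probe = 0, n_samples = 64,
                       seed = 1, n_atoms = 3), class = "iqa_contact_map")
  types <- atom_type_vocabulary()
  pot <- matrix(0, 10, 10, dimnames = list(types, types))
  pot["sidechain-C", "sidechain-C"] <- -2
  pot["sidechain-C", "solvent"] <- pot["solvent", "sidechain-C"] <- 0.5
  pot <- structure(pot, class = "iqa_potential")
  pe <- pseudo_energy(cm, s, pot)
  # contacts: (2+3) * -2 = -10; solvent: (10+5+8) * 0.5 = 11.5
  expect_equal(pe$total, -10 + 11.5)
  expect_equal(sum(pe$per_atom), pe$total)
  expect_equal(pe$per_atom,
               c(2 / 2 * -2 + 10 * 0.5,
                 (2 / 2 + 3 / 2) * -2 + 5 * 0.5,
                 3 / 2 * -2 + 8 * 0.5))
  # doubling one contact area doubles its contribution
  cm2 <- cm; cm2$contacts$area[1] <- 4
  expect_equal(pseudo_energy(cm2, s, pot)$total - pe$total, 2 * -2)
  # zero potential gives zero energy
  zpot <- structure(matrix(0, 10, 10, dimnames = list(types, types)),
                    class = "iqa_potential")
  expect_equal(pseudo_energy(cm, s, zpot)$total, 0)
})

test_that("interface energy sums cross-chain contacts only", {
  d <- fix_dimer()
  cm <- compute_contact_map(d, n_samples = 256, seed = 1)
  pot <- uniform_contact_potential(-1)
  ie <- interface_energy(cm, d, pot)
  cross <- d$atoms$chain[cm$contacts$i] != d$atoms$chain[cm$contacts$j]
  expect_equal(ie, -sum(cm$contacts$area[cross]))
  expect_lt(ie, 0)
  # explicit-loop oracle with a nonuniform potential
  pot2 <- fix_potential()
  ty <- interqa:::atom_types_of(d)
  acc <- 0
  for (k in which(cross))
    acc <- acc + cm$contacts$area[k] *
      pot2[ty[cm$contacts$i[k]], ty[cm$contacts$j[k]]]
  expect_equal(interface_energy(cm, d, pot2), acc)
  # monomers and separated dimers have no interface energy
  mono <- assign_radii(iqa_structure(d$atoms[d$atoms$chain == "A", ]))
  cmm <- compute_contact_map(mono, n_samples = 128)
  expect_warning(iem <- interface_energy(cmm, mono, pot), "single chain")
  expect_equal(iem, 0)
  apart <- transform_structure(d, t = c(0, 80, 0), chains = "B")
  cma <- compute_contact_map(apart, n_samples = 128)
  expect_equal(interface_energy(cma, apart, pot), 0)
})

test_that("energy decomposes exactly into interface, intra and solvent parts", {
  d <- fix_dimer()
  cm <- compute_contact_map(d, n_samples = 192, seed = 2)
  pot <- fix_potential()
  pe <- pseudo_energy(cm, d, pot)
  ty <- interqa:::atom_types_of(d)
  cross <- d$atoms$chain[cm$contacts$i] != d$atoms$chain[cm$contacts$j]
  intra <- sum(cm$contacts$area[!cross] *
                 pot[cbind(ty[cm$contacts$i[!cross]],
                           ty[cm$contacts$j[!cross]])])
  solv <- sum(cm$solvent * pot[cbind(ty, "solvent")])
  expect_equal(interface_energy(cm, d, pot) + intra + solv, pe$total,
               tolerance = 1e-9)
})

test_that("the light score is a calibrated monotone transform", {
  d <- fix_dimer()
  cm <- compute_contact_map(d, n_samples = 192, seed = 2)
  types <- atom_type_vocabulary()
  zpot <- structure(matrix(0, 10, 10, dimnames = list(types, types)),
                    class = "iqa_potential")
  expect_equal(light_global(pseudo_energy(cm, d, zpot), cm), 0.5)
  expect_gt(light_global(pseudo_energy(cm, d, uniform_contact_potential()),
                         cm), 0.5)
  # worsening a single contact strictly lowers the score
  pot <- fix_potential()
  pe1 <- pseudo_energy(cm, d, pot)
  pe2 <- pe1; pe2$total <- pe2$total + 50; pe2$per_atom[1] <-
    pe2$per_atom[1] + 50
  expect_gt(light_global(pe1, cm), light_global(pe2, cm))
})

test_that("scoring the derivation references gives favorable mean energy", {
  # the observed-vs-expected construction makes the area-weighted mean
  # energy of the references equal minus the KL divergence of the observed
  # type-pairing distribution from independence: non-positive, and bounded
  # in a structured but small fixture world
  refs <- list(fix_dimer(), make_dimer(14))
  pot <- fix_potential()
  dens <- vapply(refs, function(s) {
    cm <- compute_contact_map(s, n_samples = 192, seed = 3)
    pe <- pseudo_energy(cm, s, pot)
    pe$total / (2 * sum(cm$contacts$area) + sum(cm$solvent))
  }, 1)
  expect_lte(mean(dens), 0)
  expect_lt(abs(mean(dens)), 0.5)
})

test_that("potentials round-trip through the tab-separated format", {
  pot <- fix_potential()
  p <- tempfile(fileext = ".tsv")
  write_potential(pot, p)
  pot2 <- read_potential(p)
  expect_equal(unclass(pot2)[rownames(pot), colnames(pot)], unclass(pot),
               tolerance = 1e-12)
})

test_that("residue features reflect burial, interfaces and hand sums", {
  d <- fix_dimer()
  cm <- compute_contact_map(d, n_samples = 256, seed = 1)
  rcm <- fix_dimer_rcm()
  pot <- fix_potential()
  f <- dark_features(d, rcm, cm, pot)
  expect_equal(nrow(f), n_residues(d))
  expect_equal(ncol(f), 16)
  # residues with no cross-chain contacts have zero cross-chain feature
  cross_res <- unique(c(rcm$contacts$res1[rcm$contacts$interchain],
                        rcm$contacts$res2[rcm$contacts$interchain]))
  expect_true(all(f[setdiff(rownames(f), cross_res), "cross_chain_area"] == 0))
  expect_true(all(f[cross_res, "cross_chain_area"] > 0))
  # same + cross partitions the residue-pair total
  expect_equal(f[, "same_chain_area"] + f[, "cross_chain_area"],
               f[, "total_area"], tolerance = 1e-9)
  # per-residue energies sum to the structure total
  pe <- pseudo_energy(cm, d, pot)
  expect_equal(sum(f[, "residue_energy"]), pe$total, tolerance = 1e-9)
  # burial is contact / (contact + solvent)
  rk <- rownames(f)
  solv <- stats::setNames(rcm$solvent$area, rcm$solvent$res)[rk]
  expect_equal(f[, "burial"],
               stats::setNames(f[, "total_area"] /
                                 (f[, "total_area"] + solv), rk),
               tolerance = 1e-9)
  # a fully buried synthetic residue has zero solvent feature
  expect_true(any(f[, "burial"] > 0.5))
})

test_that("the predictor overfits small sets and is deterministic", {
  set.seed(42)
  X <- matrix(stats::rnorm(30 * 16), 30, 16,
              dimnames = list(NULL, paste0("f", 1:16)))
  y <- stats::runif(30)
  m1 <- dark_train(X, y, seed = 5)
  expect_lt(m1$loss, 0.01)
  m2 <- dark_train(X, y, seed = 5)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$w2, m2$w2)
  # constant targets are fit to within 0.05 everywhere
  mc <- dark_train(X, rep(0.5, 30), seed = 2, iters = 500)
  pred <- interqa:::dark_predict(mc, X)
  expect_true(all(abs(pred - 0.5) < 0.05))
  expect_error(dark_train(X[0, , drop = FALSE], numeric(0)),
               class = "iqa_insufficient_data")
  expect_error(dark_train(X, y + 2), class = "iqa_insufficient_data")
})

test_that("the global dark score is exactly the mean of the locals", {
  d <- fix_dimer()
  pot <- fix_potential()
  dm <- dark_train(matrix(stats::rnorm(50 * 16), 50, 16,
                          dimnames = list(NULL, colnames(dark_features(
                            d, fix_dimer_rcm(),
                            compute_contact_map(d, n_samples = 128), pot)))),
                   stats::runif(50), seed = 1, iters = 200)
  sc <- dark_score(dm, d, pot, n_samples = 128)
  expect_true(all(sc$local_dark > 0 & sc$local_dark < 1))
  expect_identical(sc$global_dark, mean(sc$local_dark))
  expect_error(dark_score(list(), d, pot), class = "iqa_state")
})

test_that("trained models round-trip through the JSON weight file", {
  X <- matrix(stats::rnorm(20 * 16), 20, 16,
              dimnames = list(NULL, paste0("f", 1:16)))
  m <- dark_train(X, stats::runif(20), seed = 3, iters = 100)
  p <- tempfile(fileext = ".json")
  write_dark_model(m, p)
  m2 <- read_dark_model(p)
  expect_equal(m2$W1, m$W1, tolerance = 1e-12)
  expect_equal(unname(m2$center), unname(m$center), tolerance = 1e-12)
  expect_equal(interqa:::dark_predict(m2, X), interqa:::dark_predict(m, X),
               tolerance = 1e-10)
})
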