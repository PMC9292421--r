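#' Per-residue features for the learned quality predictor
#'
#' Each residue is summarized by a fixed-length vector computed from the
#' contact areas and the contact potential: total contact area, solvent area,
#' same-chain vs cross-chain area split, contact-area sums per atom class,
#' the residue's pseudo-energy, the area-weighted mean energy density of its
#' contacting neighbor residues, and the burial fraction
#' (contact / (contact + solvent)). Feature order is fixed and versioned;
#' trained models refuse feature sets of a different version.
#'
#' @param s an \code{iqa_structure} with radii assigned.
#' @param rcm residue contact map from \code{\link{aggregate_residues}}.
#' @param cm atomic contact map from \code{\link{compute_contact_map}}.
#' @param p an \code{iqa_potential}.
#' @return numeric matrix, one row per residue (rownames are residue keys),
#'   with attribute \code{"version"}.
#' @export
dark_features <- function(s, rcm, cm, p) {
  rk_atoms <- residue_keys(s)
  res <- unique(rk_atoms)
  nres <- length(res)
  classes <- setdiff(atom_type_vocabulary(), "solvent")
  feat <- matrix(0, nres, 16,
                 dimnames = list(res, c(
                   "total_area", "solvent_area", "same_chain_area",
                   "cross_chain_area", paste0("area_", classes),
                   "residue_energy", "neighbor_energy", "burial")))
  ct <- rcm$contacts
  if (nrow(ct)) {
    add <- function(col, keys, vals) {
      acc <- rowsum(vals, keys)
      feat[rownames(acc), col] <<- feat[rownames(acc), col] + acc[, 1]
    }
    keys2 <- c(ct$res1, ct$res2); area2 <- c(ct$area, ct$area)
    add("total_area", keys2, area2)
    inter2 <- c(ct$interchain, ct$interchain)
    if (any(inter2)) add("cross_chain_area", keys2[inter2], area2[inter2])
    if (any(!inter2)) add("same_chain_area", keys2[!inter2], area2[!inter2])
  }
  sv <- rcm$solvent
  if (nrow(sv)) feat[sv$res, "solvent_area"] <- sv$area
  # per-atom-class contact area sums (area of the residue's own atoms,
  # binned by the atom's class)
  ty <- atom_types_of(s)
  act <- cm$contacts
  if (nrow(act)) {
    atom_area <- rowsum(c(act$area, act$area), c(act$i, act$j))
    idx <- as.integer(rownames(atom_area))
    key <- paste(rk_atoms[idx], ty[idx], sep = "\r")
    acc <- rowsum(atom_area[, 1], key)
    parts <- strsplit(rownames(acc), "\r", fixed = TRUE)
    rr <- vapply(parts, `[`, "", 1)
    cc <- vapply(parts, `[`, "", 2)
    for (k in seq_along(rr))
      feat[rr[k], paste0("area_", cc[k])] <-
        feat[rr[k], paste0("area_", cc[k])] + acc[k, 1]
  }
  pe <- pseudo_energy(cm, s, p)
  eres <- rowsum(pe$per_atom, rk_atoms)
  feat[rownames(eres), "residue_energy"] <- eres[, 1]
  # neighbor energy: area-weighted mean energy density of contacting residues
  dens <- stats::setNames(rep(0, nres), res)
  ra <- feat[, "total_area"] + feat[, "solvent_area"]
  ok <- ra > 0
  dens[ok] <- feat[ok, "residue_energy"] / ra[ok]
  if (nrow(ct)) {
    keys2 <- c(ct$res1, ct$res2)
    partner <- c(ct$res2, ct$res1)
    wnum <- rowsum(c(ct$area, ct$area) * dens[partner], keys2)
    wden <- rowsum(c(ct$area, ct$area), keys2)
    feat[rownames(wnum), "neighbor_energy"] <- wnum[, 1] / wden[, 1]
  }
  tot <- feat[, "total_area"] + feat[, "solvent_area"]
  feat[, "burial"] <- ifelse(tot > 0, feat[, "total_area"] / tot, 0)
  attr(feat, "version") <- dark_feature_version()
  feat
}

dark_feature_version <- function() "iqa-dark-features-1"

#' Train the per-residue quality predictor
#'
#' Fits a small feed-forward network (one tanh hidden layer, sigmoid output)
#' to predict per-residue CAD-scores from \code{\link{dark_features}}
#' vectors, by full-batch gradient descent with momentum on the mean squared
#' error. Inputs are z-score normalized with statistics stored in the model.
#' Training is deterministic given the seed.
#'
#' @param features numeric matrix of feature vectors (rows = residues).
#' @param targets numeric vector of per-residue CAD-score targets in [0,1].
#' @param hidden hidden units (default 20).
#' @param iters gradient-descent iterations (default 2000).
#' @param lr learning rate (default 0.05).
#' @param momentum momentum coefficient (default 0.9).
#' @param seed integer seed for weight initialization.
#' @return An object of class \code{iqa_dark_model}: weights, normalization
#'   statistics, feature-spec version, final training \code{loss}.
#' @export
dark_train <- function(features, targets, hidden = 20, iters = 2000,
                       lr = 0.05, momentum = 0.9, seed = 1) {
  X <- as.matrix(features)
  y <- as.numeric(targets)
  if (nrow(X) == 0L)
    stop_iqa("iqa_insufficient_data", "no training examples")
  if (length(y) != nrow(X))
    stop_iqa("iqa_insufficient_data", "feature/target length mismatch")
  if (any(y < 0 | y > 1))
    stop_iqa("iqa_insufficient_data", "targets must lie in [0,1]")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  d <- ncol(Z); n <- nrow(Z)
  W1 <- with_local_seed(seed, matrix(stats::rnorm(hidden * d, 0, 0.5), hidden, d))
  b1 <- numeric(hidden); w2 <- with_local_seed(seed + 1L,
                                               stats::rnorm(hidden, 0, 0.5))
  b2 <- 0
  vW1 <- W1 * 0; vb1 <- b1; vw2 <- w2 * 0; vb2 <- 0
  tZ <- t(Z)
  loss <- NA_real_
  for (it in seq_len(iters)) {
    H <- tanh(W1 %*% tZ + b1)          # hidden x n
    yhat <- 1 / (1 + exp(-(drop(w2 %*% H) + b2)))
    err <- yhat - y
    loss <- mean(err^2)
    dout <- (2 / n) * err * yhat * (1 - yhat)   # n
    gw2 <- drop(H %*% dout)
    gb2 <- sum(dout)
    dH <- (w2 %o% dout) * (1 - H^2)             # hidden x n
    gW1 <- dH %*% Z
    gb1 <- rowSums(dH)
    vW1 <- momentum * vW1 - lr * gW1; W1 <- W1 + vW1
    vb1 <- momentum * vb1 - lr * gb1; b1 <- b1 + vb1
    vw2 <- momentum * vw2 - lr * gw2; w2 <- w2 + vw2
    vb2 <- momentum * vb2 - lr * gb2; b2 <- b2 + vb2
  }
  structure(list(W1 = W1, b1 = b1, w2 = w2, b2 = b2, center = ctr,
                 scale = scl, loss = loss,
                 feature_names = colnames(X),
                 version = dark_feature_version(), seed = seed),
            class = "iqa_dark_model")
}

#' @export
print.iqa_dark_model <- function(x, ...) {
  cat(sprintf("iqa_dark_model: %d features -> %d hidden units, train MSE %.4g\n",
              ncol(x$W1), length(x$b1), x$loss))
  invisible(x)
}

dark_predict <- function(model, features) {
  if (!identical(attr(features, "version"), model$version) &&
      !is.null(attr(features, "version")))
    stop_iqa("iqa_consistency", "feature-spec version mismatch")
  Z <- sweep(sweep(as.matrix(features), 2, model$center), 2, model$scale, "/")
  H <- tanh(model$W1 %*% t(Z) + model$b1)
  out <- 1 / (1 + exp(-(drop(model$w2 %*% H) + model$b2)))
  stats::setNames(out, rownames(features))
}

#' Score a structure with a trained quality predictor
#'
#' Predicts a local quality score in (0,1) for every residue and returns the
#' global score as the exact arithmetic mean of the local scores.
#'
#' @param model a trained \code{iqa_dark_model}.
#' @param s an \code{iqa_structure} with radii assigned.
#' @param cm,rcm contact maps of \code{s} (computed if NULL).
#' @param p the \code{iqa_potential} the model was trained with.
#' @param probe,n_samples,seed contact-map parameters when maps are computed
#'   here.
#' @return list with \code{local_dark} (named numeric) and
#'   \code{global_dark = mean(local_dark)}.
#' @export
dark_score <- function(model, s, p, cm = NULL, rcm = NULL, probe = 1.4,
                       n_samples = 512, seed = 1) {
  if (!inherits(model, "iqa_dark_model"))
    stop_iqa("iqa_state", "model is not a trained iqa_dark_model")
  if (is.null(cm)) cm <- compute_contact_map(s, probe, n_samples, seed)
  if (is.null(rcm)) rcm <- aggregate_residues(cm, s)
  feat <- dark_features(s, rcm, cm, p)
  local <- dark_predict(model, feat)
  list(local_dark = local, global_dark = mean(local))
}

#' Write / read a trained quality predictor as JSON
#'
#' @param model an \code{iqa_dark_model}.
#' @param path file path.
#' @return \code{write_dark_model} returns \code{path} invisibly;
#'   \code{read_dark_model} returns the model.
#' @export
write_dark_model <- function(model, path) {
  obj <- list(version = model$version, seed = model$seed, loss = model$loss,
              feature_names = model$feature_names,
              W1 = as.vector(model$W1), hidden = nrow(model$W1),
              b1 = model$b1, w2 = model$w2, b2 = model$b2,
              center = model$center, scale = model$scale)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dark_model
#' @export
read_dark_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    W1 = matrix(obj$W1, obj$hidden, length(obj$feature_names),
                dimnames = list(NULL, obj$feature_names)),
    b1 = obj$b1, w2 = obj$w2, b2 = obj$b2,
    center = stats::setNames(obj$center, obj$feature_names),
    scale = stats::setNames(obj$scale, obj$feature_names),
    loss = obj$loss, feature_names = obj$feature_names,
    version = obj$version, seed = obj$seed),
    class = "iqa_dark_model")
}
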