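#' Contact-area-difference (CAD) similarity scores
#'
#' The CAD-score compares two structures through their residue-residue
#' contact areas. With target areas \eqn{T_{ij}} and model areas
#' \eqn{M_{ij}}, over the set G of residue pairs with \eqn{T_{ij} > 0},
#' \deqn{CAD = 1 - min(1, \sum_G |T_{ij} - M_{ij}| / \sum_G T_{ij}).}
#' The score is target-referenced: model-only contacts outside G are ignored,
#' which keeps the score bounded to [0,1]. Variants restrict G to inter-chain
#' pairs (interface CAD) or compare partner-agnostic per-residue inter-chain
#' areas (binding-site CAD). Residue correspondence is by chain identifier
#' and author residue number.
#'
#' @param target,model \code{iqa_residue_map} objects (see
#'   \code{\link{aggregate_residues}}) for the reference and the model.
#' @return \code{cad_global}, \code{cad_interface} and
#'   \code{cad_binding_site} return a single score in [0,1];
#'   \code{cad_local} returns a named numeric vector of per-residue scores
#'   (residues with zero target contact area are omitted).
#' @seealso \code{\link{interchain_subset}}, \code{\link{match_chains}}
#' @export
cad_global <- function(target, model) {
  tv <- pair_areas(target)
  if (length(tv) == 0L || sum(tv) <= 0)
    stop_iqa("iqa_undefined_score", "target has zero total contact area")
  mv <- pair_areas(model)
  m <- mv[names(tv)]
  m[is.na(m)] <- 0
  1 - min(1, sum(abs(tv - m)) / sum(tv))
}

pair_areas <- function(rcm) {
  ct <- rcm$contacts
  ct <- ct[ct$area > 0, , drop = FALSE]
  stats::setNames(ct$area, paste(ct$res1, ct$res2, sep = "|"))
}

#' @rdname cad_global
#' @export
cad_local <- function(target, model) {
  ct <- target$contacts
  ct <- ct[ct$area > 0, , drop = FALSE]
  if (nrow(ct) == 0L)
    stop_iqa("iqa_undefined_score", "target has zero total contact area")
  mv <- pair_areas(model)
  m <- mv[paste(ct$res1, ct$res2, sep = "|")]
  m[is.na(m)] <- 0
  adiff <- abs(ct$area - m)
  res <- c(ct$res1, ct$res2)
  num <- rowsum(c(adiff, adiff), res)
  den <- rowsum(c(ct$area, ct$area), res)
  out <- 1 - pmin(1, num[, 1] / den[, 1])
  stats::setNames(as.numeric(out), rownames(num))
}

#' @rdname cad_global
#' @export
cad_interface <- function(target, model) {
  ti <- interchain_subset(target)
  if (nrow(ti$contacts) == 0L || sum(ti$contacts$area) <= 0)
    stop_iqa("iqa_undefined_score", "target has no inter-chain contacts")
  cad_global(ti, interchain_subset(model))
}

#' @rdname cad_global
#' @export
cad_binding_site <- function(target, model) {
  tv <- residue_interface_areas(target)
  if (length(tv) == 0L || sum(tv) <= 0)
    stop_iqa("iqa_undefined_score", "target has no inter-chain contacts")
  mv <- residue_interface_areas(model)
  m <- mv[names(tv)]
  m[is.na(m)] <- 0
  1 - min(1, sum(abs(tv - m)) / sum(tv))
}

# Per-residue total inter-chain contact area, partner identity ignored.
residue_interface_areas <- function(rcm) {
  ct <- rcm$contacts[rcm$contacts$interchain & rcm$contacts$area > 0, ,
                     drop = FALSE]
  if (nrow(ct) == 0L) return(stats::setNames(numeric(0), character(0)))
  acc <- rowsum(c(ct$area, ct$area), c(ct$res1, ct$res2))
  stats::setNames(acc[, 1], rownames(acc))
}

#' Match interchangeable chains between a target and a model
#'
#' Homomeric complexes have interchangeable chain labels; before scoring, the
#' model's chains must be mapped onto the target's. Chains are grouped into
#' classes of equal residue count and all label permutations within classes
#' are enumerated (at most 8! total); the mapping maximizing the interface
#' CAD-score is returned, with ties broken by the lexicographically smallest
#' mapping. If the target has no inter-chain contacts the global CAD-score is
#' optimized instead, so monomer-pair comparisons still work.
#'
#' @param target,model \code{iqa_structure} objects with radii assigned.
#' @param probe,n_samples,seed contact-map parameters.
#' @return named character vector: model chain -> target chain, with the
#'   achieved score in attribute \code{"score"}.
#' @export
match_chains <- function(target, model, probe = 1.4, n_samples = 512,
                         seed = 1) {
  tlen <- residues_per_chain(target)
  mlen <- residues_per_chain(model)
  tcls <- sort(table(unname(tlen)))
  mcls <- sort(table(unname(mlen)))
  if (!identical(as.vector(tcls), as.vector(mcls)) ||
      !identical(names(tcls), names(mcls)))
    stop_iqa("iqa_chain_mapping",
             "chain multisets are incompatible between target and model")
  if (prod(factorial(as.numeric(tcls))) > factorial(8))
    stop_iqa("iqa_combinatorial_limit",
             "more than 8 interchangeable chains; enumeration refused")
  tgt_rcm <- aggregate_residues(
    compute_contact_map(target, probe, n_samples, seed), target)
  mod_rcm <- aggregate_residues(
    compute_contact_map(model, probe, n_samples, seed), model)
  use_interface <- any(tgt_rcm$contacts$interchain)
  score_fun <- if (use_interface) cad_interface else cad_global

  classes <- split(names(tlen), unname(tlen))
  mclasses <- split(names(mlen), unname(mlen))
  # enumerate permutations class-by-class, lexicographic over model chains
  maps <- list(stats::setNames(character(0), character(0)))
  for (len in names(mclasses)) {
    mc <- sort(mclasses[[len]])
    tc <- sort(classes[[len]])
    perms <- all_permutations(length(mc))
    maps <- unlist(lapply(maps, function(base) {
      lapply(seq_len(nrow(perms)), function(r) {
        c(base, stats::setNames(tc[perms[r, ]], mc))
      })
    }), recursive = FALSE)
  }
  best <- NULL; best_score <- -Inf
  for (mp in maps) {
    sc <- tryCatch(score_fun(tgt_rcm, remap_chains(mod_rcm, mp)),
                   iqa_undefined_score = function(e) 0)
    if (sc > best_score + 1e-12) {
      best_score <- sc
      best <- mp[order(names(mp))]
    }
  }
  attr(best, "score") <- best_score
  best
}

residues_per_chain <- function(s) {
  vapply(split(s$atoms$resno, s$atoms$chain),
         function(r) length(unique(r)), 1L)
}

# Relabel the chain component of residue keys in a residue map.
remap_chains <- function(rcm, mapping) {
  relab <- function(res) {
    ch <- sub(":.*$", "", res)
    no <- sub("^[^:]*:", "", res)
    paste(unname(mapping[ch]), no, sep = ":")
  }
  ct <- rcm$contacts
  if (nrow(ct)) {
    r1 <- relab(ct$res1); r2 <- relab(ct$res2)
    swap <- r1 > r2
    tmp <- r1[swap]; r1[swap] <- r2[swap]; r2[swap] <- tmp
    ct$res1 <- r1; ct$res2 <- r2
  }
  sv <- rcm$solvent
  if (nrow(sv)) sv$res <- relab(sv$res)
  structure(list(contacts = ct, solvent = sv), class = "iqa_residue_map")
}
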