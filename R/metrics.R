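#' Interface contacts for CASP-style accuracy metrics
#'
#' A residue pair (across chains) is an interface contact when any pair of
#' heavy atoms, one from each residue, lies strictly closer than
#' \code{cutoff}; the interface residues are the members of those pairs. The
#' 5 Angstrom heavy-atom cutoff follows CASP assessment convention.
#'
#' @param s a multimeric \code{iqa_structure}.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 5.0,
#'   strict less-than).
#' @return An object of class \code{iqa_interface_contacts}: list with
#'   \code{pairs} (character vector of \code{"chain:resno|chain:resno"} keys,
#'   endpoints ordered), \code{residues} (character vector of residue keys)
#'   and \code{cutoff}.
#' @export
interface_contacts <- function(s, cutoff = 5.0) {
  if (n_chains(s) < 2)
    stop_iqa("iqa_needs_multimer", "interface contacts require >= 2 chains")
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rk <- residue_keys(s)
  pairs <- character(0)
  chains <- unique(a$chain)
  for (ci in seq_along(chains)) for (cj in seq_along(chains)) {
    if (cj <= ci) next
    ia <- which(a$chain == chains[ci]); ib <- which(a$chain == chains[cj])
    d2 <- outer(rowSums(xyz[ia, , drop = FALSE]^2),
                rowSums(xyz[ib, , drop = FALSE]^2), "+") -
      2 * xyz[ia, , drop = FALSE] %*% t(xyz[ib, , drop = FALSE])
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(hit))
      pairs <- c(pairs, unique(paste(rk[ia[hit[, 1]]], rk[ib[hit[, 2]]],
                                     sep = "|")))
  }
  pairs <- sort(unique(pairs))
  residues <- sort(unique(unlist(strsplit(pairs, "|", fixed = TRUE))))
  structure(list(pairs = pairs, residues = residues, cutoff = cutoff),
            class = "iqa_interface_contacts")
}

#' Interface Contact Similarity (ICS / F1-score)
#'
#' F1-score between the target's and the model's sets of cross-chain residue
#' contact pairs: with precision P and recall R over shared pairs,
#' ICS = 2PR/(P+R); 0 when either set is empty.
#'
#' @param target,model \code{iqa_interface_contacts} objects computed at the
#'   same cutoff.
#' @return score in [0,1].
#' @export
ics <- function(target, model) {
  check_same_cutoff(target, model)
  tp <- length(intersect(target$pairs, model$pairs))
  if (length(target$pairs) == 0L || length(model$pairs) == 0L || tp == 0L)
    return(0)
  p <- tp / length(model$pairs)
  r <- tp / length(target$pairs)
  2 * p * r / (p + r)
}

#' Interface Patch Similarity (IPS / Jaccard coefficient)
#'
#' Jaccard coefficient between the target's and the model's sets of interface
#' residues; 0 when the union is empty. A model whose subunit is rotated in
#' place can keep a high IPS (same patch) while ICS collapses (different
#' cross-pairs).
#'
#' @inheritParams ics
#' @return score in [0,1].
#' @export
ips <- function(target, model) {
  check_same_cutoff(target, model)
  un <- union(target$residues, model$residues)
  if (length(un) == 0L) return(0)
  length(intersect(target$residues, model$residues)) / length(un)
}

check_same_cutoff <- function(target, model) {
  if (!isTRUE(all.equal(target$cutoff, model$cutoff)))
    stop_iqa("iqa_consistency", "interface contact cutoffs differ")
}

#' QS-score accuracy category
#'
#' Maps a quaternary-structure (QS) score in [0,1] to the standard accuracy
#' category: high (QS >= 0.7), medium (0.3 <= QS < 0.7), low
#' (0.1 <= QS < 0.3), incorrect (QS < 0.1).
#'
#' @param qs numeric QS-score value(s) in [0,1].
#' @return character vector of labels among
#'   \code{c("high", "medium", "low", "incorrect")}.
#' @export
qs_category <- function(qs) {
  if (any(!is.finite(qs)) || any(qs < 0) || any(qs > 1))
    stop_iqa("iqa_domain", "QS-score values must lie in [0,1]")
  ifelse(qs >= 0.7, "high",
         ifelse(qs >= 0.3, "medium",
                ifelse(qs >= 0.1, "low", "incorrect")))
}

#' Tally QS-score accuracy categories
#'
#' @param values numeric vector of QS-scores in [0,1].
#' @return named list: integer counts \code{high}, \code{medium}, \code{low},
#'   \code{incorrect}, plus \code{medium_or_better}.
#' @export
count_categories <- function(values) {
  lab <- if (length(values)) qs_category(values) else character(0)
  n <- function(l) sum(lab == l)
  list(high = n("high"), medium = n("medium"), low = n("low"),
       incorrect = n("incorrect"),
       medium_or_better = n("high") + n("medium"))
}
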