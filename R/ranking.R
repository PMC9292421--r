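#' Per-model score bundle and ranking configuration
#'
#' \code{model_scores} bundles the quantities the ranker consumes: the global
#' learned ("dark") score, the global contact-potential ("light") score, the
#' per-residue local scores and the inter-chain interface pseudo-energy.
#' \code{ranking_config} collects the tunable selection parameters: the
#' tolerance (in global-score units) below which two global scores are
#' considered indistinguishable and the interface energy decides, the
#' interface-similarity threshold for clustering, and the number of models to
#' select.
#'
#' @param id model identifier (used for deterministic tie-breaks).
#' @param global_dark global learned score in [0,1].
#' @param interface_energy inter-chain pseudo-energy (lower = better).
#' @param global_light optional global contact-potential score.
#' @param local_dark optional named per-residue scores.
#' @return \code{model_scores} returns an object of class
#'   \code{iqa_model_scores}; \code{ranking_config} a list of class
#'   \code{iqa_ranking_config}.
#' @export
model_scores <- function(id, global_dark, interface_energy,
                         global_light = NA_real_, local_dark = NULL) {
  if (is.na(global_dark) || is.na(interface_energy))
    stop_iqa("iqa_incomplete_score", "model %s lacks required scores", id)
  structure(list(id = as.character(id), global_dark = global_dark,
                 interface_energy = interface_energy,
                 global_light = global_light, local_dark = local_dark),
            class = "iqa_model_scores")
}

#' @rdname model_scores
#' @param tolerance global-score tolerance (default 0.02).
#' @param cluster_threshold interface CAD similarity threshold for joining a
#'   cluster (default 0.65).
#' @param k number of models to select (default 5).
#' @export
ranking_config <- function(tolerance = 0.02, cluster_threshold = 0.65, k = 5) {
  stopifnot(tolerance >= 0, cluster_threshold >= 0, cluster_threshold <= 1,
            k >= 1)
  structure(list(tolerance = tolerance, cluster_threshold = cluster_threshold,
                 k = as.integer(k)), class = "iqa_ranking_config")
}

#' Tolerance-gated pairwise model comparison
#'
#' If the two global scores differ by more than \code{tol}, the higher global
#' score wins; otherwise the interface pseudo-energy becomes the only
#' decisive factor and the lower (more favorable) energy wins. Exact ties are
#' broken by the higher global score, then by lexicographic model id.
#'
#' @param a,b \code{iqa_model_scores} objects.
#' @param tol tolerance in global-score units.
#' @return the winning \code{iqa_model_scores} object.
#' @export
compare_pair <- function(a, b, tol = 0.02) {
  stopifnot(inherits(a, "iqa_model_scores"), inherits(b, "iqa_model_scores"))
  if (abs(a$global_dark - b$global_dark) > tol)
    return(if (a$global_dark > b$global_dark) a else b)
  if (a$interface_energy != b$interface_energy)
    return(if (a$interface_energy < b$interface_energy) a else b)
  if (a$global_dark != b$global_dark)
    return(if (a$global_dark > b$global_dark) a else b)
  if (a$id <= b$id) a else b
}

#' Tournament (round-robin) model ranking
#'
#' Runs \code{\link{compare_pair}} over every model pair and orders models by
#' descending win count (Copeland aggregation), with ties broken by global
#' score, then interface energy, then id. The result is deterministic and
#' independent of input order.
#'
#' @param models list of \code{iqa_model_scores}.
#' @param cfg an \code{iqa_ranking_config}.
#' @return An object of class \code{iqa_ranked_list}: data.frame with columns
#'   \code{rank}, \code{id}, \code{wins}, \code{global_dark},
#'   \code{global_light}, \code{interface_energy}, \code{cluster} (NA until
#'   \code{\link{select_diverse}}); the score objects are kept in attribute
#'   \code{"models"}.
#' @export
tournament_rank <- function(models, cfg = ranking_config()) {
  if (!length(models)) stop_iqa("iqa_empty_input", "no models to rank")
  ids <- vapply(models, function(m) m$id, "")
  if (anyDuplicated(ids)) stop_iqa("iqa_empty_input", "duplicate model ids")
  n <- length(models)
  wins <- stats::setNames(integer(n), ids)
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    w <- compare_pair(models[[i]], models[[j]], cfg$tolerance)$id
    wins[w] <- wins[w] + 1L
  }
  gd <- vapply(models, function(m) m$global_dark, 1)
  gl <- vapply(models, function(m) m$global_light, 1)
  ie <- vapply(models, function(m) m$interface_energy, 1)
  ord <- order(-wins, -gd, ie, ids)
  out <- data.frame(rank = seq_len(n), id = ids[ord], wins = unname(wins[ord]),
                    global_dark = gd[ord], global_light = gl[ord],
                    interface_energy = ie[ord], cluster = NA_integer_,
                    stringsAsFactors = FALSE)
  structure(out, class = c("iqa_ranked_list", "data.frame"),
            models = stats::setNames(models, ids)[out$id])
}

#' Diverse top-k selection by interface-similarity clustering
#'
#' Greedy leader clustering in rank order: each model joins the first
#' existing cluster whose leader it resembles (interface CAD similarity at or
#' above \code{cfg$cluster_threshold}), otherwise it founds a new cluster.
#' The selected models are the leaders of the first \code{cfg$k} clusters
#' (fewer if fewer clusters form).
#'
#' @param ranked an \code{iqa_ranked_list}.
#' @param pairwise_sim symmetric numeric matrix of interface CAD similarities
#'   in [0,1], dimnames covering all ranked model ids.
#' @param cfg an \code{iqa_ranking_config}.
#' @return list with \code{selected} (character vector of up to k model ids,
#'   in rank order), \code{clusters} (named integer cluster index per model)
#'   and \code{ranked} (the ranked list with its \code{cluster} column
#'   filled).
#' @export
select_diverse <- function(ranked, pairwise_sim, cfg = ranking_config()) {
  ids <- ranked$id
  if (!all(ids %in% rownames(pairwise_sim)) ||
      !all(ids %in% colnames(pairwise_sim)))
    stop_iqa("iqa_incomplete_matrix", "similarity matrix misses model ids")
  if (anyNA(pairwise_sim[ids, ids]))
    stop_iqa("iqa_incomplete_matrix", "similarity matrix has missing entries")
  leaders <- character(0)
  cluster <- stats::setNames(integer(length(ids)), ids)
  for (id in ids) {
    joined <- FALSE
    for (ci in seq_along(leaders)) {
      if (pairwise_sim[leaders[ci], id] >= cfg$cluster_threshold) {
        cluster[id] <- ci
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      leaders <- c(leaders, id)
      cluster[id] <- length(leaders)
    }
  }
  ranked$cluster <- unname(cluster[ranked$id])
  list(selected = leaders[seq_len(min(cfg$k, length(leaders)))],
       clusters = cluster, ranked = ranked)
}
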