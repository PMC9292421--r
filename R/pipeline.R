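#' Pipeline configuration
#'
#' Collects everything a scoring-and-selection run needs: contact-map
#' parameters, the contact potential, the optional trained local-quality
#' model, ranking parameters and the output directory.
#'
#' @param potential an \code{iqa_potential} or a path to one written by
#'   \code{\link{write_potential}}; if NULL, a potential is derived from the
#'   input models themselves.
#' @param dark_model an \code{iqa_dark_model} or path to one; if NULL, the
#'   contact-potential ("light") global score is used as the global score in
#'   ranking.
#' @param probe,n_samples,seed contact-map parameters.
#' @param tolerance,cluster_threshold,k see \code{\link{ranking_config}}.
#' @param out_dir output directory (created if needed); NULL for no files.
#' @return list of class \code{iqa_run_config}.
#' @export
run_config <- function(potential = NULL, dark_model = NULL, probe = 1.4,
                       n_samples = 512, seed = 1, tolerance = 0.02,
                       cluster_threshold = 0.65, k = 5, out_dir = NULL) {
  if (is.character(potential)) potential <- read_potential(potential)
  if (is.character(dark_model)) dark_model <- read_dark_model(dark_model)
  structure(list(potential = potential, dark_model = dark_model,
                 probe = probe, n_samples = n_samples, seed = seed,
                 ranking = ranking_config(tolerance, cluster_threshold, k),
                 out_dir = out_dir),
            class = "iqa_run_config")
}

#' Score, rank, cluster and select complex models
#'
#' The automated selection workflow: each model is read, scored (contact
#' map, global light/dark scores, inter-chain interface pseudo-energy),
#' models are tournament-ranked with the tolerance rule, clustered by
#' pairwise interface CAD similarity, and a diverse top-k is selected. If a
#' reference target is supplied, CAD (global, interface, binding-site) and
#' ICS/IPS accuracy columns are appended. Models that fail to score are
#' skipped with a warning.
#'
#' @param models character vector of model PDB paths, or a named list of
#'   \code{iqa_structure} objects.
#' @param target optional reference: a PDB path or an \code{iqa_structure}.
#' @param cfg an \code{iqa_run_config}.
#' @return list with \code{ranked} (the result table), \code{selected}
#'   (model ids) and \code{files} (paths written, if \code{out_dir} set).
#' @export
run_pipeline <- function(models, target = NULL, cfg = run_config()) {
  structs <- list()
  if (is.character(models)) {
    for (path in models) {
      id <- sub("\\.pdb$", "", basename(path))
      s <- tryCatch(assign_radii(read_structure(path)),
                    error = function(e) {
                      warning(sprintf("skipping %s: %s", path,
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
      if (!is.null(s)) structs[[id]] <- s
    }
  } else {
    structs <- models
    if (is.null(names(structs)))
      names(structs) <- sprintf("model%03d", seq_along(structs))
  }
  if (!length(structs)) stop_iqa("iqa_run_error", "no readable models")

  pot <- cfg$potential
  if (is.null(pot))
    pot <- derive_potential(structs, probe = cfg$probe,
                            n_samples = cfg$n_samples, seed = cfg$seed)

  scored <- list(); rcms <- list()
  for (id in names(structs)) {
    s <- structs[[id]]
    res <- tryCatch({
      cm <- compute_contact_map(s, cfg$probe, cfg$n_samples, cfg$seed)
      rcm <- aggregate_residues(cm, s)
      pe <- pseudo_energy(cm, s, pot)
      gl <- light_global(pe, cm)
      ie <- withCallingHandlers(
        interface_energy(cm, s, pot),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!is.null(cfg$dark_model)) {
        ds <- dark_score(cfg$dark_model, s, pot, cm = cm, rcm = rcm)
        list(ms = model_scores(id, ds$global_dark, ie, gl, ds$local_dark),
             rcm = rcm)
      } else {
        list(ms = model_scores(id, gl, ie, gl), rcm = rcm)
      }
    }, error = function(e) {
      warning(sprintf("skipping %s: %s", id, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      scored[[id]] <- res$ms
      rcms[[id]] <- res$rcm
    }
  }
  if (!length(scored)) stop_iqa("iqa_run_error", "all models failed to score")

  ranked <- tournament_rank(unname(scored), cfg$ranking)
  sim <- pairwise_interface_similarity(rcms)
  sel <- select_diverse(ranked, sim, cfg$ranking)
  tab <- sel$ranked

  if (!is.null(target)) {
    if (is.character(target)) target <- assign_radii(read_structure(target))
    tcm <- compute_contact_map(target, cfg$probe, cfg$n_samples, cfg$seed)
    trcm <- aggregate_residues(tcm, target)
    tic <- tryCatch(interface_contacts(target), error = function(e) NULL)
    safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
    tab$cad_global <- vapply(tab$id, function(id)
      safe(cad_global(trcm, rcms[[id]])), 1)
    tab$cad_interface <- vapply(tab$id, function(id)
      safe(cad_interface(trcm, rcms[[id]])), 1)
    tab$cad_binding_site <- vapply(tab$id, function(id)
      safe(cad_binding_site(trcm, rcms[[id]])), 1)
    tab$ics <- vapply(tab$id, function(id)
      safe(if (is.null(tic)) NA_real_ else
        ics(tic, interface_contacts(structs[[id]]))), 1)
    tab$ips <- vapply(tab$id, function(id)
      safe(if (is.null(tic)) NA_real_ else
        ips(tic, interface_contacts(structs[[id]]))), 1)
  }

  files <- character(0)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- output_header(cfg)
    rt <- file.path(cfg$out_dir, "ranked.tsv")
    writeLines(hdr, rt)
    suppressWarnings(utils::write.table(tab, rt, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    st <- file.path(cfg$out_dir, "selected.txt")
    writeLines(c(hdr, sel$selected), st)
    files <- c(ranked = rt, selected = st)
  }
  list(ranked = tab, selected = sel$selected, files = files)
}

# Mean of the two directed interface CAD-scores between every model pair;
# pairs where neither model has inter-chain contacts count as identical.
pairwise_interface_similarity <- function(rcms) {
  ids <- names(rcms)
  n <- length(ids)
  sim <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d1 <- tryCatch(cad_interface(rcms[[i]], rcms[[j]]),
                   iqa_undefined_score = function(e) NA_real_)
    d2 <- tryCatch(cad_interface(rcms[[j]], rcms[[i]]),
                   iqa_undefined_score = function(e) NA_real_)
    v <- mean(c(d1, d2), na.rm = TRUE)
    if (is.nan(v))
      v <- if (nrow(interchain_subset(rcms[[i]])$contacts) == 0 &&
               nrow(interchain_subset(rcms[[j]])$contacts) == 0) 1 else 0
    sim[i, j] <- sim[j, i] <- v
  }
  sim
}

output_header <- function(cfg) {
  cfg_str <- paste(deparse(cfg[setdiff(names(cfg), c("potential",
                                                     "dark_model",
                                                     "out_dir"))]),
                   collapse = "")
  c(sprintf("# interqa %s",
            as.character(utils::packageVersion("interqa"))),
    sprintf("# config %s", fnv1a_hash(cfg_str)),
    sprintf("# seed %d", as.integer(cfg$seed)))
}
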