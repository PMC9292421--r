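#' Atomic structure objects
#'
#' An \code{iqa_structure} is the package's container for a (possibly
#' multi-chain) protein structure: an ordered atom table with chain identifier,
#' author residue numbering, residue and atom names, element, coordinates in
#' Angstrom, and (once assigned) a van der Waals radius per atom. Chain order
#' is the order of first appearance in the input; residue correspondence
#' between a model and its target is by chain identifier plus author residue
#' number throughout the package (no sequence alignment is performed).
#'
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{elety}, \code{elesy}, \code{x}, \code{y}, \code{z}
#'   and optionally \code{radius}.
#' @return An object of class \code{iqa_structure}.
#' @export
iqa_structure <- function(atoms) {
  req <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop_iqa("iqa_invalid_structure", "atom table lacks columns: %s",
             paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L)
    stop_iqa("iqa_empty_structure", "structure contains no atoms")
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  key <- paste(atoms$chain, atoms$resno, atoms$elety, sep = "\r")
  if (anyDuplicated(key))
    stop_iqa("iqa_invalid_structure",
             "duplicate (chain, residue, atom name) records")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "iqa_structure")
}

#' @export
print.iqa_structure <- function(x, ...) {
  a <- x$atoms
  ch <- unique(a$chain)
  cat(sprintf("iqa_structure: %d atoms, %d residues, %d chain(s) [%s]\n",
              nrow(a), length(unique(paste(a$chain, a$resno))),
              length(ch), paste(ch, collapse = ",")))
  invisible(x)
}

#' Number of chains / residues
#'
#' Small accessors used throughout the package.
#' @param s an \code{iqa_structure}.
#' @return integer count.
#' @export
n_chains <- function(s) length(unique(s$atoms$chain))

#' @rdname n_chains
#' @export
n_residues <- function(s) length(unique(paste(s$atoms$chain, s$atoms$resno)))

# residue key used as the model/target correspondence identifier
residue_keys <- function(s) paste(s$atoms$chain, s$atoms$resno, sep = ":")

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), resolves alternate locations to the
#' highest-occupancy conformer (first seen on ties), and applies the standard
#' filters: hydrogens and hetero records are dropped by default.
#'
#' @param path path to a PDB file.
#' @param drop_hydrogens drop hydrogen/deuterium atoms (default TRUE).
#' @param drop_hetero drop HETATM records (waters, ligands; default TRUE).
#' @return An \code{iqa_structure}; chain order and author residue numbering
#'   are preserved from the file.
#' @export
read_structure <- function(path, drop_hydrogens = TRUE, drop_hetero = TRUE) {
  if (!file.exists(path))
    stop_iqa("iqa_parse_error", "file not found: %s", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e)
      stop_iqa("iqa_parse_error", "cannot parse PDB file %s: %s",
               path, conditionMessage(e)))
  a <- pdb$atom
  if (drop_hetero) a <- a[a$type == "ATOM", , drop = FALSE]
  elesy <- a$elesy
  # infer element from atom name when the element column is blank
  bad <- is.na(elesy) | elesy == ""
  if (any(bad)) elesy[bad] <- gsub("[^A-Za-z].*$|[a-z0-9 ]", "",
                                   substr(trimws(a$elety[bad]), 1, 2))
  elesy <- toupper(trimws(elesy))
  a$elesy <- elesy
  if (drop_hydrogens) a <- a[!(a$elesy %in% c("H", "D")), , drop = FALSE]
  if (nrow(a) == 0L)
    stop_iqa("iqa_empty_structure", "no atoms remain after filtering: %s", path)
  # altloc resolution: per (chain, resno, elety) keep highest occupancy,
  # first-seen on ties
  occ <- ifelse(is.na(a$o), 1, a$o)
  key <- paste(a$chain, a$resno, a$elety, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -occ,
               seq_len(nrow(a)))
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$resno, a$elety, sep = "\r")), ,
         drop = FALSE]
  # restore original file order within the deduplicated set
  iqa_structure(data.frame(chain = a$chain, resno = as.integer(a$resno),
                           resid = a$resid, elety = a$elety, elesy = a$elesy,
                           x = a$x, y = a$y, z = a$z,
                           stringsAsFactors = FALSE))
}

#' Write a structure to a PDB file
#'
#' @param s an \code{iqa_structure}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain, elesy = a$elesy,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

#' Assign van der Waals radii
#'
#' Looks each atom up in \code{table} by atom name first, then by element;
#' unmatched atoms take the \code{"*"} default entry. The packaged default
#' table uses standard van der Waals values: C 1.70, N 1.55, O 1.52, S 1.80,
#' default 1.80 Angstrom.
#'
#' @param s an \code{iqa_structure}.
#' @param table named numeric vector mapping atom names and/or element symbols
#'   to radii in Angstrom; entry \code{"*"} is the fallback default.
#' @return \code{s} with every atom's \code{radius} filled in.
#' @export
assign_radii <- function(s, table = default_radius_table()) {
  a <- s$atoms
  r <- unname(table[trimws(a$elety)])
  hit <- !is.na(r)
  r[!hit] <- unname(table[a$elesy[!hit]])
  hit <- !is.na(r)
  if (any(!hit)) {
    if (is.na(table["*"]))
      stop_iqa("iqa_missing_radius",
               "no radius for element(s) %s and no '*' default in table",
               paste(unique(a$elesy[!hit]), collapse = ", "))
    r[!hit] <- unname(table["*"])
  }
  if (any(r <= 0)) stop_iqa("iqa_missing_radius", "radii must be positive")
  s$atoms$radius <- r
  s
}

#' @rdname assign_radii
#' @export
default_radius_table <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, "*" = 1.80)
}

#' Apply a rigid-body transform
#'
#' Rotates (about the origin) then translates atomic coordinates; optionally
#' restricted to a subset of chains.
#'
#' @param s an \code{iqa_structure}.
#' @param R 3x3 rotation matrix (default identity).
#' @param t length-3 translation in Angstrom (default zero).
#' @param chains chains to transform (default: all).
#' @return the transformed \code{iqa_structure}.
#' @export
transform_structure <- function(s, R = diag(3), t = c(0, 0, 0), chains = NULL) {
  idx <- if (is.null(chains)) seq_len(nrow(s$atoms)) else
    which(s$atoms$chain %in% chains)
  xyz <- as.matrix(s$atoms[idx, c("x", "y", "z")])
  xyz <- xyz %*% t(R) + matrix(t, nrow(xyz), 3, byrow = TRUE)
  s$atoms$x[idx] <- xyz[, 1]
  s$atoms$y[idx] <- xyz[, 2]
  s$atoms$z[idx] <- xyz[, 3]
  s
}

#' Merge structures into one assembly
#'
#' Concatenates atom tables; chain identifiers must not collide unless
#' \code{relabel} is TRUE, in which case the chains of \code{b} are renamed to
#' fresh single-letter identifiers.
#'
#' @param a,b \code{iqa_structure} objects.
#' @param relabel rename chains of \code{b} to avoid collisions.
#' @return merged \code{iqa_structure}; an attribute \code{"chain_groups"}
#'   records which chains came from \code{a} vs \code{b}.
#' @export
merge_structures <- function(a, b, relabel = FALSE) {
  bb <- b$atoms
  if (relabel) {
    pool <- setdiff(c(LETTERS, letters, as.character(0:9)),
                    unique(a$atoms$chain))
    old <- unique(bb$chain)
    if (length(old) > length(pool))
      stop_iqa("iqa_invalid_structure", "chain identifier pool exhausted")
    bb$chain <- pool[match(bb$chain, old)]
  } else if (length(intersect(unique(a$atoms$chain), unique(bb$chain))))
    stop_iqa("iqa_invalid_structure", "chain identifiers collide; use relabel")
  out <- iqa_structure(rbind(a$atoms, bb))
  attr(out, "chain_groups") <- list(a = unique(a$atoms$chain),
                                    b = unique(bb$chain))
  out
}
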