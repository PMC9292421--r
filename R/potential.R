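#' Coarse atom typing
#'
#' Maps standard amino-acid atoms onto a 9-class vocabulary: backbone-N,
#' backbone-C (carbonyl), backbone-O (incl. OXT), CA, CB, sidechain-C,
#' sidechain-N, sidechain-O and S. Atoms of unknown residues or names fall
#' back to the generic sidechain class of their element, with a warning. A
#' tenth pseudo-type, \code{"solvent"}, is used by the contact potential.
#'
#' @param elety atom name(s), e.g. \code{"CA"}, \code{"OD1"}.
#' @param elesy element symbol(s), e.g. \code{"C"}.
#' @return character vector of type codes.
#' @export
atom_type <- function(elety, elesy) {
  elety <- trimws(elety)
  out <- character(length(elety))
  out[elety == "N"] <- "backbone-N"
  out[elety == "C"] <- "backbone-C"
  out[elety %in% c("O", "OXT")] <- "backbone-O"
  out[elety == "CA"] <- "CA"
  out[elety == "CB"] <- "CB"
  rest <- which(out == "")
  if (length(rest)) {
    el <- toupper(elesy[rest])
    side <- ifelse(el == "S", "S",
                   ifelse(el == "N", "sidechain-N",
                          ifelse(el == "O", "sidechain-O",
                                 ifelse(el == "C", "sidechain-C", NA))))
    if (anyNA(side)) {
      warning(sprintf("unknown element(s) %s typed as sidechain-C",
                      paste(unique(el[is.na(side)]), collapse = ", ")),
              call. = FALSE)
      side[is.na(side)] <- "sidechain-C"
    }
    out[rest] <- side
  }
  out
}

#' @rdname atom_type
#' @export
atom_type_vocabulary <- function() {
  c("backbone-N", "backbone-C", "backbone-O", "CA", "CB",
    "sidechain-C", "sidechain-N", "sidechain-O", "S", "solvent")
}

atom_types_of <- function(s) atom_type(s$atoms$elety, s$atoms$elesy)

#' Derive a contact-area statistical potential
#'
#' Accumulates observed contact area between atom-type pairs (including each
#' type's contact with the solvent pseudo-type) over a set of reference
#' structures, and converts observed-vs-expected ratios into pseudo-energies:
#' \deqn{e(a,b) = -ln[(O(a,b) + c) / (E(a,b) + c)]}
#' where O is total observed area, c a pseudocount (Angstrom^2), and E the
#' area expected if contact endpoints paired independently according to each
#' type's share of total endpoint area. Favorable (over-represented) type
#' pairs get negative energies.
#'
#' @param refs list of \code{iqa_structure} objects with radii assigned.
#' @param pseudocount additive regularizer in Angstrom^2 (default 1).
#' @param probe,n_samples,seed contact-map parameters.
#' @return An object of class \code{iqa_potential}: a symmetric numeric
#'   matrix over \code{\link{atom_type_vocabulary}}.
#' @export
derive_potential <- function(refs, pseudocount = 1, probe = 1.4,
                             n_samples = 512, seed = 1) {
  if (!length(refs))
    stop_iqa("iqa_insufficient_data", "need at least one reference structure")
  types <- atom_type_vocabulary()
  O <- matrix(0, length(types), length(types), dimnames = list(types, types))
  for (s in refs) {
    cm <- compute_contact_map(s, probe, n_samples, seed)
    ty <- atom_types_of(s)
    ct <- cm$contacts
    if (nrow(ct)) {
      t1 <- ty[ct$i]; t2 <- ty[ct$j]
      for (k in seq_len(nrow(ct))) {
        O[t1[k], t2[k]] <- O[t1[k], t2[k]] + ct$area[k]
        if (t1[k] != t2[k]) O[t2[k], t1[k]] <- O[t2[k], t1[k]] + ct$area[k]
      }
    }
    sv <- rowsum(cm$solvent, ty)
    O[rownames(sv), "solvent"] <- O[rownames(sv), "solvent"] + sv[, 1]
    O["solvent", rownames(sv)] <- O[rownames(sv), "solvent"]
  }
  potential_from_counts(O, pseudocount)
}

# Log-odds energies from a symmetric observed-area matrix (upper triangle +
# diagonal are the unordered-pair totals; the matrix stores both triangles).
potential_from_counts <- function(O, pseudocount = 1) {
  total <- (sum(O) + sum(diag(O))) / 2   # unordered-pair area, diag once
  if (total <= 0)
    stop_iqa("iqa_insufficient_data", "no contact area observed")
  endpoint <- rowSums(O) + diag(O)       # each self-pair has two endpoints
  p <- endpoint / (2 * total)
  E <- 2 * total * outer(p, p)
  diag(E) <- total * p^2
  e <- -log((O + pseudocount) / (E + pseudocount))
  structure((e + t(e)) / 2, class = "iqa_potential")
}

#' @export
print.iqa_potential <- function(x, ...) {
  cat(sprintf("iqa_potential: %d atom types, energies in [%.2f, %.2f]\n",
              nrow(x), min(x), max(x)))
  invisible(x)
}

#' Write / read a potential as tab-separated text
#'
#' @param p an \code{iqa_potential}.
#' @param path file path.
#' @return \code{write_potential} returns \code{path} invisibly;
#'   \code{read_potential} returns an \code{iqa_potential}.
#' @export
write_potential <- function(p, path) {
  idx <- which(upper.tri(p, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(type_a = rownames(p)[idx[, 1]],
                   type_b = colnames(p)[idx[, 2]],
                   energy = p[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_potential
#' @export
read_potential <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  types <- sort(unique(c(df$type_a, df$type_b)))
  p <- matrix(0, length(types), length(types), dimnames = list(types, types))
  for (k in seq_len(nrow(df))) {
    p[df$type_a[k], df$type_b[k]] <- df$energy[k]
    p[df$type_b[k], df$type_a[k]] <- df$energy[k]
  }
  structure(p, class = "iqa_potential")
}

#' Uniform contact-favoring (shape-complementarity) potential
#'
#' A designed potential in which every atom-atom contact has the same
#' (by default favorable) pseudo-energy per unit area and solvent contacts
#' are neutral, so the interface pseudo-energy reduces to minus the buried
#' inter-chain contact area. This is the classic shape-complementarity
#' baseline for rigid-body pose scoring; it is well suited to idealized
#' fixture worlds whose atom-type statistics are too uniform to support a
#' meaningful log-odds potential.
#'
#' @param value energy per squared Angstrom of atom-atom contact
#'   (default -1).
#' @return an \code{iqa_potential}.
#' @export
uniform_contact_potential <- function(value = -1) {
  types <- atom_type_vocabulary()
  p <- matrix(value, length(types), length(types),
              dimnames = list(types, types))
  p["solvent", ] <- 0
  p[, "solvent"] <- 0
  structure(p, class = "iqa_potential")
}

#' Contact pseudo-energy of a structure
#'
#' Every atom-atom contact contributes area times the potential value of its
#' type pair; every solvent contact contributes area times the (type,
#' solvent) value. Each atom-atom contribution is split half/half between the
#' two atoms, making the per-atom decomposition sum exactly to the total.
#'
#' @param cm an \code{iqa_contact_map} computed from \code{s}.
#' @param s the source \code{iqa_structure}.
#' @param p an \code{iqa_potential}.
#' @return list with \code{per_atom} (numeric, one value per atom) and
#'   \code{total}.
#' @export
pseudo_energy <- function(cm, s, p) {
  ty <- atom_types_of(s)
  per <- cm$solvent * p[cbind(ty, "solvent")]
  ct <- cm$contacts
  if (nrow(ct)) {
    e <- ct$area * p[cbind(ty[ct$i], ty[ct$j])]
    half <- rowsum(c(e / 2, e / 2), c(ct$i, ct$j))
    idx <- as.integer(rownames(half))
    per[idx] <- per[idx] + half[, 1]
  }
  list(per_atom = per, total = sum(per))
}

#' Inter-chain interface pseudo-energy
#'
#' Sum of area times potential value over cross-group atom contacts only;
#' more negative is more favorable. By default atoms are grouped by chain;
#' \code{groups} can supply a coarser grouping (e.g. ring A vs ring B) so
#' that only contacts across the two sides count.
#'
#' @inheritParams pseudo_energy
#' @param groups optional vector (one entry per atom) defining the sides;
#'   default: the chain identifier.
#' @return numeric scalar; 0 (with a warning) for monomers.
#' @export
interface_energy <- function(cm, s, p, groups = NULL) {
  if (is.null(groups)) groups <- s$atoms$chain
  if (length(unique(groups)) < 2) {
    warning("structure has a single chain/group; interface energy is 0",
            call. = FALSE)
    return(0)
  }
  ct <- cm$contacts
  if (nrow(ct) == 0L) return(0)
  cross <- groups[ct$i] != groups[ct$j]
  if (!any(cross)) return(0)
  ty <- atom_types_of(s)
  sum(ct$area[cross] * p[cbind(ty[ct$i[cross]], ty[ct$j[cross]])])
}

#' Global contact-potential ("light") quality score
#'
#' Bounded transform of the mean pseudo-energy density: with total per-atom
#' energy e and total area A (contacts plus solvent), the score is
#' \eqn{1 / (1 + exp(k \bar e))} where \eqn{\bar e = e / A}. Structures with
#' uniformly favorable (negative) contacts score above 0.5; the score is
#' monotonically decreasing in the mean energy density. The calibration
#' constant k defaults to 1.
#'
#' @param pe result of \code{\link{pseudo_energy}}.
#' @param cm the \code{iqa_contact_map} the energies came from.
#' @param k calibration constant (default 1).
#' @return score in (0,1).
#' @export
light_global <- function(pe, cm, k = 1) {
  total_area <- 2 * sum(cm$contacts$area) + sum(cm$solvent)
  if (total_area <= 0)
    stop_iqa("iqa_undefined_score", "structure has zero total contact area")
  1 / (1 + exp(k * pe$total / total_area))
}
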