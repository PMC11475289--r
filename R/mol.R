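# Molecule graphs.
#
# A `rxn_mol` is a lightweight heavy-atom graph parsed (and sanitised) by the
# RDKit worker: an atom table, a bond table with kekulized orders plus
# aromaticity flags, and the canonical SMILES (atom maps stripped). Hydrogens
# are implicit throughout; the `nh` column records the total hydrogen count
# only for bookkeeping (atom-pair descriptors never use it).

new_rxn_mol <- function(smiles, canonical, atoms, bonds) {
  structure(
    list(smiles = canonical, input = smiles, atoms = atoms, bonds = bonds),
    class = "rxn_mol"
  )
}

.mol_from_parse <- function(smiles, rec) {
  atoms <- tibble::tibble(
    idx     = seq_along(rec$atoms),
    element = vapply(rec$atoms, function(a) a$element, character(1)),
    arom    = vapply(rec$atoms, function(a) isTRUE(a$arom), logical(1)),
    charge  = vapply(rec$atoms, function(a) as.integer(a$charge), integer(1)),
    nh      = vapply(rec$atoms, function(a) as.integer(a$nh), integer(1)),
    map     = vapply(rec$atoms, function(a) as.integer(a$map), integer(1)),
    ring    = vapply(rec$atoms, function(a) as.integer(a$ring), integer(1))
  )
  if (length(rec$bonds) > 0) {
    bonds <- tibble::tibble(
      a     = vapply(rec$bonds, function(b) as.integer(b$a), integer(1)),
      b     = vapply(rec$bonds, function(b) as.integer(b$b), integer(1)),
      order = vapply(rec$bonds, function(b) as.integer(b$order), integer(1)),
      arom  = vapply(rec$bonds, function(b) isTRUE(b$arom), logical(1))
    )
  } else {
    bonds <- tibble::tibble(a = integer(0), b = integer(0),
                            order = integer(0), arom = logical(0))
  }
  atoms$degree <- .atom_degrees(nrow(atoms), bonds)
  atoms$pi <- .atom_pi_electrons(atoms, bonds)
  new_rxn_mol(smiles, rec$canonical, atoms, bonds)
}

.atom_degrees <- function(n, bonds) {
  deg <- integer(n)
  if (nrow(bonds) > 0) {
    t1 <- tabulate(bonds$a, nbins = n)
    t2 <- tabulate(bonds$b, nbins = n)
    deg <- t1 + t2
  }
  deg
}

# pi-electron convention: an aromatic atom contributes 1; each non-aromatic
# double bond adds 1 to each end and each triple bond adds 2, so cumulated
# systems sum (an allene centre has p = 2). This is the classic Carhart-style
# atom-pair convention.
.atom_pi_electrons <- function(atoms, bonds) {
  p <- ifelse(atoms$arom, 1L, 0L)
  if (nrow(bonds) > 0) {
    contrib <- ifelse(bonds$arom, 0L, ifelse(bonds$order == 2L, 1L,
                                      ifelse(bonds$order == 3L, 2L, 0L)))
    for (k in seq_len(nrow(bonds))) {
      if (contrib[k] > 0L) {
        p[bonds$a[k]] <- p[bonds$a[k]] + contrib[k]
        p[bonds$b[k]] <- p[bonds$b[k]] + contrib[k]
      }
    }
  }
  p
}

#' Parse SMILES into molecule graphs
#'
#' Parses and sanitises one or more SMILES strings through RDKit, returning
#' heavy-atom graphs with kekulized bond orders, aromaticity flags, SSSR ring
#' membership counts, heavy-atom degrees and pi-electron counts. Atom maps, if
#' present, are preserved in the atom table; the `smiles` field of the result
#' is the canonical form with maps stripped.
#'
#' @param smiles Character vector of SMILES strings.
#' @return For `parse_mols()`, a list of `rxn_mol` objects; for `parse_mol()`,
#'   a single `rxn_mol`. Unparseable input raises an error naming the string.
#' @examples
#' \dontrun{
#' mol <- parse_mol("CCO")
#' mol$atoms
#' }
#' @export
parse_mols <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(list())
  out <- .rx_cached_batch("mol", smiles, "parse",
                          function(m) list(smiles = as.list(m)))
  mols <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    rec <- out[[i]]
    if (!isTRUE(rec$ok)) {
      stop("cannot parse molecule '", smiles[i], "': ",
           rec$error %||% "unknown error", call. = FALSE)
    }
    mols[[i]] <- .mol_from_parse(smiles[i], rec)
  }
  mols
}

#' @rdname parse_mols
#' @export
parse_mol <- function(smiles) {
  stopifnot(length(smiles) == 1)
  parse_mols(smiles)[[1]]
}

.as_mol <- function(x) {
  if (inherits(x, "rxn_mol")) x else parse_mol(x)
}

#' @export
print.rxn_mol <- function(x, ...) {
  cat("<rxn_mol> ", x$smiles, "\n", sep = "")
  cat("  ", nrow(x$atoms), " heavy atoms, ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Heavy-atom elemental formula
#'
#' Counts heavy atoms by element; hydrogens are ignored. Used by the
#' reaction-balancing step, which requires the same heavy-atom formula on both
#' sides of a reaction.
#'
#' @param mol A `rxn_mol` or SMILES string.
#' @return Named integer vector of element counts, sorted by element symbol.
#' @export
heavy_formula <- function(mol) {
  mol <- .as_mol(mol)
  tab <- table(mol$atoms$element)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out))]
}

.formula_diff <- function(f1, f2) {
  els <- sort(union(names(f1), names(f2)))
  v1 <- ifelse(els %in% names(f1), f1[els], 0L)
  v2 <- ifelse(els %in% names(f2), f2[els], 0L)
  d <- as.integer(v1) - as.integer(v2)
  names(d) <- els
  d[d != 0L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
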