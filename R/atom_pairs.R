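# AP2/AP3 atom-pair descriptors and signed count vectors.
#
# An atom is typed as Xhpr: element, heavy-atom degree, pi-electron count and
# SSSR ring membership count. An AP2 couples two bonded atoms through the bond
# order (4 for aromatic); an AP3 couples two atoms at topological distance
# exactly two and carries no bond information. A pair vector is a named
# integer vector mapping canonical pair strings ("Xhpr-1b-Xhpr" for AP2,
# "Xhpr-2-Xhpr" for AP3) to signed counts; reaction vectors are differences
# of such vectors.

.atom_desc_string <- function(element, h, p, r) {
  sprintf("%s%d%d%d", element, h, p, r)
}

#' Describe a heavy atom as an Xhpr tuple
#'
#' Types one atom by element symbol, heavy-atom degree `h` (count of bonds to
#' non-hydrogen atoms), pi-electron count `p` (aromatic atoms contribute 1,
#' non-aromatic double/triple bonds 1/2 per end) and SSSR ring membership
#' count `r`. Hydrogens are implicit and never described.
#'
#' @param mol A `rxn_mol` or SMILES string.
#' @param atom 1-based heavy-atom index into `mol$atoms`.
#' @return A list with fields `element`, `h`, `p`, `r` and the serialized
#'   `string` form used in pair keys.
#' @examples
#' \dontrun{
#' describe_atom("c1ccccc1", 1)  # (C, 2, 1, 1)
#' }
#' @export
describe_atom <- function(mol, atom) {
  mol <- .as_mol(mol)
  stopifnot(atom >= 1, atom <= nrow(mol$atoms))
  a <- mol$atoms[atom, ]
  if (a$element == "H") {
    stop("atom ", atom, " is a hydrogen; descriptors cover heavy atoms only",
         call. = FALSE)
  }
  list(element = a$element, h = as.integer(a$degree), p = as.integer(a$pi),
       r = as.integer(a$ring),
       string = .atom_desc_string(a$element, a$degree, a$pi, a$ring))
}

.atom_desc_strings <- function(mol) {
  .atom_desc_string(mol$atoms$element, mol$atoms$degree, mol$atoms$pi, mol$atoms$ring)
}

.ap2_key <- function(d1, d2, order) {
  lo <- pmin(d1, d2)
  hi <- pmax(d1, d2)
  sprintf("%s-1%d-%s", lo, order, hi)
}

.ap3_key <- function(d1, d2) {
  lo <- pmin(d1, d2)
  hi <- pmax(d1, d2)
  sprintf("%s-2-%s", lo, hi)
}

.as_ap_vector <- function(keys) {
  if (length(keys) == 0) {
    out <- integer(0)
  } else {
    tab <- table(keys)
    out <- as.integer(tab)
    names(out) <- names(tab)
  }
  ap_vector(out)
}

#' Atom-pair count vectors
#'
#' `enumerate_ap2()` emits one AP2 per bond between heavy atoms (bond order 4
#' for aromatic bonds); `enumerate_ap3()` emits one AP3 per unordered pair of
#' heavy atoms at topological distance exactly two; `component_vector()` is
#' their count-wise sum and is the per-component vector entering a reaction
#' difference vector.
#'
#' @param mol A `rxn_mol` or SMILES string.
#' @return A named integer vector of class `ap_vector` (pair string -> count);
#'   zero-count entries are never stored.
#' @examples
#' \dontrun{
#' enumerate_ap2("CCO")
#' component_vector("c1ccccc1")
#' }
#' @export
enumerate_ap2 <- function(mol) {
  mol <- .as_mol(mol)
  if (nrow(mol$bonds) == 0) return(ap_vector())
  desc <- .atom_desc_strings(mol)
  order <- ifelse(mol$bonds$arom, 4L, mol$bonds$order)
  .as_ap_vector(.ap2_key(desc[mol$bonds$a], desc[mol$bonds$b], order))
}

#' @rdname enumerate_ap2
#' @export
enumerate_ap3 <- function(mol) {
  mol <- .as_mol(mol)
  n <- nrow(mol$atoms)
  if (nrow(mol$bonds) == 0 || n < 3) return(ap_vector())
  adj <- .adjacency_list(n, mol$bonds)
  bonded <- .bond_key_set(mol$bonds)
  desc <- .atom_desc_strings(mol)
  keys <- character(0)
  seen <- new.env(parent = emptyenv())
  for (centre in seq_len(n)) {
    nb <- adj[[centre]]
    if (length(nb) < 2) next
    for (i in seq_len(length(nb) - 1)) {
      for (j in seq(i + 1, length(nb))) {
        u <- nb[i]; w <- nb[j]
        if (paste0(min(u, w), "_", max(u, w)) %in% bonded) next
        pk <- paste0(min(u, w), "_", max(u, w))
        if (!is.null(seen[[pk]])) next
        seen[[pk]] <- TRUE
        keys <- c(keys, .ap3_key(desc[u], desc[w]))
      }
    }
  }
  .as_ap_vector(keys)
}

#' @rdname enumerate_ap2
#' @export
component_vector <- function(mol) {
  mol <- .as_mol(mol)
  ap_sum(enumerate_ap2(mol), enumerate_ap3(mol))
}

.adjacency_list <- function(n, bonds) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

.bond_key_set <- function(bonds) {
  paste0(pmin(bonds$a, bonds$b), "_", pmax(bonds$a, bonds$b))
}

# ---- ap_vector arithmetic ---------------------------------------------------

#' Signed atom-pair count vectors
#'
#' Constructor and arithmetic for the signed multisets of atom-pair
#' descriptors that make up reaction vectors. `ap_sum()` and `ap_diff()` are
#' count-wise; `ap_contains(x, y)` tests multiset containment (every count in
#' `y` available in `x`); `ap_shortfall(x, y)` returns the part of `y` missing
#' from `x`. Zero counts are dropped everywhere.
#'
#' @param counts Named integer vector (pair string -> signed count).
#' @param x,y `ap_vector` objects.
#' @return `ap_vector` (or logical for `ap_contains`).
#' @export
ap_vector <- function(counts = integer(0)) {
  counts <- counts[counts != 0L]
  if (length(counts) == 0) {
    counts <- stats::setNames(integer(0), character(0))
  } else {
    counts <- counts[order(names(counts))]
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = "ap_vector")
}

#' @rdname ap_vector
#' @export
ap_sum <- function(x, y) {
  keys <- union(names(x), names(y))
  v <- integer(length(keys))
  names(v) <- keys
  if (length(x)) v[names(x)] <- v[names(x)] + as.integer(x)
  if (length(y)) v[names(y)] <- v[names(y)] + as.integer(y)
  ap_vector(v)
}

#' @rdname ap_vector
#' @export
ap_diff <- function(x, y) {
  ap_sum(x, ap_vector(stats::setNames(-as.integer(y), names(y))))
}

#' @rdname ap_vector
#' @export
ap_contains <- function(x, y) {
  if (length(y) == 0) return(TRUE)
  have <- stats::setNames(rep(0L, length(y)), names(y))
  common <- intersect(names(y), names(x))
  have[common] <- as.integer(x[common])
  all(have >= as.integer(y))
}

#' @rdname ap_vector
#' @export
ap_shortfall <- function(x, y) {
  if (length(y) == 0) return(ap_vector())
  have <- stats::setNames(rep(0L, length(y)), names(y))
  common <- intersect(names(y), names(x))
  have[common] <- as.integer(x[common])
  miss <- pmax(as.integer(y) - have, 0L)
  names(miss) <- names(y)
  ap_vector(miss)
}

#' @export
print.ap_vector <- function(x, ...) {
  cat("<ap_vector> ", length(x), " distinct pairs\n", sep = "")
  if (length(x)) {
    df <- data.frame(pair = names(x), count = as.integer(x), row.names = NULL)
    print(df, ...)
  }
  invisible(x)
}

#' @export
as.data.frame.ap_vector <- function(x, ...) {
  data.frame(pair = names(x), count = as.integer(unclass(x)), row.names = NULL)
}

ap_equal <- function(x, y) {
  length(x) == length(y) && all(names(x) == names(y)) &&
    all(as.integer(x) == as.integer(y))
}
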