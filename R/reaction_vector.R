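# Reaction vectors: cleaning/balancing, difference-vector derivation and
# reaction-centre template extraction.
#
# A reaction vector is the signed difference of atom-pair count vectors,
#   vector = [sum of product component vectors] - [sum of reactant vectors],
# split into a negative part (pairs lost) and a positive part (pairs gained).
# Alongside the pair parts we store one mapped transformation template: the
# atoms whose pairs change plus one shell of mapped context, with their
# bonding recorded on both sides of the reaction and each atom assigned to a
# (principal or byproduct) component per side. Forward application and
# retrosynthetic fragmentation are the same graph edit read in opposite
# directions, so the template is stored symmetrically.

#' Default small-molecule byproducts
#'
#' The condensation/substitution byproducts used to balance reactions
#' (`role = "balance"`) and to recognise leaving fragments at application time
#' (`role = "leaving"`, a superset including the boron-derived leaving group
#' of aryl couplings).
#'
#' @param role `"balance"` or `"leaving"`.
#' @return Named character vector of canonical SMILES.
#' @export
rx_default_byproducts <- function(role = c("balance", "leaving")) {
  role <- match.arg(role)
  base <- c(
    water = "O", hydrogen_chloride = "Cl", hydrogen_bromide = "Br",
    hydrogen_iodide = "I", methanol = "CO", ethanol = "CCO",
    carbon_dioxide = "O=C=O", nitrogen = "N#N"
  )
  if (role == "leaving") base <- c(base, boronic_leaving = "OBO")
  base
}

.template_atoms_proto <- function() {
  tibble::tibble(
    tid = integer(0), map = integer(0), element = character(0),
    core = logical(0),
    src_comp = integer(0), src_idx = integer(0), src_h = integer(0),
    src_p = integer(0), src_r = integer(0), src_arom = logical(0),
    src_charge = integer(0),
    tgt_comp = integer(0), tgt_idx = integer(0), tgt_h = integer(0),
    tgt_p = integer(0), tgt_r = integer(0), tgt_arom = logical(0),
    tgt_charge = integer(0)
  )
}

.template_bonds_proto <- function() {
  tibble::tibble(i = integer(0), j = integer(0), order = integer(0),
                 arom = logical(0))
}

.template_comps_proto <- function() {
  tibble::tibble(comp = integer(0), smiles = character(0), byprod = logical(0))
}

new_rxn_vector <- function(id, negative, positive, template,
                           n_reactant_components, provenance = "") {
  structure(
    list(id = id, negative = negative, positive = positive,
         template = template,
         n_reactant_components = n_reactant_components,
         provenance = provenance),
    class = "rxn_vector"
  )
}

#' @export
print.rxn_vector <- function(x, ...) {
  cat("<rxn_vector> ", x$id, "\n", sep = "")
  cat("  negative pairs: ", sum(as.integer(x$negative)),
      " (", length(x$negative), " distinct)\n", sep = "")
  cat("  positive pairs: ", sum(as.integer(x$positive)),
      " (", length(x$positive), " distinct)\n", sep = "")
  cat("  reactant components: ", x$n_reactant_components, "\n", sep = "")
  invisible(x)
}

# ---- cleaning / balancing ---------------------------------------------------

#' Clean a reaction so both sides carry the same heavy atoms
#'
#' A reaction is balanced when its reactant and product sides have identical
#' heavy-atom elemental formulas. When a side is deficient, a single
#' byproduct molecule whose formula matches the deficit exactly is appended to
#' that side (one addition per side at most). Reactions whose imbalance no
#' single byproduct can close are rejected with the formula difference.
#'
#' @param rec A `rxn_reaction` from [parse_reaction()].
#' @param byproducts Named character vector of candidate byproduct SMILES.
#' @return A balanced `rxn_reaction` (unchanged if already balanced).
#' @export
clean_reaction <- function(rec, byproducts = rx_default_byproducts("balance")) {
  stopifnot(inherits(rec, "rxn_reaction"))
  f_r <- Reduce(.formula_add, lapply(rec$reactants, heavy_formula))
  f_p <- Reduce(.formula_add, lapply(rec$products, heavy_formula))
  d <- .formula_diff(f_r, f_p)  # positive: products deficient
  if (length(d) == 0) return(rec)
  bp_formulas <- lapply(byproducts, heavy_formula)
  find_single <- function(deficit) {
    for (i in seq_along(bp_formulas)) {
      if (.formula_equal(bp_formulas[[i]], deficit)) return(byproducts[i])
    }
    NULL
  }
  deficit_p <- d[d > 0]           # must be added to the product side
  deficit_r <- -d[d < 0]          # must be added to the reactant side
  add_p <- if (length(deficit_p)) find_single(deficit_p) else NULL
  add_r <- if (length(deficit_r)) find_single(deficit_r) else NULL
  if ((length(deficit_p) && is.null(add_p)) ||
      (length(deficit_r) && is.null(add_r))) {
    stop("cannot balance reaction '", rec$id, "': heavy-atom difference ",
         .format_formula(d), " is not closed by any configured byproduct",
         call. = FALSE)
  }
  sides <- strsplit(rec$text, ">", fixed = TRUE)[[1]]
  if (length(sides) == 2) sides <- c(sides[1], "", sides[2])
  if (!is.null(add_r)) sides[1] <- paste(c(sides[1], add_r), collapse = ".")
  if (!is.null(add_p)) sides[3] <- paste(c(sides[3], add_p), collapse = ".")
  parse_reaction(paste(sides, collapse = ">"), id = rec$id, source = rec$source)
}

.formula_add <- function(f1, f2) {
  els <- sort(union(names(f1), names(f2)))
  v <- stats::setNames(integer(length(els)), els)
  v[names(f1)] <- v[names(f1)] + f1
  v[names(f2)] <- v[names(f2)] + f2
  v
}

.formula_equal <- function(f1, f2) {
  length(.formula_diff(f1, f2)) == 0
}

.format_formula <- function(d) {
  paste(sprintf("%s%+d", names(d), as.integer(d)), collapse = " ")
}

is_balanced_reaction <- function(rec) {
  f_r <- Reduce(.formula_add, lapply(rec$reactants, heavy_formula))
  f_p <- Reduce(.formula_add, lapply(rec$products, heavy_formula))
  .formula_equal(f_r, f_p)
}

# ---- derivation -------------------------------------------------------------

.side_atom_table <- function(mols, side) {
  dplyr::bind_rows(lapply(seq_along(mols), function(ci) {
    m <- mols[[ci]]
    tibble::tibble(
      side = side, comp = ci, idx = m$atoms$idx, map = m$atoms$map,
      element = m$atoms$element, h = m$atoms$degree, p = m$atoms$pi,
      r = m$atoms$ring, arom = m$atoms$arom, charge = m$atoms$charge
    )
  }))
}

.side_bond_keys <- function(mols) {
  # bonds between mapped atoms, keyed by the unordered map pair
  out <- list()
  for (ci in seq_along(mols)) {
    m <- mols[[ci]]
    if (nrow(m$bonds) == 0) next
    ma <- m$atoms$map[m$bonds$a]
    mb <- m$atoms$map[m$bonds$b]
    keep <- ma > 0 & mb > 0
    if (!any(keep)) next
    out[[length(out) + 1]] <- tibble::tibble(
      key = paste0(pmin(ma[keep], mb[keep]), "_", pmax(ma[keep], mb[keep])),
      m1 = pmin(ma[keep], mb[keep]), m2 = pmax(ma[keep], mb[keep]),
      order = m$bonds$order[keep], arom = m$bonds$arom[keep]
    )
  }
  if (length(out) == 0) return(tibble::tibble(key = character(0), m1 = integer(0),
                                              m2 = integer(0), order = integer(0),
                                              arom = logical(0)))
  dplyr::bind_rows(out)
}

# Pair unmatched one-side-only maps (and unmapped byproduct atoms) by element.
# Returns the updated record or signals a mapping error.
.complete_byproduct_maps <- function(rec, byprod_r, byprod_p) {
  at_r <- .side_atom_table(rec$reactants, "r")
  at_p <- .side_atom_table(rec$products, "p")
  maps_r <- at_r$map[at_r$map > 0]
  maps_p <- at_p$map[at_p$map > 0]
  only_r <- setdiff(maps_r, maps_p)
  only_p <- setdiff(maps_p, maps_r)
  next_map <- max(0L, maps_r, maps_p) + 1L

  assign_map <- function(side_mols, comp, idx, value) {
    side_mols[[comp]]$atoms$map[idx] <- value
    side_mols
  }

  # maps present only among reactants must land in unmapped byproduct product
  # atoms of the same element (and symmetrically)
  pair_up <- function(orphans, at_from, mols_to, byprod_to) {
    for (mp in sort(orphans)) {
      row <- at_from[at_from$map == mp, ]
      cand <- NULL
      for (ci in byprod_to) {
        m <- mols_to[[ci]]
        free <- which(m$atoms$map == 0 & m$atoms$element == row$element)
        if (length(free)) { cand <- c(ci, free[1]); break }
      }
      if (is.null(cand)) {
        stop("atom map ", mp, " appears on one side of reaction '", rec$id,
             "' only and no unmapped byproduct atom of element ", row$element,
             " can absorb it", call. = FALSE)
      }
      mols_to <- assign_map(mols_to, cand[1], cand[2], mp)
    }
    mols_to
  }
  if (length(only_r)) rec$products <- pair_up(only_r, at_r, rec$products, byprod_p)
  if (length(only_p)) rec$reactants <- pair_up(only_p, at_p, rec$reactants, byprod_r)

  # any remaining unmapped byproduct atoms: pair across sides by element
  leftover <- function(mols, comps) {
    out <- list()
    for (ci in comps) {
      m <- mols[[ci]]
      for (i in which(m$atoms$map == 0)) {
        out[[length(out) + 1]] <- c(ci, i)
      }
    }
    out
  }
  # unmapped product-side byproduct atoms may originate from any reactant
  # component (e.g. a hydroxyl oxygen leaving as water), so all reactant
  # components are eligible for pairing
  free_r <- leftover(rec$reactants, seq_along(rec$reactants))
  free_p <- leftover(rec$products, byprod_p)
  el_of <- function(mols, slot) mols[[slot[1]]]$atoms$element[slot[2]]
  for (slot_p in free_p) {
    el <- el_of(rec$products, slot_p)
    hit <- NULL
    for (k in seq_along(free_r)) {
      if (el_of(rec$reactants, free_r[[k]]) == el) { hit <- k; break }
    }
    if (!is.null(hit)) {
      rec$reactants <- assign_map(rec$reactants, free_r[[hit]][1],
                                  free_r[[hit]][2], next_map)
      rec$products <- assign_map(rec$products, slot_p[1], slot_p[2], next_map)
      next_map <- next_map + 1L
      free_r[[hit]] <- NULL
    }
  }
  rec
}

#' Derive the reaction vector and its templates from a balanced reaction
#'
#' Computes the signed pair difference (Eq.-style: sum of product component
#' vectors minus sum of reactant component vectors), splits it into negative
#' (lost) and positive (gained) parts, and extracts the mapped transformation
#' template: atoms incident to a changed bond or whose Xhpr descriptor
#' changes, plus one shell of mapped neighbours, with per-side bonding and
#' component assignment. Reactions must be balanced; atom maps are required
#' (unmapped reactions are first passed through the similarity-based
#' auto-mapper, which rejects low-confidence cases).
#'
#' @param rec A balanced `rxn_reaction`.
#' @param byproducts Named SMILES vector used to designate byproduct
#'   components on the product side.
#' @param implicit_reagents Named SMILES vector of reactant components treated
#'   as implicit (instantiated at application time rather than supplied);
#'   water by default, which makes hydrolysis-style functional transformations
#'   single-reactant vectors.
#' @param strict Enforce the supported component counts (exactly one principal
#'   product, one or two principal reactants). Relax only for analysis uses
#'   such as deriving the vector of a reversed multi-product reaction; the
#'   signed pair parts are independent of component designation.
#' @return A `rxn_vector`.
#' @export
derive_vector <- function(rec, byproducts = rx_default_byproducts("leaving"),
                          implicit_reagents = c(water = "O"), strict = TRUE) {
  stopifnot(inherits(rec, "rxn_reaction"))
  if (!is_balanced_reaction(rec)) {
    stop("reaction '", rec$id, "' is not balanced; run clean_reaction() first",
         call. = FALSE)
  }
  # Eq.-1 parts ---------------------------------------------------------------
  v_r <- Reduce(ap_sum, lapply(rec$reactants, component_vector))
  v_p <- Reduce(ap_sum, lapply(rec$products, component_vector))
  diff <- ap_diff(v_p, v_r)
  if (length(diff) == 0) {
    stop("reaction '", rec$id, "' produces the zero vector (identity or ",
         "stereochemistry-only change); no reaction vector derived",
         call. = FALSE)
  }
  negative <- ap_vector(stats::setNames(-as.integer(diff[diff < 0]),
                                        names(diff)[diff < 0]))
  positive <- ap_vector(as.integer(diff[diff > 0]) |>
                          stats::setNames(names(diff)[diff > 0]))

  # component designation ------------------------------------------------------
  bp_canon <- rx_canonical_smiles(byproducts)
  implicit_canon <- if (length(implicit_reagents))
    rx_canonical_smiles(implicit_reagents) else character(0)
  r_smiles <- vapply(rec$reactants, `[[`, "", "smiles")
  p_smiles <- vapply(rec$products, `[[`, "", "smiles")
  byprod_r <- which(r_smiles %in% implicit_canon)
  byprod_p <- which(p_smiles %in% bp_canon)
  principal_r <- setdiff(seq_along(rec$reactants), byprod_r)
  principal_p <- setdiff(seq_along(rec$products), byprod_p)
  if (strict && length(principal_p) != 1) {
    stop("reaction '", rec$id, "' has ", length(principal_p),
         " principal (non-byproduct) products; exactly one is supported",
         call. = FALSE)
  }
  if (strict && (length(principal_r) < 1 || length(principal_r) > 2)) {
    stop("reaction '", rec$id, "' has ", length(principal_r),
         " principal reactant components; 1 or 2 are supported", call. = FALSE)
  }

  # atom maps ------------------------------------------------------------------
  n_mapped <- sum(vapply(c(rec$reactants, rec$products),
                         function(m) sum(m$atoms$map > 0), integer(1)))
  if (n_mapped == 0) {
    rec <- auto_map_reaction(rec, byproducts = byproducts,
                             implicit_reagents = implicit_reagents)
  }
  rec <- .complete_byproduct_maps(rec, byprod_r, byprod_p)
  at_r <- .side_atom_table(rec$reactants, "r")
  at_p <- .side_atom_table(rec$products, "p")
  maps_r <- at_r$map[at_r$map > 0]
  maps_p <- at_p$map[at_p$map > 0]
  orphans <- c(setdiff(maps_r, maps_p), setdiff(maps_p, maps_r))
  if (length(orphans)) {
    stop("atom maps {", paste(sort(orphans), collapse = ","),
         "} appear on one side only of reaction '", rec$id, "'", call. = FALSE)
  }
  shared <- intersect(maps_r, maps_p)
  row_r <- at_r[match(shared, at_r$map), ]
  row_p <- at_p[match(shared, at_p$map), ]
  if (any(row_r$element != row_p$element)) {
    bad <- shared[row_r$element != row_p$element][1]
    stop("mapped atom ", bad, " changes element in reaction '", rec$id,
         "'; inconsistent atom map", call. = FALSE)
  }

  # changed bonds and atoms -----------------------------------------------------
  bonds_r <- .side_bond_keys(rec$reactants)
  bonds_p <- .side_bond_keys(rec$products)
  all_keys <- union(bonds_r$key, bonds_p$key)
  changed_keys <- character(0)
  for (k in all_keys) {
    br <- bonds_r[bonds_r$key == k, ]
    bp <- bonds_p[bonds_p$key == k, ]
    if (nrow(br) == 0 || nrow(bp) == 0) {
      changed_keys <- c(changed_keys, k)
    } else if (!(br$arom[1] && bp$arom[1]) &&
               (br$order[1] != bp$order[1] || br$arom[1] != bp$arom[1])) {
      changed_keys <- c(changed_keys, k)
    }
  }
  changed_maps <- unique(unlist(lapply(changed_keys, function(k) {
    as.integer(strsplit(k, "_", fixed = TRUE)[[1]])
  })))
  desc_changed <- shared[
    row_r$h != row_p$h | row_r$p != row_p$p | row_r$r != row_p$r |
      row_r$arom != row_p$arom | row_r$charge != row_p$charge
  ]
  core_maps <- sort(union(changed_maps, desc_changed))
  if (length(core_maps) == 0) {
    stop("reaction '", rec$id, "' has a nonzero pair difference but no mapped ",
         "changed atoms; the atom map does not cover the reaction centre",
         call. = FALSE)
  }

  # one shell of mapped context + all byproduct atoms ---------------------------
  neighbour_maps <- function(mols, maps_wanted) {
    out <- integer(0)
    for (m in mols) {
      if (nrow(m$bonds) == 0) next
      ma <- m$atoms$map[m$bonds$a]; mb <- m$atoms$map[m$bonds$b]
      out <- c(out, mb[ma %in% maps_wanted & mb > 0],
               ma[mb %in% maps_wanted & ma > 0])
    }
    out
  }
  shell <- union(neighbour_maps(rec$reactants, core_maps),
                 neighbour_maps(rec$products, core_maps))
  byprod_maps <- c(
    at_r$map[at_r$comp %in% byprod_r & at_r$map > 0],
    at_p$map[at_p$comp %in% byprod_p & at_p$map > 0]
  )
  tpl_maps <- sort(union(core_maps, union(shell, byprod_maps)))

  rr <- at_r[match(tpl_maps, at_r$map), ]
  pp <- at_p[match(tpl_maps, at_p$map), ]
  atoms <- tibble::tibble(
    tid = seq_along(tpl_maps), map = tpl_maps, element = rr$element,
    core = tpl_maps %in% core_maps,
    src_comp = rr$comp, src_idx = rr$idx, src_h = rr$h, src_p = rr$p,
    src_r = rr$r, src_arom = rr$arom, src_charge = rr$charge,
    tgt_comp = pp$comp, tgt_idx = pp$idx, tgt_h = pp$h, tgt_p = pp$p,
    tgt_r = pp$r, tgt_arom = pp$arom, tgt_charge = pp$charge
  )
  tid_of <- stats::setNames(atoms$tid, atoms$map)
  tpl_bonds <- function(bonds) {
    keep <- bonds$m1 %in% tpl_maps & bonds$m2 %in% tpl_maps
    b <- bonds[keep, ]
    tibble::tibble(
      i = as.integer(tid_of[as.character(b$m1)]),
      j = as.integer(tid_of[as.character(b$m2)]),
      order = b$order, arom = b$arom
    )
  }
  template <- list(
    atoms = atoms,
    src_bonds = tpl_bonds(bonds_r),
    tgt_bonds = tpl_bonds(bonds_p),
    src_comps = tibble::tibble(comp = seq_along(rec$reactants),
                               smiles = r_smiles,
                               byprod = seq_along(rec$reactants) %in% byprod_r),
    tgt_comps = tibble::tibble(comp = seq_along(rec$products),
                               smiles = p_smiles,
                               byprod = seq_along(rec$products) %in% byprod_p)
  )
  new_rxn_vector(
    id = rec$id, negative = negative, positive = positive, template = template,
    n_reactant_components = length(principal_r),
    provenance = if (nzchar(rec$source)) rec$source else rec$id
  )
}

#' Reaction-centre templates of a mapped reaction
#'
#' Convenience view over [derive_vector()]: returns the reactant-side
#' (fragmentation) and product-side (recombination) subgraph patterns with
#' their attachment correspondence (shared template atom ids).
#'
#' @param rec A balanced, atom-mapped `rxn_reaction`.
#' @return List with `reactant_template` and `product_template`, each holding
#'   `atoms` (with per-side Xhpr descriptors), `bonds` and `components`, plus
#'   the shared `attachment_map` (template atom id -> atom map number).
#' @export
extract_templates <- function(rec) {
  rv <- derive_vector(rec)
  tpl <- rv$template
  list(
    reactant_template = list(
      atoms = tpl$atoms[, c("tid", "map", "element", "core", "src_comp",
                            "src_h", "src_p", "src_r", "src_arom", "src_charge")],
      bonds = tpl$src_bonds,
      components = tpl$src_comps
    ),
    product_template = list(
      atoms = tpl$atoms[, c("tid", "map", "element", "core", "tgt_comp",
                            "tgt_h", "tgt_p", "tgt_r", "tgt_arom", "tgt_charge")],
      bonds = tpl$tgt_bonds,
      components = tpl$tgt_comps
    ),
    attachment_map = stats::setNames(tpl$atoms$map, tpl$atoms$tid)
  )
}

#' Reverse a reaction vector
#'
#' Swaps the negative and positive parts and the two sides of the stored
#' template, so that applying the result runs the reaction retrosynthetically.
#'
#' @param rv A `rxn_vector`.
#' @return The reversed `rxn_vector` (id suffixed `":rev"`).
#' @export
reverse_vector <- function(rv) {
  stopifnot(inherits(rv, "rxn_vector"))
  tpl <- rv$template
  atoms <- tpl$atoms
  swap <- function(df, a, b) {
    tmp <- df[[a]]; df[[a]] <- df[[b]]; df[[b]] <- tmp; df
  }
  for (col in c("comp", "idx", "h", "p", "r", "arom", "charge")) {
    atoms <- swap(atoms, paste0("src_", col), paste0("tgt_", col))
  }
  new_rxn_vector(
    id = paste0(rv$id, ":rev"),
    negative = rv$positive,
    positive = rv$negative,
    template = list(atoms = atoms, src_bonds = tpl$tgt_bonds,
                    tgt_bonds = tpl$src_bonds, src_comps = tpl$tgt_comps,
                    tgt_comps = tpl$src_comps),
    n_reactant_components = sum(!tpl$tgt_comps$byprod),
    provenance = rv$provenance
  )
}

#' Build a reaction-vector database from many reactions
#'
#' Cleans, derives and indexes each reaction; reactions that cannot be
#' balanced, are identities, or exceed the supported component counts are
#' skipped and reported in the `skipped` attribute.
#'
#' @param reactions Character vector of reaction SMILES, or a list of
#'   `rxn_reaction` records, or a data frame with a `reaction` column (and
#'   optional `id` column).
#' @param byproducts Byproduct configuration; see [rx_default_byproducts()].
#' @param implicit_reagents Reactant-side implicit components; see
#'   [derive_vector()].
#' @return A `rxn_vector_db` with a `skipped` attribute (tibble id/reason).
#' @export
build_vector_db <- function(reactions, byproducts = rx_default_byproducts("leaving"),
                            implicit_reagents = c(water = "O")) {
  if (is.data.frame(reactions)) {
    ids <- if ("id" %in% names(reactions)) reactions$id else NULL
    reactions <- stats::setNames(as.list(reactions$reaction), ids)
  }
  if (is.character(reactions)) reactions <- as.list(reactions)
  entries <- list()
  skipped <- list()
  for (i in seq_along(reactions)) {
    x <- reactions[[i]]
    id <- names(reactions)[i]
    if (is.null(id) || !nzchar(id)) id <- NULL
    rv <- tryCatch({
      rec <- if (inherits(x, "rxn_reaction")) x else parse_reaction(x, id = id)
      rec <- clean_reaction(rec, byproducts = rx_default_byproducts("balance"))
      derive_vector(rec, byproducts = byproducts,
                    implicit_reagents = implicit_reagents)
    }, error = function(e) e)
    if (inherits(rv, "error")) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        id = id %||% as.character(i), reason = conditionMessage(rv))
    } else {
      entries[[length(entries) + 1]] <- rv
    }
  }
  db <- new_vector_db(entries)
  attr(db, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble::tibble(id = character(0), reason = character(0))
  db
}

# ---- similarity-based auto-mapper ------------------------------------------

#' Assign atom maps to an unmapped reaction
#'
#' Heuristic mapper for reactions supplied without atom maps: each principal
#' reactant is aligned to the principal product by maximum common substructure
#' (exact element and bond-order match); colliding assignments are dropped and
#' leftover atoms are paired into byproduct components by element. Cases where
#' under half of a principal reactant can be aligned are rejected as
#' low-confidence rather than guessed.
#'
#' @param rec An unmapped balanced `rxn_reaction`.
#' @param byproducts Byproduct SMILES used to designate product-side
#'   components.
#' @param implicit_reagents Reactant-side implicit components; see
#'   [derive_vector()].
#' @return The same reaction with atom maps assigned.
#' @export
auto_map_reaction <- function(rec, byproducts = rx_default_byproducts("leaving"),
                              implicit_reagents = c(water = "O")) {
  bp_canon <- rx_canonical_smiles(byproducts)
  implicit_canon <- if (length(implicit_reagents))
    rx_canonical_smiles(implicit_reagents) else character(0)
  p_smiles <- vapply(rec$products, `[[`, "", "smiles")
  principal_p <- which(!(p_smiles %in% bp_canon))
  if (length(principal_p) != 1) {
    stop("auto-mapping supports exactly one principal product", call. = FALSE)
  }
  main <- rec$products[[principal_p]]
  r_smiles <- vapply(rec$reactants, `[[`, "", "smiles")
  principal_r <- which(!(r_smiles %in% implicit_canon))
  ord <- principal_r[order(-vapply(principal_r, function(i)
    nrow(rec$reactants[[i]]$atoms), numeric(1)))]
  pairs <- lapply(ord, function(i) list(a = rec$reactants[[i]]$input,
                                        b = main$input))
  mcs <- .rx_call("mcs", list(pairs = pairs))
  used_p <- logical(nrow(main$atoms))
  next_map <- 1L
  for (k in seq_along(ord)) {
    ci <- ord[k]
    res <- mcs[[k]]
    if (is.null(res)) stop("MCS mapping failed", call. = FALSE)
    # choose the MCS placement that maps the most not-yet-claimed product atoms
    best <- list(a = integer(0), b = integer(0))
    for (am in res$a_matches) {
      for (bm in res$b_matches) {
        a_try <- unlist(am); b_try <- unlist(bm)
        keep <- !used_p[b_try]
        if (sum(keep) > length(best$a)) {
          best <- list(a = a_try[keep], b = b_try[keep])
        }
      }
    }
    a_idx <- best$a; b_idx <- best$b
    cover <- length(a_idx) / nrow(rec$reactants[[ci]]$atoms)
    if (cover < 0.5) {
      stop("low-confidence atom mapping for reactant component ", ci,
           " (", round(100 * cover), "% aligned); supply atom maps explicitly",
           call. = FALSE)
    }
    for (t in seq_along(a_idx)) {
      rec$reactants[[ci]]$atoms$map[a_idx[t]] <- next_map
      rec$products[[principal_p]]$atoms$map[b_idx[t]] <- next_map
      used_p[b_idx[t]] <- TRUE
      next_map <- next_map + 1L
    }
  }
  rec
}
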