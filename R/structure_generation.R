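# Applying reaction vectors to new reactants.
#
# Validity is tested on the pair level (the reactant must contain the negative
# atom pairs, wholly or partially) and on the graph level (the stored
# reaction-centre template must embed). Application is the stored-template
# graph edit: bonds of the source side are removed or re-ordered, bonds of the
# target side are formed across the embedded attachment atoms, leaving
# fragments matching the configured byproduct list are dropped, and every
# emitted product must reproduce the signed pair difference exactly.

# ---- template embedding -----------------------------------------------------

.mol_bond_lookup <- function(mol) {
  env <- new.env(parent = emptyenv())
  if (nrow(mol$bonds) > 0) {
    keys <- paste0(pmin(mol$bonds$a, mol$bonds$b), "_",
                   pmax(mol$bonds$a, mol$bonds$b))
    for (k in seq_along(keys)) {
      env[[keys[k]]] <- c(order = mol$bonds$order[k], arom = mol$bonds$arom[k])
    }
  }
  env
}

.bond_compatible <- function(tpl_order, tpl_arom, mol_bond) {
  if (is.null(mol_bond)) return(FALSE)
  if (tpl_arom) return(mol_bond[["arom"]] == 1)
  mol_bond[["arom"]] == 0 && mol_bond[["order"]] == tpl_order
}

# All embeddings of one source-side template component into a molecule.
# Template atoms must match the molecule exactly on (element, h, p, r,
# aromaticity, charge): the pair difference is checked exactly downstream, so
# looser matches could never conserve it.
.embed_component <- function(tpl, comp, mol) {
  atoms <- tpl$atoms[tpl$atoms$src_comp == comp, ]
  if (nrow(atoms) == 0) return(list())
  n <- nrow(mol$atoms)
  cand <- lapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    which(mol$atoms$element == a$element & mol$atoms$degree == a$src_h &
          mol$atoms$pi == a$src_p & mol$atoms$ring == a$src_r &
          mol$atoms$arom == a$src_arom & mol$atoms$charge == a$src_charge)
  })
  if (any(vapply(cand, length, integer(1)) == 0)) return(list())
  tids <- atoms$tid
  in_comp <- tpl$src_bonds$i %in% tids & tpl$src_bonds$j %in% tids
  cbonds <- tpl$src_bonds[in_comp, ]
  # order template atoms: most constrained first, then prefer connectivity
  ord <- order(vapply(cand, length, integer(1)))
  tids_ord <- tids[ord]
  cand_ord <- cand[ord]
  pos_of <- stats::setNames(seq_along(tids_ord), tids_ord)
  blook <- .mol_bond_lookup(mol)
  results <- list()
  assign <- integer(length(tids_ord))
  used <- logical(n)
  recurse <- function(depth) {
    if (depth > length(tids_ord)) {
      emb <- stats::setNames(assign, tids_ord)
      results[[length(results) + 1]] <<- emb[order(as.integer(names(emb)))]
      return(invisible(NULL))
    }
    tid <- tids_ord[depth]
    for (m_idx in cand_ord[[depth]]) {
      if (used[m_idx]) next
      ok <- TRUE
      for (b in seq_len(nrow(cbonds))) {
        ti <- cbonds$i[b]; tj <- cbonds$j[b]
        other <- if (ti == tid) tj else if (tj == tid) ti else next
        od <- pos_of[[as.character(other)]]
        if (od >= depth) next  # other end not assigned yet
        g_other <- assign[od]
        key <- paste0(min(m_idx, g_other), "_", max(m_idx, g_other))
        if (!.bond_compatible(cbonds$order[b], cbonds$arom[b], blook[[key]])) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      assign[depth] <<- m_idx
      used[m_idx] <<- TRUE
      recurse(depth + 1)
      used[m_idx] <<- FALSE
    }
    invisible(NULL)
  }
  recurse(1)
  results
}

# ---- validity ---------------------------------------------------------------

#' Test whether a reaction vector applies to a reactant
#'
#' A match is `"full"` when the reactant's pair vector contains the entire
#' negative multiset and every principal reactant-template component embeds;
#' `"partial"` when one template component embeds and the missing negative
#' pairs are attributable to the single absent component; `"none"` otherwise.
#'
#' @param rv A `rxn_vector`.
#' @param reactant A `rxn_mol` or SMILES string.
#' @return A `rxn_match`: list with `kind`, `site_matches` (embeddings per
#'   template component), `missing_negative` (empty iff full), and for partial
#'   matches the ids of the matched and absent components.
#' @export
match_vector <- function(rv, reactant) {
  stopifnot(inherits(rv, "rxn_vector"))
  mol <- .as_mol(reactant)
  principal <- rv$template$src_comps$comp[!rv$template$src_comps$byprod]
  mol_vec <- component_vector(mol)
  missing <- ap_shortfall(mol_vec, rv$negative)
  emb <- lapply(principal, function(cc) .embed_component(rv$template, cc, mol))
  names(emb) <- as.character(principal)
  embeds <- vapply(emb, function(e) length(e) > 0, logical(1))
  res <- list(kind = "none", site_matches = emb,
              missing_negative = missing, matched_comp = NULL,
              absent_comp = NULL)
  if (length(missing) == 0 && all(embeds)) {
    res$kind <- "full"
  } else if (length(principal) == 2 && sum(embeds) == 1 && length(missing) > 0) {
    absent <- principal[!embeds]
    absent_smiles <- rv$template$src_comps$smiles[
      rv$template$src_comps$comp == absent]
    if (ap_contains(component_vector(absent_smiles), missing)) {
      res$kind <- "partial"
      res$matched_comp <- principal[embeds]
      res$absent_comp <- absent
    }
  }
  class(res) <- "rxn_match"
  res
}

#' @export
print.rxn_match <- function(x, ...) {
  cat("<rxn_match> ", x$kind, "\n", sep = "")
  if (length(x$missing_negative)) {
    cat("  missing negative pairs: ",
        paste(names(x$missing_negative), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Find reagents completing a partial match
#'
#' Scans a reagent library for building blocks whose pair vector contains the
#' missing negative pairs and which embed the absent reactant-template
#' component, ranked by the building-block score (Euclidean distance between
#' count FeatMorgan fingerprints of the reagent and of the template's own
#' source component), ties broken by canonical SMILES.
#'
#' @param rv A `rxn_vector`.
#' @param match A partial `rxn_match` from [match_vector()].
#' @param lib A `reagent_library`.
#' @param k Maximum number of reagents returned.
#' @return Tibble with `id`, `smiles`, `distance` (ascending).
#' @export
find_completing_reagents <- function(rv, match, lib, k = 10L) {
  stopifnot(inherits(match, "rxn_match"))
  if (match$kind != "partial") {
    stop("find_completing_reagents() needs a partial match; got '",
         match$kind, "'", call. = FALSE)
  }
  absent <- match$absent_comp
  keep <- logical(nrow(lib))
  for (i in seq_len(nrow(lib))) {
    mol <- parse_mol(lib$smiles[i])
    if (!ap_contains(component_vector(mol), match$missing_negative)) next
    if (length(.embed_component(rv$template, absent, mol)) == 0) next
    keep[i] <- TRUE
  }
  hits <- lib[keep, c("id", "smiles")]
  if (nrow(hits) == 0) {
    return(tibble::tibble(id = character(0), smiles = character(0),
                          distance = numeric(0)))
  }
  query <- rv$template$src_comps$smiles[rv$template$src_comps$comp == absent]
  qfp <- rx_morgan_count_vectors(query, features = TRUE)[1, ]
  hfp <- rx_morgan_count_vectors(hits$smiles, features = TRUE)
  hits$distance <- sqrt(rowSums(sweep(hfp, 2, qfp)^2))
  hits <- hits[order(hits$distance, hits$smiles), ]
  utils::head(hits, k)
}

# ---- application ------------------------------------------------------------

.apply_edit <- function(rv, mols, assignment, embeddings, byprod_allow) {
  tpl <- rv$template
  # global atom table: input molecules first, then instantiated implicit atoms
  offsets <- cumsum(c(0, vapply(mols, function(m) nrow(m$atoms), numeric(1))))
  n_atoms <- offsets[length(offsets)]
  g_element <- unlist(lapply(mols, function(m) m$atoms$element))
  g_charge <- unlist(lapply(mols, function(m) m$atoms$charge))
  bonds <- dplyr::bind_rows(lapply(seq_along(mols), function(i) {
    mb <- mols[[i]]$bonds
    tibble::tibble(a = mb$a + offsets[i], b = mb$b + offsets[i],
                   order = mb$order, arom = mb$arom)
  }))

  tid2g <- stats::setNames(rep(NA_integer_, nrow(tpl$atoms)), tpl$atoms$tid)
  for (cc in names(embeddings)) {
    emb <- embeddings[[cc]]
    mol_slot <- assignment[[cc]]
    for (tid in names(emb)) {
      tid2g[[tid]] <- emb[[tid]] + offsets[mol_slot]
    }
  }
  implicit_comps <- tpl$src_comps$comp[tpl$src_comps$byprod]
  for (cc in implicit_comps) {
    rows <- which(tpl$atoms$src_comp == cc)
    for (ri in rows) {
      n_atoms <- n_atoms + 1L
      g_element <- c(g_element, tpl$atoms$element[ri])
      g_charge <- c(g_charge, tpl$atoms$src_charge[ri])
      tid2g[[as.character(tpl$atoms$tid[ri])]] <- n_atoms
    }
    in_cc <- tpl$src_bonds$i %in% tpl$atoms$tid[rows] &
             tpl$src_bonds$j %in% tpl$atoms$tid[rows]
    for (bi in which(in_cc)) {
      bonds <- dplyr::bind_rows(bonds, tibble::tibble(
        a = tid2g[[as.character(tpl$src_bonds$i[bi])]],
        b = tid2g[[as.character(tpl$src_bonds$j[bi])]],
        order = tpl$src_bonds$order[bi], arom = tpl$src_bonds$arom[bi]))
    }
  }
  if (anyNA(tid2g)) return(list(ok = FALSE, reason = "incomplete embedding"))
  if (anyDuplicated(tid2g)) return(list(ok = FALSE, reason = "overlapping sites"))

  # charges move to their target-side values
  g_charge[tid2g] <- tpl$atoms$tgt_charge

  pair_key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  src_keys <- pair_key(tpl$src_bonds$i, tpl$src_bonds$j)
  tgt_keys <- pair_key(tpl$tgt_bonds$i, tpl$tgt_bonds$j)
  edits <- character(0)
  bond_rows_key <- pair_key(bonds$a, bonds$b)
  g_of <- function(tid) tid2g[[as.character(tid)]]
  for (key in union(src_keys, tgt_keys)) {
    ij <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
    gkey <- pair_key(g_of(ij[1]), g_of(ij[2]))
    s <- which(src_keys == key)
    t <- which(tgt_keys == key)
    if (length(s) && !length(t)) {
      hit <- which(bond_rows_key == gkey)
      if (!length(hit)) return(list(ok = FALSE, reason = "source bond missing"))
      bonds <- bonds[-hit, ]
      bond_rows_key <- bond_rows_key[-hit]
      edits <- c(edits, paste0("del:", gkey))
    } else if (length(t) && !length(s)) {
      bonds <- dplyr::bind_rows(bonds, tibble::tibble(
        a = g_of(ij[1]), b = g_of(ij[2]),
        order = tpl$tgt_bonds$order[t], arom = tpl$tgt_bonds$arom[t]))
      bond_rows_key <- c(bond_rows_key, gkey)
      edits <- c(edits, paste0("add:", gkey, ":", tpl$tgt_bonds$order[t]))
    } else if (length(s) && length(t)) {
      if (tpl$src_bonds$arom[s] && tpl$tgt_bonds$arom[t]) next
      if (tpl$src_bonds$order[s] != tpl$tgt_bonds$order[t] ||
          tpl$src_bonds$arom[s] != tpl$tgt_bonds$arom[t]) {
        hit <- which(bond_rows_key == gkey)
        if (!length(hit)) return(list(ok = FALSE, reason = "source bond missing"))
        bonds$order[hit] <- tpl$tgt_bonds$order[t]
        bonds$arom[hit] <- tpl$tgt_bonds$arom[t]
        edits <- c(edits, paste0("mod:", gkey, ":", tpl$tgt_bonds$order[t]))
      }
    }
  }

  # split into connected components
  comp_id <- .connected_components(n_atoms, bonds)
  g2tid <- stats::setNames(as.integer(names(tid2g)), tid2g)
  tgt_principal <- tpl$tgt_comps$comp[!tpl$tgt_comps$byprod]
  tgt_byprod <- tpl$tgt_comps$comp[tpl$tgt_comps$byprod]
  comp_atoms <- split(seq_len(n_atoms), comp_id)
  principal_out <- list()
  byprod_out <- list()
  for (atoms_in in comp_atoms) {
    tids_in <- g2tid[as.character(intersect(atoms_in, tid2g))]
    tgt_of_tids <- tpl$atoms$tgt_comp[match(tids_in, tpl$atoms$tid)]
    if (any(tgt_of_tids %in% tgt_byprod)) {
      bc <- unique(tgt_of_tids[tgt_of_tids %in% tgt_byprod])
      expected <- tpl$atoms$tid[tpl$atoms$tgt_comp %in% bc]
      if (length(bc) > 1 || !setequal(tids_in, expected) ||
          length(atoms_in) != length(expected)) {
        return(list(ok = FALSE,
                    reason = "leaving fragment carries non-byproduct atoms"))
      }
      byprod_out[[length(byprod_out) + 1]] <- atoms_in
    } else {
      principal_out[[length(principal_out) + 1]] <- atoms_in
    }
  }
  if (length(principal_out) != length(tgt_principal)) {
    return(list(ok = FALSE, reason = sprintf(
      "expected %d principal product component(s), got %d",
      length(tgt_principal), length(principal_out))))
  }
  graph_spec <- function(atoms_in) {
    local_id <- stats::setNames(seq_along(atoms_in), atoms_in)
    brows <- bonds[bonds$a %in% atoms_in & bonds$b %in% atoms_in, ]
    list(
      atoms = lapply(atoms_in, function(g) list(element = g_element[g],
                                                charge = g_charge[g])),
      bonds = lapply(seq_len(nrow(brows)), function(i) list(
        a = local_id[[as.character(brows$a[i])]],
        b = local_id[[as.character(brows$b[i])]],
        order = brows$order[i]))
    )
  }
  list(ok = TRUE,
       signature = paste(sort(edits), collapse = ";"),
       principal_specs = lapply(principal_out, graph_spec),
       byprod_specs = lapply(byprod_out, graph_spec))
}

.connected_components <- function(n, bonds) {
  comp <- integer(n)
  adj <- .adjacency_list(n, bonds)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

#' Apply a reaction vector to reactant(s)
#'
#' Embeds the reactant-side template at every (or one chosen) site, performs
#' the stored graph edit — breaking the source-side bonds, forming the
#' target-side bonds, instantiating implicit reagents, dropping leaving
#' fragments that match the byproduct list — and sanitises the assembled
#' product. Every emitted product must pass the signed pair-difference
#' conservation check exactly; failures are discarded with a logged reason.
#'
#' @param rv A `rxn_vector` (use [reverse_vector()] to run retrosynthetically).
#' @param reactants A single molecule/SMILES or list of them; one molecule per
#'   principal template component (a single molecule may also cover both
#'   components of a bimolecular vector, i.e. an intramolecular application).
#' @param site Optional edit signature selecting one site from a previous run.
#' @param byproducts Allow-list for leaving fragments.
#' @return Tibble of generated products: `product` (canonical SMILES),
#'   `byproducts` (list), `vector_id`, `reactants` (list), `site`. Discarded
#'   attempts are reported in the `attrition` attribute.
#' @export
apply_vector <- function(rv, reactants, site = NULL,
                         byproducts = rx_default_byproducts("leaving")) {
  stopifnot(inherits(rv, "rxn_vector"))
  if (!is.list(reactants) || inherits(reactants, "rxn_mol")) {
    reactants <- list(reactants)
  }
  mols <- lapply(reactants, .as_mol)
  tpl <- rv$template
  principal <- tpl$src_comps$comp[!tpl$src_comps$byprod]
  if (!(length(mols) == length(principal) ||
        (length(mols) == 1 && length(principal) == 2))) {
    stop("vector '", rv$id, "' needs ", length(principal),
         " principal reactant(s); got ", length(mols), call. = FALSE)
  }

  # candidate molecule assignment per template component
  if (length(mols) == length(principal)) {
    perms <- if (length(principal) == 1) list(1L) else list(c(1L, 2L), c(2L, 1L))
  } else {
    perms <- list(c(1L, 1L))
  }
  attrition <- character(0)
  seen_sig <- character(0)
  jobs <- list()
  for (perm in perms) {
    assignment <- stats::setNames(as.list(perm), principal)
    embs <- lapply(seq_along(principal), function(k) {
      .embed_component(tpl, principal[k], mols[[perm[k]]])
    })
    if (any(vapply(embs, length, integer(1)) == 0)) next
    grid <- expand.grid(lapply(embs, seq_along))
    for (gi in seq_len(nrow(grid))) {
      embeddings <- stats::setNames(
        lapply(seq_along(principal), function(k) embs[[k]][[grid[gi, k]]]),
        principal)
      edit <- .apply_edit(rv, mols, assignment, embeddings, byproducts)
      if (!edit$ok) {
        attrition <- c(attrition, edit$reason)
        next
      }
      if (edit$signature %in% seen_sig) next
      seen_sig <- c(seen_sig, edit$signature)
      if (!is.null(site) && edit$signature != site) next
      jobs[[length(jobs) + 1]] <- list(edit = edit, perm = perm)
    }
  }
  if (length(jobs) == 0) {
    if (!is.null(site)) {
      stop("vector '", rv$id, "' does not apply at the requested site",
           call. = FALSE)
    }
    out <- tibble::tibble(product = character(0), byproducts = list(),
                          vector_id = character(0), reactants = list(),
                          site = character(0))
    attr(out, "attrition") <- attrition
    return(out)
  }

  # batch-build all assembled graphs, then check conservation
  specs <- unlist(lapply(jobs, function(j) c(j$edit$principal_specs,
                                             j$edit$byprod_specs)),
                  recursive = FALSE)
  built <- rx_build_mols(specs)
  rows <- list()
  cursor <- 1L
  implicit_smiles <- tpl$src_comps$smiles[tpl$src_comps$byprod]
  target_diff <- ap_diff(rv$positive, rv$negative)
  for (j in jobs) {
    np <- length(j$edit$principal_specs)
    nb <- length(j$edit$byprod_specs)
    slice <- built[cursor:(cursor + np + nb - 1)]
    cursor <- cursor + np + nb
    if (!all(vapply(slice, function(x) isTRUE(x$ok), logical(1)))) {
      bad <- slice[[which(!vapply(slice, function(x) isTRUE(x$ok), logical(1)))[1]]]
      attrition <- c(attrition, paste0("sanitisation failed: ", bad$error))
      next
    }
    prod_smiles <- vapply(slice[seq_len(np)], `[[`, "", "smiles")
    byp_smiles <- if (nb) vapply(slice[np + seq_len(nb)], `[[`, "", "smiles")
                  else character(0)
    if (nb) {
      allow <- rx_canonical_smiles(byproducts)
      if (!all(byp_smiles %in% allow)) {
        attrition <- c(attrition, paste0("leaving fragment not a configured ",
                                         "byproduct: ",
                                         paste(setdiff(byp_smiles, allow),
                                               collapse = ", ")))
        next
      }
    }
    used_mols <- mols[unique(j$perm)]
    lhs <- Reduce(ap_sum, c(lapply(used_mols, component_vector),
                            lapply(implicit_smiles, component_vector)),
                  ap_vector())
    rhs <- Reduce(ap_sum, c(lapply(prod_smiles, component_vector),
                            lapply(byp_smiles, component_vector)),
                  ap_vector())
    if (!ap_equal(ap_diff(rhs, lhs), target_diff)) {
      attrition <- c(attrition, "pair-difference conservation check failed")
      next
    }
    for (ps in prod_smiles) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        product = ps,
        byproducts = list(byp_smiles),
        vector_id = rv$id,
        reactants = list(vapply(mols[unique(j$perm)], `[[`, "", "smiles")),
        site = j$edit$signature
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(product = character(0), byproducts = list(),
                   vector_id = character(0), reactants = list(),
                   site = character(0))
  attr(out, "attrition") <- attrition
  out
}

#' Generate products for a starting molecule against a vector database
#'
#' Runs the validity test for every vector in the database against the
#' starting molecule; full matches are applied directly and partial matches
#' are completed with library reagents containing the missing negative pairs.
#' Products are deduplicated by canonical SMILES (provenances merged), ordered
#' deterministically and capped.
#'
#' @param db A `rxn_vector_db`.
#' @param start Starting molecule (SMILES or `rxn_mol`).
#' @param lib A `reagent_library` for completing partial matches.
#' @param limits List: `max_products` (default `Inf`) and `k_reagents`
#'   (reagents tried per partial match, default 25).
#' @return Tibble `product`, `n_routes`, `provenance` (list of per-route
#'   tibbles), ordered by canonical SMILES.
#' @export
generate_products <- function(db, start, lib = NULL,
                              limits = list(max_products = Inf, k_reagents = 25L)) {
  stopifnot(inherits(db, "rxn_vector_db"))
  start <- .as_mol(start)
  max_products <- limits$max_products %||% Inf
  k_reagents <- limits$k_reagents %||% 25L
  all_rows <- list()
  for (rv in db$entries) {
    m <- match_vector(rv, start)
    if (m$kind == "full") {
      n_pr <- sum(!rv$template$src_comps$byprod)
      res <- apply_vector(rv, if (n_pr == 1) list(start) else list(start))
      if (nrow(res)) all_rows[[length(all_rows) + 1]] <- res
    } else if (m$kind == "partial" && !is.null(lib)) {
      reagents <- find_completing_reagents(rv, m, lib, k = k_reagents)
      for (smi in reagents$smiles) {
        res <- apply_vector(rv, list(start, parse_mol(smi)))
        if (nrow(res)) all_rows[[length(all_rows) + 1]] <- res
      }
    }
  }
  if (length(all_rows) == 0) {
    return(tibble::tibble(product = character(0), n_routes = integer(0),
                          provenance = list()))
  }
  rows <- dplyr::bind_rows(all_rows)
  groups <- split(rows, rows$product)
  out <- tibble::tibble(
    product = names(groups),
    n_routes = unname(vapply(groups, nrow, integer(1))),
    provenance = unname(lapply(groups, function(g)
      tibble::tibble(vector_id = g$vector_id, reactants = g$reactants,
                     site = g$site)))
  )
  out <- out[order(out$product), ]
  utils::head(out, max_products)
}
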