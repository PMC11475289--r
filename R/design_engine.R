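# The inside-out design loop: fragment reference ligands retrosynthetically,
# retrieve similar building blocks for each fragment, reassemble forward with
# the same reaction vectors under multi-objective scoring, and finish with the
# passive filter cascade.

#' Design configuration
#'
#' @param beam_width Candidates retained after scoring at each step, and
#'   reagent combinations tried per fragment set.
#' @param max_depth Retrosynthetic fragmentation depth.
#' @param max_final_products Cap on emitted candidates per reference.
#' @param k_building_blocks Similar reagents retrieved per fragment.
#' @param weights Named objective weights for the weighted-sum aggregation
#'   (default equal).
#' @param seed Seed for the only stochastic element, optional library
#'   subsampling.
#' @param subsample_library Optional integer: score against a random subset of
#'   the library of this size.
#' @param pareto If `TRUE`, rank candidates by Pareto non-domination instead
#'   of the weighted sum.
#' @param attachment_check If `TRUE`, a replacement building block must embed
#'   the template component of the fragment it replaces (a heuristic guard
#'   against fragment shuffling; off by default).
#' @return A `design_config` list.
#' @export
design_config <- function(beam_width = 50L, max_depth = 1L,
                          max_final_products = 100L, k_building_blocks = 10L,
                          weights = NULL, seed = 1L, subsample_library = NULL,
                          pareto = FALSE, attachment_check = FALSE) {
  structure(list(beam_width = as.integer(beam_width),
                 max_depth = as.integer(max_depth),
                 max_final_products = as.integer(max_final_products),
                 k_building_blocks = as.integer(k_building_blocks),
                 weights = weights, seed = as.integer(seed),
                 subsample_library = subsample_library, pareto = pareto,
                 attachment_check = attachment_check),
            class = "design_config")
}

# ---- scorers ----------------------------------------------------------------

#' Scorer contract
#'
#' A scorer is a named, direction-annotated, deterministic batch function:
#' `score(smiles)` returns one number per input, order-preserving.
#'
#' @param name Objective name.
#' @param direction `"maximize"` or `"minimize"`.
#' @param score Function from a character vector of SMILES to a numeric
#'   vector.
#' @return A `rxn_scorer`.
#' @export
new_scorer <- function(name, direction = c("maximize", "minimize"), score) {
  direction <- match.arg(direction)
  stopifnot(is.function(score))
  structure(list(name = name, direction = direction, score = score),
            class = "rxn_scorer")
}

#' Similarity-to-reference scorer
#'
#' Tanimoto similarity (binary Morgan radius-2, 1024 bits) to a reference
#' structure; maximized.
#'
#' @param reference Reference SMILES.
#' @return A `rxn_scorer`.
#' @export
similarity_scorer <- function(reference) {
  ref <- rx_canonical_smiles(reference)
  new_scorer(
    name = "similarity", direction = "maximize",
    score = function(smiles) {
      vapply(smiles, function(s) tanimoto_similarity(s, ref), numeric(1),
             USE.NAMES = FALSE)
    })
}

#' Property-window scorer
#'
#' Scores 1 inside the molecular-weight and logP windows and decays linearly
#' with the relative excursion outside them; maximized. The defaults bracket
#' lead-like space.
#'
#' @param mw_range,logp_range Two-element numeric windows.
#' @return A `rxn_scorer`.
#' @export
property_scorer <- function(mw_range = c(200, 500), logp_range = c(-1, 5)) {
  penalty <- function(x, range) {
    width <- diff(range)
    below <- pmax(range[1] - x, 0) / width
    above <- pmax(x - range[2], 0) / width
    pmax(1 - below - above, 0)
  }
  new_scorer(
    name = "property_window", direction = "maximize",
    score = function(smiles) {
      d <- rx_descriptors(smiles)
      (penalty(d$mw, mw_range) + penalty(d$logp, logp_range)) / 2
    })
}

# ---- fragmentation ----------------------------------------------------------

#' Fragment a reference ligand retrosynthetically
#'
#' Applies every database vector in reverse (positive/negative swapped,
#' product template matched against the reference); each application site
#' yields one fragment set. Sets are verified by reassembly — forward
#' application of the recorded route must regenerate the reference — before
#' being returned. With `max_depth > 1`, fragments are fragmented further and
#' routes are extended in forward-synthesis order.
#'
#' @param ref Reference molecule (SMILES or `rxn_mol`).
#' @param db A `rxn_vector_db`.
#' @param max_depth Recursion depth.
#' @return List of fragment sets: `reference`, `fragments` (canonical
#'   SMILES), `steps` (forward route; each step has `vector_id`, `inputs`
#'   — fragment labels `"f<i>"` or step outputs `"@<k>"` — and the recorded
#'   `product`). A molecule matching no vector yields one degenerate set
#'   containing itself with an empty route.
#' @export
fragment_reference <- function(ref, db, max_depth = 1L) {
  mol <- .as_mol(ref)
  sets <- .fragment_once(mol$smiles, db)
  if (length(sets) == 0) {
    return(list(list(reference = mol$smiles, fragments = mol$smiles,
                     steps = list())))
  }
  depth <- 1L
  while (depth < max_depth) {
    expanded <- list()
    for (fs in sets) {
      expanded[[length(expanded) + 1]] <- fs
      for (fi in seq_along(fs$fragments)) {
        subsets <- .fragment_once(fs$fragments[fi], db)
        for (sub in subsets) {
          expanded[[length(expanded) + 1]] <-
            .splice_fragment_set(fs, fi, sub)
        }
      }
    }
    if (length(expanded) == length(sets)) break
    sets <- unique(expanded)
    depth <- depth + 1L
  }
  sets
}

# one-level retro application of every vector; verified by reassembly
.fragment_once <- function(smiles, db) {
  sets <- list()
  for (rv in db$entries) {
    rvr <- reverse_vector(rv)
    if (sum(!rvr$template$src_comps$byprod) != 1) next
    res <- tryCatch(apply_vector(rvr, list(smiles)), error = function(e) NULL)
    if (is.null(res) || nrow(res) == 0) next
    for (sig in unique(res$site)) {
      frags <- sort(res$product[res$site == sig])
      fwd <- tryCatch(apply_vector(rv, as.list(frags)), error = function(e) NULL)
      if (is.null(fwd) || !(smiles %in% fwd$product)) next
      sets[[length(sets) + 1]] <- list(
        reference = smiles,
        fragments = frags,
        steps = list(list(vector_id = rv$id,
                          inputs = paste0("f", seq_along(frags)),
                          product = smiles)))
    }
  }
  sets
}

# replace leaf fi of set fs by the deeper set `sub`, renumbering fragment
# labels and prepending sub's steps in forward order
.splice_fragment_set <- function(fs, fi, sub) {
  old_frags <- fs$fragments
  new_frags <- append(old_frags[-fi], sub$fragments, after = fi - 1)
  relabel <- function(lbl) {
    if (grepl("^@", lbl)) return(lbl)
    k <- as.integer(sub("^f", "", lbl))
    if (k < fi) paste0("f", k)
    else if (k == fi) paste0("@", length(sub$steps))  # output of spliced chain
    else paste0("f", k + length(sub$fragments) - 1L)
  }
  sub_steps <- lapply(sub$steps, function(st) {
    st$inputs <- vapply(st$inputs, function(lbl) {
      if (grepl("^@", lbl)) return(lbl)
      k <- as.integer(sub("^f", "", lbl))
      paste0("f", k + fi - 1L)
    }, "")
    st
  })
  main_steps <- lapply(fs$steps, function(st) {
    st$inputs <- vapply(st$inputs, relabel, "")
    # step references shift by the number of prepended steps
    st$inputs <- vapply(st$inputs, function(lbl) {
      if (!grepl("^@", lbl)) return(lbl)
      paste0("@", as.integer(sub("^@", "", lbl)))
    }, "")
    st
  })
  list(reference = fs$reference, fragments = new_frags,
       steps = c(sub_steps, main_steps))
}

#' Rank building blocks by fingerprint distance to a fragment
#'
#' Full-scan ranking by Euclidean distance between count FeatMorgan
#' fingerprints (radius 2, 1024 counts) of the fragment and of each library
#' member; ties broken by canonical SMILES.
#'
#' @param fragment SMILES or `rxn_mol`.
#' @param lib A `reagent_library`.
#' @param k Number of reagents returned.
#' @return Tibble `id`, `smiles`, `distance`, ascending.
#' @export
score_building_blocks <- function(fragment, lib, k = 10L) {
  smiles <- if (inherits(fragment, "rxn_mol")) fragment$smiles
            else rx_canonical_smiles(fragment)
  if (nrow(lib) == 0) {
    return(tibble::tibble(id = character(0), smiles = character(0),
                          distance = numeric(0)))
  }
  fps <- attr(lib, "fingerprints")
  if (is.null(fps)) fps <- rx_morgan_count_vectors(lib$smiles, features = TRUE)
  qfp <- rx_morgan_count_vectors(smiles, features = TRUE)[1, ]
  d <- sqrt(rowSums(sweep(fps, 2, qfp)^2))
  out <- tibble::tibble(id = lib$id, smiles = lib$smiles, distance = d)
  out <- out[order(out$distance, out$smiles), ]
  utils::head(out, k)
}

# ---- route replay -----------------------------------------------------------

#' Replay a synthetic route
#'
#' Executes the recorded steps in forward order through [apply_vector()],
#' checking at each step that the recorded intermediate is actually produced.
#'
#' @param steps Route steps (see [fragment_reference()]); `inputs` must be
#'   SMILES or `"@<k>"` references to earlier step outputs.
#' @param db The `rxn_vector_db` holding the vectors named in the route.
#' @return Final product SMILES, or `NA_character_` if any step fails to
#'   reproduce its recorded product.
#' @export
replay_route <- function(steps, db) {
  ids <- vapply(db$entries, `[[`, "", "id")
  outputs <- character(length(steps))
  for (k in seq_along(steps)) {
    st <- steps[[k]]
    rv <- db$entries[[match(st$vector_id, ids)]]
    if (is.null(rv)) return(NA_character_)
    inputs <- vapply(st$inputs, function(lbl) {
      if (grepl("^@", lbl)) outputs[as.integer(sub("^@", "", lbl))] else lbl
    }, "")
    res <- tryCatch(apply_vector(rv, as.list(inputs)), error = function(e) NULL)
    if (is.null(res) || !(st$product %in% res$product)) return(NA_character_)
    outputs[k] <- st$product
  }
  outputs[length(outputs)]
}

# ---- the design loop --------------------------------------------------------

#' Run the inside-out design loop
#'
#' Per reference: fragment retrosynthetically, retrieve the
#' `k_building_blocks` most similar library reagents for each fragment,
#' reassemble candidate combinations forward through the same reaction
#' vectors, score each candidate with every active scorer, keep the beam, and
#' finish with the passive cascade (reactive-group conversion, exclusion
#' substructures, Lipinski). All steps are deterministic for a fixed seed;
#' randomness enters only through optional library subsampling.
#'
#' @param refs Character vector of reference SMILES (optionally named), or a
#'   data frame with `name` and `smiles` columns.
#' @param db A `rxn_vector_db`.
#' @param lib A `reagent_library`.
#' @param scorers List of `rxn_scorer` objects; defaults to
#'   similarity-to-reference plus the property-window scorer.
#' @param rules A `filter_rules` object for the passive cascade.
#' @param transform_db Optional transformation database for reactive-group
#'   conversion.
#' @param config A [design_config()].
#' @return A `rxn_design` object: `candidates` tibble (reference, structure,
#'   per-objective scores, aggregate `total`, `route`), `attrition` tibble,
#'   and the configuration.
#' @export
run_design <- function(refs, db, lib, scorers = NULL,
                       rules = default_filter_rules(), transform_db = NULL,
                       config = design_config()) {
  if (is.data.frame(refs)) {
    refs <- stats::setNames(refs$smiles, refs$name)
  }
  if (is.null(names(refs))) names(refs) <- paste0("ref", seq_along(refs))
  refs <- stats::setNames(rx_canonical_smiles(refs), names(refs))
  if (!is.null(config$subsample_library) &&
      config$subsample_library < nrow(lib)) {
    set.seed(config$seed)
    keep <- sort(sample.int(nrow(lib), config$subsample_library))
    fps <- attr(lib, "fingerprints")
    lib <- lib[keep, ]
    attr(lib, "fingerprints") <- fps[keep, , drop = FALSE]
  }

  all_candidates <- list()
  attrition <- list()
  note <- function(ref, stage, n) {
    attrition[[length(attrition) + 1]] <<- tibble::tibble(
      reference = ref, stage = stage, n = n)
  }

  for (rn in names(refs)) {
    ref <- refs[[rn]]
    fsets <- fragment_reference(ref, db, config$max_depth)
    fsets <- Filter(function(fs) length(fs$steps) > 0, fsets)
    note(rn, "fragment_sets", length(fsets))
    generated <- list()
    for (fs in fsets) {
      bb <- lapply(fs$fragments, function(f)
        score_building_blocks(f, lib, config$k_building_blocks))
      if (any(vapply(bb, nrow, integer(1)) == 0)) next
      if (config$attachment_check) {
        bb <- .attachment_filter(bb, fs, db)
        if (any(vapply(bb, nrow, integer(1)) == 0)) next
      }
      grid <- expand.grid(lapply(bb, function(b) seq_len(nrow(b))))
      total_d <- rowSums(vapply(seq_along(bb), function(j)
        bb[[j]]$distance[grid[[j]]], numeric(nrow(grid))))
      grid <- grid[order(total_d), , drop = FALSE]
      grid <- utils::head(grid, config$beam_width)
      for (gi in seq_len(nrow(grid))) {
        reagents <- vapply(seq_along(bb), function(j)
          bb[[j]]$smiles[grid[gi, j]], "")
        prods <- .replay_with_reagents(fs$steps, reagents, db)
        for (p in prods) {
          generated[[length(generated) + 1]] <- tibble::tibble(
            reference = rn, structure = p$product, route = list(p$steps))
        }
      }
    }
    if (length(generated) == 0) {
      note(rn, "generated", 0L)
      next
    }
    cands <- dplyr::bind_rows(generated)
    cands <- cands[!duplicated(cands$structure), ]
    cands <- cands[order(cands$structure), ]
    note(rn, "generated", nrow(cands))

    scs <- scorers %||% list(similarity_scorer(ref), property_scorer())
    cands <- .score_candidates(cands, scs, config)
    cands <- utils::head(
      cands[order(-cands$total, cands$structure), ], config$beam_width)
    note(rn, "beam", nrow(cands))

    # passive cascade
    if (nrow(cands) > 0 && config$max_final_products > 0) {
      casc <- apply_filter_cascade(
        tibble::tibble(smiles = cands$structure), rules, transform_db)
      if (any(casc$rescore & casc$keep)) {
        idx <- which(casc$rescore & casc$keep)
        cands$structure[idx] <- casc$smiles_out[idx]
        cands <- .score_candidates(
          cands[, c("reference", "structure", "route")], scs, config)
        casc <- apply_filter_cascade(
          tibble::tibble(smiles = cands$structure), rules, transform_db)
      }
      note(rn, "after_reactive", sum(casc$stage != "reactive"))
      note(rn, "after_exclusion", sum(!casc$stage %in% c("reactive", "exclusion")))
      note(rn, "after_lipinski", sum(casc$keep))
      cands <- cands[casc$keep, ]
    } else {
      cands <- cands[0, ]
    }
    cands <- utils::head(
      cands[order(-cands$total, cands$structure), ], config$max_final_products)
    note(rn, "emitted", nrow(cands))
    all_candidates[[length(all_candidates) + 1]] <- cands
  }

  candidates <- if (length(all_candidates)) dplyr::bind_rows(all_candidates)
                else tibble::tibble(reference = character(0),
                                    structure = character(0), route = list(),
                                    total = numeric(0))
  structure(list(candidates = candidates,
                 attrition = dplyr::bind_rows(attrition),
                 config = config),
            class = "rxn_design")
}

.attachment_filter <- function(bb, fs, db) {
  ids <- vapply(db$entries, `[[`, "", "id")
  lapply(seq_along(bb), function(j) {
    lbl <- paste0("f", j)
    st <- Filter(function(s) lbl %in% s$inputs, fs$steps)
    if (length(st) == 0) return(bb[[j]])
    rv <- db$entries[[match(st[[1]]$vector_id, ids)]]
    principal <- rv$template$src_comps$comp[!rv$template$src_comps$byprod]
    ok <- vapply(bb[[j]]$smiles, function(s) {
      m <- parse_mol(s)
      any(vapply(principal, function(cc)
        length(.embed_component(rv$template, cc, m)) > 0, logical(1)))
    }, logical(1))
    bb[[j]][ok, ]
  })
}

# forward replay with leaf fragments substituted by reagents; returns every
# distinct final product with its concrete route
.replay_with_reagents <- function(steps, reagents, db) {
  ids <- vapply(db$entries, `[[`, "", "id")
  chains <- list(list(outputs = character(length(steps)), steps = steps))
  for (k in seq_along(steps)) {
    nxt <- list()
    for (ch in chains) {
      st <- ch$steps[[k]]
      inputs <- vapply(st$inputs, function(lbl) {
        if (grepl("^@", lbl)) {
          ch$outputs[as.integer(sub("^@", "", lbl))]
        } else if (grepl("^f", lbl)) {
          reagents[as.integer(sub("^f", "", lbl))]
        } else lbl
      }, "")
      rv <- db$entries[[match(st$vector_id, ids)]]
      res <- tryCatch(apply_vector(rv, as.list(inputs)), error = function(e) NULL)
      if (is.null(res) || nrow(res) == 0) next
      for (p in unique(res$product)) {
        ch2 <- ch
        ch2$outputs[k] <- p
        ch2$steps[[k]]$inputs <- unname(inputs)
        ch2$steps[[k]]$product <- p
        nxt[[length(nxt) + 1]] <- ch2
      }
    }
    chains <- nxt
    if (length(chains) == 0) return(list())
  }
  lapply(chains, function(ch) list(product = ch$outputs[length(steps)],
                                   steps = ch$steps))
}

.score_candidates <- function(cands, scorers, config) {
  totals <- rep(0, nrow(cands))
  weights <- config$weights
  mat <- matrix(0, nrow(cands), length(scorers))
  for (j in seq_along(scorers)) {
    sc <- scorers[[j]]
    raw <- sc$score(cands$structure)
    cands[[paste0("score_", sc$name)]] <- raw
    v <- if (sc$direction == "minimize") -raw else raw
    rng <- range(v)
    mat[, j] <- if (diff(rng) == 0) rep(0.5, length(v)) else
      (v - rng[1]) / diff(rng)
  }
  w <- if (is.null(weights)) rep(1, length(scorers)) else {
    nm <- vapply(scorers, `[[`, "", "name")
    as.numeric(weights[nm])
  }
  w <- w / sum(w)
  if (isTRUE(config$pareto)) {
    cands$total <- -.pareto_rank(mat)
  } else {
    cands$total <- as.numeric(mat %*% w)
  }
  cands
}

.pareto_rank <- function(mat) {
  n <- nrow(mat)
  rank <- integer(n)
  remaining <- seq_len(n)
  level <- 0L
  while (length(remaining)) {
    level <- level + 1L
    dominated <- vapply(remaining, function(i) {
      any(vapply(remaining, function(j) {
        i != j && all(mat[j, ] >= mat[i, ]) && any(mat[j, ] > mat[i, ])
      }, logical(1)))
    }, logical(1))
    front <- remaining[!dominated]
    rank[front] <- level
    remaining <- remaining[dominated]
  }
  rank
}

#' Export candidate synthetic routes
#'
#' Writes a human-readable route report (and a JSON sidecar when `path` ends
#' in `.json`): per candidate, the ordered forward-synthesis steps with their
#' reagents and source-reaction provenance.
#'
#' @param design A `rxn_design` from [run_design()], or its candidate tibble.
#' @param path Optional output file (`.txt` report or `.json`).
#' @param db Optional `rxn_vector_db` used to attach source-reaction
#'   provenance to each step.
#' @return Tibble with one row per route step: `structure`, `step`,
#'   `vector_id`, `inputs`, `product`, `provenance`.
#' @export
export_routes <- function(design, path = NULL, db = NULL) {
  cands <- if (inherits(design, "rxn_design")) design$candidates else design
  prov <- function(vid) {
    if (is.null(db)) return(NA_character_)
    ids <- vapply(db$entries, `[[`, "", "id")
    hit <- match(vid, ids)
    if (is.na(hit)) NA_character_ else db$entries[[hit]]$provenance
  }
  rows <- list()
  for (i in seq_len(nrow(cands))) {
    steps <- cands$route[[i]]
    for (k in seq_along(steps)) {
      st <- steps[[k]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        structure = cands$structure[i], step = k, vector_id = st$vector_id,
        inputs = paste(st$inputs, collapse = " + "),
        product = st$product, provenance = prov(st$vector_id))
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(structure = character(0), step = integer(0),
                   vector_id = character(0), inputs = character(0),
                   product = character(0), provenance = character(0))
  if (!is.null(path)) {
    if (grepl("\\.json$", path)) {
      jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    } else {
      lines <- character(0)
      for (s in unique(out$structure)) {
        lines <- c(lines, paste0("candidate: ", s))
        sub <- out[out$structure == s, ]
        for (k in seq_len(nrow(sub))) {
          lines <- c(lines, sprintf("  step %d [%s]: %s -> %s", sub$step[k],
                                    sub$vector_id[k], sub$inputs[k],
                                    sub$product[k]))
        }
      }
      writeLines(lines, path)
    }
  }
  out
}

# ---- broom-style methods and plotting ---------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a design result
#'
#' @param x A `rxn_design`.
#' @param ... Unused.
#' @return The candidate tibble (one row per emitted candidate).
#' @method tidy rxn_design
#' @export
tidy.rxn_design <- function(x, ...) {
  x$candidates
}

#' One-row summary of a design run
#'
#' @param x A `rxn_design`.
#' @param ... Unused.
#' @return Tibble with reference count, candidate count and mean scores.
#' @method glance rxn_design
#' @export
glance.rxn_design <- function(x, ...) {
  score_cols <- grep("^score_", names(x$candidates), value = TRUE)
  out <- tibble::tibble(
    n_references = length(unique(x$candidates$reference)),
    n_candidates = nrow(x$candidates))
  for (sc in score_cols) out[[paste0("mean_", sub("^score_", "", sc))]] <-
    mean(x$candidates[[sc]])
  out
}

#' @export
print.rxn_design <- function(x, ...) {
  cat("<rxn_design> ", nrow(x$candidates), " candidates from ",
      length(unique(x$candidates$reference)), " reference(s)\n", sep = "")
  print(x$attrition, n = Inf)
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot candidate score distributions
#'
#' One panel per objective, scores per reference.
#'
#' @param object A `rxn_design`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rxn_design
#' @export
autoplot.rxn_design <- function(object, ...) {
  cands <- object$candidates
  score_cols <- grep("^score_", names(cands), value = TRUE)
  long <- tidyr::pivot_longer(cands[, c("reference", score_cols)],
                              dplyr::all_of(score_cols),
                              names_to = "objective", values_to = "score")
  long$objective <- sub("^score_", "", long$objective)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$reference, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~objective, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "score",
                  title = "Design candidate objective scores") +
    ggplot2::theme_minimal()
}
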