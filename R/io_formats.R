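# Readers and writers: reaction SMILES, reagent libraries (SMI/CSV/SDF),
# and the JSON-lines reaction-vector database.

RXNVEC_DB_SCHEMA_VERSION <- 1L

#' Parse a reaction SMILES string
#'
#' Splits a daylight reaction SMILES (`reactants>>products` or
#' `reactants>agents>products`) into components on `.`, parses and sanitises
#' every component, and preserves atom maps. Agents (the middle field) take no
#' part in vector derivation and are retained as provenance only.
#'
#' @param text Reaction SMILES string.
#' @param id Optional identifier; defaults to the text itself.
#' @param source Free-text provenance.
#' @return A `rxn_reaction`: lists of reactant and product `rxn_mol` graphs
#'   plus agent SMILES and provenance.
#' @examples
#' \dontrun{
#' parse_reaction("CC(=O)O.OC>>CC(=O)OC.O")
#' }
#' @export
parse_reaction <- function(text, id = NULL, source = "") {
  stopifnot(is.character(text), length(text) == 1)
  if (!grepl(">", text, fixed = TRUE)) {
    stop("not a reaction SMILES (no '>' delimiter): ", text, call. = FALSE)
  }
  parts <- strsplit(text, ">", fixed = TRUE)[[1]]
  if (length(parts) == 2) {
    parts <- c(parts[1], "", parts[2])
  }
  if (length(parts) != 3) {
    stop("malformed reaction SMILES (expected 'reactants>>products'): ",
         text, call. = FALSE)
  }
  split_side <- function(s) {
    if (!nzchar(s)) character(0) else strsplit(s, ".", fixed = TRUE)[[1]]
  }
  r_smi <- split_side(parts[1])
  a_smi <- split_side(parts[2])
  p_smi <- split_side(parts[3])
  if (length(r_smi) == 0 || length(p_smi) == 0) {
    stop("reaction must have at least one reactant and one product: ",
         text, call. = FALSE)
  }
  reactants <- tryCatch(parse_mols(r_smi), error = function(e) {
    stop("bad reactant in '", text, "': ", conditionMessage(e), call. = FALSE)
  })
  products <- tryCatch(parse_mols(p_smi), error = function(e) {
    stop("bad product in '", text, "': ", conditionMessage(e), call. = FALSE)
  })
  maps <- unlist(lapply(c(reactants, products), function(m) {
    m$atoms$map[m$atoms$map > 0]
  }))
  for (side in list(reactants, products)) {
    side_maps <- unlist(lapply(side, function(m) m$atoms$map[m$atoms$map > 0]))
    if (anyDuplicated(side_maps)) {
      stop("atom map numbers are not injective within one side of: ",
           text, call. = FALSE)
    }
  }
  structure(
    list(
      id = id %||% text,
      text = text,
      reactants = reactants,
      products = products,
      agents = a_smi,
      source = source
    ),
    class = "rxn_reaction"
  )
}

#' @export
print.rxn_reaction <- function(x, ...) {
  cat("<rxn_reaction> ", x$id, "\n", sep = "")
  cat("  reactants: ", paste(vapply(x$reactants, `[[`, "", "smiles"),
                             collapse = " . "), "\n", sep = "")
  cat("  products:  ", paste(vapply(x$products, `[[`, "", "smiles"),
                             collapse = " . "), "\n", sep = "")
  invisible(x)
}

#' Reaction SMILES text for a reaction record
#' @param rec A `rxn_reaction`.
#' @return Single reaction SMILES string (input form, maps preserved).
#' @export
reaction_smiles <- function(rec) {
  stopifnot(inherits(rec, "rxn_reaction"))
  rec$text
}

# ---- reagent libraries ------------------------------------------------------

#' Load a reagent (building-block) library
#'
#' Reads building blocks from a `.smi` file (one SMILES per line, optional
#' whitespace-separated id), a CSV with configurable columns, or an SDF.
#' Unparseable rows are skipped with a warning carrying the count; salt/ion
#' components are stripped by keeping the largest covalent component;
#' duplicates (by canonical SMILES) are collapsed. Count FeatMorgan
#' fingerprints (radius 2, 1024 counts) are precomputed for building-block
#' scoring.
#'
#' @param path File path.
#' @param format One of `"smi"`, `"csv"`, `"sdf"`; default guessed from the
#'   file extension.
#' @param smiles_col,id_col Column names for `format = "csv"`.
#' @return A `reagent_library`: a tibble with columns `id`, `smiles`
#'   (canonical) and a fingerprint matrix attribute.
#' @export
load_reagent_library <- function(path, format = c("auto", "smi", "csv", "sdf"),
                                 smiles_col = "smiles", id_col = "id") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = "smi", csv = "csv", sdf = "sdf",
                     stop("cannot guess reagent library format from '.", ext,
                          "'; pass format=", call. = FALSE))
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- switch(format,
    smi = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      fields <- strsplit(trimws(lines), "[ \t]+")
      tibble::tibble(
        smiles = vapply(fields, `[[`, "", 1),
        id = vapply(fields, function(f) if (length(f) > 1) f[2] else NA_character_,
                    character(1))
      )
    },
    csv = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      if (!smiles_col %in% names(df)) {
        stop("CSV has no '", smiles_col, "' column", call. = FALSE)
      }
      tibble::tibble(
        smiles = as.character(df[[smiles_col]]),
        id = if (id_col %in% names(df)) as.character(df[[id_col]]) else NA_character_
      )
    },
    sdf = {
      recs <- .rx_call("read_sdf", list(path = path))
      tibble::tibble(
        smiles = vapply(recs, function(r) if (is.null(r)) NA_character_ else r$smiles,
                        character(1)),
        id = vapply(recs, function(r) if (is.null(r)) NA_character_ else r$name,
                    character(1))
      )
    }
  )
  reagent_library(raw$smiles, ids = raw$id)
}

#' Build a reagent library from SMILES in memory
#'
#' @param smiles Character vector of building-block SMILES.
#' @param ids Optional identifiers (recycled with defaults where `NA`).
#' @return A `reagent_library` tibble; see [load_reagent_library()].
#' @export
reagent_library <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles))
  ids <- ids %||% rep(NA_character_, length(smiles))
  keep_largest <- function(s) {
    comps <- strsplit(s, ".", fixed = TRUE)[[1]]
    if (length(comps) == 1) return(s)
    comps[which.max(nchar(comps))]
  }
  stripped <- vapply(smiles, keep_largest, character(1), USE.NAMES = FALSE)
  canon <- rx_canonical_smiles(stripped)
  bad <- is.na(canon)
  if (any(bad)) {
    warning(sum(bad), " reagent row(s) failed to parse and were skipped",
            call. = FALSE)
  }
  canon <- canon[!bad]
  ids <- ids[!bad]
  if (length(canon) == 0) {
    stop("reagent library contains no valid molecules", call. = FALSE)
  }
  first <- !duplicated(canon)
  canon <- canon[first]
  ids <- ids[first]
  ids[is.na(ids) | !nzchar(ids)] <- sprintf("bb%04d", which(is.na(ids) | !nzchar(ids)))
  ord <- order(canon)
  lib <- tibble::tibble(id = ids[ord], smiles = canon[ord])
  attr(lib, "fingerprints") <- rx_morgan_count_vectors(lib$smiles, features = TRUE)
  class(lib) <- c("reagent_library", class(lib))
  lib
}

#' Write a reagent library to a .smi file
#' @param lib A `reagent_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_reagent_library <- function(lib, path) {
  writeLines(paste(lib$smiles, lib$id), path)
  invisible(path)
}

# ---- vector database --------------------------------------------------------

.ap_to_json <- function(v) {
  lapply(seq_along(v), function(i) list(pair = names(v)[i], count = as.integer(v[i])))
}

.ap_from_json <- function(x) {
  if (length(x) == 0) return(ap_vector())
  counts <- vapply(x, function(e) as.integer(e$count), integer(1))
  names(counts) <- vapply(x, function(e) e$pair, character(1))
  ap_vector(counts)
}

.template_to_json <- function(tpl) {
  list(
    atoms = lapply(seq_len(nrow(tpl$atoms)), function(i) as.list(tpl$atoms[i, ])),
    src_bonds = lapply(seq_len(nrow(tpl$src_bonds)), function(i) as.list(tpl$src_bonds[i, ])),
    tgt_bonds = lapply(seq_len(nrow(tpl$tgt_bonds)), function(i) as.list(tpl$tgt_bonds[i, ])),
    src_comps = lapply(seq_len(nrow(tpl$src_comps)), function(i) as.list(tpl$src_comps[i, ])),
    tgt_comps = lapply(seq_len(nrow(tpl$tgt_comps)), function(i) as.list(tpl$tgt_comps[i, ]))
  )
}

.rows_to_tibble <- function(rows, proto) {
  if (length(rows) == 0) return(proto)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::as_tibble(lapply(r, function(x) if (is.null(x)) NA else x))
  }))
}

.template_from_json <- function(x) {
  list(
    atoms = .rows_to_tibble(x$atoms, .template_atoms_proto()),
    src_bonds = .rows_to_tibble(x$src_bonds, .template_bonds_proto()),
    tgt_bonds = .rows_to_tibble(x$tgt_bonds, .template_bonds_proto()),
    src_comps = .rows_to_tibble(x$src_comps, .template_comps_proto()),
    tgt_comps = .rows_to_tibble(x$tgt_comps, .template_comps_proto())
  )
}

#' Save / load a reaction-vector database
#'
#' The database is serialized as JSON-lines: a header line carrying the schema
#' version followed by one entry per line (id, signed pair parts, the mapped
#' transformation template and provenance). The format is streamable and
#' diff-able. Loading verifies the schema version and fails closed on
#' truncated or corrupt files.
#'
#' @param db A `rxn_vector_db` (see [build_vector_db()]).
#' @param path File path.
#' @return `save_vector_db()` returns `path` invisibly; `load_vector_db()`
#'   returns the database.
#' @export
save_vector_db <- function(db, path) {
  stopifnot(inherits(db, "rxn_vector_db"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- list(schema_version = RXNVEC_DB_SCHEMA_VERSION,
                 n_entries = length(db$entries))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE), con)
  for (rv in db$entries) {
    rec <- list(
      id = rv$id,
      negative = .ap_to_json(rv$negative),
      positive = .ap_to_json(rv$positive),
      template = .template_to_json(rv$template),
      n_reactant_components = rv$n_reactant_components,
      provenance = rv$provenance
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname save_vector_db
#' @export
load_vector_db <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty vector database file: ", path, call. = FALSE)
  header <- tryCatch(jsonlite::fromJSON(lines[1], simplifyVector = FALSE),
                     error = function(e) stop("corrupt vector database header",
                                              call. = FALSE))
  if (is.null(header$schema_version) ||
      header$schema_version != RXNVEC_DB_SCHEMA_VERSION) {
    stop("vector database schema version mismatch: file has '",
         header$schema_version %||% "none", "', package expects ",
         RXNVEC_DB_SCHEMA_VERSION, call. = FALSE)
  }
  body <- lines[-1]
  if (length(body) != header$n_entries) {
    stop("vector database truncated: header promises ", header$n_entries,
         " entries, file has ", length(body), call. = FALSE)
  }
  entries <- lapply(body, function(line) {
    rec <- tryCatch(jsonlite::fromJSON(line, simplifyVector = FALSE),
                    error = function(e) stop("corrupt vector database entry",
                                             call. = FALSE))
    new_rxn_vector(
      id = rec$id,
      negative = .ap_from_json(rec$negative),
      positive = .ap_from_json(rec$positive),
      template = .template_from_json(rec$template),
      n_reactant_components = as.integer(rec$n_reactant_components),
      provenance = rec$provenance
    )
  })
  new_vector_db(entries)
}

new_vector_db <- function(entries) {
  ids <- vapply(entries, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate reaction vector ids", call. = FALSE)
  index <- new.env(parent = emptyenv())
  for (rv in entries) {
    for (pair in names(rv$negative)) {
      index[[pair]] <- c(index[[pair]], rv$id)
    }
  }
  structure(list(entries = entries, index = index), class = "rxn_vector_db")
}

#' @export
print.rxn_vector_db <- function(x, ...) {
  cat("<rxn_vector_db> ", length(x$entries), " reaction vectors, ",
      length(ls(x$index)), " indexed negative pairs\n", sep = "")
  invisible(x)
}

#' Look up vector ids whose negative part contains a pair
#' @param db A `rxn_vector_db`.
#' @param pair Pair string, e.g. `"C300-11-O103"`.
#' @return Character vector of entry ids (possibly empty).
#' @export
db_lookup_pair <- function(db, pair) {
  db$index[[pair]] %||% character(0)
}
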