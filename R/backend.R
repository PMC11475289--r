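# Bridge to the bundled RDKit worker (inst/python/chem_backend.py).
#
# One worker process per R session, spoken to over a localhost socket with
# line-delimited JSON. All wrappers are batched: a call with n molecules costs
# one round trip. The worker watches the parent pid and exits with the session.

.rx_state <- new.env(parent = emptyenv())

rx_python <- function() {
  getOption("rxnvec.python", Sys.getenv("RXNVEC_PYTHON", "python"))
}

.rx_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "rxnvec")
  if (!nzchar(path)) {
    # during development (pkgload) system.file resolves inside the source tree
    path <- file.path("inst", "python", "chem_backend.py")
  }
  normalizePath(path, mustWork = TRUE)
}

.rx_start_worker <- function() {
  portfile <- tempfile("rxnvec-port-")
  system2(rx_python(), c(.rx_script(), "--portfile", portfile),
          wait = FALSE, stdout = FALSE, stderr = FALSE)
  deadline <- Sys.time() + 120
  while (!file.exists(portfile)) {
    if (Sys.time() > deadline) {
      stop("rxnvec backend failed to start: is RDKit importable from '",
           rx_python(), "'?", call. = FALSE)
    }
    Sys.sleep(0.05)
  }
  port <- as.integer(readLines(portfile, warn = FALSE)[1])
  con <- socketConnection("127.0.0.1", port = port, blocking = TRUE,
                          open = "r+", timeout = 600)
  .rx_state$con <- con
  .rx_state$counter <- 0L
  invisible(con)
}

.rx_connection <- function() {
  con <- .rx_state$con
  if (!is.null(con) && isOpen(con)) return(con)
  .rx_start_worker()
}

.rx_call_once <- function(op, args) {
  con <- .rx_connection()
  .rx_state$counter <- .rx_state$counter + 1L
  req <- jsonlite::toJSON(
    list(id = .rx_state$counter, op = op, args = args),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  writeLines(req, con)
  line <- readLines(con, n = 1L, warn = FALSE)
  if (length(line) == 0L || !nzchar(line)) stop("backend connection lost")
  resp <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  if (!isTRUE(resp$ok)) stop("backend error in '", op, "': ", resp$error, call. = FALSE)
  resp$result
}

.rx_call <- function(op, args = list()) {
  tryCatch(
    .rx_call_once(op, args),
    error = function(e) {
      if (grepl("backend error", conditionMessage(e))) stop(e)
      # connection-level failure: restart the worker once and retry
      try(close(.rx_state$con), silent = TRUE)
      .rx_state$con <- NULL
      .rx_call_once(op, args)
    }
  )
}

#' Shut down the background chemistry worker
#'
#' Normally unnecessary: the worker exits with the R session. Provided for
#' scripts that want to release the process eagerly.
#' @return Invisibly `TRUE`.
#' @export
rx_shutdown_backend <- function() {
  con <- .rx_state$con
  if (!is.null(con) && isOpen(con)) {
    try(writeLines('{"op":"shutdown"}', con), silent = TRUE)
    try(close(con), silent = TRUE)
  }
  .rx_state$con <- NULL
  invisible(TRUE)
}

# ---- cached, vectorised wrappers --------------------------------------------

.rx_cache <- function(name) {
  if (is.null(.rx_state[[name]])) .rx_state[[name]] <- new.env(parent = emptyenv())
  .rx_state[[name]]
}

.rx_cached_batch <- function(cache_name, keys, op, build_args, extract = identity) {
  cache <- .rx_cache(cache_name)
  missing <- unique(keys[!vapply(keys, function(k) !is.null(cache[[k]]), logical(1))])
  if (length(missing) > 0) {
    res <- .rx_call(op, build_args(missing))
    for (i in seq_along(missing)) cache[[missing[i]]] <- list(value = extract(res[[i]]))
  }
  lapply(keys, function(k) cache[[k]]$value)
}

rx_canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  out <- .rx_cached_batch("canon", smiles, "canonical",
                          function(m) list(smiles = as.list(m)))
  vapply(out, function(x) if (is.null(x)) NA_character_ else x, character(1))
}

rx_morgan_bits <- function(smiles, radius = 2L, nbits = 1024L, features = FALSE) {
  if (length(smiles) == 0) return(list())
  key <- paste0(radius, ":", nbits, ":", features, ":", smiles)
  cache <- .rx_cache("morgan")
  need <- !vapply(key, function(k) !is.null(cache[[k]]), logical(1))
  if (any(need)) {
    uniq <- unique(smiles[need])
    res <- .rx_call("morgan", list(smiles = as.list(uniq), radius = radius,
                                   nbits = nbits, features = features))
    for (i in seq_along(uniq)) {
      k <- paste0(radius, ":", nbits, ":", features, ":", uniq[i])
      cache[[k]] <- list(value = if (is.null(res[[i]])) NULL else unlist(res[[i]]))
    }
  }
  lapply(key, function(k) cache[[k]]$value)
}

rx_morgan_count_vectors <- function(smiles, radius = 2L, nbits = 1024L, features = TRUE) {
  if (length(smiles) == 0) return(matrix(0, 0, nbits))
  key <- paste0("cnt:", radius, ":", nbits, ":", features, ":", smiles)
  cache <- .rx_cache("morgancnt")
  need <- !vapply(key, function(k) !is.null(cache[[k]]), logical(1))
  if (any(need)) {
    uniq <- unique(smiles[need])
    res <- .rx_call("morgan_counts", list(smiles = as.list(uniq), radius = radius,
                                          nbits = nbits, features = features))
    for (i in seq_along(uniq)) {
      k <- paste0("cnt:", radius, ":", nbits, ":", features, ":", uniq[i])
      v <- rep(0L, nbits)
      if (!is.null(res[[i]])) {
        v[unlist(res[[i]]$idx) + 1L] <- unlist(res[[i]]$cnt)
      } else {
        v <- NULL
      }
      cache[[k]] <- list(value = v)
    }
  }
  mat <- t(vapply(key, function(k) cache[[k]]$value, numeric(nbits)))
  rownames(mat) <- NULL
  mat
}

rx_smarts_counts <- function(smiles, patterns) {
  if (length(smiles) == 0) {
    return(matrix(0L, 0, length(patterns), dimnames = list(NULL, names(patterns))))
  }
  res <- .rx_call("smarts", list(smiles = as.list(smiles), patterns = as.list(unname(patterns))))
  rows <- lapply(res, function(r) {
    if (is.null(r)) rep(NA_integer_, length(patterns)) else as.integer(unlist(r))
  })
  mat <- matrix(unlist(rows), nrow = length(smiles), ncol = length(patterns),
                byrow = TRUE, dimnames = list(NULL, names(patterns)))
  mat
}

rx_descriptors <- function(smiles) {
  if (length(smiles) == 0) {
    return(tibble::tibble(smiles = character(0), mw = numeric(0), logp = numeric(0),
                          hbd = integer(0), hba = integer(0)))
  }
  out <- .rx_cached_batch("desc", smiles, "descriptors",
                          function(m) list(smiles = as.list(m)))
  tibble::tibble(
    smiles = smiles,
    mw   = vapply(out, function(x) if (is.null(x)) NA_real_ else x$mw, numeric(1)),
    logp = vapply(out, function(x) if (is.null(x)) NA_real_ else x$logp, numeric(1)),
    hbd  = vapply(out, function(x) if (is.null(x)) NA_integer_ else as.integer(x$hbd), integer(1)),
    hba  = vapply(out, function(x) if (is.null(x)) NA_integer_ else as.integer(x$hba), integer(1))
  )
}

rx_build_mols <- function(mol_specs) {
  if (length(mol_specs) == 0) return(list())
  .rx_call("build", list(mols = mol_specs))
}

rx_random_smiles <- function(smiles, n = 1L, seed = 42L) {
  res <- .rx_call("random_smiles", list(smiles = as.list(smiles), n = n, seed = seed))
  lapply(res, function(x) if (is.null(x)) NULL else unlist(x))
}
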