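# Shared fixture objects, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fx_reactions <- function() {
  if (is.null(.fixture_env$rxns)) .fixture_env$rxns <- make_toy_reactions()
  .fixture_env$rxns
}

fx_db <- function() {
  if (is.null(.fixture_env$db)) {
    rxns <- fx_reactions()
    .fixture_env$db <- build_vector_db(stats::setNames(rxns$reaction, rxns$id))
  }
  .fixture_env$db
}

fx_lib <- function() {
  if (is.null(.fixture_env$lib)) .fixture_env$lib <- make_toy_reagents()
  .fixture_env$lib
}

fx_transform_db <- function() {
  if (is.null(.fixture_env$tdb)) {
    tf <- make_transform_reactions()
    .fixture_env$tdb <- build_vector_db(stats::setNames(tf$reaction, tf$id))
  }
  .fixture_env$tdb
}

fx_vector <- function(id) {
  db <- fx_db()
  ids <- vapply(db$entries, `[[`, "", "id")
  db$entries[[match(id, ids)]]
}

# a specific esterification vector derived on demand (acetic acid + methanol)
fx_esterification <- function() {
  if (is.null(.fixture_env$est)) {
    rxn <- paste0("[CH3:6][C:1](=[O:2])[OH:3].[OH:4][CH3:5]>>",
                  "[CH3:6][C:1](=[O:2])[O:4][CH3:5].[OH2:3]")
    .fixture_env$est <- derive_vector(parse_reaction(rxn, id = "est_methyl"))
  }
  .fixture_env$est
}

# independent AP3 oracle: BFS all-pairs shortest paths, keep distance-2 pairs
oracle_ap3 <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- lapply(seq_len(n), function(i) {
    c(mol$bonds$b[mol$bonds$a == i], mol$bonds$a[mol$bonds$b == i])
  })
  dist2_pairs <- character(0)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    for (t in which(dist == 2L)) {
      if (t > s) {
        d1 <- describe_atom(mol, s)$string
        d2 <- describe_atom(mol, t)$string
        lo <- min(d1, d2); hi <- max(d1, d2)
        dist2_pairs <- c(dist2_pairs, sprintf("%s-2-%s", lo, hi))
      }
    }
  }
  if (length(dist2_pairs) == 0) return(ap_vector())
  tab <- table(dist2_pairs)
  ap_vector(stats::setNames(as.integer(tab), names(tab)))
}

ap_identical <- function(x, y) {
  isTRUE(length(x) == length(y) && all(names(x) == names(y)) &&
           all(as.integer(x) == as.integer(y)))
}

# substitute leaf labels in a route by concrete fragment SMILES
.subst_leaves <- function(steps, fragments) {
  lapply(steps, function(st) {
    st$inputs <- vapply(st$inputs, function(lbl) {
      if (grepl("^f", lbl)) fragments[as.integer(sub("^f", "", lbl))] else lbl
    }, "")
    st
  })
}
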