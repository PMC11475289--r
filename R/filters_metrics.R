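# Passive filter cascade, fingerprint similarity, stereo enumeration and the
# PAMPA permeability calculators.

#' Filter rule sets
#'
#' A rule set holds named reactive-group SMARTS (compounds matching any are
#' sent to the functional-transformation conversion step), named exclusion
#' SMARTS (matching compounds are removed outright) and the maximum number of
#' Lipinski violations tolerated (default 1: compounds violating more than one
#' rule are removed).
#'
#' @param reactive,exclusions Named character vectors of SMARTS.
#' @param lipinski_max_violations Integer.
#' @return A `filter_rules` object.
#' @export
filter_rules <- function(reactive = character(0), exclusions = character(0),
                         lipinski_max_violations = 1L) {
  stopifnot(is.character(reactive), is.character(exclusions))
  if ((length(reactive) && is.null(names(reactive))) ||
      (length(exclusions) && is.null(names(exclusions)))) {
    stop("filter SMARTS must be named", call. = FALSE)
  }
  nm <- c(names(reactive), names(exclusions))
  if (anyDuplicated(nm)) stop("filter rule names must be unique", call. = FALSE)
  # compile check: invalid SMARTS fail loudly at construction
  if (length(c(reactive, exclusions))) {
    rx_smarts_counts("C", c(reactive, exclusions))
  }
  structure(list(reactive = reactive, exclusions = exclusions,
                 lipinski_max_violations = as.integer(lipinski_max_violations)),
            class = "filter_rules")
}

#' Load filter rules from YAML
#'
#' Expected layout: `reactive:` and `exclusions:` lists of `{name, smarts}`
#' entries plus an optional `lipinski_max_violations` scalar.
#'
#' @param path YAML file path.
#' @return A `filter_rules` object.
#' @export
load_filter_rules <- function(path) {
  y <- yaml::read_yaml(path)
  grab <- function(entries) {
    if (is.null(entries)) return(character(0))
    stats::setNames(vapply(entries, `[[`, "", "smarts"),
                    vapply(entries, `[[`, "", "name"))
  }
  filter_rules(reactive = grab(y$reactive), exclusions = grab(y$exclusions),
               lipinski_max_violations = y$lipinski_max_violations %||% 1L)
}

#' Default shipped filter rules
#'
#' A minimal curated set of reactive-group and undesirable-substructure
#' patterns (acyl/sulfonyl halides, aldehydes, Michael acceptors, benzylic and
#' alkyl halides, epoxides/aziridines, anhydrides, isocyanates; nitro,
#' N-nitroso and azo exclusions). Users with curated corporate lists should
#' load them with [load_filter_rules()].
#'
#' @return A `filter_rules` object.
#' @export
default_filter_rules <- function() {
  load_filter_rules(system.file("extdata", "filter_rules.yaml",
                                package = "rxnvec", mustWork = TRUE))
}

#' Count Lipinski rule-of-five violations
#'
#' Violations counted: molecular weight > 500, computed logP > 5, hydrogen
#' bond donors > 5, hydrogen bond acceptors > 10.
#'
#' @param mol SMILES string(s).
#' @return Integer vector in `[0, 4]`.
#' @export
lipinski_violations <- function(mol) {
  smiles <- if (inherits(mol, "rxn_mol")) mol$smiles else as.character(mol)
  d <- rx_descriptors(smiles)
  as.integer((d$mw > 500) + (d$logp > 5) + (d$hbd > 5) + (d$hba > 10))
}

#' Detect reactive groups
#'
#' @param mol SMILES or `rxn_mol`.
#' @param rules A `filter_rules` object.
#' @return Character vector of matched reactive rule names (deterministic
#'   rule-definition order).
#' @export
detect_reactive <- function(mol, rules = default_filter_rules()) {
  smiles <- if (inherits(mol, "rxn_mol")) mol$smiles else as.character(mol)
  stopifnot(length(smiles) == 1)
  if (length(rules$reactive) == 0) return(character(0))
  counts <- rx_smarts_counts(smiles, rules$reactive)
  names(rules$reactive)[counts[1, ] > 0]
}

#' Convert reactive groups via functional transformations
#'
#' Applies single-reactant functional-transformation vectors to molecules
#' flagged by the reactive-group SMARTS until no transformation applies, then
#' re-checks: molecules still matching a reactive pattern are rejected;
#' converted molecules are flagged for re-scoring.
#'
#' @param mol SMILES or `rxn_mol`.
#' @param rules A `filter_rules` object.
#' @param transform_db A `rxn_vector_db` of single-reactant vectors.
#' @param max_rounds Safety bound on conversion rounds.
#' @return List: `status` (`"clean"`, `"converted"` or `"rejected"`),
#'   `smiles`, `rescore` flag, `matched` (reactive rule names on input).
#' @export
convert_reactive_groups <- function(mol, rules = default_filter_rules(),
                                    transform_db = NULL, max_rounds = 4L) {
  smiles <- if (inherits(mol, "rxn_mol")) mol$smiles else rx_canonical_smiles(mol)
  matched <- detect_reactive(smiles, rules)
  if (length(matched) == 0) {
    return(list(status = "clean", smiles = smiles, rescore = FALSE,
                matched = character(0)))
  }
  if (!is.null(transform_db)) {
    cur <- smiles
    for (round in seq_len(max_rounds)) {
      if (length(detect_reactive(cur, rules)) == 0) break
      progressed <- FALSE
      for (rv in transform_db$entries) {
        if (sum(!rv$template$src_comps$byprod) != 1) {
          stop("transform database must contain single-reactant vectors only",
               call. = FALSE)
        }
        res <- apply_vector(rv, list(cur))
        if (nrow(res) > 0) {
          cur <- res$product[1]
          progressed <- TRUE
          break
        }
      }
      if (!progressed) break
    }
    if (length(detect_reactive(cur, rules)) == 0) {
      return(list(status = "converted", smiles = cur, rescore = TRUE,
                  matched = matched))
    }
  }
  list(status = "rejected", smiles = smiles, rescore = FALSE, matched = matched)
}

#' Passive filter cascade
#'
#' Applies, in order: reactive-group conversion (with re-detection),
#' exclusion-substructure filtering, and the Lipinski filter. The survivor set
#' is independent of the input ordering.
#'
#' @param data Data frame with a `smiles` column (or character vector).
#' @param rules A `filter_rules` object.
#' @param transform_db Optional transformation database for the conversion
#'   stage.
#' @return Tibble: input columns plus `smiles_out`, `keep`, `stage`
#'   (`"pass"` or the stage that removed the compound) and `rescore`.
#' @export
apply_filter_cascade <- function(data, rules = default_filter_rules(),
                                 transform_db = NULL) {
  if (is.character(data)) data <- tibble::tibble(smiles = data)
  stopifnot("smiles" %in% names(data))
  out <- tibble::as_tibble(data)
  n <- nrow(out)
  smiles_out <- out$smiles
  stage <- rep("pass", n)
  rescore <- logical(n)
  for (i in seq_len(n)) {
    conv <- convert_reactive_groups(out$smiles[i], rules, transform_db)
    if (conv$status == "rejected") {
      stage[i] <- "reactive"
    } else {
      smiles_out[i] <- conv$smiles
      rescore[i] <- conv$rescore
    }
  }
  alive <- stage == "pass"
  if (length(rules$exclusions) && any(alive)) {
    counts <- rx_smarts_counts(smiles_out[alive], rules$exclusions)
    hit <- rowSums(counts > 0) > 0
    stage[alive][hit] <- "exclusion"
  }
  alive <- stage == "pass"
  if (any(alive)) {
    viol <- lipinski_violations(smiles_out[alive])
    stage[alive][viol > rules$lipinski_max_violations] <- "lipinski"
  }
  out$smiles_out <- smiles_out
  out$keep <- stage == "pass"
  out$stage <- stage
  out$rescore <- rescore
  out
}

#' Enumerate stereoisomers of a flat structure
#'
#' Structure generation works at the constitution level; this enumerates all
#' assignments of unspecified stereocentres and double-bond geometries
#' (already-assigned centres are untouched), capped.
#'
#' @param mol SMILES or `rxn_mol`.
#' @param cap Maximum number of isomers returned.
#' @return Character vector of isomeric SMILES (sorted; the input itself when
#'   nothing is unassigned).
#' @export
enumerate_stereoisomers <- function(mol, cap = 32L) {
  smiles <- if (inherits(mol, "rxn_mol")) mol$smiles else as.character(mol)
  stopifnot(length(smiles) == 1)
  res <- .rx_call("stereo_enum", list(smiles = list(smiles), cap = cap))
  if (is.null(res[[1]])) stop("cannot parse molecule: ", smiles, call. = FALSE)
  unlist(res[[1]])
}

#' Tanimoto similarity on binary Morgan fingerprints
#'
#' Radius-2 circular fingerprints folded to 1024 bits, Tanimoto coefficient.
#' Two empty fingerprints compare as 1 for identical canonical structures and
#' 0 otherwise (documented convention; only sub-heavy-atom edge cases reach
#' it).
#'
#' @param a,b SMILES or `rxn_mol`.
#' @param fp Fingerprint name; `"morgan1024"` (binary Morgan, radius 2,
#'   1024 bits) is the only built-in.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto_similarity <- function(a, b, fp = "morgan1024") {
  fp <- match.arg(fp, "morgan1024")
  sa <- if (inherits(a, "rxn_mol")) a$smiles else as.character(a)
  sb <- if (inherits(b, "rxn_mol")) b$smiles else as.character(b)
  bits <- rx_morgan_bits(c(sa, sb), radius = 2L, nbits = 1024L)
  if (is.null(bits[[1]])) stop("cannot parse molecule: ", sa, call. = FALSE)
  if (is.null(bits[[2]])) stop("cannot parse molecule: ", sb, call. = FALSE)
  n1 <- length(bits[[1]]); n2 <- length(bits[[2]])
  if (n1 == 0 && n2 == 0) {
    return(as.numeric(identical(rx_canonical_smiles(sa), rx_canonical_smiles(sb))))
  }
  inter <- length(intersect(bits[[1]], bits[[2]]))
  inter / (n1 + n2 - inter)
}

# ---- PAMPA calculators ------------------------------------------------------

#' PAMPA apparent permeability
#'
#' \deqn{P_{app} = \frac{V_D V_A}{V_D + V_A} \cdot \frac{1}{A t} \cdot
#'   (-\ln(1 - r))}
#' with donor/acceptor volumes in cm^3, membrane area in cm^2, incubation time
#' in seconds and `r` the ratio of the acceptor concentration to the
#' equilibrium concentration in the total volume; the result is in cm/s.
#'
#' @param v_d,v_a Donor and acceptor volumes (cm^3), positive.
#' @param area Effective membrane area (cm^2), positive.
#' @param time Incubation time (s), positive.
#' @param r Concentration ratio, `0 <= r < 1`.
#' @return Apparent permeability in cm/s.
#' @export
papp <- function(v_d, v_a, area, time, r) {
  if (any(v_d <= 0) || any(v_a <= 0) || any(area <= 0) || any(time <= 0)) {
    stop("volumes, area and time must be positive", call. = FALSE)
  }
  if (any(r < 0) || any(r >= 1)) {
    stop("r must satisfy 0 <= r < 1", call. = FALSE)
  }
  (v_d * v_a / (v_d + v_a)) * (1 / (area * time)) * (-log(1 - r))
}

#' PAMPA membrane retention
#'
#' \deqn{\%MR = \frac{r - (D + A)}{Eq} \times 100} with `r` the
#' acceptor-to-equilibrium concentration ratio and `D`, `A`, `Eq` the donor,
#' acceptor and equilibrium concentrations (any common unit). The formula is
#' implemented exactly as conventionally printed; note that it mixes a
#' dimensionless ratio with concentration sums, so the caller is responsible
#' for supplying consistently scaled inputs.
#'
#' @param r Acceptor/equilibrium concentration ratio.
#' @param d,a,eq Donor, acceptor and equilibrium concentrations; `eq > 0`.
#' @return Membrane retention in percent.
#' @export
membrane_retention <- function(r, d, a, eq) {
  if (any(eq == 0)) stop("equilibrium concentration must be nonzero", call. = FALSE)
  (r - (d + a)) / eq * 100
}
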