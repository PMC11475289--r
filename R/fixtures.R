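# Deterministic toy fixtures: a mapped reaction corpus over four common
# medicinal-chemistry couplings (esterification, amide coupling, N-alkylation,
# biaryl Suzuki coupling) plus single-reactant functional transformations, a
# matching building-block library, and vendored reference/candidate
# structures.
#
# Fixture reactions are written fully balanced and atom-mapped over the
# reaction centre and one shell of context, with substituents drawn from a
# fixed alphabet so that the reagent library is closed over every fixture
# reactant.

.aryl_subs <- c("", "C", "CC", "CCC", "C(C)C", "OC", "OCC", "F", "C#N",
                "C(F)(F)F", "CO", "N(C)C", "OC(C)C", "CC#N")
.alkyl_subs <- c("", "C", "CC", "CCC", "C(C)C", "CCCC", "c1ccccc1", "COC",
                 "CCOC", "C1CC1")

#' Fixture generator settings
#'
#' @param seed Integer seed; the same seed yields byte-identical fixtures.
#' @param n_per_template Named integer vector: reactions instantiated per
#'   reaction template.
#' @param aryl_subs,alkyl_subs Substituent alphabets (SMILES branches) for
#'   aromatic para positions and alkyl chains.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 20240101L,
                         n_per_template = c(esterification = 12L,
                                            amide_coupling = 12L,
                                            n_alkylation = 10L,
                                            biaryl_coupling = 10L),
                         aryl_subs = .aryl_subs,
                         alkyl_subs = .alkyl_subs) {
  structure(list(seed = as.integer(seed), n_per_template = n_per_template,
                 aryl_subs = aryl_subs, alkyl_subs = alkyl_subs),
            class = "fixture_spec")
}

# mapped para-substituted phenyl, inline form starting at the ipso atom
.ar_inline <- function(R, m) {
  para <- if (R == "") sprintf("[cH:%d]", m + 3) else sprintf("[c:%d](%s)", m + 3, R)
  sprintf("[c:%d]1[cH:%d][cH:%d]%s[cH:%d][cH:%d]1", m, m + 1, m + 2, para,
          m + 4, m + 5)
}

# mapped methylene/methyl anchor, inline
.ch2_inline <- function(R, m) {
  if (R == "") sprintf("[CH3:%d]", m) else sprintf("[CH2:%d]%s", m, R)
}

.fixture_templates <- function() {
  list(
    esterification = function(acid_anchor, alcohol_anchor) {
      sprintf(
        "[C:1](=[O:2])([OH:3])%s.[OH:20]%s>>[C:1](=[O:2])([O:20]%s)%s.[OH2:3]",
        acid_anchor, alcohol_anchor, alcohol_anchor, acid_anchor)
    },
    amide_coupling = function(acid_anchor, amine_anchor) {
      sprintf(
        "[C:1](=[O:2])([OH:3])%s.[NH2:20]%s>>[C:1](=[O:2])([NH:20]%s)%s.[OH2:3]",
        acid_anchor, amine_anchor, amine_anchor, acid_anchor)
    },
    n_alkylation = function(halide_anchor, amine_anchor) {
      sprintf(
        "[Cl:2][CH2:1]%s.[NH2:20]%s>>[NH:20](%s)[CH2:1]%s.[ClH:2]",
        halide_anchor, amine_anchor, amine_anchor, halide_anchor)
    },
    biaryl_coupling = function(R1, R2) {
      para1 <- if (R1 == "") "[cH:6]" else sprintf("[c:6](%s)", R1)
      para2 <- if (R2 == "") "[cH:16]" else sprintf("[c:16](%s)", R2)
      sprintf(paste0(
        "[Br:2][c:1]1[cH:4][cH:5]%s[cH:7][cH:8]1.",
        "[OH:11][B:10]([OH:12])[c:13]1[cH:14][cH:15]%s[cH:17][cH:18]1",
        ">>",
        "[c:1]1([c:13]2[cH:14][cH:15]%s[cH:17][cH:18]2)[cH:4][cH:5]%s[cH:7][cH:8]1",
        ".[BrH:2].[OH:11][BH:10][OH:12]"),
        para1, para2, para2, para1)
    }
  )
}

#' Toy reaction corpus
#'
#' Instantiates the four coupling templates over seeded substituent choices.
#' Every record is balanced, atom-mapped over the reaction centre plus one
#' shell, and carries its recorded product for round-trip tests.
#'
#' @param spec A [fixture_spec()].
#' @return Tibble: `id`, `template`, `reaction` (mapped reaction SMILES),
#'   `reactants` (list of canonical SMILES), `product` (canonical SMILES),
#'   `byproducts` (list).
#' @export
make_toy_reactions <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  tmpl <- .fixture_templates()
  # anchors per role; acids/alcohols/amines come in aryl and alkyl flavours
  acid_anchors <- c(
    vapply(spec$aryl_subs, .ar_inline, "", m = 10L),
    vapply(spec$alkyl_subs, .ch2_inline, "", m = 10L))
  alcohol_anchors <- c(
    vapply(spec$alkyl_subs, .ch2_inline, "", m = 21L),
    vapply(spec$aryl_subs, function(R) {
      sprintf("[CH2:21]%s", .ar_inline(R, 22L))
    }, ""))
  amine_anchors <- alcohol_anchors
  halide_anchors <- vapply(spec$aryl_subs, .ar_inline, "", m = 10L)

  draw_pairs <- function(n, a, b, salt) {
    grid <- expand.grid(i = seq_along(a), j = seq_along(b))
    pick <- sample.int(nrow(grid), min(n, nrow(grid)))
    list(a = a[grid$i[pick]], b = b[grid$j[pick]])
  }
  set.seed(spec$seed)
  rows <- list()
  for (tname in names(spec$n_per_template)) {
    n <- spec$n_per_template[[tname]]
    pairs <- switch(tname,
      esterification = draw_pairs(n, acid_anchors, alcohol_anchors),
      amide_coupling = draw_pairs(n, acid_anchors, amine_anchors),
      n_alkylation = draw_pairs(n, halide_anchors, amine_anchors),
      biaryl_coupling = draw_pairs(n, spec$aryl_subs, spec$aryl_subs))
    for (k in seq_along(pairs$a)) {
      rxn <- tmpl[[tname]](pairs$a[k], pairs$b[k])
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = sprintf("%s_%03d", tname, k), template = tname, reaction = rxn)
    }
  }
  out <- dplyr::bind_rows(rows)
  parsed <- lapply(out$reaction, parse_reaction)
  out$reactants <- lapply(parsed, function(rec)
    vapply(rec$reactants, `[[`, "", "smiles"))
  bp <- rx_canonical_smiles(rx_default_byproducts("leaving"))
  prods <- lapply(parsed, function(rec)
    vapply(rec$products, `[[`, "", "smiles"))
  out$product <- vapply(prods, function(p) {
    main <- setdiff(p, bp)
    if (length(main) != 1) stop("fixture reaction without unique main product")
    main
  }, "")
  out$byproducts <- lapply(prods, function(p) p[p %in% bp])
  out
}

#' Toy building-block library
#'
#' Enumerates acids, alcohols, amines, boronic acids, benzylic chlorides and
#' aryl bromides over the substituent alphabet (plus aldehyde, ketone and
#' aniline decoys that match no coupling template), so that every reactant of
#' [make_toy_reactions()] is present. Deduplicated by canonical SMILES.
#'
#' @param spec A [fixture_spec()].
#' @return A `reagent_library` with a `class` column.
#' @export
make_toy_reagents <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  ar <- function(R) if (R == "") "c1ccccc1" else sprintf("c1ccc(%s)cc1", R)
  ch2 <- function(R) if (R == "") "C" else sprintf("C%s", R)
  classes <- list(
    acid = c(sprintf("OC(=O)%s", vapply(spec$aryl_subs, ar, "")),
             sprintf("OC(=O)%s", vapply(spec$alkyl_subs, ch2, ""))),
    alcohol = c(sprintf("O%s", vapply(spec$alkyl_subs, ch2, "")),
                sprintf("OC%s", vapply(spec$aryl_subs, ar, ""))),
    amine = c(sprintf("N%s", vapply(spec$alkyl_subs, ch2, "")),
              sprintf("NC%s", vapply(spec$aryl_subs, ar, ""))),
    boronic_acid = sprintf("OB(O)%s", vapply(spec$aryl_subs, ar, "")),
    benzyl_chloride = sprintf("ClC%s", vapply(spec$aryl_subs, ar, "")),
    aryl_bromide = sprintf("Br%s", vapply(spec$aryl_subs, ar, "")),
    aldehyde = sprintf("O=C%s", vapply(spec$aryl_subs, ar, "")),
    ketone = sprintf("CC(=O)%s", vapply(spec$aryl_subs, ar, "")),
    aniline = sprintf("N%s", vapply(spec$aryl_subs, ar, ""))
  )
  smiles <- unlist(classes, use.names = FALSE)
  cls <- rep(names(classes), vapply(classes, length, integer(1)))
  canon <- rx_canonical_smiles(smiles)
  keep <- !duplicated(canon)
  lib <- reagent_library(canon[keep],
                         ids = sprintf("%s_%03d", cls[keep], seq_len(sum(keep))))
  lib$class <- cls[keep][match(lib$smiles, canon[keep])]
  lib
}

#' Single-reactant functional-transformation reactions
#'
#' Mapped reactions that convert reactive groups into unreactive ones (acyl
#' chloride and benzylic chloride hydrolysis, aldehyde and enone reduction),
#' used to build the transformation database of the reactive-group conversion
#' filter stage.
#'
#' @param spec A [fixture_spec()].
#' @return Tibble `id`, `reaction`.
#' @export
make_transform_reactions <- function(spec = fixture_spec()) {
  anchors <- vapply(spec$aryl_subs[1:6], .ar_inline, "", m = 10L)
  rows <- list()
  add <- function(id, rxn) {
    rows[[length(rows) + 1]] <<- tibble::tibble(id = id, reaction = rxn)
  }
  for (k in seq_along(anchors)) {
    a <- anchors[k]
    add(sprintf("tf_acyl_chloride_hydrolysis_%02d", k),
        sprintf("[C:1](=[O:2])([Cl:3])%s.[OH2:4]>>[C:1](=[O:2])([OH:4])%s.[ClH:3]",
                a, a))
    add(sprintf("tf_aldehyde_reduction_%02d", k),
        sprintf("[CH:1](=[O:2])%s>>[CH2:1]([OH:2])%s", a, a))
    add(sprintf("tf_benzyl_chloride_hydrolysis_%02d", k),
        sprintf("[Cl:2][CH2:1]%s.[OH2:3]>>[OH:3][CH2:1]%s.[ClH:2]", a, a))
    add(sprintf("tf_enone_reduction_%02d", k),
        sprintf("[CH2:1]=[CH:2][C:3](=[O:4])%s>>[CH3:1][CH2:2][C:3](=[O:4])%s",
                a, a))
  }
  dplyr::bind_rows(rows)
}

#' Reference ligands and designed candidates
#'
#' Vendored structures: the five PARP1 reference inhibitors and the designed
#' candidates whose structures were transcribed once from their published
#' IUPAC names (recorded in the source comments). Row745(2) carries its
#' (1S,2S) cyclopropane annotation; all other candidates are constitution
#' level.
#'
#' @return Tibble `name`, `role` (reference/candidate/intermediate), `smiles`.
#' @export
paper_compounds <- function() {
  refs <- c(
    # 4-[(3-{[4-(cyclopropanecarbonyl)piperazin-1-yl]carbonyl}-4-fluorophenyl)
    # methyl]phthalazin-1(2H)-one
    Olaparib = "O=c1[nH]nc(Cc2ccc(F)c(C(=O)N3CCN(C(=O)C4CC4)CC3)c2)c2ccccc12",
    # 8-fluoro-2-{4-[(methylamino)methyl]phenyl}-1,3,4,5-tetrahydro-6H-
    # azepino[5,4,3-cd]indol-6-one
    Rucaparib = "CNCc1ccc(-c2[nH]c3cc(F)cc4c3c2CCNC4=O)cc1",
    # 2-{4-[(3S)-piperidin-3-yl]phenyl}-2H-indazole-7-carboxamide
    Niraparib = "NC(=O)c1cccc2cn(-c3ccc([C@H]4CCCNC4)cc3)nc12",
    # (8S,9R)-5-fluoro-8-(4-fluorophenyl)-9-(1-methyl-1H-1,2,4-triazol-5-yl)-
    # 2,7,8,9-tetrahydro-3H-pyrido[4,3,2-de]phthalazin-3-one
    Talazoparib = "CN1C(=NC=N1)[C@H]1[C@@H](NC2=CC(F)=CC3=C2C1=NNC3=O)c1ccc(F)cc1",
    # N-(6-oxo-5,6-dihydrophenanthridin-2-yl)-N,N-dimethylglycinamide
    PJ34 = "CN(C)CC(=O)NC1=CC2=C(C=C1)NC(=O)C3=CC=CC=C32"
  )
  cands <- c(
    # [3-Methyl-4-(morpholine-4-carbonyl)phenyl]methyl 3-methyl-1-oxo-
    # 1,2-dihydroisoquinoline-6-carboxylate
    Row514 = "CC1=CC2=CC(=CC=C2C(=O)N1)C(=O)OCc1ccc(c(C)c1)C(=O)N1CCOCC1",
    # [3-Methyl-4-(morpholine-4-carbonyl)phenyl]methyl 5-methyl-1H-indazole-
    # 4-carboxylate
    Row26 = "Cc1ccc2[nH]ncc2c1C(=O)OCc1ccc(C(=O)N2CCOCC2)c(C)c1",
    # 3-(2-Aminoethyl)-1-[(4-methylphenyl)methyl]-1H-indole-4-carbonitrile
    Row847 = "N#Cc1cccc2c1c(CCN)cn2Cc1ccc(C)cc1",
    # 4-[4-(1-Hydroxybutyl)phenyl]-1,2-dihydrophthalazin-1-one
    Row86 = "O=C1NN=C(c2ccc(C(O)CCC)cc2)c2ccccc12",
    # 4-[4-(2-Methylcyclopropanecarbonyl)phenyl]-1,2-dihydrophthalazin-1-one,
    # (1S,2S) isomer
    `Row745(2)` = "C[C@H]1C[C@H]1C(=O)c1ccc(C2=NNC(=O)c3ccccc32)cc1",
    # 7-(4-{[(But-3-yn-1-yl)amino]methyl}-2-methylphenyl)-5-fluoro-1,2,3,4-
    # tetrahydroisoquinolin-1-one
    Row528 = "O=C1NCCc2c(F)cc(-c3ccc(CNCCC#C)cc3C)cc21"
  )
  inter <- c(
    # 4-(4-Bromophenyl)-2H-phthalazin-1-one
    `Row86(I)` = "O=C1NN=C(c2ccc(Br)cc2)c2ccccc12",
    # 7-[4-(Aminomethyl)-2-methylphenyl]-5-fluoro-1,2,3,4-tetrahydro-
    # isoquinolin-1-one
    `Row528(I)` = "O=C1NCCc2c(F)cc(-c3ccc(CN)cc3C)cc21"
  )
  tibble::tibble(
    name = c(names(refs), names(cands), names(inter)),
    role = c(rep("reference", length(refs)), rep("candidate", length(cands)),
             rep("intermediate", length(inter))),
    smiles = c(unname(refs), unname(cands), unname(inter))
  )
}

#' Write fixture files to a directory
#'
#' Emits `reactions.rsmi` (mapped reaction SMILES with ids),
#' `transforms.rsmi`, `reagents.smi` and `compounds.smi`.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [fixture_spec()].
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(dir, spec = fixture_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rxns <- make_toy_reactions(spec)
  writeLines(paste(rxns$reaction, rxns$id), file.path(dir, "reactions.rsmi"))
  tf <- make_transform_reactions(spec)
  writeLines(paste(tf$reaction, tf$id), file.path(dir, "transforms.rsmi"))
  save_reagent_library(make_toy_reagents(spec), file.path(dir, "reagents.smi"))
  pc <- paper_compounds()
  writeLines(paste(pc$smiles, pc$name), file.path(dir, "compounds.smi"))
  invisible(dir)
}
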