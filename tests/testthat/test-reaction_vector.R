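test_that("cleaning appends a matching byproduct to the deficient side", {
  rec <- parse_reaction("CC(=O)O.OC>>CC(=O)OC")
  cleaned <- clean_reaction(rec)
  expect_length(cleaned$products, 2)
  expect_equal(cleaned$products[[2]]$smiles, "O")
  expect_true(rxnvec:::is_balanced_reaction(cleaned))
  # already balanced reactions pass through unchanged
  rec2 <- parse_reaction("CC(=O)O.OC>>CC(=O)OC.O")
  expect_identical(clean_reaction(rec2)$text, rec2$text)
  # a C2 deficit matches no configured byproduct
  expect_error(clean_reaction(parse_reaction("CCO>>CCCCO")), "cannot balance")
})

test_that("identity reactions and unbalanced reactions yield no vector", {
  expect_error(derive_vector(parse_reaction("CCO>>CCO")), "zero vector")
  expect_error(derive_vector(parse_reaction("CC(=O)O.OC>>CC(=O)OC")),
               "not balanced")
})

test_that("the esterification vector carries the expected lost and gained pairs", {
  rv <- fx_esterification()
  # lost: the acid C-OH bond pair and the alcohol C-OH pair
  expect_true(ap_contains(rv$negative, ap_vector(c("C310-11-O100" = 1L))))
  expect_true(ap_contains(rv$negative, ap_vector(c("C100-11-O100" = 1L))))
  # gained: the two ester C-O bonds around the bridging oxygen
  expect_true(ap_contains(rv$positive, ap_vector(c("C310-11-O200" = 1L))))
  expect_true(ap_contains(rv$positive, ap_vector(c("C100-11-O200" = 1L))))
  expect_equal(rv$n_reactant_components, 2L)
})

test_that("the signed vector equals the component-wise subtraction oracle", {
  rxns <- fx_reactions()
  db <- fx_db()
  ids <- vapply(db$entries, `[[`, "", "id")
  for (i in seq_len(nrow(rxns))) {
    rv <- db$entries[[match(rxns$id[i], ids)]]
    lhs <- Reduce(ap_sum, lapply(c(rxns$product[i], rxns$byproducts[[i]]),
                                 component_vector))
    rhs <- Reduce(ap_sum, lapply(rxns$reactants[[i]], component_vector))
    expect_true(ap_identical(ap_diff(lhs, rhs), ap_diff(rv$positive, rv$negative)),
                info = paste("subtraction oracle mismatch for", rxns$id[i]))
  }
})

test_that("reversing a reaction swaps the negative and positive parts exactly", {
  rxns <- fx_reactions()
  for (i in seq_len(nrow(rxns))) {
    rec <- parse_reaction(rxns$reaction[i], id = rxns$id[i])
    fwd <- derive_vector(rec)
    parts <- strsplit(rxns$reaction[i], ">>", fixed = TRUE)[[1]]
    rev_rec <- parse_reaction(paste0(parts[2], ">>", parts[1]), id = "rev")
    bwd <- derive_vector(rev_rec, implicit_reagents = character(0),
                         strict = FALSE)
    expect_true(ap_identical(fwd$negative, bwd$positive),
                info = paste("antisymmetry (negative) fails for", rxns$id[i]))
    expect_true(ap_identical(fwd$positive, bwd$negative),
                info = paste("antisymmetry (positive) fails for", rxns$id[i]))
  }
})

test_that("derivation is invariant to component order and atom renumbering", {
  rxn <- paste0("[CH3:6][C:1](=[O:2])[OH:3].[OH:4][CH3:5]>>",
                "[CH3:6][C:1](=[O:2])[O:4][CH3:5].[OH2:3]")
  swapped <- paste0("[OH:4][CH3:5].[CH3:6][C:1](=[O:2])[OH:3]>>",
                    "[OH2:3].[CH3:6][C:1](=[O:2])[O:4][CH3:5]")
  renumbered <- paste0("[CH3:6][C:1]([OH:3])=[O:2].[CH3:5][OH:4]>>",
                       "[O:2]=[C:1]([CH3:6])[O:4][CH3:5].[OH2:3]")
  base <- derive_vector(parse_reaction(rxn, id = "a"))
  for (alt in c(swapped, renumbered)) {
    rv <- derive_vector(parse_reaction(alt, id = "b"))
    expect_true(ap_identical(rv$negative, base$negative))
    expect_true(ap_identical(rv$positive, base$positive))
  }
})

test_that("templates cover the reaction centre with attachment correspondence", {
  rxn <- paste0("[CH3:6][C:1](=[O:2])[OH:3].[OH:4][CH3:5]>>",
                "[CH3:6][C:1](=[O:2])[O:4][CH3:5].[OH2:3]")
  tpl <- extract_templates(parse_reaction(rxn, id = "est"))
  ratoms <- tpl$reactant_template$atoms
  # core: acyl carbon, leaving hydroxyl O, alcohol O
  expect_setequal(ratoms$map[ratoms$core], c(1L, 3L, 4L))
  # one shell: carbonyl O, both methyl carbons
  expect_setequal(ratoms$map[!ratoms$core], c(2L, 5L, 6L))
  # product template forms the ester C-O bond between template atoms 1 and 4
  tids <- tpl$product_template$atoms$tid[tpl$product_template$atoms$map %in% c(1L, 4L)]
  formed <- tpl$product_template$bonds
  expect_true(any((formed$i %in% tids) & (formed$j %in% tids)))
  # attachment map is a bijection template id -> atom map number
  expect_false(anyDuplicated(tpl$attachment_map) > 0)
})

test_that("a bond-order-only change yields a degenerate bondless-break template", {
  rxn <- "[CH:1](=[O:2])c1ccccc1>>[CH2:1]([OH:2])c1ccccc1"
  rv <- derive_vector(parse_reaction(rxn, id = "red"))
  tpl <- rv$template
  core <- tpl$atoms[tpl$atoms$core, ]
  expect_setequal(core$map, c(1L, 2L))
  # no bonds broken or formed, only the C=O order change
  expect_equal(nrow(tpl$src_bonds), nrow(tpl$tgt_bonds))
})

test_that("inconsistent maps and element changes are template errors", {
  expect_error(
    derive_vector(parse_reaction("[CH3:1][OH:2].[CH3:1]O>>[CH3:1][OH:2].CO")),
    "not injective")
  expect_error(
    derive_vector(parse_reaction("[CH3:1][O:2][CH3:3]>>[CH3:1][CH2:2][OH:3]"),
                  byproducts = character(0)),
    "changes element")
})

test_that("symmetric reactants record automorphic sites once", {
  # boronic acid hydroxyls are equivalent; the Suzuki edit is recorded once
  rxns <- fx_reactions()
  i <- which(rxns$template == "biaryl_coupling")[1]
  db <- fx_db()
  ids <- vapply(db$entries, `[[`, "", "id")
  rv <- db$entries[[match(rxns$id[i], ids)]]
  res <- apply_vector(rv, as.list(rxns$reactants[[i]]))
  expect_equal(length(unique(res$site)), length(res$site))
})

test_that("the auto-mapper aligns unmapped reactions or rejects them", {
  rec <- parse_reaction("CC(=O)O.OC>>CC(=O)OC.O", id = "unmapped_est")
  rv <- derive_vector(rec)
  res <- apply_vector(rv, list("CC(=O)O", "CO"))
  expect_true("COC(C)=O" %in% res$product)
  # a product unrelated to its reactant is a low-confidence mapping
  expect_error(
    derive_vector(parse_reaction("CCCCCC>>c1ccccc1", id = "nonsense")),
    "low-confidence|zero vector|no mapped")
})
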