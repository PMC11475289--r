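test_that("the toy corpus is balanced, mapped and at least forty reactions deep", {
  rxns <- fx_reactions()
  expect_gte(nrow(rxns), 40)
  expect_length(unique(rxns$template), 4)
  for (i in seq_len(nrow(rxns))) {
    rec <- parse_reaction(rxns$reaction[i], id = rxns$id[i])
    expect_true(rxnvec:::is_balanced_reaction(rec),
                info = paste("unbalanced fixture", rxns$id[i]))
    # cleaning a pre-balanced record is the identity
    expect_identical(clean_reaction(rec)$text, rec$text)
    n_mapped <- sum(vapply(c(rec$reactants, rec$products),
                           function(m) sum(m$atoms$map > 0), integer(1)))
    expect_gt(n_mapped, 0)
  }
})

test_that("fixtures are deterministic in the seed and vary with it", {
  a <- make_toy_reactions(fixture_spec(seed = 42))
  b <- make_toy_reactions(fixture_spec(seed = 42))
  expect_identical(a, b)
  c <- make_toy_reactions(fixture_spec(seed = 43))
  expect_false(identical(a$reaction, c$reaction))
  expect_identical(a$template, c$template)  # same template structure
})

test_that("the reagent library is closed over fixture reactants and duplicate-free", {
  rxns <- fx_reactions()
  lib <- fx_lib()
  expect_gt(nrow(lib), 100)
  expect_false(anyDuplicated(lib$smiles) > 0)
  expect_true(all(unlist(rxns$reactants) %in% lib$smiles))
  expect_true(all(c("acid", "alcohol", "amine", "boronic_acid",
                    "benzyl_chloride", "aryl_bromide") %in% lib$class))
  # precomputed fingerprints align with the rows
  fps <- attr(lib, "fingerprints")
  expect_equal(nrow(fps), nrow(lib))
})

test_that("vendored reference and candidate structures sanitise", {
  pc <- paper_compounds()
  expect_gte(nrow(pc), 11)
  for (i in seq_len(nrow(pc))) {
    expect_silent(parse_mol(pc$smiles[i]))
  }
  expect_setequal(unique(pc$role), c("reference", "candidate", "intermediate"))
  # the phthalazinone ketone candidate carries its cyclopropane stereo labels
  row745 <- pc$smiles[pc$name == "Row745(2)"]
  expect_true(grepl("@", row745))
  expect_length(unlist(strsplit(row745, "@")), 3)  # two stereocentres annotated
})

test_that("fixture files write as plain text and reload", {
  dir <- withr::local_tempdir()
  write_fixtures(dir, fixture_spec(seed = 5))
  expect_true(all(file.exists(file.path(dir, c("reactions.rsmi",
                                               "transforms.rsmi",
                                               "reagents.smi",
                                               "compounds.smi")))))
  lib <- load_reagent_library(file.path(dir, "reagents.smi"))
  expect_gt(nrow(lib), 100)
  # reactions file reparses into balanced records
  first <- strsplit(readLines(file.path(dir, "reactions.rsmi"))[1], " ")[[1]]
  expect_true(rxnvec:::is_balanced_reaction(parse_reaction(first[1])))
})

test_that("every fixture reaction is reproducible from library reagents", {
  # package-level closure: derive each vector, then regenerate the recorded
  # product using the library copies of its reactants
  rxns <- fx_reactions()
  db <- fx_db()
  lib <- fx_lib()
  ids <- vapply(db$entries, `[[`, "", "id")
  set.seed(9)
  for (i in sample(nrow(rxns), 10)) {
    rv <- db$entries[[match(rxns$id[i], ids)]]
    from_lib <- lib$smiles[match(rxns$reactants[[i]], lib$smiles)]
    res <- apply_vector(rv, as.list(from_lib))
    expect_true(rxns$product[i] %in% res$product,
                info = paste("library closure fails for", rxns$id[i]))
  }
})
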