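test_that("a product fragments into its own reactants and reassembles", {
  rv <- fx_esterification()
  db <- rxnvec:::new_vector_db(list(rv))
  fsets <- fragment_reference("COC(C)=O", db)
  expect_gte(length(fsets), 1)
  fs <- fsets[[1]]
  expect_setequal(fs$fragments, c("CC(=O)O", "CO"))
  # reassembly: the recorded route replays to the reference
  expect_equal(replay_route(.subst_leaves(fs$steps, fs$fragments), db),
               "COC(C)=O")
})

test_that("a molecule matching no vector yields the degenerate fragment set", {
  db <- rxnvec:::new_vector_db(list(fx_esterification()))
  fsets <- fragment_reference("c1ccccc1", db)
  expect_length(fsets, 1)
  expect_equal(fsets[[1]]$fragments, "c1ccccc1")
  expect_length(fsets[[1]]$steps, 0)
})

test_that("two-step fragmentation yields three leaf fragments", {
  # target: benzoate ester of 4-phenylbenzyl alcohol; the alcohol itself is a
  # biaryl coupling product
  est <- paste0("[C:1](=[O:2])([OH:3])[c:30]1[cH:31][cH:32][cH:33][cH:34]",
                "[cH:35]1.[OH:4][CH2:5][c:36]1[cH:37][cH:38][cH:39][cH:40]",
                "[cH:41]1>>[C:1](=[O:2])([O:4][CH2:5][c:36]1[cH:37][cH:38]",
                "[cH:39][cH:40][cH:41]1)[c:30]1[cH:31][cH:32][cH:33][cH:34]",
                "[cH:35]1.[OH2:3]")
  suz <- paste0("[Br:2][c:1]1[cH:4][cH:5][cH:6][cH:7][cH:8]1.",
                "[OH:11][B:10]([OH:12])[c:13]1[cH:14][cH:15][cH:16][cH:17]",
                "[cH:18]1>>[c:1]1([c:13]2[cH:14][cH:15][cH:16][cH:17]",
                "[cH:18]2)[cH:4][cH:5][cH:6][cH:7][cH:8]1.[BrH:2].",
                "[OH:11][BH:10][OH:12]")
  db <- build_vector_db(c(est_aryl = est, suzuki = suz))
  expect_equal(nrow(attr(db, "skipped")), 0)
  target <- "O=C(OCc1ccc(-c2ccccc2)cc1)c1ccccc1"
  fsets <- fragment_reference(target, db, max_depth = 2)
  depths <- vapply(fsets, function(fs) length(fs$fragments), integer(1))
  expect_true(2 %in% depths)  # one-step split survives
  expect_true(3 %in% depths)  # two-step split reaches three leaves
  deep <- fsets[[which(depths == 3)[1]]]
  expect_length(deep$steps, 2)
  # replaying the two-step route with its own leaves regenerates the target
  expect_equal(replay_route(.subst_leaves(deep$steps, deep$fragments), db),
               target)
})

test_that("building-block scoring is a full-scan Euclidean ranking", {
  lib <- fx_lib()
  # a library member queries itself at distance zero
  member <- lib$smiles[25]
  top <- score_building_blocks(member, lib, k = 3)
  expect_equal(top$smiles[1], member)
  expect_equal(top$distance[1], 0)
  # symmetric distance
  a <- lib$smiles[10]; b <- lib$smiles[60]
  fa <- rxnvec:::rx_morgan_count_vectors(c(a, b), features = TRUE)
  expect_equal(sqrt(sum((fa[1, ] - fa[2, ])^2)),
               sqrt(sum((fa[2, ] - fa[1, ])^2)))
  # brute-force oracle: independent distance computation and ordering
  query <- "OC(=O)c1ccc(C)cc1"
  k <- 7
  got <- score_building_blocks(query, lib, k = k)
  qfp <- rxnvec:::rx_morgan_count_vectors(query, features = TRUE)[1, ]
  lfp <- rxnvec:::rx_morgan_count_vectors(lib$smiles, features = TRUE)
  d <- sqrt(colSums((t(lfp) - qfp)^2))
  ord <- order(d, lib$smiles)[seq_len(k)]
  expect_equal(got$smiles, lib$smiles[ord])
  expect_equal(got$distance, unname(d[ord]))
})

test_that("the design loop is deterministic and its routes replay", {
  rxns <- fx_reactions()
  db <- fx_db()
  lib <- fx_lib()
  tdb <- fx_transform_db()
  ref <- rxns$product[rxns$template == "esterification"][2]
  cfg <- design_config(beam_width = 15, k_building_blocks = 4,
                       max_final_products = 20, seed = 7)
  d1 <- run_design(c(ref1 = ref), db, lib, transform_db = tdb, config = cfg)
  d2 <- run_design(c(ref1 = ref), db, lib, transform_db = tdb, config = cfg)
  expect_identical(d1$candidates, d2$candidates)
  expect_gt(nrow(d1$candidates), 0)
  for (i in seq_len(nrow(d1$candidates))) {
    expect_equal(replay_route(d1$candidates$route[[i]], db),
                 d1$candidates$structure[i],
                 info = paste("route replay failed for",
                              d1$candidates$structure[i]))
  }
  # the aggregate score orders the output
  expect_true(all(diff(d1$candidates$total) <= 1e-12))
})

test_that("a zero product cap still produces the attrition report", {
  rxns <- fx_reactions()
  db <- fx_db()
  lib <- fx_lib()
  ref <- rxns$product[rxns$template == "amide_coupling"][1]
  d <- run_design(c(r = ref), db, lib,
                  config = design_config(beam_width = 5, k_building_blocks = 2,
                                         max_final_products = 0))
  expect_equal(nrow(d$candidates), 0)
  expect_true("generated" %in% d$attrition$stage)
  expect_gt(sum(d$attrition$n[d$attrition$stage == "generated"]), 0)
})

test_that("a wider beam output is a superset of the narrow beam when caps allow", {
  rxns <- fx_reactions()
  db <- fx_db()
  lib <- fx_lib()
  ref <- rxns$product[rxns$template == "esterification"][2]
  narrow <- run_design(c(r = ref), db, lib,
                       config = design_config(beam_width = 5,
                                              k_building_blocks = 3,
                                              max_final_products = 1000))
  wide <- run_design(c(r = ref), db, lib,
                     config = design_config(beam_width = 50,
                                            k_building_blocks = 3,
                                            max_final_products = 1000))
  expect_true(all(narrow$candidates$structure %in% wide$candidates$structure))
})

test_that("exported routes list steps in forward order with provenance", {
  rxns <- fx_reactions()
  db <- fx_db()
  lib <- fx_lib()
  ref <- rxns$product[rxns$template == "esterification"][2]
  d <- run_design(c(r = ref), db, lib,
                  config = design_config(beam_width = 10,
                                         k_building_blocks = 3,
                                         max_final_products = 5))
  routes <- export_routes(d, db = db)
  expect_gt(nrow(routes), 0)
  one_step <- routes[routes$structure == routes$structure[1], ]
  expect_equal(one_step$step, seq_len(nrow(one_step)))
  expect_false(any(is.na(one_step$provenance)))
  # a written report round-trips through the text file
  path <- withr::local_tempfile(fileext = ".txt")
  export_routes(d, path = path, db = db)
  expect_true(any(grepl("^candidate:", readLines(path))))
})

test_that("scorers honour the contract and the aggregation is direction-aware", {
  sc <- similarity_scorer("CCO")
  expect_equal(sc$score(c("CCO", "CCO")), c(1, 1))
  ps <- property_scorer(mw_range = c(0, 100), logp_range = c(-5, 5))
  v <- ps$score(c("CCO", paste(rep("C", 40), collapse = "")))
  expect_gt(v[1], v[2])
  # a custom minimized scorer flips under normalisation
  heavy <- new_scorer("heavy_atoms", "minimize", function(s)
    vapply(s, function(x) nrow(parse_mol(x)$atoms), numeric(1)))
  cands <- tibble::tibble(reference = "r", structure = c("CCO", "CCCCCCCCCO"),
                          route = list(list(), list()))
  scored <- rxnvec:::.score_candidates(cands, list(heavy), design_config())
  expect_gt(scored$total[1], scored$total[2])
})
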