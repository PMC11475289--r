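test_that("atom descriptors encode element, heavy degree, pi electrons and rings", {
  # isolated heavy atom
  methane <- describe_atom("C", 1)
  expect_equal(methane[c("element", "h", "p", "r")],
               list(element = "C", h = 0L, p = 0L, r = 0L))
  # ethanol oxygen: one heavy neighbour, no pi, no ring
  etoh <- parse_mol("CCO")
  o_idx <- which(etoh$atoms$element == "O")
  expect_equal(describe_atom(etoh, o_idx)$string, "O100")
  # aromatic carbon in benzene: two heavy neighbours, one pi electron, one ring
  expect_equal(describe_atom("c1ccccc1", 1)$string, "C211")
  # carbonyl carbon of acetone picks up one pi electron per double bond
  acetone <- parse_mol("CC(=O)C")
  cidx <- which(acetone$atoms$degree == 3)
  expect_equal(describe_atom(acetone, cidx)$string, "C310")
  # allene centre accumulates pi electrons from both double bonds
  allene <- parse_mol("C=C=C")
  centre <- which(allene$atoms$degree == 2)
  expect_equal(describe_atom(allene, centre)$p, 2L)
})

test_that("AP2 enumeration yields one pair per heavy-atom bond", {
  expect_length(enumerate_ap2("C"), 0)
  etoh <- enumerate_ap2("CCO")
  expect_equal(as.integer(etoh[c("C100-11-C200", "C200-11-O100")]), c(1L, 1L))
  benzene <- enumerate_ap2("c1ccccc1")
  expect_equal(as.integer(benzene), 6L)
  expect_equal(names(benzene), "C211-14-C211")  # bond order 4 = aromatic
})

test_that("AP3 enumeration yields one pair per distance-2 atom pair", {
  expect_length(enumerate_ap3("CC"), 0)
  etoh <- enumerate_ap3("CCO")
  expect_equal(as.integer(etoh["C100-2-O100"]), 1L)
  expect_length(etoh, 1)
  benzene <- enumerate_ap3("c1ccccc1")
  expect_equal(as.integer(benzene), 6L)
  expect_equal(names(benzene), "C211-2-C211")
})

test_that("component vector is the count-wise AP2 + AP3 union", {
  v <- component_vector("CCO")
  expect_length(v, 3)
  expect_true(ap_identical(v, ap_sum(enumerate_ap2("CCO"), enumerate_ap3("CCO"))))
})

test_that("AP3 matches a brute-force shortest-path oracle on fixture molecules", {
  lib <- fx_lib()
  pool <- unique(c(lib$smiles, fx_reactions()$product))
  set.seed(11)
  sample_smiles <- sample(pool, min(100, length(pool)))
  for (smi in sample_smiles) {
    mol <- parse_mol(smi)
    expect_true(ap_identical(enumerate_ap3(mol), oracle_ap3(mol)),
                info = paste("AP3 oracle mismatch for", smi))
  }
})

test_that("pair vectors are invariant to atom renumbering", {
  pool <- c("CC(=O)OCc1ccc(OC)cc1", "O=C1NN=C(c2ccc(Br)cc2)c2ccccc12",
            "CN(C)CC(=O)Nc1ccc2[nH]c(=O)c3ccccc3c2c1")
  variants <- rx_random_smiles(pool, n = 4, seed = 7)
  for (i in seq_along(pool)) {
    ref <- component_vector(pool[i])
    for (alt in variants[[i]]) {
      expect_true(ap_identical(component_vector(alt), ref),
                  info = paste("renumbering changed the vector of", pool[i]))
    }
  }
})

test_that("pair-vector arithmetic behaves as a signed multiset", {
  x <- ap_vector(c(a = 2L, b = 1L))
  y <- ap_vector(c(a = 1L, c = 3L))
  expect_equal(as.integer(ap_sum(x, y)[c("a", "b", "c")]), c(3L, 1L, 3L))
  d <- ap_diff(x, y)
  expect_equal(as.integer(d[c("a", "b", "c")]), c(1L, 1L, -3L))
  expect_true(ap_contains(x, ap_vector(c(a = 2L))))
  expect_false(ap_contains(x, ap_vector(c(a = 3L))))
  expect_equal(as.integer(ap_shortfall(x, ap_vector(c(a = 3L, c = 1L)))),
               c(1L, 1L))
  # zero counts never stored
  expect_length(ap_diff(x, x), 0)
})

test_that("hydrogen atoms are rejected by the descriptor contract", {
  mol <- parse_mol("[H][H]")
  expect_error(describe_atom(mol, 1), "hydrogen")
})
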