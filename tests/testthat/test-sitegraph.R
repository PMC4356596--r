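# Canonical labeling and embedding enumeration, checked against brute-force
# oracles (exhaustive permutations; exhaustive injective assignment).

test_that("canonical labels are invariant under molecule permutations", {
  net <- nominal_network()
  multi <- which(vapply(net$graphs, function(g) length(g$mols), 1L) >= 2L)
  set.seed(42)
  for (s in sample(multi, 25)) {
    g <- net$graphs[[s]]
    ref <- canonical_label(g)
    for (perm in all_permutations(length(g$mols)))
      expect_identical(canonical_label(permute_species(g, perm)), ref)
  }
})

test_that("distinct site states give distinct labels", {
  types <- build_model()$molecule_types
  a <- parse_species("RPTOR(RNC,ulk1,WD40,S792~0,S855_S859~P)", types)
  b <- parse_species("RPTOR(RNC,ulk1,WD40,S792~0,S855_S859~PP)", types)
  expect_false(canonical_label(a) == canonical_label(b))
})

test_that("labels separate all species of the nominal network", {
  net <- nominal_network()
  expect_equal(anyDuplicated(net$species), 0)
})

test_that("symmetric complexes canonicalize by exhaustive permutation", {
  types <- list(A = molecule_type("A", list(x = character(0),
                                            s = c("0", "P"))),
                B = molecule_type("B", list(a1 = character(0),
                                            a2 = character(0))))
  # B bridging two A copies identical in type and state
  g <- parse_species("A(x!1,s~0).B(a1!1,a2!2).A(x!2,s~0)", types)
  ref <- canonical_label(g)
  for (perm in all_permutations(3))
    expect_identical(canonical_label(permute_species(g, perm)), ref)
})

test_that("embeddings match simple by-hand cases", {
  types <- build_model()$molecule_types
  ulk_p <- parse_species("ULK1(straptor,stampk,S317~0,S758~P,S778~0)", types)
  expect_length(find_embeddings(parse_pattern("ULK1(S758~P)"), ulk_p), 1)
  expect_length(find_embeddings(parse_pattern("ULK1(S758~0)"), ulk_p), 0)
  mtor <- parse_species("MTOR(HEAT,FRB)", types)
  expect_length(find_embeddings(parse_pattern("rapa(mtor)"), mtor), 0)
  # required-free versus bonded site conditions
  cplx <- parse_species("rapa(mtor!1).MTOR(HEAT,FRB!1)", types)
  expect_length(find_embeddings(parse_pattern("MTOR(FRB!1).rapa(mtor!1)"), cplx), 1)
  expect_length(find_embeddings(parse_pattern("MTOR(FRB)"), cplx), 0)
  expect_length(find_embeddings(parse_pattern("MTOR(HEAT)"), cplx), 1)
})

test_that("embedding counts equal the brute-force matcher on the nominal network", {
  net <- nominal_network()
  m <- net$model
  patterns <- list()
  for (r in m$rules) {
    for (p in r$reactants) patterns[[length(patterns) + 1L]] <- p
    if (r$direction == "bidirectional")
      for (p in r$products) patterns[[length(patterns) + 1L]] <- p
  }
  got <- matrix(0L, length(patterns), length(net$graphs))
  want <- got
  for (p in seq_along(patterns)) {
    for (s in seq_along(net$graphs)) {
      got[p, s] <- length(find_embeddings(patterns[[p]], net$graphs[[s]]))
      want[p, s] <- oracle_count_embeddings(patterns[[p]], net$graphs[[s]])
    }
  }
  expect_identical(got, want)
})

test_that("every nominal (rule, reactant tuple) has embedding multiplicity 1", {
  net <- nominal_network()
  expect_true(all(net$reactions$mult == 1L))
})

test_that("species parsing rejects malformed graphs", {
  types <- build_model()$molecule_types
  expect_error(parse_species("ULK1(straptor,stampk,S317~0,S758~P,S778~0).MTOR(HEAT,FRB)", types),
               "not connected")
  expect_error(parse_species("MTOR(HEAT!1,FRB)", types), "unpaired bond")
  expect_error(parse_species("AMBRA1(ST)", types), "must specify state")
})
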