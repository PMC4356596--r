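# Network expansion: toy-model oracles, closure, conservation structure,
# determinism, and network-file round trips.

test_that("toy models expand to their closed-form species sets", {
  toys <- toy_models()
  expect_gte(length(toys), 5)
  for (nm in names(toys)) {
    t <- toys[[nm]]
    net <- expand_network(t$model)
    expect_equal(length(net$species), t$expected_species, info = nm)
    expect_equal(nrow(net$reactions), t$expected_reactions, info = nm)
  }
})

test_that("phosphoform lattice equals exhaustive state enumeration", {
  t <- toy_models()$phosphoforms
  net <- expand_network(t$model)
  types <- t$model$molecule_types
  combos <- expand.grid(s = c("0", "P"), t = c("0", "P", "PP"),
                        stringsAsFactors = FALSE)
  want <- sort(vapply(seq_len(nrow(combos)), function(i)
    canonical_label(parse_species(
      sprintf("M(s~%s,t~%s)", combos$s[i], combos$t[i]), types)), ""))
  expect_identical(sort(net$species), want)
})

test_that("binding fixtures enumerate exactly the hand-listed complexes", {
  toys <- toy_models()
  lab <- function(model, txt)
    canonical_label(parse_species(txt, model$molecule_types))
  cases <- list(
    dimer = c("A(b)", "B(a)", "A(b!1).B(a!1)"),
    scaffold = c("A(b)", "B(a,c)", "C(b)", "A(b!1).B(a!1,c)",
                 "B(a,c!1).C(b!1)", "A(b!1).B(a!1,c!2).C(b!2)"),
    competition = c("R(s)", "L1(r)", "L2(r)", "R(s!1).L1(r!1)",
                    "R(s!1).L2(r!1)"),
    context_unbound = c("T(h,f)", "X(t)", "Y(t)", "X(t!1).T(h,f!1)",
                        "Y(t!1).T(h!1,f)"))
  for (nm in names(cases)) {
    model <- toys[[nm]]$model
    net <- expand_network(model)
    want <- sort(unname(vapply(cases[[nm]], lab, "", model = model)))
    expect_identical(sort(net$species), want, info = nm)
  }
})

test_that("mutually exclusive binding never produces doubly bound species", {
  net <- expand_network(toy_models()$context_unbound$model)
  n_bonds <- vapply(net$graphs, function(g) length(g$bonds), 1L)
  expect_true(all(n_bonds <= 1L))
})

test_that("expansion of the nominal model is closed and deterministic", {
  net <- nominal_network()
  net2 <- expand_network(build_model())   # independent second run
  expect_identical(net2$species, net$species)
  expect_identical(net2$reactions, net$reactions)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_network(net, f1)
  write_network(net2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("reactions conserve per-type molecule counts", {
  net <- nominal_network()
  M <- composition_matrix(net)
  rr <- net$reactions
  for (tp in rownames(M)) {
    lhs <- M[tp, rr$r1] + ifelse(is.na(rr$r2), 0, M[tp, ifelse(is.na(rr$r2), 1, rr$r2)])
    rhs <- M[tp, rr$p1] + ifelse(is.na(rr$p2), 0, M[tp, ifelse(is.na(rr$p2), 1, rr$p2)])
    expect_true(all(lhs == rhs), info = tp)
  }
})

test_that("network files round-trip and honour hand edits", {
  net <- expand_network(toy_models()$scaffold$model)
  f <- withr::local_tempfile()
  write_network(net, f, header = c(note = "fixture"))
  back <- read_network(f, model = toy_models()$scaffold$model)
  expect_identical(back$species, net$species)
  expect_equal(back$init, net$init)
  expect_equal(back$reactions$rate, net$reactions$rate)
  expect_identical(back$reactions$r1, net$reactions$r1)
  # hand-edit a rate value and re-read
  txt <- readLines(f)
  i <- grep("^  1 ", txt)[2]   # first reaction line
  parts <- strsplit(txt[i], "[[:space:]]+")[[1]]
  parts[6] <- "0.5"
  txt[i] <- paste(parts, collapse = " ")
  writeLines(txt, f)
  back2 <- read_network(f)
  expect_equal(back2$reactions$rate[1], 0.5)
  # malformed line is rejected with a line reference
  writeLines(c(txt[1:3], "garbage here", txt[-(1:3)]), f)
  expect_error(read_network(f), "parse error")
})

test_that("non-terminating rule sets hit the species cap", {
  model <- parse_bngl(c(
    "begin parameters", "  k 1", "end parameters",
    "begin molecule types", "  P(h,t)", "end molecule types",
    "begin seed species", "  P(h,t) 10", "end seed species",
    "begin reaction rules",
    "  1: P(t)+P(h) -> P(t!1).P(h!1)  k",   # unbounded polymerisation
    "end reaction rules"))
  expect_error(expand_network(model, max_species = 25), "max_species")
})
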