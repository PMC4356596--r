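# Model specification: molecule types, rule censuses, parameter handling,
# variants, validation, and model-file round trips.

test_that("nominal model has the published composition", {
  m <- build_model()
  expect_length(m$molecule_types, 7)
  expect_setequal(names(m$molecule_types),
                  c("rapa", "AMPK", "MTOR", "RPTOR", "ULK1", "EIF4EBP1",
                    "AMBRA1"))
  dirs <- vapply(m$rules, function(r) r$direction, "")
  expect_length(m$rules, 29)
  expect_equal(sum(dirs == "unidirectional"), 27)
  expect_equal(sum(dirs == "bidirectional"), 2)
  # the two reversible rules are the rapamycin*-MTOR and RPTOR-MTOR bindings
  expect_setequal(names(m$rules)[dirs == "bidirectional"], c("1", "2"))
})

test_that("rule classes partition as published", {
  cc <- count_rules_by_class(build_model())
  expect_equal(cc$dephosphorylation, 10)
  expect_equal(cc$phosphorylation, 10)
  expect_equal(cc$reversible_assoc_dissoc, 2)
  expect_equal(cc$unidirectional_assoc_dissoc, 7)
  expect_equal(cc$dephosphorylation + cc$phosphorylation +
                 cc$reversible_assoc_dissoc + cc$unidirectional_assoc_dissoc,
               length(build_model()$rules))
})

test_that("nominal parameter values match the published table", {
  p <- build_model()$params
  expect_identical(p$a1, 1e-3)
  expect_identical(p$a4, 1e-5)
  expect_identical(p$d3max, 10)
  expect_identical(p$d3max, 100 * p$d3)
  expect_identical(p$p6, 1e-6)
  expect_identical(p$p9, 0)
  expect_identical(p$u0, 1e-2)
  expect_identical(p$u1, 1e-3)
  expect_identical(p$u2, 1e-4)
  expect_identical(p$MTOR_0, 2e4)
  expect_identical(p$ULK1_0, 1e4)
})

test_that("statistical factor 2 appears exactly on the doubled-site rules", {
  m <- build_model()
  sf <- vapply(m$rules, function(r) r$stat_factor, 1)
  expect_setequal(names(m$rules)[sf == 2], c("8B", "15C"))
  expect_true(all(sf[!names(m$rules) %in% c("8B", "15C")] == 1))
})

test_that("both S792 dephosphorylation routes are present (u1 and u0)", {
  m <- build_model()
  refs <- vapply(m$rules[c("15A", "19")], function(r) r$rate_ref, "")
  expect_equal(unname(refs), c("u1", "u0"))
  # removing either changes the census
  expect_length(m$rules[setdiff(names(m$rules), "19")], 28)
})

test_that("model file round-trips parameter values bit-for-bit", {
  m <- build_model()
  f <- withr::local_tempfile(fileext = ".bngl")
  write_bngl(m, f)
  m2 <- read_bngl(f)
  expect_identical(m2$params, m$params)
  expect_equal(length(m2$rules), length(m$rules))
  expect_identical(unname(vapply(m2$rules, function(r) r$rate_ref, "")),
                   unname(vapply(m$rules, function(r) r$rate_ref, "")))
})

test_that("variants apply feedback, p9 and input settings", {
  m <- build_model(model_variant(feedback = FALSE))
  expect_identical(m$params$p6, 0)
  m <- build_model(model_variant(p9 = 1e-7, ampk_star = 9e4,
                                 rapamycin_star = 6e3))
  expect_identical(m$params$p9, 1e-7)
  expect_identical(m$params$AMPK_star, 9e4)
  expect_identical(m$params$rapa_star, 6e3)
  m <- build_model(model_variant(overrides = list(u2 = 5e-4)))
  expect_identical(m$params$u2, 5e-4)
  expect_error(build_model(model_variant(overrides = list(zz = 1))),
               "unknown parameter")
})

test_that("site-name aliases of the lumped S855/S859 site are normalized", {
  p1 <- parse_pattern("RPTOR(S855_Ser859~P)")
  p2 <- parse_pattern("RPTOR(S855-9~P)")
  expect_equal(names(p1$mols[[1]]$conds), "S855_S859")
  expect_equal(names(p2$mols[[1]]$conds), "S855_S859")
})

test_that("validation is clean on the nominal model and flags defects", {
  m <- build_model()
  expect_equal(nrow(validate_model(m)), 0)
  bad <- m
  bad$rules[["20"]] <- rewrite_rule("20", "ULK1(S999~P)", "ULK1(S999~0)", "u0")
  rep <- validate_model(bad)
  expect_true(any(rep$kind == "undeclared_site" &
                    grepl("S999", rep$detail)))
  bad2 <- m
  bad2$rules[["21"]] <- rewrite_rule("21", "AMBRA1(ST~P)", "AMBRA1(ST~0)", "qq")
  rep2 <- validate_model(bad2)
  expect_true(any(rep2$kind == "unbound_parameter" & rep2$detail == "qq"))
})
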