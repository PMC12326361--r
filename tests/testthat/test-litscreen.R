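test_that("spread is max minus min and invariant to order and duplication", {
  expect_equal(spread(c(0.30, 3.08, 4.80)), 4.5)
  expect_equal(spread(c(3.45, 3.31)), 0.14)
  expect_identical(spread(2.4), 0)
  set.seed(9)
  v <- rnorm(12)
  expect_identical(spread(v), spread(sample(v)))
  expect_identical(spread(v), spread(c(v, v, v[3])))
  expect_gte(spread(v), 0)
  expect_error(spread(numeric()), "empty")
})

test_that("the packaged literature table matches the curated source values", {
  lit <- kow_literature()
  expect_identical(nrow(lit), 54L)
  expect_identical(length(unique(lit$substance)), 18L)
  # the four nonionizable APIs
  expect_setequal(unique(lit$substance[!lit$ionizable]),
                  c("carbamazepine", "felodipine", "fenofibrate",
                    "griseofulvin"))
  # spot checks across the table
  expect_equal(sort(lit$value[lit$substance == "glibenclamide"]),
               c(0.30, 3.08, 4.80))
  expect_equal(lit$value[lit$substance == "naproxen" & lit$ph %in% 7.4],
               0.33)
  gri <- lit[lit$substance == "griseofulvin" & lit$determination == "exp", ]
  expect_equal(gri$value, 1.98)
  expect_equal(gri$ionic_strength_mol_L, 0.15)
  ter <- lit[lit$substance == "terfenadine", ]
  expect_identical(ter$property_reported, c("logD", "logP", "logD"))
  # N/A cells are genuine missing values, never zeros
  expect_true(anyNA(lit$ph))
  expect_false(any(lit$ph == 0, na.rm = TRUE))
})

test_that("class spread summary averages per-substance spreads by class", {
  toy <- data.frame(
    substance = c("a", "a", "b", "b", "c"),
    ionizable = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    determination = "exp",
    value = c(1, 2, 0, 3, 5))
  sm <- class_spread_summary(toy)
  ion <- sm$class_means[sm$class_means$class == "ionizable", ]
  expect_equal(ion$mean_spread, 2)           # mean of spreads {1, 3}
  expect_identical(ion$n_substances, 2L)
  non <- sm$class_means[sm$class_means$class == "nonionizable", ]
  expect_equal(non$mean_spread, 0)           # singleton substance
  # a class with no substances is simply absent
  sm2 <- class_spread_summary(toy[toy$ionizable, ])
  expect_identical(sm2$class_means$class, "ionizable")
})

test_that("recomputed class spreads from the packaged table are reported", {
  sm <- class_spread_summary(kow_literature())
  per <- sm$per_substance
  expect_equal(per$spread[per$substance == "glibenclamide"], 4.5)
  # the ionizable class scatters far more than the nonionizable one
  cm <- sm$class_means
  ion <- cm$mean_spread[cm$class == "ionizable"]
  non <- cm$mean_spread[cm$class == "nonionizable"]
  expect_gt(ion, non)
  expect_gt(ion / non, 1.5)
  # experimental-only filtering drops calculated/unknown rows
  sme <- class_spread_summary(kow_literature(), determination = "exp")
  expect_lt(nrow(sme$per_substance), nrow(per))
})

test_that("the method-comparison table reproduces the printed differences", {
  t3 <- kow_method_comparison()
  expect_identical(t3$substance,
                   c("naproxen", "ibuprofen", "lidocaine", "griseofulvin"))
  d <- abs(t3$method1 - t3$method2)
  expect_equal(d[t3$substance == "naproxen"], 0.14, tolerance = 1e-12)
  expect_equal(d[t3$substance == "ibuprofen"], 0.11, tolerance = 1e-12)
  expect_equal(d[t3$substance == "lidocaine"], 1.4, tolerance = 1e-12)
  expect_true(is.na(t3$method1[t3$substance == "griseofulvin"]))
  # the solubility ratio does not approximate any method's value
  expect_gt(abs(t3$logP_SLE[2] - t3$method2[2]), 1)
})

test_that("consistency checks flag mismatches and convert companions", {
  lit <- kow_literature()
  ter <- lit[lit$substance == "terfenadine" & lit$value == 4.47, ]
  chk <- consistency_check(ter, solute("terfenadine", "base", 9.5))
  expect_true(chk$mismatch)                  # stated log P, reported log D
  nap <- lit[lit$substance == "naproxen" & lit$value == 0.33, ]
  chk2 <- consistency_check(nap, naproxen)
  expect_false(chk2$mismatch)
  expect_identical(chk2$companion_property, "logP")
  expect_equal(chk2$companion_value, 3.5502616, tolerance = 1e-6)
  # neutral substances: conversion skipped, the two properties coincide
  gri <- lit[lit$substance == "griseofulvin" & lit$value == 1.98, ]
  chk3 <- consistency_check(gri, griseofulvin)
  expect_match(chk3$skipped_reason, "coincide")
  # missing pH: skipped with a reason, not an error
  fen <- lit[lit$substance == "fenofibrate", ][1, ]
  chk4 <- consistency_check(fen, solute("fenofibrate", "acid", 9))
  expect_match(chk4$skipped_reason, "no pH")
})
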