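# Formula arithmetic, masses, shorthand and the packaged registries.

test_that("formula construction, Hill rendering and equality", {
  f <- chem_formula(c(O = 2, C = 16, H = 32))
  expect_equal(format(f), "C16H32O2")
  expect_true(f == chem_formula("C16H32O2"))
  expect_equal(format(chem_formula("H2O")), "H2O")
  expect_equal(format(chem_formula(c(C = 0, H = 2, O = 1))), "H2O")
  expect_error(chem_formula(c(C = -1)), "negative")
  expect_error(chem_formula(c(C = 1.5)), "integer")
})

test_that("formula arithmetic is commutative, associative, and guards negatives", {
  a <- chem_formula("C4H12N2"); b <- chem_formula("H2O"); c3 <- chem_formula("C2H7N")
  expect_true((a + b) == (b + a))
  expect_true(((a + b) + c3) == (a + (b + c3)))
  expect_true((a + b) - b == a)
  expect_error(b - a, "negative")
})

test_that("monoisotopic masses agree with an independent per-atom oracle", {
  expect_equal(monoisotopic_mass(chem_formula(integer(0))), 0)
  for (fs in c("H2O", "C16H32O2", "C18H34O2", "C34H66O4", "C4H12N2",
               "C4H8D4N2", "C2H9NO")) {
    expect_equal(monoisotopic_mass(chem_formula(fs)), oracle_mass(fs),
                 tolerance = 1e-4, label = fs)
  }
  expect_equal(monoisotopic_mass(chem_formula("H2O")), 18.0106, tolerance = 1e-4)
  expect_equal(monoisotopic_mass(chem_formula("C16H32O2")), 256.2402,
               tolerance = 1e-4)
  expect_error(monoisotopic_mass(chem_formula(c(Xx = 1))), "Xx")
})

test_that("free-acid formulas follow chain arithmetic", {
  expect_equal(format(acyl_formula(fatty_acyl(16, 0))), "C16H32O2")
  expect_equal(format(acyl_formula(fatty_acyl(18, 1))), "C18H34O2")
  expect_equal(format(acyl_formula(fatty_acyl(18, 0, 9))), "C18H36O3")
})

test_that("fatty acyl invariants are enforced", {
  expect_error(fatty_acyl(3), "carbon")
  expect_error(fatty_acyl(18, 17), "double bond")
  expect_error(fatty_acyl(18, 0, 1), "hydroxyl")
  expect_error(fatty_acyl(18, 0, 19), "hydroxyl")
})

test_that("esterification combines formulas with water loss", {
  r <- combine_esterify(fatty_acyl(16, 0), fatty_acyl(18, 0), 9)
  expect_equal(format(r$formula), "C34H66O4")
  expect_equal(r$family, "16:0-O-18:0")
  r5 <- combine_esterify(fatty_acyl(16, 0), fatty_acyl(18, 0), 5)
  expect_equal(r5$family, r$family)
  expect_false(r5$ester_position == r$ester_position)
  expect_error(combine_esterify(fatty_acyl(16, 0), fatty_acyl(18, 0), 0),
               "position")
  expect_error(combine_esterify(fatty_acyl(16, 0, 2), fatty_acyl(18, 0), 9),
               "hydroxyl")
})

test_that("shorthand parses, errors on junk, and round-trips", {
  fa <- parse_shorthand("18:0")
  expect_identical(unclass(fa), unclass(fatty_acyl(18, 0)))
  hfa <- parse_shorthand("9-OH-18:0")
  expect_identical(hfa$hydroxyl, 9L)
  fam <- parse_shorthand("FAHFA (16:0-O-18:0)")
  expect_equal(fam$family, "16:0-O-18:0")
  expect_true(is.na(fam$ester_position))
  pahsa <- parse_shorthand("9-PAHSA")
  expect_equal(pahsa$family, "16:0-O-18:0")
  expect_equal(pahsa$ester_position, 9L)
  reg <- parse_shorthand("16:0-O-9-OH-18:0")
  expect_equal(reg$ester_position, 9L)
  expect_error(parse_shorthand("16:0-O-banana"), "banana")
})

test_that("packaged registries hold 23 + 23 entries that round-trip", {
  fa <- default_fa_registry()
  hfa <- default_hfa_registry()
  expect_equal(nrow(fa), 23L)
  expect_equal(nrow(hfa), 23L)
  expect_true(all(is.na(fa$hydroxyl_position)))
  expect_true(all(!is.na(hfa$hydroxyl_position)))
  for (reg in list(fa, hfa)) {
    acyls <- registry_acyls(reg)
    for (i in seq_along(acyls)) {
      expect_equal(format(acyls[[i]]), reg$abbreviation[i])
      expect_identical(unclass(parse_shorthand(format(acyls[[i]]))),
                       unclass(acyls[[i]]))
    }
  }
  # registry masses agree with the independent oracle
  for (acyl in registry_acyls(hfa)) {
    fs <- format(acyl_formula(acyl))
    expect_equal(monoisotopic_mass(acyl_formula(acyl)), oracle_mass(fs),
                 tolerance = 1e-4, label = fs)
  }
})

test_that("esterification mass identity holds across registry pairs", {
  fas <- registry_acyls(default_fa_registry())
  hfas <- registry_acyls(default_hfa_registry())
  set.seed(11)
  for (k in 1:25) {
    fa <- fas[[sample(length(fas), 1)]]
    hfa <- hfas[[sample(length(hfas), 1)]]
    r <- combine_esterify(fa, hfa)
    expect_equal(
      monoisotopic_mass(r$formula),
      monoisotopic_mass(acyl_formula(fa)) +
        monoisotopic_mass(acyl_formula(hfa)) - 18.0106,
      tolerance = 1e-4
    )
  }
})

test_that("registry tables round-trip through TSV", {
  reg <- default_hfa_registry()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_registry(reg, path)
  expect_equal(read_registry(path), reg)
})
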