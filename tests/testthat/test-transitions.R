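# Combinatorial transition design, labeling mass rules, scheduling.

test_that("family enumeration is the deduplicated Cartesian product", {
  fam <- enumerate_families()
  expect_equal(nrow(fam), 529L)
  expect_false(any(duplicated(fam$family)))
  one <- enumerate_families(list(fatty_acyl(16, 0)), list(fatty_acyl(18, 0, 9)))
  expect_equal(one$family, "16:0-O-18:0")
  small <- enumerate_families(
    list(fatty_acyl(16, 0), fatty_acyl(18, 0)),
    list(fatty_acyl(14, 0, 9), fatty_acyl(16, 0, 9), fatty_acyl(18, 0, 9))
  )
  expect_equal(nrow(small), 6L)
  expect_equal(nrow(enumerate_families(list(), list(fatty_acyl(18, 0, 9)))), 0L)
  expect_error(enumerate_families(list(fatty_acyl(18, 0, 9)),
                                  list(fatty_acyl(18, 0, 9))),
               "non-hydroxylated")
})

test_that("labeling scheme masses follow the DMED chemistry", {
  sch <- default_labeling_schemes()
  expect_equal(sch$light$net_addition_mass, 70.0895, tolerance = 1e-4)
  expect_equal(sch$heavy$net_addition_mass - sch$light$net_addition_mass,
               4.0251, tolerance = 1e-4)
  expect_equal(sch$light$neutral_loss_mass, 63.0684, tolerance = 1e-4)
  expect_equal(sch$heavy$neutral_loss_mass, 67.0935, tolerance = 1e-4)
})

test_that("precursor and product m/z reproduce the labeled-ion arithmetic", {
  sch <- default_labeling_schemes()
  expect_equal(precursor_mz("16:0-O-18:0", sch$light), 609.5929, tolerance = 1e-3)
  expect_equal(precursor_mz("16:0-O-18:0", sch$heavy), 613.6180, tolerance = 1e-3)
  expect_equal(product_mz("16:0-O-18:0", sch$light), 308.2948, tolerance = 1e-3)
  expect_equal(product_mz("16:0-O-18:0", sch$heavy),
               product_mz("16:0-O-18:0", sch$light), tolerance = 1e-3)
  # product depends only on the HFA backbone
  expect_equal(product_mz("14:0-O-18:0", sch$light),
               product_mz("18:1-O-18:0", sch$light))
})

test_that("transition list has one light/heavy pair per family", {
  fam <- enumerate_families()
  tl <- build_transition_list(fam)
  expect_equal(nrow(tl), 1058L)
  expect_equal(nrow(tl), 2L * nrow(fam))
  expect_equal(unname(table(tl$channel)[c("light", "heavy")]),
               c(529L, 529L), ignore_attr = TRUE)
  expect_true(all(tl$polarity == "positive"))
  expect_true(all(tl$precursor_mz > tl$product_mz))
  expect_true(all(tl$product_mz > 50))
  # pairwise label mass relations across every family
  wide <- merge(tl[tl$channel == "light", ], tl[tl$channel == "heavy", ],
                by = "compound", suffixes = c("_l", "_h"))
  expect_equal(wide$precursor_mz_h - wide$precursor_mz_l,
               rep(4.0251, nrow(wide)), tolerance = 1e-3)
  expect_equal(wide$product_mz_h, wide$product_mz_l, tolerance = 1e-3)
  expect_equal(nrow(build_transition_list(fam[1, ])), 2L)
  expect_equal(nrow(build_transition_list(fam[0, ])), 0L)
})

test_that("scheduling partitions evenly with co-located pairs", {
  tl <- schedule_methods(build_transition_list(enumerate_families()))
  expect_equal(attr(tl, "n_methods"), 20L)
  expect_false(any(is.na(tl$method_index)))
  # partition: every transition scheduled exactly once
  expect_equal(nrow(tl), 1058L)
  # pair co-location
  by_fam <- tapply(tl$method_index, tl$compound, function(x) length(unique(x)))
  expect_true(all(by_fam == 1L))
  # evenness at pair granularity
  fam_per_method <- table(tl$method_index[tl$channel == "light"])
  expect_lte(max(fam_per_method) - min(fam_per_method), 1L)
  sizes <- table(tl$method_index)
  expect_true(all(sizes <= 54L))
  # small cases
  two <- schedule_methods(build_transition_list(enumerate_families(
    list(fatty_acyl(16, 0)), list(fatty_acyl(18, 0, 9)))), capacity = 53)
  expect_equal(attr(two, "n_methods"), 1L)
  expect_error(schedule_methods(tl, capacity = 1), "at least 2")
})

test_that("transition lists round-trip through CSV", {
  tl <- schedule_methods(build_transition_list(enumerate_families(
    list(fatty_acyl(16, 0), fatty_acyl(18, 1)),
    list(fatty_acyl(16, 0, 9), fatty_acyl(18, 0, 9))
  )))
  path <- withr::local_tempfile(fileext = ".csv")
  write_transition_list(tl, path)
  back <- read_transition_list(path)
  expect_equal(back, as.data.frame(tl), ignore_attr = TRUE)
})
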