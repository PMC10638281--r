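# RI-matching annotation, dataset compilation, dataset validation.

# candidates table with given measured RIs under a known calibration
cand_at_ri <- function(family, ri, cal, height = 1000) {
  data.frame(family = family, apex_rt = ri_to_rt(ri, cal),
             light_height = height, heavy_height = height,
             stringsAsFactors = FALSE)
}

pred_16 <- function() {
  data.frame(family = "16:0-O-16:0", hfa = "16:0", fa_carbon = 16L,
             ester_position = c(9L, 8L), predicted_ri = c(2608, 2637),
             stringsAsFactors = FALSE)
}

test_that("candidates match the nearest prediction within tolerance", {
  cal <- make_calibration()
  rec <- annotate_by_ri(cand_at_ri("16:0-O-16:0", 2610, cal), cal, pred_16(),
                        ri_tol = 10)
  expect_equal(rec$status, "identified")
  expect_equal(rec$ester_position, 9L)
  expect_equal(rec$ri_delta, 2, tolerance = 1e-9)
  far <- annotate_by_ri(cand_at_ri("16:0-O-16:0", 2700, cal), cal, pred_16(),
                        ri_tol = 10)
  expect_equal(far$status, "detected_only")
  none <- annotate_by_ri(cand_at_ri("12:0-O-12:0", 2610, cal), cal, pred_16(),
                         ri_tol = 10)
  expect_equal(none$status, "detected_only")
})

test_that("assignment is one-to-one within a family", {
  cal <- make_calibration()
  cand <- cand_at_ri(rep("16:0-O-16:0", 2), c(2610, 2604), cal)
  rec <- annotate_by_ri(cand, cal, pred_16(), ri_tol = 40)
  # 2610 sits closest to the 2608 prediction and wins position 9; the
  # displaced 2604 candidate falls back to the in-tolerance position 8
  expect_equal(rec$ester_position[rec$measured_ri > 2606], 9L)
  expect_equal(rec$ester_position[rec$measured_ri < 2606], 8L)
  expect_false(any(duplicated(paste(rec$family, rec$ester_position))))
})

test_that("annotation is idempotent and monotone in tolerance", {
  cal <- make_calibration()
  cand <- cand_at_ri(rep("16:0-O-16:0", 3), c(2604, 2611, 2660), cal)
  rec1 <- annotate_by_ri(cand, cal, pred_16(), ri_tol = 10)
  rec2 <- annotate_by_ri(rec1[names(cand)], cal, pred_16(), ri_tol = 10)
  expect_equal(rec1, rec2)
  frac <- vapply(c(2, 5, 10, 30, 60), function(tol) {
    mean(annotate_by_ri(cand, cal, pred_16(), ri_tol = tol)$status == "identified")
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
})

test_that("dataset compilation counts per sample and deduplicates globally", {
  cal <- make_calibration()
  pred <- pred_16()
  s1 <- annotate_by_ri(cand_at_ri(rep("16:0-O-16:0", 2), c(2608, 2637), cal),
                       cal, pred, ri_tol = 10)
  s2 <- annotate_by_ri(cand_at_ri("16:0-O-16:0", 2609, cal), cal, pred,
                       ri_tol = 10)
  sum3 <- compile_dataset(list(A = s1, B = s2, C = s1[0, ]))
  expect_equal(sum3$per_sample$n_regioisomers, c(2L, 1L, 0L))
  expect_equal(sum3$per_sample$n_families, c(1L, 1L, 0L))
  # the shared position-9 regioisomer is counted once globally
  expect_equal(sum3$global$n_regioisomers, 2L)
  expect_equal(sum3$global$n_families, 1L)
  expect_true(sum3$global$n_families <= sum3$global$n_regioisomers)
  expect_true(all(sum3$per_sample$n_families <= sum3$per_sample$n_regioisomers))
})

test_that("dataset validation recomputes counts and flags mismatches", {
  # synthetic stand-in for the published per-sample sheets
  sheet <- function(n, fams, ri0) {
    data.frame(`FAHFA ID` = rep(fams, length.out = n),
               `retention index` = ri0 + seq_len(n) * 30,
               check.names = FALSE)
  }
  detected <- list(
    "food A" = sheet(5, c("16:0-O-16:0", "18:0-O-16:0"), 2400),
    "food B" = sheet(3, "16:0-O-16:0", 2400)
  )
  rep1 <- validate_published_dataset(
    detected, identified = data.frame(name = letters[1:4]),
    # food A plants 3 + 2 distinct (family, RI) species, food B re-observes
    # two RI clusters of the first family and adds one new one: 6 globally
    reference = list(total_regioisomers = 6, total_families = 2,
                     per_sample = c("food B" = 3), identified_rows = 4)
  )
  expect_true(all(rep1$pass))
  rep2 <- validate_published_dataset(
    detected,
    reference = list(total_regioisomers = 99, total_families = 2,
                     per_sample = NULL, identified_rows = 0)
  )
  expect_false(rep2$pass[rep2$check == "total_regioisomers"])
  expect_error(
    validate_published_dataset(detected, required_samples = c("food A", "food C")),
    "food C"
  )
  # malformed rows are excluded and counted
  bad <- detected
  bad[["food A"]][["FAHFA ID"]][2] <- NA
  expect_message(
    rep3 <- validate_published_dataset(
      bad, reference = list(total_regioisomers = 5, total_families = 2,
                            per_sample = NULL, identified_rows = 0)),
    "malformed"
  )
  expect_equal(attr(rep3, "n_malformed"), 1L)
  expect_true(rep3$pass[rep3$check == "total_regioisomers"])
})
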