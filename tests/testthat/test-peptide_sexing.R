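panoria_areas <- read_peak_areas(fixture_path("panoria_peak_areas.tsv"))

test_that("peptide detection is inclusive at the cut-off", {
  expect_setequal(detect_peptides(make_row(x1 = 6.7e7, x2 = 3.9e7)), c("X1", "X2"))
  expect_length(detect_peptides(make_row()), 0)
  # boundary: an area exactly at its cut-off counts as detected
  expect_true("Y2" %in% detect_peptides(make_row(y2 = 1e6)))
  expect_false("Y2" %in% detect_peptides(make_row(y2 = 1e6 - 1)))
  # every peptide has its own threshold
  expect_setequal(detect_peptides(make_row(y1 = 1.5e5, y2 = 1e6, y3 = 1e5,
                                           x1 = 1.5e5, x2 = 1e6)),
                  c("Y1", "Y2", "Y3", "X1", "X2"))
})

test_that("X1/Y2 ratio is defined exactly when a Y2 area was recorded", {
  expect_equal(compute_xy_ratio(make_row(y2 = 13.4e7, x1 = 10.5e7)),
               10.5 / 13.4)
  expect_true(is.na(compute_xy_ratio(make_row(x1 = 5e7))))
  expect_equal(compute_xy_ratio(make_row(y2 = 2e6, x1 = 2e6)), 1.0)
})

test_that("single-sample classification follows the ordered decision rule", {
  # X only -> female
  f <- classify_peptide_sample(make_row(x1 = 6.7e7, x2 = 3.9e7))
  expect_equal(f$call, "female")
  expect_false(f$carryover_flag)

  # X and Y with near-equimolar ratio -> male
  m <- classify_peptide_sample(make_row(y1 = 6.6e7, y2 = 13.4e7, y3 = 1.7e7,
                                        x1 = 10.5e7, x2 = 5.4e7))
  expect_equal(m$call, "male")
  expect_equal(round(m$xy_ratio, 1), 0.8)
  expect_false(m$carryover_flag)

  # Y2 above cut-off but ratio far beyond 10/1 -> carryover female
  co <- classify_peptide_sample(make_row(y2 = 4.1e6, x1 = 20.1e7, x2 = 9.5e7))
  expect_equal(co$call, "female")
  expect_true(co$carryover_flag)
  expect_gt(co$xy_ratio, 10)

  # nothing detected -> indeterminate
  expect_equal(classify_peptide_sample(make_row())$call, "indeterminate")

  # direct rule-3 case: both above cut-off, ratio 0.5
  expect_equal(classify_peptide_sample(make_row(y2 = 2e6, x1 = 1e6))$call, "male")

  # Y via Y1 only (no Y2 area): male without the ratio check, QC-noted
  noy2 <- classify_peptide_sample(make_row(y1 = 2e5, x1 = 1e6))
  expect_equal(noy2$call, "male")
  expect_true(is.na(noy2$xy_ratio))
  expect_match(noy2$qc_note, "validation")
})

test_that("batch classification reproduces the bundled assemblage: 6 female, 1 male", {
  res <- classify_peptide_batch(panoria_areas)
  expect_equal(unname(res$summary), c(6, 1, 0))
  expect_equal(res$calls$call[res$calls$sample_id == "Panoria 3"], "male")
  expect_equal(res$calls$carryover_flag,
               panoria_areas$sample_id %in% c("Panoria 4", "Panoria 5"))
  # ratio reproduces the reported one-decimal value for the male sample
  expect_equal(round(res$calls$xy_ratio[res$calls$sample_id == "Panoria 3"], 1), 0.8)

  # empty input and determinism
  expect_equal(nrow(classify_peptide_batch(panoria_areas[0, ])$calls), 0)
  rep3 <- panoria_areas[rep(3, 7), ]
  rep3$sample_id <- paste0("r", 1:7)
  expect_equal(unname(classify_peptide_batch(rep3)$summary["male"]), 7)
})

test_that("calls are invariant under area rescaling that preserves detection", {
  set.seed(42)
  for (i in 1:50) {
    row <- make_row(y1 = sample(c(0, 1e6), 1), y2 = sample(c(0, 5e6, 2e8), 1),
                    y3 = 0, x1 = sample(c(0, 2e7), 1), x2 = sample(c(0, 3e7), 1))
    base <- classify_peptide_sample(row)
    for (k in c(2, 10)) {
      scaled <- row
      for (col in c("area_y1", "area_y2", "area_y3", "area_x1", "area_x2")) {
        scaled[[col]] <- scaled[[col]] * k
      }
      # scaling up never un-detects a peptide; the ratio is scale-free
      res <- classify_peptide_sample(scaled)
      if (identical(detect_peptides(scaled), detect_peptides(row))) {
        expect_equal(res$call, base$call)
        expect_equal(res$carryover_flag, base$carryover_flag)
      }
    }
  }
})

test_that("raising Y2 moves the call only along female -> carryover -> male", {
  x1 <- 2e7
  states <- vapply(c(0, 5e5, 1e6, 1.9e6, 2.1e6, 1e7, 5e7), function(y2) {
    r <- classify_peptide_sample(make_row(y2 = y2, x1 = x1, x2 = 3e7))
    paste0(r$call, ifelse(r$carryover_flag, "+carryover", ""))
  }, character(1))
  allowed_order <- c("female", "female+carryover", "male")
  idx <- match(states, allowed_order)
  expect_false(anyNA(idx))
  expect_true(all(diff(idx) >= 0))
})

test_that("every detection pattern receives exactly one call", {
  # enumerate all 32 on/off patterns of the five peptides
  big <- 1e8
  grid <- expand.grid(y1 = c(0, big), y2 = c(0, big), y3 = c(0, big),
                      x1 = c(0, big), x2 = c(0, big))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- classify_peptide_sample(make_row(g$y1, g$y2, g$y3, g$x1, g$x2))
    expect_true(res$call %in% c("female", "male", "indeterminate"))
    expect_length(res$call, 1)
    # rule table: no X -> indeterminate; X without Y -> female
    if (g$x1 == 0 && g$x2 == 0) expect_equal(res$call, "indeterminate")
    else if (g$y1 == 0 && g$y2 == 0 && g$y3 == 0) expect_equal(res$call, "female")
  }
})

test_that("reference transition list carries the five peptide definitions", {
  defs <- peptide_definitions()
  expect_equal(defs$precursor_mz[defs$peptide == "Y1"], 432.2257)
  expect_equal(defs$retention_time[defs$peptide == "Y1"], 1.59)
  expect_equal(nrow(defs), 5)
})
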