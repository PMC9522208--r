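test_that("elliptical area matches the circle, Monte Carlo and degenerate limits", {
  # circle of radius 1 mm
  expect_equal(elliptical_area(2, 2), pi / 100, tolerance = 1e-12)
  # 4 x 2 mm ellipse: hit-count oracle (1e7 uniform samples, seed 20250925)
  # gave 0.0628517 cm^2; the analytic value must agree to Monte Carlo error
  expect_equal(elliptical_area(4, 2), 0.0628517, tolerance = 1e-3)
  # degenerate limit: vanishing sagittal diameter
  expect_lt(elliptical_area(1, 1e-9), 1e-10)
})

test_that("elliptical area is symmetric, homogeneous of degree 2, and validates input", {
  set.seed(1)
  for (i in 1:20) {
    d1 <- runif(1, 0.01, 10); d2 <- runif(1, 0.01, 10); s <- runif(1, 0.1, 5)
    expect_equal(elliptical_area(d1, d2), elliptical_area(d2, d1))
    expect_equal(elliptical_area(s * d1, s * d2), s^2 * elliptical_area(d1, d2),
                 tolerance = 1e-12)
  }
  expect_error(elliptical_area(-1, 2), "d_transverse")
  expect_error(elliptical_area(1, 0), "d_sagittal")
  # the literal semi-axis reading inflates area exactly 4x
  expect_equal(elliptical_area(3, 2, literal_semi_axes = TRUE),
               4 * elliptical_area(3, 2))
})

test_that("derived morphometrics satisfy their defining identities", {
  # area 1 cm^2 (circle of diameter sqrt(400/pi) mm), depth 1 cm
  d <- sqrt(400 / pi)
  tab <- measurement_row("u", "spA", 1, "S", d, d, 10)
  m <- spiracle_morphometrics(tab)
  expect_equal(m$area_cm2, 1, tolerance = 1e-12)
  expect_equal(m$diff_index_cm, 1, tolerance = 1e-12)
  expect_equal(m$adv_index_cm3, 1, tolerance = 1e-12)

  # area 0.02 cm^2, depth 0.05 cm -> indices 0.4 cm and 0.008 cm^3
  d2 <- sqrt(4 * 2 / pi)  # 2 mm^2 circle
  tab2 <- measurement_row("h", "spA", 1, "T", d2, d2, 0.5)
  m2 <- spiracle_morphometrics(tab2)
  expect_equal(m2$diff_index_cm, 0.4, tolerance = 1e-12)
  expect_equal(m2$adv_index_cm3, 0.008, tolerance = 1e-12)

  # identities on a generated table, and homogeneity under diameter doubling
  gen <- generate_specimens(generator_config(seed = 5))
  g <- spiracle_morphometrics(gen)
  expect_equal(g$diff_index_cm * g$depth_cm, g$area_cm2, tolerance = 1e-12)
  expect_equal(g$adv_index_cm3 * g$depth_cm, g$area_cm2^2, tolerance = 1e-12)
  gen2 <- gen
  gen2$d_transverse_mm <- 2 * gen2$d_transverse_mm
  gen2$d_sagittal_mm <- 2 * gen2$d_sagittal_mm
  g2 <- spiracle_morphometrics(gen2)
  expect_equal(g2$area_cm2, 4 * g$area_cm2, tolerance = 1e-12)
  expect_equal(g2$diff_index_cm, 4 * g$diff_index_cm, tolerance = 1e-12)
  expect_equal(g2$adv_index_cm3, 16 * g$adv_index_cm3, tolerance = 1e-12)
})

test_that("specimen totals sum all eight spiracles and double for both sides", {
  # 8 identical spiracles with area 1 cm^2, depth 1 cm
  d <- sqrt(400 / pi)
  tab <- do.call(rbind, lapply(spiracle_labels(), function(lab)
    measurement_row("b1", "spA", 1, lab, d, d, 10)))
  tot <- specimen_totals(tab)
  expect_equal(tot$total_diff_cm, 16, tolerance = 1e-10)
  expect_equal(tot$total_adv_cm3, 16, tolerance = 1e-10)

  # mixed fixture against the brute-force oracle
  mixed <- complete_specimen()
  oracle <- totals_oracle(mixed)
  tm <- specimen_totals(mixed)
  expect_equal(tm$total_diff_cm, unname(oracle["diff"]), tolerance = 1e-12)
  expect_equal(tm$total_adv_cm3, unname(oracle["adv"]), tolerance = 1e-12)

  # duplicating a specimen's spiracles on a second specimen doubles the summed total
  two <- rbind(mixed, transform(mixed, specimen_id = "b2"))
  t2 <- specimen_totals(two)
  expect_equal(sum(t2$total_diff_cm), 2 * tm$total_diff_cm)
})

test_that("incomplete specimens are refused, listing missing labels, unless imputed", {
  tab <- complete_specimen("b1", "spA")
  part <- tab[tab$spiracle != "A3", ]
  expect_error(specimen_totals(part), "A3")
  # imputation borrows the conspecific mean for the missing label
  donor <- complete_specimen("b2", "spA", mass = 1)
  imp <- specimen_totals(rbind(part, donor), impute = TRUE)
  expect_equal(nrow(imp), 2)
  expect_equal(imp$total_diff_cm[imp$specimen_id == "b1"],
               imp$total_diff_cm[imp$specimen_id == "b2"], tolerance = 1e-12)
  # no conspecific donor -> hard error
  expect_error(specimen_totals(part, impute = TRUE), "no conspecific")
})

test_that("measurement table I/O round-trips and reports parse errors by row", {
  dir <- withr::local_tempdir()
  # empty table
  empty <- complete_specimen()[0, ]
  p0 <- file.path(dir, "empty.csv")
  write_measurement_table(empty, p0)
  expect_equal(nrow(read_measurement_table(p0)), 0)

  # one specimen, 8 rows
  p1 <- file.path(dir, "one.csv")
  write_measurement_table(complete_specimen(), p1)
  r1 <- read_measurement_table(p1)
  expect_equal(nrow(r1), 8)
  expect_equal(length(unique(r1$specimen_id)), 1)

  # synthetic 17-specimen table round-trips exactly (property, 3 seeds)
  for (s in 1:3) {
    tab <- generate_specimens(generator_config(seed = s))
    p <- file.path(dir, sprintf("t%d.csv", s))
    write_measurement_table(tab, p)
    back <- read_measurement_table(p)
    expect_equal(back, tab, tolerance = 1e-12)
  }

  # comment lines are ignored
  pc <- file.path(dir, "comment.csv")
  writeLines(c("# a comment", readLines(p1)), pc)
  expect_equal(nrow(read_measurement_table(pc)), 8)

  # unknown label, duplicate pair -> parse error with a row number
  bad <- complete_specimen(); bad$spiracle[3] <- "A9"
  pb <- file.path(dir, "bad.csv")
  utils::write.csv(bad, pb, row.names = FALSE, quote = FALSE)
  expect_error(read_measurement_table(pb), "row 3")
  dup <- complete_specimen(); dup$spiracle[2] <- "S"
  utils::write.csv(dup, pb, row.names = FALSE, quote = FALSE)
  expect_error(read_measurement_table(pb), "parse error")
  nn <- complete_specimen(); nn$depth_mm <- as.character(nn$depth_mm)
  nn$depth_mm[5] <- "deep"
  utils::write.csv(nn, pb, row.names = FALSE, quote = FALSE)
  expect_error(read_measurement_table(pb), "parse error")
})
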