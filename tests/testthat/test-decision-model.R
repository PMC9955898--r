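test_that("percentage banding follows half-open intervals with a closed last band", {
  pb <- percentage_bands()
  expect_equal(band_value(c(94.1, 86, 99.9, 95, 100, 70, 89.99), pb),
               c("H", "M", "VH", "VH", "VH", "L", "M"))
  err <- expect_error(band_value(65, pb), class = "fprom_error_input")
  expect_match(conditionMessage(err), "65")
  expect_error(band_value(100.01, pb), class = "fprom_error_input")
  # order preservation: larger values never map to a lower-ordered term
  set.seed(21)
  x <- sort(runif(200, 70, 100))
  idx <- match(band_value(x, pb), default_scale()$term) # scale order: highest first
  expect_true(all(diff(idx) <= 0))
  expect_error(bands(c(0, 5), c(10, 15), c("A", "B")), class = "fprom_error_input")
})

test_that("crisp evaluation defuzzifies terms, passes raw values through, and bands on demand", {
  df <- data.frame(alternative = c("a", "b"), metric = c("H", "M"))
  dm <- decision_matrix(df, aim = "max", weight = "VH")
  expect_equal(crisp_values(dm, "linguistic")$metric, c(0.75, 0.5))

  df2 <- data.frame(alternative = c("a", "b"), metric = c(94.1, 81.2))
  dm2 <- decision_matrix(df2, aim = "max", weight = "VH",
                         banding = percentage_bands())
  expect_equal(crisp_values(dm2, "raw")$metric, c(94.1, 81.2))
  # raw 94.1 -> band H -> centroid 0.75
  expect_equal(crisp_values(dm2, "linguistic")$metric, c(0.75, 0.5))

  dm3 <- decision_matrix(df2, aim = "max", weight = "VH")
  err <- expect_error(crisp_values(dm3, "linguistic"), class = "fprom_error_input")
  expect_match(conditionMessage(err), "a")
  expect_match(conditionMessage(err), "metric")
  expect_match(conditionMessage(err), "linguistic")
  dm4 <- decision_matrix(df, aim = "max", weight = "VH")
  expect_error(crisp_values(dm4, "raw"), class = "fprom_error_input")
})

test_that("the bundled fixture disagrees with its own banding rule in exactly 6 cells", {
  dm <- load_fixture("brain_tumor_linguistic")
  audit <- validate_labels(dm, banding = fixture_banding(dm))
  expect_equal(nrow(audit), 6L)
  expect_equal(attr(audit, "n_checked"), 54L) # all cells carry value + term
  got <- audit |> dplyr::arrange(alternative, criterion)
  expected <- tibble::tribble(
    ~alternative, ~criterion,    ~value, ~printed, ~banded,
    "CNN",         "sensitivity",  95,    "H",      "VH",
    "CNN VGG19",   "sensitivity",  95.2,  "H",      "VH",
    "CNN VGG19",   "specificity",  94.69, "VH",     "H",
    "GoogLeNet",   "precision",    95.78, "H",      "VH",
    "RF",          "specificity",  95.23, "H",      "VH",
    "SVM",         "sensitivity",  95.02, "H",      "VH"
  ) |> dplyr::arrange(alternative, criterion)
  expect_equal(as.data.frame(got), as.data.frame(expected), ignore_attr = TRUE)
})

test_that("matrices whose terms came from banding audit clean; term-only cells are skipped", {
  dm <- simulate_decision_matrix(seed = 5)
  audit <- validate_labels(dm)
  expect_equal(nrow(audit), 0L)
  expect_gt(attr(audit, "n_checked"), 0L)

  dm_terms <- term_dm(matrix(c("H", "M", "L", "VL"), 2, 2), c("max", "max"), c("H", "H"))
  audit2 <- validate_labels(dm_terms)
  expect_equal(attr(audit2, "n_checked"), 0L)
  expect_equal(attr(audit2, "n_skipped"), 4L)

  # single lower-boundary cell is consistent
  df <- data.frame(alternative = c("a", "b"), m = c("70|L", "71|L"))
  dm_edge <- decision_matrix(df, aim = "max", weight = "H",
                             banding = percentage_bands())
  expect_equal(nrow(validate_labels(dm_edge)), 0L)
})

test_that("decision matrices round-trip exactly through the CSV dialect", {
  dm <- load_fixture("brain_tumor_linguistic")
  path <- withr::local_tempfile(fileext = ".csv")
  write_decision_csv(dm, path)
  expect_equal(read_decision_csv(path), dm)

  dm2 <- simulate_decision_matrix(seed = 9, plant_duplicate = TRUE)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_decision_csv(dm2, path2)
  back <- read_decision_csv(path2)
  expect_equal(back, dm2, ignore_attr = FALSE)
  expect_equal(attr(back, "seed"), 9L)

  # explicit thresholds survive the round trip
  dm3 <- raw_dm(matrix(c(1, 2, 3, 4), 2, 2), c("max", "min"), c(0.6, 0.4),
                pf = c("linear", "gaussian"), q = c(0.1, NA), p = c(0.9, NA),
                s = c(NA, 0.25))
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_decision_csv(dm3, path3)
  expect_equal(read_decision_csv(path3), dm3)
})

test_that("constructor enforces the matrix invariants", {
  one_row <- data.frame(alternative = "a", x = "H")
  expect_error(decision_matrix(one_row, "max", "H"), class = "fprom_error_input")
  two <- data.frame(alternative = c("a", "b"), x = c("H", "M"))
  expect_error(decision_matrix(two, "upwards", "H"), class = "fprom_error_input")
  expect_error(decision_matrix(two, "max", "0"), class = "fprom_error_input")
  expect_error(decision_matrix(two, "max", "sideways"), class = "fprom_error_input")
  expect_error(
    decision_matrix(data.frame(alternative = c("a", "b"), x = c("", "H")), "max", "H"),
    class = "fprom_error_input"
  )
  expect_error(
    decision_matrix(data.frame(alternative = c("a", "a"), x = c("H", "M")), "max", "H"),
    class = "fprom_error_input"
  )
  # weights given as numbers or terms both land in weight_crisp
  dm <- decision_matrix(two, "max", "0.37")
  expect_equal(criteria(dm)$weight_crisp, 0.37)
  expect_true(is.na(criteria(dm)$weight_term))
})
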