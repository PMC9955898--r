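test_that("pairwise deviations respect the aim direction", {
  dm <- load_fixture("brain_tumor_linguistic")
  dev <- deviations(dm)
  pick <- function(a, b, crit) {
    dev |> dplyr::filter(a == !!a, b == !!b, criterion == crit) |> dplyr::pull(deviation)
  }
  expect_equal(pick("SVM", "KNN", "accuracy"), 0)
  # VH vs H centroids: 0.9167 - 0.75
  expect_equal(pick("CNN", "RF", "recall"), 2.75 / 3 - 0.75, tolerance = 1e-12)
  # processing time is a min criterion: L beats M, sign flips to +0.25
  expect_equal(pick("CNN", "SVM", "processing_time"), 0.25, tolerance = 1e-12)
  expect_equal(pick("SVM", "CNN", "processing_time"), -0.25, tolerance = 1e-12)
})

test_that("the preference-function catalogue matches its closed forms", {
  # no preference without a positive deviation, for every kind
  expect_equal(preference_degree(c(-0.3, 0), "usual"), c(0, 0))
  expect_equal(preference_degree(c(-0.3, 0), "gaussian", s = 0.4), c(0, 0))
  expect_equal(preference_degree(c(-1, 0), "v_shape", p = 1), c(0, 0))

  expect_equal(preference_degree(0.2, "usual"), 1)
  expect_equal(preference_degree(c(0.05, 0.2), "u_shape", q = 0.1), c(0, 1))
  expect_equal(preference_degree(c(0.5, 2), "v_shape", p = 1), c(0.5, 1))
  expect_equal(preference_degree(c(0.05, 0.3, 0.9), "level", q = 0.1, p = 0.5),
               c(0, 0.5, 1))
  expect_equal(preference_degree(c(0.1, 0.3, 0.9), "linear", q = 0.1, p = 0.5),
               c(0, 0.5, 1))
  # gaussian hits 1 - e^(-1/2) exactly at d = s
  for (s in c(0.1, 0.37, 2)) {
    expect_equal(preference_degree(s, "gaussian", s = s), 1 - exp(-0.5), tolerance = 1e-12)
  }
  # degenerate s = 0 contributes nothing
  expect_equal(preference_degree(c(0.2, 5), "gaussian", s = 0), c(0, 0))

  expect_error(preference_degree(0.1, "linear", q = 0.5, p = 0.5),
               class = "fprom_error_input")
  expect_error(preference_degree(0.1, "v_shape"), class = "fprom_error_input")
  expect_error(preference_degree(0.1, "level", q = 0.6, p = 0.2),
               class = "fprom_error_input")
})

test_that("aggregated preference is the weight-normalised mean of criterion preferences", {
  # identical profiles never generate preference
  dm_id <- term_dm(matrix(c("H", "H", "M", "M"), 2, 2), c("max", "max"), c("VH", "H"))
  expect_equal(aggregated_preference(dm_id, "a01", "a02"), 0)

  # full preference on every criterion saturates at 1
  dm_dom <- term_dm(matrix(c("VH", "L", "VH", "L"), 2, 2), c("max", "max"),
                    c("VH", "H"), pf = "usual")
  expect_equal(aggregated_preference(dm_dom, "a01", "a02"), 1)

  # two criteria, weights 0.92 / 0.75, P = (0.4, 0): 0.92*0.4 / 1.67
  dm_hand <- raw_dm(matrix(c(0.4, 0, 0, 0), 2, 2), c("max", "max"),
                    c(0.92, 0.75), pf = "v_shape", p = 1)
  expect_equal(aggregated_preference(dm_hand, "a01", "a02", mode = "raw"),
               0.92 * 0.4 / 1.67, tolerance = 1e-12)
  expect_error(aggregated_preference(dm_hand, "a01", "nobody", mode = "raw"),
               class = "fprom_error_input")
})

test_that("flows on the bundled fixture: CNN first, SVM/KNN an exact tie, flows conserved", {
  dm <- load_fixture("brain_tumor_linguistic")
  fl <- promethee_flows(dm)
  td <- tidy(fl)
  expect_equal(td$rank[td$alternative == "CNN"], 1L)
  svm <- td[td$alternative == "SVM", ]
  knn <- td[td$alternative == "KNN", ]
  expect_identical(svm$phi_plus, knn$phi_plus)
  expect_identical(svm$phi_minus, knn$phi_minus)
  expect_identical(svm$net_flow, knn$net_flow)
  expect_equal(svm$rank, knn$rank)
  expect_true(any(purrr::map_lgl(fl$tie_groups,
                                 function(g) setequal(g, c("SVM", "KNN")))))
  expect_lt(abs(sum(td$net_flow)), 1e-9)
  expect_true(all(td$phi_plus >= 0 & td$phi_plus <= 1))
  expect_true(all(td$phi_minus >= 0 & td$phi_minus <= 1))
  expect_equal(td$net_flow, td$phi_plus - td$phi_minus)

  # two identical alternatives: zero flows, one tie group
  dm2 <- term_dm(matrix(c("H", "H", "M", "M"), 2, 2), c("max", "min"), c("VH", "H"))
  fl2 <- promethee_flows(dm2)
  expect_equal(tidy(fl2)$net_flow, c(0, 0))
  expect_equal(length(fl2$tie_groups), 1L)
  expect_equal(tidy(fl2)$rank, c(1L, 1L))
})

test_that("competition ranking groups ties and skips ranks", {
  expect_equal(rank_complete(c(0.3, 0.1, 0.1, -0.5)), c(1L, 2L, 2L, 4L))
  expect_equal(rank_complete(rep(0.2, 5)), rep(1L, 5))
  set.seed(31)
  for (i in 1:20) {
    net <- runif(7)
    expect_equal(sort(rank_complete(net)), 1:7) # distinct flows: a permutation
  }
  # near-ties within tolerance collapse
  expect_equal(rank_complete(c(0.5, 0.5 - 1e-12, 0.1)), c(1L, 1L, 3L))
})

test_that("flows match an independent brute-force oracle on small random matrices", {
  set.seed(41)
  for (i in 1:40) {
    n <- sample(2:4, 1)
    k <- sample(1:3, 1)
    E <- matrix(runif(n * k, 0, 10), n, k)
    aims <- sample(c("max", "min"), k, replace = TRUE)
    w <- runif(k, 0.1, 1)
    dm <- raw_dm(E, aims, w)
    fl <- tidy(promethee_flows(dm, mode = "raw"))
    ref <- oracle_flows(E, aims, w)
    expect_equal(fl$phi_plus, ref$phi_plus, tolerance = 1e-12)
    expect_equal(fl$phi_minus, ref$phi_minus, tolerance = 1e-12)
    expect_equal(fl$net_flow, ref$net, tolerance = 1e-12)
  }
})

test_that("flows are conserved, permutation-invariant, and weight-scale-invariant", {
  set.seed(51)
  for (i in 1:10) {
    dm <- simulate_decision_matrix(n_alternatives = sample(3:8, 1),
                                   n_criteria = sample(2:6, 1),
                                   seed = sample.int(1e6, 1))
    fl <- tidy(promethee_flows(dm, mode = "raw"))
    expect_lt(abs(sum(fl$net_flow)), 1e-9)

    # shuffling alternatives only reorders the report
    perm <- sample(n_alternatives(dm))
    df <- cbind(data.frame(alternative = alternatives(dm)[perm]),
                as.data.frame(unname(dm$raw[perm, , drop = FALSE])))
    names(df)[-1] <- criteria(dm)$name
    dm_perm <- decision_matrix(df, aim = criteria(dm)$aim,
                               weight = criteria(dm)$weight_crisp)
    fl_perm <- tidy(promethee_flows(dm_perm, mode = "raw"))
    merged <- dplyr::inner_join(fl, fl_perm, by = "alternative")
    expect_equal(merged$net_flow.x, merged$net_flow.y, tolerance = 1e-12)
    expect_equal(merged$rank.x, merged$rank.y)

    # scaling all weights leaves everything unchanged
    dm_scaled <- dm
    for (cn in criteria(dm)$name) {
      dm_scaled <- set_weight(dm_scaled, cn, criteria(dm_scaled)$weight_crisp[
        match(cn, criteria(dm_scaled)$name)] * 7.3)
    }
    expect_equal(tidy(promethee_flows(dm_scaled, mode = "raw")), fl, tolerance = 1e-12)
  }
})

test_that("gaussian flows vanish as s grows and approach the usual criterion as s shrinks", {
  set.seed(61)
  E <- matrix(round(runif(12, 0, 10), 2), 4, 3)
  aims <- c("max", "min", "max")
  w <- c(0.5, 0.3, 0.2)
  dm_g <- raw_dm(E, aims, w)
  huge <- tidy(promethee_flows(dm_g, mode = "raw", s = 1e6))
  expect_lt(max(abs(huge$net_flow)), 1e-9)
  tiny <- tidy(promethee_flows(dm_g, mode = "raw", s = 1e-6))
  dm_u <- raw_dm(E, aims, w, pf = "usual")
  usual <- tidy(promethee_flows(dm_u, mode = "raw"))
  expect_equal(tiny$net_flow, usual$net_flow, tolerance = 1e-9)
  expect_equal(tiny$rank, usual$rank)
})
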