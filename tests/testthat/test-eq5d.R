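# inline model/value-set builders keep these tests independent of fixtures
flat_model <- function(eta2 = 0, eta3 = 0) {
  dims <- c(
    "mobility", "self_care", "usual_activities",
    "pain_discomfort", "anxiety_depression"
  )
  structure(
    list(
      name = "inline",
      dimensions = stats::setNames(
        lapply(dims, function(d) {
          list(
            "2" = c("(Intercept)" = eta2),
            "3" = c("(Intercept)" = eta3)
          )
        }),
        dims
      )
    ),
    class = "mapping_model"
  )
}

make_value_set <- function(anchor = 1, any_dys = 0, any_l3 = 0, dec2 = 0.1, dec3 = 0.3) {
  dims <- c(
    "mobility", "self_care", "usual_activities",
    "pain_discomfort", "anxiety_depression"
  )
  dec <- matrix(c(rep(dec2, 5), rep(dec3, 5)),
    ncol = 2,
    dimnames = list(dims, c("2", "3"))
  )
  structure(
    list(
      name = "inline", anchor = anchor,
      any_dysfunction = any_dys, any_level3 = any_l3,
      decrements = dec
    ),
    class = "value_set"
  )
}

test_that("all-zero coefficients give uniform response probabilities", {
  sc <- score_qlq_items(c(rep(2, 28), 4, 4))
  dist <- map_scores_to_response_probs(sc, flat_model())
  expect_equal(dist$p1, rep(1 / 3, 5), tolerance = 1e-12)
  expect_equal(dist$p2, rep(1 / 3, 5), tolerance = 1e-12)
  expect_equal(dist$p3, rep(1 / 3, 5), tolerance = 1e-12)
})

test_that("eta = (0, log 2, 0) gives probabilities (0.25, 0.5, 0.25)", {
  dist <- map_scores_to_response_probs(
    score_qlq_items(c(rep(1, 28), 7, 7)),
    flat_model(eta2 = log(2), eta3 = 0)
  )
  expect_equal(dist$p1, rep(0.25, 5), tolerance = 1e-12)
  expect_equal(dist$p2, rep(0.50, 5), tolerance = 1e-12)
  expect_equal(dist$p3, rep(0.25, 5), tolerance = 1e-12)
})

test_that("response probabilities are normalized for random score vectors", {
  set.seed(7)
  model <- read_mapping_model()
  n <- 1000
  scores <- tibble::as_tibble(
    stats::setNames(
      lapply(qlq_dimensions()$dimension, function(d) runif(n, 0, 100)),
      qlq_dimensions()$dimension
    )
  )
  dist <- map_scores_to_response_probs(scores, model)
  sums <- dist$p1 + dist$p2 + dist$p3
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(dist$p1 >= 0 & dist$p2 >= 0 & dist$p3 >= 0))
})

test_that("a degenerate distribution at full health returns the anchor", {
  vs <- make_value_set(anchor = 1.0, any_dys = 0.081, any_l3 = 0.269)
  dist <- tibble::tibble(
    .row = 1L,
    dimension = c(
      "mobility", "self_care", "usual_activities",
      "pain_discomfort", "anxiety_depression"
    ),
    p1 = 1, p2 = 0, p3 = 0
  )
  expect_equal(expected_utility(dist, vs), 1.0)
  expect_equal(expected_utility(dist, vs, rule = "modal"), 1.0)
})

test_that("expected utility is linear over mixtures for additive value sets", {
  # 50/50 mixture of 11111 (utility 1.0) and the profile with all level 2
  # under a value set where the level-2 decrements sum to 0.5 and there are
  # no extra terms -> expectation 0.75
  vs <- make_value_set(anchor = 1, dec2 = 0.1, dec3 = 0.3)
  expect_equal(profile_utility(rep(2, 5), vs), 0.5)
  dist <- tibble::tibble(
    .row = 1L,
    dimension = rownames(vs$decrements),
    p1 = 0.5, p2 = 0.5, p3 = 0
  )
  expect_equal(expected_utility(dist, vs), 0.75, tolerance = 1e-12)
})

test_that("increasing a decrement never increases EQ-5DP", {
  set.seed(12)
  model <- read_mapping_model()
  vs1 <- read_value_set()
  vs2 <- vs1
  vs2$decrements["pain_discomfort", "3"] <- vs2$decrements["pain_discomfort", "3"] + 0.1
  scores <- tibble::as_tibble(
    stats::setNames(
      lapply(qlq_dimensions()$dimension, function(d) runif(50, 0, 100)),
      qlq_dimensions()$dimension
    )
  )
  dist <- map_scores_to_response_probs(scores, model)
  expect_true(all(expected_utility(dist, vs2) <= expected_utility(dist, vs1) + 1e-12))
})

test_that("profile utilities match the tabulated British tariff", {
  vs <- read_value_set()
  expect_equal(profile_utility(c(1, 1, 1, 1, 1), vs), 1.0)
  # one level-2 movement: anchor - any_dysfunction - dimension decrement
  expect_equal(profile_utility(c(2, 1, 1, 1, 1), vs), 1 - 0.081 - 0.069)
  # worst state: floor of the British tariff
  expect_equal(profile_utility(rep(3, 5), vs), -0.594, tolerance = 1e-12)
})

test_that("swapping value sets changes utilities but not response distributions", {
  model <- read_mapping_model()
  sc <- score_qlq_items(c(rep(2, 28), 5, 5))
  d1 <- map_scores_to_response_probs(sc, model)
  uk <- read_value_set()
  se <- read_value_set(
    system.file("extdata", "value_set_swedish_style_synthetic.tsv",
      package = "eprocua"
    )
  )
  d2 <- map_scores_to_response_probs(sc, model)
  expect_equal(d1, d2)
  u_uk <- expected_utility(d1, uk)
  u_se <- expected_utility(d1, se)
  expect_false(isTRUE(all.equal(u_uk, u_se)))
})

test_that("EQ-5DP is bounded by the value set's range", {
  set.seed(5)
  model <- read_mapping_model()
  vs <- read_value_set()
  scores <- tibble::as_tibble(
    stats::setNames(
      lapply(qlq_dimensions()$dimension, function(d) runif(200, 0, 100)),
      qlq_dimensions()$dimension
    )
  )
  u <- eq5dp(scores, model, vs)
  expect_true(all(u <= vs$anchor + 1e-12))
  expect_true(all(u >= profile_utility(rep(3, 5), vs) - 1e-12))
})

test_that("missing scores at mapping time are rejected", {
  sc <- score_qlq_items(c(rep(2, 28), 4, 4))
  sc$pf <- NA_real_
  expect_error(
    map_scores_to_response_probs(sc, read_mapping_model()),
    class = "eprocua_validation_error"
  )
})

test_that("eq5dp_change follows the after-minus-before convention", {
  expect_equal(eq5dp_change(0.86, 0.84), -0.02)
  expect_equal(eq5dp_change(0.5, 0.5), 0)
  expect_equal(eq5dp_change(0.89, 0.88), -0.01)
})
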