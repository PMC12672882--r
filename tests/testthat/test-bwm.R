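test_that("questionnaire validation enforces the 1-9 scale invariants", {
  ok <- bwm_questionnaire("e1", c("c1", "c2", "c3"), best = 1, worst = 3,
                          best_to_others = c(1, 2, 4),
                          others_to_worst = c(4, 2, 1))
  expect_identical(validate_questionnaire(ok), ok)

  bad_scale <- bwm_questionnaire("e2", c("c1", "c2", "c3"), 1, 3,
                                 c(1, 2, 10), c(10, 5, 1))
  expect_error(validate_questionnaire(bad_scale), "scale violation")

  bad_dom <- bwm_questionnaire("e3", c("c1", "c2", "c3"), 1, 3,
                               c(1, 2, 4), c(5, 2, 1))
  expect_error(validate_questionnaire(bad_dom), "dominance violation")

  bad_desig <- bwm_questionnaire("e4", c("c1", "c2"), 1, 1, c(1, 3), c(3, 1))
  expect_error(validate_questionnaire(bad_desig), "designation|dominance")

  frac <- bwm_questionnaire("e5", c("c1", "c2", "c3"), 1, 3,
                            c(1, 2.5, 5), c(5, 2, 1))
  expect_error(validate_questionnaire(frac), "scale violation")
  expect_silent(validate_questionnaire(frac, strict = FALSE))
})

test_that("perfectly consistent ratios solve to exact weights with xi = 0", {
  q <- bwm_questionnaire("e1", c("c1", "c2", "c3"), 1, 3,
                         c(1, 2, 4), c(4, 2, 1))
  s <- solve_bwm(q)
  expect_equal(s$weights, c(4, 2, 1) / 7, tolerance = 1e-9)
  expect_lt(s$xi, 1e-9)
  expect_equal(sum(s$weights), 1, tolerance = 1e-9)

  q2 <- bwm_questionnaire("e2", c("c1", "c2"), 1, 2, c(1, 5), c(5, 1))
  s2 <- solve_bwm(q2)
  expect_equal(s2$weights, c(5 / 6, 1 / 6), tolerance = 1e-9)
  expect_lt(s2$xi, 1e-9)
})

test_that("inconsistent questionnaire matches the frozen grid-oracle optimum", {
  # oracle values computed independently by dense two-stage simplex grid
  # search (step 1e-4): w = (38, 12, 5)/55, xi = 2/55
  q <- bwm_questionnaire("e1", c("c1", "c2", "c3"), 1, 3,
                         c(1, 3, 8), c(8, 2, 1))
  s <- solve_bwm(q)
  expect_equal(s$xi, 2 / 55, tolerance = 1e-6)
  expect_equal(s$weights, c(38, 12, 5) / 55, tolerance = 1e-6)
})

test_that("LP objective agrees with the simplex-grid oracle on random n=3 cases", {
  set.seed(11)
  for (i in 1:10) {
    q <- random_questionnaire_n3(paste0("e", i))
    s <- solve_bwm(q)
    o <- grid_oracle_bwm(q$best_to_others, q$others_to_worst,
                         q$best_index, q$worst_index)
    expect_lt(abs(s$xi - o$xi), 1e-3,
              label = sprintf("|xi - oracle| for aB=(%s) aW=(%s)",
                              toString(q$best_to_others),
                              toString(q$others_to_worst)))
  }
})

test_that("consistency implies exact weight recovery (real-valued ratios)", {
  set.seed(7)
  for (i in 1:12) {
    w <- random_representable_weights(sample(3:6, 1))
    q <- consistent_questionnaire(w)
    validate_questionnaire(q, strict = FALSE)
    s <- solve_bwm(q)
    expect_lt(s$xi, 1e-6)
    expect_equal(s$weights, w, tolerance = 1e-6)
  }
})

test_that("consistency filter retains xi <= threshold inclusively", {
  mk <- function(id, xi) structure(list(expert_id = id, criteria = "c",
                                        weights = 1, xi = xi,
                                        degenerate = FALSE, retained = NA),
                                   class = "bwm_solution")
  sols <- Map(mk, paste0("e", 1:4), c(0, 0.05, 0.1, 0.11))
  f <- consistency_filter(sols, 0.1)
  expect_identical(vapply(f$retained, `[[`, character(1), "expert_id"),
                   c("e1", "e2", "e3"))
  expect_identical(vapply(f$excluded, `[[`, character(1), "expert_id"), "e4")
  expect_true(all(vapply(f$retained, `[[`, logical(1), "retained")))
  expect_false(any(vapply(f$excluded, `[[`, logical(1), "retained")))

  # 23-expert panel with 10 inconsistent members retains 13
  set.seed(3)
  xis <- c(runif(13, 0, 0.1), runif(10, 0.10001, 0.5))
  panel <- Map(mk, paste0("x", 1:23), sample(xis))
  f23 <- consistency_filter(panel, 0.1)
  expect_length(f23$retained, 13)
  expect_length(f23$excluded, 10)

  # partition depends on xi alone: permuting inputs permutes outputs
  perm <- sample(23)
  fp <- consistency_filter(panel[perm], 0.1)
  expect_setequal(vapply(fp$retained, `[[`, character(1), "expert_id"),
                  vapply(f23$retained, `[[`, character(1), "expert_id"))

  expect_identical(consistency_filter(list(), 0.1),
                   list(retained = list(), excluded = list()))
  expect_warning(consistency_filter(list(mk("e", 0.5)), 0.1), "no expert")
})

test_that("weight aggregation averages, renormalizes and stays in bounds", {
  a <- weight_scheme(c("c1", "c2"), c(0.6, 0.4))
  b <- weight_scheme(c("c1", "c2"), c(0.4, 0.6))
  expect_equal(aggregate_weights(list(a, a))$weights, a$weights)
  expect_equal(aggregate_weights(list(a, b))$weights, c(0.5, 0.5))
  expect_match(aggregate_weights(list(a, b))$source, "aggregate-of-2")

  set.seed(5)
  schemes <- lapply(1:6, function(i)
    weight_scheme(paste0("c", 1:4), random_representable_weights(4)))
  agg <- aggregate_weights(schemes)
  mat <- sapply(schemes, `[[`, "weights")
  expect_true(all(agg$weights >= apply(mat, 1, min) - 1e-12))
  expect_true(all(agg$weights <= apply(mat, 1, max) + 1e-12))
  expect_equal(sum(agg$weights), 1, tolerance = 1e-12)

  flipped <- weight_scheme(c("c2", "c1"), c(0.4, 0.6))
  expect_error(aggregate_weights(list(a, flipped)), "mismatch")
  expect_error(aggregate_weights(list()), "no weight schemes")

  geo <- aggregate_weights(list(a, b), method = "geometric")
  expect_equal(geo$weights[1], geo$weights[2], tolerance = 1e-12)
})

test_that("weight schemes renormalize rounded percentages within the gate", {
  ws <- weight_scheme(c("a", "b"), c(0.505, 0.5))
  expect_equal(sum(ws$weights), 1, tolerance = 1e-12)
  expect_error(weight_scheme(c("a", "b"), c(0.7, 0.4)), "0.99")
})
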