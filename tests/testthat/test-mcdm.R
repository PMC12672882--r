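random_weighted_gaps <- function(nalt, ncrit) {
  w <- weight_scheme(paste0("c", 1:ncrit), random_representable_weights(ncrit))
  r <- matrix(runif(nalt * ncrit), nalt, ncrit,
              dimnames = list(paste0("p", 1:nalt), w$criteria))
  weighted_gaps(r, w)
}

test_that("modified VIKOR synthesizes S, R and V from weighted gaps", {
  fx <- load_fixtures()
  vik <- modified_vikor(fx$gaps_trusted, delta = 0.5)
  v5 <- vik$V[vik$alternative == "5"]
  expect_equal(vik$S[vik$alternative == "5"], 0.262, tolerance = 1e-9)
  expect_equal(vik$R[vik$alternative == "5"], 0.055, tolerance = 1e-9)
  expect_equal(round(v5, 3), 0.158)
  expect_equal(round(vik$V[vik$alternative == "3"], 3), 0.184)

  # gap-free alternative sits exactly at the aspiration point
  w <- weight_scheme(c("c1", "c2"), c(0.4, 0.6))
  g0 <- weighted_gaps(matrix(0, 1, 2, dimnames = list("p", c("c1", "c2"))), w)
  v0 <- modified_vikor(g0)
  expect_equal(c(v0$S, v0$R, v0$V), c(0, 0, 0))

  # improvement priorities are the gaps in descending order
  pri <- attr(vik, "priorities")[["5"]]
  expect_equal(unname(pri), sort(as.numeric(fx$gaps_trusted["5", ]),
                                 decreasing = TRUE))
  expect_equal(names(pri)[1], "Amenities")
})

test_that("S, R and V satisfy their structural invariants on random matrices", {
  set.seed(21)
  for (i in 1:8) {
    g <- random_weighted_gaps(sample(3:9, 1), sample(3:8, 1))
    d <- runif(1)
    vik <- modified_vikor(g, delta = d)
    expect_equal(vik$S, unname(rowSums(g)), tolerance = 1e-12)
    expect_true(all(vik$R <= vik$S + 1e-12))
    expect_equal(vik$V, d * vik$S + (1 - d) * vik$R, tolerance = 1e-12)
    expect_true(all(vik$V >= 0 & vik$V <= 1))
    # V is monotone non-decreasing in every gap cell
    gm <- unclass(g)
    k <- sample(nrow(gm), 1); j <- sample(ncol(gm), 1)
    w <- attr(g, "weight_scheme")
    gm[k, j] <- min(gm[k, j] + 0.01, w$weights[j])
    vik2 <- modified_vikor(as_weighted_gaps(gm, w), delta = d)
    expect_gte(vik2$V[k] + 1e-12, vik$V[k])
  }
})

test_that("the unweighted regret convention maximizes raw gaps instead", {
  fx <- load_fixtures()
  vik <- modified_vikor(fx$gaps_trusted, regret = "unweighted")
  raw <- recover_gaps(fx$gaps_trusted)
  expect_equal(vik$R, unname(apply(unclass(raw), 1, max)), tolerance = 1e-12)
  expect_gt(vik$V[vik$alternative == "5"], 0.25) # far from the printed 0.158
})

test_that("classical VIKOR interpolates between the sample extremes", {
  Q <- classical_vikor(S = c(0.2, 0.3, 0.4), R = c(0.05, 0.10, 0.15))
  expect_equal(unname(Q$values), c(0, 0.5, 1))
  expect_identical(Q$orientation, "gap")
  # degenerate regret term contributes zero
  Qd <- classical_vikor(S = c(0.2, 0.4), R = c(0.1, 0.1))
  expect_equal(unname(Qd$values), c(0, 0.5))
  expect_error(classical_vikor(0.5, 0.5), "at least 2")
})

test_that("SAW is the exact utility complement of the VIKOR group utility", {
  fx <- load_fixtures()
  sw <- saw(fx$gaps_trusted)
  expect_identical(sw$orientation, "utility")
  expect_equal(round(sw$values[["2"]], 3), 0.577)
  set.seed(31)
  for (i in 1:5) {
    g <- random_weighted_gaps(sample(3:9, 1), sample(3:8, 1))
    expect_equal(unname(saw(g)$values + rowSums(g)), rep(1, nrow(g)),
                 tolerance = 1e-15)
  }
  w <- weight_scheme(c("c1", "c2"), c(0.4, 0.6))
  gw <- weighted_gaps(matrix(1, 1, 2, dimnames = list("p", w$criteria)), w)
  expect_equal(unname(saw(gw)$values), 0, tolerance = 1e-12)
})

test_that("TOPSIS closeness hits its bounds at the ideals and respects symmetry", {
  w <- weight_scheme(c("c1", "c2"), c(0.5, 0.5))
  m <- rating_matrix(matrix(c(9, 3, 5, 8, 2, 4), 3, 2,
                            dimnames = list(c("hi", "lo", "mid"),
                                            c("c1", "c2"))))
  C <- topsis(m, w)
  expect_equal(unname(C$values[c("hi", "lo")]), c(1, 0))
  expect_true(C$values["mid"] > 0 && C$values["mid"] < 1)

  sym <- rating_matrix(matrix(c(3, 7, 7, 3), 2, 2,
                              dimnames = list(c("a", "b"), c("c1", "c2"))))
  expect_equal(unname(topsis(sym, w)$values), c(0.5, 0.5), tolerance = 1e-12)

  # constant criterion contributes nothing and produces no NaN
  cst <- rating_matrix(matrix(c(5, 5, 2, 8), 2, 2,
                              dimnames = list(c("a", "b"), c("c1", "c2"))))
  expect_equal(unname(topsis(cst, w)$values), c(0, 1))
})

test_that("TOPSIS preserves weak dominance", {
  set.seed(41)
  for (i in 1:6) {
    ncrit <- sample(3:6, 1)
    w <- weight_scheme(paste0("c", 1:ncrit),
                       random_representable_weights(ncrit))
    f <- matrix(runif(4 * ncrit, 2, 9), 4, ncrit,
                dimnames = list(paste0("p", 1:4), w$criteria))
    f[1, ] <- pmin(f[2, ] + runif(ncrit, 0, 1), 10)  # p1 dominates p2
    for (norm in c("minmax", "vector")) {
      C <- topsis(rating_matrix(f), w, normalization = norm)
      expect_gte(C$values[["p1"]], C$values[["p2"]] - 1e-12)
    }
  }
})

test_that("PROMETHEE II net flows are zero-sum and honor full dominance", {
  w <- weight_scheme(c("c1", "c2"), c(0.5, 0.5))
  same <- rating_matrix(matrix(5, 3, 2, dimnames = list(NULL, c("c1", "c2"))))
  expect_equal(unname(promethee2(same, w)$values), c(0, 0, 0))

  dom <- rating_matrix(matrix(c(8, 3, 9, 4), 2, 2,
                              dimnames = list(c("A", "B"), c("c1", "c2"))))
  phi <- promethee2(dom, w)
  expect_equal(unname(phi$values), c(1, -1))  # usual preference, two pairs

  set.seed(51)
  for (i in 1:5) {
    nalt <- sample(3:9, 1); ncrit <- sample(3:6, 1)
    w2 <- weight_scheme(paste0("c", 1:ncrit),
                        random_representable_weights(ncrit))
    m <- rating_matrix(matrix(runif(nalt * ncrit, 1, 10), nalt, ncrit,
                              dimnames = list(NULL, w2$criteria)))
    expect_equal(sum(promethee2(m, w2)$values), 0, tolerance = 1e-12)
    expect_equal(sum(promethee2(m, w2, "linear", p = 2)$values), 0,
                 tolerance = 1e-12)
  }
  expect_error(promethee2(dom, w, "linear"), "threshold")
})

test_that("ranks are ascending in value with average ties, orientation carried", {
  r <- rank_alternatives(method_scores("V", c(0.245, 0.158, 0.184), "gap"))
  expect_equal(unname(r$rank), c(3, 1, 2))
  expect_identical(r$orientation, "gap")

  u <- rank_alternatives(method_scores("SAW", c(0.586, 0.740, 0.463),
                                       "utility"))
  expect_equal(unname(u$rank), c(2, 3, 1))

  fx <- load_fixtures()
  rk <- rank_alternatives(fx$methods$`Modified VIKOR`)
  expect_equal(unname(rk$rank), c(7, 8, 2, 3, 1, 6, 4, 5, 9))

  tied <- rank_alternatives(method_scores("t", c(1, 2, 2, 5), "utility"))
  expect_equal(unname(tied$rank), c(1, 2.5, 2.5, 4))
  set.seed(61)
  for (m in c(4, 7, 9)) {
    v <- sample(1:4, m, replace = TRUE)
    rk2 <- rank_alternatives(method_scores("t", v, "utility"))
    expect_equal(sum(rk2$rank), m * (m + 1) / 2)
  }
})
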