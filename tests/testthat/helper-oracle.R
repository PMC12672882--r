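# Independent brute-force oracle for the three-criterion BWM programme:
# dense grid over the 2-simplex minimizing the max absolute deviation,
# coarse pass at 2e-3 refined to 1e-4 around the coarse optimum.
grid_oracle_bwm <- function(aB, aW, B, W, step = 1e-4) {
  objective <- function(w1, w2, w3) {
    wmat <- rbind(w1, w2, w3)
    wB <- wmat[B, ]; wW <- wmat[W, ]
    d <- abs(wB - aB[1] * wmat[1, ])
    for (j in 2:3) d <- pmax(d, abs(wB - aB[j] * wmat[j, ]))
    for (j in 1:3) d <- pmax(d, abs(wmat[j, ] - aW[j] * wW))
    d
  }
  search <- function(r1, r2) {
    g <- expand.grid(w1 = r1, w2 = r2)
    g <- g[g$w1 + g$w2 <= 1, ]
    d <- objective(g$w1, g$w2, 1 - g$w1 - g$w2)
    i <- which.min(d)
    list(w = c(g$w1[i], g$w2[i], 1 - g$w1[i] - g$w2[i]), xi = d[i])
  }
  coarse <- 2e-3
  c1 <- search(seq(0, 1, coarse), seq(0, 1, coarse))
  search(seq(max(0, c1$w[1] - 2 * coarse), min(1, c1$w[1] + 2 * coarse), step),
         seq(max(0, c1$w[2] - 2 * coarse), min(1, c1$w[2] + 2 * coarse), step))
}

# Random valid integer questionnaire with n = 3 criteria (uses the current
# RNG stream; seed at the call site).
random_questionnaire_n3 <- function(id = "e") {
  repeat {
    perm <- sample(3)
    B <- perm[1]; W <- perm[2]
    abw <- sample(2:9, 1)
    aB <- rep(NA_real_, 3); aW <- rep(NA_real_, 3)
    aB[B] <- 1; aB[W] <- abw
    aW[W] <- 1; aW[B] <- abw
    mid <- setdiff(1:3, c(B, W))
    aB[mid] <- sample(seq_len(abw), 1)
    aW[mid] <- sample(seq_len(abw), 1)
    q <- bwm_questionnaire(id, c("c1", "c2", "c3"), best = B, worst = W,
                           best_to_others = aB, others_to_worst = aW)
    ok <- !inherits(try(validate_questionnaire(q), silent = TRUE), "try-error")
    if (ok) return(q)
  }
}

# Classical closed form for tie-free ranks; the hand-rolled counterpart to
# the stats::cor route used by the package.
spearman_closed_form <- function(a, b) {
  m <- length(a)
  1 - 6 * sum((a - b)^2) / (m * (m^2 - 1))
}

# A weight vector on the simplex with max/min ratio <= 9 (uses current RNG).
random_representable_weights <- function(n) {
  repeat {
    w <- stats::runif(n, 1, 6)
    w <- w / sum(w)
    if (max(w) / min(w) <= 9) return(w)
  }
}

# Build the perfectly consistent real-valued questionnaire implied by w.
consistent_questionnaire <- function(w, id = "c") {
  B <- which.max(w); W <- which.min(w)
  bwm_questionnaire(id, paste0("c", seq_along(w)), best = B, worst = W,
                    best_to_others = w[B] / w,
                    others_to_worst = w / w[W])
}
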