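#' Construct a Best-Worst Method questionnaire
#'
#' One expert's pairwise-comparison record: the criterion judged most
#' important (best), the one judged least important (worst), the
#' Best-to-Others vector `a_Bj` (importance of the best criterion relative
#' to each criterion j) and the Others-to-Worst vector `a_jW` (importance of
#' each criterion j relative to the worst criterion), both on the 1-9 scale.
#'
#' @param expert_id identifier for the expert (coerced to character).
#' @param criteria character vector of criterion names (length n >= 2).
#' @param best name or index of the best criterion.
#' @param worst name or index of the worst criterion.
#' @param best_to_others numeric vector `a_Bj`, length n.
#' @param others_to_worst numeric vector `a_jW`, length n.
#' @return An object of class `bwm_questionnaire`.
#' @seealso [validate_questionnaire()], [solve_bwm()]
#' @examples
#' q <- bwm_questionnaire("e1", c("c1", "c2", "c3"), best = "c1", worst = "c3",
#'                        best_to_others = c(1, 2, 4), others_to_worst = c(4, 2, 1))
#' solve_bwm(q)
#' @export
bwm_questionnaire <- function(expert_id, criteria, best, worst,
                              best_to_others, others_to_worst) {
  criteria <- as.character(criteria)
  n <- length(criteria)
  idx <- function(x, what) {
    if (is.character(x)) {
      i <- match(x, criteria)
      if (is.na(i)) stop("unknown ", what, " criterion '", x, "' for expert ",
                         expert_id, call. = FALSE)
      i
    } else as.integer(x)
  }
  q <- structure(list(
    expert_id = as.character(expert_id),
    criteria = criteria,
    best_index = idx(best, "best"),
    worst_index = idx(worst, "worst"),
    best_to_others = as.numeric(best_to_others),
    others_to_worst = as.numeric(others_to_worst)
  ), class = "bwm_questionnaire")
  q
}

#' @export
print.bwm_questionnaire <- function(x, ...) {
  cat("BWM questionnaire - expert", x$expert_id, "\n")
  cat("  best:", x$criteria[x$best_index],
      " worst:", x$criteria[x$worst_index], "\n")
  cat("  best-to-others: ", paste(x$best_to_others, collapse = " "), "\n")
  cat("  others-to-worst:", paste(x$others_to_worst, collapse = " "), "\n")
  invisible(x)
}

#' Validate a BWM questionnaire
#'
#' Checks the structural invariants of a questionnaire: all entries on the
#' 1-9 scale (integers when `strict = TRUE`), unit self-comparisons
#' (`a_BB = 1`, `a_WW = 1`), dominance of the best-versus-worst comparison
#' (`a_BW` is the maximum of both vectors and identical in both), and a
#' best/worst designation that is coherent with the vectors. Nothing is
#' normalized or altered.
#'
#' @param q a [bwm_questionnaire()].
#' @param strict require integer entries (the elicitation scale); set
#'   `FALSE` to admit real-valued ratios, e.g. ratios constructed from a
#'   known weight vector.
#' @return `q`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_questionnaire <- function(q, strict = TRUE) {
  stopifnot(inherits(q, "bwm_questionnaire"))
  n <- length(q$criteria)
  who <- paste0("expert ", q$expert_id)
  if (n < 2) stop("questionnaire needs at least 2 criteria (", who, ")",
                  call. = FALSE)
  if (length(q$best_to_others) != n || length(q$others_to_worst) != n)
    stop("comparison vectors must have one entry per criterion (", who, ")",
         call. = FALSE)
  for (v in c("best_to_others", "others_to_worst")) {
    x <- q[[v]]
    bad <- which(x < 1 | x > 9 | !is.finite(x))
    if (length(bad))
      stop("scale violation: ", v, " entry for criterion '",
           q$criteria[bad[1]], "' (", who, ") is ", x[bad[1]],
           ", outside [1, 9]", call. = FALSE)
    if (strict && any(x != round(x)))
      stop("scale violation: non-integer ", v, " entry (", who,
           "); use strict = FALSE for real-valued ratios", call. = FALSE)
  }
  B <- q$best_index; W <- q$worst_index
  if (B == W && any(c(q$best_to_others, q$others_to_worst) > 1))
    stop("designation error: best and worst criterion coincide but the ",
         "comparisons are non-trivial (", who, ")", call. = FALSE)
  if (q$best_to_others[B] != 1)
    stop("self-comparison a_BB must be 1 (", who, ")", call. = FALSE)
  if (q$others_to_worst[W] != 1)
    stop("self-comparison a_WW must be 1 (", who, ")", call. = FALSE)
  abw <- q$best_to_others[W]
  if (abw != max(q$best_to_others) || q$others_to_worst[B] != abw ||
      abw != max(q$others_to_worst))
    stop("dominance violation: best-vs-worst comparison must be the maximum ",
         "of both vectors and agree between them (", who, ": a_BW = ", abw,
         ", max a_jW = ", max(q$others_to_worst), ")", call. = FALSE)
  invisible(q)
}

#' Solve the linearized BWM weight programme for one expert
#'
#' Minimizes the scalar consistency value `xi` subject to
#' `|w_B - a_Bj w_j| <= xi` and `|w_j - a_jW w_W| <= xi` for every
#' criterion j, with the weights on the probability simplex. A consistency
#' value of 0 means the expert's ratios are perfectly coherent
#' (`a_Bj = w_B / w_j` exactly); larger values quantify internal
#' contradiction. The programme is solved exactly with the simplex method.
#'
#' The linear model can admit multiple optimal weight vectors at the same
#' `xi`; the solver's vertex solution is returned and `degenerate` is set
#' when a second optimum is detected (an alternative vertex attains `xi`
#' within 1e-9 with weights differing by more than 1e-9).
#'
#' @param q a validated [bwm_questionnaire()].
#' @param validate run [validate_questionnaire()] first (non-strict).
#' @return An object of class `bwm_solution`: list with `expert_id`,
#'   `criteria`, `weights` (non-negative, summing to 1), `xi`, `degenerate`,
#'   and `retained` (`NA` until [consistency_filter()] is applied).
#' @export
solve_bwm <- function(q, validate = TRUE) {
  if (validate) validate_questionnaire(q, strict = FALSE)
  n <- length(q$criteria)
  if (n < 2) stop("need at least 2 criteria", call. = FALSE)
  B <- q$best_index; W <- q$worst_index
  aB <- q$best_to_others; aW <- q$others_to_worst
  nv <- n + 1L                       # variables: w_1..w_n, xi
  rows <- vector("list", 4L * n)
  for (j in seq_len(n)) {
    rB <- numeric(nv); rB[B] <- rB[B] + 1; rB[j] <- rB[j] - aB[j]
    rW <- numeric(nv); rW[j] <- rW[j] + 1; rW[W] <- rW[W] - aW[j]
    k <- 4L * (j - 1L)
    rows[[k + 1L]] <- c(rB[-nv], -1)   #  (w_B - a_Bj w_j) - xi <= 0
    rows[[k + 2L]] <- c(-rB[-nv], -1)  # -(w_B - a_Bj w_j) - xi <= 0
    rows[[k + 3L]] <- c(rW[-nv], -1)
    rows[[k + 4L]] <- c(-rW[-nv], -1)
  }
  A1 <- do.call(rbind, rows)
  A3 <- matrix(c(rep(1, n), 0), nrow = 1)
  sol <- boot::simplex(a = c(rep(0, n), 1),
                       A1 = A1, b1 = rep(0, nrow(A1)),
                       A3 = A3, b3 = 1, maxi = FALSE)
  if (sol$solved != 1)
    stop("internal error: BWM linear programme did not solve (expert ",
         q$expert_id, ")", call. = FALSE)
  w <- unname(sol$soln[seq_len(n)])
  xi <- unname(sol$value)
  # degeneracy probe: push w_B to its extreme at (almost) the same xi
  degen <- FALSE
  probe <- try(boot::simplex(a = c(seq_len(n) == B, 0) * 1,
                             A1 = rbind(A1, c(rep(0, n), 1)),
                             b1 = c(rep(0, nrow(A1)), xi + 1e-9),
                             A3 = A3, b3 = 1, maxi = TRUE), silent = TRUE)
  if (!inherits(probe, "try-error") && probe$solved == 1) {
    w2 <- unname(probe$soln[seq_len(n)])
    if (max(abs(w2 - w)) > 1e-7) degen <- TRUE
  }
  w <- pmax(w, 0)
  structure(list(expert_id = q$expert_id, criteria = q$criteria,
                 weights = w, xi = max(xi, 0),
                 degenerate = degen, retained = NA),
            class = "bwm_solution")
}

#' @export
print.bwm_solution <- function(x, ...) {
  cat("BWM solution - expert", x$expert_id,
      sprintf("(xi = %.4g%s)\n", x$xi,
              if (isTRUE(x$degenerate)) ", degenerate optimum" else ""))
  print(round(stats::setNames(x$weights, x$criteria), 4))
  invisible(x)
}

#' Partition BWM solutions by consistency
#'
#' Splits solutions into those retained (`xi <= threshold`, inclusive) and
#' those excluded (`xi > threshold`). The boundary is inclusive: only
#' consistency values strictly above the threshold are excluded.
#'
#' @param solutions list of [solve_bwm()] results.
#' @param threshold consistency cutoff; default 0.1.
#' @return list with elements `retained` and `excluded`, each a list of
#'   `bwm_solution` objects with their `retained` flag set.
#' @export
consistency_filter <- function(solutions, threshold = 0.1) {
  stopifnot(is.numeric(threshold), threshold > 0)
  if (length(solutions) == 0)
    return(list(retained = list(), excluded = list()))
  keep <- vapply(solutions, function(s) s$xi <= threshold, logical(1))
  solutions <- lapply(seq_along(solutions), function(i) {
    s <- solutions[[i]]; s$retained <- keep[i]; s
  })
  if (!any(keep))
    warning("no expert passed the consistency threshold of ", threshold,
            call. = FALSE)
  list(retained = solutions[keep], excluded = solutions[!keep])
}

#' Construct a criterion weight scheme
#'
#' A named, normalized weight vector with provenance. Fixture schemes
#' transcribed from rounded percentages are renormalized to sum exactly 1;
#' the pre-normalization sum must lie within \[0.99, 1.01\].
#'
#' @param criteria criterion names.
#' @param weights non-negative weights; renormalized to sum 1.
#' @param source provenance tag: `"single-expert"`, `"aggregate-of-<k>"`, or
#'   `"fixture"`.
#' @return An object of class `weight_scheme`.
#' @export
weight_scheme <- function(criteria, weights, source = "single-expert") {
  criteria <- as.character(criteria)
  weights <- as.numeric(weights)
  stopifnot(length(criteria) == length(weights), all(weights >= 0))
  s <- sum(weights)
  if (s < 0.99 || s > 1.01)
    stop("weights sum to ", format(s),
         "; expected within [0.99, 1.01] before renormalization",
         call. = FALSE)
  structure(list(criteria = criteria, weights = weights / s, source = source),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("Criterion weights (", x$source, ")\n", sep = "")
  print(round(stats::setNames(x$weights, x$criteria), 4))
  invisible(x)
}

#' Aggregate per-expert weight schemes into a final scheme
#'
#' Takes the unweighted arithmetic mean of the weights per criterion across
#' experts (the default aggregation for a retained panel) and renormalizes.
#' A geometric-mean alternative is available via `method = "geometric"`.
#'
#' @param schemes non-empty list of [weight_scheme()] objects (or
#'   `bwm_solution` objects, whose weights are used directly) sharing one
#'   criteria ordering.
#' @param method `"arithmetic"` (default) or `"geometric"`.
#' @return A `weight_scheme` with source `"aggregate-of-<k>"`.
#' @export
aggregate_weights <- function(schemes, method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  if (length(schemes) == 0) stop("no weight schemes to aggregate", call. = FALSE)
  crit <- schemes[[1]]$criteria
  mat <- vapply(schemes, function(s) {
    if (!identical(s$criteria, crit))
      stop("criterion-order mismatch across schemes", call. = FALSE)
    s$weights
  }, numeric(length(crit)))
  mat <- matrix(mat, nrow = length(crit))
  w <- if (method == "arithmetic") rowMeans(mat)
       else exp(rowMeans(log(pmax(mat, 1e-300))))
  weight_scheme(crit, w / sum(w),
                source = paste0("aggregate-of-", length(schemes)))
}
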