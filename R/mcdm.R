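#' Modified VIKOR compromise evaluation against aspiration levels
#'
#' Computes, for every alternative k, the weighted group utility
#' `S_k = sum_j g_kj` (total weighted shortfall from the aspired level),
#' the individual regret `R_k` (the single worst gap term), and the
#' synthesized gap `V_k = delta * S_k + (1 - delta) * R_k`. Because the
#' reference levels are the theoretical anchors (aspired S = R = 0, worst
#' S = R = 1), no renormalization against the sample is involved and
#' smaller V is better.
#'
#' Two regret conventions are provided. The default, `"weighted"`, takes
#' `R_k = max_j g_kj` — the largest weighted gap, i.e. the improvement
#' priority of the weakest weighted dimension. The `"unweighted"`
#' alternative takes `R_k = max_j r_kj` on the raw gaps (dividing the
#' attached weights back out), which treats every criterion's shortfall on
#' an equal footing regardless of weight.
#'
#' @param g a `weighted_gap_matrix` (see [weighted_gaps()]).
#' @param delta compromise parameter in \[0, 1\]; 1 ranks purely by total
#'   shortfall, 0 purely by the worst single criterion. Default 0.5.
#' @param regret `"weighted"` (default) or `"unweighted"`.
#' @return An object of class `vikor_result`: data frame with columns
#'   `alternative`, `S`, `R`, `V`, `rank`, plus attributes `gaps` (the
#'   matrix), `priorities` (per alternative, criteria ordered by descending
#'   weighted gap) and the settings used.
#' @export
modified_vikor <- function(g, delta = 0.5, regret = c("weighted", "unweighted")) {
  regret <- match.arg(regret)
  stopifnot(inherits(g, "weighted_gap_matrix"),
            is.numeric(delta), delta >= 0, delta <= 1)
  gm <- unclass(g)
  attr(gm, "weight_scheme") <- NULL
  if (nrow(gm) == 0) stop("empty gap matrix", call. = FALSE)
  S <- rowSums(gm)
  R <- if (regret == "weighted") apply(gm, 1, max)
       else apply(unclass(recover_gaps(g)), 1, max)
  V <- delta * S + (1 - delta) * R
  pri <- lapply(seq_len(nrow(gm)), function(k) {
    o <- order(gm[k, ], decreasing = TRUE)
    stats::setNames(gm[k, o], colnames(gm)[o])
  })
  names(pri) <- rownames(gm)
  out <- data.frame(alternative = rownames(gm), S = unname(S),
                    R = unname(R), V = unname(V),
                    rank = rank_alternatives(method_scores("Modified VIKOR",
                                                           V, "gap"))$rank,
                    row.names = NULL)
  structure(out, gaps = g, priorities = pri, delta = delta, regret = regret,
            class = c("vikor_result", "data.frame"))
}

#' @export
print.vikor_result <- function(x, digits = 3, ...) {
  cat(sprintf("Modified VIKOR (delta = %g, %s regret)\n",
              attr(x, "delta"), attr(x, "regret")))
  y <- x; y[c("S", "R", "V")] <- round(y[c("S", "R", "V")], digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Classical VIKOR index from group utility and regret
#'
#' `Q_k = delta * (S_k - S*) / (S- - S*) + (1 - delta) * (R_k - R*) / (R- - R*)`
#' where `S* = min S`, `S- = max S` and likewise for R: the compromise
#' index normalized against the best and worst alternatives observed in the
#' sample rather than theoretical anchors. A degenerate term (all-equal S
#' or R) contributes 0.
#'
#' @param S,R numeric vectors of group utility and regret per alternative.
#' @param delta compromise parameter in \[0, 1\].
#' @return A gap-oriented [method_scores()] of Q values in \[0, 1\].
#' @export
classical_vikor <- function(S, R, delta = 0.5) {
  stopifnot(length(S) == length(R), delta >= 0, delta <= 1)
  if (length(S) < 2) stop("need at least 2 alternatives", call. = FALSE)
  term <- function(x) {
    d <- max(x) - min(x)
    if (d <= 0) rep(0, length(x)) else (x - min(x)) / d
  }
  Q <- delta * term(S) + (1 - delta) * term(R)
  method_scores("VIKOR", stats::setNames(Q, names(S)), "gap")
}

#' One ranking method's per-alternative scores with orientation
#'
#' @param method method name.
#' @param values named numeric vector of per-alternative performance values.
#' @param orientation `"gap"` if smaller values indicate a better
#'   alternative (compromise/gap indices) or `"utility"` if larger do
#'   (additive utilities, closeness, net flows, expert scores).
#' @return An object of class `method_scores`.
#' @export
method_scores <- function(method, values, orientation = c("utility", "gap")) {
  orientation <- match.arg(orientation)
  structure(list(method = method, values = values, orientation = orientation),
            class = "method_scores")
}

#' @export
print.method_scores <- function(x, digits = 3, ...) {
  cat(x$method, " scores (", x$orientation, "-oriented)\n", sep = "")
  print(round(x$values, digits))
  invisible(x)
}

#' Simple additive weighting utility from weighted gaps
#'
#' `SAW_k = sum_j w_j (1 - r_kj) = 1 - S_k`: the weighted sum of normalized
#' utilities, the exact complement of the Modified VIKOR group utility.
#'
#' @param g a `weighted_gap_matrix`.
#' @return A utility-oriented [method_scores()].
#' @export
saw <- function(g) {
  stopifnot(inherits(g, "weighted_gap_matrix"))
  s <- rowSums(unclass(g))
  method_scores("SAW", stats::setNames(1 - s, rownames(g)), "utility")
}

#' TOPSIS relative closeness to the ideal solutions
#'
#' Normalizes the rating matrix, weights it, takes per-criterion maxima and
#' minima across alternatives as positive and negative ideals, and scores
#' each alternative by `C_k = d- / (d+ + d-)` with Euclidean distances to
#' the two ideals. Default normalization is min-max on the assessment scale
#' (`(f - 1) / 9`, consistent with the aspired/worst anchors); vector
#' normalization (`f / sqrt(sum_k f^2)` per criterion) is available.
#' A criterion constant across alternatives contributes 0 to both distances.
#'
#' @param m a [rating_matrix()].
#' @param w a [weight_scheme()] matching the matrix criteria.
#' @param normalization `"minmax"` (default) or `"vector"`.
#' @return A utility-oriented [method_scores()] of closeness values in
#'   \[0, 1\].
#' @export
topsis <- function(m, w, normalization = c("minmax", "vector")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(m, "rating_matrix"), inherits(w, "weight_scheme"))
  if (!identical(colnames(m), w$criteria))
    stop("criteria mismatch between ratings and weight scheme", call. = FALSE)
  f <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  if (nrow(f) < 2) stop("need at least 2 alternatives", call. = FALSE)
  sc <- attr(m, "scale")
  v <- switch(normalization,
    minmax = (f - sc[["worst"]]) / (sc[["aspired"]] - sc[["worst"]]),
    vector = sweep(f, 2, sqrt(colSums(f^2)), `/`))
  v <- sweep(v, 2, w$weights, `*`)
  pos <- apply(v, 2, max); neg <- apply(v, 2, min)
  dpos <- sqrt(rowSums(sweep(v, 2, pos)^2))
  dneg <- sqrt(rowSums(sweep(v, 2, neg)^2))
  C <- ifelse(dpos + dneg == 0, 0.5, dneg / (dpos + dneg))
  method_scores("TOPSIS", stats::setNames(C, rownames(f)), "utility")
}

#' PROMETHEE II net outranking flows
#'
#' For each ordered pair of alternatives (a, b), the preference index
#' `pi(a, b) = sum_j w_j P_j(f_aj - f_bj)` aggregates per-criterion
#' preference functions; the net flow of alternative k is
#' `phi_k = sum_{b != k} [pi(k, b) - pi(b, k)]`, left unnormalized so flows
#' range over \[-(m-1), m-1\]. Flows always sum to zero. The `"usual"`
#' preference function is a step (any positive difference counts fully);
#' `"linear"` ramps linearly up to the indifference-to-strict threshold `p`.
#'
#' @param m a [rating_matrix()].
#' @param w a [weight_scheme()].
#' @param preference `"usual"` (default) or `"linear"`.
#' @param p strict-preference threshold for the linear function (score
#'   units, > 0).
#' @return A utility-oriented [method_scores()] of net flows.
#' @export
promethee2 <- function(m, w, preference = c("usual", "linear"), p = NULL) {
  preference <- match.arg(preference)
  stopifnot(inherits(m, "rating_matrix"), inherits(w, "weight_scheme"))
  if (!identical(colnames(m), w$criteria))
    stop("criteria mismatch between ratings and weight scheme", call. = FALSE)
  f <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  if (nrow(f) < 2) stop("need at least 2 alternatives", call. = FALSE)
  P <- switch(preference,
    usual = function(d) as.numeric(d > 0),
    linear = {
      if (is.null(p) || p <= 0)
        stop("linear preference needs a threshold p > 0", call. = FALSE)
      function(d) pmin(pmax(d, 0) / p, 1)
    })
  nalt <- nrow(f)
  pi_mat <- matrix(0, nalt, nalt)
  for (a in seq_len(nalt)) for (b in seq_len(nalt)) {
    if (a == b) next
    pi_mat[a, b] <- sum(w$weights * P(f[a, ] - f[b, ]))
  }
  phi <- rowSums(pi_mat) - colSums(pi_mat)
  method_scores("PROMETHEE II", stats::setNames(phi, rownames(f)), "utility")
}

#' Ordinal ranks of method scores
#'
#' Ranks alternatives in ascending order of the performance value: rank 1
#' is the smallest value, ties receive average ranks. Whether rank 1 means
#' best or worst depends on the method's orientation, which is carried
#' along rather than folded into the ranks (a gap-oriented method's rank 1
#' is its best alternative; a utility-oriented method's rank 1 is its
#' worst).
#'
#' @param s a [method_scores()] or plain numeric vector.
#' @param orientation orientation when `s` is a plain vector.
#' @return An object of class `rank_vector`: list with `method`, `rank`
#'   (numeric, average ties) and `orientation`.
#' @export
rank_alternatives <- function(s, orientation = c("utility", "gap")) {
  if (inherits(s, "method_scores")) {
    v <- s$values; orientation <- s$orientation; method <- s$method
  } else {
    v <- s; orientation <- match.arg(orientation); method <- "scores"
  }
  if (length(v) == 0) stop("no scores to rank", call. = FALSE)
  structure(list(method = method,
                 rank = rank(v, ties.method = "average"),
                 orientation = orientation),
            class = "rank_vector")
}

#' @export
print.rank_vector <- function(x, ...) {
  cat(x$method, " ranks (", x$orientation,
      "-oriented; rank 1 = smallest value)\n", sep = "")
  print(x$rank)
  invisible(x)
}
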