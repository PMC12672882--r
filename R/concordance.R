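#' Align a rank vector to a target orientation
#'
#' Gap-oriented and utility-oriented methods order the same merit scale in
#' opposite directions, so their raw rank vectors are antitonic. Before
#' rank-correlating methods, every vector is mapped to a common
#' orientation: when orientations already match this is the identity,
#' otherwise each rank r becomes `(m + 1) - r` (an involution, and valid
#' for average tie ranks too).
#'
#' @param r a `rank_vector` (see [rank_alternatives()]).
#' @param target `"gap"` or `"utility"`.
#' @return A `rank_vector` in the target orientation.
#' @export
align_orientation <- function(r, target = c("gap", "utility")) {
  target <- match.arg(target)
  stopifnot(inherits(r, "rank_vector"))
  if (r$orientation == target) return(r)
  m <- length(r$rank)
  structure(list(method = r$method, rank = (m + 1) - r$rank,
                 orientation = target),
            class = "rank_vector")
}

#' Spearman rank correlation between two rank vectors
#'
#' Product-moment correlation of the ranks; for tie-free integer ranks this
#' equals the classical `1 - 6 sum(d^2) / (m (m^2 - 1))`. Orientations are
#' NOT aligned here — pass pre-aligned vectors (see [align_orientation()])
#' or use [correlation_matrix()], which aligns by default.
#'
#' @param a,b `rank_vector` objects or plain numeric rank vectors of equal
#'   length (>= 3), same alternative ordering.
#' @return Spearman's rho in \[-1, 1\].
#' @export
spearman_rho <- function(a, b) {
  ra <- if (inherits(a, "rank_vector")) a$rank else as.numeric(a)
  rb <- if (inherits(b, "rank_vector")) b$rank else as.numeric(b)
  if (length(ra) != length(rb))
    stop("rank vectors differ in length", call. = FALSE)
  if (length(ra) < 3) stop("need at least 3 alternatives", call. = FALSE)
  stats::cor(ra, rb, method = "spearman")
}

#' Pairwise rank-concordance matrix across methods
#'
#' Computes the symmetric matrix of Spearman correlations between every
#' pair of methods' rank vectors, after aligning all vectors to a common
#' orientation (default on; disable to see the raw signed matrix, in which
#' gap- vs utility-oriented pairs correlate negatively). The per-method
#' average includes the unit self-correlation, i.e. it is the plain column
#' mean of the matrix.
#'
#' @param ranks named list of `rank_vector` objects (names = method labels;
#'   unnamed lists take each vector's own `method` field).
#' @param align align orientations before correlating (default `TRUE`).
#' @param p_values also compute two-sided Spearman test p-values
#'   ([stats::cor.test()], exact for small tie-free vectors).
#' @return An object of class `concordance_matrix`: list with `rho`
#'   (symmetric matrix, unit diagonal), `average` (named vector of column
#'   means including the diagonal), `aligned`, and optionally `p`.
#' @export
correlation_matrix <- function(ranks, align = TRUE, p_values = FALSE) {
  if (length(ranks) < 2) stop("need at least 2 methods", call. = FALSE)
  nm <- names(ranks)
  if (is.null(nm) || any(nm == ""))
    nm <- vapply(ranks, function(r) r$method, character(1))
  if (anyDuplicated(nm)) stop("duplicate method names", call. = FALSE)
  if (align) ranks <- lapply(ranks, align_orientation, target = "gap")
  k <- length(ranks)
  rho <- diag(1, k); dimnames(rho) <- list(nm, nm)
  p <- if (p_values) rho * NA else NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    rho[i, j] <- rho[j, i] <- spearman_rho(ranks[[i]], ranks[[j]])
    if (p_values) {
      ct <- suppressWarnings(
        stats::cor.test(ranks[[i]]$rank, ranks[[j]]$rank,
                        method = "spearman", exact = TRUE))
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(rho = rho, average = colMeans(rho), aligned = align, p = p),
            class = "concordance_matrix")
}

#' @export
print.concordance_matrix <- function(x, digits = 3, ...) {
  cat("Spearman rank concordance",
      if (x$aligned) "(orientation-aligned)" else "(raw signed)", "\n")
  out <- rbind(round(x$rho, digits),
               `Average correlation` = round(x$average, digits))
  print(out)
  invisible(x)
}
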