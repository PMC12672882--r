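#' Construct a performance rating matrix
#'
#' Alternative-by-criterion performance scores `f_kj` on the 10-point
#' assessment scale, where 10 is the aspired level and 1 the worst level.
#'
#' @param values numeric matrix, alternatives in rows, criteria in columns.
#' @param alternatives,criteria optional dimension names (taken from
#'   `dimnames(values)` when absent).
#' @return An object of class `rating_matrix` (a numeric matrix with
#'   `scale` attribute `c(worst = 1, aspired = 10)`).
#' @export
rating_matrix <- function(values, alternatives = rownames(values),
                          criteria = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(alternatives)) alternatives <- paste0("A", seq_len(nrow(values)))
  if (is.null(criteria)) criteria <- paste0("c", seq_len(ncol(values)))
  dimnames(values) <- list(alternatives, criteria)
  if (anyNA(values)) stop("rating matrix has missing cells", call. = FALSE)
  if (any(values < 1 | values > 10))
    stop("rating outside the [1, 10] scale", call. = FALSE)
  structure(values, scale = c(worst = 1, aspired = 10),
            class = c("rating_matrix", "matrix", "array"))
}

#' Aggregate long-format expert ratings into a rating matrix
#'
#' Each (alternative, criterion) cell becomes the arithmetic mean of the
#' expert scores for that cell. Per-cell rater counts and score standard
#' deviations are attached as attributes `n_raters` and `dispersion` so
#' panel disagreement stays visible.
#'
#' @param raw data frame with columns `expert_id`, `alternative`,
#'   `criterion`, `score` (scores in \[1, 10\]).
#' @param alternatives,criteria optional orderings; default is order of
#'   first appearance.
#' @return A [rating_matrix()].
#' @export
aggregate_ratings <- function(raw, alternatives = NULL, criteria = NULL) {
  need <- c("expert_id", "alternative", "criterion", "score")
  if (!all(need %in% names(raw)))
    stop("ratings need columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (any(raw$score < 1 | raw$score > 10 | !is.finite(raw$score)))
    stop("scale error: scores must lie in [1, 10]", call. = FALSE)
  if (is.null(alternatives)) alternatives <- unique(as.character(raw$alternative))
  if (is.null(criteria)) criteria <- unique(as.character(raw$criterion))
  fa <- factor(raw$alternative, levels = alternatives)
  fc <- factor(raw$criterion, levels = criteria)
  if (anyNA(fa) || anyNA(fc))
    stop("ratings mention alternatives/criteria missing from the given order",
         call. = FALSE)
  m <- tapply(raw$score, list(fa, fc), mean)
  nr <- tapply(raw$score, list(fa, fc), length)
  sdv <- tapply(raw$score, list(fa, fc), stats::sd)
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop("completeness error: unrated (alternative, criterion) pairs: ",
         paste(sprintf("(%s, %s)", alternatives[miss[, 1]],
                       criteria[miss[, 2]]), collapse = ", "),
         call. = FALSE)
  }
  out <- rating_matrix(m, alternatives, criteria)
  attr(out, "n_raters") <- nr
  attr(out, "dispersion") <- sdv
  out
}

#' Aspiration-level gap transform
#'
#' Maps each performance score to its normalized distance from the aspired
#' level: `r_kj = (10 - f_kj) / (10 - 1)`. A score at the aspired level
#' (10) has gap 0; a score at the worst level (1) has gap 1. The reference
#' frame is the theoretical scale, not the best alternative in the sample,
#' so gaps measure room for improvement rather than relative standing.
#'
#' @param m a [rating_matrix()].
#' @return A `gap_matrix`: numeric matrix of gaps in \[0, 1\], same shape.
#' @export
gap_normalize <- function(m) {
  stopifnot(inherits(m, "rating_matrix"))
  sc <- attr(m, "scale")
  r <- (sc[["aspired"]] - unclass(m)) / (sc[["aspired"]] - sc[["worst"]])
  attr(r, "scale") <- NULL; attr(r, "n_raters") <- NULL
  attr(r, "dispersion") <- NULL
  structure(r, class = c("gap_matrix", "matrix", "array"))
}

#' Weight a gap matrix by a criterion weight scheme
#'
#' Elementwise `g_kj = w_j * r_kj`. The weighted gap is the per-criterion
#' improvement priority: the cost, in weighted shortfall, of alternative k's
#' distance from the aspired level on criterion j.
#'
#' @param r a `gap_matrix` from [gap_normalize()] (or a plain numeric matrix
#'   of gaps in \[0, 1\] with criterion column names).
#' @param w a [weight_scheme()] whose criteria match `colnames(r)` in order.
#' @return A `weighted_gap_matrix` with the scheme attached as attribute
#'   `weight_scheme`.
#' @export
weighted_gaps <- function(r, w) {
  stopifnot(inherits(w, "weight_scheme"))
  r <- as.matrix(r)
  if (!identical(colnames(r), w$criteria))
    stop("criteria mismatch between gap matrix and weight scheme",
         call. = FALSE)
  if (any(r < 0 | r > 1)) stop("gaps must lie in [0, 1]", call. = FALSE)
  g <- sweep(r, 2, w$weights, `*`)
  structure(g, weight_scheme = w,
            class = c("weighted_gap_matrix", "matrix", "array"))
}

#' Assemble a weighted gap matrix directly from known gap values
#'
#' For transcribed tables that print the weighted gaps `g_kj` themselves.
#' The raw gaps `r_kj = g_kj / w_j` are recoverable with
#' [recover_gaps()] and are flagged as derived.
#'
#' @param g numeric matrix of weighted gaps with criterion column names.
#' @param w the [weight_scheme()] the gaps were weighted with.
#' @return A `weighted_gap_matrix`.
#' @export
as_weighted_gaps <- function(g, w) {
  stopifnot(inherits(w, "weight_scheme"))
  g <- as.matrix(g)
  if (!identical(colnames(g), w$criteria))
    stop("criteria mismatch between gap matrix and weight scheme",
         call. = FALSE)
  bad <- sweep(g, 2, w$weights, `/`)
  if (any(g < 0) || any(bad > 1 + 1e-6))
    stop("weighted gaps must satisfy 0 <= g_kj <= w_j", call. = FALSE)
  structure(g, weight_scheme = w,
            class = c("weighted_gap_matrix", "matrix", "array"))
}

#' Recover raw gap scores from a weighted gap matrix
#'
#' Divides out the attached weights: `r_kj = g_kj / w_j`. Values are
#' derived, not observed, when the weighted matrix itself was transcribed.
#'
#' @param g a `weighted_gap_matrix`.
#' @return A `gap_matrix` of raw gaps in \[0, 1\].
#' @export
recover_gaps <- function(g) {
  stopifnot(inherits(g, "weighted_gap_matrix"))
  w <- attr(g, "weight_scheme")
  r <- sweep(unclass(g), 2, w$weights, `/`)
  attr(r, "weight_scheme") <- NULL
  structure(pmin(r, 1), class = c("gap_matrix", "matrix", "array"),
            derived = TRUE)
}
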