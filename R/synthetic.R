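#' Configure a synthetic expert-panel study
#'
#' Defines a study with planted ground truth: a true criterion weight
#' vector (what the panel "really" believes) and a true quality profile
#' per alternative (what the parks are "really" like), plus noise levels
#' controlling how faithfully individual experts report them. Defaults
#' emulate the empirical panel the package was built around: 23 experts,
#' 9 community parks, 8 criteria, ratings on the 10-point scale.
#'
#' @param n_criteria,n_alternatives,n_experts study dimensions.
#' @param true_weights planted simplex weight vector with
#'   `max/min <= 9` (representable on the 1-9 comparison scale); default is
#'   the bundled final weight scheme when dimensions permit, otherwise a
#'   seeded draw renormalized from Uniform(1, 5).
#' @param true_quality planted alternative x criterion quality matrix on
#'   \[1, 10\]; default a seeded Uniform(2, 9.8) draw.
#' @param bwm_noise standard deviation of the log-scale multiplicative
#'   noise on comparison ratios (0 = perfectly consistent experts).
#' @param rating_noise standard deviation of the additive noise on expert
#'   scores, in scale points.
#' @param seed integer seed; every generated quantity is a deterministic
#'   function of the config.
#' @return An object of class `synthetic_study`.
#' @export
synthetic_study <- function(n_criteria = 8, n_alternatives = 9,
                            n_experts = 23, true_weights = NULL,
                            true_quality = NULL, bwm_noise = 0.15,
                            rating_noise = 1.0, seed = 1L) {
  stopifnot(n_criteria >= 2, n_alternatives >= 1, n_experts >= 1,
            bwm_noise >= 0, rating_noise >= 0)
  seed <- as.integer(seed)
  if (is.null(true_weights)) {
    if (n_criteria == 8) {
      true_weights <- park_tables()$weights$weights
    } else {
      rs <- local({ set.seed(seed); stats::runif(n_criteria, 1, 5) })
      true_weights <- rs / sum(rs)
    }
  }
  true_weights <- true_weights / sum(true_weights)
  if (length(true_weights) != n_criteria)
    stop("true_weights length must equal n_criteria", call. = FALSE)
  if (max(true_weights) / min(true_weights) > 9)
    stop("config error: weight ratio exceeds 9, unrepresentable on the ",
         "1-9 comparison scale", call. = FALSE)
  if (is.null(true_quality)) {
    true_quality <- local({
      set.seed(seed + 1L)
      matrix(stats::runif(n_alternatives * n_criteria, 2, 9.8),
             n_alternatives, n_criteria)
    })
  }
  true_quality <- as.matrix(true_quality)
  stopifnot(nrow(true_quality) == n_alternatives,
            ncol(true_quality) == n_criteria,
            all(true_quality >= 1 & true_quality <= 10))
  dimnames(true_quality) <- list(paste0("park", seq_len(n_alternatives)),
                                 paste0("c", seq_len(n_criteria)))
  structure(list(n_criteria = n_criteria, n_alternatives = n_alternatives,
                 n_experts = n_experts, true_weights = true_weights,
                 true_quality = true_quality, bwm_noise = bwm_noise,
                 rating_noise = rating_noise, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("Synthetic study: %d experts, %d alternatives, ",
                     "%d criteria (seed %d)\n"),
              x$n_experts, x$n_alternatives, x$n_criteria, x$seed))
  cat(sprintf("  bwm_noise = %g, rating_noise = %g\n",
              x$bwm_noise, x$rating_noise))
  cat("  true weights:", paste(round(x$true_weights, 3), collapse = " "), "\n")
  invisible(x)
}

# Per-expert sub-stream: a fixed offset from the study seed, so adding
# experts never perturbs earlier experts' data. Offsets stay below 2^31.
.expert_seed <- function(cfg, e, stream) {
  (cfg$seed %% 1000000L) + 1000000L * stream + e
}

#' Generate BWM questionnaires from a planted weight vector
#'
#' Every expert designates best = argmax and worst = argmin of the true
#' weights (ties broken by lowest index). Comparison entries are the true
#' ratios perturbed by multiplicative log-normal noise, rounded, and
#' clamped to the 1-9 scale:
#' `a_Bj = clamp(round(exp(log(w_B / w_j) + eps)), 1, 9)` with
#' `eps ~ Normal(0, bwm_noise)`, and analogously for `a_jW`. The
#' best-versus-worst entry is then forced consistent across the two
#' vectors (both set to the maximum observed), and self-comparisons to 1,
#' so every generated questionnaire passes validation. Deterministic per
#' config seed; each expert draws from an independent fixed-offset
#' sub-stream.
#'
#' @param cfg a [synthetic_study()].
#' @return List of validated [bwm_questionnaire()] objects.
#' @export
generate_questionnaires <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_study"))
  tw <- cfg$true_weights
  n <- cfg$n_criteria
  B <- which.max(tw); W <- which.min(tw)
  crit <- colnames(cfg$true_quality)
  lapply(seq_len(cfg$n_experts), function(e) {
    set.seed(.expert_seed(cfg, e, 1L))
    noisy_ratio <- function(true_ratio) {
      eps <- stats::rnorm(length(true_ratio), 0, cfg$bwm_noise)
      pmin(pmax(round(exp(log(true_ratio) + eps)), 1), 9)
    }
    aB <- noisy_ratio(tw[B] / tw)
    aW <- noisy_ratio(tw / tw[W])
    aB[B] <- 1; aW[W] <- 1
    top <- max(aB, aW)
    aB[W] <- top; aW[B] <- top
    q <- bwm_questionnaire(paste0("expert", e), crit, best = B, worst = W,
                           best_to_others = aB, others_to_worst = aW)
    validate_questionnaire(q)
    q
  })
}

#' Generate long-format expert ratings from a planted quality profile
#'
#' Every expert rates every (alternative, criterion) cell:
#' `score = clamp(true_quality + Normal(0, rating_noise), 1, 10)`.
#' Deterministic per config seed, with independent fixed-offset
#' sub-streams per expert.
#'
#' @param cfg a [synthetic_study()].
#' @return Data frame with columns `expert_id`, `alternative`, `criterion`,
#'   `score`, ready for [aggregate_ratings()].
#' @export
generate_ratings <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_study"))
  tq <- cfg$true_quality
  cells <- expand.grid(alternative = rownames(tq), criterion = colnames(tq),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- lapply(seq_len(cfg$n_experts), function(e) {
    set.seed(.expert_seed(cfg, e, 2L))
    noise <- stats::rnorm(nrow(cells), 0, cfg$rating_noise)
    score <- pmin(pmax(as.vector(tq) + noise, 1), 10)
    data.frame(expert_id = paste0("expert", e), cells, score = score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
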