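#' Analysis run configuration
#'
#' Bundles every tunable setting of the evaluation pipeline with its
#' default. Defaults are the settings of the published study or the
#' conventions this package validates by derivation: compromise parameter
#' `delta = 0.5`, consistency threshold 0.1 (inclusive), weighted regret,
#' min-max TOPSIS normalization, usual PROMETHEE preference function, and
#' orientation alignment before correlating.
#'
#' @param delta Modified VIKOR compromise parameter in \[0, 1\].
#' @param consistency_threshold BWM retention cutoff on `xi`.
#' @param regret `"weighted"` or `"unweighted"` (see [modified_vikor()]).
#' @param topsis_normalization `"minmax"` or `"vector"`.
#' @param promethee_preference `"usual"` or `"linear"`.
#' @param promethee_p linear-preference threshold (score units).
#' @param align_correlations align rank orientations before Spearman.
#' @param seed integer seed recorded with the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(delta = 0.5, consistency_threshold = 0.1,
                       regret = c("weighted", "unweighted"),
                       topsis_normalization = c("minmax", "vector"),
                       promethee_preference = c("usual", "linear"),
                       promethee_p = NULL, align_correlations = TRUE,
                       seed = 1L) {
  structure(list(delta = delta,
                 consistency_threshold = consistency_threshold,
                 regret = match.arg(regret),
                 topsis_normalization = match.arg(topsis_normalization),
                 promethee_preference = match.arg(promethee_preference),
                 promethee_p = promethee_p,
                 align_correlations = isTRUE(align_correlations),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read BWM questionnaires from CSV
#'
#' One row per expert: `expert_id`, `best`, `worst`, then `BO_<criterion>`
#' and `OW_<criterion>` columns for the Best-to-Others and Others-to-Worst
#' vectors. Criterion order is fixed by `criteria` (default: the bundled
#' eight-criterion catalogue, matched by the sanitized column suffixes).
#'
#' @param path CSV file path.
#' @param criteria criterion names in order; `NULL` derives them from the
#'   `BO_` column suffixes.
#' @return List of validated [bwm_questionnaire()] objects.
#' @export
read_questionnaires <- function(path, criteria = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  bo_cols <- grep("^BO_", names(df), value = TRUE)
  ow_cols <- grep("^OW_", names(df), value = TRUE)
  found <- sub("^BO_", "", bo_cols)
  if (is.null(criteria)) criteria <- found
  if (!setequal(found, criteria) ||
      !setequal(sub("^OW_", "", ow_cols), criteria))
    stop("questionnaire columns do not cover the expected criteria",
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    q <- bwm_questionnaire(
      df$expert_id[i], criteria, best = df$best[i], worst = df$worst[i],
      best_to_others = as.numeric(df[i, paste0("BO_", criteria)]),
      others_to_worst = as.numeric(df[i, paste0("OW_", criteria)]))
    validate_questionnaire(q)
  })
}

#' Write questionnaires to the CSV dialect read_questionnaires() accepts
#'
#' @param qs list of [bwm_questionnaire()] objects sharing one criteria
#'   ordering.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_questionnaires <- function(qs, path) {
  crit <- qs[[1]]$criteria
  rows <- lapply(qs, function(q) {
    stopifnot(identical(q$criteria, crit))
    c(list(expert_id = q$expert_id, best = crit[q$best_index],
           worst = crit[q$worst_index]),
      stats::setNames(as.list(q$best_to_others), paste0("BO_", crit)),
      stats::setNames(as.list(q$others_to_worst), paste0("OW_", crit)))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read long-format expert ratings from CSV
#'
#' Expects columns `expert_id`, `alternative`, `criterion`, `score`.
#'
#' @param path CSV file path.
#' @return Data frame suitable for [aggregate_ratings()].
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("expert_id", "alternative", "criterion", "score")
  if (!all(need %in% names(df)))
    stop("ratings CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Serialize a weight-elicitation result to JSON
#'
#' @param scheme the aggregated [weight_scheme()].
#' @param filtered the [consistency_filter()] partition the scheme came
#'   from (optional; adds per-expert xi and retention lists).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_weights_json <- function(scheme, filtered = NULL, path) {
  obj <- list(criteria = scheme$criteria, weights = scheme$weights,
              source = scheme$source)
  if (!is.null(filtered)) {
    all_sol <- c(filtered$retained, filtered$excluded)
    obj$xi_per_expert <- stats::setNames(
      vapply(all_sol, `[[`, numeric(1), "xi"),
      vapply(all_sol, `[[`, character(1), "expert_id"))
    obj$retained_ids <- vapply(filtered$retained, `[[`, character(1), "expert_id")
    obj$excluded_ids <- vapply(filtered$excluded, `[[`, character(1), "expert_id")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Elicit final criterion weights from a questionnaire set
#'
#' Solves the linearized BWM programme per expert, drops experts whose
#' consistency value exceeds the threshold, and averages the retained
#' experts' weight vectors.
#'
#' @param qs list of [bwm_questionnaire()] objects.
#' @param config a [run_config()].
#' @return List: `scheme` (aggregate [weight_scheme()]), `solutions` (all
#'   per-expert solutions), `filtered` (the retention partition).
#' @export
elicit_weights <- function(qs, config = run_config()) {
  solutions <- lapply(qs, solve_bwm)
  filtered <- consistency_filter(solutions, config$consistency_threshold)
  if (length(filtered$retained) == 0)
    stop("no expert passed the consistency threshold; cannot aggregate",
         call. = FALSE)
  scheme <- aggregate_weights(filtered$retained)
  list(scheme = scheme, solutions = solutions, filtered = filtered)
}

#' Run the full evaluation pipeline
#'
#' Composes every stage: BWM weight elicitation with consistency filtering
#' and aggregation, rating aggregation, aspiration-gap and weighted-gap
#' transforms, the Modified VIKOR compromise ranking with per-criterion
#' improvement priorities, the four comparator methods (classical VIKOR,
#' SAW, TOPSIS, PROMETHEE II), per-method ranks, and the
#' orientation-aligned Spearman concordance matrix.
#'
#' @param questionnaires list of [bwm_questionnaire()] objects (or a
#'   questionnaire CSV path).
#' @param ratings long-format ratings data frame (or a ratings CSV path).
#' @param config a [run_config()].
#' @return An object of class `park_evaluation`: list with `config`,
#'   `weights` ([elicit_weights()] output), `ratings` (aggregated
#'   [rating_matrix()]), `gaps`, `weighted_gaps`, `vikor`
#'   ([modified_vikor()] result), `methods` (named [method_scores()] list),
#'   `ranks` (named `rank_vector` list), `concordance`
#'   ([correlation_matrix()] result).
#' @export
evaluate_study <- function(questionnaires, ratings, config = run_config()) {
  if (is.character(questionnaires))
    questionnaires <- read_questionnaires(questionnaires)
  if (is.character(ratings)) ratings <- read_ratings(ratings)
  el <- elicit_weights(questionnaires, config)
  rm_ <- aggregate_ratings(ratings, criteria = el$scheme$criteria)
  gaps <- gap_normalize(rm_)
  wg <- weighted_gaps(gaps, el$scheme)
  vik <- modified_vikor(wg, delta = config$delta, regret = config$regret)
  methods <- list(
    `Modified VIKOR` = method_scores("Modified VIKOR",
                                     stats::setNames(vik$V, vik$alternative),
                                     "gap"),
    VIKOR = classical_vikor(stats::setNames(vik$S, vik$alternative),
                            stats::setNames(vik$R, vik$alternative),
                            delta = config$delta),
    SAW = saw(wg),
    TOPSIS = topsis(rm_, el$scheme,
                    normalization = config$topsis_normalization),
    `PROMETHEE II` = promethee2(rm_, el$scheme,
                                preference = config$promethee_preference,
                                p = config$promethee_p))
  ranks <- lapply(methods, rank_alternatives)
  conc <- correlation_matrix(ranks, align = config$align_correlations)
  structure(list(config = config, weights = el, ratings = rm_, gaps = gaps,
                 weighted_gaps = wg, vikor = vik, methods = methods,
                 ranks = ranks, concordance = conc),
            class = "park_evaluation")
}

#' @export
print.park_evaluation <- function(x, ...) {
  cat("Park evaluation -", nrow(x$ratings), "alternatives,",
      ncol(x$ratings), "criteria,",
      length(x$weights$solutions), "experts (",
      length(x$weights$filtered$retained), "retained )\n\n")
  print(x$weights$scheme)
  cat("\n")
  print(x$vikor)
  invisible(x)
}

#' Serialize an evaluation to a JSON report
#'
#' Full precision; rounding happens only in printed comparisons.
#'
#' @param ev a [evaluate_study()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_evaluation_json <- function(ev, path) {
  obj <- list(
    config = unclass(ev$config),
    weights = list(criteria = ev$weights$scheme$criteria,
                   weights = ev$weights$scheme$weights,
                   retained = vapply(ev$weights$filtered$retained, `[[`,
                                     character(1), "expert_id"),
                   excluded = vapply(ev$weights$filtered$excluded, `[[`,
                                     character(1), "expert_id")),
    vikor = as.data.frame(ev$vikor),
    priorities = lapply(attr(ev$vikor, "priorities"), function(p)
      list(criterion = names(p), weighted_gap = unname(p))),
    scores = lapply(ev$methods, function(s)
      list(orientation = s$orientation, values = as.list(s$values))),
    ranks = lapply(ev$ranks, function(r)
      list(orientation = r$orientation, rank = as.list(r$rank))),
    concordance = list(rho = ev$concordance$rho,
                       average = as.list(ev$concordance$average)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Reproduce the published tables from the bundled fixtures
#'
#' Recomputes, from the bundled transcriptions alone: the Modified VIKOR
#' synthesized gaps and ranking from the printed per-criterion weighted
#' gaps (trusted cases only), the SAW performances as the complement of
#' the gap sums, and the full orientation-aligned Spearman matrix with its
#' average row from the printed rank columns. Each recomputed cell is
#' compared with its printed counterpart.
#'
#' Printed inputs carry 3 decimals, so a quantity recomputed from them can
#' legitimately differ from its printed counterpart by the propagated
#' input-rounding error. Each check therefore uses the worst-case bound for
#' its own arithmetic: half an ulp (0.0005) per rounded cell entering a sum
#' — 0.0025 for a synthesized gap (8 summed cells at delta = 0.5 plus the
#' max term), 0.004 for a SAW complement (8 summed cells), half an ulp for
#' a Spearman cell (computed from exact integer ranks), 0.001 for an
#' average-correlation entry (the printed averages are themselves rounded
#' from rounded cells), and exact equality for ranks.
#'
#' @param config a [run_config()]; deviating from the default settings
#'   (e.g. `regret = "unweighted"`, `align_correlations = FALSE`) shows
#'   which checks those conventions break.
#' @return An object of class `repro_report`: data frame with columns
#'   `check`, `computed`, `printed`, `pass`; attribute `status` is 0 when
#'   all checks pass, 2 otherwise.
#' @export
repro_report <- function(config = run_config()) {
  fx <- load_fixtures()
  rows <- list()
  add <- function(check, computed, printed, tol)
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, computed = computed, printed = printed,
      pass = abs(computed - printed) <= tol + 1e-9)

  vik <- modified_vikor(fx$gaps_trusted, delta = config$delta,
                        regret = config$regret)
  printed <- fx$vikor_printed[match(vik$alternative, fx$vikor_printed$case), ]
  for (i in seq_len(nrow(vik)))
    add(paste0("V case ", vik$alternative[i]), vik$V[i], printed$V[i], 0.0025)

  # the printed ranking column follows from the printed V values
  rk <- rank_alternatives(method_scores("Modified VIKOR",
                                        stats::setNames(fx$vikor_printed$V,
                                                        fx$vikor_printed$case),
                                        "gap"))
  for (i in seq_along(rk$rank))
    add(paste0("V rank case ", fx$vikor_printed$case[i]),
        rk$rank[i], fx$vikor_printed$rank[i], 0)

  sw <- saw(fx$gaps_trusted)
  sp <- fx$methods$SAW$values[names(sw$values)]
  for (i in seq_along(sw$values))
    add(paste0("SAW case ", names(sw$values)[i]), sw$values[[i]], sp[[i]],
        0.004)

  cm <- correlation_matrix(fx$ranks, align = config$align_correlations)
  nm <- rownames(cm$rho)
  for (i in seq_len(length(nm) - 1)) for (j in (i + 1):length(nm))
    add(paste0("rho ", nm[i], " vs ", nm[j]),
        cm$rho[i, j], fx$spearman$rho[i, j], 0.0005)
  for (i in seq_along(nm))
    add(paste0("average rho ", nm[i]), cm$average[[i]],
        fx$spearman$average[[i]], 0.001)

  out <- do.call(rbind, rows)
  structure(out, status = if (all(out$pass)) 0L else 2L,
            class = c("repro_report", "data.frame"))
}

#' @export
print.repro_report <- function(x, ...) {
  n <- nrow(x); ok <- sum(x$pass)
  cat("Reproduction report:", ok, "of", n, "checks pass\n")
  if (ok < n) {
    cat("failing cells:\n")
    y <- x[!x$pass, ]
    y[c("computed", "printed")] <- round(y[c("computed", "printed")], 3)
    print.data.frame(y, row.names = FALSE)
  }
  invisible(x)
}
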