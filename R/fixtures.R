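# Frozen md5 digests of the bundled table transcriptions; load_fixtures()
# refuses silently edited copies.
.fixture_md5 <- c(
  criteria.csv        = "80a25826ea8ab8dd31bbf5fece30882b",
  table3_weights.csv  = "7aee2a0cb092cacda100238f854e748b",
  table4_gaps.csv     = "d70ded7cd8b860fb4e6b4ba28ce977a6",
  table5_methods.csv  = "081da0edf51f30e54e75f9546d589ec9",
  table6_spearman.csv = "d04beb9bdd7622e736565c1eeb103623"
)

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "agepark")
  if (path == "") stop("bundled fixture '", file, "' not found", call. = FALSE)
  path
}

#' Load the bundled nine-park evaluation tables
#'
#' Returns the published nine-community-park evaluation as package objects:
#' the final BWM criterion weights (printed as rounded percentages summing
#' to 100.1, renormalized on load), the per-criterion weighted gap matrix
#' with its printed synthesized gaps and ranking, the six ranking methods'
#' performance values and ranks, the printed Spearman concordance matrix,
#' and the criteria catalogue.
#'
#' One printed gap row is known-corrupt: case 9's per-criterion gaps
#' duplicate case 1's verbatim while its synthesized gap differs, so its
#' gap row cannot be trusted. The row is flagged (`gaps_corrupt`), and
#' gap-based reproduction work should use `gaps_trusted` (cases 1-8);
#' case 9's printed rank columns are internally consistent and remain
#' usable.
#'
#' @param integrity verify the frozen md5 checksum of every fixture file
#'   before parsing (default `TRUE`).
#' @return A list with elements `criteria` (data frame), `weights`
#'   ([weight_scheme()], source `"fixture"`), `gaps` (`weighted_gap_matrix`,
#'   all 9 cases), `gaps_trusted` (cases 1-8), `gaps_corrupt` (character
#'   vector of corrupt case labels), `vikor_printed` (data frame: case,
#'   synthesized gap V, rank), `methods` (named list of [method_scores()]),
#'   `ranks` (named list of `rank_vector`s as printed), and `spearman`
#'   (list: `rho` printed matrix, `average` printed row).
#' @export
load_fixtures <- function(integrity = TRUE) {
  if (integrity) {
    for (f in names(.fixture_md5)) {
      got <- unname(tools::md5sum(.extdata(f)))
      if (!identical(got, unname(.fixture_md5[[f]])))
        stop("fixture-integrity error: ", f, " does not match its frozen ",
             "transcription checksum", call. = FALSE)
    }
  }
  criteria <- utils::read.csv(.extdata("criteria.csv"), check.names = FALSE)

  w3 <- utils::read.csv(.extdata("table3_weights.csv"), check.names = FALSE)
  weights <- weight_scheme(w3$criterion, w3$weight_pct / 100, source = "fixture")

  t4 <- utils::read.csv(.extdata("table4_gaps.csv"), check.names = FALSE)
  gmat <- as.matrix(t4[, weights$criteria])
  rownames(gmat) <- as.character(t4$case)
  gaps <- as_weighted_gaps(gmat, weights)
  corrupt <- as.character(t4$case[t4$corrupted])
  trusted <- as_weighted_gaps(gmat[!t4$corrupted, , drop = FALSE], weights)
  vikor_printed <- data.frame(case = as.character(t4$case),
                              V = t4$synthesized_gap, rank = t4$rank)

  t5 <- utils::read.csv(.extdata("table5_methods.csv"), check.names = FALSE)
  spec <- list(`Modified VIKOR` = c("mv", "gap"),
               VIKOR            = c("vikor", "gap"),
               SAW              = c("saw", "utility"),
               TOPSIS           = c("topsis", "utility"),
               `PROMETHEE II`   = c("promethee", "utility"),
               EXPERT           = c("expert", "utility"))
  cases <- as.character(t5$case)
  methods <- lapply(names(spec), function(nm) {
    v <- stats::setNames(t5[[paste0(spec[[nm]][1], "_performance")]], cases)
    method_scores(nm, v, spec[[nm]][2])
  })
  names(methods) <- names(spec)
  ranks <- lapply(names(spec), function(nm) {
    structure(list(method = nm,
                   rank = stats::setNames(
                     as.numeric(t5[[paste0(spec[[nm]][1], "_rank")]]), cases),
                   orientation = spec[[nm]][2]),
              class = "rank_vector")
  })
  names(ranks) <- names(spec)

  t6 <- utils::read.csv(.extdata("table6_spearman.csv"), check.names = FALSE)
  rho <- as.matrix(t6[t6$method != "Average correlation", -1])
  rownames(rho) <- t6$method[t6$method != "Average correlation"]
  avg <- unlist(t6[t6$method == "Average correlation", -1])

  list(criteria = criteria, weights = weights, gaps = gaps,
       gaps_trusted = trusted, gaps_corrupt = corrupt,
       vikor_printed = vikor_printed, methods = methods, ranks = ranks,
       spearman = list(rho = rho, average = avg))
}

#' @rdname load_fixtures
#' @export
park_tables <- load_fixtures
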