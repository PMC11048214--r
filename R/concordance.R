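#' Pathogenicity-predictor label lexicons
#'
#' Categorical outputs from heterogeneous pathogenicity predictors (SIFT,
#' PolyPhen flavours, APOGEE, MutPred, PhD-SNP, PON-mt-tRNA, MitoTIP, ...)
#' are condensed to `D` (deleterious) or `B` (benign) via two editable
#' lexicons; anything outside both (VUS, empty, "conflicting", unknown
#' vocabulary) becomes `NA`. Matching is case-insensitive and tolerant of
#' `_`/`-` vs space.
#'
#' @param path Optional JSON file with fields `deleterious` and `benign`
#'   overriding the bundled defaults.
#' @return List with character vectors `deleterious` and `benign`.
#' @export
predictor_lexicons <- function(path = NULL) {
  if (!is.null(path)) {
    lex <- jsonlite::read_json(path, simplifyVector = TRUE)
    stopifnot(all(c("deleterious", "benign") %in% names(lex)))
    return(lex[c("deleterious", "benign")])
  }
  list(
    deleterious = c("possibly damaging", "probably damaging", "deleterious",
                    "pathogenic", "medium deleterious", "high deleterious"),
    benign = c("tolerated", "benign", "neutral", "likely benign")
  )
}

normalise_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("\\s+", " ", gsub("[_-]", " ", x))
}

#' Simplify raw predictor labels to D/B/NA
#'
#' @param raw Character vector of raw categorical predictor labels.
#' @param lexicons Lexicon list from [predictor_lexicons()].
#' @return Character vector of `"D"`, `"B"` or `NA`.
#' @examples
#' simplify_label(c("Probably_Damaging", "tolerated", "VUS"))
#' @export
simplify_label <- function(raw, lexicons = predictor_lexicons()) {
  x <- normalise_label(raw)
  out <- rep(NA_character_, length(x))
  out[x %in% normalise_label(lexicons$deleterious)] <- "D"
  out[x %in% normalise_label(lexicons$benign)] <- "B"
  out
}

#' Five-level concordance score across predictors
#'
#' With `n_D` deleterious and `n_B` benign simplified calls for one variant:
#' any profile containing both D and B calls is conflicting and scores 0
#' (so the +/-1 and +/-2 levels require unanimity among non-NA calls);
#' otherwise `n_D >= 4` scores +2, `1 <= n_D <= 3` scores +1, `n_B >= 4`
#' scores -2, `1 <= n_B <= 3` scores -1, and an unpredicted variant
#' (`n_D = n_B = 0`) scores 0.
#'
#' @param simplified Character vector of `"D"`/`"B"`/`NA` calls for one
#'   variant (may be empty).
#' @param conflicting_zero If `FALSE`, mixed profiles are scored by the
#'   majority class count instead of forcing 0 (non-default reading).
#' @return List with integer `score` and counts `n_D`, `n_B`.
#' @examples
#' score_variant(c("D", "D", "D", "D", "D"))$score  # +2
#' score_variant(character(0))$score                #  0
#' @export
score_variant <- function(simplified, conflicting_zero = TRUE) {
  n_D <- sum(simplified == "D", na.rm = TRUE)
  n_B <- sum(simplified == "B", na.rm = TRUE)
  score <- if (conflicting_zero && n_D >= 1 && n_B >= 1) {
    0L
  } else if (n_D >= 4 && n_D > n_B) {
    2L
  } else if (n_D >= 1 && n_D > n_B) {
    1L
  } else if (n_B >= 4 && n_B > n_D) {
    -2L
  } else if (n_B >= 1 && n_B > n_D) {
    -1L
  } else {
    0L
  }
  list(score = score, n_D = n_D, n_B = n_B)
}

#' Score a variant-by-predictor label table
#'
#' @param labels Data frame of raw predictor labels, one row per variant, one
#'   column per predictor (id columns may be excluded via `id_cols`).
#' @param id_cols Names of non-predictor columns carried through unchanged.
#' @param lexicons Lexicon list from [predictor_lexicons()].
#' @param conflicting_zero See [score_variant()].
#' @return `labels` with appended integer columns `n_D`, `n_B`, `score`.
#' @export
score_table <- function(labels, id_cols = character(0),
                        lexicons = predictor_lexicons(),
                        conflicting_zero = TRUE) {
  pred_cols <- setdiff(names(labels), id_cols)
  if (length(pred_cols) == 0L) stop("no predictor columns")
  simp <- vapply(pred_cols,
                 function(cn) simplify_label(labels[[cn]], lexicons),
                 character(nrow(labels)))
  if (nrow(labels) == 1L) simp <- matrix(simp, nrow = 1L)
  scored <- apply(simp, 1L, function(r) score_variant(r, conflicting_zero))
  labels$n_D <- vapply(scored, `[[`, integer(1), "n_D")
  labels$n_B <- vapply(scored, `[[`, integer(1), "n_B")
  labels$score <- vapply(scored, `[[`, integer(1), "score")
  labels
}
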