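## Normalization of PROVEAN and DANN evidence to categorical B/D/U calls.
## The clinical tables print categorical calls obtained from the tools' web
## front-ends at default settings; raw scores are therefore only a fallback,
## and a categorical input always wins.

.normCall <- function(categorical) {
    if (is.na(categorical)) return(NA_character_)
    if (categorical == "N") return("U")   # undocumented table entry -> U
    if (!categorical %in% c("B", "D", "U"))
        stop("categorical call must be one of B/D/U", call. = FALSE)
    categorical
}

#' Categorical PROVEAN call
#'
#' PROVEAN measures the impact of an amino-acid change on protein function;
#' more negative scores are more damaging. A categorical input (as printed in
#' the clinical tables) is passed through unchanged; otherwise a score at or
#' below the cutoff is deleterious. With neither, the variant is unscorable
#' (e.g. start-loss or frameshift notation) and the call is U.
#'
#' @param score PROVEAN score, or NA.
#' @param categorical precomputed \code{"B"}/\code{"D"}/\code{"U"} call, or
#'   NA. Takes precedence over the score.
#' @param cutoff deleteriousness cutoff; the tool's published default is
#'   -2.5.
#' @return A list with elements \code{tool}, \code{call} and \code{source}
#'   (\code{categorical_input}, \code{score_threshold} or
#'   \code{unscorable}).
#' @examples
#' callProvean(categorical = "D")$call        # "D"
#' callProvean(score = -7.1)$call             # "D"
#' callProvean()$call                         # "U"
#' @export
callProvean <- function(score = NA, categorical = NA, cutoff = -2.5) {
    if (!is.na(categorical))
        return(list(tool = "provean", call = .normCall(categorical),
                    source = "categorical_input"))
    if (!is.na(score))
        return(list(tool = "provean",
                    call = if (score <= cutoff) "D" else "B",
                    source = "score_threshold"))
    list(tool = "provean", call = "U", source = "unscorable")
}

#' Categorical DANN call
#'
#' DANN scores deleteriousness in [0, 1], higher = more damaging. Categorical
#' input takes precedence; otherwise a score at or above the cutoff is
#' deleterious; with neither the call is U.
#'
#' @param score DANN score in [0, 1], or NA.
#' @param categorical precomputed \code{"B"}/\code{"D"}/\code{"U"} call, or
#'   NA.
#' @param cutoff deleteriousness cutoff (default 0.96, a widely used
#'   operating point).
#' @return A list as in [callProvean()] with \code{tool = "dann"}.
#' @examples
#' callDann(score = 1.0)$call    # "D"
#' @export
callDann <- function(score = NA, categorical = NA, cutoff = 0.96) {
    if (!is.na(score) && (score < 0 || score > 1))
        stop("DANN score must lie in [0, 1]", call. = FALSE)
    if (!is.na(categorical))
        return(list(tool = "dann", call = .normCall(categorical),
                    source = "categorical_input"))
    if (!is.na(score))
        return(list(tool = "dann",
                    call = if (score >= cutoff) "D" else "B",
                    source = "score_threshold"))
    list(tool = "dann", call = "U", source = "unscorable")
}
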