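#' @title Final score and ranking
#' @description
#' The final score blends the objective (CRITIC) and subjective scores as
#' the convex combination \eqn{S_{final} = \delta S_i + \mu S_{i,sub}} with
#' \eqn{\delta + \mu = 1}; the default \eqn{\delta = \mu = 0.5} weighs both
#' considerations equally. Alternatives are ranked by descending final score
#' at full precision; display values are rounded half-up to two decimals.
#' @name ranking
NULL

#' Round half away from zero
#'
#' Unlike base `round()` (round-half-to-even), ties at 5 in the last dropped
#' digit round up, matching how the reference score tables are printed.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(0.845, 2)  # 0.85, where round() gives 0.84
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Combine objective and subjective scores
#'
#' @param critic named numeric vector of CRITIC scores.
#' @param subjective numeric vector of subjective scores over the same
#'   alternatives (matched by name when both are named).
#' @param delta weight on the objective score, in [0, 1]; the subjective
#'   weight is `mu = 1 - delta`. Default 0.5.
#' @return A `score_table` data frame with columns `alternative`,
#'   `critic_score`, `subjective_score`, `final_score` and attributes
#'   `delta`, `mu`.
#' @export
final_scores <- function(critic, subjective, delta = 0.5) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta < 0 || delta > 1)
    stop("delta must be a single number in [0, 1]", call. = FALSE)
  if (length(critic) != length(subjective))
    stop("score vectors have different lengths", call. = FALSE)
  if (!is.null(names(critic)) && !is.null(names(subjective))) {
    if (!setequal(names(critic), names(subjective)))
      stop("score vectors cover different alternatives", call. = FALSE)
    subjective <- subjective[names(critic)]
  }
  ids <- if (is.null(names(critic))) as.character(seq_along(critic)) else names(critic)
  st <- data.frame(alternative = ids,
                   critic_score = as.numeric(critic),
                   subjective_score = as.numeric(subjective),
                   final_score = delta * as.numeric(critic) +
                     (1 - delta) * as.numeric(subjective),
                   stringsAsFactors = FALSE)
  structure(st, delta = delta, mu = 1 - delta,
            class = c("score_table", "data.frame"))
}

#' Rank alternatives on their final score
#'
#' Rank 1 is the best (highest) final score. Ties are broken by higher
#' CRITIC score, then higher subjective score, then alternative identifier
#' in lexicographic order — a documented convention; reference tables never
#' tie. Ranking uses full precision, never the 2-decimal display values.
#'
#' @param st a `score_table` from [final_scores()].
#' @return The same table with a `rank` column (a permutation of 1..n); row
#'   order is preserved.
#' @export
rank_alternatives <- function(st) {
  stopifnot(inherits(st, "score_table"))
  ord <- order(-st$final_score, -st$critic_score, -st$subjective_score,
               st$alternative, method = "radix")
  st$rank <- integer(nrow(st))
  st$rank[ord] <- seq_len(nrow(st))
  st
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score table (delta = %.2f, mu = %.2f)\n",
              attr(x, "delta"), attr(x, "mu")))
  shown <- data.frame(alternative = x$alternative,
                      critic = round_half_up(x$critic_score, 2),
                      subjective = round_half_up(x$subjective_score, 2),
                      final = round_half_up(x$final_score, 2))
  if (!is.null(x$rank)) {
    shown$rank <- x$rank
    shown <- shown[order(shown$rank), ]
  }
  print(shown, row.names = FALSE)
  invisible(x)
}
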