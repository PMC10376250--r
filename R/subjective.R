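#' @title Subjective (expert) weighting
#' @description
#' Objective weights ignore clinical judgement, so the pipeline also scores
#' each alternative with an expert-elicited weight vector over the same
#' criteria: \eqn{S_{i,sub} = \sum_j w_j x'_{ij}}. The packaged default
#' scheme puts the bulk of the weight on segmentation overlap (IoU, 0.3) and
#' inference speed (FPS, 0.3) — an accurate and fast diagnosis being the
#' fundamental clinical requirement — with 0.05 each on ACC/RE/PR/F1 and 0.1
#' each on the two complexity criteria (parameter count, MACs).
#' @name subjective
NULL

#' Construct a subjective weight vector
#'
#' Weights must be named, lie in [0, 1], and sum to exactly one within 1e-9;
#' there is no silent renormalization.
#'
#' @param w named numeric vector of weights.
#' @param renormalize if TRUE, a vector not summing to one is rescaled with a
#'   warning instead of raising an error.
#' @param provenance free-text note on where the weights came from.
#' @return A `subjective_weights` vector (also class `criterion_weights`).
#' @export
subjective_weights <- function(w, renormalize = FALSE, provenance = "") {
  if (is.list(w)) w <- unlist(w)
  if (is.null(names(w)) || any(!nzchar(names(w))))
    stop("subjective weights must be named by criterion", call. = FALSE)
  if (anyNA(w) || any(w < 0) || any(w > 1))
    stop("subjective weights must lie in [0, 1]", call. = FALSE)
  s <- sum(w)
  if (abs(s - 1) > 1e-9) {
    if (!renormalize)
      stop("subjective weights must sum to one (got ",
           format(s, digits = 12), "); pass renormalize = TRUE to rescale",
           call. = FALSE)
    warning("renormalizing subjective weights (sum was ",
            format(s, digits = 12), ")", call. = FALSE)
    w <- w / s
  }
  structure(w, method = "subjective", provenance = provenance,
            class = c("subjective_weights", "criterion_weights"))
}

#' Default expert weight scheme
#'
#' @return The packaged eight-criterion expert scheme: IoU 0.3, ACC 0.05,
#'   RE 0.05, PR 0.05, F1 0.05, Params 0.1, GMACs 0.1, FPS 0.3.
#' @export
default_subjective_weights <- function() {
  subjective_weights(
    c(IoU = 0.3, ACC = 0.05, RE = 0.05, PR = 0.05, F1 = 0.05,
      Params = 0.1, GMACs = 0.1, FPS = 0.3),
    provenance = "packaged expert elicitation (endoscopists)")
}

#' Subjective scores of the alternatives
#'
#' @param nm a `normalized_matrix`.
#' @param weights a `subjective_weights` vector covering exactly `nm`'s
#'   criteria; defaults to [default_subjective_weights()].
#' @return Named numeric vector of per-alternative scores in [0, 1].
#' @export
subjective_scores <- function(nm, weights = default_subjective_weights()) {
  if (!inherits(weights, "criterion_weights")) weights <- subjective_weights(weights)
  weighted_scores(nm, weights)
}
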