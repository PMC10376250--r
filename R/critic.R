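#' @title CRITIC objective weighting
#' @description
#' CRITIC (Criteria Importance Through Intercriteria Correlation) derives
#' objective criterion weights from the decision matrix itself, with no
#' expert input. On the normalized matrix, criterion j carries
#' \deqn{C_j = \sigma_j R_j, \qquad R_j = \sum_{k=1}^{p} (1 - r_{jk})}
#' where \eqn{\sigma_j} is the column standard deviation (contrast
#' intensity), \eqn{r_{jk}} the correlation between criterion columns, and
#' \eqn{R_j} the conflict: a criterion that correlates strongly with the
#' others is largely redundant and carries little extra information. Weights
#' are the information amounts normalized to unity,
#' \eqn{\omega_j = C_j / \sum_j C_j}, and the CRITIC score of alternative i
#' is the weighted sum \eqn{S_i = \sum_j \omega_j x'_{ij}}.
#'
#' The self term in \eqn{R_j} contributes zero (\eqn{r_{jj} = 1}) and is
#' summed literally.
#' @name critic
NULL

#' Spearman rank correlation coefficient
#'
#' Ranks both vectors with average ranks for ties, then applies the Pearson
#' product-moment formula to the ranks.
#'
#' @param a,b numeric vectors of equal length >= 2, neither constant.
#' @return Correlation in [-1, 1].
#' @examples
#' spearman_rho(1:3, c(10, 20, 30))
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  if (length(a) < 2L) stop("need at least two observations", call. = FALSE)
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  da <- ra - mean(ra); db <- rb - mean(rb)
  denom <- sqrt(sum(da^2) * sum(db^2))
  if (denom == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  v <- sum(da * db) / denom
  min(1, max(-1, v))
}

critic_cor_matrix <- function(X, corr_kind) {
  p <- ncol(X)
  r <- diag(1, p)
  for (j in seq_len(p - 1L)) {
    for (k in (j + 1L):p) {
      r[j, k] <- r[k, j] <- if (corr_kind == "spearman") {
        spearman_rho(X[, j], X[, k])
      } else {
        stats::cor(X[, j], X[, k])
      }
    }
  }
  dimnames(r) <- list(colnames(X), colnames(X))
  r
}

#' CRITIC diagnostics: contrast, conflict, information
#'
#' @param nm a `normalized_matrix` (see [normalize_matrix()]).
#' @param sd_form `"sample"` (divisor n-1, default) or `"population"`
#'   (divisor n). The two differ by a constant factor per column, which
#'   cancels in the weight normalization, so downstream scores are identical.
#' @param corr_kind `"pearson"` (default; calibrated against the packaged
#'   reference table, and the choice of the original CRITIC formulation) or
#'   `"spearman"` (rank correlation).
#' @param corr_basis `"normalized"` (default) computes correlations on the
#'   normalized, direction-consistent columns; `"raw"` uses the raw columns
#'   for sensitivity analysis.
#' @return An object of class `critic_diagnostics`: per-criterion `sigma`,
#'   `conflict`, `information`, the `corr` matrix, and the settings used.
#' @export
critic_diagnostics <- function(nm,
                               sd_form = c("sample", "population"),
                               corr_kind = c("pearson", "spearman"),
                               corr_basis = c("normalized", "raw")) {
  sd_form <- match.arg(sd_form)
  corr_kind <- match.arg(corr_kind)
  corr_basis <- match.arg(corr_basis)
  if (!inherits(nm, "normalized_matrix"))
    stop("critic_diagnostics expects a normalized matrix; call normalize_matrix() first",
         call. = FALSE)
  X <- nm$values
  const <- apply(X, 2, function(x) max(x) == min(x))
  if (any(const))
    stop("degenerate criterion with zero contrast: ",
         paste(colnames(X)[const], collapse = ", "), call. = FALSE)
  sigma <- apply(X, 2, function(x) {
    if (sd_form == "sample") stats::sd(x) else sqrt(mean((x - mean(x))^2))
  })
  basis <- if (corr_basis == "normalized") X else nm$raw
  corr <- critic_cor_matrix(basis, corr_kind)
  conflict <- colSums(1 - corr)
  structure(list(sigma = sigma, conflict = conflict,
                 information = sigma * conflict, corr = corr,
                 sd_form = sd_form, corr_kind = corr_kind,
                 corr_basis = corr_basis),
            class = "critic_diagnostics")
}

#' @export
print.critic_diagnostics <- function(x, ...) {
  cat(sprintf("CRITIC diagnostics (%s SD, %s correlation on %s matrix)\n",
              x$sd_form, x$corr_kind, x$corr_basis))
  print(round(data.frame(sigma = x$sigma, conflict = x$conflict,
                         information = x$information), 4))
  invisible(x)
}

#' CRITIC objective weights
#'
#' @param diagnostics a `critic_diagnostics` object.
#' @return A named `criterion_weights` vector summing to one, with attribute
#'   `method` = `"critic"`.
#' @export
critic_weights <- function(diagnostics) {
  stopifnot(inherits(diagnostics, "critic_diagnostics"))
  total <- sum(diagnostics$information)
  if (total <= 0)
    stop("no information: all criteria have zero contrast or zero conflict",
         call. = FALSE)
  w <- diagnostics$information / total
  structure(w, method = "critic", class = "criterion_weights")
}

#' @export
print.criterion_weights <- function(x, ...) {
  cat(sprintf("%s weights (sum = %.9f)\n", attr(x, "method"), sum(x)))
  print(round(unclass(x), 4))
  invisible(x)
}

#' CRITIC scores of the alternatives
#'
#' @param nm a `normalized_matrix`.
#' @param weights weights over exactly `nm`'s criteria (any named vector
#'   summing to one).
#' @return Named numeric vector of per-alternative scores in [0, 1].
#' @export
critic_scores <- function(nm, weights) {
  weighted_scores(nm, weights)
}

# shared weighted-sum kernel for the objective and subjective scores
weighted_scores <- function(nm, weights) {
  if (!inherits(nm, "normalized_matrix"))
    stop("scores are computed on a normalized matrix", call. = FALSE)
  wn <- names(weights)
  if (is.null(wn) || !setequal(wn, nm$criteria$name))
    stop("weight names do not match the matrix criteria", call. = FALSE)
  w <- as.numeric(weights)[match(nm$criteria$name, wn)]
  if (abs(sum(w) - 1) > 1e-9)
    stop("weights must sum to one (got ", format(sum(w), digits = 12), ")",
         call. = FALSE)
  drop(nm$values %*% w)
}
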