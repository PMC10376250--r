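#' @title Reference fixture and synthetic generators
#' @description
#' The package ships, as its worked reference example, the published test
#' results of 21 gastric-polyp segmentation models (7 architectures x 3
#' encoders) on 8 criteria: five accuracy metrics in percent (IoU, ACC, RE,
#' PR, F1), parameter count in millions (Params, cost), multiply-accumulate
#' operations in GMACs (cost), and throughput in FPS (benefit). Synthetic
#' generators produce mask pairs with exact confusion counts and random
#' decision matrices with controlled correlation structure so that every
#' pipeline stage is testable offline.
#' @name fixtures
NULL

# 21 x 8 benchmark values, transcribed verbatim from the published table.
table6_values <- function() {
  vals <- matrix(c(
    94.96, 97.29, 97.31, 97.27, 97.29,  32.52, 10.70, 24,
    95.56, 97.56, 97.57, 97.55, 97.56,   6.63,  3.39, 26,
    96.53, 98.14, 98.16, 98.12, 98.14,   8.76,  2.53, 22,
    96.57, 98.18, 98.20, 98.16, 98.18,  48.99, 57.54, 20,
    96.27, 98.00, 98.03, 97.98, 98.00,   6.82,  4.50, 26,
    96.79, 98.11, 98.14, 98.09, 98.11,   9.08,  5.10, 21,
    96.23, 97.95, 97.98, 97.93, 97.96,  39.63, 40.99, 24,
    95.79, 97.69, 97.73, 97.66, 97.69,  12.65, 12.74, 26,
    95.46, 97.37, 97.40, 97.34, 97.37,   9.81,  3.37, 23,
    96.25, 97.97, 98.02, 97.93, 97.97,  26.68,  9.20, 26,
    95.22, 97.36, 97.42, 97.32, 97.37,   4.38,  1.52, 27,
    95.93, 97.75, 97.83, 97.70, 97.76,   7.41,  0.56, 23,
    96.06, 97.87, 98.00, 97.78, 97.89,   8.71, 24.26, 26,
    95.17, 97.27, 97.50, 97.14, 97.31,   2.42,  0.79, 26,
    91.83, 95.09, 98.86, 92.71, 95.52,   6.60,  0.09, 22,
    96.31, 98.03, 98.03, 98.03, 98.03,  31.18, 10.77, 26,
    95.11, 97.32, 97.33, 97.32, 97.32,   4.32,  0.94, 26,
    96.32, 98.04, 98.08, 98.00, 98.04,   3.67,  0.19, 22,
    96.34, 98.03, 98.06, 98.01, 98.03, 147.44, 18.64, 21,
    96.23, 97.98, 98.00, 97.96, 97.98,  48.89,  5.27, 24,
    96.57, 98.15, 98.16, 98.14, 98.15,  11.60,  2.41, 21),
    ncol = 8, byrow = TRUE)
  models <- rep(c("U-Net", "UNet++", "DeepLabv3", "DeepLabv3+", "PAN",
                  "LinkNet", "MA-Net"), each = 3)
  encoders <- rep(c("ResNet50", "MobileNet v2", "EfficientNet-B1"), times = 7)
  dimnames(vals) <- list(paste(models, encoders, sep = "/"),
                         c("IoU", "ACC", "RE", "PR", "F1", "Params", "GMACs", "FPS"))
  vals
}

#' Default criteria schema of the packaged benchmark
#'
#' @return A `criteria_set` with benefit directions for IoU/ACC/RE/PR/F1/FPS,
#'   cost for Params/GMACs, and the default expert weights attached.
#' @export
default_criteria <- function() {
  criteria_set(
    name = c("IoU", "ACC", "RE", "PR", "F1", "Params", "GMACs", "FPS"),
    direction = c(rep("benefit", 5), "cost", "cost", "benefit"),
    weight = c(0.3, 0.05, 0.05, 0.05, 0.05, 0.1, 0.1, 0.3),
    level = c(rep("segmentation accuracy", 5),
              rep("computational efficiency", 3)))
}

#' The packaged 21 x 8 benchmark decision matrix
#'
#' @return A `decision_matrix` of 21 model/encoder alternatives against the
#'   eight default criteria.
#' @examples
#' table6_fixture()$values["UNet++/MobileNet v2", ]
#' @export
table6_fixture <- function() {
  decision_matrix(table6_values(), criteria = default_criteria())
}

#' Published score columns of the packaged benchmark
#'
#' The three score columns (CRITIC, subjective, final) as printed alongside
#' the benchmark matrix, at their printed 2-decimal precision. Used only for
#' regression comparison, never as a computation input.
#'
#' @return Data frame with columns `alternative`, `critic`, `subjective`,
#'   `final`.
#' @export
table6_printed_scores <- function() {
  data.frame(
    alternative = rownames(table6_values()),
    critic = c(0.59, 0.75, 0.77, 0.53, 0.84, 0.73, 0.65, 0.75, 0.63, 0.81,
               0.75, 0.72, 0.77, 0.72, 0.52, 0.81, 0.71, 0.76, 0.54, 0.74, 0.74),
    subjective = c(0.63, 0.81, 0.74, 0.53, 0.88, 0.70, 0.70, 0.81, 0.65, 0.86,
                   0.82, 0.72, 0.82, 0.77, 0.33, 0.86, 0.77, 0.72, 0.55, 0.76, 0.70),
    final = c(0.61, 0.78, 0.75, 0.53, 0.86, 0.72, 0.67, 0.78, 0.64, 0.83,
              0.78, 0.72, 0.80, 0.75, 0.43, 0.83, 0.74, 0.74, 0.55, 0.75, 0.72),
    stringsAsFactors = FALSE)
}

# run fn with a private RNG stream, leaving global state untouched
with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a mask pair with exact confusion counts
#'
#' The ground truth occupies the first `tp + fn` cells in row-major order (a
#' filled block); the prediction agrees on the first `tp` of them and toggles
#' a seeded deterministic set of `fp` background pixels. `confusion(pred,
#' truth)` on the result recovers the requested counts exactly.
#'
#' @param height,width grid dimensions (positive integers).
#' @param tp,fp,fn requested confusion counts with
#'   `tp + fp + fn <= height * width`.
#' @param seed integer seed; same seed, same masks.
#' @return `list(pred =, truth =)` of logical matrices.
#' @export
gen_mask_pair <- function(height, width, tp, fp, fn, seed = 1L) {
  dims <- c(height, width)
  if (any(dims < 1) || any(dims != round(dims)))
    stop("height and width must be positive integers", call. = FALSE)
  counts <- c(tp, fp, fn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("tp, fp, fn must be non-negative integers", call. = FALSE)
  n <- height * width
  if (tp + fp + fn > n)
    stop(sprintf("counts tp+fp+fn = %d exceed the %dx%d grid", tp + fp + fn,
                 height, width), call. = FALSE)
  truth_cells <- seq_len(tp + fn)                    # filled leading block
  background <- setdiff(seq_len(n), truth_cells)
  fp_cells <- with_seed(seed, function() {
    if (fp > 0) sort(background[sample.int(length(background), fp)]) else integer(0)
  })
  make_mask <- function(cells) {
    m <- matrix(FALSE, nrow = height, ncol = width, byrow = TRUE)
    # cells index row-major; R matrices are column-major
    m[cbind((cells - 1L) %/% width + 1L, (cells - 1L) %% width + 1L)] <- TRUE
    m
  }
  list(pred = make_mask(c(seq_len(tp), fp_cells)),
       truth = make_mask(truth_cells))
}

#' Generate a random decision matrix
#'
#' @param n,p numbers of alternatives (>= 2) and criteria (>= 2).
#' @param seed integer seed.
#' @param structure `"independent"` (iid uniform columns), `"correlated"`
#'   (latent-factor columns with pairwise Spearman correlation near `rho`),
#'   or `"dominant_row"` (one alternative strictly best on every criterion;
#'   its identifier is in attribute `dominant`).
#' @param rho target pairwise rank correlation for `"correlated"`, in [0, 1].
#' @return A `decision_matrix` with criteria `C1..Cp`, all benefit, uniform
#'   subjective weights.
#' @export
gen_random_matrix <- function(n, p, seed = 1L,
                              structure = c("independent", "correlated",
                                            "dominant_row"),
                              rho = 0.8) {
  structure_kind <- match.arg(structure)
  if (n < 2 || p < 2) stop("need n >= 2 alternatives and p >= 2 criteria",
                           call. = FALSE)
  vals <- with_seed(seed, function() {
    if (structure_kind == "correlated") {
      if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
      # Gaussian latent factor; pearson loading chosen so the implied
      # Spearman correlation of the pair is approximately rho
      r_p <- min(1, 2 * sin(pi * rho / 6))
      f <- stats::rnorm(n)
      sapply(seq_len(p), function(j)
        sqrt(r_p) * f + sqrt(1 - r_p) * stats::rnorm(n))
    } else {
      m <- matrix(stats::runif(n * p), n, p)
      if (structure_kind == "dominant_row") {
        winner <- sample(n, 1)
        m[winner, ] <- apply(m, 2, max) + stats::runif(p, 0.01, 0.1)
      }
      m
    }
  })
  ids <- sprintf("alt%02d", seq_len(n))
  colnames(vals) <- sprintf("C%d", seq_len(p))
  dm <- decision_matrix(vals, ids,
                        criteria_set(colnames(vals), "benefit",
                                     weight = rep(1 / p, p)))
  if (structure_kind == "dominant_row")
    attr(dm, "dominant") <- ids[which.max(rowSums(vals))]
  dm
}
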