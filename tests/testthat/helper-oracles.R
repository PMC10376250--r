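# Independent oracles, deliberately coded by a different route than the
# package: explicit per-pixel loops, counting-based ranks, and a one-pass
# matrix-algebra CRITIC reference.

# per-pixel confusion tally by explicit double loop
brute_confusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (r in seq_len(nrow(pred))) {
    for (c in seq_len(ncol(pred))) {
      p <- pred[r, c]; t <- truth[r, c]
      if (p && t) tp <- tp + 1L
      else if (p && !t) fp <- fp + 1L
      else if (!p && t) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# direct evaluation of the metric formulas with the degenerate conventions
brute_metrics <- function(tp, fp, tn, fn) {
  safe <- function(num, den) {
    if (den > 0) num / den else if (tp + fp + fn == 0) 1 else 0
  }
  pr <- safe(tp, tp + fp)
  re <- safe(tp, tp + fn)
  c(iou = safe(tp, tp + fp + fn),
    acc = (tp + tn) / (tp + fp + tn + fn),
    re = re, pr = pr,
    f1 = if (pr + re > 0) 2 * pr * re / (pr + re) else safe(0, 0))
}

# average ranks by counting smaller/equal elements, then the Pearson
# product-moment formula written out in sums
brute_spearman <- function(a, b) {
  rank_of <- function(x) {
    vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
  }
  ra <- rank_of(a); rb <- rank_of(b)
  n <- length(a)
  num <- n * sum(ra * rb) - sum(ra) * sum(rb)
  den <- sqrt(n * sum(ra^2) - sum(ra)^2) * sqrt(n * sum(rb^2) - sum(rb)^2)
  num / den
}

# one-pass CRITIC pipeline on raw values via matrix algebra
reference_critic_scores <- function(values, directions) {
  n <- nrow(values)
  X <- values
  for (j in seq_len(ncol(X))) {
    rng <- range(X[, j])
    X[, j] <- if (directions[j] == "cost") (rng[2] - X[, j]) / diff(rng)
              else (X[, j] - rng[1]) / diff(rng)
  }
  Z <- scale(X)                        # centered, sample-sd scaled
  corr <- crossprod(Z) / (n - 1)
  sigma <- apply(X, 2, stats::sd)
  C <- sigma * colSums(1 - corr)
  drop(X %*% (C / sum(C)))
}

# deterministic random logical mask
random_mask <- function(h, w, p = 0.5) {
  matrix(stats::runif(h * w) < p, h, w)
}
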