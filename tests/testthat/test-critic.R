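norm2 <- function(vals, directions = "benefit") {
  p <- ncol(vals)
  colnames(vals) <- paste0("c", seq_len(p))
  normalize_matrix(decision_matrix(vals, paste0("m", seq_len(nrow(vals))),
                                   criteria_set(colnames(vals), directions)))
}

test_that("spearman_rho handles order, reversal, ties and degeneracy", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1)

  a <- c(1, 2, 2, 4); b <- c(1, 3, 2, 4)
  expect_equal(spearman_rho(a, b), brute_spearman(a, b), tolerance = 1e-12)
  expect_equal(spearman_rho(a, b), cor(a, b, method = "spearman"),
               tolerance = 1e-12)

  expect_error(spearman_rho(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("spearman_rho matches stats::cor on random tied data", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    a <- sample(1:6, n, replace = TRUE) + runif(n, 0, 0.01)
    b <- sample(1:6, n, replace = TRUE)
    if (max(b) == min(b)) next
    expect_equal(spearman_rho(a, b), cor(a, b, method = "spearman"),
                 tolerance = 1e-12)
    expect_equal(spearman_rho(a, b), brute_spearman(a, b), tolerance = 1e-12)
  }
})

test_that("critic_diagnostics computes sigma, conflict and information", {
  # identical columns: full correlation, zero conflict, zero information
  nm <- norm2(cbind(c(1, 2, 3), c(1, 2, 3)))
  d <- critic_diagnostics(nm, corr_kind = "spearman")
  expect_equal(unname(d$conflict), c(0, 0))
  expect_equal(unname(d$information), c(0, 0))
  expect_error(critic_weights(d), "no information")

  # anti-correlated columns: hand-derived sigma, R, C
  nm <- norm2(cbind(c(1, 2, 3), c(3, 2, 1)))
  for (kind in c("spearman", "pearson")) {
    d <- critic_diagnostics(nm, corr_kind = kind)
    expect_equal(unname(d$sigma), c(0.5, 0.5))   # sample SD of (0, .5, 1)
    expect_equal(unname(d$conflict), c(2, 2))
    expect_equal(unname(d$information), c(1, 1))
    expect_equal(d$information, d$sigma * d$conflict)
    expect_equal(d$corr, t(d$corr))
    expect_equal(unname(diag(d$corr)), c(1, 1))
    w <- critic_weights(d)
    expect_equal(as.numeric(w), c(0.5, 0.5))
  }

  # population SD differs by sqrt((n-1)/n) but weights are unchanged
  nm <- norm2(matrix(runif(12), 4, 3))
  ds <- critic_diagnostics(nm, sd_form = "sample")
  dp <- critic_diagnostics(nm, sd_form = "population")
  expect_equal(dp$sigma, ds$sigma * sqrt(3 / 4), tolerance = 1e-12)
  expect_equal(critic_weights(dp), critic_weights(ds), tolerance = 1e-12)
})

test_that("critic_weights are proportional to information and sum to one", {
  d <- structure(list(sigma = c(a = 1, b = 1), conflict = c(a = 3, b = 1),
                      information = c(a = 3, b = 1)),
                 class = "critic_diagnostics")
  expect_equal(unclass(critic_weights(d)), c(a = 0.75, b = 0.25),
               ignore_attr = TRUE)
  set.seed(3)
  nm <- norm2(matrix(runif(24), 6, 4))
  w <- critic_weights(critic_diagnostics(nm))
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(w >= 0 & w <= 1))
})

test_that("critic_scores: dominance, mirror rows, weight-name checks", {
  # dominant row normalizes to all ones and scores 1
  vals <- rbind(c(5, 9, 4), c(1, 3, 2), c(2, 5, 3))
  nm <- norm2(vals)
  w <- critic_weights(critic_diagnostics(nm))
  s <- critic_scores(nm, w)
  expect_equal(unname(s[1]), 1)
  expect_true(all(s <= 1 + 1e-12 & s >= 0))

  # two alternatives, one dominating: min-max endpoints give exactly {1, 0}
  nm2 <- norm2(rbind(c(4, 9), c(1, 2)))
  s2 <- critic_scores(nm2, c(c1 = 0.4, c2 = 0.6))
  expect_equal(sort(unname(s2)), c(0, 1))

  expect_error(critic_scores(nm, c(x = 0.5, y = 0.5)), "do not match")
  expect_error(critic_scores(nm, c(c1 = 0.5, c2 = 0.4, c3 = 0.4)), "sum to one")
})

test_that("scores and weights are invariant under row permutation", {
  set.seed(9)
  vals <- matrix(runif(18), 6, 3, dimnames = list(NULL, paste0("c", 1:3)))
  ids <- paste0("m", 1:6)
  crit <- criteria_set(colnames(vals), "benefit")
  nm <- normalize_matrix(decision_matrix(vals, ids, crit))
  w <- critic_weights(critic_diagnostics(nm))
  s <- critic_scores(nm, w)
  perm <- sample(6)
  nm_p <- normalize_matrix(decision_matrix(vals[perm, ], ids[perm], crit))
  w_p <- critic_weights(critic_diagnostics(nm_p))
  expect_equal(w_p, w, tolerance = 1e-12)
  expect_equal(critic_scores(nm_p, w_p), s[perm], tolerance = 1e-12)
})

test_that("critic_scores matches the independent one-pass reference", {
  set.seed(21)
  for (i in 1:20) {
    vals <- matrix(runif(15, 1, 100), 5, 3,
                   dimnames = list(paste0("m", 1:5), paste0("c", 1:3)))
    directions <- sample(c("benefit", "cost"), 3, replace = TRUE)
    dm <- decision_matrix(vals, rownames(vals),
                          criteria_set(colnames(vals), directions))
    nm <- normalize_matrix(dm)
    s <- critic_scores(nm, critic_weights(critic_diagnostics(nm)))
    expect_equal(unname(s), unname(reference_critic_scores(vals, directions)),
                 tolerance = 1e-12)
  }
})

test_that("raw-basis correlation is exposed for sensitivity analysis", {
  vals <- cbind(c1 = c(10, 20, 70), c2 = c(9, 4, 2))
  dm <- decision_matrix(vals, paste0("m", 1:3),
                        criteria_set(colnames(vals), c("benefit", "cost")))
  nm <- normalize_matrix(dm)
  d_norm <- critic_diagnostics(nm, corr_basis = "normalized")
  d_raw <- critic_diagnostics(nm, corr_basis = "raw")
  # on the normalized basis the cost column is flipped, so the sign differs
  expect_equal(d_raw$corr[1, 2], -d_norm$corr[1, 2], tolerance = 1e-12)
})
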