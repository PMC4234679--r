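test_that("exact SD-mean proportionality gives slope 1 and a gamma call", {
  means <- c(50, 100, 200)
  amounts <- unlist(lapply(means, function(m) exact_mean_sd_group(m, 0.3 * m)))
  group <- rep(c("g1", "g2", "g3"), each = 12)
  vm <- variance_mean_slope(amounts, group)
  expect_equal(vm$slope, 1, tolerance = 1e-10)
  expect_equal(vm$lambda_hat, 2, tolerance = 1e-10)
  expect_identical(vm$suggested_family, "gamma-like")
})

test_that("identical SDs across differing means give slope 0", {
  means <- c(50, 100, 200, 400)
  amounts <- unlist(lapply(means, function(m) exact_mean_sd_group(m, 5)))
  group <- rep(paste0("g", 1:4), each = 12)
  vm <- variance_mean_slope(amounts, group)
  expect_equal(vm$slope, 0, tolerance = 1e-10)
  expect_equal(vm$lambda_hat, 0, tolerance = 1e-10)
  expect_identical(vm$suggested_family, "constant-variance")
})

test_that("lambda-hat is exactly twice the slope (doubling rule)", {
  # groups constructed with SD = c * mean^1.057 exactly, the slope reported
  # for leafy-vegetable-like data
  means <- c(30, 60, 120, 240)
  amounts <- unlist(lapply(means, function(m)
    exact_mean_sd_group(m, 0.2 * m^1.057)))
  group <- rep(paste0("g", 1:4), each = 12)
  vm <- variance_mean_slope(amounts, group)
  expect_equal(vm$slope, 1.057, tolerance = 1e-9)
  expect_equal(vm$lambda_hat, 2.114, tolerance = 1e-9)
  expect_equal(vm$lambda_hat, 2 * vm$slope)
})

test_that("small groups are excluded and degenerate inputs error", {
  amounts <- c(exact_mean_sd_group(50, 10), exact_mean_sd_group(100, 20),
               exact_mean_sd_group(150, 30), 60, 70)  # last group n = 2
  group <- c(rep("a", 12), rep("b", 12), rep("c", 12), "d", "d")
  vm <- variance_mean_slope(amounts, group)
  expect_equal(vm$n_excluded, 1L)
  expect_false(vm$groups$used[vm$groups$group == "d"])

  expect_error(variance_mean_slope(c(1, 2, -3, 4), rep("a", 4)), "positive")
  expect_error(variance_mean_slope(rep(c(1, 2), 4), rep(c("a", "b"), each = 4)),
               ">= 3 groups")
})

test_that("variance power recovery: simulated Var = k^2 * mean^delta", {
  set.seed(101)
  means <- exp(seq(log(20), log(200), length.out = 12))
  n_per <- 400
  for (delta in c(0, 1, 2)) {
    amounts <- unlist(lapply(means, function(m) {
      s <- 3 * m^(delta / 2)
      pmax(stats::rnorm(n_per, m, s), 0.1)
    }))
    group <- rep(seq_along(means), each = n_per)
    vm <- variance_mean_slope(amounts, group)
    expect_lt(abs(vm$slope - delta / 2), 3 * vm$slope_se)
  }
})

test_that("empirical logit matches direct evaluation and stays finite", {
  expect_equal(empirical_logit(3, 10), log(3.5 / 7.5))
  expect_equal(empirical_logit(3, 10), -0.7621401, tolerance = 1e-6)
  expect_equal(empirical_logit(0, 5), log(0.5 / 5.5))
  expect_equal(empirical_logit(0, 5), -2.397895, tolerance = 1e-6)
  expect_equal(empirical_logit(5, 5), 2.397895, tolerance = 1e-6)
  expect_true(is.finite(empirical_logit(0, 1000)))
  expect_error(empirical_logit(6, 5), "0 <= y <= n")
})

test_that("empirical logit curve bins Q with never-consumers first", {
  q <- c(0, 0, 0, 5, 9.99, 10, 15, 25, 25, 40)
  r <- c(0, 1, 0, 1, 1, 0, 1, 1, 1, 0)
  curve <- empirical_logit_curve(r, q, bin_width = 10)
  expect_identical(curve$category[1], "Q=0")
  expect_equal(curve$n[1], 3)
  expect_equal(curve$y[1], 1)
  expect_equal(curve$logit[1], log(1.5 / 2.5))
  # bins: [0,10) holds 5 and 9.99; [10,20) holds 10 and 15; [20,30); [40,50)
  expect_equal(curve$n, c(3, 2, 2, 2, 1))
  expect_true(all(is.finite(curve$logit)))

  # oracle equivalence on a random small table
  set.seed(33)
  q2 <- c(rep(0, 20), stats::rgamma(80, 2, 0.05))
  r2 <- stats::rbinom(100, 1, 0.4)
  curve2 <- empirical_logit_curve(r2, q2, bin_width = 10)
  oracle <- oracle_empirical_logit(r2, q2, 10)
  expect_equal(curve2$n, unname(oracle[, "n"]))
  expect_equal(curve2$y, unname(oracle[, "y"]))
  expect_equal(curve2$logit, unname(oracle[, "logit"]))
})

test_that("single-category input warns and returns a length-1 curve", {
  expect_warning(curve <- empirical_logit_curve(c(1, 0, 1), c(0, 0, 0)),
                 "single category")
  expect_equal(nrow(curve), 1L)
  expect_true(attr(curve, "degenerate"))
})

test_that("empirical logit curve is monotone when true probability is", {
  set.seed(55)
  n <- 20000
  q <- stats::rgamma(n, shape = 1.2, scale = 30)
  p <- stats::plogis(-1.5 + 0.8 * log1p(q))
  r <- stats::rbinom(n, 1, p)
  curve <- empirical_logit_curve(r, q, bin_width = 10)
  big <- curve[curve$n >= 200, ]
  # a smooth fit through the binned logits must be increasing over the grid
  lo <- stats::loess(logit ~ q_mean, data = big, span = 0.9)
  grid <- seq(min(big$q_mean), max(big$q_mean), length.out = 50)
  fitted <- stats::predict(lo, newdata = data.frame(q_mean = grid))
  expect_true(all(diff(fitted) > -0.02))
})

test_that("AIC transform selection finds the generating transform", {
  set.seed(202)
  n <- 5000
  wins <- c(log = 0, identity = 0)
  for (rep in 1:12) {
    x1 <- stats::rnorm(n)
    q <- stats::rgamma(n, shape = 1.2, scale = 40)
    # log-linear truth
    p_log <- stats::plogis(-2 + 1.2 * log1p(q) + 0.2 * x1)
    d_log <- data.frame(Q = q, x1 = x1,
                        R = stats::rbinom(n, 1, p_log) *
                          stats::rgamma(n, 2, 0.02))
    sel <- select_transform("probability", d_log, "x1")
    wins["log"] <- wins["log"] + (sel$chosen == "log")
    # linear truth
    p_id <- stats::plogis(-1.5 + 0.03 * q + 0.2 * x1)
    d_id <- data.frame(Q = q, x1 = x1,
                       R = stats::rbinom(n, 1, p_id) *
                         stats::rgamma(n, 2, 0.02))
    sel_id <- select_transform("probability", d_id, "x1")
    wins["identity"] <- wins["identity"] + (sel_id$chosen == "identity")
  }
  expect_gte(wins[["log"]], 10)
  expect_gte(wins[["identity"]], 10)
})

test_that("transform ties break toward the simpler candidate", {
  # Q constant: all transforms give identical fits, so AICs tie and the
  # simplicity order identity < sqrt < log must decide
  set.seed(8)
  d <- data.frame(Q = rep(4, 300),
                  x1 = stats::rnorm(300),
                  R = stats::rbinom(300, 1, 0.5) * stats::rgamma(300, 2, 0.1))
  sel <- select_transform("probability", d, "x1", tie_tol = 1e-6)
  expect_identical(sel$chosen, "identity")
})

test_that("the spline partial prediction is produced on request", {
  ca <- make_calib_fixture(800, seed = 61)
  sel <- select_transform("probability", ca, c("x1"), spline = TRUE)
  expect_false(is.null(sel$spline_partial))
  expect_true(all(c("Q", "partial") %in% names(sel$spline_partial)))
  expect_equal(nrow(sel$spline_partial), 100)
})
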