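test_that("model specs enforce hierarchy and transform rules", {
  expect_error(model_spec("probability", "log1p", main_effects = "age",
                          interactions = "sex"), "absent from main_effects")
  expect_error(model_spec("amount", "identity", main_effects = "sex",
                          quad_age = TRUE), "requires 'age'")
  sp <- model_spec("probability", "log1p", main_effects = c("age", "sex"),
                   interactions = "sex")
  expect_s3_class(sp, "model_spec")
})

test_that("the standard specs mirror the published covariate sets", {
  specs <- build_standard_specs()
  mains <- c("bmi", "smoking_status", "physical_activity", "alcohol",
             "education", "age", "energy", "sex", "season", "center",
             "weight")
  expect_setequal(specs$probability$main_effects, mains)
  expect_setequal(specs$amount$main_effects, mains)
  # five Q interactions in each part, including Q x center
  expect_length(specs$probability$interactions, 5)
  expect_setequal(specs$probability$interactions,
                  c("sex", "age", "season", "bmi", "center"))
  expect_true("center" %in% specs$amount$interactions)
  # quadratic age in the amount part only
  expect_true(specs$amount$quad_age)
  expect_false(specs$probability$quad_age)
})

test_that("intercept-only two-part fit recovers the sample fractions", {
  # 40% consumers, every positive amount exactly 120, Q pure noise: the
  # MLE must reproduce the sample fractions exactly (saturated-mean property)
  n <- 200
  set.seed(1)
  r <- c(rep(0, 120), rep(120, 80))
  d <- data.frame(subject_id = as.character(1:n), Q = stats::runif(n), R = r)
  sp1 <- model_spec("probability", "identity")
  sp2 <- model_spec("amount", "identity")
  fit <- fit_two_part(d, sp1, sp2)
  p_hat <- mean(stats::predict(fit$part1$fit, type = "response"))
  mu_hat <- mean(stats::predict(fit$part2$fit, type = "response"))
  expect_equal(mean(r > 0), 0.4)
  expect_equal(p_hat, 0.4, tolerance = 1e-6)
  expect_equal(mu_hat, 120, tolerance = 1e-6)
})

test_that("degenerate consumer patterns violate the preconditions", {
  d <- make_calib_fixture(50)
  d$R <- abs(d$R) + 1  # everyone consumes
  expect_error(fit_two_part(d, model_spec("probability", "log1p"),
                            model_spec("amount", "sqrt")),
               "consumers and non-consumers")
  d$R <- 0
  expect_error(fit_two_part(d, model_spec("probability", "log1p"),
                            model_spec("amount", "sqrt")),
               "consumers and non-consumers")
})

test_that("both GLM parts agree with direct likelihood maximisation", {
  ca <- make_calib_fixture(30, seed = 12)
  sp1 <- model_spec("probability", "log1p", main_effects = "x1")
  sp2 <- model_spec("amount", "log1p", main_effects = "x1")
  fit <- fit_two_part(ca, sp1, sp2)

  X1 <- cbind(1, log1p(ca$Q), ca$x1)
  b1 <- oracle_logistic(X1, as.integer(ca$R > 0))
  expect_equal(unname(fit$part1$coefficients), unname(b1), tolerance = 1e-6)

  cons <- ca$R > 0
  X2 <- cbind(1, log1p(ca$Q[cons]), ca$x1[cons])
  b2 <- oracle_gamma_log(X2, ca$R[cons])
  expect_equal(unname(fit$part2$coefficients), unname(b2), tolerance = 1e-6)
})

test_that("gamma IRLS with step halving matches glm on well-behaved data", {
  set.seed(14)
  n <- 500
  x <- stats::rnorm(n)
  y <- stats::rgamma(n, shape = 2, scale = exp(1 + 0.5 * x) / 2)
  X <- cbind(1, x)
  b <- twopartRC:::irls_gamma_log(X, y)
  b_glm <- stats::coef(stats::glm(y ~ x, family = stats::Gamma("log")))
  expect_equal(unname(b), unname(b_glm), tolerance = 1e-7)
})

test_that("predicted usual intake is the product of the two parts", {
  ca <- make_calib_fixture(400, seed = 23)
  sp1 <- model_spec("probability", "log1p", main_effects = "x1")
  sp2 <- model_spec("amount", "sqrt", main_effects = "x1")
  fit <- fit_two_part(ca, sp1, sp2)
  pred <- predict_usual_intake(fit, ca)
  d1 <- twopartRC:::prepare_model_frame(sp1, ca)
  d2 <- twopartRC:::prepare_model_frame(sp2, ca)
  p <- stats::predict(fit$part1$fit, newdata = d1, type = "response")
  mu <- stats::predict(fit$part2$fit, newdata = d2, type = "response")
  expect_equal(pred$predicted, unname(p * mu))
  expect_true(all(pred$p_consumption > 0 & pred$p_consumption < 1))
  expect_true(all(pred$amount > 0))
})

test_that("extreme flagging uses five times the 99th percentile", {
  # 1000 predictions whose 99th percentile is exactly 300: ranks 990 and 991
  # both hold the value 300
  pred <- c(seq_len(988) * 0.3, rep(300, 10), 1600, 200)
  stopifnot(length(pred) == 1000)
  expect_equal(stats::quantile(sort(pred), 0.99, names = FALSE), 300)
  thr <- 5 * stats::quantile(pred, 0.99, names = FALSE)
  expect_equal(thr, 1500)
  expect_true(1600 > thr)
  expect_false(200 > thr)

  # and the same rule inside the prediction path
  ca <- make_calib_fixture(500, seed = 31)
  fit <- fit_two_part(ca, model_spec("probability", "log1p"),
                      model_spec("amount", "sqrt"))
  out <- predict_usual_intake(fit, ca)
  expect_equal(attr(out, "threshold"),
               5 * stats::quantile(out$predicted, 0.99, names = FALSE))
  expect_equal(out$extreme, out$predicted > attr(out, "threshold"))
})

test_that("near-certain consumption degenerates to the amount prediction", {
  set.seed(41)
  n <- 600
  q <- stats::rgamma(n, shape = 4, scale = 30)
  # a handful of non-consumers scattered over the low-Q range (overlapping
  # with low-Q consumers, so the logistic part is identifiable)
  consumed <- rep(1L, n)
  consumed[sample(order(q)[1:100], 12)] <- 0L
  r <- consumed * stats::rgamma(n, shape = 3, scale = exp(3) / 3)
  d <- data.frame(subject_id = as.character(1:n), Q = q, R = r)
  fit <- fit_two_part(d, model_spec("probability", "log1p"),
                      model_spec("amount", "sqrt"))
  pred <- predict_usual_intake(fit, d)
  hi <- d$Q > stats::quantile(d$Q, 0.5)
  expect_true(all(pred$p_consumption[hi] > 0.99))
  expect_equal(pred$predicted[hi], pred$amount[hi], tolerance = 0.01)
})

test_that("unseen factor levels at prediction time are reported", {
  ca <- make_calib_fixture(200, seed = 51)
  fit <- fit_two_part(ca, model_spec("probability", "log1p",
                                     main_effects = "g"),
                      model_spec("amount", "sqrt", main_effects = "g"))
  new <- ca[1:5, ]
  new$g <- factor("c")
  expect_error(predict_usual_intake(fit, new), "unseen at fit time.*c")
})

test_that("one-part linear calibration matches the normal equations", {
  # exact line: R = 2 Q
  d <- data.frame(subject_id = as.character(1:10),
                  Q = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  d$R <- 2 * d$Q
  fit <- suppressWarnings(fit_one_part(d, model_spec("one_part", "identity")))
  expect_equal(unname(fit$coefficients), c(0, 2), tolerance = 1e-10)
  expect_equal(unname(stats::residuals(fit$fit)), rep(0, 10), tolerance = 1e-10)

  # normal-equations oracle on a 10-row fixture with a covariate
  set.seed(71)
  d$x1 <- stats::rnorm(10)
  d$R <- 5 + 1.5 * d$Q + 2 * d$x1 + stats::rnorm(10)
  fit2 <- fit_one_part(d, model_spec("one_part", "identity",
                                     main_effects = "x1"))
  X <- cbind(1, d$Q, d$x1)
  b <- solve(crossprod(X), crossprod(X, d$R))
  expect_equal(unname(fit2$coefficients), drop(b), tolerance = 1e-10)

  # fitted-mean property: prediction at covariate means equals mean(R)
  at_mean <- data.frame(subject_id = "m", Q = mean(d$Q), x1 = mean(d$x1))
  p <- suppressWarnings(predict_one_part(fit2, at_mean))
  expect_equal(p$predicted, mean(d$R), tolerance = 1e-10)
})

test_that("rank-deficient one-part designs name the aliased column", {
  d <- make_calib_fixture(50, seed = 81)
  d$dup <- d$x1
  expect_error(fit_one_part(d, model_spec("one_part", "identity",
                                          main_effects = c("x1", "dup"))),
               "aliased.*dup")
})

test_that("negative one-part predictions are kept and counted", {
  set.seed(91)
  d <- data.frame(subject_id = as.character(1:200),
                  Q = stats::rgamma(200, 1.2, 0.02))
  d$R <- pmax(0, -30 + 0.5 * d$Q + stats::rnorm(200, 0, 10))
  fit <- fit_one_part(d, model_spec("one_part", "identity"))
  expect_warning(p <- predict_one_part(fit, d), "negative")
  expect_gt(attr(p, "n_negative"), 0)
  expect_true(any(p$predicted < 0))
})

test_that("backward elimination respects hierarchy and keeps Q", {
  set.seed(111)
  n <- 3000
  q <- stats::rgamma(n, 1.5, 0.03)
  sex <- factor(sample(c("F", "M"), n, replace = TRUE))
  noise <- stats::rnorm(n)
  # interaction Q x sex truly active, sex main effect null
  p <- stats::plogis(-1 + 0.01 * q + 0.02 * q * (sex == "M"))
  r <- stats::rbinom(n, 1, p) * stats::rgamma(n, 2, 0.02)
  d <- data.frame(subject_id = as.character(1:n), Q = q, sex = sex,
                  noise = noise, R = r)
  sp <- model_spec("probability", "identity",
                   main_effects = c("sex", "noise"),
                   interactions = "sex")
  red <- backward_eliminate(d, sp, alpha = 0.2)
  # hierarchy: sex retained as a main effect while Q x sex is in the model
  expect_true("sex" %in% red$main_effects)
  expect_true("sex" %in% red$interactions)
  # the pure-noise covariate should usually go; at minimum the reduced spec
  # is nested in the input spec
  expect_true(all(red$main_effects %in% sp$main_effects))
  expect_true(all(red$interactions %in% sp$interactions))
  path <- attr(red, "elimination_path")
  expect_false("qt" %in% path$term)
})

test_that("fully significant specs are returned unchanged", {
  set.seed(121)
  n <- 4000
  q <- stats::rgamma(n, 1.5, 0.03)
  x1 <- stats::rnorm(n)
  p <- stats::plogis(-1.5 + 0.02 * q + 0.8 * x1)
  r <- stats::rbinom(n, 1, p) * stats::rgamma(n, 2, 0.02)
  d <- data.frame(subject_id = as.character(1:n), Q = q, x1 = x1, R = r)
  sp <- model_spec("probability", "identity", main_effects = "x1")
  red <- backward_eliminate(d, sp, alpha = 0.2)
  expect_equal(red$main_effects, sp$main_effects)
  expect_equal(nrow(attr(red, "elimination_path")), 0L)
})

test_that("fit scores match brute-force oracles", {
  # AUC equals the all-pairs concordance count, ties included
  set.seed(131)
  score <- round(stats::runif(20), 1)  # rounding forces ties
  label <- stats::rbinom(20, 1, 0.5) == 1
  if (all(label) || !any(label)) label[1:2] <- c(TRUE, FALSE)
  expect_equal(twopartRC:::auc_rank(score, label), oracle_auc(score, label))

  # perfect separation and random scores
  expect_equal(twopartRC:::auc_rank(c(1, 2, 3, 10, 11, 12),
                                    c(rep(FALSE, 3), rep(TRUE, 3))), 1)
  set.seed(141)
  lab <- rep(c(TRUE, FALSE), each = 5000)
  expect_lt(abs(twopartRC:::auc_rank(stats::runif(10000), lab) - 0.5), 0.02)

  # RMSE and mean bias definitions on a fitted model
  ca <- make_calib_fixture(300, seed = 151)
  fit <- fit_two_part(ca, model_spec("probability", "log1p"),
                      model_spec("amount", "sqrt"))
  sc <- score_fit(fit, ca)
  cons <- ca$R > 0
  d2 <- twopartRC:::prepare_model_frame(fit$part2$spec, ca[cons, ])
  mu <- stats::predict(fit$part2$fit, newdata = d2, type = "response")
  expect_equal(sc$rmse, sqrt(mean((ca$R[cons] - mu)^2)))
  expect_equal(sc$mean_bias, mean(mu - ca$R[cons]))
  expect_gte(sc$rmse, abs(sc$mean_bias))
  expect_error(score_fit(fit, transform(ca, R = 0)), "no consumers")
})

test_that("predictions are monotone in Q when both parts increase in Q", {
  set.seed(161)
  n <- 800
  q <- stats::rgamma(n, 2, 0.03)
  p <- stats::plogis(-1 + 0.8 * log1p(q))
  r <- stats::rbinom(n, 1, p) * stats::rgamma(n, 2, 2 / exp(2 + 0.3 * log1p(q)))
  d <- data.frame(subject_id = as.character(1:n), Q = q, R = r)
  fit <- fit_two_part(d, model_spec("probability", "log1p"),
                      model_spec("amount", "log1p"))
  expect_gt(fit$part1$coefficients[["qt"]], 0)
  expect_gt(fit$part2$coefficients[["qt"]], 0)
  grid <- data.frame(subject_id = as.character(1:50),
                     Q = seq(0, max(q), length.out = 50))
  pg <- predict_usual_intake(fit, grid)
  expect_true(all(diff(pg$predicted) >= 0))
})

test_that("mean predicted intake matches mean truth on generator data", {
  cfg <- generator_preset("default", n_main = 5000, n_calib = 5000, seed = 171)
  co <- generate_cohort(cfg)
  ca <- draw_reference(co, cfg)
  specs <- build_standard_specs()
  fit <- fit_two_part(ca, specs$probability, specs$amount)
  pred <- predict_usual_intake(fit, co)
  se <- stats::sd(ca$R) / sqrt(nrow(ca))
  expect_lt(abs(mean(pred$predicted) - mean(co$T)), 3 * se)
})
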