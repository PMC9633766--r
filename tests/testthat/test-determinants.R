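sim_clustered <- function(n_cl, per_cl, beta, sigma, seed, p_x = 0.5) {
  set.seed(seed)
  u <- rnorm(n_cl, 0, sigma)
  cl <- rep(seq_len(n_cl), each = per_cl)
  x <- rbinom(n_cl * per_cl, 1, p_x)
  y <- rbinom(length(x), 1, plogis(beta[1] + beta[2] * x + u[cl]))
  list(y = y, X = cbind("(Intercept)" = 1, x = x), cl = cl)
}

test_that("the PPH risk profile is the union of its four risk factors", {
  expect_true(risk_profile(FALSE, FALSE, FALSE, 4200))
  expect_false(risk_profile(FALSE, FALSE, FALSE, 3200))
  expect_true(risk_profile(TRUE, FALSE, FALSE, 3200))
  expect_true(is.na(risk_profile(FALSE, FALSE, FALSE, NA)))
  expect_true(risk_profile(FALSE, TRUE, FALSE, NA))  # determinable despite NA
  expect_equal(risk_profile(c(TRUE, FALSE), c(FALSE, FALSE),
                            c(FALSE, FALSE), c(3000, 4400)), c(TRUE, TRUE))
})

make_unit_data <- function(n = 60, seed = 5) {
  set.seed(seed)
  data.frame(
    inadequate = rbinom(n, 1, 0.25) == 1,
    unit_id = sample(paste0("U", 1:8), n, replace = TRUE),
    level_of_care = sample(c("1", "2", "3"), n, replace = TRUE),
    status = sample(c("public_university", "public_non_university",
                      "private"), n, replace = TRUE),
    annual_deliveries_band = sample(c(">=3500", "<1000"), n, replace = TRUE),
    onsite_anesthesiologist_24_7 = sample(c(TRUE, FALSE), n, replace = TRUE),
    risk_profile = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

test_that("designs are dummy-coded against the fixed reference levels", {
  d <- build_design(make_unit_data(), "level_of_care")
  expect_equal(colnames(d$X),
               c("(Intercept)", "level_of_care2", "level_of_care1"))
  d2 <- build_design(make_unit_data(), "status",
                     adjustment_set = "risk_profile")
  expect_true(all(c("statusprivate", "risk_profileTRUE") %in% colnames(d2$X)))
  # staffing indicator: absence is the coded level, presence the reference
  d3 <- build_design(make_unit_data(), "onsite_anesthesiologist_24_7")
  expect_equal(setdiff(colnames(d3$X), "(Intercept)"),
               "onsite_anesthesiologist_24_7no")
})

test_that("unobserved factor levels are dropped with a warning", {
  dat <- make_unit_data()
  dat$level_of_care <- "2"   # single observed level
  w <- capture_warnings(d0 <- build_design(dat, "level_of_care"))
  expect_true(any(grepl("single observed level", w)))
  expect_equal(colnames(d0$X), "(Intercept)")  # no dummies
  dat$level_of_care <- sample(c("2", "3"), nrow(dat), replace = TRUE)
  w2 <- capture_warnings(d <- build_design(dat, "level_of_care"))
  expect_true(any(grepl("unobserved level", w2)))
  expect_equal(colnames(d$X), c("(Intercept)", "level_of_care2"))
})

test_that("variance inflation factors match their closed forms", {
  set.seed(31)
  X <- cbind(a = c(rep(1, 10), rep(0, 10)), b = rep(c(1, 0), 10))
  expect_equal(unname(vif(X)), c(1, 1))
  w <- capture_warnings(v <- vif(cbind(a = rnorm(20), b = 1:20, dup = 1:20)))
  expect_true(any(grepl("collinearity", w)))
  expect_true(any(is.infinite(v)))
  # two standardized regressors with correlation rho have VIF 1/(1-rho^2)
  n <- 20000; rho <- 0.8
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  v2 <- vif(cbind(x1 = z1, x2 = z2))
  expect_equal(unname(v2), rep(1 / (1 - rho^2), 2), tolerance = 0.05)
})

test_that("with no cluster variance the fit collapses to ordinary logistic regression", {
  # every cluster holds the identical outcome pattern, so the
  # between-cluster variance is exactly zero and the random intercept must
  # be estimated at the boundary
  set.seed(42)
  x_pat <- rbinom(15, 1, 0.5)
  y_pat <- rbinom(15, 1, plogis(-0.5 + 0.8 * x_pat))
  x <- rep(x_pat, 40); y <- rep(y_pat, 40); cl <- rep(1:40, each = 15)
  fit <- fit_random_intercept_logistic(y, cbind("(Intercept)" = 1, x = x), cl)
  glm_fit <- glm(y ~ x, family = binomial())
  expect_lt(fit$random_intercept_sd, 1e-3)
  expect_equal(unname(fit$coefficients), unname(coef(glm_fit)),
               tolerance = 1e-4)
})

test_that("the quadrature log-likelihood matches brute-force integration on a toy dataset", {
  d <- sim_clustered(3, 4, c(-0.4, 0.9), sigma = 0.7, seed = 9)
  beta <- c(-0.3, 0.8)
  for (sigma in c(0.4, 0.9)) {
    agq <- ri_loglik(beta, sigma, d$y, d$X, d$cl, method = "agq")
    grid <- ri_loglik(beta, sigma, d$y, d$X, d$cl, method = "grid")
    brute <- oracle_ri_loglik(beta, sigma, d$y, d$X, d$cl)
    expect_equal(agq, brute, tolerance = 1e-6)
    expect_equal(grid, brute, tolerance = 1e-6)
  }
})

test_that("doubling the quadrature nodes barely moves the optimum log-likelihood", {
  d <- sim_clustered(3, 4, c(-0.4, 0.9), sigma = 0.7, seed = 9)
  fit <- fit_random_intercept_logistic(d$y, d$X, d$cl)
  b <- fit$coefficients
  ll15 <- ri_loglik(b, fit$random_intercept_sd, d$y, d$X, d$cl, nodes = 15)
  ll30 <- ri_loglik(b, fit$random_intercept_sd, d$y, d$X, d$cl, nodes = 30)
  expect_lt(abs(ll15 - ll30), 1e-4)
  expect_equal(fit$log_likelihood, ll15)
})

test_that("odds ratios are the exponentiated coefficients with ordered Wald intervals", {
  d <- sim_clustered(30, 12, c(-1, 0.7), sigma = 0.4, seed = 12)
  fit <- fit_random_intercept_logistic(d$y, d$X, d$cl)
  expect_equal(fit$odds_ratios$or, exp(unname(fit$coefficients)))
  expect_true(all(fit$odds_ratios$ci_low < fit$odds_ratios$or))
  expect_true(all(fit$odds_ratios$or < fit$odds_ratios$ci_high))
  expect_equal(fit$n_clusters, 30L)
  expect_equal(fit$n_obs, 360L)
})

suite_cohort <- function(seed = 2203) {
  sim <- simulate_cohort(default_sim_config(), seed = seed)
  prepare_analysis_dataset(sim$cohort, sim$units)$data
}

test_that("crude and adjusted models coincide under an empty adjustment set", {
  dat <- suite_cohort()
  suite <- run_model_suite(dat, stratum = "cesarean",
                           adjustment_set = character(0), nAGQ = 7)
  done <- !is.na(suite$cor) & !is.na(suite$aor)
  expect_true(any(done))
  expect_equal(suite$cor[done], suite$aor[done], tolerance = 1e-6)
})

test_that("the model suite has the published shape per stratum", {
  dat <- suite_cohort()
  suite_c <- run_model_suite(dat, stratum = "cesarean",
                             adjustment_set = character(0), nAGQ = 7)
  expect_setequal(unique(suite_c$model), paste0("model_", 1:5))
  suite_v <- run_model_suite(dat, stratum = "vaginal",
                             adjustment_set = character(0), nAGQ = 7)
  expect_setequal(unique(suite_v$model), paste0("model_", 1:6))
  expect_setequal(
    unique(suite_v$characteristic[suite_v$model == "model_6"]),
    "status_and_volume")
  # reference rows carry OR exactly 1 and no interval
  refs <- grepl("reference", suite_v$term)
  expect_true(all(suite_v$cor[refs] == 1))
  expect_true(all(is.na(suite_v$cor_low[refs])))
})

test_that("delivery-mode strata partition the analysis population", {
  dat <- suite_cohort()
  n_all <- nrow(build_design(dat, "status")$X)
  n_v <- nrow(build_design(dat[dat$delivery_mode == "vaginal", ], "status")$X)
  n_c <- nrow(build_design(dat[dat$delivery_mode == "cesarean", ], "status")$X)
  expect_equal(n_v + n_c, n_all)
})
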