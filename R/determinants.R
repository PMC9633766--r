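#' PPH risk-profile composite
#'
#' A woman is "at risk of PPH" when she has at least one risk factor among a
#' history of PPH, a multiple pregnancy, pre-eclampsia, and delivering a
#' baby with birth weight of 4000 g or more. With no positive risk factor
#' and a missing birth weight the profile is undetermined (`NA`, imputable).
#'
#' @param previous_pph,multiple_pregnancy,pre_eclampsia logical vectors.
#' @param birth_weight_g numeric vector, grams.
#' @return Logical vector (NA when undeterminable).
#' @export
risk_profile <- function(previous_pph, multiple_pregnancy, pre_eclampsia,
                         birth_weight_g) {
  tf <- function(x) !is.na(x) & as.logical(x)
  any_flag <- tf(previous_pph) | tf(multiple_pregnancy) | tf(pre_eclampsia)
  big_baby <- !is.na(birth_weight_g) & birth_weight_g >= 4000
  out <- any_flag | big_baby
  out[!any_flag & is.na(birth_weight_g)] <- NA
  out
}

# reference-first level orders for the unit characteristics and the
# maternal adjustment covariates (reference rows carry OR exactly 1)
unit_factor_levels <- list(
  status = c("public_university", "public_non_university", "private"),
  annual_deliveries_band = c(">=3500", "2000-3500", "1000-2000", "<1000"),
  level_of_care = c("3", "2", "1"))

woman_factor_levels <- list(
  country_of_birth = c("France", "other_Europe", "North_Africa",
                       "sub_Saharan_Africa", "other"),
  parity_cesarean = c("primiparous", "multip_no_prior_cesarean",
                      "multip_prior_cesarean"),
  age_band = c("25-35", "<25", ">35"),
  bmi_band = c("18.5-25", "<18.5", "25-30", ">=30"))

#' The five maternity-unit characteristics analysed as determinants
#' @return Character vector of column names.
#' @export
unit_characteristics <- function() {
  c("status", "annual_deliveries_band", "level_of_care",
    "onsite_obstetrician_24_7", "onsite_anesthesiologist_24_7")
}

#' Default maternal adjustment set
#'
#' Adjusted models control for the individual characteristics: the PPH
#' risk-profile composite, maternal country of birth, and parity / previous
#' cesarean delivery.
#' @return Character vector of covariate names.
#' @export
default_adjustment_set <- function() {
  c("risk_profile", "country_of_birth", "parity_cesarean")
}

as_analysis_factor <- function(x, name) {
  lv <- c(unit_factor_levels, woman_factor_levels)[[name]]
  if (!is.null(lv)) return(factor(as.character(x), levels = lv))
  if (name %in% c("onsite_obstetrician_24_7", "onsite_anesthesiologist_24_7")) {
    # absence is the exposure; 24/24 onsite presence is the reference
    return(factor(ifelse(as.logical(x), "yes", "no"), levels = c("yes", "no")))
  }
  if (is.logical(x) || all(x %in% c(TRUE, FALSE, NA))) return(as.logical(x))
  factor(x)
}

#' Build the regression design for one determinant model
#'
#' Dummy-codes the requested maternity-unit characteristic (or
#' `"status_and_volume"` for the combined model) plus an adjustment set,
#' with fixed reference levels: public-university status, >= 3500
#' deliveries/year, level-3 care, and 24/24 onsite presence for the two
#' staffing indicators. Levels absent from the data are dropped with a
#' warning.
#'
#' @param data data frame with the outcome column `inadequate`, `unit_id`,
#'   and the characteristic / covariate columns.
#' @param characteristic one of [unit_characteristics()] or
#'   `"status_and_volume"`.
#' @param adjustment_set character vector of covariate column names
#'   (possibly empty for a crude design).
#' @return List: `y` (0/1), `X` (model matrix incl. intercept),
#'   `cluster_ids`, `terms` (column names of X).
#' @export
build_design <- function(data, characteristic,
                         adjustment_set = character(0)) {
  vars <- if (characteristic == "status_and_volume")
    c("status", "annual_deliveries_band") else characteristic
  stopifnot(all(vars %in% names(data)), "inadequate" %in% names(data),
            "unit_id" %in% names(data))
  all_vars <- c(vars, adjustment_set)
  df <- data.frame(row.names = seq_len(nrow(data)))
  for (v in all_vars) df[[v]] <- as_analysis_factor(data[[v]], v)
  for (v in all_vars) {
    if (is.factor(df[[v]])) {
      obs <- levels(droplevels(df[[v]]))
      if (length(obs) < nlevels(df[[v]]))
        warning(sprintf("dropping unobserved level(s) of '%s': %s", v,
                        paste(setdiff(levels(df[[v]]), obs), collapse = ", ")),
                call. = FALSE)
      if (length(obs) < 2)
        warning(sprintf("'%s' has a single observed level; no contrast", v),
                call. = FALSE)
      df[[v]] <- droplevels(df[[v]])
    }
  }
  y <- as.integer(data$inadequate)
  keep <- stats::complete.cases(df) & !is.na(y)
  estimable <- all_vars[vapply(all_vars, function(v)
    !is.factor(df[[v]]) || nlevels(df[[v]]) >= 2, logical(1))]
  form <- stats::as.formula(paste("~", if (length(estimable))
    paste(estimable, collapse = " + ") else "1"))
  X <- stats::model.matrix(form, df[keep, , drop = FALSE])
  list(y = y[keep], X = X, cluster_ids = data$unit_id[keep],
       terms = colnames(X))
}

#' Variance inflation factors
#'
#' VIF_k = 1 / (1 - R^2_k), where R^2_k comes from regressing column k on
#' all other columns (with intercept). Perfect collinearity is reported as
#' `Inf` with a warning.
#'
#' @param X numeric design matrix; an `(Intercept)` column, if present, is
#'   excluded from the diagnostics.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) < 2) stop("need at least two non-intercept columns", call. = FALSE)
  out <- vapply(seq_len(ncol(X)), function(k) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((X[, k] - mean(X[, k]))^2)
    if (r2 >= 1 - 1e-12) {
      warning("perfect collinearity: infinite VIF", call. = FALSE)
      Inf
    } else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, colnames(X))
}

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' Evaluates the marginal likelihood
#' L(beta, sigma) = prod_j int prod_{i in j} p_ij^y (1-p_ij)^(1-y)
#' phi(u; 0, sigma^2) du with logit(p_ij) = x_ij' beta + u_j, either by
#' adaptive Gauss-Hermite quadrature (integrand re-centred at its
#' per-cluster mode and re-scaled by its curvature) or by brute-force
#' trapezoidal integration on a dense grid, used as an internal
#' cross-check of the quadrature.
#'
#' @param beta fixed-effect coefficients (matching columns of `X`).
#' @param sigma random-intercept standard deviation (>= 0).
#' @param y 0/1 outcomes; `X` design matrix; `cluster_ids` cluster labels.
#' @param method "agq" or "grid".
#' @param nodes number of quadrature nodes (agq) — default 15.
#' @param grid_width,grid_points half-width (in sd of the integrand
#'   envelope) and number of points of the dense grid.
#' @return Marginal log-likelihood (scalar).
#' @export
ri_loglik <- function(beta, sigma, y, X, cluster_ids,
                      method = c("agq", "grid"), nodes = 15,
                      grid_width = 12, grid_points = 20001) {
  method <- match.arg(method)
  X <- as.matrix(X)
  eta0 <- drop(X %*% beta)
  if (sigma <= 0) {
    p <- stats::plogis(eta0)
    return(sum(y * log(p) + (1 - y) * log1p(-p)))
  }
  cl <- split(seq_along(y), cluster_ids)
  log_integrand <- function(u, idx) {
    # log of prod Bernoulli * normal density, as a function of u
    eta <- outer(eta0[idx], u, "+")
    ll <- colSums(y[idx] * stats::plogis(eta, log.p = TRUE) +
                  (1 - y[idx]) * stats::plogis(-eta, log.p = TRUE))
    ll + stats::dnorm(u, 0, sigma, log = TRUE)
  }
  if (method == "agq") {
    gh <- pracma::gaussHermite(nodes)
    sum(vapply(cl, function(idx) {
      opt <- stats::optimize(function(u) -log_integrand(u, idx),
                             interval = c(-12 * sigma, 12 * sigma),
                             tol = 1e-10)
      mode <- opt$minimum
      h <- 1e-4 * max(sigma, 1)
      curv <- (log_integrand(mode + h, idx) - 2 * log_integrand(mode, idx) +
               log_integrand(mode - h, idx)) / h^2
      tau <- 1 / sqrt(max(-curv, 1e-12))
      u <- mode + sqrt(2) * tau * gh$x
      lg <- log_integrand(u, idx)
      m <- max(lg)
      log(sqrt(2) * tau) + m + log(sum(gh$w * exp(gh$x^2) * exp(lg - m)))
    }, numeric(1)))
  } else {
    sum(vapply(cl, function(idx) {
      u <- seq(-grid_width * sigma, grid_width * sigma,
               length.out = grid_points)
      lg <- log_integrand(u, idx)
      m <- max(lg)
      du <- u[2] - u[1]
      w <- rep(1, grid_points); w[c(1, grid_points)] <- 0.5
      m + log(sum(w * exp(lg - m)) * du)
    }, numeric(1)))
  }
}

#' Fit a random-intercept logistic regression
#'
#' Maximum marginal likelihood via adaptive Gauss-Hermite quadrature
#' (default 15 nodes), with a normally distributed random intercept for the
#' cluster (maternity unit). Estimation is delegated to
#' [lme4::glmer()]; the reported `log_likelihood` is re-evaluated with the
#' package's own quadrature ([ri_loglik()]) at the fitted parameters.
#' Confidence intervals are Wald intervals on the log-odds scale,
#' exponentiated for odds ratios.
#'
#' @param y 0/1 outcome vector.
#' @param X design matrix including an `(Intercept)` column (as produced by
#'   [build_design()]).
#' @param cluster_ids cluster labels, one per observation.
#' @param nAGQ quadrature nodes (default 15; 1 = Laplace).
#' @param conf_level confidence level for Wald intervals (default 0.95).
#' @return Object of class `pph_fit`: `coefficients`, `standard_errors`,
#'   `random_intercept_sd`, `odds_ratios` (data frame: term, or, ci_low,
#'   ci_high), `log_likelihood`, `converged`, `singular` (sigma estimated at
#'   the zero boundary), `n_obs`, `n_clusters`.
#' @export
fit_random_intercept_logistic <- function(y, X, cluster_ids, nAGQ = 15,
                                          conf_level = 0.95) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(cluster_ids) == nrow(X),
            all(y %in% c(0, 1)))
  fixed <- colnames(X)[colnames(X) != "(Intercept)"]
  safe <- paste0("v", seq_along(fixed))
  df <- as.data.frame(X[, fixed, drop = FALSE])
  names(df) <- safe
  df$.y <- y
  df$.cl <- factor(cluster_ids)
  rhs <- if (length(safe)) paste(safe, collapse = " + ") else "1"
  form <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .cl)"))
  converged <- TRUE
  fit <- withCallingHandlers(
    tryCatch(
      lme4::glmer(form, data = df, family = stats::binomial(), nAGQ = nAGQ),
      error = function(e) e),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error")) {
    return(structure(list(coefficients = NULL, standard_errors = NULL,
                          random_intercept_sd = NA_real_, odds_ratios = NULL,
                          log_likelihood = NA_real_, converged = FALSE,
                          singular = NA, n_obs = length(y),
                          n_clusters = length(unique(cluster_ids)),
                          message = conditionMessage(fit)),
                     class = "pph_fit"))
  }
  beta <- lme4::fixef(fit)
  names(beta) <- c("(Intercept)", fixed)[seq_along(beta)]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  names(se) <- names(beta)
  sigma_u <- sqrt(unname(lme4::VarCorr(fit)$.cl[1]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  or <- data.frame(term = names(beta),
                   estimate = unname(beta), se = unname(se),
                   or = exp(unname(beta)),
                   ci_low = exp(unname(beta) - z * unname(se)),
                   ci_high = exp(unname(beta) + z * unname(se)),
                   row.names = NULL)
  b <- numeric(ncol(X))
  names(b) <- colnames(X)
  b[names(beta)] <- beta
  ll <- ri_loglik(b, sigma_u, y, X, cluster_ids,
                  method = "agq", nodes = max(nAGQ, 15))
  structure(list(coefficients = beta, standard_errors = se,
                 random_intercept_sd = sigma_u, odds_ratios = or,
                 log_likelihood = ll, converged = converged,
                 singular = lme4::isSingular(fit),
                 n_obs = length(y),
                 n_clusters = nlevels(df$.cl)),
            class = "pph_fit")
}

#' @export
print.pph_fit <- function(x, ...) {
  cat(sprintf("<random-intercept logistic fit: %d obs, %d clusters, sigma_u=%.3f, %s>\n",
              x$n_obs, x$n_clusters, x$random_intercept_sd,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  if (!is.null(x$odds_ratios)) print(x$odds_ratios, digits = 3)
  invisible(x)
}

fit_design <- function(data, characteristic, adjustment_set, nAGQ = 15) {
  d <- build_design(data, characteristic, adjustment_set)
  fit <- fit_random_intercept_logistic(d$y, d$X, d$cluster_ids, nAGQ = nAGQ)
  fit$design_terms <- d$terms
  fit
}

# pooled or single-fit OR table restricted to the characteristic's own terms
or_rows <- function(fits, characteristic, which_label) {
  vars <- if (characteristic == "status_and_volume")
    c("status", "annual_deliveries_band") else characteristic
  ok <- Filter(function(f) !is.null(f$coefficients), fits)
  if (!length(ok)) {
    return(data.frame(model = which_label, characteristic = characteristic,
                      term = NA_character_, or = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, converged = FALSE))
  }
  terms <- names(ok[[1]]$coefficients)
  keep <- terms[grepl(paste0("^(", paste(vars, collapse = "|"), ")"), terms)]
  rows <- lapply(keep, function(tm) {
    est <- vapply(ok, function(f) f$coefficients[[tm]], numeric(1))
    vr <- vapply(ok, function(f) f$standard_errors[[tm]]^2, numeric(1))
    if (length(ok) > 1) {
      p <- pool_rubin(est, vr)
      data.frame(term = tm, or = exp(p$estimate), ci_low = exp(p$ci_low),
                 ci_high = exp(p$ci_high))
    } else {
      z <- stats::qnorm(0.975)
      data.frame(term = tm, or = exp(est), ci_low = exp(est - z * sqrt(vr)),
                 ci_high = exp(est + z * sqrt(vr)))
    }
  })
  out <- do.call(rbind, rows)
  out$model <- which_label
  out$characteristic <- characteristic
  out$converged <- all(vapply(ok, function(f) isTRUE(f$converged), logical(1)))
  # reference rows, OR exactly 1, no CI
  refs <- lapply(vars, function(v) {
    lv <- unit_factor_levels[[v]]
    ref <- if (!is.null(lv)) lv[1] else "yes"
    data.frame(term = paste0(v, ref, " (reference)"), or = 1,
               ci_low = NA_real_, ci_high = NA_real_, model = which_label,
               characteristic = characteristic, converged = out$converged[1])
  })
  rbind(do.call(rbind, refs), out)[, c("model", "characteristic", "term",
                                       "or", "ci_low", "ci_high", "converged")]
}

#' Run the determinant model suite for a delivery-mode stratum
#'
#' For the requested stratum, fits for each maternity-unit characteristic a
#' crude model (characteristic + unit random intercept) and an adjusted
#' model (plus the maternal adjustment set) — models 1 to 5 — and, for the
#' vaginal stratum, the combined status + annual-volume model (model 6).
#' When `data` is a list of imputed datasets the per-imputation fits are
#' pooled with Rubin's rules on the log-odds scale.
#'
#' @param data a scored, classified cohort data frame (columns `inadequate`,
#'   `unit_id`, unit characteristics, adjustment covariates,
#'   `delivery_mode`) or a list of such data frames (imputations).
#' @param stratum "all", "vaginal" or "cesarean".
#' @param adjustment_set covariates for the adjusted models
#'   (default [default_adjustment_set()]).
#' @param nAGQ quadrature nodes per fit.
#' @return Data frame with crude (`cor`, `cor_low`, `cor_high`) and
#'   adjusted (`aor`, `aor_low`, `aor_high`) odds ratios per model term;
#'   non-converged models are flagged, never dropped.
#' @export
run_model_suite <- function(data, stratum = c("all", "vaginal", "cesarean"),
                            adjustment_set = default_adjustment_set(),
                            nAGQ = 15) {
  stratum <- match.arg(stratum)
  datasets <- if (is.data.frame(data)) list(data) else data
  datasets <- lapply(datasets, function(d) {
    if (stratum != "all") d[d$delivery_mode == stratum, , drop = FALSE] else d
  })
  chars <- unit_characteristics()
  models <- stats::setNames(as.list(chars), paste0("model_", seq_along(chars)))
  if (stratum == "vaginal") models$model_6 <- "status_and_volume"
  out <- lapply(names(models), function(ml) {
    ch <- models[[ml]]
    crude <- lapply(datasets, fit_design, characteristic = ch,
                    adjustment_set = character(0), nAGQ = nAGQ)
    adj <- lapply(datasets, fit_design, characteristic = ch,
                  adjustment_set = adjustment_set, nAGQ = nAGQ)
    ctab <- or_rows(crude, ch, ml)
    atab <- or_rows(adj, ch, ml)
    names(ctab)[names(ctab) %in% c("or", "ci_low", "ci_high")] <-
      c("cor", "cor_low", "cor_high")
    names(ctab)[names(ctab) == "converged"] <- "crude_converged"
    atab <- atab[, c("term", "or", "ci_low", "ci_high", "converged")]
    names(atab) <- c("term", "aor", "aor_low", "aor_high", "adj_converged")
    merge(ctab, atab, by = "term", all = TRUE, sort = FALSE)
  })
  res <- do.call(rbind, out)
  res$stratum <- stratum
  res[, c("stratum", "model", "characteristic", "term", "cor", "cor_low",
          "cor_high", "aor", "aor_low", "aor_high", "crude_converged",
          "adj_converged")]
}
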