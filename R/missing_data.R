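#' Multiple imputation by chained equations
#'
#' Fills in missing cells by iteratively drawing each incomplete variable
#' from a conditional model given all other analysis variables, producing
#' `m` completed datasets (default 12). Per-type default conditional
#' models: Bayesian-flavoured logistic regression for binary variables
#' (coefficients drawn from the approximate MVN posterior before drawing
#' the imputation), multinomial logistic regression fitted on a bootstrap
#' resample for unordered categoricals, and predictive mean matching (5
#' donors) for numerics. Observed cells are never modified, and the whole
#' procedure is deterministic for a fixed seed.
#'
#' @param data data frame; every variable with missing cells must be (or be
#'   coercible to) logical, factor/character, or numeric.
#' @param m number of imputed datasets (>= 2 for Rubin pooling; default 12).
#' @param n_cycles chained-equation cycles per imputation (default 10).
#' @param seed integer seed; fully determines the output.
#' @param predictors columns used as predictors in every conditional model
#'   (default: all columns of `data`).
#' @param models optional named list overriding the per-variable model type:
#'   "logistic", "multinomial" or "pmm".
#' @return Object of class `pph_mice`: list with `imputations` (list of `m`
#'   completed data frames), `missing_pattern` (logical matrix), `m`,
#'   `n_cycles`, `seed`, and `trace` (per variable x cycle x imputation mean
#'   of imputed cells, for convergence diagnostics).
#' @export
mice_impute <- function(data, m = 12, n_cycles = 10, seed = 1,
                        predictors = names(data), models = list()) {
  stopifnot(is.data.frame(data), m >= 1, n_cycles >= 1)
  miss <- is.na(data) | vapply(data, function(col)
    is.character(col) & !nzchar(trimws(as.character(col))), logical(nrow(data)))
  if (is.null(dim(miss))) miss <- matrix(miss, nrow = nrow(data))
  dimnames(miss) <- list(NULL, names(data))
  incomplete <- names(data)[colSums(miss) > 0]
  if (any(colSums(miss) == nrow(data)))
    stop("variable missing for all records: ",
         paste(names(data)[colSums(miss) == nrow(data)], collapse = ", "),
         call. = FALSE)
  work <- data
  for (v in names(work)) {
    if (is.character(work[[v]])) {
      work[[v]][miss[, v]] <- NA
      work[[v]] <- factor(work[[v]])
    }
    if (is.character(data[[v]]) || is.factor(data[[v]]))
      work[[v]] <- factor(work[[v]])
  }
  model_for <- function(v) {
    if (!is.null(models[[v]])) return(models[[v]])
    col <- work[[v]]
    if (is.logical(col) || (is.factor(col) && nlevels(col) == 2)) "logistic"
    else if (is.factor(col)) "multinomial"
    else "pmm"
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  pred_of <- function(v) setdiff(intersect(predictors, names(work)), v)
  imputations <- vector("list", m)
  trace <- list()
  for (k in seq_len(m)) {
    cur <- work
    # initial fill: sample from observed values
    for (v in incomplete) {
      obs <- cur[[v]][!miss[, v]]
      cur[[v]][miss[, v]] <- sample(obs, sum(miss[, v]), replace = TRUE)
    }
    for (cyc in seq_len(n_cycles)) {
      for (v in incomplete) {
        cur[[v]][miss[, v]] <-
          draw_conditional(cur, v, miss[, v], pred_of(v), model_for(v))
        imp_vals <- cur[[v]][miss[, v]]
        trace[[paste(v, k, cyc, sep = ".")]] <-
          if (is.numeric(imp_vals)) mean(imp_vals)
          else mean(imp_vals == levels(factor(imp_vals))[1])
      }
    }
    # restore original column types
    for (v in names(cur)) {
      if (is.character(data[[v]])) cur[[v]] <- as.character(cur[[v]])
    }
    imputations[[k]] <- cur
  }
  structure(list(imputations = imputations, missing_pattern = miss,
                 m = m, n_cycles = n_cycles, seed = seed, trace = trace),
            class = "pph_mice")
}

# one Gibbs-style draw of variable v for the rows in `which_miss`
draw_conditional <- function(cur, v, which_miss, preds, model) {
  rhs_df <- cur[preds]
  # drop single-level predictors (inestimable contrast)
  keep <- vapply(rhs_df, function(col)
    length(unique(col[!is.na(col)])) > 1, logical(1))
  rhs_df <- rhs_df[keep]
  mm <- if (ncol(rhs_df))
    stats::model.matrix(~ ., data = rhs_df) else
    matrix(1, nrow(cur), 1, dimnames = list(NULL, "(Intercept)"))
  obs <- !which_miss
  if (model == "logistic") {
    yv <- cur[[v]]
    lv <- if (is.factor(yv)) levels(yv) else c(FALSE, TRUE)
    y01 <- if (is.factor(yv)) as.integer(yv == lv[2]) else as.integer(yv)
    fit <- suppressWarnings(stats::glm.fit(mm[obs, , drop = FALSE], y01[obs],
                                           family = stats::binomial()))
    qrX <- qr(mm[obs, , drop = FALSE] *
                       sqrt(pmax(fit$weights, 1e-10)))
    R <- qr.R(qrX)
    Sigma <- tryCatch(chol2inv(R), error = function(e)
      diag(1e-4, ncol(mm)))
    bstar <- MASS::mvrnorm(1, fit$coefficients, Sigma)
    bstar[is.na(bstar)] <- 0
    p <- stats::plogis(drop(mm[which_miss, , drop = FALSE] %*% bstar))
    draw <- stats::rbinom(sum(which_miss), 1, p)
    if (is.factor(yv)) factor(lv[draw + 1], levels = lv) else as.logical(draw)
  } else if (model == "multinomial") {
    yv <- cur[[v]]
    boot <- sample(which(obs), sum(obs), replace = TRUE)
    df <- data.frame(.y = yv[boot], mm[boot, -1, drop = FALSE],
                     check.names = TRUE)
    fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 200)
    nd <- data.frame(mm[which_miss, -1, drop = FALSE], check.names = TRUE)
    pr <- stats::predict(fit, newdata = nd, type = "probs")
    if (is.null(dim(pr))) pr <- rbind(pr)
    if (ncol(pr) == 1) pr <- cbind(1 - pr, pr)
    lv <- fit$lev
    idx <- apply(pr, 1, function(p) sample.int(length(p), 1, prob = p))
    factor(lv[idx], levels = levels(yv))
  } else { # predictive mean matching
    yv <- as.numeric(cur[[v]])
    fit <- stats::lm.fit(mm[obs, , drop = FALSE], yv[obs])
    s2 <- sum(fit$residuals^2) / max(fit$df.residual, 1)
    R <- qr.R(fit$qr)
    Sigma <- tryCatch(chol2inv(R) * s2, error = function(e)
      diag(1e-4, ncol(mm)))
    b <- fit$coefficients; b[is.na(b)] <- 0
    bstar <- MASS::mvrnorm(1, b, Sigma)
    bstar[is.na(bstar)] <- 0
    pred_obs <- drop(mm[obs, , drop = FALSE] %*% b)
    pred_mis <- drop(mm[which_miss, , drop = FALSE] %*% bstar)
    donors <- vapply(pred_mis, function(pm) {
      cand <- order(abs(pred_obs - pm))[seq_len(min(5, sum(obs)))]
      sample(cand, 1)
    }, integer(1))
    yv[which(obs)[donors]]
  }
}

#' Pool estimates across imputations with Rubin's rules
#'
#' Pooled point estimate = mean of the per-imputation estimates; total
#' variance = within-imputation variance + (1 + 1/m) x between-imputation
#' variance; degrees of freedom from the classical formula
#' (m - 1)(1 + W / ((1 + 1/m) B))^2. Estimates on the log-odds scale should
#' be pooled before exponentiation. With zero between-imputation variance
#' the df are infinite and a normal quantile is used.
#'
#' @param estimates numeric vector of length m (>= 2).
#' @param variances squared standard errors, same length, positive.
#' @param conf_level confidence level (default 0.95).
#' @return Object of class `pph_pooled`: `estimate`, `within_var`,
#'   `between_var`, `total_var`, `df`, `ci_low`, `ci_high`, `m`.
#' @export
pool_rubin <- function(estimates, variances, conf_level = 0.95) {
  m <- length(estimates)
  stopifnot(m >= 2, length(variances) == m, all(variances > 0))
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  total <- w + (1 + 1 / m) * b
  df <- if (b <= 0) Inf else (m - 1) * (1 + w / ((1 + 1 / m) * b))^2
  q <- if (is.finite(df)) stats::qt(1 - (1 - conf_level) / 2, df) else
    stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(estimate = qbar, within_var = w, between_var = b,
                 total_var = total, df = df,
                 ci_low = qbar - q * sqrt(total),
                 ci_high = qbar + q * sqrt(total), m = m),
            class = "pph_pooled")
}

#' @export
print.pph_pooled <- function(x, ...) {
  cat(sprintf("<pooled (m=%d): %.4f [%.4f, %.4f], T=%.5f (W=%.5f, B=%.5f)>\n",
              x$m, x$estimate, x$ci_low, x$ci_high, x$total_var,
              x$within_var, x$between_var))
  invisible(x)
}
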