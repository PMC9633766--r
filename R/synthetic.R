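#' Default configuration of the synthetic-cohort generator
#'
#' The defaults emulate the published severe-PPH cohort: 119 maternity
#' units, roughly 1100 women, 35.7% cesarean deliveries, 69.8% uterine
#' atony, per-criterion compliance close to the published audit margins,
#' a shared unit-level latent-quality random effect (sd 0.5 on the
#' log-odds scale), and ~9.6% missing-at-random missingness in country of
#' birth. Unit characteristics are drawn from a joint table of realistic
#' archetypes (university units are large, level-3 and fully staffed;
#' private units tend to be small, level-1 and without 24/24 onsite
#' staff), which generates the real-world collinearity between status,
#' size and level of care.
#'
#' @param n_units number of maternity units.
#' @param women_per_unit list(mean, dispersion) of the negative-binomial
#'   unit size; the mean is scaled by a per-volume-band factor so larger
#'   units contribute more women.
#' @param sigma_u sd of the unit latent-quality random effect (log-odds).
#' @param effect_map named numeric vector of additive log-odds shifts on
#'   criterion compliance, keyed "column:level" (e.g.
#'   `c("onsite_anesthesiologist_24_7:no" = -0.8)`). Default: no effects.
#' @param atony_probability,cesarean_probability context mix.
#' @param missing_country_rate overall MAR missingness of country of birth.
#' @param missing_context_rate fraction of women with an unrecoverable
#'   clinical context (unscoreable records); default 0.
#' @param etiology_rate marginal rate of each etiology exclusion flag;
#'   default 0.
#' @return Named list of generator settings.
#' @export
default_sim_config <- function(n_units = 119,
                               women_per_unit = list(mean = 10.6, dispersion = 2),
                               sigma_u = 0.5,
                               effect_map = numeric(0),
                               atony_probability = 0.698,
                               cesarean_probability = 0.357,
                               missing_country_rate = 0.096,
                               missing_context_rate = 0,
                               etiology_rate = 0) {
  list(
    n_units = n_units, women_per_unit = women_per_unit, sigma_u = sigma_u,
    effect_map = effect_map, atony_probability = atony_probability,
    cesarean_probability = cesarean_probability,
    missing_country_rate = missing_country_rate,
    missing_context_rate = missing_context_rate,
    etiology_rate = etiology_rate,
    unit_table = default_unit_table(),
    # women-per-unit multiplier by annual-volume band
    volume_size_factor = c(">=3500" = 1.9, "2000-3500" = 1.3,
                           "1000-2000" = 0.75, "<1000" = 0.45),
    # per-criterion compliance and delay distributions (minutes, log-normal);
    # calibrated so the scored margins echo the published audit:
    # e.g. ~89% first-line administration with ~81% of administrations
    # within 30 min of PPH diagnosis
    criteria = list(
      prophylactic_uterotonic = list(p = 0.917),
      blood_loss_documented = list(p = 0.849),
      first_line_uterotonic = list(p = 0.889, meanlog = 2.601, sdlog = 0.9,
                                   cutoff = 30),
      hemoglobin_measured = list(p = 0.75, meanlog = 2.941, sdlog = 0.9,
                                 cutoff = 60),
      hemostasis_measured = list(p = 0.55, meanlog = 3.214, sdlog = 0.9,
                                 cutoff = 60),
      manual_uterine_exam = list(p = 0.80, meanlog = 2.201, sdlog = 0.9,
                                 cutoff = 30),
      cervix_vagina_exam = list(p = 0.63),
      second_line_uterotonic = list(p_atony = 0.65, p_no_atony = 0.357,
                                    meanlog = 2.644, sdlog = 0.9,
                                    cutoff = 30)),
    covariates = list(
      age_band = c("25-35" = 0.637, "<25" = 0.149, ">35" = 0.214),
      country_of_birth = c(France = 0.709, other_Europe = 0.034,
                           North_Africa = 0.096, sub_Saharan_Africa = 0.093,
                           other = 0.068),
      bmi_band = c("18.5-25" = 0.603, "<18.5" = 0.072, "25-30" = 0.197,
                   ">=30" = 0.128),
      parity_cesarean = c(primiparous = 0.501,
                          multip_no_prior_cesarean = 0.360,
                          multip_prior_cesarean = 0.139),
      previous_pph = 0.063, multiple_pregnancy = 0.103,
      pre_eclampsia = 0.045,
      birth_weight = list(mean = 3400, sd = 560),
      gestational_age = list(mean = 39.2, sd = 1.8),
      spontaneous_given_vaginal = 0.707,
      antepartum_given_cesarean = 0.510))
}

default_unit_table <- function() {
  tab <- read.csv(text = "status,level_of_care,annual_deliveries_band,onsite_obstetrician_24_7,onsite_anesthesiologist_24_7,prob
public_university,3,>=3500,TRUE,TRUE,0.07
public_university,3,2000-3500,TRUE,TRUE,0.08
public_university,2,2000-3500,TRUE,TRUE,0.03
public_non_university,3,2000-3500,TRUE,TRUE,0.05
public_non_university,2,2000-3500,TRUE,TRUE,0.09
public_non_university,2,1000-2000,TRUE,TRUE,0.11
public_non_university,2,1000-2000,FALSE,TRUE,0.06
public_non_university,1,<1000,FALSE,TRUE,0.07
public_non_university,1,<1000,FALSE,FALSE,0.04
private,2,1000-2000,TRUE,TRUE,0.05
private,2,1000-2000,FALSE,TRUE,0.05
private,1,2000-3500,FALSE,TRUE,0.02
private,1,1000-2000,FALSE,TRUE,0.05
private,1,<1000,FALSE,TRUE,0.15
private,1,<1000,FALSE,FALSE,0.08
", stringsAsFactors = FALSE)
  tab$level_of_care <- as.character(tab$level_of_care)
  tab
}

#' Generate maternity-unit profiles
#'
#' Draws `n_units` profiles from the configured joint characteristic table
#' and a latent quality effect u_j ~ Normal(0, sigma_u^2) shared by all
#' criteria of all women delivering in the unit.
#'
#' @param config generator configuration ([default_sim_config()]).
#' @param seed optional integer seed (the current RNG state is used when
#'   `NULL`).
#' @return Data frame: `unit_id`, characteristic columns,
#'   `latent_quality`.
#' @export
generate_units <- function(config = default_sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  tab <- config$unit_table
  if (nrow(tab) == 1) warning("degenerate unit table: a single cell",
                              call. = FALSE)
  stopifnot(abs(sum(tab$prob) - 1) < 1e-8)
  cell <- sample.int(nrow(tab), config$n_units, replace = TRUE,
                     prob = tab$prob)
  units <- tab[cell, setdiff(names(tab), "prob"), drop = FALSE]
  rownames(units) <- NULL
  units <- cbind(unit_id = sprintf("U%03d", seq_len(config$n_units)), units)
  units$latent_quality <- stats::rnorm(config$n_units, 0, config$sigma_u)
  units
}

# log-odds shift for one unit from the configured effect map
unit_effect <- function(unit_row, effect_map) {
  if (!length(effect_map)) return(0)
  keys <- names(effect_map)
  got <- vapply(keys, function(k) {
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    col <- parts[1]; lev <- parts[2]
    val <- unit_row[[col]]
    if (is.logical(val)) val <- ifelse(val, "yes", "no")
    identical(as.character(val), lev)
  }, logical(1))
  sum(effect_map[got])
}

#' Generate women nested in maternity units
#'
#' Draws per-unit cohort sizes (negative binomial scaled by the unit's
#' volume band), clinical context (delivery mode, uterine atony), maternal
#' covariates, severity indicators, and injects missing-at-random
#' missingness into country of birth with probability depending on
#' observed covariates (private-unit status and maternal age band), with
#' the per-row missingness probability recorded.
#'
#' @param units data frame from [generate_units()].
#' @param config generator configuration.
#' @param seed optional integer seed.
#' @return Data frame, one row per woman, with attribute
#'   `country_missing_prob` (the per-row MAR probability actually used).
#' @export
generate_women <- function(units, config = default_sim_config(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(nrow(units) > 0)
  fac <- config$volume_size_factor[units$annual_deliveries_band]
  n_w <- stats::rnbinom(nrow(units), size = config$women_per_unit$dispersion,
                        mu = config$women_per_unit$mean * fac)
  unit_idx <- rep(seq_len(nrow(units)), n_w)
  n <- length(unit_idx)
  cv <- config$covariates
  draw_cat <- function(p, n) sample(names(p), n, replace = TRUE, prob = p)
  cesarean <- stats::runif(n) < config$cesarean_probability
  atony <- stats::runif(n) < config$atony_probability
  detail <- ifelse(cesarean,
    ifelse(stats::runif(n) < cv$antepartum_given_cesarean,
           "antepartum_cesarean", "intrapartum_cesarean"),
    ifelse(stats::runif(n) < cv$spontaneous_given_vaginal,
           "spontaneous_vaginal", "operative_vaginal"))
  w <- data.frame(
    woman_id = sprintf("W%05d", seq_len(n)),
    unit_id = units$unit_id[unit_idx],
    delivery_mode = ifelse(cesarean, "cesarean", "vaginal"),
    uterine_atony = ifelse(atony, "yes", "no"),
    delivery_mode_detail = detail,
    age_band = draw_cat(cv$age_band, n),
    country_of_birth = draw_cat(cv$country_of_birth, n),
    bmi_band = draw_cat(cv$bmi_band, n),
    parity_cesarean = draw_cat(cv$parity_cesarean, n),
    previous_pph = stats::runif(n) < cv$previous_pph,
    multiple_pregnancy = stats::runif(n) < cv$multiple_pregnancy,
    pre_eclampsia = stats::runif(n) < cv$pre_eclampsia,
    birth_weight_g = round(stats::rnorm(n, cv$birth_weight$mean,
                                        cv$birth_weight$sd)),
    gestational_age_weeks = round(stats::rnorm(n, cv$gestational_age$mean,
                                               cv$gestational_age$sd), 1),
    stringsAsFactors = FALSE)
  # severity indicators: all generated cases are severe PPH by construction
  w$blood_loss_ml <- round(stats::rlnorm(n, log(2100), 0.35))
  w$rbc_units_transfused <- stats::rpois(n, 1.6)
  w$surgical_procedure_or_embolization <- stats::runif(n) < 0.15
  w$hemoglobin_nadir_g_dl <- round(stats::rnorm(n, 7.8, 1.1), 1)
  w$platelets_per_mm3 <- round(stats::rnorm(n, 150000, 45000))
  w$dic <- stats::runif(n) < 0.05
  w$organ_failure <- stats::runif(n) < 0.05
  w$icu_admission <- stats::runif(n) < 0.20
  w$maternal_death <- FALSE
  w$near_miss <- stats::runif(n) < 0.33
  not_severe <- !is_severe_pph(
    w$blood_loss_ml, w$rbc_units_transfused,
    w$surgical_procedure_or_embolization, w$hemoglobin_nadir_g_dl,
    w$platelets_per_mm3, w$dic, w$organ_failure, w$icu_admission,
    w$maternal_death)
  w$blood_loss_ml[not_severe] <-
    1500 + round(stats::rlnorm(sum(not_severe), log(300), 0.5))
  for (f in etiology_flag_names())
    w[[f]] <- stats::runif(n) < config$etiology_rate
  if (config$missing_context_rate > 0) {
    drop_ctx <- stats::runif(n) < config$missing_context_rate
    w$uterine_atony[drop_ctx] <- ""
  }
  # MAR missingness in country of birth: depends on unit status and age
  lp <- 0.6 * (units$status[unit_idx] == "private") +
    0.4 * (w$age_band != "25-35")
  p_miss <- if (config$missing_country_rate > 0) {
    a <- stats::uniroot(function(a) mean(stats::plogis(a + lp)) -
                          config$missing_country_rate, c(-20, 10))$root
    stats::plogis(a + lp)
  } else rep(0, n)
  w$country_of_birth[stats::runif(n) < p_miss] <- ""
  attr(w, "country_missing_prob") <- p_miss
  w
}

#' Generate criterion-level care records
#'
#' For each woman and criterion, compliance is drawn from
#' logit^-1(logit(base rate) + unit effect + u_j), where u_j is the unit's
#' latent quality. Delays for performed timed procedures are log-normal in
#' minutes; the second-line uterotonic delay is anchored at the first-line
#' administration and is only drawn when the first-line drug was given.
#'
#' @param women data frame from [generate_women()].
#' @param units data frame from [generate_units()] (carries
#'   `latent_quality`).
#' @param config generator configuration.
#' @param seed optional integer seed.
#' @return `women` with the eight criterion columns appended in the cohort
#'   cell encoding (delay minutes, "done", "not_done", "").
#' @export
generate_care <- function(women, units, config = default_sim_config(),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(women)
  ui <- match(women$unit_id, units$unit_id)
  shift <- vapply(seq_len(nrow(units)), function(j)
    unit_effect(units[j, ], config$effect_map), numeric(1))[ui] +
    units$latent_quality[ui]
  comply <- function(base_p) stats::runif(n) < stats::plogis(stats::qlogis(base_p) + shift)
  enc_untimed <- function(done) ifelse(done, "done", "not_done")
  enc_timed <- function(done, meanlog, sdlog)
    ifelse(done, as.character(round(stats::rlnorm(n, meanlog, sdlog))),
           "not_done")
  cr <- config$criteria
  women$prophylactic_uterotonic <- enc_untimed(comply(cr$prophylactic_uterotonic$p))
  women$blood_loss_documented <- enc_untimed(comply(cr$blood_loss_documented$p))
  fl_done <- comply(cr$first_line_uterotonic$p)
  women$first_line_uterotonic <-
    enc_timed(fl_done, cr$first_line_uterotonic$meanlog,
              cr$first_line_uterotonic$sdlog)
  women$hemoglobin_measured <-
    enc_timed(comply(cr$hemoglobin_measured$p), cr$hemoglobin_measured$meanlog,
              cr$hemoglobin_measured$sdlog)
  women$hemostasis_measured <-
    enc_timed(comply(cr$hemostasis_measured$p), cr$hemostasis_measured$meanlog,
              cr$hemostasis_measured$sdlog)
  women$manual_uterine_exam <-
    enc_timed(comply(cr$manual_uterine_exam$p), cr$manual_uterine_exam$meanlog,
              cr$manual_uterine_exam$sdlog)
  women$cervix_vagina_exam <- enc_untimed(comply(cr$cervix_vagina_exam$p))
  atony <- women$uterine_atony == "yes"
  sl_p <- ifelse(atony, cr$second_line_uterotonic$p_atony,
                 cr$second_line_uterotonic$p_no_atony)
  sl_done <- stats::runif(n) < stats::plogis(stats::qlogis(sl_p) + shift)
  # anchor at first-line administration: no first-line drug, no usable delay
  sl_delay <- round(stats::rlnorm(n, cr$second_line_uterotonic$meanlog,
                                  cr$second_line_uterotonic$sdlog))
  women$second_line_uterotonic <-
    ifelse(!sl_done, "not_done",
           ifelse(fl_done, as.character(sl_delay), "done"))
  women
}

#' Generate a complete synthetic severe-PPH cohort
#'
#' Convenience wrapper: units, then women, then care records, from one
#' seed. The returned truth object records the generating configuration
#' and the latent unit effects for parameter-recovery studies.
#'
#' @param config generator configuration ([default_sim_config()]).
#' @param seed integer seed (fully determines the output).
#' @return List: `cohort` (one row per woman, scoring-ready), `units`
#'   (profiles without the latent effect), `truth` (config, latent
#'   effects, MAR mechanism).
#' @export
simulate_cohort <- function(config = default_sim_config(), seed = 1) {
  set.seed(as.integer(seed))
  units <- generate_units(config)
  women <- generate_women(units, config)
  cohort <- generate_care(women, units, config)
  truth <- list(config = config, latent_quality = stats::setNames(
    units$latent_quality, units$unit_id),
    country_missing_prob = attr(women, "country_missing_prob"))
  units_out <- units[, setdiff(names(units), "latent_quality")]
  list(cohort = cohort, units = units_out, truth = truth)
}
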