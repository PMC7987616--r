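#' Configure the synthetic-records generator
#'
#' Describes a THIN/CPRD-like synthetic population with planted
#' epidemiological structure: practices with key/collection dates, patient
#' lifecycles (registration, deregistration, death), a planted exposure
#' whose first occurrence arises from a per-year Bernoulli incidence (with
#' an optional prescription entity recorded a fixed lag after it, to
#' exercise order-sensitive logic), outcome events from a
#' piecewise-exponential clock whose rate is `outcome_rate` before the
#' patient's first exposure event and `outcome_rate * hazard_ratio` after
#' it, and covariates/measurements (Townsend quintile, ethnicity, BMI,
#' HbA1c, smoking) recorded at a per-year rate with a missingness
#' fraction.  Constant hazards keep every planted rate recoverable in
#' closed form.
#'
#' Defaults describe the reference validation population: roughly 50,000
#' patients observed 1998-2019, exposure incidence 1%/year, an unexposed
#' outcome rate of 44 per 100,000 person-years and a hazard ratio of 3 —
#' the magnitudes of a primary-care epilepsy cohort — together yielding on
#' the order of 200,000 person-years of matched-cohort follow-up.
#'
#' @param n_practices,patients_per_practice population size.
#' @param span_start,span_end calendar span of the simulated database.
#' @param sex_ratio probability a patient is female.
#' @param birth_year_range inclusive range of birth years.
#' @param year_dob_fraction fraction of patients whose birth date is
#'   year-precision only.
#' @param registration_range calendar range of registration dates.
#' @param deregistration_rate,death_rate per-person-year rates of leaving
#'   the practice and of death.
#' @param exposure_codes,rx_codes,outcome_codes clinical code sets used for
#'   the planted entities.
#' @param exposure_incidence per-year probability of a first exposure
#'   record while registered.
#' @param prevalent_fraction fraction of patients carrying the exposure
#'   from registration onwards (an exposure record on their registration
#'   day), planting a known point prevalence for cross-sectional studies.
#' @param rx_prob,rx_lag_days probability that an exposure is followed by a
#'   prescription record, and its lag.
#' @param outcome_rate unexposed outcome hazard (events per person-year).
#' @param hazard_ratio multiplies the outcome hazard after the first
#'   exposure event.
#' @param bmi_mean,bmi_sd,hba1c_mean,hba1c_sd measurement value
#'   distributions (kg/m2; mmol/mol).
#' @param measurement_rate measurements per person-year (each of BMI and
#'   HbA1c).
#' @param missingness fraction of would-be measurement records never
#'   entered.
#' @param smoking_prob probability a patient has a smoking status record.
#' @param ethnicity_levels,ethnicity_probs ethnicity categories and their
#'   probabilities.
#' @param townsend_missing fraction of patients with no Townsend score.
#' @return a `sim_config` object.
#' @export
sim_config <- function(n_practices = 20,
                       patients_per_practice = 2500,
                       span_start = "1998-01-01", span_end = "2019-12-31",
                       sex_ratio = 0.5,
                       birth_year_range = c(1930, 1990),
                       year_dob_fraction = 0.05,
                       registration_range = c("1985-01-01", "2010-12-31"),
                       deregistration_rate = 0.015,
                       death_rate = 0.01,
                       exposure_codes = c("C10F.00", "C10F.11"),
                       rx_codes = "RX0001",
                       outcome_codes = "F25..00",
                       exposure_incidence = 0.01,
                       prevalent_fraction = 0,
                       rx_prob = 0.9, rx_lag_days = 30,
                       outcome_rate = 44 / 1e5,
                       hazard_ratio = 3.0,
                       bmi_mean = 27, bmi_sd = 4.5,
                       hba1c_mean = 42, hba1c_sd = 8,
                       measurement_rate = 0.4,
                       missingness = 0.2,
                       smoking_prob = 0.6,
                       ethnicity_levels = c("white", "asian", "black", "mixed", "other"),
                       ethnicity_probs = c(0.8, 0.09, 0.05, 0.03, 0.03),
                       townsend_missing = 0.1) {
  cfg <- list(
    n_practices = as.integer(n_practices),
    patients_per_practice = as.integer(patients_per_practice),
    span_start = parse_date_flex(span_start),
    span_end = parse_date_flex(span_end),
    sex_ratio = sex_ratio,
    birth_year_range = as.integer(birth_year_range),
    year_dob_fraction = year_dob_fraction,
    registration_range = parse_date_flex(registration_range),
    deregistration_rate = deregistration_rate,
    death_rate = death_rate,
    exposure_codes = exposure_codes,
    rx_codes = rx_codes,
    outcome_codes = outcome_codes,
    exposure_incidence = exposure_incidence,
    prevalent_fraction = prevalent_fraction,
    rx_prob = rx_prob, rx_lag_days = as.integer(rx_lag_days),
    outcome_rate = outcome_rate,
    hazard_ratio = hazard_ratio,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    hba1c_mean = hba1c_mean, hba1c_sd = hba1c_sd,
    measurement_rate = measurement_rate,
    missingness = missingness,
    smoking_prob = smoking_prob,
    ethnicity_levels = ethnicity_levels,
    ethnicity_probs = ethnicity_probs,
    townsend_missing = townsend_missing
  )
  rates <- c(cfg$deregistration_rate, cfg$death_rate, cfg$exposure_incidence,
    cfg$outcome_rate, cfg$measurement_rate)
  if (any(rates < 0)) abort("all rates must be non-negative")
  if (cfg$hazard_ratio <= 0) abort("hazard_ratio must be positive")
  if (cfg$prevalent_fraction < 0 || cfg$prevalent_fraction > 1) {
    abort("prevalent_fraction must lie in [0, 1]")
  }
  if (cfg$span_start >= cfg$span_end) abort("empty calendar span")
  if (cfg$registration_range[1] > cfg$registration_range[2]) {
    abort("impossible registration range")
  }
  if (abs(sum(cfg$ethnicity_probs) - 1) > 1e-8) abort("ethnicity_probs must sum to 1")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic EHR database
#'
#' Draws a complete [ehr_db()] from a [sim_config()], reproducibly from the
#' seed.  Exposure first-occurrence dates arise from per-year Bernoulli
#' draws while the patient is registered and alive; outcome events form a
#' piecewise-rate Poisson stream (rate `outcome_rate` until the first
#' exposure event, `outcome_rate * hazard_ratio` after), so a patient's
#' post-index event risk is independent of any selection on their
#' pre-index history; measurement counts are Poisson in registered time.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; everything is reproducible from it.
#' @return an `ehr_db`, with the config stored in attribute `sim_config`.
#' @export
simulate_ehr <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  n_pr <- config$n_practices
  n_pa <- n_pr * config$patients_per_practice
  span_days <- as.integer(config$span_end - config$span_start)

  practices <- tibble(
    practice_id = sprintf("p%03d", seq_len(n_pr)),
    key_date = config$span_start - sample(0:3650, n_pr, replace = TRUE),
    collection_date = config$span_end - sample(0:730, n_pr, replace = TRUE)
  )

  reg_span <- as.integer(config$registration_range[2] - config$registration_range[1])
  birth_year <- sample(config$birth_year_range[1]:config$birth_year_range[2],
    n_pa, replace = TRUE)
  birth_date <- as.Date(sprintf("%04d-01-01", birth_year)) +
    sample(0:364, n_pa, replace = TRUE)
  year_prec <- runif(n_pa) < config$year_dob_fraction
  registration_date <- config$registration_range[1] +
    sample(0:reg_span, n_pa, replace = TRUE)
  registration_date <- pmax_date(registration_date, birth_date)

  # lifecycle: competing exponential clocks from registration
  t_dereg <- rexp(n_pa, rate = max(config$deregistration_rate, 1e-12)) * 365.25
  t_death <- rexp(n_pa, rate = max(config$death_rate, 1e-12)) * 365.25
  deregistration_date <- registration_date + round(t_dereg)
  death_date <- registration_date + round(t_death)
  deregistration_date[config$deregistration_rate == 0 |
    deregistration_date > config$span_end] <- NA
  death_date[config$death_rate == 0 | death_date > config$span_end] <- NA
  # death trumps a later deregistration
  both <- !is.na(deregistration_date) & !is.na(death_date) &
    death_date <= deregistration_date
  deregistration_date[both] <- NA

  patients <- tibble(
    patient_id = sprintf("s%06d", seq_len(n_pa)),
    practice_id = rep(practices$practice_id, each = config$patients_per_practice),
    sex = ifelse(runif(n_pa) < config$sex_ratio, "female", "male"),
    birth_date = birth_date,
    birth_precision = ifelse(year_prec, "year", "day"),
    registration_date = registration_date,
    deregistration_date = deregistration_date,
    death_date = death_date,
    townsend_quintile = ifelse(runif(n_pa) < config$townsend_missing,
      NA_integer_, sample(1:5, n_pa, replace = TRUE)),
    ethnicity = sample(config$ethnicity_levels, n_pa, replace = TRUE,
      prob = config$ethnicity_probs)
  )

  # recording window: registration .. earliest of deregistration/death/span end
  rec_start <- registration_date
  rec_end <- pmin_date(deregistration_date, death_date, config$span_end)
  rec_years <- pmax(as.numeric(rec_end - rec_start) / 365.25, 0)

  # planted exposure: per-year Bernoulli incidence over registered years;
  # geometric first-success year plus a uniform day within it
  n_years <- floor(rec_years)
  first_year <- rep(NA_integer_, n_pa)
  if (config$exposure_incidence > 0) {
    g <- rgeom(n_pa, prob = config$exposure_incidence)  # failures before success
    first_year[g < n_years] <- g[g < n_years]
  }
  has_exp <- !is.na(first_year)
  exposure_date <- as.Date(rep(NA_real_, n_pa), origin = "1970-01-01")
  exposure_date[has_exp] <- rec_start[has_exp] + first_year[has_exp] * 365L +
    sample.int(365L, sum(has_exp), replace = TRUE) - 1L
  exposure_date <- pmin_date(exposure_date, rec_end)
  # planted point prevalence: carriers are exposed from registration day one
  prevalent <- runif(n_pa) < config$prevalent_fraction
  exposure_date[prevalent] <- rec_start[prevalent]
  has_exp <- has_exp | prevalent

  ev_exposure <- tibble(
    patient_id = patients$patient_id[has_exp],
    code = sample(config$exposure_codes, sum(has_exp), replace = TRUE),
    event_date = exposure_date[has_exp],
    value = NA_real_, unit = NA_character_, table_of_origin = "clinical"
  )
  with_rx <- has_exp & runif(n_pa) < config$rx_prob
  rx_date <- pmin_date(exposure_date + config$rx_lag_days, rec_end)
  ev_rx <- tibble(
    patient_id = patients$patient_id[with_rx],
    code = sample(config$rx_codes, sum(with_rx), replace = TRUE),
    event_date = rx_date[with_rx],
    value = NA_real_, unit = NA_character_, table_of_origin = "therapy"
  )

  # outcome events as a piecewise-rate Poisson stream: rate lam0 before the
  # first exposure event, lam0 * hazard_ratio after it.  Coded outcomes in
  # real records recur, and independent post-index increments keep every
  # planted rate recoverable after any selection on pre-index history.
  lam0 <- config$outcome_rate / 365.25
  lam1 <- lam0 * config$hazard_ratio
  t_switch <- ifelse(has_exp, as.numeric(exposure_date - rec_start), Inf)
  horizon <- as.numeric(rec_end - rec_start)
  next_event <- function(t_cur, t_sw) {
    # inverse of the remaining piecewise cumulative hazard from t_cur
    e <- rexp(length(t_cur))
    pre <- t_cur < t_sw
    cap <- ifelse(pre, lam0 * (t_sw - t_cur), 0)
    t_nxt <- rep(Inf, length(t_cur))
    in_pre <- pre & lam0 > 0 & e <= cap
    t_nxt[in_pre] <- t_cur[in_pre] + e[in_pre] / lam0
    spill <- pre & !in_pre & lam1 > 0
    t_nxt[spill] <- t_sw[spill] + (e[spill] - cap[spill]) / lam1
    post <- !pre & lam1 > 0
    t_nxt[post] <- t_cur[post] + e[post] / lam1
    t_nxt
  }
  out_idx <- integer()
  out_t <- numeric()
  t_cur <- rep(0, n_pa)
  active <- rep(TRUE, n_pa)
  while (any(active)) {
    ids <- which(active)
    t_new <- next_event(t_cur[ids], t_switch[ids])
    t_cur[ids] <- t_new
    hit <- t_new <= horizon[ids]
    active[ids[!hit]] <- FALSE
    out_idx <- c(out_idx, ids[hit])
    out_t <- c(out_t, t_new[hit])
  }
  ev_outcome <- tibble(
    patient_id = patients$patient_id[out_idx],
    code = sample(config$outcome_codes, length(out_idx), replace = TRUE),
    event_date = rec_start[out_idx] + round(out_t),
    value = NA_real_, unit = NA_character_, table_of_origin = "clinical"
  )

  meas <- function(code, mean, sd, unit) {
    n_m <- rpois(n_pa, config$measurement_rate * rec_years)
    n_m <- round(n_m * (1 - config$missingness))
    idx <- rep.int(seq_len(n_pa), n_m)
    if (!length(idx)) return(NULL)
    tibble(
      patient_id = patients$patient_id[idx],
      code = code,
      event_date = rec_start[idx] +
        floor(runif(length(idx)) * pmax(as.numeric(rec_end - rec_start)[idx], 1)),
      value = round(rnorm(length(idx), mean, sd), 1),
      unit = unit, table_of_origin = "measurement"
    )
  }
  ev_bmi <- meas("22K..00", config$bmi_mean, config$bmi_sd, "kg/m2")
  ev_hba1c <- meas("42W5.00", config$hba1c_mean, config$hba1c_sd, "mmol/mol")
  smoker <- runif(n_pa) < config$smoking_prob
  ev_smoke <- tibble(
    patient_id = patients$patient_id[smoker],
    code = "137R.00",
    event_date = rec_start[smoker] +
      floor(runif(sum(smoker)) * pmax(as.numeric(rec_end - rec_start)[smoker], 1)),
    value = NA_real_, unit = NA_character_, table_of_origin = "clinical"
  )

  events <- bind_rows(ev_exposure, ev_rx, ev_outcome, ev_bmi, ev_hba1c, ev_smoke)
  db <- ehr_db(practices, patients, events)
  attr(db, "sim_config") <- config
  db
}
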