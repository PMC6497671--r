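#' Simulate longitudinal clinical-marker records for a coached cohort
#'
#' Each participant gets a latent baseline level
#' \code{grand mean + covariate effects + genetic component + random intercept},
#' and every observation adds the true population trajectory (piecewise-linear
#' in days with a knot at day 183), a stratum-specific differential change that
#' accrues linearly to its configured 12-month value, and independent
#' measurement noise.  Because the observed baseline contains measurement
#' noise while the person-level intercept persists across visits, stratifying
#' on the observed baseline reproduces regression-to-the-mean artifacts.
#'
#' The genetic component is controlled by \code{genetic}:
#' \describe{
#'   \item{NULL}{a standard-normal true score is drawn and scaled so that it
#'     explains exactly \code{config$baseline_h2} of \code{baseline_sd^2} in
#'     the generated sample; genetic strata are its quartiles.}
#'   \item{\code{list(score =)}}{as above but with a caller-supplied score
#'     (e.g. a dosage-weighted sum from \code{\link{simulate_genotypes}}).}
#'   \item{\code{list(strata =, offsets =)}}{a categorical genetic feature:
#'     \code{strata} is a factor over participants (genotypes or score
#'     quartiles) and \code{offsets} gives each level's true baseline offset in
#'     marker units (reference level 0); \code{baseline_h2} is ignored and the
#'     empirical offset variance is used in the variance budget.}
#' }
#'
#' Visit days: baseline uniform in \code{[0, baseline_window]}; one visit per
#' follow-up target with Gaussian jitter, clipped to
#' \code{[followup_min, followup_max]}.  Medication flags are participant
#' level; fasting status is per blood draw.
#'
#' @param config a \code{\link{sim_config}}.
#' @param genetic NULL, \code{list(score =)}, or \code{list(strata =, offsets =)}.
#' @param marker marker name written into the records.
#' @return list with
#'   \item{records}{long data.frame: \code{participant_id, marker, value, day,
#'     fasting, med_lipid, med_glucose, med_bp, sex, season}.}
#'   \item{covariates}{one row per participant: \code{participant_id, age, sex,
#'     channel, vendor, ancestry, t1d, stratum} and medication flags.}
#'   \item{true_params}{ground truth actually used: genetic component values,
#'     stratum assignment and offsets, trajectory at 6/12 months, differential
#'     change per stratum, and the realized variance budget.}
#' @export
#' @examples
#' sim <- simulate_longitudinal(sim_config(n_participants = 50, seed = 3))
#' head(sim$records)
simulate_longitudinal <- function(config, genetic = NULL, marker = "marker") {
  validate_sim_config(config)
  set.seed(config$seed + 101L)
  n <- config$n_participants
  total_var <- config$baseline_sd^2

  ## participant covariates
  age <- stats::rnorm(n, 48, 12)
  sex <- ifelse(stats::runif(n) < 0.6, "F", "M")
  channel <- ifelse(stats::runif(n) < 0.5, "self", "partner")
  vendor <- ifelse(stats::runif(n) < 0.5, "LCA", "Quest")
  ancestry <- stats::rnorm(n)
  t1d <- stats::runif(n) < 0.007
  enroll_doy <- sample.int(365L, n, replace = TRUE)
  ce <- config$covariate_effects
  cov_term <- ce[["age"]] * (age - 48) + ce[["sexM"]] * (sex == "M") +
    ce[["channel"]] * (channel == "partner") + ce[["vendor"]] * (vendor == "Quest") +
    ce[["ancestry"]] * ancestry
  # center so baseline_mean is the population mean, not the reference cell
  cov_term <- cov_term - mean(cov_term)

  ## genetic component
  if (is.null(genetic) || !is.null(genetic$score)) {
    score <- if (is.null(genetic)) stats::rnorm(n) else genetic$score
    stopifnot(length(score) == n)
    if (config$baseline_h2 > 0 && stats::sd(score) > 0) {
      g <- (score - mean(score)) / stats::sd(score) *
        sqrt(config$baseline_h2 * total_var)
    } else {
      g <- rep(0, n)
    }
    qs <- stats::quantile(score, c(0.25, 0.75))
    strata <- factor(ifelse(score < qs[1], "Q1",
                            ifelse(score >= qs[2], "Q4", "Q2/Q3")),
                     levels = c("Q2/Q3", "Q1", "Q4"))
    offsets <- NULL
  } else {
    strata <- as.factor(genetic$strata)
    stopifnot(length(strata) == n)
    offsets <- genetic$offsets
    miss <- setdiff(levels(strata), names(offsets))
    offsets[miss] <- 0
    g <- as.numeric(offsets[as.character(strata)])
  }
  var_g <- stats::var(g)

  ## variance budget: intercept picks up what genetic/covariate/noise leave
  cov_var <- sum(ce["age"]^2 * 144, ce["sexM"]^2 * 0.6 * 0.4,
                 ce["channel"]^2 * 0.25, ce["vendor"]^2 * 0.25,
                 ce["ancestry"]^2, na.rm = TRUE)
  u_var <- total_var - var_g - cov_var - config$measurement_sd^2
  if (u_var < 0)
    stop("variance budget exceeded: genetic + covariate + noise > baseline_sd^2")
  u <- stats::rnorm(n, 0, sqrt(u_var))
  latent <- config$baseline_mean + cov_term + g + u

  ## differential change per stratum (12-month values, linear accrual)
  delta12 <- stats::setNames(rep(0, nlevels(strata)), levels(strata))
  hit <- intersect(names(config$change_effect), names(delta12))
  delta12[hit] <- config$change_effect[hit]

  ## visit days
  vs <- config$visit_schedule
  base_day <- floor(stats::runif(n, 0, vs$baseline_window + 1))
  k <- length(vs$targets)
  fup <- matrix(round(stats::rnorm(n * k, rep(vs$targets, each = n), vs$jitter_sd)),
                nrow = n)
  fup <- pmin(pmax(fup, vs$followup_min), vs$followup_max)
  days <- cbind(base_day, fup)

  ## medication / fasting flags
  med_lipid <- stats::runif(n) < config$medication_rate
  med_glucose <- stats::runif(n) < config$medication_rate
  med_bp <- stats::runif(n) < config$medication_rate

  nvis <- k + 1L
  pid <- rep(paste0("P", seq_len(n)), each = nvis)
  day <- as.vector(t(days))
  idx <- rep(seq_len(n), each = nvis)
  doy <- (enroll_doy[idx] + day - 1L) %% 365L + 1L
  season <- cut(doy, breaks = c(0, 91, 182, 273, 365),
                labels = c("S1", "S2", "S3", "S4"))
  traj <- trajectory_value(day, config$trajectory)
  value <- latent[idx] + traj +
    delta12[as.character(strata[idx])] * day / 365 +
    stats::rnorm(length(day), 0, config$measurement_sd)
  fasting <- stats::runif(length(day)) >= config$nonfasting_rate

  records <- data.frame(participant_id = pid, marker = marker, value = value,
                        day = day, fasting = fasting,
                        med_lipid = med_lipid[idx], med_glucose = med_glucose[idx],
                        med_bp = med_bp[idx], sex = sex[idx], season = season,
                        stringsAsFactors = FALSE)
  covariates <- data.frame(participant_id = paste0("P", seq_len(n)),
                           age = age, sex = sex, channel = channel,
                           vendor = vendor, ancestry = ancestry, t1d = t1d,
                           med_lipid = med_lipid, med_glucose = med_glucose,
                           med_bp = med_bp, stratum = strata,
                           stringsAsFactors = FALSE)
  true_params <- list(genetic_component = g, strata = strata,
                      stratum_offsets = offsets,
                      trajectory = config$trajectory,
                      change_effect_12mo = delta12,
                      latent_baseline = latent,
                      variance_budget = c(genetic = var_g, covariate = cov_var,
                                          intercept = u_var,
                                          noise = config$measurement_sd^2,
                                          total = total_var))
  list(records = records, covariates = covariates, true_params = true_params)
}

#' True population trajectory at given days
#'
#' Piecewise-linear interpolation of the configured 6- and 12-month changes:
#' 0 at day 0, \code{trajectory[1]} at day 183, \code{trajectory[2]} at day
#' 365, extended linearly beyond day 365.
#'
#' @param day numeric days.
#' @param trajectory length-2 changes at 6 and 12 months.
#' @return numeric change values.
#' @export
trajectory_value <- function(day, trajectory) {
  s1 <- trajectory[1] / 183
  s2 <- (trajectory[2] - trajectory[1]) / (365 - 183)
  ifelse(day <= 183, s1 * day, trajectory[1] + s2 * (day - 183))
}
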