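#' Simulation configuration for a synthetic coached cohort
#'
#' Collects every tunable of the synthetic-cohort generator in one validated
#' object.  Defaults describe an LDL-cholesterol-like marker (baseline mean
#' 116.6, SD 33.5 mg/dL) in a cohort with semi-annual blood draws.
#'
#' The baseline variance of the marker is decomposed into four configured
#' components: genetic (\code{baseline_h2} of the total), covariate
#' (determined by \code{covariate_effects}), a person-level random intercept
#' (the remainder), and measurement noise (\code{measurement_sd^2}).  The
#' constructor errors when the genetic, covariate and noise components already
#' exceed \code{baseline_sd^2}.
#'
#' @param n_participants number of participants.
#' @param n_snps number of biallelic SNPs.
#' @param n_blocks number of LD blocks (must not exceed \code{n_snps}).
#' @param within_block_rho latent AR(1) correlation inside a block, in [0, 1).
#'   Note the observed dosage correlation is attenuated relative to this latent
#'   value by the threshold (liability) construction.
#' @param causal_fraction fraction of SNPs with nonzero true effect.
#' @param baseline_h2 fraction of total baseline marker variance explained by
#'   the true genetic score (or stratum offsets), in [0, 1].
#' @param change_effect named numeric vector of true differential change at 12
#'   months (marker units) per genetic stratum, e.g.
#'   \code{c(Q1 = -3.82, Q4 = 0)}; reference stratum implicitly 0.
#' @param trajectory length-2 numeric: true population change (marker units)
#'   at 6 and 12 months, linearly interpolated with a knot at day 183.
#' @param visit_schedule list with elements \code{targets} (follow-up target
#'   days), \code{jitter_sd} (Gaussian jitter SD, days), \code{baseline_window}
#'   (baseline drawn uniformly in [0, window]), \code{followup_min} and
#'   \code{followup_max} (retention window, days).
#' @param measurement_sd within-person measurement noise SD (marker units).
#'   Defaults to 30 percent of \code{baseline_sd}; repeated-lab reliability is
#'   not published for this design, so it is exposed rather than asserted.
#' @param baseline_mean,baseline_sd marker baseline mean and total SD.
#' @param covariate_effects named numeric vector of marker-unit effects for
#'   \code{age} (per year), \code{sexM}, \code{channel}, \code{vendor},
#'   \code{ancestry} (per SD), \code{season} (per season step).
#' @param maf_range range minor-allele frequencies are drawn from.
#' @param missing_genotype_rate per-genotype missingness probability.
#' @param medication_rate probability a participant reports the
#'   marker-class medication.
#' @param nonfasting_rate probability a blood draw is non-fasting (default the
#'   observed 1.7 percent).
#' @param seed integer seed; fixing it makes all generator output reproducible.
#'
#' @return object of class \code{sim_config} (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 200, n_snps = 50, n_blocks = 10, seed = 1)
#' cfg$baseline_sd
sim_config <- function(n_participants = 2000,
                       n_snps = 500,
                       n_blocks = 50,
                       within_block_rho = 0.8,
                       causal_fraction = 0.1,
                       baseline_h2 = 0.111,
                       change_effect = c(Q1 = 0, Q4 = 0),
                       trajectory = c(-2.58, -3.26),
                       visit_schedule = list(targets = c(180, 360),
                                             jitter_sd = 45,
                                             baseline_window = 30,
                                             followup_min = 90,
                                             followup_max = 456),
                       measurement_sd = NULL,
                       baseline_mean = 116.6,
                       baseline_sd = 33.5,
                       covariate_effects = NULL,
                       maf_range = c(0.05, 0.5),
                       missing_genotype_rate = 0.02,
                       medication_rate = 0.1,
                       nonfasting_rate = 0.017,
                       seed = 1L) {
  if (is.null(measurement_sd)) measurement_sd <- 0.3 * baseline_sd
  if (is.null(covariate_effects)) {
    covariate_effects <- c(age     = 0.010 * baseline_sd,
                           sexM    = 0.150 * baseline_sd,
                           channel = 0.080 * baseline_sd,
                           vendor  = 0.050 * baseline_sd,
                           ancestry = 0.100 * baseline_sd,
                           season  = 0)
  }
  cfg <- list(n_participants = as.integer(n_participants),
              n_snps = as.integer(n_snps),
              n_blocks = as.integer(n_blocks),
              within_block_rho = within_block_rho,
              causal_fraction = causal_fraction,
              baseline_h2 = baseline_h2,
              change_effect = change_effect,
              trajectory = trajectory,
              visit_schedule = visit_schedule,
              measurement_sd = measurement_sd,
              baseline_mean = baseline_mean,
              baseline_sd = baseline_sd,
              covariate_effects = covariate_effects,
              maf_range = maf_range,
              missing_genotype_rate = missing_genotype_rate,
              medication_rate = medication_rate,
              nonfasting_rate = nonfasting_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_snps < 1L) stop("invalid config: n_snps must be >= 1")
  if (cfg$n_participants < 1L) stop("invalid config: n_participants must be >= 1")
  if (cfg$n_blocks < 1L || cfg$n_blocks > cfg$n_snps)
    stop("invalid config: need 1 <= n_blocks <= n_snps")
  props <- c(causal_fraction = cfg$causal_fraction,
             baseline_h2 = cfg$baseline_h2,
             missing_genotype_rate = cfg$missing_genotype_rate,
             medication_rate = cfg$medication_rate,
             nonfasting_rate = cfg$nonfasting_rate)
  bad <- props < 0 | props > 1
  if (any(bad))
    stop("invalid config: proportions outside [0,1]: ",
         paste(names(props)[bad], collapse = ", "))
  if (cfg$within_block_rho < 0 || cfg$within_block_rho >= 1)
    stop("invalid config: within_block_rho must be in [0,1)")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] >= 1 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("invalid config: maf_range must satisfy 0 < lo <= hi < 1")
  if (cfg$measurement_sd < 0 || cfg$baseline_sd <= 0)
    stop("invalid config: SDs must be positive")
  if (length(cfg$trajectory) != 2L)
    stop("invalid config: trajectory must give changes at 6 and 12 months")
  vs <- cfg$visit_schedule
  need <- c("targets", "jitter_sd", "baseline_window", "followup_min", "followup_max")
  if (!all(need %in% names(vs)))
    stop("invalid config: visit_schedule missing ",
         paste(setdiff(need, names(vs)), collapse = ", "))
  invisible(cfg)
}

#' Baseline variance budget implied by a configuration
#'
#' Splits \code{baseline_sd^2} into genetic, covariate, random-intercept and
#' measurement-noise components.  Errors when the fixed components exceed the
#' total (no room left for the person-level intercept).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return named numeric vector with components \code{genetic},
#'   \code{covariate}, \code{intercept}, \code{noise}, \code{total}.
#' @export
variance_budget <- function(cfg) {
  validate_sim_config(cfg)
  total <- cfg$baseline_sd^2
  genetic <- cfg$baseline_h2 * total
  ce <- cfg$covariate_effects
  # variances of the generator's covariates: age SD 12 y, sex p=0.6 female,
  # channel p=0.5, vendor p=0.5, ancestry SD 1; season is observation-level
  covariate <- sum(ce["age"]^2 * 144,
                   ce["sexM"]^2 * 0.6 * 0.4,
                   ce["channel"]^2 * 0.25,
                   ce["vendor"]^2 * 0.25,
                   ce["ancestry"]^2, na.rm = TRUE)
  noise <- cfg$measurement_sd^2
  intercept <- total - genetic - covariate - noise
  if (intercept < 0)
    stop("invalid config: genetic + covariate + noise variance exceeds baseline_sd^2")
  c(genetic = genetic, covariate = covariate, intercept = intercept,
    noise = noise, total = total)
}

#' Marker presets taken from published cohort summaries
#'
#' Baseline mean/SD, analysis n, marker class and reference range for the
#' markers used throughout the package's examples and tests: LDL cholesterol,
#' triglycerides, HbA1c, vitamin D and arachidonic acid.
#'
#' @return data.frame with one row per marker.
#' @export
#' @examples
#' marker_presets()
marker_presets <- function() {
  data.frame(
    marker = c("LDL-C", "Triglycerides", "HbA1c", "Vitamin D", "Arachidonic acid"),
    units = c("mg/dL", "mg/dL", "%", "ng/mL", "% by wt"),
    n = c(1801L, 1809L, 1992L, 2085L, 1578L),
    baseline_mean = c(116.6, 101.6, 5.5, 33.7, 10.6),
    baseline_sd = c(33.5, 55.0, 0.4, 14.7, 1.7),
    class = c("lipid", "lipid", "diabetes", "other", "other"),
    low = c(NA, NA, 4.8, 30, NA),
    high = c(99, 149, 5.6, 100, NA),
    stringsAsFactors = FALSE)
}
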