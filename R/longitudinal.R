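#' Piecewise-linear regression-spline basis for time
#'
#' Truncated-line basis anchored at day 0: with knots \code{k1 < k2 < ...},
#' the columns are \code{min(t, k1)}, \code{min(max(t - k1, 0), k2 - k1)},
#' ..., \code{max(t - kK, 0)}.  Every column is 0 at \code{t = 0}, so a
#' fitted curve evaluated at day 0 is exactly no change; with no knots the
#' basis is the single linear column \code{t}.
#'
#' @param days numeric vector of days.
#' @param knots strictly increasing knot days (possibly empty).
#' @param check warn when a knot lies outside the observed day range
#'   (disable when evaluating the basis at single prediction days).
#' @return numeric matrix with columns \code{.t1, .t2, ...} and attribute
#'   \code{knots}.  A knot outside the observed day range triggers a warning
#'   but is kept.
#' @export
#' @examples
#' build_time_spline(c(0, 365), knots = 183)
build_time_spline <- function(days, knots = 183, check = TRUE) {
  knots <- sort(knots)
  if (length(knots) > 0 && any(duplicated(knots))) stop("knots must be distinct")
  if (check && length(knots) > 0 && length(days) > 0 &&
      (min(knots) < min(days) || max(knots) > max(days)))
    warning("knot outside observed day range; proceeding")
  bounds <- c(0, knots, Inf)
  k <- length(bounds) - 1L
  basis <- matrix(0, nrow = length(days), ncol = k,
                  dimnames = list(NULL, paste0(".t", seq_len(k))))
  for (j in seq_len(k)) {
    basis[, j] <- pmin(pmax(days - bounds[j], 0), bounds[j + 1L] - bounds[j])
  }
  attr(basis, "knots") <- knots
  basis
}

#' Default analysis covariates
#'
#' The fixed-effect adjustment set used throughout: age at baseline, sex,
#' enrollment channel, genetic ancestry, observation season and observation
#' vendor.
#'
#' @return character vector of covariate names.
#' @export
default_covariates <- function() {
  c("age", "sex", "channel", "ancestry", "vendor", "season")
}

# Merge records with participant covariates, attach the spline basis, and
# drop factor covariates that are constant in the data (they carry no
# information and would make the design singular).
prepare_model_data <- function(records, covariates = NULL,
                               covariate_names = default_covariates(),
                               knots = 183) {
  dat <- records
  if (!is.null(covariates)) {
    add <- setdiff(names(covariates), setdiff(names(dat), "participant_id"))
    dat <- merge(dat, covariates[, add, drop = FALSE], by = "participant_id",
                 sort = FALSE)
  }
  covariate_names <- intersect(covariate_names, names(dat))
  dropped <- character(0)
  for (v in covariate_names) {
    if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
    if (is.factor(dat[[v]])) dat[[v]] <- droplevels(dat[[v]])
    if ((is.factor(dat[[v]]) && nlevels(dat[[v]]) < 2L) ||
        (is.numeric(dat[[v]]) && stats::var(dat[[v]]) == 0)) {
      dropped <- c(dropped, v)
    }
  }
  covariate_names <- setdiff(covariate_names, dropped)
  basis <- build_time_spline(dat$day, knots)
  dat <- cbind(dat, basis)
  list(data = dat, covariate_names = covariate_names,
       basis_cols = colnames(basis), knots = attr(basis, "knots"),
       dropped = dropped)
}

# Error on a rank-deficient fixed-effect design, naming offending columns.
check_full_rank <- function(formula_fixed, data) {
  mm <- stats::model.matrix(formula_fixed, data)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_$pivot[(qr_$rank + 1L):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Fit the longitudinal mixed model for one marker
#'
#' Gaussian linear mixed model (identity link) with the piecewise-linear time
#' spline as fixed effects, the standard adjustment covariates, and a
#' per-participant random intercept, fitted by REML via \pkg{lme4}.
#'
#' @param records long data.frame (\code{participant_id}, \code{value},
#'   \code{day}, plus any observation-level covariates such as
#'   \code{season}).
#' @param covariates optional participant-level covariate data.frame.
#' @param covariate_names fixed-effect adjustment set (default
#'   \code{\link{default_covariates}}); names absent from the data are
#'   ignored, constant ones dropped.
#' @param knots spline knot days (default 183).
#' @param extra_fixed character vector of additional fixed-effect terms
#'   (model formula syntax), e.g. \code{"stratum * (.t1 + .t2)"}.
#' @return object of class \code{cgx_fit}: list with elements \code{fit}
#'   (the \code{lmerMod}), \code{coef}, \code{vcov}, \code{knots},
#'   \code{basis_cols}, \code{sigma_u2}, \code{sigma_e2}, \code{n_obs},
#'   \code{n_participants}, \code{max_day}, \code{data}.
#' @export
fit_longitudinal <- function(records, covariates = NULL,
                             covariate_names = default_covariates(),
                             knots = 183, extra_fixed = character(0)) {
  prep <- prepare_model_data(records, covariates, covariate_names, knots)
  dat <- prep$data
  rhs <- c(prep$basis_cols, prep$covariate_names, extra_fixed)
  fixed <- stats::reformulate(rhs, response = "value")
  check_full_rank(fixed, dat)
  full <- stats::as.formula(paste("value ~", paste(rhs, collapse = " + "),
                                  "+ (1 | participant_id)"))
  fit <- tryCatch(
    lme4::lmer(full, data = dat, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    error = function(e) stop("mixed model failed to converge: ",
                             conditionMessage(e)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- list(fit = fit,
              coef = lme4::fixef(fit),
              vcov = as.matrix(stats::vcov(fit)),
              knots = prep$knots,
              basis_cols = prep$basis_cols,
              covariate_names = prep$covariate_names,
              sigma_u2 = vc$vcov[vc$grp == "participant_id"],
              sigma_e2 = vc$vcov[vc$grp == "Residual"],
              n_obs = nrow(dat),
              n_participants = length(unique(dat$participant_id)),
              max_day = max(dat$day),
              data = dat)
  class(out) <- "cgx_fit"
  out
}

#' @export
print.cgx_fit <- function(x, ...) {
  cat("Longitudinal mixed model:", x$n_obs, "observations,",
      x$n_participants, "participants\n")
  cat("Spline knots (days):", paste(x$knots, collapse = ", "), "\n")
  cat("Variance components: intercept", signif(x$sigma_u2, 4),
      "residual", signif(x$sigma_e2, 4), "\n")
  invisible(x)
}

# day at which a month horizon is evaluated: 6 -> 183, 12 -> 365,
# otherwise round(30.4 * months)
horizon_day <- function(horizon) {
  if (horizon == 6) 183 else if (horizon == 12) 365 else round(30.4 * horizon)
}

# contrast vector over the fixed-effect coefficients for the change at `day`
# in `stratum` (NULL or reference = spline terms only)
change_contrast <- function(fit, day, stratum = NULL) {
  b <- drop(build_time_spline(day, fit$knots, check = FALSE))
  cvec <- stats::setNames(numeric(length(fit$coef)), names(fit$coef))
  cvec[fit$basis_cols] <- b
  if (!is.null(stratum)) {
    if (is.null(fit$stratum_levels))
      stop("fit has no stratum interactions; refit with fit_strata_interaction")
    if (!stratum %in% fit$stratum_levels)
      stop("unknown stratum '", stratum, "'")
    if (stratum != fit$stratum_levels[1]) {  # reference uses spline terms only
      for (j in seq_along(fit$basis_cols)) {
        nm <- c(paste0("stratum", stratum, ":", fit$basis_cols[j]),
                paste0(fit$basis_cols[j], ":stratum", stratum))
        nm <- nm[nm %in% names(cvec)]
        if (length(nm) == 0)
          stop("interaction coefficient missing for stratum '", stratum, "'")
        cvec[nm[1]] <- b[j]
      }
    }
  }
  cvec
}

#' Adjusted change at a horizon for the average participant
#'
#' Linear contrast of the spline (and, for a stratum, interaction)
#' coefficients at the horizon's evaluation day (183 days for 6 months, 365
#' for 12), with a 95 percent Wald confidence interval from the coefficient
#' covariance.  The change at horizon 0 is exactly 0 by construction of the
#' basis.
#'
#' @param fit a \code{\link{fit_longitudinal}} /
#'   \code{\link{fit_strata_interaction}} result.
#' @param horizon months (6 or 12).
#' @param stratum optional stratum label of an interaction fit; the
#'   reference stratum or \code{NULL} uses the spline terms alone.
#' @param conf confidence level (default 0.95).
#' @return one-row data.frame \code{horizon, stratum, estimate, ci_low,
#'   ci_high, p, n}.
#' @export
estimate_adjusted_change <- function(fit, horizon, stratum = NULL, conf = 0.95) {
  day <- horizon_day(horizon)
  if (day > fit$max_day)
    stop("horizon day ", day, " beyond observed range (max ", fit$max_day, ")")
  cvec <- change_contrast(fit, day, stratum)
  est <- sum(cvec * fit$coef)
  se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  n <- fit$n_participants
  if (!is.null(stratum) && !is.null(fit$stratum_n) &&
      stratum %in% names(fit$stratum_n)) n <- fit$stratum_n[[stratum]]
  data.frame(horizon = horizon,
             stratum = if (is.null(stratum)) "All" else stratum,
             estimate = est, ci_low = est - z * se, ci_high = est + z * se,
             p = 2 * stats::pnorm(-abs(est / se)), n = n,
             stringsAsFactors = FALSE)
}

#' Fit the baseline-stratum by time interaction model
#'
#' Adds stratum main effects and stratum-by-spline interactions to the
#' longitudinal model, so each baseline stratum gets its own trajectory.
#' Strata with fewer than \code{min_n} participants are dropped with a
#' warning (their changes are not estimated); if a single stratum remains the
#' fit falls back to the unstratified model with a warning.
#'
#' @param records long data.frame; must contain or be joinable to a
#'   \code{stratum} column.
#' @param strata data.frame \code{participant_id, stratum} (e.g. from
#'   \code{\link{classify_baseline_strata}}); ignored when \code{records}
#'   already has a stratum column.
#' @param covariates,covariate_names,knots as in
#'   \code{\link{fit_longitudinal}}.
#' @param min_n stratum size floor (default 50).
#' @return \code{cgx_fit} with an extra \code{stratum_n} element (participant
#'   counts per retained stratum, reference first).
#' @export
fit_strata_interaction <- function(records, strata = NULL, covariates = NULL,
                                   covariate_names = default_covariates(),
                                   knots = 183, min_n = 50) {
  dat <- records
  if (!"stratum" %in% names(dat)) {
    stopifnot(!is.null(strata))
    dat <- merge(dat, strata[, c("participant_id", "stratum")],
                 by = "participant_id", sort = FALSE)
  }
  dat$stratum <- droplevels(as.factor(dat$stratum))
  per <- tapply(dat$participant_id, dat$stratum,
                function(x) length(unique(x)))
  small <- names(per)[is.na(per) | per < min_n]
  if (length(small) > 0) {
    warning("dropping strata below the ", min_n, "-participant floor: ",
            paste(small, collapse = ", "))
    dat <- dat[!dat$stratum %in% small, , drop = FALSE]
    dat$stratum <- droplevels(dat$stratum)
  }
  if (nlevels(dat$stratum) < 2L) {
    warning("single stratum present; falling back to unstratified fit")
    fit <- fit_longitudinal(dat, covariates, covariate_names, knots)
    fit$stratum_n <- stats::setNames(list(fit$n_participants),
                                     levels(dat$stratum))
    fit$stratum_levels <- levels(dat$stratum)
    return(fit)
  }
  basis_cols <- paste0(".t", seq_len(length(knots) + 1L))
  inter <- paste0("stratum * (", paste(basis_cols, collapse = " + "), ")")
  fit <- fit_longitudinal(dat, covariates, covariate_names, knots,
                          extra_fixed = inter)
  fit$stratum_n <- as.list(per[levels(dat$stratum)])
  fit$stratum_levels <- levels(dat$stratum)
  fit
}
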