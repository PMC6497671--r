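#' Variance in baseline levels explained by a genetic feature
#'
#' Fits the covariate-only (reduced) and covariate-plus-genetics (full)
#' linear regressions of the baseline value and reports the partial
#' r-squared, \code{(SSE_reduced - SSE_full) / SSE_reduced}: the share of
#' covariate-adjusted baseline variance the genetic feature explains.  A
#' categorical feature (PGS quartiles or SNP genotypes) additionally yields
#' per-stratum effects versus the reference level with Wald confidence
#' intervals.
#'
#' @param baselines data.frame with \code{participant_id} and \code{value}
#'   (one baseline row per participant).
#' @param feature named factor (strata) or numeric vector (score), names =
#'   participant ids; unnamed vectors must match \code{baselines} row order.
#' @param covariates optional participant-level covariate data.frame.
#' @param covariate_names adjustment set (default
#'   \code{\link{default_covariates}} less season, which is
#'   observation-level); missing/constant ones are dropped.
#' @param conf confidence level for stratum effects (default 0.95).
#' @return list with \code{partial_r2}, \code{effects} (data.frame
#'   \code{stratum, estimate, ci_low, ci_high, p, n}, reference row 0/NA),
#'   \code{p} (F-test of the genetic term), \code{n}.
#' @export
baseline_variance_explained <- function(baselines, feature, covariates = NULL,
                                        covariate_names =
                                          setdiff(default_covariates(), "season"),
                                        conf = 0.95) {
  stopifnot(all(c("participant_id", "value") %in% names(baselines)))
  dat <- baselines
  if (!is.null(covariates)) {
    add <- setdiff(names(covariates), setdiff(names(dat), "participant_id"))
    dat <- merge(dat, covariates[, add, drop = FALSE], by = "participant_id",
                 sort = FALSE)
  }
  if (!is.null(names(feature)) && all(dat$participant_id %in% names(feature))) {
    dat$.g <- feature[dat$participant_id]
  } else {
    stopifnot(length(feature) == nrow(baselines))
    dat$.g <- feature[match(dat$participant_id, baselines$participant_id)]
  }
  dat <- dat[!is.na(dat$.g), , drop = FALSE]
  categorical <- is.factor(dat$.g) || is.character(dat$.g)
  if (categorical) {
    dat$.g <- droplevels(as.factor(dat$.g))
    if (nlevels(dat$.g) < 2L) stop("genetic feature has a single stratum")
    if (any(table(dat$.g) == 0L)) stop("empty genetic stratum")
  }
  covariate_names <- intersect(covariate_names, names(dat))
  keep <- character(0)
  for (v in covariate_names) {
    if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
    if (is.factor(dat[[v]])) dat[[v]] <- droplevels(dat[[v]])
    ok <- if (is.factor(dat[[v]])) nlevels(dat[[v]]) >= 2L
          else stats::var(dat[[v]]) > 0
    if (ok) keep <- c(keep, v)
  }
  reduced_f <- if (length(keep) > 0) stats::reformulate(keep, "value")
               else value ~ 1
  full_f <- stats::reformulate(c(keep, ".g"), "value")
  reduced <- stats::lm(reduced_f, data = dat)
  full <- stats::lm(full_f, data = dat)
  sse_r <- sum(stats::residuals(reduced)^2)
  sse_f <- sum(stats::residuals(full)^2)
  if (sse_r <= 1e-10 * nrow(dat))
    stop("reduced model has zero residual variance; partial r2 undefined")
  partial_r2 <- (sse_r - sse_f) / sse_r
  p_global <- stats::anova(reduced, full)[2, "Pr(>F)"]

  effects <- NULL
  if (categorical) {
    cf <- summary(full)$coefficients
    z <- stats::qnorm(1 - (1 - conf) / 2)
    ref <- levels(dat$.g)[1]
    counts <- table(dat$.g)
    rows <- lapply(levels(dat$.g)[-1], function(lv) {
      nm <- paste0(".g", lv)
      data.frame(stratum = lv, estimate = cf[nm, 1],
                 ci_low = cf[nm, 1] - z * cf[nm, 2],
                 ci_high = cf[nm, 1] + z * cf[nm, 2],
                 p = 2 * stats::pnorm(-abs(cf[nm, 1] / cf[nm, 2])),
                 n = as.integer(counts[lv]), stringsAsFactors = FALSE)
    })
    effects <- rbind(data.frame(stratum = ref, estimate = 0, ci_low = NA,
                                ci_high = NA, p = NA,
                                n = as.integer(counts[ref]),
                                stringsAsFactors = FALSE),
                     do.call(rbind, rows))
    rownames(effects) <- NULL
  }
  list(partial_r2 = partial_r2, effects = effects, p = p_global,
       n = nrow(dat))
}

#' Gene-by-time interaction model for differential longitudinal change
#'
#' Linear mixed model on follow-up observations only, with fixed effects:
#' the participant's baseline value of the marker (conditioning covariate,
#' never an outcome), the time spline, the genetic stratum and its
#' interaction with every spline column, plus the standard adjustment
#' covariates; random intercept per participant.  The differential change of
#' a stratum versus the reference is the interaction contrast at the horizon
#' (default 12 months, evaluated at day 365).
#'
#' @param records analysis-set records carrying an \code{is_baseline} flag
#'   (from \code{\link{select_analysis_set}}).
#' @param strata named factor of genetic strata (participant ids as names),
#'   reference level first.
#' @param covariates,covariate_names,knots as in
#'   \code{\link{fit_longitudinal}}.
#' @param horizon months at which the differential change is reported.
#' @param conf confidence level.
#' @return list with \code{effects}: data.frame \code{stratum,
#'   diff_change, ci_low, ci_high, p, n} (reference row 0/NA), \code{fit}
#'   (the underlying \code{cgx_fit}), \code{baseline_coef} (coefficient on
#'   the baseline value), \code{horizon}.
#' @export
fit_genetic_longitudinal <- function(records, strata, covariates = NULL,
                                     covariate_names = default_covariates(),
                                     knots = 183, horizon = 12, conf = 0.95) {
  stopifnot("is_baseline" %in% names(records))
  strata <- as.factor(strata)
  base <- records[records$is_baseline, c("participant_id", "value")]
  names(base)[2] <- "baseline_value"
  fup <- records[!records$is_baseline, , drop = FALSE]
  dat <- merge(fup, base, by = "participant_id", sort = FALSE)
  dat$stratum <- droplevels(strata[dat$participant_id])
  dat <- dat[!is.na(dat$stratum), , drop = FALSE]
  if (nlevels(dat$stratum) < nlevels(droplevels(strata)))
    stop("stratum absent from follow-up data: ",
         paste(setdiff(levels(droplevels(strata)), levels(dat$stratum)),
               collapse = ", "))
  basis_cols <- paste0(".t", seq_len(length(knots) + 1L))
  inter <- c("baseline_value",
             paste0("stratum * (", paste(basis_cols, collapse = " + "), ")"))
  fit <- fit_longitudinal(dat, covariates, covariate_names, knots,
                          extra_fixed = inter)
  day <- horizon_day(horizon)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  counts <- tapply(dat$participant_id, dat$stratum,
                   function(x) length(unique(x)))
  ref <- levels(dat$stratum)[1]
  rows <- lapply(levels(dat$stratum)[-1], function(lv) {
    b <- drop(build_time_spline(day, fit$knots, check = FALSE))
    cvec <- stats::setNames(numeric(length(fit$coef)), names(fit$coef))
    for (j in seq_along(fit$basis_cols)) {
      nm <- c(paste0("stratum", lv, ":", fit$basis_cols[j]),
              paste0(fit$basis_cols[j], ":stratum", lv))
      nm <- nm[nm %in% names(cvec)]
      if (length(nm) == 0) stop("interaction coefficient missing for ", lv)
      cvec[nm[1]] <- b[j]
    }
    est <- sum(cvec * fit$coef)
    se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
    data.frame(stratum = lv, diff_change = est, ci_low = est - z * se,
               ci_high = est + z * se,
               p = 2 * stats::pnorm(-abs(est / se)),
               n = as.integer(counts[lv]), stringsAsFactors = FALSE)
  })
  effects <- rbind(data.frame(stratum = ref, diff_change = 0, ci_low = NA,
                              ci_high = NA, p = NA, n = as.integer(counts[ref]),
                              stringsAsFactors = FALSE),
                   do.call(rbind, rows))
  rownames(effects) <- NULL
  list(effects = effects, fit = fit,
       baseline_coef = unname(fit$coef["baseline_value"]), horizon = horizon)
}

#' Benjamini-Hochberg adjustment of a results table
#'
#' Adds a \code{p_adj} column with BH-adjusted p-values, computed within each
#' declared family (default: the whole table is one family).  Adjusted values
#' are monotone in the raw p-values, never smaller than them, and capped at
#' 1; \code{NA} p-values (reference rows) stay \code{NA}.
#'
#' @param results data.frame with a \code{p} column.
#' @param family optional column name or vector defining adjustment families.
#' @return \code{results} with a \code{p_adj} column.
#' @export
bh_adjust_results <- function(results, family = NULL) {
  stopifnot("p" %in% names(results))
  groups <- if (is.null(family)) rep(1L, nrow(results))
            else if (length(family) == 1L && family %in% names(results))
              results[[family]]
            else family
  p_adj <- rep(NA_real_, nrow(results))
  for (g in unique(groups)) {
    idx <- which(groups == g & !is.na(results$p))
    p_adj[idx] <- stats::p.adjust(results$p[idx], method = "BH")
  }
  results$p_adj <- p_adj
  results
}
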