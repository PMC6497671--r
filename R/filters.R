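#' Select the longitudinal analysis set for a marker
#'
#' A participant enters the analysis of a marker only with (a) a baseline
#' measurement within \code{baseline_window} days of their first record and
#' (b) at least one follow-up between \code{followup_min} days and
#' \code{followup_max} days after day 0.  All window boundaries are
#' inclusive.  When several records fall inside the baseline window the
#' earliest is the baseline and the others are discarded (they are neither
#' baselines nor follow-ups); records after \code{followup_max} are dropped.
#'
#' @param records long data.frame with at least \code{participant_id},
#'   \code{value}, \code{day}.
#' @param baseline_window,followup_min,followup_max day cutoffs
#'   (defaults 30 / 90 / 456, i.e. 15 months at 30.4 days per month).
#' @return list with \code{records} (baseline + retained follow-ups, flagged
#'   by logical column \code{is_baseline}) and \code{baselines} (one row per
#'   retained participant).
#' @export
#' @examples
#' r <- data.frame(participant_id = "P1", value = 1:4,
#'                 day = c(0, 40, 200, 500))
#' select_analysis_set(r)$records$day  # 0 200
select_analysis_set <- function(records, baseline_window = 30,
                                followup_min = 90, followup_max = 456) {
  stopifnot(all(c("participant_id", "day", "value") %in% names(records)))
  records <- records[order(records$participant_id, records$day), , drop = FALSE]
  keep <- logical(nrow(records))
  is_base <- logical(nrow(records))
  for (idx in split(seq_len(nrow(records)), records$participant_id)) {
    day <- records$day[idx]
    b <- which(day <= baseline_window)
    if (length(b) == 0L) next
    b <- b[1L]
    f <- which(day >= followup_min & day <= followup_max)
    if (length(f) == 0L) next
    keep[idx[c(b, f)]] <- TRUE
    is_base[idx[b]] <- TRUE
  }
  out <- records[keep, , drop = FALSE]
  out$is_baseline <- is_base[keep]
  rownames(out) <- NULL
  list(records = out, baselines = out[out$is_baseline, , drop = FALSE])
}

#' Apply fasting and medication exclusions
#'
#' Non-fasting blood draws are removed for every blood marker.  Participants
#' reporting the medication matching the marker's class lose all records of
#' that class: cholesterol-lowering medication for lipids, blood sugar
#' medication for diabetes markers, blood pressure medication for blood
#' pressure.  Markers of class \code{other} have no medication rule.
#' Participants flagged type-1 diabetic (covariate \code{t1d}) are excluded
#' from diabetes markers.
#'
#' @param records long data.frame with \code{fasting} and medication flag
#'   columns (\code{med_lipid}, \code{med_glucose}, \code{med_bp}).
#' @param marker_class one of \code{"lipid"}, \code{"diabetes"},
#'   \code{"blood_pressure"}, \code{"other"}.
#' @param t1d optional named logical vector (participant -> type-1 flag).
#' @param blood whether the marker is a blood draw (fasting rule applies).
#' @return the filtered data.frame.
#' @export
apply_exclusions <- function(records, marker_class, t1d = NULL, blood = TRUE) {
  classes <- c("lipid", "diabetes", "blood_pressure", "other")
  if (!marker_class %in% classes)
    stop("unknown marker_class '", marker_class, "'; expected one of: ",
         paste(classes, collapse = ", "))
  out <- records
  if (blood && "fasting" %in% names(out))
    out <- out[out$fasting, , drop = FALSE]
  med_col <- switch(marker_class, lipid = "med_lipid", diabetes = "med_glucose",
                    blood_pressure = "med_bp", other = NULL)
  if (!is.null(med_col) && med_col %in% names(out))
    out <- out[!out[[med_col]], , drop = FALSE]
  if (marker_class == "diabetes" && !is.null(t1d)) {
    flagged <- names(t1d)[t1d]
    out <- out[!out$participant_id %in% flagged, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a reference-range table
#'
#' Ranges ship as an editable TSV (see
#' \code{system.file("extdata", "reference_ranges.tsv", package = "coachgx")}),
#' seeded from published clinical reference ranges, with optional sex-specific
#' bounds and a marker class column driving medication exclusions.
#'
#' @param path TSV path; default the packaged table.
#' @return data.frame \code{marker, low, high, low_M, high_M, low_F, high_F,
#'   class}.
#' @export
read_reference_ranges <- function(path = system.file("extdata",
                                                     "reference_ranges.tsv",
                                                     package = "coachgx")) {
  rr <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("marker", "low", "high", "low_M", "high_M", "low_F", "high_F", "class")
  if (!all(need %in% names(rr)))
    stop("reference range file missing columns: ",
         paste(setdiff(need, names(rr)), collapse = ", "))
  bad <- !is.na(rr$low) & !is.na(rr$high) & rr$low >= rr$high
  if (any(bad)) stop("invalid range (low >= high) for: ",
                     paste(rr$marker[bad], collapse = ", "))
  rr
}

resolve_range <- function(ranges, marker, sex = NULL) {
  row <- ranges[ranges$marker == marker, , drop = FALSE]
  if (nrow(row) == 0L) return(NULL)
  low <- row$low; high <- row$high
  if (!is.null(sex)) {
    sexed <- ifelse(sex == "M", 1L, 2L)
    lows <- cbind(row$low_M, row$low_F)[1L, sexed]
    highs <- cbind(row$high_M, row$high_F)[1L, sexed]
    low <- ifelse(is.na(lows), low, lows)
    high <- ifelse(is.na(highs), high, highs)
  }
  list(low = low, high = high)
}

#' Classify participants into baseline reference-range strata
#'
#' Participants with a baseline measurement inside the (sex-resolved) healthy
#' range are \code{normal}, below it \code{low}, above it \code{high}.  A
#' marker without a defined range yields \code{all} for everyone.  Strata
#' with fewer than \code{min_n} participants are flagged not estimable
#' (changes are not estimated for them downstream).
#'
#' @param baselines data.frame with \code{participant_id}, \code{value} and,
#'   for sex-specific ranges, \code{sex}.
#' @param ranges reference-range table (\code{\link{read_reference_ranges}}).
#' @param marker marker name looked up in \code{ranges}.
#' @param min_n stratum size floor (default 50).
#' @return data.frame \code{participant_id, stratum, estimable}.
#' @export
#' @examples
#' rr <- data.frame(marker = "Vitamin D", low = 30, high = 100, low_M = NA,
#'                  high_M = NA, low_F = NA, high_F = NA, class = "other")
#' b <- data.frame(participant_id = "P1", value = 25, sex = "F")
#' classify_baseline_strata(b, rr, "Vitamin D", min_n = 1)$stratum  # low
classify_baseline_strata <- function(baselines, ranges, marker, min_n = 50) {
  stopifnot(all(c("participant_id", "value") %in% names(baselines)))
  sex <- if ("sex" %in% names(baselines)) baselines$sex else NULL
  n <- nrow(baselines)
  rowr <- ranges[ranges$marker == marker, , drop = FALSE]
  if (nrow(rowr) == 0L) {
    out <- data.frame(participant_id = baselines$participant_id,
                      stratum = factor(rep("all", n)),
                      estimable = rep(TRUE, n), stringsAsFactors = FALSE)
    return(out)
  }
  low <- rep(rowr$low, n); high <- rep(rowr$high, n)
  if (!is.null(sex)) {
    lm_ <- ifelse(sex == "M", rowr$low_M, rowr$low_F)
    hm_ <- ifelse(sex == "M", rowr$high_M, rowr$high_F)
    low <- ifelse(is.na(lm_), low, lm_)
    high <- ifelse(is.na(hm_), high, hm_)
  }
  stratum <- rep("normal", n)
  stratum[!is.na(low) & baselines$value < low] <- "low"
  stratum[!is.na(high) & baselines$value > high] <- "high"
  stratum <- factor(stratum, levels = c("normal", "low", "high"))
  counts <- table(stratum)
  estimable <- counts[stratum] >= min_n
  data.frame(participant_id = baselines$participant_id, stratum = stratum,
             estimable = as.logical(estimable), stringsAsFactors = FALSE)
}

#' Out-of-range summary at baseline and latest measurement
#'
#' Per-marker population summary: mean and SD at baseline and at each
#' participant's last retained measurement, the share of participants outside
#' the reference range at each, and the change in that share.  Following the
#' reporting convention of such cohort tables, out-of-range percentages are
#' \code{NA} when the marker has no range definition or fewer than
#' \code{min_oor} participants are out of range (set \code{min_oor = 0} to
#' suspend the rule on toy data).
#'
#' @param baselines data.frame \code{participant_id, value} (+ \code{sex}).
#' @param latest data.frame \code{participant_id, value}, one row per
#'   participant (their last retained record).
#' @param ranges reference-range table.
#' @param marker marker name.
#' @param min_oor minimum out-of-range count for reporting (default 50).
#' @return one-row data.frame \code{marker, n, mean_baseline, sd_baseline,
#'   mean_latest, sd_latest, pct_oor_baseline, pct_oor_latest, delta_oor}.
#' @export
oor_summary <- function(baselines, latest, ranges, marker, min_oor = 50) {
  stopifnot(nrow(baselines) == nrow(latest))
  latest <- latest[match(baselines$participant_id, latest$participant_id), ,
                   drop = FALSE]
  out <- data.frame(marker = marker, n = nrow(baselines),
                    mean_baseline = mean(baselines$value),
                    sd_baseline = stats::sd(baselines$value),
                    mean_latest = mean(latest$value),
                    sd_latest = stats::sd(latest$value),
                    pct_oor_baseline = NA_real_, pct_oor_latest = NA_real_,
                    delta_oor = NA_real_, stringsAsFactors = FALSE)
  rowr <- ranges[ranges$marker == marker, , drop = FALSE]
  if (nrow(rowr) == 0L) return(out)
  sex <- if ("sex" %in% names(baselines)) baselines$sex else NULL
  oor <- function(values) {
    n <- length(values)
    low <- rep(rowr$low, n); high <- rep(rowr$high, n)
    if (!is.null(sex)) {
      lm_ <- ifelse(sex == "M", rowr$low_M, rowr$low_F)
      hm_ <- ifelse(sex == "M", rowr$high_M, rowr$high_F)
      low <- ifelse(is.na(lm_), low, lm_)
      high <- ifelse(is.na(hm_), high, hm_)
    }
    (!is.na(low) & values < low) | (!is.na(high) & values > high)
  }
  oor_b <- oor(baselines$value)
  oor_l <- oor(latest$value)
  if (sum(oor_b) >= min_oor || sum(oor_l) >= min_oor) {
    out$pct_oor_baseline <- 100 * mean(oor_b)
    out$pct_oor_latest <- 100 * mean(oor_l)
    out$delta_oor <- out$pct_oor_latest - out$pct_oor_baseline
  }
  out
}
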