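# shared fixture builders (everything generated in code, nothing on disk)

# symmetric r2 matrix from a named upper-triangle spec, e.g.
# make_ld(c("A","B","C"), "A:B" = 0.5)
make_ld <- function(ids, ...) {
  pairs <- list(...)
  m <- diag(length(ids))
  dimnames(m) <- list(ids, ids)
  for (nm in names(pairs)) {
    ij <- strsplit(nm, ":", fixed = TRUE)[[1]]
    m[ij[1], ij[2]] <- m[ij[2], ij[1]] <- pairs[[nm]]
  }
  m
}

# brute-force BH step-up oracle: largest s such that at least s p-values
# fall at or below s*q/m; rejects all p <= that cutoff
bh_oracle <- function(p, q) {
  m <- length(p)
  for (s in rev(seq_len(m))) {
    if (sum(p <= s * q / m) >= s) return(which(p <= s * q / m))
  }
  integer(0)
}

# quick small cohort with stratum offsets (categorical genetic mode)
quick_sim <- function(n = 400, offsets = c(`Q2/Q3` = 0, Q1 = -15.74, Q4 = 13.69),
                      change = c(Q1 = 0, Q4 = 0), trajectory = c(-2.58, -3.26),
                      seed = 1, ...) {
  cfg <- sim_config(n_participants = n, n_snps = 10, n_blocks = 2,
                    change_effect = change, trajectory = trajectory,
                    seed = seed, ...)
  set.seed(seed + 77)
  score <- stats::rnorm(n)
  qs <- stats::quantile(score, c(0.25, 0.75))
  strata <- factor(ifelse(score < qs[1], "Q1",
                          ifelse(score >= qs[2], "Q4", "Q2/Q3")),
                   levels = c("Q2/Q3", "Q1", "Q4"))
  sim <- simulate_longitudinal(cfg, genetic = list(strata = strata,
                                                   offsets = offsets))
  sim$config <- cfg
  sim
}

# baseline/follow-up split of a generated records table (no filtering edge
# cases: generator visits are always 1 baseline + followups)
split_baseline <- function(records) {
  sel <- select_analysis_set(records)
  list(records = sel$records, baselines = sel$baselines)
}
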