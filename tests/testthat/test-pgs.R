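test_that("BH step-up selects the hand-traced set", {
  # thresholds at q=0.05, m=4: 0.0125, 0.025, 0.0375, 0.05
  expect_setequal(bh_fdr_filter(c(0.001, 0.01, 0.02, 0.8), 0.05), 1:3)
  expect_length(bh_fdr_filter(c(0.9, 0.8), 0.05), 0)
  # boundary equality is inclusive: all p exactly at q/m are all selected
  expect_setequal(bh_fdr_filter(rep(0.05 / 6, 6), 0.05), 1:6)
  expect_length(bh_fdr_filter(numeric(0), 0.05), 0)
  expect_error(bh_fdr_filter(c(0.5, 0), 0.05), "in \\(0, 1\\]")
  expect_error(bh_fdr_filter(c(0.5, 1.2), 0.05), "in \\(0, 1\\]")
})

test_that("BH step-up matches the brute-force oracle on random vectors", {
  set.seed(41)
  for (rep in 1:60) {
    m <- sample(1:12, 1)
    # mix of null and signal-like p-values, plus occasional ties
    p <- round(c(runif(m)^sample(1:3, 1)), 3)
    p[p == 0] <- 1e-4
    q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    expect_setequal(bh_fdr_filter(p, q), bh_oracle(p, q))
    # equivalence with the standard adjusted-p route
    expect_setequal(bh_fdr_filter(p, q), which(p.adjust(p, "BH") <= q))
  }
})

test_that("LD pruning follows the significance-first greedy rule", {
  cand <- data.frame(snp_id = c("A", "B", "C"), p = c(1e-8, 1e-6, 1e-4))
  ld <- make_ld(c("A", "B", "C"), "A:B" = 0.5, "A:C" = 0.1, "B:C" = 0.05)
  expect_equal(ld_prune(cand, ld)$snp_id, c("A", "C"))

  # nothing correlated: input unchanged
  ld0 <- make_ld(c("A", "B", "C"))
  expect_equal(ld_prune(cand, ld0)$snp_id, cand$snp_id)

  # equal p: exactly one kept, tie broken lexicographically by snp_id
  tie <- data.frame(snp_id = c("rsB", "rsA"), p = c(1e-5, 1e-5))
  ldt <- make_ld(c("rsA", "rsB"), "rsA:rsB" = 0.95)
  expect_equal(ld_prune(tie, ldt)$snp_id, "rsA")

  # missing LD entry is an error, not assumed independence
  expect_error(ld_prune(cand, ld0[1:2, 1:2]), "LD matrix lacks")
  ldna <- ld; ldna["B", "C"] <- ldna["C", "B"] <- NA
  expect_error(ld_prune(cand, ldna), "missing LD entry")
})

test_that("pruned sets never contain a pair at or above the threshold", {
  set.seed(42)
  for (rep in 1:25) {
    m <- sample(3:12, 1)
    ids <- paste0("s", seq_len(m))
    r <- matrix(runif(m * m), m, dimnames = list(ids, ids))
    ld <- (r + t(r)) / 2; diag(ld) <- 1
    thr <- runif(1, 0.1, 0.6)
    kept <- ld_prune(data.frame(snp_id = ids, p = runif(m)), ld, thr)
    sub <- ld[kept$snp_id, kept$snp_id, drop = FALSE]
    expect_true(all(sub[upper.tri(sub)] < thr))
  }
})

test_that("model construction composes FDR filter and LD pruning", {
  one <- data.frame(snp_id = "rs1", effect_allele = "A", other_allele = "G",
                    beta = 0.4, p = 1e-12, eaf = 0.3)
  m <- build_pgs_model(one, make_ld("rs1"))
  expect_equal(nrow(m), 1L)
  expect_equal(m$weight, 0.4)
  expect_equal(attr(m, "q"), 0.05)

  null_stats <- data.frame(snp_id = c("rs1", "rs2"),
                           effect_allele = "A", other_allele = "G",
                           beta = 0, p = c(0.4, 0.7), eaf = 0.3)
  expect_error(build_pgs_model(null_stats, make_ld(c("rs1", "rs2")), q = 1e-12),
               "empty model")
})

test_that("block-structured synthetic stats yield one SNP per causal block", {
  cfg <- sim_config(n_participants = 800, n_snps = 50, n_blocks = 10,
                    within_block_rho = 0.9, missing_genotype_rate = 0, seed = 11)
  g <- simulate_genotypes(cfg)
  true_effects <- setNames(numeric(50), rownames(g$genotypes))
  causal <- which(seq_len(50) %% 5 == 3)  # one per 5-SNP block
  true_effects[causal] <- 8
  st <- simulate_summary_stats(true_effects, g$freqs, gwas_n = 10000,
                               sd_y = 10, alleles = g$alleles, seed = 12)
  model <- build_pgs_model(st, g$ld)
  blocks_hit <- unique(g$blocks[match(model$snp_id, rownames(g$genotypes))])
  expect_length(blocks_hit, 10L)  # every detectable block represented
  # mutually uncorrelated at build-time LD
  sub <- g$ld[model$snp_id, model$snp_id]
  expect_true(all(sub[upper.tri(sub)] < 0.2))
})

test_that("scoring is a weighted dosage sum with 2*EAF mean imputation", {
  m <- data.frame(snp_id = "rs1", effect_allele = "A", other_allele = "C",
                  weight = 0.5, eaf = 0.3, stringsAsFactors = FALSE)
  gt <- matrix(c(2L, NA), 1, 2, dimnames = list("rs1", c("P1", "P2")))
  s <- score_individuals(m, gt)
  expect_equal(unname(s["P1"]), 1.0)
  expect_equal(unname(s["P2"]), 2 * 0.3 * 0.5)

  # stored dosage counts the other allele: flip before weighting
  m2 <- data.frame(snp_id = "rs1", effect_allele = "A", other_allele = "C",
                   weight = 1, eaf = 0.3)
  stored <- data.frame(snp_id = "rs1", effect_allele = "C", other_allele = "A")
  gt0 <- matrix(0L, 1, 1, dimnames = list("rs1", "P1"))
  expect_equal(unname(score_individuals(m2, gt0, stored)), 2)

  # errors: absent SNP, allele mismatch
  expect_error(score_individuals(
    data.frame(snp_id = "rsX", effect_allele = "A", other_allele = "C",
               weight = 1, eaf = 0.5), gt), "rsX")
  badal <- data.frame(snp_id = "rs1", effect_allele = "T", other_allele = "G")
  expect_error(score_individuals(m2, gt0, badal), "allele mismatch")
})

test_that("scoring is linear in the weight vector", {
  set.seed(5)
  gt <- matrix(sample(c(0:2, NA), 60, TRUE), nrow = 6,
               dimnames = list(paste0("s", 1:6), paste0("P", 1:10)))
  base <- data.frame(snp_id = paste0("s", 1:6), effect_allele = "A",
                     other_allele = "C", eaf = runif(6, 0.1, 0.9))
  w1 <- rnorm(6); w2 <- rnorm(6)
  s1 <- score_individuals(cbind(base, weight = w1), gt)
  s2 <- score_individuals(cbind(base, weight = w2), gt)
  s12 <- score_individuals(cbind(base, weight = w1 + w2), gt)
  expect_equal(s12, s1 + s2, tolerance = 1e-12)
})

test_that("mean-imputed participants score at the HWE population mean", {
  set.seed(6)
  p <- 0.3
  gt <- matrix(rbinom(4000, 2, p), nrow = 1,
               dimnames = list("s1", paste0("P", 1:4000)))
  model <- data.frame(snp_id = "s1", effect_allele = "A", other_allele = "C",
                      weight = 0.7, eaf = p)
  observed_mean <- mean(score_individuals(model, gt))
  gt_na <- matrix(NA_integer_, 1, 1, dimnames = list("s1", "Px"))
  imputed <- unname(score_individuals(model, gt_na))
  expect_equal(imputed, 2 * p * 0.7)
  expect_lt(abs(imputed - observed_mean), 0.02)
})

test_that("quartile strata follow the < 25th / >= 75th convention", {
  q <- assign_pgs_quartiles(setNames(1:8, paste0("P", 1:8)))
  expect_equal(as.character(q[paste0("P", 1:2)]), c("Q1", "Q1"))
  expect_equal(as.character(q[paste0("P", 3:6)]), rep("Q2/Q3", 4))
  expect_equal(as.character(q[paste0("P", 7:8)]), c("Q4", "Q4"))
  expect_equal(levels(q)[1], "Q2/Q3")  # reference stratum

  expect_error(assign_pgs_quartiles(rep(1, 10)), "degenerate")
  expect_error(assign_pgs_quartiles(1:3), "at least 4")

  set.seed(7)
  big <- assign_pgs_quartiles(rnorm(2531))
  expect_true(abs(sum(big == "Q1") - 2531 / 4) <= 1)
  expect_true(abs(sum(big == "Q4") - 2531 / 4) <= 1)
})

test_that("genotype strata map dosages to labels and drop missing", {
  d <- c(P1 = 0, P2 = 1, P3 = 2, P4 = NA)
  s <- assign_genotype_strata(d, "G", "T")
  expect_equal(as.character(s), c("TT", "GT", "GG"))
  expect_equal(levels(s)[1], "TT")  # first-listed homozygote is reference
  expect_false("P4" %in% names(s))
  # partition: labels sum to non-missing count
  set.seed(8)
  dd <- sample(c(0:2, NA), 500, TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  names(dd) <- paste0("P", seq_along(dd))
  ss <- assign_genotype_strata(dd, "A", "C")
  expect_equal(length(ss), sum(!is.na(dd)))
  expect_error(assign_genotype_strata(c(P1 = 3), "A", "C"), "dosages")
})

test_that("rule-table scoring sums matching genotype contributions", {
  gt <- matrix(c(0L, 1L, 2L, NA, 0L, 1L), nrow = 2, byrow = TRUE,
               dimnames = list(c("r1", "r2"), paste0("P", 1:3)))
  rules <- data.frame(snp_id = c("r1", "r1", "r2"), dosage = c(1, 2, 0),
                      contribution = c(5, 10, 2), default = 0)
  s <- score_by_rules(rules, gt)
  expect_equal(unname(s), c(0 + 0, 5 + 2, 10 + 0))
  expect_error(score_by_rules(data.frame(snp_id = "zz", dosage = 0,
                                         contribution = 1), gt), "zz")
})
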