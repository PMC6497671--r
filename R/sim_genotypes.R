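#' Simulate LD-blocked biallelic genotypes
#'
#' Dosages are generated per haplotype from a latent AR(1) Gaussian within each
#' LD block: haplotype \code{h} carries the effect allele at SNP \code{j} when
#' its latent value falls below \code{qnorm(maf_j)}, and the two haplotypes are
#' independent, so genotypes are in Hardy-Weinberg proportions at each SNP.
#' Latent correlation between SNPs \code{i} and \code{j} of the same block is
#' \code{within_block_rho^|i-j|}; SNPs of different blocks are independent.
#' The observed dosage correlation is attenuated relative to the latent
#' correlation by the thresholding (about r2 0.4-0.5 for adjacent SNPs at
#' latent rho 0.9, depending on allele frequency).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with
#'   \item{genotypes}{integer matrix, SNPs in rows (named \code{snp<j>}),
#'     participants in columns (named \code{P<i>}); dosages 0/1/2 with
#'     \code{NA} at \code{missing_genotype_rate}.}
#'   \item{freqs}{effect-allele frequency used for each SNP.}
#'   \item{ld}{SNP-by-SNP squared Pearson correlation of dosages (complete
#'     pairs), the r2 matrix used for pruning.}
#'   \item{blocks}{integer block index per SNP.}
#'   \item{alleles}{data.frame of effect/other allele per SNP.}
#' @export
#' @examples
#' g <- simulate_genotypes(sim_config(n_participants = 100, n_snps = 20,
#'                                    n_blocks = 4, seed = 7))
#' table(g$genotypes[1, ], useNA = "ifany")
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  m <- config$n_snps
  rho <- config$within_block_rho
  blocks <- sort(rep_len(seq_len(config$n_blocks), m))
  freqs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  thr <- stats::qnorm(freqs)

  dose <- matrix(0L, nrow = m, ncol = n)
  for (h in 1:2) {
    z <- matrix(0, nrow = m, ncol = n)
    for (j in seq_len(m)) {
      e <- stats::rnorm(n)
      if (j > 1L && blocks[j] == blocks[j - 1L]) {
        z[j, ] <- rho * z[j - 1L, ] + sqrt(1 - rho^2) * e
      } else {
        z[j, ] <- e
      }
    }
    dose <- dose + (z < thr)
  }
  storage.mode(dose) <- "integer"
  if (config$missing_genotype_rate > 0) {
    miss <- stats::runif(length(dose)) < config$missing_genotype_rate
    dose[miss] <- NA_integer_
  }
  rownames(dose) <- paste0("snp", seq_len(m))
  colnames(dose) <- paste0("P", seq_len(n))

  ld <- stats::cor(t(dose), use = "pairwise.complete.obs")^2
  ld[is.na(ld)] <- 0
  diag(ld) <- 1

  # alternating allele pair so orientation handling is exercised downstream
  alleles <- data.frame(snp_id = rownames(dose),
                        effect_allele = rep(c("A", "G"), length.out = m),
                        other_allele = rep(c("C", "T"), length.out = m),
                        stringsAsFactors = FALSE)
  list(genotypes = dose, freqs = stats::setNames(freqs, rownames(dose)),
       ld = ld, blocks = blocks, alleles = alleles)
}

#' Simulate GWAS summary statistics consistent with true effects
#'
#' Emulates a published GWAS of size \code{gwas_n}: the estimated effect is the
#' true effect plus Gaussian sampling noise with the analytic standard error
#' \code{SE = sd_y / (sd_g * sqrt(gwas_n))}, where \code{sd_g =
#' sqrt(2 p (1-p))} is the dosage SD under Hardy-Weinberg equilibrium, and the
#' p-value is the two-sided normal p of \code{beta_hat / SE}.  Null SNPs
#' (true effect 0) therefore get uniform p-values.  Monomorphic SNPs
#' (frequency 0 or 1) have no defined SE; they are flagged \code{excluded}.
#'
#' @param true_effects numeric vector of per-allele true effects (marker units),
#'   named by snp_id.
#' @param freqs effect-allele frequencies, same order.
#' @param gwas_n GWAS sample size (> 0).
#' @param sd_y phenotype SD in the GWAS population (marker units).
#' @param alleles optional data.frame \code{snp_id/effect_allele/other_allele};
#'   defaults to A/C for every SNP.
#' @param seed integer seed.
#' @return data.frame with columns \code{snp_id}, \code{effect_allele},
#'   \code{other_allele}, \code{beta}, \code{se}, \code{p}, \code{eaf},
#'   \code{excluded}.
#' @export
simulate_summary_stats <- function(true_effects, freqs, gwas_n, sd_y = 1,
                                   alleles = NULL, seed = 1L) {
  if (gwas_n <= 0) stop("gwas_n must be > 0")
  m <- length(true_effects)
  stopifnot(length(freqs) == m)
  set.seed(seed)
  ids <- names(true_effects)
  if (is.null(ids)) ids <- paste0("snp", seq_len(m))
  if (is.null(alleles)) {
    alleles <- data.frame(snp_id = ids, effect_allele = "A", other_allele = "C",
                          stringsAsFactors = FALSE)
  }
  mono <- freqs <= 0 | freqs >= 1
  sd_g <- sqrt(2 * freqs * (1 - freqs))
  se <- sd_y / (sd_g * sqrt(gwas_n))
  se[mono] <- NA_real_
  beta_hat <- true_effects + ifelse(mono, 0, stats::rnorm(m) * se)
  p <- 2 * stats::pnorm(-abs(beta_hat / se))
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  data.frame(snp_id = ids,
             effect_allele = alleles$effect_allele[match(ids, alleles$snp_id)],
             other_allele = alleles$other_allele[match(ids, alleles$snp_id)],
             beta = beta_hat, se = se, p = p, eaf = freqs,
             excluded = mono, row.names = NULL, stringsAsFactors = FALSE)
}
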