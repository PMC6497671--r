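#' Benjamini-Hochberg step-up selection
#'
#' Returns the indices of all p-values passing the BH step-up rule at FDR
#' level \code{q}: with order statistics \code{p_(1) <= ... <= p_(m)}, find
#' \code{k = max(i : p_(i) <= i q / m)}; select every p at or below
#' \code{p_(k)} (inclusive), or nothing if no \code{i} qualifies.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param q FDR level in (0, 1).
#' @return integer vector of selected indices (possibly empty), in the order
#'   of the input.
#' @export
#' @examples
#' bh_fdr_filter(c(0.001, 0.01, 0.02, 0.8), q = 0.05)  # 1 2 3
bh_fdr_filter <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) return(integer(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must be in (0, 1]")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0L) return(integer(0))
  which(p_values <= ps[max(ok)])
}

#' Greedy LD pruning of candidate SNPs
#'
#' Repeatedly takes the most significant remaining SNP (ties broken
#' lexicographically by snp_id) and discards every remaining SNP whose squared
#' dosage correlation with it is at or above \code{r2_threshold}.  The
#' returned set is mutually uncorrelated: every retained pair has
#' \code{r2 < r2_threshold} (strict).
#'
#' @param candidates data.frame with columns \code{snp_id} and \code{p}.
#' @param ld symmetric r2 matrix with dimnames covering every candidate.
#' @param r2_threshold pruning threshold (default 0.2).
#' @return the retained subset of \code{candidates}, in selection order.
#' @export
ld_prune <- function(candidates, ld, r2_threshold = 0.2) {
  stopifnot(is.data.frame(candidates), all(c("snp_id", "p") %in% names(candidates)))
  if (nrow(candidates) == 0L) return(candidates)
  ids <- candidates$snp_id
  if (anyDuplicated(ids)) stop("duplicated snp_id among candidates")
  if (is.null(dimnames(ld)) || !all(ids %in% rownames(ld)) ||
      !all(ids %in% colnames(ld)))
    stop("LD matrix lacks entries for candidates: ",
         paste(setdiff(ids, rownames(ld)), collapse = ", "))
  sub <- ld[ids, ids, drop = FALSE]
  if (any(is.na(sub)))
    stop("missing LD entry for a candidate pair; refusing to assume independence")
  ord <- order(candidates$p, candidates$snp_id)
  remaining <- ord
  keep <- integer(0)
  while (length(remaining) > 0L) {
    top <- remaining[1L]
    keep <- c(keep, top)
    remaining <- remaining[-1L]
    if (length(remaining) > 0L) {
      r2 <- sub[ids[top], ids[remaining]]
      remaining <- remaining[r2 < r2_threshold]
    }
  }
  candidates[keep, , drop = FALSE]
}

#' Build a pruning-and-thresholding polygenic score model
#'
#' Composition of \code{\link{bh_fdr_filter}} (SNP selection controlling the
#' FDR at level \code{q} over all GWAS p-values) and \code{\link{ld_prune}}
#' (greedy removal of correlated SNPs at \code{r2 >= r2_threshold}).  Weights
#' are the published effect sizes oriented to the effect allele, used as
#' given.
#'
#' @param stats summary-statistic data.frame with columns \code{snp_id},
#'   \code{effect_allele}, \code{other_allele}, \code{beta}, \code{p},
#'   \code{eaf}, and optionally \code{excluded} (monomorphic flags, dropped
#'   before selection).
#' @param ld r2 matrix (dimnames = snp ids).
#' @param q FDR level (default 0.05).
#' @param r2_threshold LD pruning threshold (default 0.2).
#' @return object of class \code{pgs_model}: data.frame \code{snp_id,
#'   effect_allele, other_allele, weight, eaf} with attributes \code{q} and
#'   \code{r2_threshold} (provenance).
#' @export
build_pgs_model <- function(stats, ld, q = 0.05, r2_threshold = 0.2) {
  stopifnot(is.data.frame(stats), nrow(stats) > 0)
  need <- c("snp_id", "effect_allele", "other_allele", "beta", "p", "eaf")
  if (!all(need %in% names(stats)))
    stop("summary stats missing columns: ",
         paste(setdiff(need, names(stats)), collapse = ", "))
  if ("excluded" %in% names(stats)) stats <- stats[!stats$excluded, , drop = FALSE]
  if (any(stats$effect_allele == stats$other_allele))
    stop("effect and other allele identical for some SNPs")
  sel <- bh_fdr_filter(stats$p, q)
  if (length(sel) == 0L)
    stop("empty model: no SNP passes the FDR filter at q = ", q)
  cand <- stats[sel, , drop = FALSE]
  kept <- ld_prune(cand[, c("snp_id", "p")], ld, r2_threshold)
  kept_stats <- cand[match(kept$snp_id, cand$snp_id), , drop = FALSE]
  model <- data.frame(snp_id = kept_stats$snp_id,
                      effect_allele = kept_stats$effect_allele,
                      other_allele = kept_stats$other_allele,
                      weight = kept_stats$beta,
                      eaf = kept_stats$eaf,
                      row.names = NULL, stringsAsFactors = FALSE)
  attr(model, "q") <- q
  attr(model, "r2_threshold") <- r2_threshold
  class(model) <- c("pgs_model", "data.frame")
  model
}

#' Score individuals with a polygenic score model
#'
#' The score is the weighted sum of effect-allele dosages over the model SNPs.
#' Missing genotypes are mean imputed as \code{2 * eaf}.  When the genotype
#' matrix stores dosages of the model's other allele (per the \code{alleles}
#' table), the dosage is flipped (\code{2 - d}) before weighting; a SNP whose
#' stored alleles match neither model allele is an error.
#'
#' @param model a \code{\link{build_pgs_model}} result (or a data.frame with
#'   the same columns).
#' @param genotypes dosage matrix, SNPs in rows (rownames = snp ids),
#'   participants in columns; \code{NA} = missing.
#' @param alleles optional data.frame \code{snp_id, effect_allele,
#'   other_allele} describing which allele the stored dosage counts; defaults
#'   to the model's own orientation.
#' @return named numeric vector of scores, one per participant.
#' @export
#' @examples
#' m <- data.frame(snp_id = "rs1", effect_allele = "A", other_allele = "C",
#'                 weight = 0.5, eaf = 0.3)
#' score_individuals(m, matrix(c(2, NA), 1, 2,
#'                   dimnames = list("rs1", c("P1", "P2"))))
score_individuals <- function(model, genotypes, alleles = NULL) {
  stopifnot(is.matrix(genotypes) || is.data.frame(genotypes))
  genotypes <- as.matrix(genotypes)
  missing_snps <- setdiff(model$snp_id, rownames(genotypes))
  if (length(missing_snps) > 0L)
    stop("model SNPs absent from genotypes: ",
         paste(missing_snps, collapse = ", "))
  d <- genotypes[model$snp_id, , drop = FALSE]
  if (!is.null(alleles)) {
    stored <- alleles[match(model$snp_id, alleles$snp_id), , drop = FALSE]
    if (any(is.na(stored$effect_allele)))
      stop("alleles table lacks entries for some model SNPs")
    same <- stored$effect_allele == model$effect_allele &
      stored$other_allele == model$other_allele
    flipped <- stored$effect_allele == model$other_allele &
      stored$other_allele == model$effect_allele
    if (any(!same & !flipped))
      stop("allele mismatch for: ",
           paste(model$snp_id[!same & !flipped], collapse = ", "))
    d[flipped, ] <- 2 - d[flipped, , drop = FALSE]
  }
  # mean imputation at 2 * effect-allele frequency
  for (j in seq_len(nrow(d))) d[j, is.na(d[j, ])] <- 2 * model$eaf[j]
  scores <- drop(crossprod(d, model$weight))
  stats::setNames(as.numeric(scores), colnames(d))
}

#' Assign polygenic-score quartile strata
#'
#' Q1 = score below the 25th percentile, Q4 = score at or above the 75th
#' percentile, Q2/Q3 (the reference) otherwise; percentiles are computed on
#' the supplied analysis population.
#'
#' @param scores numeric vector (>= 4 values).
#' @return factor with levels \code{Q2/Q3} (reference), \code{Q1}, \code{Q4}.
#' @export
assign_pgs_quartiles <- function(scores) {
  if (length(scores) < 4L) stop("need at least 4 participants for quartiles")
  qs <- stats::quantile(scores, c(0.25, 0.75), na.rm = TRUE)
  lab <- ifelse(scores < qs[1], "Q1", ifelse(scores >= qs[2], "Q4", "Q2/Q3"))
  lab <- factor(lab, levels = c("Q2/Q3", "Q1", "Q4"))
  if (any(table(lab) == 0L))
    stop("degenerate scores: a quartile stratum is empty (heavy ties)")
  stats::setNames(lab, names(scores))
}

#' Assign genotype strata from single-SNP dosages
#'
#' Maps dosage of the effect allele to a genotype label (0 ->
#' other/other, 1 -> heterozygote, 2 -> effect/effect); the first-listed
#' homozygote (dosage 0) is the reference.  Missing dosages are dropped.
#'
#' @param dosages named numeric vector in \{0, 1, 2, NA\}.
#' @param effect_allele,other_allele single characters, e.g. "G", "T".
#' @return named factor over the non-missing participants; levels ordered
#'   reference first.
#' @export
#' @examples
#' assign_genotype_strata(c(P1 = 0, P2 = 1, P3 = 2), "G", "T")  # TT GT GG
assign_genotype_strata <- function(dosages, effect_allele, other_allele) {
  ok <- !is.na(dosages)
  d <- dosages[ok]
  if (!all(d %in% 0:2)) stop("dosages must be 0, 1, 2 or NA")
  het <- paste(sort(c(other_allele, effect_allele)), collapse = "")
  labs <- c(paste0(other_allele, other_allele), het,
            paste0(effect_allele, effect_allele))
  stats::setNames(factor(labs[d + 1L], levels = labs), names(d))
}

#' Score individuals with a genotype-pattern rule table
#'
#' Some published scores are rule based rather than weighted sums: each rule
#' maps a genotype pattern at one SNP to a score contribution.  The rule
#' table is user supplied; contributions of matching rules are summed per
#' participant.  Participants missing a rule's genotype get that rule's
#' \code{default} contribution (0 unless given).
#'
#' @param rules data.frame with columns \code{snp_id}, \code{dosage} (0/1/2),
#'   \code{contribution}, and optionally \code{default}.
#' @param genotypes dosage matrix, SNPs in rows.
#' @return named numeric vector of scores.
#' @export
score_by_rules <- function(rules, genotypes) {
  stopifnot(all(c("snp_id", "dosage", "contribution") %in% names(rules)))
  missing_snps <- setdiff(unique(rules$snp_id), rownames(genotypes))
  if (length(missing_snps) > 0L)
    stop("rule SNPs absent from genotypes: ", paste(missing_snps, collapse = ", "))
  scores <- stats::setNames(numeric(ncol(genotypes)), colnames(genotypes))
  for (s in unique(rules$snp_id)) {
    rs <- rules[rules$snp_id == s, , drop = FALSE]
    def <- if ("default" %in% names(rs)) rs$default[1] else 0
    d <- genotypes[s, ]
    contrib <- rs$contribution[match(d, rs$dosage)]
    contrib[is.na(contrib)] <- def
    scores <- scores + contrib
  }
  scores
}
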