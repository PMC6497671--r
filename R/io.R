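#' Write and read a dosage matrix as TSV
#'
#' SNPs in rows, participants in columns, first column \code{snp_id};
#' missing genotypes written as \code{NA}.
#'
#' @param genotypes dosage matrix (rownames = snp ids).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(snp_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$snp_id
  m
}

#' Write and read GWAS summary statistics as TSV
#'
#' Schema: \code{snp_id, effect_allele, other_allele, beta, p, eaf} (plus any
#' extra columns such as \code{se} or \code{excluded}).
#'
#' @param stats summary-statistic data.frame.
#' @param path file path.
#' @return \code{path} (write) or the data.frame (read).
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  st <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "effect_allele", "other_allele", "beta", "p", "eaf")
  if (!all(need %in% names(st)))
    stop("summary-stat file ", path, " missing columns: ",
         paste(setdiff(need, names(st)), collapse = ", "))
  st
}

#' Write and read long-format phenotype records as CSV
#'
#' Schema: \code{participant_id, marker, value, day, fasting, med_lipid,
#' med_glucose, med_bp} plus any extra columns (sex, season).
#'
#' @param records long data.frame.
#' @param path file path.
#' @return \code{path} (write) or the data.frame (read).
#' @export
write_phenotypes <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "marker", "value", "day")
  if (!all(need %in% names(rec)))
    stop("phenotype file ", path, " missing columns: ",
         paste(setdiff(need, names(rec)), collapse = ", "))
  for (v in intersect(c("fasting", "med_lipid", "med_glucose", "med_bp"),
                      names(rec)))
    rec[[v]] <- as.logical(rec[[v]])
  rec
}

#' Write genotypes as a minimal VCF
#'
#' Unphased GT-only VCF; the effect allele is written as ALT and the other
#' allele as REF, so the ALT dosage equals the effect-allele dosage.  Missing
#' genotypes become \code{./.}.
#'
#' @param genotypes dosage matrix (SNPs x participants).
#' @param alleles data.frame \code{snp_id, effect_allele, other_allele}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(genotypes, alleles, path) {
  al <- alleles[match(rownames(genotypes), alleles$snp_id), , drop = FALSE]
  if (any(is.na(al$effect_allele)))
    stop("alleles table lacks entries for some SNPs")
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- apply(genotypes, 2, function(d)
    ifelse(is.na(d), "./.", gt_codes[d + 1L]))
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(genotypes)), collapse = "\t"))
  rows <- paste("1", seq_len(nrow(genotypes)), rownames(genotypes),
                al$other_allele, al$effect_allele, ".", "PASS", ".", "GT",
                apply(body, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, rows), path)
  invisible(path)
}

#' Read effect-allele dosages from a GT-only VCF
#'
#' Parses the GT field of an unphased, biallelic VCF into an ALT-allele
#' dosage matrix.  The returned \code{alleles} attribute records REF/ALT so
#' scoring can resolve allele orientation.
#'
#' @param path VCF file.
#' @return dosage matrix (SNPs x participants) with attribute \code{alleles}
#'   (data.frame \code{snp_id, effect_allele, other_allele}; ALT is the
#'   counted allele).
#' @export
read_vcf_dosages <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-(1:9)]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- vapply(rows, `[`, "", 3L)
  ref <- vapply(rows, `[`, "", 4L)
  alt <- vapply(rows, `[`, "", 5L)
  dose <- t(vapply(rows, function(r) {
    gt <- substr(r[-(1:9)], 1, 3)
    out <- rep(NA_integer_, length(gt))
    out[gt == "0/0"] <- 0L
    out[gt %in% c("0/1", "1/0")] <- 1L
    out[gt == "1/1"] <- 2L
    out
  }, integer(length(samples))))
  dimnames(dose) <- list(ids, samples)
  attr(dose, "alleles") <- data.frame(snp_id = ids, effect_allele = alt,
                                      other_allele = ref,
                                      stringsAsFactors = FALSE)
  dose
}

#' Write and read a polygenic score model
#'
#' The model is written as TSV (\code{snp_id, effect_allele, other_allele,
#' weight, eaf}) with a YAML provenance sidecar (\code{<path>.yaml}) recording
#' the FDR level and r2 threshold used at build time and the quartile
#' boundary convention.
#'
#' @param model a \code{\link{build_pgs_model}} result.
#' @param path TSV path.
#' @return \code{path} (write) or the \code{pgs_model} (read).
#' @export
write_pgs_model <- function(model, path) {
  utils::write.table(as.data.frame(model), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  prov <- list(fdr_q = attr(model, "q"),
               r2_threshold = attr(model, "r2_threshold"),
               quartile_convention = "Q1 < 25th percentile; Q4 >= 75th percentile")
  yaml::write_yaml(prov, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_pgs_model
#' @export
read_pgs_model <- function(path) {
  model <- utils::read.delim(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    prov <- yaml::read_yaml(side)
    attr(model, "q") <- prov$fdr_q
    attr(model, "r2_threshold") <- prov$r2_threshold
  }
  class(model) <- c("pgs_model", "data.frame")
  model
}
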