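# Reading phased VCF and phenotype tables; SNP/individual QC filters and
# phenotype outlier removal.

#' Read phased genotypes from a VCF file
#'
#' Parses a VCF with phased GT fields ("0|1") into a [phased_genotypes()]
#' panel. Multiallelic records are skipped and counted. Unphased homozygous
#' calls ("0/0", "1/1") are unambiguous and accepted; unphased heterozygous
#' calls ("0/1") are an error in strict mode, otherwise set to missing and
#' counted. "." alleles become missing.
#'
#' @param path VCF file (plain or gzipped)
#' @param strict reject unphased heterozygous calls (default TRUE)
#' @return a `phased_genotypes` with an attribute `"read_report"` listing the
#'   number of multiallelic records skipped and unphased calls flagged
#' @export
read_phased_genotypes <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stop("VCF contains no variant records")
  gt_field <- vcf@gt
  if (is.null(gt_field) || ncol(gt_field) < 2L) stop("VCF has no sample genotypes")
  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT) | fix$ALT == ""
  n_multi <- sum(multi)
  fix <- fix[!multi, , drop = FALSE]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  samples <- colnames(gt)
  if (!length(samples)) stop("zero samples with GT in VCF")
  # split GT strings: allele1 sep allele2 (biallelic, single-char alleles)
  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  unphased_het <- sep == "/" & a1 != a2 & a1 != "." & a2 != "."
  unphased_het[is.na(unphased_het)] <- FALSE
  n_unphased <- sum(unphased_het)
  if (strict && n_unphased > 0)
    stop(n_unphased, " unphased heterozygous calls; phase upstream or use strict = FALSE")
  a1[unphased_het] <- "."; a2[unphased_het] <- "."
  to_int <- function(x) {
    v <- suppressWarnings(as.integer(x))
    v[!x %in% c("0", "1")] <- NA_integer_
    v
  }
  m <- nrow(fix); n <- length(samples)
  H <- matrix(NA_integer_, 2L * n, m)
  H[seq(1L, 2L * n, by = 2L), ] <- t(matrix(to_int(a1), m, n))
  H[seq(2L, 2L * n, by = 2L), ] <- t(matrix(to_int(a2), m, n))
  map <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                paste0(fix$CHROM, ":", fix$POS), fix$ID),
                    ref = fix$REF, alt = fix$ALT)
  ord <- order(match(map$chrom, unique(map$chrom)), map$pos)
  g <- phased_genotypes(map[ord, , drop = FALSE], samples, H[, ord, drop = FALSE])
  attr(g, "read_report") <- list(n_multiallelic_skipped = n_multi,
                                 n_unphased_flagged = n_unphased)
  g
}

#' Write phased genotypes as a VCF text file
#'
#' Minimal VCF 4.2 writer for phased panels (GT field only, "|" separators,
#' "." for missing alleles).
#'
#' @param g a `phased_genotypes`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_phased_vcf <- function(g, path) {
  n <- length(g$ids)
  odd <- seq(1L, 2L * n, by = 2L)
  a1 <- g$H[odd, , drop = FALSE]; a2 <- g$H[odd + 1L, , drop = FALSE]
  fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
  gt <- matrix(paste0(fmt(t(a1)), "|", fmt(t(a2))), nrow = nrow(g$map))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$ids), collapse = "\t"))
  body <- paste(g$map$chrom, g$map$pos, g$map$id, g$map$ref, g$map$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Reads a delimited text table and maps its columns to the standard layout
#' (`id`, `sex`, `age`, `birth_date`, trait columns). Rows with missing sex
#' or age are dropped and counted; retained rows must carry at least one
#' trait value.
#'
#' @param path delimited text file with a header
#' @param columns named list mapping standard names to file column names:
#'   `id`, `sex`, `age`, `birth_date` (optional) and `traits` (character
#'   vector)
#' @param sep field separator (default tab)
#' @return data.frame with standard column names and an attribute
#'   `"read_report"` (rows dropped for missing sex/age or all-missing traits)
#' @export
read_phenotypes <- function(path,
                            columns = list(id = "id", sex = "sex", age = "age",
                                           birth_date = "birth_date",
                                           traits = c("CWT", "EMA", "BFT")),
                            sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(columns$id, columns$sex, columns$age, columns$traits)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("phenotype file lacks columns: ", paste(missing_cols, collapse = ", "))
  out <- data.frame(id = as.character(tab[[columns$id]]),
                    sex = as.character(tab[[columns$sex]]),
                    age = as.numeric(tab[[columns$age]]))
  if (!is.null(columns$birth_date) && columns$birth_date %in% names(tab))
    out$birth_date <- as.character(tab[[columns$birth_date]])
  for (tr in columns$traits) out[[tr]] <- as.numeric(tab[[tr]])
  if (anyDuplicated(out$id)) stop("duplicate individual ids in phenotype file")
  has_sex_age <- !is.na(out$sex) & out$sex != "" & !is.na(out$age)
  has_trait <- rowSums(!is.na(out[, columns$traits, drop = FALSE])) > 0L
  keep <- has_sex_age & has_trait
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "read_report") <- list(n_dropped_sex_age = sum(!has_sex_age),
                                   n_dropped_no_trait = sum(has_sex_age & !has_trait))
  res
}

#' Chi-square test of Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit of observed genotype counts against
#' expectations from the sample allele frequency. Monomorphic input returns
#' p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total > 0)
#' @return p-value
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotypes")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

.empty_axis_report <- function() {
  list(duplicate_position = 0L, call_rate = 0L, maf = 0L, hwe = 0L)
}

#' Filter SNPs by duplicate position, call rate, MAF and HWE
#'
#' Applies the SNP-axis filters in the order: duplicated (chromosome,
#' position) records (first kept), genotype call rate, minor allele
#' frequency, Hardy-Weinberg equilibrium. MAF is computed from phased
#' haplotype counts with missing entries excluded from the denominator; call
#' rate counts genotypes with both haplotypes present. Map order is
#' preserved.
#'
#' @param g a `phased_genotypes`
#' @param maf_min minimum minor allele frequency (default 0.01)
#' @param call_rate_min minimum genotype call rate (default 0.95)
#' @param hwe_alpha HWE p-value threshold (default 0.001)
#' @return list with `genotypes` (filtered) and `report` (removal counts per
#'   filter plus input/output dimensions)
#' @export
filter_snps <- function(g, maf_min = 0.01, call_rate_min = 0.95,
                        hwe_alpha = 0.001) {
  stopifnot(maf_min >= 0, maf_min <= 1, call_rate_min >= 0, call_rate_min <= 1)
  m0 <- nrow(g$map)
  rep_ <- .empty_axis_report()
  keep <- rep(TRUE, m0)
  dup <- duplicated(g$map[, c("chrom", "pos")])
  rep_$duplicate_position <- sum(dup)
  keep[dup] <- FALSE
  n <- length(g$ids)
  odd <- seq(1L, 2L * n, by = 2L)
  h1 <- g$H[odd, , drop = FALSE]; h2 <- g$H[odd + 1L, , drop = FALSE]
  called <- !is.na(h1) & !is.na(h2)
  cr <- colMeans(called)
  fail_cr <- keep & cr < call_rate_min
  rep_$call_rate <- sum(fail_cr)
  keep[fail_cr] <- FALSE
  p_alt <- colMeans(g$H, na.rm = TRUE)
  maf <- pmin(p_alt, 1 - p_alt)
  maf[is.nan(maf)] <- 0
  fail_maf <- keep & maf < maf_min
  rep_$maf <- sum(fail_maf)
  keep[fail_maf] <- FALSE
  dos <- h1 + h2
  hwe_p <- vapply(which(keep), function(j) {
    d <- dos[, j]
    hwe_test(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
             sum(d == 2, na.rm = TRUE))
  }, numeric(1))
  fail_hwe <- which(keep)[hwe_p < hwe_alpha]
  rep_$hwe <- length(fail_hwe)
  keep[fail_hwe] <- FALSE
  if (!any(keep)) stop("all SNPs removed by QC")
  out <- subset_genotypes(g, snps = which(keep))
  report <- list(axis = "snp", input = m0, retained = sum(keep),
                 removed = rep_)
  list(genotypes = out, report = report)
}

#' Filter individuals by genotyping call rate
#'
#' Removes individuals whose fraction of SNPs with both haplotypes called
#' falls below the threshold.
#'
#' @param g a `phased_genotypes`
#' @param call_rate_min minimum call rate (default 0.95)
#' @return list with `genotypes` and `report`
#' @export
filter_individuals <- function(g, call_rate_min = 0.95) {
  n <- length(g$ids)
  odd <- seq(1L, 2L * n, by = 2L)
  called <- !is.na(g$H[odd, , drop = FALSE]) & !is.na(g$H[odd + 1L, , drop = FALSE])
  cr <- rowMeans(called)
  keep <- cr >= call_rate_min
  if (!any(keep)) stop("all individuals removed by QC")
  out <- subset_genotypes(g, individuals = which(keep))
  list(genotypes = out,
       report = list(axis = "individual", input = n, retained = sum(keep),
                     removed = list(call_rate = sum(!keep))))
}

#' Two-sided Grubbs test for a single outlier
#'
#' G = max |x_i - mean| / sd; the p-value follows from the t-distribution
#' relation behind the Grubbs critical value. The outlier index (position in
#' the input vector, NA entries retained) is reported only when p < alpha.
#'
#' @param values numeric vector (>= 3 non-missing, nonzero variance)
#' @param alpha significance level (default 0.05)
#' @return list with `statistic`, `p_value`, `outlier_index` (NA when not
#'   significant)
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  idx <- which(!is.na(values))
  x <- values[idx]
  n <- length(x)
  if (n < 3L) stop("need at least 3 non-missing values")
  s <- stats::sd(x)
  if (s == 0) stop("zero variance: Grubbs test undefined")
  dev <- abs(x - mean(x))
  G <- max(dev) / s
  i <- idx[which.max(dev)]
  if (n * G^2 >= (n - 1)^2) {
    p <- 0
  } else {
    t <- sqrt(n * (n - 2) * G^2 / ((n - 1)^2 - n * G^2))
    p <- min(1, 2 * n * stats::pt(t, df = n - 2, lower.tail = FALSE))
  }
  list(statistic = G, p_value = p,
       outlier_index = if (p < alpha) i else NA_integer_)
}

#' Iteratively remove phenotype outliers by the Grubbs test
#'
#' For each trait column and the age covariate, the two-sided Grubbs test is
#' applied and the flagged value removed (set to missing for traits; the row
#' is dropped for age), then re-tested, until no test is significant at
#' `alpha`. Each iteration strictly shortens the tested vector, so the
#' procedure terminates.
#'
#' @param tab phenotype data.frame as from [read_phenotypes()]
#' @param alpha significance level (default 0.05)
#' @param traits trait columns to screen (default: those of CWT/EMA/BFT
#'   present)
#' @return list with `table` (cleaned) and `report` (removals per variable
#'   and the final Grubbs p-value per variable)
#' @export
remove_phenotype_outliers <- function(tab, alpha = 0.05,
                                      traits = intersect(c("CWT", "EMA", "BFT"),
                                                         names(tab))) {
  stopifnot(nrow(tab) > 0)
  removed <- stats::setNames(integer(length(traits) + 1L), c(traits, "age"))
  final_p <- stats::setNames(rep(NA_real_, length(traits) + 1L), c(traits, "age"))
  for (tr in traits) {
    repeat {
      v <- tab[[tr]]
      if (sum(!is.na(v)) < 3L || stats::sd(v, na.rm = TRUE) == 0) break
      res <- grubbs_test(v, alpha)
      final_p[tr] <- res$p_value
      if (is.na(res$outlier_index)) break
      tab[[tr]][res$outlier_index] <- NA
      removed[tr] <- removed[tr] + 1L
    }
  }
  repeat {
    v <- tab$age
    if (sum(!is.na(v)) < 3L || stats::sd(v, na.rm = TRUE) == 0) break
    res <- grubbs_test(v, alpha)
    final_p["age"] <- res$p_value
    if (is.na(res$outlier_index)) break
    tab <- tab[-res$outlier_index, , drop = FALSE]
    removed["age"] <- removed["age"] + 1L
  }
  rownames(tab) <- NULL
  list(table = tab,
       report = list(removed = as.list(removed), final_p = as.list(final_p)))
}

#' Full genotype QC pipeline
#'
#' Applies the filters in a fixed, logged order: duplicate positions and the
#' individual call-rate filter first, then the SNP-axis filters (call rate,
#' MAF, HWE). The order affects the counts and is therefore part of the
#' report.
#'
#' @inheritParams filter_snps
#' @param ind_call_rate_min minimum individual call rate
#' @return list with `genotypes` and `report` (per-step reports, in order)
#' @export
qc_pipeline <- function(g, maf_min = 0.01, call_rate_min = 0.95,
                        ind_call_rate_min = 0.95, hwe_alpha = 0.001) {
  ind <- filter_individuals(g, ind_call_rate_min)
  snp <- filter_snps(ind$genotypes, maf_min, call_rate_min, hwe_alpha)
  list(genotypes = snp$genotypes,
       report = list(order = c("individual_call_rate", "duplicate_position",
                               "snp_call_rate", "maf", "hwe"),
                     individual = ind$report, snp = snp$report))
}
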