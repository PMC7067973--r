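# Small in-code fixtures shared by the suite.

# A hand-sized phased panel: n individuals, given haplotype matrix or random.
tiny_panel <- function(n = 4, m = 6, seed = 1, H = NULL, chrom = NULL, pos = NULL) {
  set.seed(seed)
  if (is.null(H)) H <- matrix(rbinom(2 * n * m, 1, 0.5), 2 * n, m)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- unlist(lapply(split(seq_len(m), chrom)[unique(chrom)],
                                         function(i) seq_along(i) * 100L))
  map <- data.frame(chrom = chrom, pos = pos,
                    id = paste0("s", seq_len(m)), ref = "A", alt = "C")
  phased_genotypes(map, paste0("i", seq_len(n)), H)
}

# Haplotype columns drawn from a small founder pool so that D' structure is
# nontrivial (columns are not independent).
ld_panel <- function(n = 50, m = 12, founders = 4, seed = 1) {
  set.seed(seed)
  pool <- matrix(rbinom(founders * m, 1, runif(m, 0.2, 0.8)), founders, m, byrow = TRUE)
  for (j in seq_len(m)) if (length(unique(pool[, j])) == 1L)
    pool[sample(founders, 1), j] <- 1L - pool[1, j]
  H <- pool[sample(founders, 2 * n, replace = TRUE), , drop = FALSE]
  flips <- matrix(rbinom(2 * n * m, 1, 0.08), 2 * n, m)
  H <- abs(H - flips)
  tiny_panel(n = n, m = m, H = H)
}

# Minimal VCF text for parser tests.
write_test_vcf <- function(path, records, samples = c("A", "B")) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, id, ref, alt, gts) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts), collapse = "\t")
}

# Phenotype table with known structure.
tiny_pheno <- function(n = 20, seed = 1) {
  set.seed(seed)
  data.frame(id = sprintf("i%d", seq_len(n)),
             sex = sample(c("F", "M"), n, replace = TRUE),
             age = runif(n, 24, 36),
             birth_date = as.character(as.Date("2011-01-01") + seq_len(n) * 30),
             CWT = rnorm(n, 10, 1))
}
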