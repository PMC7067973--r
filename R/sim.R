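# Founder-mosaic simulator of phased genotypes with blockwise LD and
# quantitative phenotypes with SNP-additive or haplotype-allelic architecture.
#
# Each chromosome is partitioned into LD segments. Every segment carries a
# small pool of founder haplotype patterns; an individual haplotype picks one
# founder per segment, keeping the previous segment's founder with
# probability 1 - recomb_rate. Within-segment LD is therefore founder-pool
# LD (a pool of K founders gives mean pairwise r2 of roughly 1/(K - 1));
# between-segment LD decays with the switch rate.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is tested under: two
#' 10-Mb chromosomes of 2,500 SNPs each (~4 kb mean spacing), three founder
#' haplotypes per LD segment of ~8 SNPs (mean adjacent r2 around 0.4, and
#' haplotype-allele counts that grow with block size), 1,000 diploid individuals, one carcass-weight-like trait with
#' heritability 0.4, a two-level sex effect and a linear slaughter-age
#' effect, and birth dates spanning 2010-2013 so a 2012-01-01 forward split
#' is meaningful.
#'
#' @param n_individuals diploid sample size
#' @param n_chr number of chromosomes
#' @param n_snps_per_chr SNPs per chromosome
#' @param spacing_bp mean SNP spacing in bp (exponential gaps)
#' @param founders_per_segment founder haplotypes per LD segment (>= 2)
#' @param segment_mean_snps mean LD-segment length in SNPs (>= 3)
#' @param recomb_rate probability a haplotype switches founder between
#'   adjacent segments
#' @param founder_drift strength of birth-cohort drift in founder sampling
#'   weights (0 = none); positive values make allele frequencies drift over
#'   birth dates, for forward-validation experiments
#' @param h2 target narrow-sense heritability of the simulated trait
#' @param architecture `"snp_additive"` or `"haplotype_allelic"` (QTL effects
#'   attached to whole founder haplotype alleles of multi-SNP segments, so no
#'   single SNP tags a QTL)
#' @param n_qtl number of QTL (must be 0 when `h2 = 0`)
#' @param trait name of the simulated trait column
#' @param sex_effect additive effect of male sex on the phenotype
#' @param age_range slaughter-age range in months (uniform)
#' @param age_effect phenotype change per month of age
#' @param birth_range birth-date span (ISO strings)
#' @param seed master seed; identical configs give bit-identical output
#' @return a `sim_config` list
#' @export
sim_config <- function(n_individuals = 1000, n_chr = 2, n_snps_per_chr = 2500,
                       spacing_bp = 4000, founders_per_segment = 3,
                       segment_mean_snps = 8, recomb_rate = 0.5,
                       founder_drift = 0, h2 = 0.4,
                       architecture = c("haplotype_allelic", "snp_additive"),
                       n_qtl = 100, trait = "CWT", sex_effect = 0.5,
                       age_range = c(24, 36), age_effect = 0.05,
                       birth_range = c("2010-01-01", "2013-12-31"), seed = 1) {
  architecture <- match.arg(architecture)
  stopifnot(n_individuals > 0, n_chr > 0, n_snps_per_chr > 0,
            founders_per_segment >= 2, segment_mean_snps >= 3,
            recomb_rate >= 0, recomb_rate <= 1, h2 >= 0, h2 <= 1)
  if (founders_per_segment > 2 * n_individuals)
    stop("more founders per segment than haplotypes in the panel")
  if (h2 == 0 && n_qtl > 0)
    stop("h2 = 0 with n_qtl > 0 is contradictory; set n_qtl = 0")
  if (h2 > 0 && n_qtl == 0)
    stop("h2 > 0 requires at least one QTL")
  structure(list(n_individuals = n_individuals, n_chr = n_chr,
                 n_snps_per_chr = n_snps_per_chr, spacing_bp = spacing_bp,
                 founders_per_segment = founders_per_segment,
                 segment_mean_snps = segment_mean_snps,
                 recomb_rate = recomb_rate, founder_drift = founder_drift,
                 h2 = h2, architecture = architecture, n_qtl = n_qtl,
                 trait = trait, sex_effect = sex_effect,
                 age_range = age_range, age_effect = age_effect,
                 birth_range = birth_range, seed = seed),
            class = "sim_config")
}

# Draw segment lengths (in SNPs) covering n SNPs, geometric with the
# configured mean, minimum 3.
.segment_lengths <- function(n, mean_len) {
  lens <- integer(0)
  left <- n
  while (left > 0) {
    l <- 3L + stats::rgeom(1L, 1 / max(1, mean_len - 3))
    l <- min(l, left)
    lens <- c(lens, l)
    left <- left - l
  }
  # avoid a trailing stub shorter than 3 when possible
  k <- length(lens)
  if (k > 1L && lens[k] < 3L) {
    lens[k - 1L] <- lens[k - 1L] + lens[k]
    lens <- lens[-k]
  }
  lens
}

# Founder pattern matrix (K x len): each SNP column segregates among the
# founders (never monomorphic in the pool).
.founder_patterns <- function(K, len) {
  m <- matrix(0L, K, len)
  for (j in seq_len(len)) {
    repeat {
      q <- stats::runif(1, 0.1, 0.9)
      col <- stats::rbinom(K, 1L, q)
      if (any(col == 1L) && any(col == 0L)) break
    }
    m[, j] <- col
  }
  m
}

#' Simulate phased genotypes by founder mosaics
#'
#' Builds the SNP map, LD-segment structure and founder pools from the
#' configuration, then assembles each of the 2N haplotypes as a mosaic of
#' founders. With `founder_drift > 0`, founder sampling weights shift with
#' each individual's birth-cohort rank, producing allele-frequency drift
#' between older and younger animals.
#'
#' @param cfg a [sim_config()]
#' @return a `sim_panel`: list with `genotypes` (a `phased_genotypes`),
#'   `segments` (per-segment chromosome/first/last SNP indices), `founders`
#'   (list of founder pattern matrices), `founder_of` (2N x n_segments founder
#'   assignment), `cohort` (per-individual birth-cohort fraction in [0, 1])
#'   and `birth_date`
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  nh <- 2L * n
  # map
  maps <- lapply(seq_len(cfg$n_chr), function(ch) {
    gaps <- 1L + round(stats::rexp(cfg$n_snps_per_chr, 1 / cfg$spacing_bp))
    pos <- cumsum(gaps)
    data.frame(chrom = paste0("chr", ch), pos = pos,
               id = sprintf("chr%d_snp%d", ch, seq_along(pos)),
               ref = "A", alt = "C")
  })
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  # segments and founders
  seg_rows <- list(); founders <- list()
  offset <- 0L
  for (ch in seq_len(cfg$n_chr)) {
    lens <- .segment_lengths(cfg$n_snps_per_chr, cfg$segment_mean_snps)
    first <- offset + cumsum(c(1L, lens[-length(lens)]))
    last <- offset + cumsum(lens)
    for (s in seq_along(lens)) {
      seg_rows[[length(seg_rows) + 1L]] <-
        data.frame(chrom = paste0("chr", ch), first = first[s], last = last[s])
      founders[[length(founders) + 1L]] <-
        .founder_patterns(cfg$founders_per_segment, lens[s])
    }
    offset <- offset + cfg$n_snps_per_chr
  }
  segments <- do.call(rbind, seg_rows)
  segments$segment_id <- seq_len(nrow(segments))
  n_seg <- nrow(segments)
  K <- cfg$founders_per_segment
  # birth dates / cohort fraction (drives drift and the forward split)
  bd0 <- as.Date(cfg$birth_range[1]); bd1 <- as.Date(cfg$birth_range[2])
  birth <- bd0 + sort(sample.int(as.integer(bd1 - bd0) + 1L, n, replace = TRUE)) - 1L
  cohort <- (rank(birth, ties.method = "first") - 1) / max(1, n - 1)
  cohort_h <- rep(cohort, each = 2L) # per-haplotype
  # founder drift direction per (segment, founder)
  zdrift <- if (cfg$founder_drift > 0)
    matrix(stats::rnorm(n_seg * K), n_seg, K) else NULL
  # founder assignment per haplotype per segment
  founder_of <- matrix(0L, nh, n_seg)
  new_chr <- c(TRUE, segments$chrom[-1] != segments$chrom[-n_seg])
  for (s in seq_len(n_seg)) {
    if (is.null(zdrift)) {
      draw <- sample.int(K, nh, replace = TRUE)
    } else {
      w <- exp(cfg$founder_drift * outer(cohort_h, zdrift[s, ]))
      cw <- w / rowSums(w)
      u <- stats::runif(nh)
      draw <- max.col(t(apply(cw, 1L, cumsum)) >= u, ties.method = "first")
    }
    if (new_chr[s]) {
      founder_of[, s] <- draw
    } else {
      keep <- stats::runif(nh) >= cfg$recomb_rate
      founder_of[, s] <- ifelse(keep, founder_of[, s - 1L], draw)
    }
  }
  # assemble haplotypes
  H <- matrix(0L, nh, nrow(map))
  for (s in seq_len(n_seg)) {
    cols <- segments$first[s]:segments$last[s]
    H[, cols] <- founders[[s]][founder_of[, s], , drop = FALSE]
  }
  ids <- sprintf("ind%04d", seq_len(n))
  g <- phased_genotypes(map, ids, H)
  structure(list(genotypes = g, segments = segments, founders = founders,
                 founder_of = founder_of, cohort = cohort,
                 birth_date = birth, config = cfg),
            class = "sim_panel")
}

# A causal haplotype allele is the string of founder f over a short window
# of a segment. It is eligible when no single window SNP identifies the
# carrier founders exactly: for every column, some non-carrier founder shares
# the causal allele's value there (so no single SNP is a perfect tag).
.eligible_window_founders <- function(pat) {
  K <- nrow(pat)
  strs <- do.call(paste0, as.data.frame(pat))
  ok <- logical(K)
  for (f in seq_len(K)) {
    carriers <- strs == strs[f]
    ok[f] <- all(vapply(seq_len(ncol(pat)), function(j) {
      any(!carriers & pat[, j] == pat[f, j])
    }, logical(1)))
  }
  which(ok)
}

#' Simulate phenotypes on a simulated panel
#'
#' Adds a quantitative trait to a [simulate_genotypes()] panel. Under
#' `"snp_additive"` architecture, additive effects are drawn for randomly
#' chosen SNPs; under `"haplotype_allelic"`, effects attach to whole founder
#' haplotype alleles of multi-SNP segments chosen so that no single SNP is a
#' perfect tag. True breeding values are rescaled to variance `h2` and
#' residuals drawn with variance `1 - h2`, so the genetic-plus-residual
#' phenotype has unit variance; sex and age fixed effects are added on top.
#'
#' @param panel a `sim_panel` from [simulate_genotypes()]
#' @return list with `pheno` (data.frame: `id`, `sex`, `age`, `birth_date`,
#'   trait column) and `truth` (list: `tbv`, `qtl`, `h2_target`,
#'   `realized_h2`, `segments`)
#' @export
simulate_phenotypes <- function(panel) {
  stopifnot(inherits(panel, "sim_panel"))
  cfg <- panel$config
  set.seed(cfg$seed + 1L)
  g <- panel$genotypes
  n <- length(g$ids)
  tbv <- rep(0, n)
  qtl <- NULL
  if (cfg$h2 > 0) {
    if (cfg$architecture == "snp_additive") {
      snps <- sort(sample.int(nrow(g$map), cfg$n_qtl))
      beta <- stats::rnorm(cfg$n_qtl)
      D <- geno_dosage(g)[, snps, drop = FALSE]
      tbv <- drop(D %*% beta)
      qtl <- data.frame(segment = NA_integer_, snp = snps, founder = NA_integer_,
                        effect = beta)
    } else {
      seg_len <- panel$segments$last - panel$segments$first + 1L
      cand <- sample(which(seg_len >= 3L)) # random order, no replacement
      odd <- seq(1L, 2L * n, by = 2L)
      rows <- list()
      beta <- stats::rnorm(cfg$n_qtl)
      q <- 0L
      for (s in cand) {
        if (q >= cfg$n_qtl) break
        w <- min(seg_len[s], 5L)
        # try a handful of window placements before giving up on the segment
        elig <- integer(0)
        for (try in 1:5) {
          start <- panel$segments$first[s] +
            sample.int(seg_len[s] - w + 1L, 1L) - 1L
          cols <- start:(start + w - 1L)
          rel <- cols - panel$segments$first[s] + 1L
          pat <- panel$founders[[s]][, rel, drop = FALSE]
          elig <- .eligible_window_founders(pat)
          if (length(elig)) break
        }
        if (!length(elig)) next
        f <- if (length(elig) == 1L) elig else sample(elig, 1L)
        target <- paste0(pat[f, ], collapse = "")
        hap_str <- do.call(paste0, as.data.frame(g$H[, cols, drop = FALSE]))
        carrier <- hap_str == target
        dose <- as.integer(carrier[odd]) + as.integer(carrier[odd + 1L])
        if (stats::var(dose) == 0) next
        q <- q + 1L
        tbv <- tbv + beta[q] * dose
        rows[[q]] <- data.frame(segment = s, snp = start, founder = f,
                                window = w, effect = beta[q])
      }
      if (q < cfg$n_qtl)
        stop("not enough eligible segments for ", cfg$n_qtl, " haplotype QTL")
      qtl <- do.call(rbind, rows)
    }
    v <- stats::var(tbv)
    if (v <= 0) stop("simulated genetic variance is zero; increase n_qtl")
    tbv <- (tbv - mean(tbv)) * sqrt(cfg$h2 / v)
  }
  se2 <- 1 - cfg$h2
  e <- stats::rnorm(n, 0, sqrt(se2))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  y <- 10 + cfg$sex_effect * (sex == "M") + cfg$age_effect * age + tbv + e
  pheno <- data.frame(id = g$ids, sex = sex, age = age,
                      birth_date = as.character(panel$birth_date))
  pheno[[cfg$trait]] <- y
  truth <- list(tbv = tbv, qtl = qtl, h2_target = cfg$h2,
                realized_h2 = stats::var(tbv) / (stats::var(tbv) + se2),
                segments = panel$segments)
  list(pheno = pheno, truth = truth)
}

#' Simulate a complete dataset (genotypes, phenotypes, truth)
#'
#' Convenience wrapper over [simulate_genotypes()] and
#' [simulate_phenotypes()].
#'
#' @param cfg a [sim_config()]
#' @return list with `genotypes`, `pheno`, `truth`, `panel`
#' @export
simulate_dataset <- function(cfg) {
  panel <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(panel)
  list(genotypes = panel$genotypes, pheno = ph$pheno, truth = ph$truth,
       panel = panel)
}
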