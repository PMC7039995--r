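# Per-locus diversity metrics: allele frequencies by gene counting,
# observed/expected heterozygosity, a Monte-Carlo exact Hardy-Weinberg
# test, polymorphism information content (PIC) and power of discrimination
# (PD) -- the forensic parameters population HLA tables report.

#' Allele frequencies at one locus by gene counting
#'
#' Counts over the 2N typed chromosomes after truncating allele names to
#' the requested resolution (sub-alleles aggregate onto their lower-
#' resolution parent, as bolded rows in published tables do). Subjects
#' missing a call at the locus are skipped (they still contribute at other
#' loci).
#'
#' @param cohort An `hla_cohort`.
#' @param locus Locus name.
#' @param resolution Fields to keep (default 2); `NULL` for as-typed.
#' @return Named numeric vector of frequencies, descending, summing to 1.
#' @export
allele_freqs <- function(cohort, locus, resolution = 2L) {
  cols <- locus_cols(locus)
  if (!all(cols %in% names(cohort))) {
    stop("locus ", locus, " not present in cohort", call. = FALSE)
  }
  alleles <- c(cohort[[cols[1L]]], cohort[[cols[2L]]])
  alleles <- alleles[!is.na(alleles) & alleles != ""]
  if (!length(alleles)) {
    stop("no subject typed at locus ", locus, call. = FALSE)
  }
  if (!is.null(resolution)) {
    alleles <- truncate_name(alleles, resolution)
  }
  tab <- table(alleles)
  f <- as.numeric(tab) / sum(tab)
  names(f) <- names(tab)
  sort(f, decreasing = TRUE)
}

#' Polymorphism information content
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`, evaluated through the
#' identity `sum_{i<j} 2 p_i^2 p_j^2 = (sum p_i^2)^2 - sum p_i^4`. Values
#' above 0.5 conventionally indicate a highly informative marker.
#'
#' @param freqs Allele frequency vector summing to 1 within `1e-6`.
#' @return PIC in `[0, 1)`.
#' @examples
#' pic(c(0.5, 0.5))        # 0.375
#' pic(rep(0.25, 4))       # 0.703125
#' @export
pic <- function(freqs) {
  if (any(freqs < 0)) stop("negative allele frequency", call. = FALSE)
  if (abs(sum(freqs) - 1) > 1e-6) {
    stop("allele frequencies must sum to 1", call. = FALSE)
  }
  s2 <- sum(freqs^2)
  s4 <- sum(freqs^4)
  1 - s2 - (s2^2 - s4)
}

#' Observed and expected heterozygosity at one locus
#'
#' `OH` is the fraction of heterozygous subjects; `EH = 1 - sum(p_i^2)`
#' from the gene-counting frequencies (plain estimator by default; set
#' `unbiased = TRUE` for the `2N/(2N-1)` small-sample factor).
#'
#' @inheritParams allele_freqs
#' @param unbiased Apply the `2N/(2N-1)` correction to EH.
#' @return Named numeric vector `c(OH = ..., EH = ...)`.
#' @export
heterozygosity <- function(cohort, locus, resolution = 2L,
                           unbiased = FALSE) {
  cols <- locus_cols(locus)
  a <- cohort[[cols[1L]]]
  b <- cohort[[cols[2L]]]
  ok <- !is.na(a) & !is.na(b) & a != "" & b != ""
  if (!any(ok)) stop("no subject typed at locus ", locus, call. = FALSE)
  a <- a[ok]; b <- b[ok]
  if (!is.null(resolution)) {
    a <- truncate_name(a, resolution)
    b <- truncate_name(b, resolution)
  }
  oh <- mean(a != b)
  p <- allele_freqs(cohort, locus, resolution)
  eh <- 1 - sum(p^2)
  if (unbiased) {
    two_n <- 2L * length(a)
    eh <- eh * two_n / (two_n - 1L)
  }
  c(OH = oh, EH = eh)
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Repeatedly shuffles the 2N observed allele copies into N random
#' genotype pairs and compares a statistic against its observed value;
#' the p-value is the proportion of shuffles at least as extreme
#' (including the observed arrangement itself, the standard Monte-Carlo
#' exact convention). The default statistic is the heterozygote count,
#' two-sided; `statistic = "prob"` uses the log conditional probability of
#' the genotype configuration given allele counts, mirroring the
#' Guo-Thompson style chains used by standard population-genetics tools.
#'
#' @inheritParams allele_freqs
#' @param n_steps Monte-Carlo shuffles (published analyses in this field
#'   use 1e6; smaller values are adequate for calibration studies).
#' @param seed Integer seed; fixed seed implies a reproducible p-value.
#' @param statistic `"het"` (default) or `"prob"`.
#' @return p-value in (0, 1]; a monomorphic locus returns 1 with a warning.
#' @export
hwe_test <- function(cohort, locus, n_steps = 1e6, seed = 1L,
                     resolution = 2L, statistic = c("het", "prob")) {
  statistic <- match.arg(statistic)
  cols <- locus_cols(locus)
  a <- cohort[[cols[1L]]]
  b <- cohort[[cols[2L]]]
  ok <- !is.na(a) & !is.na(b) & a != "" & b != ""
  a <- a[ok]; b <- b[ok]
  if (!is.null(resolution)) {
    a <- truncate_name(a, resolution)
    b <- truncate_name(b, resolution)
  }
  alleles <- factor(c(a, b))
  if (nlevels(alleles) < 2L) {
    warning("monomorphic locus: HWE p-value set to 1 by convention")
    return(1)
  }
  n <- length(a)
  codes <- as.integer(alleles)
  obs_stat <- hwe_statistic(codes[seq_len(n)], codes[n + seq_len(n)],
                            statistic)
  # exact expected heterozygote count under random pairing of the 2N
  # copies (drawing two copies without replacement), for the two-sided rule
  cnt_k <- tabulate(codes)
  p_same <- sum(cnt_k * (cnt_k - 1)) / (2 * n * (2 * n - 1))
  e_het <- n * (1 - p_same)
  as_extreme <- function(stat) {
    if (statistic == "het") {
      abs(stat - e_het) >= abs(obs_stat - e_het) - 1e-12
    } else {
      stat <= obs_stat + 1e-12  # low conditional probability = extreme
    }
  }
  with_seed(seed, {
    extreme <- 0L
    for (s in seq_len(n_steps)) {
      perm <- sample.int(2L * n)
      x <- codes[perm[seq_len(n)]]
      y <- codes[perm[n + seq_len(n)]]
      if (as_extreme(hwe_statistic(x, y, statistic))) {
        extreme <- extreme + 1L
      }
    }
    (extreme + 1L) / (n_steps + 1L)
  })
}

hwe_statistic <- function(x, y, statistic) {
  if (statistic == "het") {
    sum(x != y)
  } else {
    # log conditional probability of the genotype configuration given
    # allele counts (up to a configuration-independent constant):
    # log P = n_het * log(2) - sum over genotype classes log(count!)
    g <- paste(pmin(x, y), pmax(x, y))
    cnt <- table(g)
    sum(x != y) * log(2) - sum(lgamma(as.numeric(cnt) + 1))
  }
}

#' Genotype frequencies at one locus
#'
#' Unordered genotype (allele pair) frequencies among typed subjects,
#' after resolution truncation.
#'
#' @inheritParams allele_freqs
#' @return Named numeric vector (names `"a/b"` with a <= b) summing to 1.
#' @export
genotype_freqs <- function(cohort, locus, resolution = 2L) {
  cols <- locus_cols(locus)
  a <- cohort[[cols[1L]]]
  b <- cohort[[cols[2L]]]
  ok <- !is.na(a) & !is.na(b) & a != "" & b != ""
  if (!any(ok)) stop("no subject typed at locus ", locus, call. = FALSE)
  a <- a[ok]; b <- b[ok]
  if (!is.null(resolution)) {
    a <- truncate_name(a, resolution)
    b <- truncate_name(b, resolution)
  }
  g <- paste(pmin(a, b), pmax(a, b), sep = "/")
  tab <- table(g)
  f <- as.numeric(tab) / sum(tab)
  names(f) <- names(tab)
  sort(f, decreasing = TRUE)
}

#' Power of discrimination
#'
#' `PD = 1 - sum(G_i^2)` over genotype frequencies: the probability that
#' two random individuals carry different genotypes at the locus. Computed
#' from observed genotype frequencies by convention; pass HWE-expected
#' genotype frequencies for the model-based variant.
#'
#' @param genotype_freqs Genotype frequency vector summing to 1 within
#'   `1e-6`.
#' @return PD in `[0, 1)`.
#' @examples
#' pd(rep(0.25, 4))  # 0.75
#' @export
pd <- function(genotype_freqs) {
  if (any(genotype_freqs < 0)) {
    stop("negative genotype frequency", call. = FALSE)
  }
  if (abs(sum(genotype_freqs) - 1) > 1e-6) {
    stop("genotype frequencies must sum to 1", call. = FALSE)
  }
  1 - sum(genotype_freqs^2)
}

#' Per-locus diversity summary table
#'
#' One row per locus with observed heterozygosity, expected
#' heterozygosity, the Monte-Carlo HWE p-value, PIC and PD -- the layout
#' of published forensic-parameter tables.
#'
#' @param cohort An `hla_cohort`.
#' @param loci Loci to summarize (default: all cohort loci).
#' @param n_steps,seed Passed to [hwe_test()].
#' @param resolution Allele resolution (fields) for all metrics.
#' @return `data.frame` with columns `locus`, `OH`, `EH`, `p_value`,
#'   `PIC`, `PD`.
#' @export
diversity_summary <- function(cohort, loci = hla_loci(cohort),
                              n_steps = 1e4, seed = 1L, resolution = 2L) {
  rows <- lapply(seq_along(loci), function(k) {
    loc <- loci[k]
    het <- heterozygosity(cohort, loc, resolution)
    data.frame(locus = loc, OH = het[["OH"]], EH = het[["EH"]],
               p_value = hwe_test(cohort, loc, n_steps = n_steps,
                                  seed = child_seed(seed, k),
                                  resolution = resolution),
               PIC = pic(allele_freqs(cohort, loc, resolution)),
               PD = pd(genotype_freqs(cohort, loc, resolution)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
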