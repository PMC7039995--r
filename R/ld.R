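# Two-locus and block-level linkage disequilibrium: delta, Lewontin's
# standardized delta-prime, a Fisher-exact p-value on the 2x2 chromosome
# table, and a sample-size adjusted t statistic. Blocks (e.g. B~C) are
# treated as composite alleles when extending to conserved extended
# haplotypes and their HLA-A extension.

#' Two-locus linkage disequilibrium for one haplotype
#'
#' Given the haplotype frequency `h` of an allele pair and the marginal
#' allele frequencies `pA`, `pB` over `two_n` chromosomes:
#' `delta = h - pA*pB`; `delta_prime = delta / delta_max` with the Lewontin
#' normalization `delta_max = min(pA*(1-pB), pB*(1-pA))` for positive
#' `delta` and `min(pA*pB, (1-pA)*(1-pB))` for negative `delta`
#' (`delta = 0` gives `delta_prime = 0`), clamped to `[-1, 1]` against
#' rounding. The p-value is a two-sided Fisher exact test on the 2x2
#' chromosome table (carrier vs non-carrier of each allele; a chi-square
#' option is provided for comparison). The t statistic is
#' `delta / sqrt(var(delta))` with the binomial-sampling variance
#' `[pA(1-pA) pB(1-pB) + delta(1-2pA)(1-2pB) - delta^2] / two_n` -- a
#' documented variant: published tables in this field cite but do not print
#' their t formula, so only qualitative behaviour (monotone in |delta| and
#' sample size) should be relied on.
#'
#' @param h Haplotype frequency (from unrounded counts, never from printed
#'   4-decimal values).
#' @param pA,pB Marginal allele frequencies (> 0).
#' @param two_n Number of chromosomes (2N >= 1).
#' @param p_method `"fisher"` (default) or `"chisq"`.
#' @return One-row `data.frame`: `h`, `n`, `pA`, `pB`, `delta`,
#'   `delta_prime`, `p_value`, `t`.
#' @examples
#' ld_pair(29/436, 29/436, 122/436, 436)  # complete association: D' = 1
#' @export
ld_pair <- function(h, pA, pB, two_n, p_method = c("fisher", "chisq")) {
  p_method <- match.arg(p_method)
  if (pA <= 0 || pB <= 0 || pA >= 1 + 1e-12 || pB >= 1 + 1e-12) {
    stop("undefined LD: marginal frequencies must lie in (0, 1]",
         call. = FALSE)
  }
  if (pA >= 1 - 1e-12 || pB >= 1 - 1e-12) {
    stop("undefined LD: a monomorphic locus has no disequilibrium",
         call. = FALSE)
  }
  slack <- 0.5 / two_n + 1e-9
  if (h > min(pA, pB) + slack || h < 0) {
    stop("inconsistent input: h must lie in [0, min(pA, pB)]",
         call. = FALSE)
  }
  h <- min(h, min(pA, pB))
  delta <- h - pA * pB
  dmax <- if (delta > 0) {
    min(pA * (1 - pB), pB * (1 - pA))
  } else {
    min(pA * pB, (1 - pA) * (1 - pB))
  }
  dprime <- if (delta == 0 || dmax == 0) 0 else delta / dmax
  dprime <- max(-1, min(1, dprime))
  # 2x2 chromosome table: carrier of A x carrier of B
  nAB <- round(h * two_n)
  nA <- round(pA * two_n)
  nB <- round(pB * two_n)
  tab <- matrix(c(nAB, nA - nAB, nB - nAB, two_n - nA - nB + nAB), 2L, 2L)
  tab[tab < 0] <- 0
  p_value <- if (p_method == "fisher") {
    stats::fisher.test(tab)$p.value
  } else {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  v <- (pA * (1 - pA) * pB * (1 - pB) +
          delta * (1 - 2 * pA) * (1 - 2 * pB) - delta^2) / two_n
  t_stat <- if (v > 0) delta / sqrt(v) else sign(delta) * Inf
  data.frame(h = h, n = nAB, pA = pA, pB = pB, delta = delta,
             delta_prime = dprime, p_value = p_value, t = t_stat)
}

# marginalize a joint haplotype table onto a subset of its loci
marginalize <- function(table, loci) {
  all_loci <- hla_loci(table)
  idx <- match(loci, all_loci)
  if (anyNA(idx)) {
    stop("locus/loci not in table: ",
         paste(loci[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  parts <- strsplit(table$haplotype, "~", fixed = TRUE)
  sub <- vapply(parts, function(p) paste(p[idx], collapse = "~"),
                character(1L))
  freq <- tapply(table$frequency, sub, sum)
  cnt <- if (all(!is.na(table$count))) {
    as.integer(tapply(table$count, sub, sum))
  } else NULL
  hla_haplotable(names(freq), as.numeric(freq), loci = loci, count = cnt,
                 total_chromosomes = attr(table, "total_chromosomes"),
                 complete = abs(sum(table$frequency) - 1) < 1e-6)
}

# LD rows for a joint table split into a left and right composite unit
ld_rows <- function(joint, left_loci, right_loci, min_count = 2L,
                    p_method = "fisher") {
  two_n <- attr(joint, "total_chromosomes")
  if (is.na(two_n)) {
    stop("table needs total_chromosomes to compute LD", call. = FALSE)
  }
  sub <- marginalize(joint, c(left_loci, right_loci))
  left <- marginalize(sub, left_loci)
  right <- marginalize(sub, right_loci)
  parts <- strsplit(sub$haplotype, "~", fixed = TRUE)
  nl <- length(left_loci)
  lkey <- vapply(parts, function(p) paste(p[seq_len(nl)], collapse = "~"),
                 character(1L))
  rkey <- vapply(parts, function(p) paste(p[-seq_len(nl)], collapse = "~"),
                 character(1L))
  cnt <- sub$count
  if (all(is.na(cnt))) cnt <- round(sub$frequency * two_n)
  keep <- cnt >= min_count
  rows <- lapply(which(keep), function(k) {
    pA <- left$frequency[match(lkey[k], left$haplotype)]
    pB <- right$frequency[match(rkey[k], right$haplotype)]
    res <- tryCatch(
      ld_pair(sub$frequency[k], pA, pB, two_n, p_method = p_method),
      error = function(e) {
        data.frame(h = sub$frequency[k], n = cnt[k], pA = pA, pB = pB,
                   delta = NA_real_, delta_prime = NA_real_,
                   p_value = NA_real_, t = NA_real_)
      })
    res$n <- cnt[k]
    cbind(data.frame(haplotype = sub$haplotype[k],
                     stringsAsFactors = FALSE), res)
  })
  if (!length(rows)) {
    out <- data.frame(haplotype = character(), h = numeric(), n = integer(),
                      pA = numeric(), pB = numeric(), delta = numeric(),
                      delta_prime = numeric(), p_value = numeric(),
                      t = numeric())
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(-out$h, out$haplotype), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "left_loci") <- left_loci
  attr(out, "right_loci") <- right_loci
  class(out) <- c("hla_ld", "data.frame")
  out
}

#' Scan a haplotype table for LD blocks
#'
#' Marginalizes a joint haplotype table onto the block loci and emits one
#' LD row per surviving block haplotype (published block tables include
#' only haplotypes seen more than once, i.e. `min_count = 2`), sorted by
#' descending frequency then haplotype string. The two-locus statistics
#' treat the first `split` block loci as the left unit and the rest as the
#' right unit (for a two-locus block this is simply allele vs allele).
#'
#' @param table Joint `hla_haplotable` whose loci contain the block's.
#' @param block Ordered character vector of >= 2 distinct block loci.
#' @param min_count Minimum chromosome count to include (default 2).
#' @param split Number of leading block loci forming the left unit.
#' @param p_method Passed to [ld_pair()].
#' @return `data.frame` of class `hla_ld` with columns `haplotype`, `h`,
#'   `n`, `pA`, `pB`, `delta`, `delta_prime`, `p_value`, `t`. Rows where
#'   LD is undefined (monomorphic unit) carry `NA` statistics.
#' @export
block_scan <- function(table, block, min_count = 2L, split = 1L,
                       p_method = "fisher") {
  if (length(block) < 2L || anyDuplicated(block)) {
    stop("a block needs >= 2 distinct loci", call. = FALSE)
  }
  if (split < 1L || split >= length(block)) {
    stop("split must leave both units non-empty", call. = FALSE)
  }
  ld_rows(table, block[seq_len(split)], block[-seq_len(split)],
          min_count = min_count, p_method = p_method)
}

#' LD between two blocks treated as composite alleles
#'
#' Applies [ld_pair()] to every co-occurring pair of block haplotypes in a
#' joint table: the machinery behind conserved extended haplotypes
#' (`B~C x DRB1~DQB1`) and their HLA-A extension (`A x CEH`).
#'
#' @param joint Joint `hla_haplotable` covering both blocks.
#' @param left_loci,right_loci Disjoint locus vectors of the two blocks.
#' @inheritParams block_scan
#' @return An `hla_ld` data frame as in [block_scan()].
#' @export
extend_block <- function(joint, left_loci, right_loci, min_count = 2L,
                         p_method = "fisher") {
  if (length(intersect(left_loci, right_loci))) {
    stop("the two blocks must be disjoint", call. = FALSE)
  }
  ld_rows(joint, left_loci, right_loci, min_count = min_count,
          p_method = p_method)
}
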