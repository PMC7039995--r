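# Non-overlapping allele associations between locus pairs. The f* score
# measures how strongly alleles at two loci pair off into near-exclusive
# partnerships; the permutation z-score (observed minus permutation mean,
# over permutation SD) is the reported, calibration-free quantity used to
# rank locus pairs. The f*adj operationalization here is a documented
# stand-in (mutual-best association, chance-corrected): the original
# metric's formula is not printed in the population reports that use it,
# and the permutation z does not depend on the score's absolute
# calibration.

#' Non-overlap score for paired alleles at two loci
#'
#' `f*` is the fraction of haplotypes `(i, j)` such that `j` is the modal
#' partner of allele `i` AND `i` is the modal partner of allele `j`
#' (mutual-best association; ties count as modal). The chance-corrected
#' `f*adj = (f* - e) / (1 - e)` subtracts the mutual-best fraction `e`
#' expected under independence, computed exactly from the marginal
#' frequencies (under an independent joint the modal partner of every
#' allele is the globally most frequent partner allele, so
#' `e = max(p) * max(q)`), and is clamped to `[-1, 1]`. When `e = 1`
#' (both loci monomorphic) `f*adj` is 0 by convention.
#'
#' @param x,y Character vectors: the allele carried at locus X and at
#'   locus Y on each chromosome (equal length >= 2).
#' @return Named numeric vector `c(f_star = ..., f_star_adj = ...)`.
#' @export
fstar <- function(x, y) {
  if (!length(x) || length(x) != length(y)) {
    stop("x and y must be non-empty and of equal length", call. = FALSE)
  }
  if (length(x) < 2L) stop("need >= 2 haplotype pairs", call. = FALSE)
  tab <- table(x, y)
  # modal partner(s) of each x allele (row maxima) and y allele (col maxima)
  row_max <- apply(tab, 1L, max)
  col_max <- apply(tab, 2L, max)
  mutual <- (tab == row_max[rep(seq_len(nrow(tab)), ncol(tab))]) &
    (tab == matrix(col_max, nrow(tab), ncol(tab), byrow = TRUE)) &
    tab > 0
  f_star <- sum(tab[mutual]) / sum(tab)
  p <- rowSums(tab) / sum(tab)
  q <- colSums(tab) / sum(tab)
  e <- max(p) * max(q)
  f_star_adj <- if (abs(1 - e) < 1e-12) 0 else (f_star - e) / (1 - e)
  c(f_star = f_star, f_star_adj = max(-1, min(1, f_star_adj)))
}

#' Permutation null for the non-overlap score of a locus pair
#'
#' Shuffles the order of the Y-column alleles `n_perm` times (which locus
#' is shuffled is irrelevant by symmetry; both marginal allele-frequency
#' vectors are preserved exactly), recomputes `f*adj` for each shuffle,
#' and reports the observed score, the permutation mean and SD, and
#' `z = (observed - mean) / sd`.
#'
#' @inheritParams fstar
#' @param n_perm Number of permutations (default 5000, the convention of
#'   published non-overlap analyses).
#' @param seed Integer seed; fixed seed implies identical output.
#' @return One-row `data.frame`: `f_star`, `f_star_adj`, `perm_mean`,
#'   `perm_sd`, `z`, `n_perm`. A degenerate null (`sd = 0`) reports
#'   `z = Inf` (or 0 when the observed equals the null) with a warning;
#'   `n_perm < 2` leaves `sd` and `z` as `NA` with a warning.
#' @export
permutation_null <- function(x, y, n_perm = 5000L, seed = 1L) {
  obs <- fstar(x, y)
  null_scores <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      fstar(x, y[sample.int(length(y))])[["f_star_adj"]]
    }, numeric(1L))
  })
  if (n_perm < 2L) {
    warning("fewer than 2 permutations: null SD undefined")
    m <- if (n_perm) mean(null_scores) else NA_real_
    return(data.frame(f_star = obs[["f_star"]],
                      f_star_adj = obs[["f_star_adj"]],
                      perm_mean = m, perm_sd = NA_real_, z = NA_real_,
                      n_perm = n_perm))
  }
  m <- mean(null_scores)
  s <- stats::sd(null_scores)
  z <- if (s > 0) {
    (obs[["f_star_adj"]] - m) / s
  } else {
    warning("degenerate permutation null (sd = 0)")
    if (abs(obs[["f_star_adj"]] - m) < 1e-12) 0 else
      sign(obs[["f_star_adj"]] - m) * Inf
  }
  data.frame(f_star = obs[["f_star"]], f_star_adj = obs[["f_star_adj"]],
             perm_mean = m, perm_sd = s, z = z, n_perm = n_perm)
}

#' Non-overlap permutation scan over all locus pairs
#'
#' Runs [permutation_null()] for every pair of the requested loci on a
#' phased chromosome-by-locus allele matrix (e.g. built from a haplotype
#' table via [haplotype_matrix()]). One master seed spawns a deterministic
#' child seed per pair, so adding a pair does not perturb the others'
#' nulls.
#'
#' @param alleles Character matrix: chromosomes x loci, column names =
#'   locus names.
#' @param loci Loci to scan (default: all columns).
#' @param n_perm Permutations per pair.
#' @param seed Master integer seed.
#' @return `data.frame` with `locus_x`, `locus_y` and the
#'   [permutation_null()] columns, ranked by descending `z` (ties by pair
#'   name).
#' @export
nonoverlap_scan <- function(alleles, loci = colnames(alleles),
                            n_perm = 5000L, seed = 1L) {
  stopifnot(is.matrix(alleles), !is.null(colnames(alleles)))
  pairs <- utils::combn(loci, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    lx <- pairs[1L, k]; ly <- pairs[2L, k]
    # child seed keyed to the pair name, not the scan order
    ck <- sum(utf8ToInt(paste(lx, ly, sep = "~")))
    res <- permutation_null(alleles[, lx], alleles[, ly],
                            n_perm = n_perm,
                            seed = child_seed(seed, ck))
    cbind(data.frame(locus_x = lx, locus_y = ly,
                     stringsAsFactors = FALSE), res)
  })
  rank_pairs(do.call(rbind, rows))
}

#' Rank non-overlap results by permutation z-score
#'
#' @param results `data.frame` with at least `z` and the pair-identifying
#'   columns `locus_x`, `locus_y`.
#' @return The same rows sorted by descending `z`, ties by pair name.
#' @export
rank_pairs <- function(results) {
  if (!nrow(results)) stop("no results to rank", call. = FALSE)
  key <- paste(results$locus_x, results$locus_y, sep = "~")
  out <- results[order(-results$z, key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand a haplotype table into a chromosome-by-locus allele matrix
#'
#' Each haplotype contributes `count` rows (or `round(frequency * 2N)`
#' when counts are absent): the phased input the non-overlap scan
#' consumes.
#'
#' @param table An `hla_haplotable` with `total_chromosomes`.
#' @return Character matrix with one row per chromosome, columns named by
#'   the table's loci.
#' @export
haplotype_matrix <- function(table) {
  two_n <- attr(table, "total_chromosomes")
  cnt <- table$count
  if (all(is.na(cnt))) {
    if (is.na(two_n)) {
      stop("table needs counts or total_chromosomes", call. = FALSE)
    }
    cnt <- round(table$frequency * two_n)
  }
  rows <- rep(seq_len(nrow(table)), cnt)
  mat <- do.call(rbind,
                 strsplit(table$haplotype[rows], "~", fixed = TRUE))
  colnames(mat) <- hla_loci(table)
  mat
}
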