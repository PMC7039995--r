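# Cross-population analyses: Nei's DA allele-sharing distance,
# neighbor-joining population trees (via ape) with bootstrap support from
# resampling alleles within loci, and PCA on concatenated allele-frequency
# vectors.

#' Construct a population frequency set
#'
#' Per-locus allele-frequency vectors for one population, plus optional
#' geography/richness metadata. Vectors are aligned across populations
#' lazily: an allele absent from a population has frequency 0.
#'
#' @param population Population id.
#' @param freqs Named list: one named numeric vector per locus, each
#'   summing to 1 within `1e-6` (vectors summing to less than 0.995 are
#'   renormalized with a warning, the usual fix for truncated published
#'   tables).
#' @param metadata Optional named list (latitude, longitude, richness,
#'   sample size, ...).
#' @return A list of class `pop_freq_set`.
#' @export
pop_freq_set <- function(population, freqs, metadata = list()) {
  stopifnot(is.list(freqs), length(freqs) >= 1L,
            !is.null(names(freqs)))
  loci <- names(freqs)
  freqs <- lapply(seq_along(freqs), function(i) {
    v <- freqs[[i]]
    if (is.null(names(v)) || any(v < 0)) {
      stop("locus ", loci[i],
           ": frequencies must be named and nonnegative", call. = FALSE)
    }
    s <- sum(v)
    if (s < 0.995) {
      warning("population ", population, ", locus ", loci[i],
              ": frequencies sum to ", format(s), "; renormalizing")
    }
    if (abs(s - 1) > 1e-6) v <- v / s
    v
  })
  names(freqs) <- loci
  structure(list(population = population, freqs = freqs,
                 metadata = metadata),
            class = "pop_freq_set")
}

#' Nei's DA genetic distance between two populations
#'
#' `DA = 1 - (1/L) * sum over loci of sum over alleles of sqrt(x_i y_i)`,
#' over the outer-joined allele universe (absent allele = frequency 0).
#' A value in `[0, 1]`, symmetric, 0 for identical frequency sets.
#'
#' @param x,y `pop_freq_set` objects.
#' @param loci Loci to use (default: those of `x`).
#' @return DA distance.
#' @examples
#' a <- pop_freq_set("a", list(L = c(u = 0.5, v = 0.5)))
#' b <- pop_freq_set("b", list(L = c(u = 1)))
#' da_distance(a, b)  # 1 - sqrt(0.5)
#' @export
da_distance <- function(x, y, loci = names(x$freqs)) {
  miss <- setdiff(loci, intersect(names(x$freqs), names(y$freqs)))
  if (length(miss)) {
    stop("locus/loci absent from a population: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  shared <- vapply(loci, function(loc) {
    u <- x$freqs[[loc]]
    v <- y$freqs[[loc]]
    alleles <- union(names(u), names(v))
    sum(sqrt(ifelse(is.na(u[alleles]), 0, u[alleles]) *
               ifelse(is.na(v[alleles]), 0, v[alleles])))
  }, numeric(1L))
  1 - mean(shared)
}

#' DA distance matrix over a list of populations
#'
#' @param freq_sets List of [pop_freq_set()] objects.
#' @param loci Loci to use (default: loci of the first set).
#' @return Symmetric `dist`-compatible matrix with zero diagonal, row and
#'   column names = population ids.
#' @export
da_matrix <- function(freq_sets, loci = names(freq_sets[[1L]]$freqs)) {
  n <- length(freq_sets)
  ids <- vapply(freq_sets, function(s) s$population, character(1L))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        m[i, j] <- m[j, i] <- da_distance(freq_sets[[i]], freq_sets[[j]],
                                          loci)
      }
    }
  }
  m
}

#' Neighbor-joining population tree
#'
#' Saitou-Nei neighbor joining (via `ape::nj`) on a symmetric distance
#' matrix; negative branch lengths (an NJ artifact on non-additive data)
#' are clamped to 0 with a message. Deterministic given the input matrix.
#'
#' @param d Symmetric distance matrix with zero diagonal (>= 3
#'   populations).
#' @return An `ape::phylo` unrooted tree; leaf set = population ids.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need >= 3 populations", call. = FALSE)
  if (!isSymmetric(unname(d), tol = 1e-9)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  tree <- ape::nj(stats::as.dist(d))
  if (any(tree$edge.length < 0)) {
    message("clamped ", sum(tree$edge.length < 0),
            " negative NJ branch length(s) to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

# resample allele columns within loci (with replacement) and renormalize
resample_freq_sets <- function(freq_sets, loci) {
  universe <- lapply(loci, function(loc) {
    sort(unique(unlist(lapply(freq_sets, function(s)
      names(s$freqs[[loc]])))))
  })
  names(universe) <- loci
  idx <- lapply(loci, function(loc) {
    k <- length(universe[[loc]])
    sample.int(k, k, replace = TRUE)
  })
  names(idx) <- loci
  lapply(freq_sets, function(s) {
    fr <- lapply(loci, function(loc) {
      full <- universe[[loc]]
      v <- s$freqs[[loc]][full]
      v[is.na(v)] <- 0
      names(v) <- full
      r <- v[idx[[loc]]]
      names(r) <- paste0(full, "__b", seq_along(r)) # resampled columns
      if (sum(r) <= 0) r else r / sum(r)
    })
    names(fr) <- loci
    out <- s
    out$freqs <- fr
    out
  })
}

#' Bootstrap support for the neighbor-joining tree
#'
#' With few loci the classic resample-loci bootstrap is degenerate, so
#' replicates resample the allele columns within each locus (with
#' replacement, to the original dimension), recompute DA and NJ, and
#' score each internal bipartition of the main tree by the fraction of
#' replicates containing it.
#'
#' @param freq_sets List of [pop_freq_set()] objects (>= 3).
#' @param loci Loci to use.
#' @param n_reps Bootstrap replicates (default 1200, the convention of
#'   published HLA population trees); 0 returns the tree without support.
#' @param seed Integer seed.
#' @return List: `tree` (`phylo`), `support` (numeric vector over the
#'   tree's internal nodes, `NA` for the root trichotomy), `n_reps`.
#' @export
bootstrap_support <- function(freq_sets, loci =
                                names(freq_sets[[1L]]$freqs),
                              n_reps = 1200L, seed = 1L) {
  main <- nj_tree(da_matrix(freq_sets, loci))
  if (n_reps == 0L) {
    return(list(tree = main, support = NULL, n_reps = 0L))
  }
  boots <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      nj_tree(da_matrix(resample_freq_sets(freq_sets, loci), loci))
    })
  })
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  list(tree = main, support = counts / n_reps, n_reps = n_reps)
}

#' Principal components of a population x allele frequency matrix
#'
#' Column-centred singular value decomposition of the concatenated
#' per-locus frequency vectors (not scaled: frequencies share units).
#'
#' @param m Numeric matrix, populations in rows, alleles in columns (>= 2
#'   rows); or a list of [pop_freq_set()] objects, which is aligned on the
#'   outer-joined allele universe first.
#' @param loci When `m` is a list: loci to concatenate.
#' @return List: `coordinates` (populations x components),
#'   `explained` (non-increasing variance fractions summing to <= 1).
#' @export
pca_freq <- function(m, loci = NULL) {
  if (!is.matrix(m)) {
    freq_sets <- m
    if (is.null(loci)) loci <- names(freq_sets[[1L]]$freqs)
    m <- freq_matrix(freq_sets, loci)
  }
  if (nrow(m) < 2L) stop("need >= 2 populations", call. = FALSE)
  if (all(abs(sweep(m, 2L, colMeans(m))) < 1e-12)) {
    warning("constant frequency matrix: zero variance")
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  v <- fit$sdev^2
  list(coordinates = fit$x, explained = v / sum(v))
}

#' Align population frequency sets into one matrix
#'
#' Outer join on allele names per locus (absent allele = 0), columns
#' named `<locus>:<allele>`.
#'
#' @inheritParams bootstrap_support
#' @return Numeric matrix, populations x alleles.
#' @export
freq_matrix <- function(freq_sets, loci = names(freq_sets[[1L]]$freqs)) {
  cols <- list()
  for (loc in loci) {
    alleles <- sort(unique(unlist(lapply(freq_sets, function(s)
      names(s$freqs[[loc]])))))
    block <- t(vapply(freq_sets, function(s) {
      v <- s$freqs[[loc]][alleles]
      v[is.na(v)] <- 0
      as.numeric(v)
    }, numeric(length(alleles))))
    colnames(block) <- paste0(loc, ":", alleles)
    cols[[loc]] <- block
  }
  m <- do.call(cbind, cols)
  rownames(m) <- vapply(freq_sets, function(s) s$population, character(1L))
  m
}
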