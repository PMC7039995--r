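# Fixtures built in code: small pools, toy cohorts and published-style
# frequency vectors shared across the test files.

# two-field allele frequencies at HLA-A in a small, isolated Native
# American-style population (17 alleles, summing to 1)
hla_a_freqs <- function() {
  c(0.1904, 0.1697, 0.1445, 0.1399, 0.1376, 0.0940, 0.0550, 0.0275,
    0.0115, 0.0069, 0.0046, 0.0046, 0.0046, 0.0023, 0.0023, 0.0023,
    0.0023)
}

# a 2-locus, 4-haplotype pool with moderate LD, for EM recovery tests
small_pool <- function(freqs = c(0.4, 0.3, 0.2, 0.1)) {
  out <- data.frame(
    haplotype = c("A*01:01~B*07:02", "A*01:01~B*08:01",
                  "A*02:01~B*07:02", "A*02:01~B*08:01"),
    frequency = freqs,
    ancestry = c("NativeAmerican", "NativeAmerican", "European",
                 "European"),
    stringsAsFactors = FALSE
  )
  attr(out, "loci") <- c("A", "B")
  out
}

# a single-locus biallelic pool
biallelic_pool <- function(p = 0.5) {
  out <- data.frame(haplotype = c("A*01:01", "A*02:01"),
                    frequency = c(p, 1 - p),
                    stringsAsFactors = FALSE)
  attr(out, "loci") <- "A"
  out
}

# build an hla_cohort directly from explicit genotype rows
toy_cohort <- function(rows, loci) {
  hla_cohort(do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)
  })), loci)
}

# one trio over two loci (father, mother, child), given as allele pairs
trio_rows <- function(fa1, fa2, mo1, mo2, ch1, ch2,
                      loci = c("A", "B"), fam = "F1") {
  mk <- function(id, role, g1, g2) {
    r <- list(subject_id = id, family_id = fam, role = role)
    r[[paste0(loci[1L], "_1")]] <- g1[1L]
    r[[paste0(loci[1L], "_2")]] <- g1[2L]
    r[[paste0(loci[2L], "_1")]] <- g2[1L]
    r[[paste0(loci[2L], "_2")]] <- g2[2L]
    r
  }
  list(mk(paste0(fam, "_FA"), "father", fa1, fa2),
       mk(paste0(fam, "_MO"), "mother", mo1, mo2),
       mk(paste0(fam, "_CH"), "child", ch1, ch2))
}

# independent multinomial likelihood oracle for 2-locus EM: enumerates the
# phase-compatible haplotype pairs of each genotype directly and maximizes
# the likelihood over the frequency simplex by multi-start BFGS on a
# softmax parametrization (no EM machinery involved)
em_oracle <- function(cohort, haplotypes, loci = c("A", "B"),
                      n_starts = 8L, seed = 42L) {
  split_h <- strsplit(haplotypes, "~", fixed = TRUE)
  genos <- lapply(seq_len(nrow(cohort)), function(i) {
    a <- sort(c(cohort[[paste0(loci[1L], "_1")]][i],
                cohort[[paste0(loci[1L], "_2")]][i]))
    b <- sort(c(cohort[[paste0(loci[2L], "_1")]][i],
                cohort[[paste0(loci[2L], "_2")]][i]))
    list(a = a, b = b)
  })
  # for each subject, list the (i, j) haplotype index pairs consistent
  # with its unordered genotypes
  pairs <- lapply(genos, function(g) {
    idx <- which(vapply(seq_along(haplotypes), function(i) {
      any(vapply(seq_along(haplotypes), function(j) {
        identical(sort(c(split_h[[i]][1L], split_h[[j]][1L])), g$a) &&
          identical(sort(c(split_h[[i]][2L], split_h[[j]][2L])), g$b)
      }, logical(1L)))
    }, logical(1L)))
    out <- list()
    for (i in idx) for (j in idx) {
      if (j < i) next
      if (identical(sort(c(split_h[[i]][1L], split_h[[j]][1L])), g$a) &&
          identical(sort(c(split_h[[i]][2L], split_h[[j]][2L])), g$b)) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
    out
  })
  negll <- function(theta) {
    f <- exp(c(theta, 0)); f <- f / sum(f)
    -sum(vapply(pairs, function(ps) {
      log(sum(vapply(ps, function(p) {
        if (p[1L] == p[2L]) f[p[1L]]^2 else 2 * f[p[1L]] * f[p[2L]]
      }, numeric(1L))))
    }, numeric(1L)))
  }
  k <- length(haplotypes)
  best <- NULL
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    th0 <- if (s == 1L) rep(0, k - 1L) else stats::rnorm(k - 1L)
    fit <- stats::optim(th0, negll, method = "BFGS",
                        control = list(maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  f <- exp(c(best$par, 0)); f <- f / sum(f)
  names(f) <- haplotypes
  f
}
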