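test_that("delta-prime reproduces worked two-locus examples", {
  # allele A occurs on 29/436 chromosomes, always with allele B (122/436)
  r1 <- ld_pair(29 / 436, 29 / 436, 122 / 436, 436)
  expect_equal(r1$delta_prime, 1)
  # a rare co-occurrence against frequent marginals: strong repulsion;
  # frozen from direct evaluation of the stated formulas on counts
  # h = 2/436, pA = 48/436, pB = 165/436
  r2 <- ld_pair(2 / 436, 48 / 436, 165 / 436, 436)
  expect_equal(r2$delta_prime, -0.88990, tolerance = 5e-4)
  expect_equal(r2$delta_prime, -0.890, tolerance = 0.005)
  # independence: pA = pB = 0.5, h = 0.25
  r3 <- ld_pair(0.25, 0.5, 0.5, 400)
  expect_equal(r3$delta, 0)
  expect_equal(r3$delta_prime, 0)
  expect_equal(r3$t, 0)
})

test_that("delta-prime attains its bounds at the coupling extremes", {
  set.seed(4)
  for (i in 1:25) {
    pA <- stats::runif(1, 0.05, 0.95)
    pB <- stats::runif(1, 0.05, 0.95)
    two_n <- 400L
    # complete coupling: h = min(pA, pB)
    expect_equal(ld_pair(min(pA, pB), pA, pB, two_n)$delta_prime, 1)
    # complete repulsion: h = max(0, pA + pB - 1)
    h_min <- max(0, pA + pB - 1)
    expect_equal(ld_pair(h_min, pA, pB, two_n)$delta_prime, -1)
    # role antisymmetry: swapping the loci changes nothing
    h <- stats::runif(1, h_min, min(pA, pB))
    a <- ld_pair(h, pA, pB, two_n)
    b <- ld_pair(h, pB, pA, two_n)
    expect_equal(a$delta, b$delta)
    expect_equal(a$delta_prime, b$delta_prime)
    # invariants
    expect_lte(abs(a$delta_prime), 1 + 1e-9)
    expect_equal(a$delta, h - pA * pB, tolerance = 1e-12)
  }
})

test_that("the t statistic grows with sample size and association", {
  t1 <- ld_pair(0.10, 0.2, 0.3, 200)$t
  t2 <- ld_pair(0.10, 0.2, 0.3, 800)$t
  expect_equal(t2, 2 * t1, tolerance = 1e-9)  # sqrt(n) scaling
  t3 <- ld_pair(0.08, 0.2, 0.3, 200)$t
  expect_lt(t3, t1)  # weaker association, smaller t
})

test_that("ld_pair rejects undefined and inconsistent inputs", {
  expect_error(ld_pair(0.1, 0, 0.5, 100), "undefined LD")
  expect_error(ld_pair(0.5, 1, 0.5, 100), "monomorphic")
  expect_error(ld_pair(0.4, 0.2, 0.5, 100), "inconsistent")
})

test_that("block scans marginalize correctly and filter rare haplotypes", {
  # 3-locus joint table; B~C marginals computable by hand
  tab <- hla_haplotable(
    c("A*01:01~B*07:02~C*07:02", "A*02:01~B*07:02~C*07:02",
      "A*01:01~B*08:01~C*07:01", "A*02:01~B*40:02~C*03:04",
      "A*01:01~B*40:02~C*03:04"),
    c(20, 10, 6, 3, 1) / 40, loci = c("A", "B", "C"),
    count = c(20L, 10L, 6L, 3L, 1L), total_chromosomes = 40L)
  scan <- block_scan(tab, c("B", "C"), min_count = 1L)
  expect_identical(scan$haplotype,
                   c("B*07:02~C*07:02", "B*08:01~C*07:01",
                     "B*40:02~C*03:04"))
  expect_equal(scan$h, c(30, 6, 4) / 40)
  expect_equal(scan$n, c(30L, 6L, 4L))
  # marginals of emitted rows match the table's locus marginals
  expect_equal(scan$pA, c(30, 6, 4) / 40)  # B marginals
  expect_equal(scan$pB, c(30, 6, 4) / 40)  # C marginals here equal B's
  expect_lte(sum(scan$h), 1)
  # B*07:02 occurs only with C*07:02: complete coupling
  expect_equal(scan$delta_prime[1L], 1)
  # min_count = 2 drops nothing here (every B~C block has >= 2 copies);
  # a singleton B~C block is dropped
  tab2 <- hla_haplotable(c("A*01:01~B*07:02~C*07:02",
                           "A*01:01~B*13:02~C*06:02"),
                         c(39, 1) / 40, loci = c("A", "B", "C"),
                         count = c(39L, 1L), total_chromosomes = 40L)
  expect_identical(nrow(block_scan(tab2, c("B", "C"), min_count = 2L)), 1L)
  expect_identical(nrow(block_scan(tab2, c("B", "C"), min_count = 1L)), 2L)
  expect_error(block_scan(tab, c("B", "DQB1")), "not in table")
  expect_error(block_scan(tab, "B"), ">= 2 distinct loci")
})

test_that("a single-haplotype table yields an undefined-LD row", {
  tab <- hla_haplotable("B*07:02~C*07:02", 1, loci = c("B", "C"),
                        count = 10L, total_chromosomes = 10L)
  scan <- block_scan(tab, c("B", "C"), min_count = 1L)
  expect_identical(nrow(scan), 1L)
  expect_true(is.na(scan$delta_prime))
})

test_that("block extension treats blocks as composite alleles", {
  # A allele (4/10) fully contains a B~C block (3/10): delta-prime 1
  tab <- hla_haplotable(
    c("A*24:02~B*40:02~C*15:02", "A*24:02~B*35:01~C*07:02",
      "A*31:01~B*40:02~C*03:04"),
    c(3, 1, 6) / 10, loci = c("A", "B", "C"),
    count = c(3L, 1L, 6L), total_chromosomes = 10L)
  ext <- extend_block(tab, "A", c("B", "C"), min_count = 1L)
  row <- ext[ext$haplotype == "A*24:02~B*40:02~C*15:02", ]
  expect_equal(row$pA, 0.4)
  expect_equal(row$pB, 0.3)
  expect_equal(row$delta_prime, 1)
  expect_error(extend_block(tab, c("A", "B"), c("B", "C")), "disjoint")
})

test_that("an independent joint table has all delta-prime near zero", {
  # product of marginals: 2 x 2 blocks with independent 0.6/0.4 margins
  h <- c("B*07:02~C*07:02", "B*07:02~C*03:04",
         "B*08:01~C*07:02", "B*08:01~C*03:04")
  f <- c(0.36, 0.24, 0.24, 0.16)
  tab <- hla_haplotable(h, f, loci = c("B", "C"),
                        count = as.integer(f * 100),
                        total_chromosomes = 100L)
  scan <- block_scan(tab, c("B", "C"), min_count = 1L)
  expect_equal(scan$delta_prime, rep(0, 4L), tolerance = 1e-12)
})

test_that("pool-implied LD is recovered from a zero-scramble truth table", {
  pool <- small_pool()
  truth <- hla_haplotable(pool$haplotype, pool$frequency,
                          loci = c("A", "B"))
  attr(truth, "total_chromosomes") <- 1000L
  scan <- block_scan(truth, c("A", "B"), min_count = 1L)
  # exhaustive 2x2 oracle over the pool composition
  for (k in seq_len(nrow(scan))) {
    al <- hap_split(scan$haplotype[k])
    pA <- sum(pool$frequency[startsWith(pool$haplotype, al[1L])])
    pB <- sum(pool$frequency[endsWith(pool$haplotype, al[2L])])
    h <- pool$frequency[pool$haplotype == scan$haplotype[k]]
    d <- h - pA * pB
    dmax <- if (d > 0) min(pA * (1 - pB), pB * (1 - pA)) else
      min(pA * pB, (1 - pA) * (1 - pB))
    expect_equal(scan$delta_prime[k], d / dmax, tolerance = 1e-9)
  }
})
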