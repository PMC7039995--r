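test_that("segregation resolves forced and transmission-determined phase", {
  # child homozygous at all loci: both transmitted haplotypes forced, and
  # each heterozygous parent's untransmitted haplotype follows
  rows <- trio_rows(fa1 = c("A*01:01", "A*02:01"),
                    fa2 = c("B*07:02", "B*08:01"),
                    mo1 = c("A*01:01", "A*03:01"),
                    mo2 = c("B*07:02", "B*44:02"),
                    ch1 = c("A*01:01", "A*01:01"),
                    ch2 = c("B*07:02", "B*07:02"))
  seg <- count_phase_known(toy_cohort(rows, c("A", "B")))
  expect_identical(seg$n_chromosomes, 4L)
  cnt <- stats::setNames(seg$table$count, seg$table$haplotype)
  expect_identical(cnt[["A*01:01~B*07:02"]], 2L)  # transmitted by both
  expect_identical(cnt[["A*02:01~B*08:01"]], 1L)  # father untransmitted
  expect_identical(cnt[["A*03:01~B*44:02"]], 1L)  # mother untransmitted
  expect_identical(nrow(seg$inconsistencies), 0L)
})

test_that("all-distinct alleles resolve phase at every locus", {
  rows <- trio_rows(fa1 = c("A*01:01", "A*02:01"),
                    fa2 = c("B*07:02", "B*08:01"),
                    mo1 = c("A*03:01", "A*24:02"),
                    mo2 = c("B*44:02", "B*40:02"),
                    ch1 = c("A*02:01", "A*24:02"),
                    ch2 = c("B*08:01", "B*40:02"))
  seg <- count_phase_known(toy_cohort(rows, c("A", "B")))
  expect_identical(seg$n_chromosomes, 4L)
  expect_setequal(seg$table$haplotype,
                  c("A*02:01~B*08:01", "A*01:01~B*07:02",
                    "A*24:02~B*40:02", "A*03:01~B*44:02"))
})

test_that("Mendelian inconsistency is reported, not counted", {
  rows <- trio_rows(fa1 = c("A*01:01", "A*01:01"),
                    fa2 = c("B*07:02", "B*07:02"),
                    mo1 = c("A*01:01", "A*01:01"),
                    mo2 = c("B*07:02", "B*07:02"),
                    ch1 = c("A*26:01", "A*01:01"),  # A*26:01 from nowhere
                    ch2 = c("B*07:02", "B*07:02"))
  seg <- count_phase_known(toy_cohort(rows, c("A", "B")))
  expect_identical(seg$n_chromosomes, 0L)
  expect_identical(nrow(seg$inconsistencies), 1L)
  expect_identical(seg$inconsistencies$locus, "A")
})

test_that("ambiguous transmissions are left to EM, not guessed", {
  # both parents and child share the same heterozygous genotype at both
  # loci: either allele could have been transmitted at either locus
  rows <- trio_rows(fa1 = c("A*01:01", "A*02:01"),
                    fa2 = c("B*07:02", "B*08:01"),
                    mo1 = c("A*01:01", "A*02:01"),
                    mo2 = c("B*07:02", "B*08:01"),
                    ch1 = c("A*01:01", "A*02:01"),
                    ch2 = c("B*07:02", "B*08:01"))
  seg <- count_phase_known(toy_cohort(rows, c("A", "B")))
  expect_identical(seg$n_chromosomes, 0L)
  expect_identical(nrow(seg$inconsistencies), 0L)
})

test_that("EM equals direct gene counting when phase is known", {
  rows <- list(
    list(subject_id = "s1", A_1 = "A*01:01", A_2 = "A*01:01",
         B_1 = "B*07:02", B_2 = "B*07:02"),
    list(subject_id = "s2", A_1 = "A*01:01", A_2 = "A*01:01",
         B_1 = "B*07:02", B_2 = "B*07:02"),
    list(subject_id = "s3", A_1 = "A*02:01", A_2 = "A*02:01",
         B_1 = "B*08:01", B_2 = "B*08:01"),
    list(subject_id = "s4", A_1 = "A*02:01", A_2 = "A*02:01",
         B_1 = "B*07:02", B_2 = "B*07:02")
  )
  em <- em_frequencies(toy_cohort(rows, c("A", "B")))
  est <- stats::setNames(em$frequency, em$haplotype)
  expect_equal(est[["A*01:01~B*07:02"]], 0.5)
  expect_equal(est[["A*02:01~B*08:01"]], 0.25)
  expect_equal(est[["A*02:01~B*07:02"]], 0.25)
})

test_that("the symmetric solution is an EM fixed point for one double het", {
  rows <- list(list(subject_id = "s1", A_1 = "A*01:01", A_2 = "A*02:01",
                    B_1 = "B*07:02", B_2 = "B*08:01"))
  em <- em_frequencies(toy_cohort(rows, c("A", "B")),
                       settings = em_settings(n_restarts = 1L))
  expect_equal(sort(em$frequency), rep(0.25, 4L), tolerance = 1e-9)
})

test_that("EM matches a brute-force likelihood oracle on hidden phase", {
  pool <- small_pool()
  cfg <- synthetic_config(pool = pool, n_subjects = 50L, n_trios = 0L,
                          inbreeding_f = 0, seed = 17L)
  sim <- simulate_cohort(cfg)
  em <- em_frequencies(sim$cohort, settings = em_settings(seed = 17L))
  oracle <- em_oracle(as.data.frame(sim$cohort), pool$haplotype)
  est <- stats::setNames(em$frequency, em$haplotype)[pool$haplotype]
  est[is.na(est)] <- 0
  expect_lt(max(abs(est - oracle)), 0.03)
  # and the EM log-likelihood is at least the oracle's optimum (up to
  # numerical slack): both maximize the same function
  ll_at <- function(f) {
    # direct likelihood evaluation at the oracle's estimate
    sum(log(vapply(seq_len(nrow(sim$cohort)), function(i) {
      a <- sort(c(sim$cohort$A_1[i], sim$cohort$A_2[i]))
      b <- sort(c(sim$cohort$B_1[i], sim$cohort$B_2[i]))
      tot <- 0
      for (x in seq_along(f)) for (y in seq_along(f)) {
        hx <- strsplit(names(f)[x], "~")[[1L]]
        hy <- strsplit(names(f)[y], "~")[[1L]]
        if (identical(sort(c(hx[1L], hy[1L])), a) &&
            identical(sort(c(hx[2L], hy[2L])), b)) {
          tot <- tot + f[x] * f[y]
        }
      }
      tot
    }, numeric(1L))))
  }
  expect_gte(attr(em, "loglik"), ll_at(oracle) - 1e-6)
})

test_that("EM log-likelihood trace is non-decreasing", {
  for (seed in c(1L, 23L)) {
    cfg <- synthetic_config(pool = small_pool(), n_subjects = 30L,
                            n_trios = 0L, seed = seed)
    sim <- simulate_cohort(cfg)
    em <- em_frequencies(sim$cohort,
                         settings = em_settings(seed = seed))
    expect_true(all(diff(attr(em, "loglik_trace")) >= -1e-8))
  }
})

test_that("estimation error shrinks as the cohort grows", {
  pool <- small_pool()
  mae <- vapply(c(50L, 200L, 800L), function(n) {
    cfg <- synthetic_config(pool = pool, n_subjects = n, n_trios = 0L,
                            inbreeding_f = 0, seed = 91L)
    sim <- simulate_cohort(cfg)
    em <- em_frequencies(sim$cohort,
                         settings = em_settings(n_restarts = 2L))
    est <- stats::setNames(em$frequency, em$haplotype)[pool$haplotype]
    est[is.na(est)] <- 0
    mean(abs(est - pool$frequency))
  }, numeric(1L))
  expect_true(mae[3L] < mae[1L])
  expect_lt(mae[3L], 0.02)
})

test_that("counted and EM tables merge by chromosome-weighted arithmetic", {
  counted <- hla_haplotable(c("A*01:01~B*07:02", "A*02:01~B*08:01"),
                            c(0.75, 0.25), loci = c("A", "B"),
                            count = c(3L, 1L), total_chromosomes = 4L)
  em <- hla_haplotable(c("A*01:01~B*07:02", "A*03:01~B*44:02"),
                       c(0.5, 0.5), loci = c("A", "B"),
                       total_chromosomes = 6L)
  merged <- combine_estimates(counted, em)
  f <- stats::setNames(merged$frequency, merged$haplotype)
  expect_equal(f[["A*01:01~B*07:02"]], (3 + 0.5 * 6) / 10)
  expect_equal(f[["A*02:01~B*08:01"]], 1 / 10)
  expect_equal(f[["A*03:01~B*44:02"]], 3 / 10)
  expect_identical(attr(merged, "total_chromosomes"), 10L)
  # degenerate merges pass the other table through
  empty <- count_phase_known(toy_cohort(list(
    list(subject_id = "x", A_1 = "A*01:01", A_2 = "A*01:01",
         B_1 = "B*07:02", B_2 = "B*07:02")), c("A", "B")))$table
  expect_identical(combine_estimates(empty, em), em)
  mismatched <- hla_haplotable("A*01:01", 1, loci = "A",
                               total_chromosomes = 2L)
  expect_error(combine_estimates(counted, mismatched), "locus lists")
})
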