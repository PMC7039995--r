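test_that("DA distance matches its closed forms and semimetric axioms", {
  a <- pop_freq_set("a", list(L1 = c(u = 0.5, v = 0.5),
                              L2 = c(x = 1)))
  b <- pop_freq_set("b", list(L1 = c(u = 1),
                              L2 = c(x = 1)))
  c_ <- pop_freq_set("c", list(L1 = c(w = 1),
                               L2 = c(y = 1)))
  expect_equal(da_distance(a, a), 0)
  expect_equal(da_distance(a, c_), 1)  # disjoint alleles at every locus
  # one locus shared exactly, the other 1 - sqrt(0.5)
  expect_equal(da_distance(a, b), (1 - sqrt(0.5)) / 2)
  one <- pop_freq_set("a1", list(L1 = c(u = 0.5, v = 0.5)))
  two <- pop_freq_set("b1", list(L1 = c(u = 1)))
  expect_equal(da_distance(one, two), 1 - sqrt(0.5))
  expect_equal(da_distance(one, two), da_distance(two, one))
  expect_error(da_distance(a, pop_freq_set("d", list(L9 = c(u = 1)))),
               "absent")
})

test_that("sub-unity published vectors are renormalized with a warning", {
  expect_warning(
    p <- pop_freq_set("p", list(L = c(u = 0.6, v = 0.3))),
    "renormalizing")
  expect_equal(sum(p$freqs$L), 1)
})

test_that("neighbor joining recovers a 4-taxon additive tree exactly", {
  # tree: (A,B) vs (C,D); external 1,2,3,4; internal branch 5
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  ext <- c(A = 1, B = 2, C = 3, D = 4)
  d["A", "B"] <- d["B", "A"] <- 3
  d["C", "D"] <- d["D", "C"] <- 7
  for (i in c("A", "B")) for (j in c("C", "D")) {
    d[i, j] <- d[j, i] <- ext[i] + ext[j] + 5
  }
  tree <- nj_tree(d)
  expect_setequal(tree$tip.label, LETTERS[1:4])
  # patristic distances reproduce the additive input exactly
  coph <- ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(unname(coph), unname(d), tolerance = 1e-9)
  expect_error(nj_tree(d[1:2, 1:2]), ">= 3 populations")
  d_bad <- d; d_bad[1, 2] <- 99
  expect_error(nj_tree(d_bad), "symmetric")
})

test_that("NJ finds the best topology among all 5-taxon trees", {
  skip_if_not_installed("phangorn")
  set.seed(13)
  for (rep in 1:3) {
    # random additive tree on 5 taxa
    true <- ape::rtree(5, rooted = FALSE)
    true$edge.length <- stats::runif(nrow(true$edge), 0.5, 2)
    d <- ape::cophenetic.phylo(true)
    est <- nj_tree(d[true$tip.label, true$tip.label])
    # brute force: the true topology is the unique additive fit among all
    # 15 unrooted 5-taxon topologies (least-squares fit per topology)
    all_tops <- phangorn::allTrees(5, rooted = FALSE,
                                   tip.label = true$tip.label)
    fits <- vapply(all_tops, function(tp) {
      f <- phangorn::nnls.tree(stats::as.dist(d), tp, method = "unrooted")
      sum((ape::cophenetic.phylo(f)[rownames(d), colnames(d)] - d)^2)
    }, numeric(1L))
    best <- all_tops[[which.min(fits)]]
    expect_equal(ape::dist.topo(est, best), 0, ignore_attr = TRUE)
    expect_equal(ape::dist.topo(est, true), 0, ignore_attr = TRUE)
  }
})

test_that("input order does not change the NJ topology", {
  set.seed(99)
  true <- ape::rtree(6, rooted = FALSE)
  true$edge.length <- stats::runif(nrow(true$edge), 0.5, 2)
  d <- ape::cophenetic.phylo(true)
  t1 <- nj_tree(d)
  perm <- sample(rownames(d))
  t2 <- nj_tree(d[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("bootstrap support separates clean clusters", {
  # two clusters of four populations with within-cluster jitter
  set.seed(55)
  mk <- function(id, center) {
    f <- abs(center + stats::rnorm(6, sd = 0.01))
    f <- f / sum(f)
    pop_freq_set(id, list(A = stats::setNames(f, paste0("A*", 1:6))))
  }
  c1 <- c(10, 8, 6, 0.2, 0.2, 0.2)
  c2 <- c(0.2, 0.2, 0.2, 10, 8, 6)
  sets <- c(lapply(1:4, function(i) mk(paste0("x", i), c1)),
            lapply(1:4, function(i) mk(paste0("y", i), c2)))
  bs <- bootstrap_support(sets, n_reps = 100L, seed = 7L)
  expect_identical(bs$n_reps, 100L)
  # the x/y bipartition is an internal edge with near-full support
  expect_gt(max(bs$support[-1L], na.rm = TRUE), 0.95)
  # n_reps = 0: tree without support, no error
  bs0 <- bootstrap_support(sets, n_reps = 0L)
  expect_null(bs0$support)
  expect_s3_class(bs0$tree, "phylo")
})

test_that("star-like data yields no confidently supported bipartition", {
  # near-equidistant populations: any internal edge is arbitrary, so
  # bootstrap replicates scatter over topologies
  set.seed(17)
  sets <- lapply(1:5, function(i) {
    f <- abs(stats::rnorm(8, mean = 1, sd = 0.02))
    f[i] <- 8
    f <- f / sum(f)
    pop_freq_set(paste0("p", i),
                 list(A = stats::setNames(f, paste0("A*", 1:8))))
  })
  bs <- bootstrap_support(sets, n_reps = 80L, seed = 3L)
  internal <- bs$support[-1L]  # drop the root pseudo-node
  expect_lt(min(internal, na.rm = TRUE), 0.7)
})

test_that("PCA on frequency matrices behaves as an SVD should", {
  m2 <- rbind(p1 = c(1, 0, 0), p2 = c(0, 1, 0))
  res2 <- pca_freq(m2)
  expect_equal(res2$explained[1L], 1)
  # duplicated populations get identical coordinates
  m3 <- rbind(p1 = c(0.6, 0.4, 0), p2 = c(0.6, 0.4, 0),
              p3 = c(0.1, 0.1, 0.8))
  res3 <- pca_freq(m3)
  expect_equal(res3$coordinates["p1", ], res3$coordinates["p2", ])
  # a rank-2 matrix concentrates all variance on two components
  set.seed(2)
  u <- matrix(stats::rnorm(12), 6, 2)
  v <- matrix(stats::rnorm(8), 2, 4)
  res4 <- pca_freq(u %*% v)
  expect_equal(sum(res4$explained[1:2]), 1, tolerance = 1e-9)
  expect_true(all(diff(res4$explained) <= 1e-12))
  expect_warning(pca_freq(rbind(a = c(1, 0), b = c(1, 0))), "zero variance")
})

test_that("population sets align on an outer-joined allele universe", {
  sets <- list(
    pop_freq_set("p1", list(A = c("A*01" = 0.5, "A*02" = 0.5))),
    pop_freq_set("p2", list(A = c("A*02" = 0.25, "A*03" = 0.75))))
  m <- freq_matrix(sets)
  expect_identical(colnames(m), c("A:A*01", "A:A*02", "A:A*03"))
  expect_equal(unname(m["p1", ]), c(0.5, 0.5, 0))
  expect_equal(unname(m["p2", ]), c(0, 0.25, 0.75))
})
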