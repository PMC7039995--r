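# Haplotype frequency estimation: direct gene counting where phase is known
# from family segregation, expectation-maximization where it is not, and the
# weighted merge of the two -- the hybrid procedure population HLA studies
# use when a minority of subjects come with typed relatives.

#' Settings for the haplotype-frequency EM
#'
#' @param tol Convergence tolerance on the log-likelihood change (> 0).
#' @param max_iter Maximum EM iterations.
#' @param n_restarts Random restarts (>= 1); the first restart starts from
#'   uniform frequencies, the rest from seeded random (exponential/Dirichlet)
#'   initial frequencies. The best final log-likelihood wins, ties broken by
#'   lexicographic haplotype order of the estimate.
#' @param prune_threshold Candidate haplotypes with estimated frequency
#'   below this are dropped between iterations (as phase-ambiguity EM
#'   implementations conventionally do to keep the candidate set tractable);
#'   never prunes a subject's last compatible pair.
#' @param seed Integer seed for the random restarts.
#' @return A list of class `em_settings`.
#' @export
em_settings <- function(tol = 1e-8, max_iter = 500L, n_restarts = 5L,
                        prune_threshold = 1e-7, seed = 1L) {
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (n_restarts < 1L) stop("n_restarts must be >= 1", call. = FALSE)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts),
                 prune_threshold = prune_threshold,
                 seed = as.integer(seed)),
            class = "em_settings")
}

# genotype of one subject as a 2 x n_loci character matrix
subject_genotype <- function(cohort, i, loci) {
  g <- matrix(NA_character_, 2L, length(loci))
  for (j in seq_along(loci)) {
    cols <- locus_cols(loci[j])
    g[1L, j] <- cohort[[cols[1L]]][i]
    g[2L, j] <- cohort[[cols[2L]]][i]
  }
  g
}

# all phase-compatible unordered haplotype pairs for one genotype matrix;
# the first heterozygous locus is pinned to break the mirror symmetry
enumerate_pairs <- function(g) {
  n_loci <- ncol(g)
  het <- which(g[1L, ] != g[2L, ])
  if (length(het) == 0L) {
    h <- paste(g[1L, ], collapse = "~")
    return(data.frame(h1 = h, h2 = h, stringsAsFactors = FALSE))
  }
  free <- het[-1L]
  k <- length(free)
  n_cfg <- 2L^k
  h1 <- matrix(rep(g[1L, ], n_cfg), nrow = n_cfg, byrow = TRUE)
  h2 <- matrix(rep(g[2L, ], n_cfg), nrow = n_cfg, byrow = TRUE)
  if (k > 0L) {
    for (b in seq_len(k)) {
      flip <- bitwAnd(seq_len(n_cfg) - 1L, bitwShiftL(1L, b - 1L)) > 0L
      j <- free[b]
      h1[flip, j] <- g[2L, j]
      h2[flip, j] <- g[1L, j]
    }
  }
  data.frame(h1 = apply(h1, 1L, paste, collapse = "~"),
             h2 = apply(h2, 1L, paste, collapse = "~"),
             stringsAsFactors = FALSE)
}

#' Estimate haplotype frequencies by expectation-maximization
#'
#' Standard genotype-likelihood EM for unphased multi-locus data: the
#' E-step distributes each subject's unit mass over its phase-compatible
#' haplotype pairs proportionally to the current frequency product
#' (`2 f_i f_j` for heterozygous pairs, `f_i^2` for homozygous), the M-step
#' renormalizes the expected chromosome counts. Only haplotypes compatible
#' with at least one subject are enumerated, and candidates falling below
#' `prune_threshold` are dropped between iterations. The log-likelihood is
#' checked to be non-decreasing at every iteration.
#'
#' @param cohort An `hla_cohort` (all loci present in all records).
#' @param loci Loci to build haplotypes over (default: all cohort loci).
#' @param settings An [em_settings()].
#' @return An `hla_haplotable` with attributes `loglik` (best final
#'   log-likelihood), `loglik_trace`, `n_iter` and
#'   `total_chromosomes = 2N`.
#' @export
em_frequencies <- function(cohort, loci = hla_loci(cohort),
                           settings = em_settings()) {
  stopifnot(inherits(cohort, "hla_cohort"), nrow(cohort) >= 1L)
  n <- nrow(cohort)
  pair_list <- vector("list", n)
  for (i in seq_len(n)) {
    g <- subject_genotype(cohort, i, loci)
    if (anyNA(g)) {
      stop("subject ", cohort$subject_id[i],
           " has a missing call at a requested locus", call. = FALSE)
    }
    pair_list[[i]] <- cbind(subject = i, enumerate_pairs(g))
  }
  pairs <- do.call(rbind, pair_list)
  haps <- sort(unique(c(pairs$h1, pairs$h2)))
  i_idx <- match(pairs$h1, haps)
  j_idx <- match(pairs$h2, haps)
  subj <- pairs$subject
  hom <- i_idx == j_idx
  run_em <- function(f0) {
    f <- f0
    keep <- rep(TRUE, length(f))
    ll_trace <- numeric(0)
    ll_old <- -Inf
    for (iter in seq_len(settings$max_iter)) {
      term <- ifelse(hom, f[i_idx]^2, 2 * f[i_idx] * f[j_idx])
      term[!keep[i_idx] | !keep[j_idx]] <- 0
      denom <- rowsum(term, subj)[, 1L]
      if (any(denom <= 0)) {
        stop("internal error: a subject lost all compatible haplotype pairs",
             call. = FALSE)
      }
      ll <- sum(log(denom))
      if (ll < ll_old - 1e-8 * max(1, abs(ll_old))) {
        stop("internal error: EM log-likelihood decreased", call. = FALSE)
      }
      ll_trace <- c(ll_trace, ll)
      post <- term / denom[subj]
      cnt <- rowsum(c(post, post), c(i_idx, j_idx))
      f_new <- numeric(length(f))
      f_new[as.integer(rownames(cnt))] <- cnt[, 1L] / (2 * n)
      # prune, but never a subject's last surviving pair
      keep_new <- f_new >= settings$prune_threshold & keep
      pair_ok <- keep_new[i_idx] & keep_new[j_idx]
      lost <- setdiff(unique(subj), unique(subj[pair_ok]))
      if (length(lost)) {
        for (s in lost) {
          rows <- which(subj == s)
          best <- rows[which.max(post[rows])]
          keep_new[c(i_idx[best], j_idx[best])] <- TRUE
        }
      }
      keep <- keep_new
      f_new[!keep] <- 0
      f <- f_new / sum(f_new)
      if (abs(ll - ll_old) < settings$tol) break
      ll_old <- ll
    }
    list(f = f, ll = ll_trace[length(ll_trace)], trace = ll_trace,
         n_iter = length(ll_trace))
  }
  best <- NULL
  with_seed(settings$seed, {
    for (r in seq_len(settings$n_restarts)) {
      f0 <- if (r == 1L) {
        rep(1 / length(haps), length(haps))
      } else {
        x <- stats::rexp(length(haps))
        x / sum(x)
      }
      fit <- run_em(f0)
      if (is.null(best) || fit$ll > best$ll + 1e-10 ||
          (abs(fit$ll - best$ll) <= 1e-10 &&
           paste(round(fit$f, 10), collapse = ",") <
           paste(round(best$f, 10), collapse = ","))) {
        best <- fit
      }
    }
  })
  nz <- best$f > 0
  out <- hla_haplotable(haps[nz], best$f[nz] / sum(best$f[nz]), loci = loci,
                        total_chromosomes = 2L * n)
  attr(out, "loglik") <- best$ll
  attr(out, "loglik_trace") <- best$trace
  attr(out, "n_iter") <- best$n_iter
  out
}

#' Count phase-known haplotypes by family segregation
#'
#' For each father/mother/child trio, the transmitted allele of each parent
#' is identified at every locus from Mendelian transmission; where the
#' assignment is unique at all loci, the parent's transmitted and
#' untransmitted haplotypes are both fully resolved and each contributes a
#' count of 1 (the child's chromosomes are copies of transmitted parental
#' ones and are not double-counted). Ambiguous parents are left to EM, not
#' guessed. Trios in which the child carries an allele absent from the
#' relevant parent at any locus are reported as Mendelian inconsistencies
#' and contribute no counts.
#'
#' @param cohort An `hla_cohort` containing trio members with `family_id`
#'   and `role` in `father`/`mother`/`child`.
#' @param loci Loci to resolve haplotypes over.
#' @return List with `table` (an `hla_haplotable` of resolved counts;
#'   frequencies are counts over the resolved chromosomes),
#'   `n_chromosomes` (resolved chromosomes) and `inconsistencies`
#'   (`data.frame` of `family_id`, `locus`).
#' @export
count_phase_known <- function(cohort, loci = hla_loci(cohort)) {
  stopifnot(inherits(cohort, "hla_cohort"))
  fams <- unique(cohort$family_id[!is.na(cohort$family_id)])
  counts <- list()
  inconsistent <- data.frame(family_id = character(), locus = character(),
                             stringsAsFactors = FALSE)
  for (fam in fams) {
    members <- cohort[!is.na(cohort$family_id) & cohort$family_id == fam, ,
                      drop = FALSE]
    fa <- which(members$role == "father")
    mo <- which(members$role == "mother")
    ch <- which(members$role == "child")
    if (length(fa) != 1L || length(mo) != 1L || length(ch) < 1L) next
    ch <- ch[1L]
    gf <- subject_genotype(members, fa, loci)
    gm <- subject_genotype(members, mo, loci)
    gc <- subject_genotype(members, ch, loci)
    fam_bad <- FALSE
    # per locus: which child allele came from which parent
    tr_fa <- rep(NA_character_, length(loci))
    tr_mo <- rep(NA_character_, length(loci))
    ambiguous <- rep(FALSE, length(loci))
    for (j in seq_along(loci)) {
      c1 <- gc[1L, j]; c2 <- gc[2L, j]
      opts <- unique(list(c(c1, c2), c(c2, c1)))
      valid <- Filter(function(o) {
        o[1L] %in% gf[, j] && o[2L] %in% gm[, j]
      }, opts)
      if (length(valid) == 0L) {
        inconsistent <- rbind(inconsistent,
                              data.frame(family_id = fam, locus = loci[j],
                                         stringsAsFactors = FALSE))
        fam_bad <- TRUE
      } else if (length(valid) == 1L) {
        tr_fa[j] <- valid[[1L]][1L]
        tr_mo[j] <- valid[[1L]][2L]
      } else {
        ambiguous[j] <- TRUE
      }
    }
    if (fam_bad) next
    add <- function(h) {
      key <- paste(h, collapse = "~")
      counts[[key]] <<- (counts[[key]] %||% 0L) + 1L
    }
    # a parent is resolved if transmission is unambiguous at every locus;
    # the untransmitted allele is then the parent's other copy
    resolve_parent <- function(gp, tr) {
      if (any(ambiguous) || anyNA(tr)) return(NULL)
      untr <- character(length(tr))
      for (j in seq_along(tr)) {
        k <- match(tr[j], gp[, j])
        untr[j] <- gp[c(2L, 1L)[k], j]
      }
      list(tr, untr)
    }
    for (p in list(resolve_parent(gf, tr_fa), resolve_parent(gm, tr_mo))) {
      if (!is.null(p)) { add(p[[1L]]); add(p[[2L]]) }
    }
  }
  n_chr <- sum(unlist(counts))
  if (n_chr > 0L) {
    tab <- hla_haplotable(names(counts),
                          unlist(counts) / n_chr, loci = loci,
                          count = unlist(counts),
                          total_chromosomes = n_chr)
  } else {
    tab <- hla_haplotable(character(), numeric(), loci = loci,
                          complete = FALSE)
    attr(tab, "total_chromosomes") <- 0L
  }
  list(table = tab, n_chromosomes = n_chr, inconsistencies = inconsistent)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge family-counted and EM-estimated haplotype tables
#'
#' Family-resolved chromosomes enter as fixed counts; the EM mass is scaled
#' to the remaining chromosomes:
#' `frequency = (fixed count + EM frequency * EM chromosomes) / total`.
#'
#' @param counted `hla_haplotable` with counts (from
#'   [count_phase_known()]).
#' @param em `hla_haplotable` of EM frequencies with a
#'   `total_chromosomes` attribute.
#' @return Combined `hla_haplotable` over
#'   `total = counted + EM chromosomes`.
#' @export
combine_estimates <- function(counted, em) {
  if (!identical(hla_loci(counted), hla_loci(em))) {
    stop("locus lists of the two tables differ", call. = FALSE)
  }
  n_c <- attr(counted, "total_chromosomes")
  n_e <- attr(em, "total_chromosomes")
  if (is.na(n_c)) n_c <- sum(counted$count)
  if (is.na(n_e)) stop("EM table needs total_chromosomes", call. = FALSE)
  if (n_c == 0L) return(em)
  if (n_e == 0L) return(counted)
  haps <- union(counted$haplotype, em$haplotype)
  cnt <- counted$count[match(haps, counted$haplotype)]
  cnt[is.na(cnt)] <- 0L
  fem <- em$frequency[match(haps, em$haplotype)]
  fem[is.na(fem)] <- 0
  total <- n_c + n_e
  hla_haplotable(haps, (cnt + fem * n_e) / total, loci = hla_loci(counted),
                 total_chromosomes = total)
}
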