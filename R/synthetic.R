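# Synthetic cohorts, reference panels and cross-population covariate tables.
# The generator states a world with the structure the downstream analyses
# assume: a small multi-locus haplotype pool with near-rigid B~C pairing and
# strong class I/class II blocks, configurable whole-haplotype inbreeding,
# a minority of phase-known family trios, and ancestry-labelled haplotypes.

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic child seed derived from a master seed, kept below 2^31
child_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629
}

#' Built-in ancestry-labelled haplotype pool
#'
#' Twenty-two nine-locus haplotypes with true frequencies patterned on a
#' small, isolated Native American population: a handful of conserved
#' extended haplotypes carry most of the mass, every HLA-B allele pairs with
#' a single HLA-C partner, class II diversity is low, and minority
#' European/African/Asian haplotypes reflect post-contact admixture. One
#' haplotype carries the structural absence (`NULL`) of DRB3/4/5.
#'
#' @return `data.frame` with columns `haplotype`, `frequency`, `ancestry`;
#'   attribute `loci` gives the nine-locus order.
#' @export
default_haplotype_pool <- function() {
  loci <- c("A", "B", "C", "DRB1", "DRB3/4/5", "DQB1", "DQA1",
            "DPA1", "DPB1")
  h <- c(
    "A*31:01~B*40:02~C*03:04~DRB1*04:11~DRB4*01:03~DQB1*03:02~DQA1*03:01~DPA1*01:03~DPB1*04:02",
    "A*31:01~B*40:02~C*03:04~DRB1*04:11~DRB4*01:01~DQB1*03:02~DQA1*03:01~DPA1*01:03~DPB1*04:02",
    "A*68:03~B*35:01~C*07:02~DRB1*16:02~DRB5*02:02~DQB1*03:01~DQA1*05:05~DPA1*01:03~DPB1*04:02",
    "A*24:02~B*35:12~C*04:01~DRB1*04:11~DRB4*01:03~DQB1*03:02~DQA1*03:01~DPA1*01:03~DPB1*04:02",
    "A*68:01~B*39:05~C*07:02~DRB1*04:11~DRB4*01:03~DQB1*03:02~DQA1*03:01~DPA1*01:03~DPB1*04:02",
    "A*02:06~B*35:01~C*07:02~DRB1*04:11~DRB4*01:03~DQB1*03:02~DQA1*03:01~DPA1*01:03~DPB1*04:02",
    "A*68:03~B*39:05~C*07:02~DRB1*04:07~DRB4*01:01~DQB1*03:02~DQA1*03:01~DPA1*01:03~DPB1*04:02",
    "A*24:02~B*40:02~C*15:02~DRB1*14:06~DRB3*01:01~DQB1*03:01~DQA1*05:03~DPA1*01:03~DPB1*04:01",
    "A*68:01~B*40:08~C*03:04~DRB1*04:07~DRB4*01:03~DQB1*03:02~DQA1*03:01~DPA1*01:03~DPB1*04:02",
    "A*02:01~B*18:01~C*07:01~DRB1*11:04~DRB3*02:02~DQB1*03:01~DQA1*05:05~DPA1*01:03~DPB1*04:02",
    "A*02:01~B*35:12~C*04:01~DRB1*04:11~DRB4*01:03~DQB1*03:02~DQA1*03:01~DPA1*01:03~DPB1*04:02",
    "A*24:14~B*35:01~C*04:01~DRB1*04:04~DRB4*01:01~DQB1*03:02~DQA1*03:01~DPA1*02:02~DPB1*05:01",
    "A*68:02~B*53:01~C*04:01~DRB1*13:03~DRB3*02:02~DQB1*02:02~DQA1*02:01~DPA1*02:02~DPB1*11:01",
    "A*02:06~B*52:01~C*03:03~DRB1*04:04~DRB4*01:03~DQB1*03:02~DQA1*03:01~DPA1*01:03~DPB1*04:02",
    "A*24:02~B*35:12~C*04:01~DRB1*08:02~NULL~DQB1*04:02~DQA1*04:01~DPA1*01:03~DPB1*04:02",
    "A*24:02~B*35:01~C*07:02~DRB1*04:07~DRB4*01:01~DQB1*03:02~DQA1*03:01~DPA1*01:03~DPB1*04:02",
    "A*31:01~B*40:02~C*03:04~DRB1*04:07~DRB4*01:01~DQB1*03:02~DQA1*03:01~DPA1*01:03~DPB1*04:02",
    "A*02:06~B*39:05~C*07:02~DRB1*04:11~DRB4*01:03~DQB1*03:02~DQA1*03:01~DPA1*01:03~DPB1*04:02",
    "A*68:01~B*40:08~C*03:04~DRB1*04:03~DRB4*01:01~DQB1*03:02~DQA1*03:01~DPA1*01:03~DPB1*04:02",
    "A*68:03~B*35:01~C*07:02~DRB1*16:02~DRB5*02:02~DQB1*03:01~DQA1*05:05~DPA1*01:03~DPB1*02:01",
    "A*24:02~B*39:06~C*07:02~DRB1*04:04~DRB4*01:03~DQB1*03:02~DQA1*03:01~DPA1*01:03~DPB1*04:02",
    "A*33:01~B*14:02~C*08:02~DRB1*01:02~NULL~DQB1*05:01~DQA1*01:01~DPA1*01:03~DPB1*04:01"
  )
  f <- c(0.0667, 0.0529, 0.0414, 0.0368, 0.0345, 0.0299, 0.0299, 0.0253,
         0.0230, 0.0161, 0.0161, 0.0115, 0.0046, 0.0069, 0.0200, 0.1200,
         0.1200, 0.1100, 0.0800, 0.0744, 0.0754, 0.0046)
  anc <- c("NativeAmerican", "NativeAmerican", "NotPreviouslyReported",
           "NativeAmerican", "NativeAmerican", "NativeAmerican",
           "NativeAmerican", "NativeAmerican", "NotPreviouslyReported",
           "European", "NativeAmerican", "NativeAmerican", "African",
           "Asian", "NativeAmerican", "NativeAmerican", "NativeAmerican",
           "NativeAmerican", "NotPreviouslyReported",
           "NotPreviouslyReported", "NativeAmerican", "European")
  stopifnot(abs(sum(f) - 1) < 1e-9)
  out <- data.frame(haplotype = h, frequency = f, ancestry = anc,
                    stringsAsFactors = FALSE)
  attr(out, "loci") <- loci
  out
}

#' Configuration for the synthetic cohort generator
#'
#' @param pool `data.frame` with `haplotype`, `frequency` (summing to 1
#'   within `1e-9`) and optionally `ancestry`; attribute `loci` or the
#'   `loci` argument gives the locus order.
#' @param loci Locus order of the pool haplotypes.
#' @param n_subjects Unrelated subjects to simulate (default 218, a cohort
#'   size typical of field studies of small endogamous populations).
#' @param n_trios Father/mother/child families typed alongside the
#'   unrelated panel (default 36).
#' @param inbreeding_f Probability that a subject's second chromosome is an
#'   identity-by-descent copy of the first (whole-haplotype copying;
#'   default 0.05, the heterozygote deficit scale seen in highly inbred
#'   isolates).
#' @param scramble_rate Probability that a sampled chromosome recombines two
#'   pool haplotypes at a random locus boundary (default 0: fully conserved
#'   extended haplotypes).
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(pool = default_haplotype_pool(),
                             loci = attr(pool, "loci"),
                             n_subjects = 218L, n_trios = 36L,
                             inbreeding_f = 0.05, scramble_rate = 0,
                             seed = 1L) {
  stopifnot(is.data.frame(pool), nrow(pool) >= 1L,
            all(c("haplotype", "frequency") %in% names(pool)))
  if (abs(sum(pool$frequency) - 1) > 1e-9) {
    stop("pool frequencies must sum to 1 within 1e-9", call. = FALSE)
  }
  if (inbreeding_f < 0 || inbreeding_f > 1) {
    stop("inbreeding_f must lie in [0, 1]", call. = FALSE)
  }
  if (scramble_rate < 0 || scramble_rate > 1) {
    stop("scramble_rate must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(loci)) stop("locus list required", call. = FALSE)
  if (!"ancestry" %in% names(pool)) pool$ancestry <- "NativeAmerican"
  structure(list(pool = pool, loci = loci,
                 n_subjects = as.integer(n_subjects),
                 n_trios = as.integer(n_trios),
                 inbreeding_f = inbreeding_f,
                 scramble_rate = scramble_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# sample one chromosome (matrix of allele names, loci in columns)
draw_chromosomes <- function(cfg, n) {
  pool_mat <- do.call(rbind, strsplit(cfg$pool$haplotype, "~", fixed = TRUE))
  idx <- sample.int(nrow(pool_mat), n, replace = TRUE,
                    prob = cfg$pool$frequency)
  chrom <- pool_mat[idx, , drop = FALSE]
  if (cfg$scramble_rate > 0 && ncol(pool_mat) > 1L) {
    scramble <- stats::runif(n) < cfg$scramble_rate
    if (any(scramble)) {
      n_loci <- ncol(pool_mat)
      other <- sample.int(nrow(pool_mat), sum(scramble), replace = TRUE,
                          prob = cfg$pool$frequency)
      cut <- sample.int(n_loci - 1L, sum(scramble), replace = TRUE)
      rows <- which(scramble)
      for (k in seq_along(rows)) {
        right <- (cut[k] + 1L):n_loci
        chrom[rows[k], right] <- pool_mat[other[k], right]
      }
    }
  }
  chrom
}

#' Simulate a diploid HLA cohort from a haplotype pool
#'
#' Each unrelated subject draws a first chromosome from the pool; with
#' probability `inbreeding_f` the second chromosome is an identity-by-
#' descent copy of the first, otherwise an independent draw. Trio children
#' inherit one (randomly chosen) chromosome from each parent without
#' recombination, so trios carry phase-known haplotypes for segregation
#' counting. The generating ("truth") table is returned for recovery tests.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `cohort` (an `hla_cohort`; trio members carry
#'   `family_id` and `role`), and `truth` (the pool as an
#'   `hla_haplotable`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    loci <- cfg$loci
    n_unrel <- cfg$n_subjects
    blocks <- list()
    make_block <- function(id, fam, role, c1, c2) {
      g <- data.frame(subject_id = id, family_id = fam, role = role,
                      stringsAsFactors = FALSE)
      for (j in seq_along(loci)) {
        g[[paste0(loci[j], "_1")]] <- c1[, j]
        g[[paste0(loci[j], "_2")]] <- c2[, j]
      }
      g
    }
    # unrelated panel
    if (n_unrel > 0L) {
      first <- draw_chromosomes(cfg, n_unrel)
      second <- draw_chromosomes(cfg, n_unrel)
      ibd <- stats::runif(n_unrel) < cfg$inbreeding_f
      second[ibd, ] <- first[ibd, , drop = FALSE]
      blocks$unrel <- make_block(sprintf("S%04d", seq_len(n_unrel)),
                                 NA_character_, "unrelated", first, second)
    }
    # family trios: child takes one randomly chosen chromosome per parent
    if (cfg$n_trios > 0L) {
      nt <- cfg$n_trios
      fam <- sprintf("F%03d", seq_len(nt))
      fa1 <- draw_chromosomes(cfg, nt); fa2 <- draw_chromosomes(cfg, nt)
      mo1 <- draw_chromosomes(cfg, nt); mo2 <- draw_chromosomes(cfg, nt)
      pick_fa <- stats::runif(nt) < 0.5
      pick_mo <- stats::runif(nt) < 0.5
      ch1 <- fa1; ch1[!pick_fa, ] <- fa2[!pick_fa, , drop = FALSE]
      ch2 <- mo1; ch2[!pick_mo, ] <- mo2[!pick_mo, , drop = FALSE]
      blocks$fa <- make_block(paste0(fam, "_FA"), fam, "father", fa1, fa2)
      blocks$mo <- make_block(paste0(fam, "_MO"), fam, "mother", mo1, mo2)
      blocks$ch <- make_block(paste0(fam, "_CH"), fam, "child", ch1, ch2)
    }
    cohort <- hla_cohort(do.call(rbind, blocks), loci)
    truth <- hla_haplotable(cfg$pool$haplotype, cfg$pool$frequency,
                            loci = loci)
    list(cohort = cohort, truth = truth)
  })
}

#' Simulate ancestry-labelled reference panels
#'
#' For each ancestry group in the pool, each requested panel's frequencies
#' are a multinomial resample (size `2n`) of that ancestry's renormalized
#' sub-pool, emulating the finite published reference populations used for
#' most-probable-ancestry assignment.
#'
#' @param pool Pool `data.frame` as in [synthetic_config()] with an
#'   `ancestry` column.
#' @param panel_n Named integer vector: panels to create, named
#'   `"<population>"`, values = sample size n (2n chromosomes); names must
#'   be unique. Ancestry of each panel is given by `panel_ancestry`.
#' @param panel_ancestry Character vector parallel to `panel_n` giving each
#'   panel's ancestry group.
#' @param seed Integer seed.
#' @param loci Locus order of the pool haplotypes.
#' @return List of [reference_panel()] objects.
#' @export
simulate_reference_panels <- function(pool, panel_n, panel_ancestry,
                                      seed = 1L,
                                      loci = attr(pool, "loci")) {
  stopifnot(length(panel_n) == length(panel_ancestry))
  if (any(panel_n <= 0L)) stop("panel sample sizes must be positive",
                               call. = FALSE)
  with_seed(seed, {
    lapply(seq_along(panel_n), function(i) {
      grp <- panel_ancestry[i]
      sub <- pool[pool$ancestry == grp, , drop = FALSE]
      if (nrow(sub) == 0L) {
        stop("no pool haplotypes with ancestry '", grp, "'", call. = FALSE)
      }
      p <- sub$frequency / sum(sub$frequency)
      counts <- as.vector(stats::rmultinom(1L, size = 2L * panel_n[i],
                                           prob = p))
      keep <- counts > 0L
      tab <- hla_haplotable(sub$haplotype[keep],
                            counts[keep] / sum(counts),
                            loci = loci, count = counts[keep],
                            total_chromosomes = sum(counts))
      reference_panel(population = names(panel_n)[i], ancestry = grp,
                      table = tab, sample_size = panel_n[i])
    })
  })
}

#' Scenario for the diversity-vs-geography regression generator
#'
#' States the world of the cross-population regression: per-population
#' logit(PIC) follows a linear model in distance-from-origin (km) and
#' pathogen richness with Gaussian noise on the logit scale.
#'
#' @param n_populations Number of populations (default 122, a typical
#'   compiled panel size for three-locus high-resolution data).
#' @param b0,b1,b2 True intercept, distance slope (per km) and richness
#'   slope on the logit scale. Defaults state a clear out-of-Africa decay
#'   (`b1 = -6e-5`) and no richness effect (`b2 = 0`).
#' @param noise_sd Gaussian noise SD on the logit scale (>= 0; default 0.4).
#' @param distance_range,richness_range,viral_range Uniform covariate
#'   generator ranges.
#' @param seed Integer seed.
#' @return A list of class `geo_scenario`.
#' @export
geo_scenario <- function(n_populations = 122L, b0 = 2.0, b1 = -6e-5,
                         b2 = 0, noise_sd = 0.4,
                         distance_range = c(500, 25000),
                         richness_range = c(50, 400),
                         viral_range = c(20, 200), seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_populations = as.integer(n_populations),
                 b0 = b0, b1 = b1, b2 = b2, noise_sd = noise_sd,
                 distance_range = distance_range,
                 richness_range = richness_range,
                 viral_range = viral_range, seed = as.integer(seed)),
            class = "geo_scenario")
}

#' Simulate a cross-population diversity/covariate table
#'
#' `logit(PIC) = b0 + b1 * distance_km + b2 * pathogen_richness + noise`,
#' independently per locus (A, B, DRB1), back-transformed into (0, 1).
#'
#' @param sc A [geo_scenario()].
#' @return `data.frame` with columns `population`, `distance_km`,
#'   `pathogen_richness`, `viral_richness`, `PIC_A`, `PIC_B`, `PIC_DRB1`.
#' @export
simulate_geo_dataset <- function(sc) {
  stopifnot(inherits(sc, "geo_scenario"))
  with_seed(sc$seed, {
    n <- sc$n_populations
    dist <- stats::runif(n, sc$distance_range[1L], sc$distance_range[2L])
    rich <- stats::runif(n, sc$richness_range[1L], sc$richness_range[2L])
    viral <- stats::runif(n, sc$viral_range[1L], sc$viral_range[2L])
    mu <- sc$b0 + sc$b1 * dist + sc$b2 * rich
    out <- data.frame(population = sprintf("POP%03d", seq_len(n)),
                      distance_km = dist, pathogen_richness = rich,
                      viral_richness = viral, stringsAsFactors = FALSE)
    for (loc in c("A", "B", "DRB1")) {
      eta <- mu + stats::rnorm(n, sd = sc$noise_sd)
      out[[paste0("PIC_", loc)]] <- inv_logit(eta)
    }
    out
  })
}
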