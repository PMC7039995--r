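# End-to-end pipeline wiring and the KIR-ligand frequency aggregation.

#' Bw4/C1/C2 KIR-ligand lookup for common class I alleles
#'
#' Classification of two-field HLA class I alleles into the epitope groups
#' serving as ligands for KIR receptors on natural killer cells: Bw4 (some
#' HLA-B and some HLA-A allotypes), and the mutually exclusive C1/C2
#' groups of HLA-C. Shipped as an editable table (the residue-77/80
#' sequence rule is out of scope); covers the alleles of the built-in
#' pool plus the common published classifications.
#'
#' @return `data.frame` with columns `allele`, `ligand`
#'   (`Bw4`/`C1`/`C2`/`none`).
#' @export
kir_ligand_table <- function() {
  data.frame(
    allele = c(
      # Bw4-carrying HLA-B allotypes
      "B*13:02", "B*27:05", "B*37:01", "B*38:01", "B*44:02", "B*44:03",
      "B*49:01", "B*51:01", "B*52:01", "B*53:01", "B*57:01", "B*58:01",
      # Bw4-carrying HLA-A allotypes
      "A*23:01", "A*24:02", "A*24:14", "A*25:01", "A*32:01",
      # HLA-C C2 group
      "C*02:02", "C*04:01", "C*05:01", "C*06:02", "C*15:02", "C*15:04",
      "C*15:15", "C*17:01", "C*18:01",
      # HLA-C C1 group
      "C*01:02", "C*03:03", "C*03:04", "C*03:05", "C*07:01", "C*07:02",
      "C*08:01", "C*08:02", "C*12:02", "C*12:03", "C*14:02", "C*16:01"
    ),
    ligand = c(rep("Bw4", 17L), rep("C2", 9L), rep("C1", 12L)),
    stringsAsFactors = FALSE
  )
}

#' Aggregate allele frequencies per KIR-ligand class
#'
#' Sums study frequencies per ligand class after two-field truncation.
#' Alleles absent from the lookup count as `"none"` with a warning. By
#' default Bw4 totals combine contributions from HLA-B and Bw4-flagged
#' HLA-A alleles when both are present in `freqs` (set
#' `combine_a_bw4 = FALSE` to report `Bw4_A` separately).
#'
#' @param freqs Named numeric vector: allele name -> study frequency.
#' @param lookup `data.frame` with `allele`, `ligand` columns (default
#'   [kir_ligand_table()]).
#' @param combine_a_bw4 Pool HLA-A Bw4 mass into the Bw4 total.
#' @return Named numeric vector of aggregate frequencies per ligand class
#'   (always including `Bw4`, `C1`, `C2`, `none`).
#' @export
kir_ligand_aggregate <- function(freqs, lookup = kir_ligand_table(),
                                 combine_a_bw4 = TRUE) {
  stopifnot(!is.null(names(freqs)))
  # truncate parseable names to two fields; aggregate labels (or other
  # unparseable keys) match the lookup verbatim
  alleles <- vapply(names(freqs), function(nm) {
    tryCatch(truncate_name(nm, 2L), error = function(e) nm)
  }, character(1L), USE.NAMES = FALSE)
  cls <- lookup$ligand[match(alleles, lookup$allele)]
  unknown <- is.na(cls)
  if (any(unknown) && nrow(lookup)) {
    warning("allele(s) absent from ligand lookup counted as 'none': ",
            paste(utils::head(alleles[unknown], 5L), collapse = ", "),
            if (sum(unknown) > 5L) ", ...")
  }
  cls[unknown] <- "none"
  is_a <- startsWith(alleles, "A*")
  if (!combine_a_bw4) cls[is_a & cls == "Bw4"] <- "Bw4_A"
  classes <- unique(c("Bw4", "C1", "C2", "none", cls))
  out <- vapply(classes, function(k) sum(freqs[cls == k]), numeric(1L))
  names(out) <- classes
  out
}

#' Run the full population-immunogenetics pipeline
#'
#' Executes the analysis stages on a cohort: haplotype estimation
#' (family segregation counting merged with EM), block and conserved-
#' extended-haplotype LD scans, the per-locus diversity summary,
#' most-probable-ancestry assignment with aggregate block frequencies
#' (when panels are supplied), and the non-overlap permutation scan.
#' Identical inputs and seed give identical output tables.
#'
#' @param cohort An `hla_cohort`.
#' @param panels Optional list of [reference_panel()] objects for the
#'   MPA/ABF stage.
#' @param loci Loci to analyze.
#' @param resolution Allele resolution for haplotype analyses.
#' @param min_count Minimum block count (default 2).
#' @param mpa_threshold Panel frequency threshold (default 0.01).
#' @param n_perm Permutations per locus pair in the non-overlap scan.
#' @param hwe_steps Monte-Carlo steps for the HWE tests.
#' @param seed Master seed.
#' @param em An [em_settings()].
#' @return Named list of result tables: `haplotypes`, `blocks_bc`, `ceh`,
#'   `ceh_a`, `diversity`, `mpa`, `abf`, `nonoverlap`,
#'   `segregation_inconsistencies`.
#' @export
run_pipeline <- function(cohort, panels = NULL, loci = hla_loci(cohort),
                         resolution = 2L, min_count = 2L,
                         mpa_threshold = 0.01, n_perm = 1000L,
                         hwe_steps = 1e4, seed = 1L,
                         em = em_settings(seed = seed)) {
  cohort_r <- truncate_cohort(cohort, resolution)
  # phase-known counting on trios, EM on the unrelated remainder
  seg <- count_phase_known(cohort_r)
  unrel <- cohort_r[cohort_r$role == "unrelated", , drop = FALSE]
  class(unrel) <- class(cohort_r)
  attr(unrel, "loci") <- loci
  haplotypes <- if (nrow(unrel)) {
    emtab <- em_frequencies(unrel, loci, em)
    if (seg$n_chromosomes > 0L) combine_estimates(seg$table, emtab) else
      emtab
  } else {
    seg$table
  }
  blocks_bc <- if (all(c("B", "C") %in% loci)) {
    block_scan(haplotypes, c("B", "C"), min_count = min_count)
  } else NULL
  ceh_loci <- c("B", "C", "DRB1", "DQB1")
  ceh <- if (all(ceh_loci %in% loci)) {
    extend_block(haplotypes, c("B", "C"), c("DRB1", "DQB1"),
                 min_count = min_count)
  } else NULL
  ceh_a <- if (all(c("A", ceh_loci) %in% loci)) {
    extend_block(haplotypes, "A", ceh_loci, min_count = min_count)
  } else NULL
  diversity <- diversity_summary(cohort_r, loci, n_steps = hwe_steps,
                                 seed = child_seed(seed, 101L),
                                 resolution = NULL)
  mpa_tab <- NULL
  abf_tab <- NULL
  if (!is.null(panels) && !is.null(blocks_bc) && nrow(blocks_bc)) {
    mpa_tab <- assign_mpa(blocks_bc$haplotype, c("B", "C"), panels,
                          threshold = mpa_threshold)
    freqs <- stats::setNames(blocks_bc$h, blocks_bc$haplotype)
    abf_tab <- abf(mpa_tab, freqs)
  }
  nonover <- nonoverlap_scan(haplotype_matrix(haplotypes), loci,
                             n_perm = n_perm,
                             seed = child_seed(seed, 202L))
  list(haplotypes = haplotypes, blocks_bc = blocks_bc, ceh = ceh,
       ceh_a = ceh_a, diversity = diversity, mpa = mpa_tab,
       abf = abf_tab, nonoverlap = nonover,
       segregation_inconsistencies = seg$inconsistencies)
}

#' Truncate every allele call of a cohort to a resolution
#'
#' @param cohort An `hla_cohort`.
#' @param resolution Fields to keep; `NULL` returns the cohort unchanged.
#' @return An `hla_cohort` with truncated calls (pairs re-canonicalized).
#' @export
truncate_cohort <- function(cohort, resolution = 2L) {
  if (is.null(resolution)) return(cohort)
  loci <- hla_loci(cohort)
  out <- as.data.frame(cohort)
  for (loc in loci) {
    for (col in locus_cols(loc)) {
      v <- out[[col]]
      ok <- !is.na(v) & v != ""
      v[ok] <- truncate_name(v[ok], resolution)
      out[[col]] <- v
    }
  }
  hla_cohort(out, loci)
}
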