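# Most-probable-ancestry (MPA) assignment and aggregate block frequencies
# (ABF): a haplotype/block is labelled with a continental ancestry when it
# reaches a threshold frequency (1% by convention) in a reference panel of
# that group; study-frequency mass is then aggregated per label.

ANCESTRY_GROUPS <- c("NativeAmerican", "European", "African", "Asian")

#' Construct a reference panel
#'
#' @param population Population name.
#' @param ancestry One of `NativeAmerican`, `European`, `African`, `Asian`,
#'   or `MixedAncestry`. Mixed-ancestry panels never confer an ancestry
#'   label by themselves; they are reported as supporting context only.
#' @param table `hla_haplotable` (haplotype- or allele-level frequencies).
#' @param sample_size Panel sample size n (2n chromosomes).
#' @return A list of class `reference_panel`.
#' @export
reference_panel <- function(population, ancestry, table, sample_size) {
  if (!ancestry %in% c(ANCESTRY_GROUPS, "MixedAncestry")) {
    stop("ancestry must be one of ",
         paste(c(ANCESTRY_GROUPS, "MixedAncestry"), collapse = ", "),
         call. = FALSE)
  }
  structure(list(population = population, ancestry = ancestry,
                 table = table, sample_size = sample_size),
            class = "reference_panel")
}

# frequency of a (two-field-truncated) haplotype in one panel, matching on
# the loci of the query block only
panel_frequency <- function(h, block_loci, panel, resolution = 2L) {
  tab <- panel$table
  panel_loci <- hla_loci(tab)
  if (!all(block_loci %in% panel_loci)) {
    stop("panel '", panel$population, "' lacks locus/loci: ",
         paste(setdiff(block_loci, panel_loci), collapse = ", "),
         call. = FALSE)
  }
  idx <- match(block_loci, panel_loci)
  parts <- strsplit(tab$haplotype, "~", fixed = TRUE)
  key <- vapply(parts, function(p) {
    hap_join(truncate_name(p[idx], resolution))
  }, character(1L))
  target <- hap_join(truncate_name(hap_split(h), resolution))
  sum(tab$frequency[key == target])
}

#' Assign most probable ancestry to haplotypes
#'
#' For each haplotype and each non-mixed ancestry group the maximum panel
#' frequency is computed (matching at two-field resolution on the block's
#' loci); groups reaching `threshold` are candidates and the candidate
#' with the highest maximum frequency wins (ties broken by the fixed
#' precedence NativeAmerican > European > African > Asian). A haplotype
#' reaching the threshold only in mixed-ancestry panels, or in no panel,
#' is `NotPreviouslyReported` for the four-group accounting (mixed-panel
#' support is still reported in `max_mixed_freq`).
#'
#' @param haplotypes Character vector of haplotype strings.
#' @param block_loci Loci of the haplotypes.
#' @param panels List of [reference_panel()] objects (non-empty).
#' @param threshold Panel frequency needed to support a label
#'   (default 0.01).
#' @param resolution Truncation used for matching (default 2 fields).
#' @return `data.frame`: `haplotype`, `ancestry`, `max_freq` (of the
#'   winning group), `max_mixed_freq`, plus one `freq_<group>` column per
#'   ancestry group.
#' @export
assign_mpa <- function(haplotypes, block_loci, panels, threshold = 0.01,
                       resolution = 2L) {
  if (!length(panels)) stop("no reference panels supplied", call. = FALSE)
  rows <- lapply(haplotypes, function(h) {
    by_group <- vapply(ANCESTRY_GROUPS, function(g) {
      fs <- vapply(Filter(function(p) p$ancestry == g, panels),
                   function(p) panel_frequency(h, block_loci, p, resolution),
                   numeric(1L))
      if (length(fs)) max(fs) else 0
    }, numeric(1L))
    mixed <- vapply(Filter(function(p) p$ancestry == "MixedAncestry",
                           panels),
                    function(p) panel_frequency(h, block_loci, p,
                                                resolution),
                    numeric(1L))
    max_mixed <- if (length(mixed)) max(mixed) else 0
    candidates <- ANCESTRY_GROUPS[by_group >= threshold]
    if (!length(candidates)) {
      label <- "NotPreviouslyReported"
      max_freq <- 0
    } else {
      best <- max(by_group[candidates])
      # max frequency wins; precedence order breaks exact ties
      label <- candidates[by_group[candidates] >= best - 1e-15][1L]
      max_freq <- by_group[[label]]
    }
    out <- data.frame(haplotype = h, ancestry = label, max_freq = max_freq,
                      max_mixed_freq = max_mixed, stringsAsFactors = FALSE)
    for (g in ANCESTRY_GROUPS) out[[paste0("freq_", g)]] <- by_group[[g]]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate block frequency per ancestry label
#'
#' `ABF(g)` is the summed study frequency of all blocks assigned label `g`;
#' the label sums conserve the total included block mass exactly.
#'
#' @param assignments `data.frame` from [assign_mpa()] (columns
#'   `haplotype`, `ancestry`).
#' @param frequencies Named numeric vector of study block frequencies,
#'   names matching `assignments$haplotype`.
#' @return Named numeric vector over
#'   `c(NativeAmerican, European, African, Asian, NotPreviouslyReported)`.
#' @export
abf <- function(assignments, frequencies) {
  f <- frequencies[assignments$haplotype]
  if (anyNA(f)) {
    stop("missing study frequency for haplotype(s): ",
         paste(assignments$haplotype[is.na(f)], collapse = ", "),
         call. = FALSE)
  }
  labels <- c(ANCESTRY_GROUPS, "NotPreviouslyReported")
  out <- vapply(labels, function(g) {
    sum(f[assignments$ancestry == g])
  }, numeric(1L))
  names(out) <- labels
  out
}
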