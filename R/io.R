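# Containers and delimited-text IO for cohorts, haplotype tables and
# reference panels. File dialect: UTF-8, comma- or tab-delimited
# (autodetected from the header line); "~" joins alleles in haplotype
# strings; writers emit 4-decimal frequencies, the convention of published
# HLA tables.

#' Construct a multi-locus haplotype frequency table
#'
#' The central container: one row per haplotype (alleles joined by `"~"`,
#' ordered as `loci`), a frequency in `[0, 1]` and, where known, an integer
#' count over `total_chromosomes = 2N` chromosomes.
#'
#' @param haplotype Character vector of haplotype strings.
#' @param frequency Numeric frequencies.
#' @param loci Character vector naming the loci, in haplotype order.
#' @param count Optional integer counts (NA allowed).
#' @param total_chromosomes Number of chromosomes (2N) the table describes.
#' @param complete If `TRUE` (default) frequencies must sum to 1 within
#'   `1e-6`; set `FALSE` for filtered/partial tables.
#' @return A `data.frame` of class `hla_haplotable` with attributes
#'   `loci` and `total_chromosomes`, sorted by descending frequency then
#'   haplotype string.
#' @export
hla_haplotable <- function(haplotype, frequency, loci, count = NULL,
                           total_chromosomes = NA_integer_,
                           complete = TRUE) {
  stopifnot(is.character(haplotype), is.numeric(frequency),
            length(haplotype) == length(frequency))
  if (anyDuplicated(haplotype)) {
    stop("duplicated haplotype strings in table", call. = FALSE)
  }
  if (any(frequency < -1e-12 | frequency > 1 + 1e-12)) {
    stop("haplotype frequencies must lie in [0, 1]", call. = FALSE)
  }
  n_loci <- lengths(strsplit(haplotype, "~", fixed = TRUE))
  if (length(haplotype) && any(n_loci != length(loci))) {
    stop("haplotype strings do not all have ", length(loci), " loci",
         call. = FALSE)
  }
  if (complete && length(frequency) &&
      abs(sum(frequency) - 1) > 1e-6) {
    stop("frequencies of a complete table must sum to 1 (got ",
         format(sum(frequency)), ")", call. = FALSE)
  }
  if (is.null(count)) count <- rep(NA_integer_, length(haplotype))
  if (!is.na(total_chromosomes)) {
    ok <- is.na(count) | abs(count / total_chromosomes - frequency) <=
      0.5 / total_chromosomes + 1e-9
    if (!all(ok)) {
      stop("count/total_chromosomes disagrees with frequency", call. = FALSE)
    }
  }
  out <- data.frame(haplotype = haplotype, frequency = frequency,
                    count = as.integer(round(count)),
                    stringsAsFactors = FALSE)
  ord <- order(-out$frequency, out$haplotype)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "loci") <- loci
  attr(out, "total_chromosomes") <- as.integer(total_chromosomes)
  class(out) <- c("hla_haplotable", "data.frame")
  out
}

#' @export
print.hla_haplotable <- function(x, ...) {
  cat("HLA haplotype table: ", nrow(x), " haplotypes over loci ",
      paste(attr(x, "loci"), collapse = "~"),
      if (!is.na(attr(x, "total_chromosomes")))
        paste0(" (2N = ", attr(x, "total_chromosomes"), ")"),
      "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Loci of a cohort or haplotype table
#' @param x An `hla_cohort` or `hla_haplotable`.
#' @return Character vector of locus names.
#' @export
hla_loci <- function(x) attr(x, "loci")

# column names holding the two allele calls of a locus
locus_cols <- function(locus) paste0(locus, c("_1", "_2"))

#' Construct a diploid genotype cohort
#'
#' One row per subject with two unordered allele calls per locus. The pair
#' order carries no phase information and is canonicalized (sorted) on
#' construction, so swapping a subject's two calls yields an identical
#' cohort.
#'
#' @param genotypes `data.frame` with columns `subject_id`, optionally
#'   `family_id` and `role` (`"father"`, `"mother"`, `"child"` or
#'   `"unrelated"`), and `<locus>_1`, `<locus>_2` per locus.
#' @param loci Loci the cohort is typed at.
#' @return A `data.frame` of class `hla_cohort` with attribute `loci`.
#' @export
hla_cohort <- function(genotypes, loci) {
  stopifnot(is.data.frame(genotypes))
  if (!"subject_id" %in% names(genotypes)) {
    stop("cohort needs a subject_id column", call. = FALSE)
  }
  if (anyDuplicated(genotypes$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(genotypes$subject_id[duplicated(genotypes$subject_id)]),
               collapse = ", "), call. = FALSE)
  }
  missing_cols <- character()
  for (loc in loci) {
    if (!all(locus_cols(loc) %in% names(genotypes))) {
      missing_cols <- c(missing_cols, loc)
    }
  }
  if (length(missing_cols)) {
    stop("cohort file is missing allele columns for locus/loci: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"family_id" %in% names(genotypes)) genotypes$family_id <- NA_character_
  if (!"role" %in% names(genotypes)) genotypes$role <- "unrelated"
  genotypes$subject_id <- as.character(genotypes$subject_id)
  genotypes$family_id <- as.character(genotypes$family_id)
  genotypes$role <- as.character(genotypes$role)
  genotypes$role[is.na(genotypes$role) | genotypes$role == ""] <- "unrelated"
  # canonicalize the unordered pair at every locus
  for (loc in loci) {
    cols <- locus_cols(loc)
    a <- as.character(genotypes[[cols[1L]]])
    b <- as.character(genotypes[[cols[2L]]])
    swap <- !is.na(a) & !is.na(b) & b < a
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    genotypes[[cols[1L]]] <- a
    genotypes[[cols[2L]]] <- b
  }
  keep <- c("subject_id", "family_id", "role",
            unlist(lapply(loci, locus_cols)))
  out <- genotypes[, keep, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "loci") <- loci
  class(out) <- c("hla_cohort", "data.frame")
  out
}

#' @export
`[.hla_cohort` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "loci") <- attr(x, "loci")
    class(out) <- class(x)
  }
  out
}

#' Subjects with a missing call at any configured locus
#' @param cohort An `hla_cohort`.
#' @return Character vector of subject ids (possibly empty).
#' @export
incomplete_subjects <- function(cohort) {
  loci <- hla_loci(cohort)
  cols <- unlist(lapply(loci, locus_cols))
  bad <- apply(is.na(cohort[, cols, drop = FALSE]) |
                 cohort[, cols, drop = FALSE] == "", 1L, any)
  as.character(cohort$subject_id[bad])
}

# detect "," vs tab from the header line
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a genotype cohort file
#'
#' Delimited text (comma or tab, autodetected) with columns `subject_id`,
#' optional `family_id`/`role`, and `<locus>_1`, `<locus>_2` per requested
#' locus. Subjects with a missing call at any locus are flagged via a
#' message, never silently dropped.
#'
#' @param path File path.
#' @param loci Loci to read.
#' @return An `hla_cohort`.
#' @export
read_cohort <- function(path, loci) {
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "#", fileEncoding = "UTF-8")
  cohort <- hla_cohort(raw, loci)
  message("read ", nrow(cohort), " genotype records from ", path)
  inc <- incomplete_subjects(cohort)
  if (length(inc)) {
    message(length(inc), " subject(s) with a missing locus: ",
            paste(utils::head(inc, 5L), collapse = ", "),
            if (length(inc) > 5L) ", ...")
  }
  cohort
}

#' Write a genotype cohort file
#' @param cohort An `hla_cohort`.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  utils::write.table(as.data.frame(cohort), path, sep = sep,
                     row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a haplotype/allele frequency table file
#'
#' Columns: `haplotype` (alleles joined by `"~"`), `frequency`, optional
#' `count`.
#'
#' @param path File path.
#' @param loci Loci of the haplotypes in the file.
#' @param total_chromosomes Optional 2N for the table.
#' @param complete Passed to [hla_haplotable()].
#' @return An `hla_haplotable`.
#' @export
read_haplotable <- function(path, loci, total_chromosomes = NA_integer_,
                            complete = FALSE) {
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#", fileEncoding = "UTF-8")
  if (!all(c("haplotype", "frequency") %in% names(raw))) {
    stop("frequency table needs 'haplotype' and 'frequency' columns",
         call. = FALSE)
  }
  hla_haplotable(as.character(raw$haplotype), as.numeric(raw$frequency),
                 loci = loci,
                 count = if ("count" %in% names(raw)) raw$count else NULL,
                 total_chromosomes = total_chromosomes, complete = complete)
}

#' Write a haplotype frequency table file
#'
#' Frequencies are printed with 4 decimals, the convention of published HLA
#' tables; counts are written when present.
#'
#' @param table An `hla_haplotable`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_haplotable <- function(table, path, sep = ",") {
  out <- data.frame(haplotype = table$haplotype,
                    frequency = sprintf("%.4f", table$frequency),
                    stringsAsFactors = FALSE)
  if (!all(is.na(table$count))) out$count <- table$count
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
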