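#' @keywords internal
"_PACKAGE"

# Recognized HLA loci. DRB3, DRB4 and DRB5 are carried as a single composite
# locus "DRB3/4/5": the three genes segregate as alternative alleles of one
# chromosomal slot and population tables list them in one column, with the
# structural absence of all three ("NULL") as an additional allele-like state.
HLA_LOCI <- c("A", "B", "C", "DRB1", "DRB3/4/5", "DQA1", "DQB1",
              "DPA1", "DPB1")

DRB345_GENES <- c("DRB3", "DRB4", "DRB5")

#' Construct an HLA allele object
#'
#' The atom of every table in the package: a locus, one to four numeric name
#' fields (leading zeros preserved), an optional expression/annotation suffix
#' (`N`, `L`, `e1`, ...), and a flag for the structural absence of the
#' DRB3/4/5 gene.
#'
#' @param locus One of A, B, C, DRB1, DRB3/4/5, DQA1, DQB1, DPA1, DPB1.
#' @param fields Character vector of 1-4 numeric name fields.
#' @param suffix Optional expression suffix, `NA` for none.
#' @param gene For the composite DRB3/4/5 locus, which gene the allele
#'   belongs to; for all other loci this equals the locus.
#' @param is_absent `TRUE` for the structural absence of a DRB3/4/5 gene.
#' @return An object of class `hla_allele`.
#' @seealso [parse_allele()], [format_allele()], [truncate_allele()]
#' @export
hla_allele <- function(locus, fields = character(), suffix = NA_character_,
                       gene = NULL, is_absent = FALSE) {
  if (!locus %in% HLA_LOCI) {
    stop("unknown HLA locus: '", locus, "'", call. = FALSE)
  }
  if (is.null(gene)) gene <- locus
  if (!is_absent && length(fields) < 1L) {
    stop("an allele needs at least one name field unless it is absent",
         call. = FALSE)
  }
  if (length(fields) > 0L && !all(grepl("^[0-9]+$", fields))) {
    stop("malformed allele name field(s): ",
         paste(fields[!grepl("^[0-9]+$", fields)], collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(locus = locus, gene = gene, fields = as.character(fields),
         suffix = suffix, is_absent = isTRUE(is_absent)),
    class = "hla_allele"
  )
}

#' Parse an HLA allele name
#'
#' Accepts names such as `"A*31:01:02:01"`, `"DRB4*01:03:02e1"` or
#' `"A*24:02:01:02L"` (an optional space before the suffix is tolerated).
#' The token `"NULL"` (or `"ABSENT"`) is accepted for the composite
#' DRB3/4/5 locus and denotes the structural absence of the gene.
#'
#' @param text Allele name string.
#' @param locus Optional locus context; required to interpret `"NULL"` and
#'   checked against the name's own prefix otherwise.
#' @return An `hla_allele`.
#' @examples
#' parse_allele("A*31:01:02:01")
#' parse_allele("NULL", locus = "DRB3/4/5")
#' @export
parse_allele <- function(text, locus = NULL) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("allele name must be a non-empty string", call. = FALSE)
  }
  text <- trimws(text)
  if (toupper(text) %in% c("NULL", "ABSENT")) {
    if (is.null(locus)) locus <- "DRB3/4/5"
    if (locus != "DRB3/4/5") {
      stop("'NULL' allele is only meaningful at the DRB3/4/5 locus, not ",
           locus, call. = FALSE)
    }
    return(hla_allele("DRB3/4/5", is_absent = TRUE))
  }
  if (!grepl("*", text, fixed = TRUE)) {
    stop("malformed allele name (no '*' separator): '", text, "'",
         call. = FALSE)
  }
  parts <- strsplit(text, "*", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) {
    stop("malformed allele name: '", text, "'", call. = FALSE)
  }
  gene <- toupper(trimws(parts[1L]))
  gene_locus <- if (gene %in% DRB345_GENES) "DRB3/4/5" else gene
  if (!gene_locus %in% HLA_LOCI) {
    stop("unknown HLA locus prefix: '", parts[1L], "'", call. = FALSE)
  }
  if (!is.null(locus) && locus != gene_locus) {
    stop("allele '", text, "' does not belong to locus ", locus,
         call. = FALSE)
  }
  name <- gsub("[[:space:]]", "", parts[2L])
  # strip a trailing expression/annotation suffix (N, L, Q, S, C, A, e1, ...)
  m <- regmatches(name, regexpr("[A-Za-z][0-9]*$", name))
  suffix <- NA_character_
  if (length(m) == 1L && nzchar(m)) {
    suffix <- m
    name <- substr(name, 1L, nchar(name) - nchar(m))
  }
  fields <- strsplit(name, ":", fixed = TRUE)[[1L]]
  if (length(fields) < 1L || length(fields) > 4L ||
      !all(grepl("^[0-9]+$", fields))) {
    stop("malformed allele name field(s) in '", text, "'", call. = FALSE)
  }
  hla_allele(gene_locus, fields = fields, suffix = suffix, gene = gene)
}

#' Format an HLA allele back to its name
#'
#' Inverse of [parse_allele()]: `format_allele(parse_allele(x)) == x` for
#' well-formed names (suffixes are emitted without a separating space).
#' Absent DRB3/4/5 genes format as `"NULL"`.
#'
#' @param a An `hla_allele`.
#' @return Allele name string.
#' @export
format_allele <- function(a) {
  stopifnot(inherits(a, "hla_allele"))
  if (a$is_absent) return("NULL")
  out <- paste0(a$gene, "*", paste(a$fields, collapse = ":"))
  if (!is.na(a$suffix)) out <- paste0(out, a$suffix)
  out
}

#' @export
format.hla_allele <- function(x, ...) format_allele(x)

#' @export
print.hla_allele <- function(x, ...) {
  cat("<hla_allele> ", format_allele(x), " [", x$locus, "]\n", sep = "")
  invisible(x)
}

#' Truncate an allele to a lower typing resolution
#'
#' Keeps the first `min(n, length(fields))` name fields. The expression
#' suffix is dropped whenever fields are removed (it annotates the full-
#' resolution name). Absence passes through unchanged: it has no resolution.
#'
#' @param a An `hla_allele`.
#' @param n Number of fields to keep (>= 1).
#' @return An `hla_allele` with at most `n` fields.
#' @export
truncate_allele <- function(a, n = 2L) {
  stopifnot(inherits(a, "hla_allele"))
  if (!is.numeric(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (a$is_absent) return(a)
  keep <- min(as.integer(n), length(a$fields))
  suffix <- if (keep < length(a$fields)) NA_character_ else a$suffix
  hla_allele(a$locus, fields = a$fields[seq_len(keep)], suffix = suffix,
             gene = a$gene)
}

#' Truncate an allele name string to a lower resolution
#'
#' Vectorized string-level convenience over [truncate_allele()], used
#' everywhere frequencies are aggregated onto two-field names. By default
#' expression suffixes are dropped so that e.g. a low-expression variant and
#' its normally expressed sub-alleles aggregate onto the same two-field
#' parent (configurable).
#'
#' @param x Character vector of allele names (`"NULL"` allowed).
#' @param n Fields to keep.
#' @param keep_suffix Retain the expression suffix when no field is dropped.
#' @return Character vector of truncated names.
#' @examples
#' truncate_name(c("A*31:01:02:01", "A*24:02:01:02L"), 2)
#' @export
truncate_name <- function(x, n = 2L, keep_suffix = FALSE) {
  vapply(x, function(nm) {
    a <- parse_allele(nm)
    a <- truncate_allele(a, n)
    if (!keep_suffix) a$suffix <- NA_character_
    format_allele(a)
  }, character(1L), USE.NAMES = FALSE)
}

# --- haplotype string helpers -----------------------------------------------

#' Join allele names into a haplotype string
#'
#' `"~"` is the conventional separator in published HLA block tables.
#' @param alleles Character vector of allele names, ordered by locus.
#' @return Single haplotype string.
#' @export
hap_join <- function(alleles) paste(alleles, collapse = "~")

#' Split a haplotype string into its allele names
#' @param h Haplotype string (alleles joined by `"~"`).
#' @return Character vector of allele names.
#' @export
hap_split <- function(h) strsplit(h, "~", fixed = TRUE)[[1L]]

#' Truncate every allele of haplotype strings to a resolution
#' @param h Character vector of haplotype strings.
#' @inheritParams truncate_name
#' @return Character vector of truncated haplotype strings.
#' @export
hap_truncate <- function(h, n = 2L, keep_suffix = FALSE) {
  vapply(h, function(x) {
    hap_join(truncate_name(hap_split(x), n = n, keep_suffix = keep_suffix))
  }, character(1L), USE.NAMES = FALSE)
}
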