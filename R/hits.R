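# Domain-hit tables: one row per profile match on one gene, the atom of all
# classification. No cutoff filtering happens at read time (see
# apply_cutoffs()), so the same table can be reused under different
# registries.

empty_hits <- function() {
  data.frame(gene_id = character(0), profile = character(0),
             bitscore = numeric(0), evalue = numeric(0),
             ali_start = integer(0), ali_end = integer(0),
             stringsAsFactors = FALSE)
}

#' Read a domain-hit table
#'
#' Two dialects are supported. `"domtblout"` is HMMER3's per-domain tabular
#' output (`hmmsearch --domtblout`): whitespace-separated, `#` comment
#' lines, target name in column 1, query (profile) name in column 4, the
#' per-domain independent E-value and bitscore in columns 13 and 14, and
#' 1-based inclusive alignment coordinates in columns 18-19 (stored 0-based
#' half-open). `"tsv"` is a simple tab-separated table with columns
#' `gene_id`, `profile`, `bitscore`, `evalue` (header optional; `#`
#' comments skipped).
#'
#' @param path Path to the hit table.
#' @param dialect `"domtblout"` or `"tsv"`.
#' @return A data frame with columns `gene_id`, `profile`, `bitscore`,
#'   `evalue`, `ali_start`, `ali_end` (alignment columns `NA` for tsv).
#' @export
read_domain_hits <- function(path, dialect = c("domtblout", "tsv")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) return(empty_hits())

  if (dialect == "domtblout") {
    rows <- lapply(seq_along(lines), function(i) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) < 19L) {
        stop(sprintf("malformed domtblout row at line %d: expected >= 19 columns, found %d",
                     line_no[i], length(f)), call. = FALSE)
      }
      vals <- suppressWarnings(as.numeric(f[c(13L, 14L, 18L, 19L)]))
      if (anyNA(vals)) {
        stop(sprintf("malformed domtblout row at line %d: non-numeric score/coordinate",
                     line_no[i]), call. = FALSE)
      }
      list(gene_id = f[1], profile = f[4], evalue = vals[1],
           bitscore = vals[2], ali_start = as.integer(vals[3]) - 1L,
           ali_end = as.integer(vals[4]))
    })
  } else {
    rows <- lapply(seq_along(lines), function(i) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      f <- trimws(f)
      if (length(f) < 4L) {
        # tolerate whitespace-separated tsv fixtures
        f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      }
      if (length(f) < 4L) {
        stop(sprintf("malformed tsv hit row at line %d: expected 4 columns",
                     line_no[i]), call. = FALSE)
      }
      if (i == 1L && f[1] == "gene_id") return(NULL)  # header
      vals <- suppressWarnings(as.numeric(f[3:4]))
      if (anyNA(vals)) {
        stop(sprintf("malformed tsv hit row at line %d: non-numeric bitscore/evalue",
                     line_no[i]), call. = FALSE)
      }
      list(gene_id = f[1], profile = f[2], evalue = vals[2],
           bitscore = vals[1], ali_start = NA_integer_,
           ali_end = NA_integer_)
    })
    rows <- Filter(Negate(is.null), rows)
  }
  if (length(rows) == 0L) return(empty_hits())
  hits <- data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    profile = vapply(rows, `[[`, "", "profile"),
    bitscore = vapply(rows, `[[`, 0, "bitscore"),
    evalue = vapply(rows, `[[`, 0, "evalue"),
    ali_start = vapply(rows, `[[`, 0L, "ali_start"),
    ali_end = vapply(rows, `[[`, 0L, "ali_end"),
    stringsAsFactors = FALSE)
  if (any(hits$evalue < 0)) {
    stop("negative e-value in hit table", call. = FALSE)
  }
  if (any(!is.finite(hits$bitscore))) {
    stop("non-finite bitscore in hit table", call. = FALSE)
  }
  bad <- !is.na(hits$ali_start) & !is.na(hits$ali_end) &
    hits$ali_start >= hits$ali_end
  if (any(bad)) {
    stop("alignment coordinates must satisfy start < end", call. = FALSE)
  }
  hits
}

#' Write a domain-hit table in the tsv dialect
#'
#' Inverse of `read_domain_hits(..., dialect = "tsv")` on the
#' (`gene_id`, `profile`, `bitscore`, `evalue`) columns.
#'
#' @param hits A hit data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  out <- hits[, c("gene_id", "profile", "bitscore", "evalue")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read curated truth labels
#'
#' Truth labels are a TSV with columns `contig_id`, `start`, `end` (0-based
#' half-open span of the labelled region, `NA` allowed when a contig holds
#' a single region) and `is_metallophore` (logical), plus free-text extras.
#'
#' @param path Path to a truth TSV.
#' @return A data frame.
#' @export
read_truth_labels <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#",
                         quote = "")
  stopifnot(all(c("contig_id", "is_metallophore") %in% names(x)))
  x$is_metallophore <- as.logical(x$is_metallophore)
  key <- if (all(c("start", "end") %in% names(x))) {
    paste(x$contig_id, x$start, x$end, sep = ":")
  } else {
    x$contig_id
  }
  if (anyDuplicated(key)) {
    stop("duplicate region_key in truth labels", call. = FALSE)
  }
  x
}
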