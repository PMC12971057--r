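# GenBank flat-file reading and writing.
#
# Internal coordinate convention everywhere in the package: 0-based,
# half-open [start, end), start < end. GenBank (and GFF3) are 1-based
# inclusive; the conversion happens only at the file boundary, here and in
# write_outputs(), so a round-trip is the identity.

#' Construct a contig record
#'
#' @param contig_id Contig name.
#' @param length Contig length in nucleotides.
#' @param genes Data frame with columns `gene_id`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), `translation` (may be `NA`).
#' @param sequence Optional nucleotide sequence string (length must match).
#' @return A `contig_record`.
#' @export
contig_record <- function(contig_id, length, genes = NULL, sequence = NULL) {
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        translation = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "start", "end", "strand") %in% names(genes)))
  if (!"translation" %in% names(genes)) genes$translation <- NA_character_
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  if (nrow(genes) > 0L) {
    if (any(genes$start < 0L | genes$start >= genes$end |
            genes$end > length)) {
      stop(sprintf("contig %s: gene coordinates out of [0, %d) bounds",
                   contig_id, length), call. = FALSE)
    }
    if (anyDuplicated(genes$gene_id)) {
      stop(sprintf("contig %s: duplicate gene_id", contig_id), call. = FALSE)
    }
  }
  structure(list(contig_id = contig_id, length = as.integer(length),
                 genes = genes, sequence = sequence),
            class = "contig_record")
}

#' @export
print.contig_record <- function(x, ...) {
  cat(sprintf("<contig_record> %s: %d bp, %d genes\n",
              x$contig_id, x$length, nrow(x$genes)))
  invisible(x)
}

#' Read an annotated genome from a GenBank flat file
#'
#' Parses a (possibly multi-record) GenBank flat file into one
#' `contig_record` per LOCUS. Every CDS feature becomes a gene; 1-based
#' inclusive GenBank locations are converted to 0-based half-open internal
#' coordinates, `complement(...)` sets the strand, and compound
#' `join(...)`/`order(...)` locations collapse to their outermost bounds.
#' Genes are sorted by start. A CDS without a `locus_tag` or `protein_id`
#' qualifier gets a synthesized id `<contig>_cdsN` with a warning. A count
#' check guarantees no CDS is silently dropped.
#'
#' @param path Path to a GenBank file.
#' @return A list of `contig_record` objects (empty for an empty file).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) return(list())
  locus_idx <- grep("^LOCUS ", lines)
  if (length(locus_idx) == 0L) {
    stop(sprintf("GenBank format error in '%s': no LOCUS line found", path),
         call. = FALSE)
  }
  end_idx <- grep("^//\\s*$", lines)
  contigs <- vector("list", length(locus_idx))
  for (k in seq_along(locus_idx)) {
    rec_start <- locus_idx[k]
    rec_end <- end_idx[end_idx >= rec_start][1]
    if (is.na(rec_end)) rec_end <- length(lines)
    contigs[[k]] <- parse_genbank_record(lines[rec_start:rec_end])
  }
  contigs
}

parse_genbank_record <- function(rec) {
  locus <- strsplit(trimws(rec[1]), "\\s+")[[1]]
  if (length(locus) < 3L || is.na(suppressWarnings(as.integer(locus[3])))) {
    stop(sprintf("GenBank format error in record '%s': malformed LOCUS line",
                 paste(locus[-1], collapse = " ")), call. = FALSE)
  }
  contig_id <- locus[2]
  contig_len <- as.integer(locus[3])

  feat_start <- grep("^FEATURES", rec)
  gene_rows <- list()
  n_cds <- 0L
  n_synth <- 0L
  if (length(feat_start) == 1L) {
    i <- feat_start + 1L
    # collect (key, block-of-lines) for each feature
    while (i <= length(rec)) {
      line <- rec[i]
      if (grepl("^(ORIGIN|CONTIG|BASE COUNT|//)", line)) break
      m <- regmatches(line, regexec("^ {5}(\\S+)\\s+(\\S.*)$", line))[[1]]
      if (length(m) == 3L && !startsWith(trimws(line), "/")) {
        key <- m[2]
        block <- m[3]
        j <- i + 1L
        while (j <= length(rec) &&
               grepl("^ {6,}\\S", rec[j]) &&
               !grepl("^ {5}\\S", rec[j]) &&
               !grepl("^(ORIGIN|CONTIG|BASE COUNT|//)", rec[j])) {
          block <- c(block, trimws(rec[j]))
          j <- j + 1L
        }
        if (key == "CDS") {
          n_cds <- n_cds + 1L
          g <- parse_cds_block(block, contig_id, n_cds)
          if (is.null(g$gene_id)) {
            n_synth <- n_synth + 1L
            g$gene_id <- sprintf("%s_cds%d", contig_id, n_cds)
          }
          gene_rows[[length(gene_rows) + 1L]] <- g
        }
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }
  if (n_synth > 0L) {
    warning(sprintf("contig %s: %d CDS feature(s) without locus_tag/protein_id; ids synthesized",
                    contig_id, n_synth), call. = FALSE)
  }
  genes <- if (length(gene_rows) == 0L) NULL else {
    data.frame(
      gene_id = vapply(gene_rows, `[[`, "", "gene_id"),
      start = vapply(gene_rows, `[[`, 0L, "start"),
      end = vapply(gene_rows, `[[`, 0L, "end"),
      strand = vapply(gene_rows, `[[`, "", "strand"),
      translation = vapply(gene_rows, function(g) {
        if (is.null(g$translation)) NA_character_ else g$translation
      }, ""),
      stringsAsFactors = FALSE)
  }
  ctg <- contig_record(contig_id, contig_len, genes)
  if (nrow(ctg$genes) != n_cds) {
    stop(sprintf("contig %s: parsed %d genes from %d CDS features",
                 contig_id, nrow(ctg$genes), n_cds), call. = FALSE)
  }
  ctg
}

parse_cds_block <- function(block, contig_id, ordinal) {
  # location: first element plus any leading lines that are not qualifiers
  qual_at <- which(startsWith(block, "/"))
  loc_end <- if (length(qual_at) > 0L) qual_at[1] - 1L else length(block)
  loc <- paste(block[seq_len(loc_end)], collapse = "")
  loc <- gsub("\\s", "", loc)
  strand <- if (grepl("complement", loc, fixed = TRUE)) "-" else "+"
  nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
  if (length(nums) == 0L) {
    stop(sprintf("contig %s: CDS %d has unparseable location '%s'",
                 contig_id, ordinal, loc), call. = FALSE)
  }
  nums <- as.integer(nums)
  start1 <- min(nums)  # 1-based inclusive outermost bounds
  end1 <- max(nums)
  # qualifiers (each may span multiple block lines, already trimmed)
  quals <- list()
  if (length(qual_at) > 0L) {
    starts <- qual_at
    stops <- c(qual_at[-1] - 1L, length(block))
    for (q in seq_along(starts)) {
      qtext <- paste(block[starts[q]:stops[q]], collapse = "")
      m <- regmatches(qtext, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?', qtext))[[1]]
      if (length(m) == 3L) quals[[m[2]]] <- m[3]
    }
  }
  gene_id <- quals$locus_tag
  if (is.null(gene_id)) gene_id <- quals$protein_id
  list(gene_id = gene_id, start = start1 - 1L, end = end1, strand = strand,
       translation = quals$translation)
}

#' Write contig records as a GenBank flat file
#'
#' The inverse of [read_genbank()] for the feature subset this package uses
#' (LOCUS, CDS features with `locus_tag` and `translation` qualifiers,
#' ORIGIN sequence). Internal 0-based half-open coordinates become 1-based
#' inclusive. When a contig carries no `sequence`, a deterministic filler
#' sequence is written. Output is byte-stable for identical input.
#'
#' @param contigs A list of `contig_record` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(contigs, path) {
  con <- file(path, open = "wb")  # "wb": fixed newlines across platforms
  on.exit(close(con))
  out <- character(0)
  for (ctg in contigs) {
    stopifnot(inherits(ctg, "contig_record"))
    out <- c(out, sprintf("LOCUS       %-16s %d bp    DNA     linear   BCT 01-JAN-2026",
                          ctg$contig_id, ctg$length))
    out <- c(out, "DEFINITION  synthetic contig.")
    out <- c(out, "FEATURES             Location/Qualifiers")
    out <- c(out, sprintf("     source          1..%d", ctg$length))
    g <- ctg$genes
    for (i in seq_len(nrow(g))) {
      loc <- sprintf("%d..%d", g$start[i] + 1L, g$end[i])
      if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      out <- c(out, sprintf("     CDS             %s", loc))
      out <- c(out, sprintf("                     /locus_tag=\"%s\"", g$gene_id[i]))
      if (!is.na(g$translation[i])) {
        out <- c(out, sprintf("                     /translation=\"%s\"",
                              g$translation[i]))
      }
    }
    seq <- ctg$sequence
    if (is.null(seq)) {
      seq <- paste(rep_len(c("a", "c", "g", "t"), ctg$length), collapse = "")
    }
    out <- c(out, "ORIGIN")
    pos <- seq(1L, nchar(seq), by = 60L)
    for (p in pos) {
      chunk <- substr(seq, p, min(p + 59L, nchar(seq)))
      groups <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", p, paste(groups, collapse = " ")))
    }
    out <- c(out, "//")
  }
  writeLines(out, con)
  invisible(path)
}
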