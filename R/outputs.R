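#' Write detection outputs
#'
#' Writes three files into `dest`: `regions.gff3` (1-based inclusive GFF3,
#' feature type `region`, attributes `product` =
#' `NRP-metallophore`/`NRPS`, `completeness` and semicolon-joined sorted
#' `chelators`), `regions.tsv` (one row per region, ordered by contig and
#' start), and `results.json` (full machine-readable results with sorted
#' keys). Output is byte-stable for identical input.
#'
#' @param detection A `metallophore_detection` object from [detect()].
#' @param dest Destination directory (created if missing).
#' @return Character vector of the three file paths, invisibly.
#' @export
write_outputs <- function(detection, dest) {
  stopifnot(inherits(detection, "metallophore_detection"))
  if (!dir.exists(dest)) {
    ok <- dir.create(dest, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dest)) {
      stop("destination not writable: ", dest, call. = FALSE)
    }
  }
  df <- as.data.frame(detection)
  ord <- order(df$contig_id, df$start)
  df <- df[ord, , drop = FALSE]

  gff_path <- file.path(dest, "regions.gff3")
  tsv_path <- file.path(dest, "regions.tsv")
  json_path <- file.path(dest, "results.json")

  if (nrow(df) == 0L) {
    writeLines("##gff-version 3", gff_path)
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = df$contig_id,
      ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
      strand = "*")
    S4Vectors::mcols(gr)$source <- "metallominer"
    S4Vectors::mcols(gr)$type <- "region"
    S4Vectors::mcols(gr)$ID <- df$region_id
    S4Vectors::mcols(gr)$product <- ifelse(df$ensemble, "NRP-metallophore",
                                           "NRPS")
    S4Vectors::mcols(gr)$completeness <- ifelse(df$complete, "complete",
                                                "partial")
    S4Vectors::mcols(gr)$chelators <- ifelse(nzchar(df$chelators),
                                             df$chelators, "none")
    rtracklayer::export.gff3(gr, gff_path)
    # drop the run-date pragma: outputs must be byte-stable given the same
    # inputs
    gff <- readLines(gff_path)
    writeLines(gff[!startsWith(gff, "##date")], gff_path)
  }

  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  payload <- lapply(detection$results[ord], function(r) {
    r[sort(names(r))]
  })
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(gff_path, tsv_path, json_path))
}
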