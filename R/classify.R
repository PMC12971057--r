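# Region classification: the chelator-based rule, the chelator-group
# profile, the two-of-three transporter criterion, and the either/or
# ensemble.

TRANSPORTER_FAMILIES <- c("PF00593", "PF01032", "PF01497")

#' Classify a region with the chelator-based rule
#'
#' Evaluates the detection rule on the region's significant hits and, when
#' satisfied, derives the chelator-group profile from the triggering
#' identifiers via the registry's `category` column. Profiles whose
#' category is a chelating group (catechol, salicylate, hydroxamate,
#' beta-OHAsp, beta-OHHis, graminine, Dmaq, pyoverdine-chromophore)
#' contribute that group; the metallophore-specific NRPS domain markers
#' (VibH-like, tandem Cy) contribute the `NRPS-domain-marker` group; core
#' NRPS domains contribute nothing. Identifiers on vetoed branches (e.g. an
#' ornithine monooxygenase next to KtzT) never trigger and so never
#' contribute to the profile.
#'
#' @param region A `region`.
#' @param sig_hits Named list gene_id -> significant profiles (whole
#'   genome or contig; automatically restricted to the region's members).
#' @param rule A `rule_expr`.
#' @param registry A `profile_registry`.
#' @return A list with `satisfied` (logical), `groups` (sorted character
#'   vector, empty when unsatisfied) and `triggering` (named list
#'   group -> profiles).
#' @export
classify_chelator_rule <- function(region, sig_hits,
                                   rule = nrp_metallophore_rule(),
                                   registry = default_registry()) {
  registry <- as_profile_registry(registry)
  validate_rule_registry(rule, registry)
  region_hits <- sig_hits[intersect(names(sig_hits), region$member_gene_ids)]
  verdict <- evaluate_rule(rule, region_hits)
  if (!verdict$satisfied) {
    return(list(satisfied = FALSE, groups = character(0),
                triggering = list()))
  }
  cats <- registry_lookup(registry, verdict$triggering, "category")
  in_group <- cats %in% CHELATOR_GROUPS
  groups <- sort(unique(cats[in_group]))
  triggering <- lapply(stats::setNames(groups, groups), function(gr) {
    sort(verdict$triggering[in_group & cats == gr])
  })
  list(satisfied = TRUE, groups = groups, triggering = triggering)
}

#' Classify a region with the transporter criterion
#'
#' A region is transporter-positive iff at least two of the three
#' siderophore-associated Pfam transporter families -- PF00593
#' (TonB-dependent receptor), PF01032 (FecCD transmembrane transporter) and
#' PF01497 (periplasmic binding protein) -- have a significant hit on some
#' gene of the region. Families are counted distinctly: three genes hitting
#' the same family count once.
#'
#' @param region A `region`.
#' @param sig_hits Named list gene_id -> significant profiles.
#' @param families Character vector of transporter family names.
#' @return Logical.
#' @export
classify_transporter_rule <- function(region, sig_hits,
                                      families = TRANSPORTER_FAMILIES) {
  region_hits <- sig_hits[intersect(names(sig_hits), region$member_gene_ids)]
  present <- intersect(families, unlist(region_hits, use.names = FALSE))
  length(present) >= 2L
}

#' Either/or ensemble of the two classifiers
#'
#' @param chelator Logical verdict of the chelator-based rule.
#' @param transporter Logical verdict of the transporter criterion.
#' @return Logical OR of the two.
#' @export
classify_ensemble <- function(chelator, transporter) {
  chelator | transporter
}

#' Detect and classify NRP metallophore BGC regions
#'
#' The full pipeline: filter hits by registry cutoffs, find anchor genes on
#' each contig, assemble candidate regions, flag completeness, and classify
#' every region with the chelator-based rule, the two-of-three transporter
#' criterion, and their either/or ensemble. Classification is fully
#' deterministic.
#'
#' @param contigs A list of `contig_record` objects (see [read_genbank()]).
#' @param hits A raw domain-hit data frame (see [read_domain_hits()]).
#' @param registry A `profile_registry`.
#' @param rule A `rule_expr`.
#' @param params A [region_params()] list.
#' @return A `metallophore_detection` object: list with `regions` (list of
#'   `region`), `results` (list of per-region classification records), and
#'   the inputs used. `as.data.frame()` gives one row per region.
#' @examples
#' bench <- benchmark_set(3, seed = 1)
#' det <- detect(bench$contigs, bench$hits)
#' summary(det)
#' @export
detect <- function(contigs, hits, registry = default_registry(),
                   rule = nrp_metallophore_rule(), params = region_params()) {
  registry <- as_profile_registry(registry)
  if (inherits(contigs, "contig_record")) contigs <- list(contigs)
  sig <- apply_cutoffs(hits, registry)
  regions <- list()
  results <- list()
  for (ctg in contigs) {
    anchors <- find_anchor_genes(ctg$genes, sig, rule)
    regs <- build_regions(ctg, anchors, params)
    for (reg in regs) {
      chel <- classify_chelator_rule(reg, sig, rule, registry)
      trans <- classify_transporter_rule(reg, sig)
      res <- list(region_id = reg$region_id, contig_id = reg$contig_id,
                  start = reg$start, end = reg$end,
                  complete = reg$complete,
                  chelator_rule = chel$satisfied,
                  transporter_rule = trans,
                  ensemble = classify_ensemble(chel$satisfied, trans),
                  groups = chel$groups,
                  triggering = chel$triggering)
      regions[[length(regions) + 1L]] <- reg
      results[[length(results) + 1L]] <- res
    }
  }
  ord <- order(vapply(results, `[[`, "", "contig_id"),
               vapply(results, `[[`, 0L, "start"))
  structure(list(regions = regions[ord], results = results[ord],
                 registry = registry, rule = rule, params = params),
            class = "metallophore_detection")
}

#' @export
as.data.frame.metallophore_detection <- function(x, ...) {
  rs <- x$results
  data.frame(
    region_id = vapply(rs, `[[`, "", "region_id"),
    contig_id = vapply(rs, `[[`, "", "contig_id"),
    start = vapply(rs, `[[`, 0L, "start"),
    end = vapply(rs, `[[`, 0L, "end"),
    complete = vapply(rs, `[[`, NA, "complete"),
    chelator_rule = vapply(rs, `[[`, NA, "chelator_rule"),
    transporter_rule = vapply(rs, `[[`, NA, "transporter_rule"),
    ensemble = vapply(rs, `[[`, NA, "ensemble"),
    chelators = vapply(rs, function(r) paste(r$groups, collapse = ";"), ""),
    stringsAsFactors = FALSE)
}

#' @export
print.metallophore_detection <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<metallophore_detection> %d region(s), %d metallophore-positive (ensemble)\n",
              nrow(df), sum(df$ensemble)))
  if (nrow(df) > 0L) print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.metallophore_detection <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("Regions: %d (%d complete, %d partial)\n", nrow(df),
              sum(df$complete), sum(!df$complete)))
  cat(sprintf("Chelator rule positive:  %d\n", sum(df$chelator_rule)))
  cat(sprintf("Transporter rule positive: %d\n", sum(df$transporter_rule)))
  cat(sprintf("Ensemble positive:       %d\n", sum(df$ensemble)))
  groups <- unlist(lapply(object$results, `[[`, "groups"))
  if (length(groups) > 0L) {
    tab <- sort(table(groups), decreasing = TRUE)
    cat("Chelator groups:", paste(sprintf("%s=%d", names(tab), tab),
                                  collapse = ", "), "\n")
  }
  invisible(df)
}
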