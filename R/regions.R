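# Candidate BGC region assembly: anchor genes, distance merging,
# neighborhood extension, and contig-edge completeness.

#' Region-building parameters
#'
#' `merge_distance` is the maximum nucleotide gap between anchor gene spans
#' for them to share one region (transitively); `neighborhood` is the
#' extension added on both sides of the merged anchor span. Both default to
#' 20 kb, the usual NRPS-region convention.
#'
#' @param merge_distance Nucleotides, >= 0.
#' @param neighborhood Nucleotides, >= 0.
#' @return A list with the two validated parameters.
#' @export
region_params <- function(merge_distance = 20000L, neighborhood = 20000L) {
  stopifnot(merge_distance >= 0, neighborhood >= 0)
  list(merge_distance = as.numeric(merge_distance),
       neighborhood = as.numeric(neighborhood))
}

#' Find anchor genes
#'
#' A gene anchors a candidate NRPS region iff it carries significant hits to
#' both a condensation and an adenylation (AMP-binding) domain, or it
#' carries one of the metallophore-specific condensation-domain subtypes
#' (VibH-like or tandem heterocyclization), which act as standalone Type II
#' entry points. The criterion is derived from the detection rule: the
#' gene-scoped `cds(...)` sub-expressions and the standalone region-scope
#' disjuncts of the rule's top-level `or` chain define what can seed a
#' region.
#'
#' @param genes Gene data frame of a contig (`gene_id`, `start`, `end`).
#' @param sig_hits Named list gene_id -> significant profiles, from
#'   [apply_cutoffs()].
#' @param rule A `rule_expr`; defaults to the canonical rule.
#' @return Character vector of anchor gene ids (possibly empty).
#' @export
find_anchor_genes <- function(genes, sig_hits,
                              rule = nrp_metallophore_rule()) {
  anchor_exprs <- anchor_expressions(rule)
  anchors <- character(0)
  for (gid in intersect(genes$gene_id, names(sig_hits))) {
    profs <- sig_hits[[gid]]
    for (ex in anchor_exprs) {
      if (evaluate_rule(ex, stats::setNames(list(profs), gid))$satisfied) {
        anchors <- c(anchors, gid)
        break
      }
    }
  }
  sort(unique(anchors))
}

# The anchoring sub-expressions of a rule: every cds(...) node (evaluated
# per gene) and every standalone identifier disjunct of top-level or/and
# chains outside cds(). For the canonical rule this yields
# cds(Condensation and AMP-binding), VibH_like, and Cy_tandem.
anchor_expressions <- function(rule) {
  out <- list()
  walk <- function(node) {
    switch(node$kind,
      cds = { out[[length(out) + 1L]] <<- node$child },
      identifier = { out[[length(out) + 1L]] <<- node },
      "or" = { walk(node$left); walk(node$right) },
      "and" = { walk(node$left); walk(node$right) },
      "not" = NULL)
    invisible(NULL)
  }
  walk(rule)
  # an identifier that only ever occurs under 'and' with a cds() sibling
  # would over-anchor; restrict standalone identifiers to top-level or-chain
  # disjuncts.
  top_idents <- character(0)
  top <- function(node) {
    if (node$kind == "or") { top(node$left); top(node$right) }
    else if (node$kind == "identifier") top_idents <<- c(top_idents, node$name)
  }
  top(rule)
  keep <- vapply(out, function(ex) {
    ex$kind != "identifier" || ex$name %in% top_idents
  }, logical(1))
  # cds() children are gene-scoped expressions already
  cds_children <- out[keep]
  cds_children
}

#' Build candidate regions on one contig
#'
#' Anchor genes whose spans are within `merge_distance` of each other
#' (transitively) share one region. Each merged anchor span is extended by
#' `neighborhood` on both sides and clamped to the contig; clusters whose
#' extended spans would overlap are merged too, so regions on a contig are
#' always pairwise disjoint. Members are all genes overlapping the final
#' span. The pre-clamp bounds are retained (fields `raw_start`, `raw_end`)
#' to decide completeness.
#'
#' @param contig A `contig_record`.
#' @param anchors Character vector of anchor gene ids on this contig.
#' @param params A [region_params()] list.
#' @return A list of `region` objects sorted by start; empty if no anchors.
#' @export
build_regions <- function(contig, anchors, params = region_params()) {
  stopifnot(inherits(contig, "contig_record"))
  anchors <- intersect(contig$genes$gene_id, anchors)
  if (length(anchors) == 0L) return(list())
  g <- contig$genes
  a <- g[g$gene_id %in% anchors, , drop = FALSE]
  a <- a[order(a$start, a$end), , drop = FALSE]
  nb <- params$neighborhood
  # transitive single-linkage clustering along the contig
  cluster_id <- integer(nrow(a))
  cluster_id[1] <- 1L
  cur_end <- a$end[1]
  for (i in seq_len(nrow(a))[-1]) {
    gap <- a$start[i] - cur_end
    same <- gap <= params$merge_distance || gap < 2 * nb
    cluster_id[i] <- if (same) cluster_id[i - 1L] else cluster_id[i - 1L] + 1L
    cur_end <- max(cur_end, a$end[i])
  }
  regions <- list()
  for (cl in unique(cluster_id)) {
    aa <- a[cluster_id == cl, , drop = FALSE]
    raw_start <- min(aa$start) - nb
    raw_end <- max(aa$end) + nb
    start <- max(0, raw_start)
    end <- min(contig$length, raw_end)
    members <- g$gene_id[g$start < end & g$end > start]
    reg <- structure(list(
      region_id = sprintf("%s_r%d", contig$contig_id, cl),
      contig_id = contig$contig_id,
      start = as.integer(start), end = as.integer(end),
      raw_start = as.numeric(raw_start), raw_end = as.numeric(raw_end),
      anchor_gene_ids = sort(aa$gene_id),
      member_gene_ids = sort(members),
      complete = NA), class = "region")
    regions[[length(regions) + 1L]] <- flag_completeness(reg, contig)
  }
  regions[order(vapply(regions, `[[`, 0L, "start"))]
}

#' Flag a region's completeness
#'
#' A region is complete iff its neighborhood extension was not truncated by
#' a contig boundary: pre-clamp start >= 0 and pre-clamp end <= contig
#' length (both boundaries inclusive). This is the concrete proxy for "not
#' on a contig edge".
#'
#' @param region A `region`.
#' @param contig The `contig_record` the region lies on.
#' @return The region with its `complete` field set.
#' @export
flag_completeness <- function(region, contig) {
  stopifnot(inherits(region, "region"), inherits(contig, "contig_record"))
  region$complete <- region$raw_start >= 0 && region$raw_end <= contig$length
  region
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> %s %s:[%d,%d) %s, %d genes (%d anchors)\n",
              x$region_id, x$contig_id, x$start, x$end,
              if (isTRUE(x$complete)) "complete" else "partial",
              length(x$member_gene_ids), length(x$anchor_gene_ids)))
  invisible(x)
}
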