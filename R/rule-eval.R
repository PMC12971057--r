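#' Filter domain hits by per-profile bitscore cutoffs
#'
#' Applies the registry's significance cutoffs to a raw domain-hit table and
#' groups the surviving hits by gene. A hit survives iff its bitscore is
#' greater than or equal to the cutoff of its profile (the boundary is
#' inclusive). No hits are dropped at read time; this is the single explicit
#' filtering step, so one hit table can be reused under different registries.
#'
#' @param hits A domain-hit data frame as returned by [read_domain_hits()]
#'   (columns `gene_id`, `profile`, `bitscore`; other columns ignored).
#' @param registry A `profile_registry`.
#' @return A named list mapping `gene_id` to the sorted character vector of
#'   profile names with at least one significant hit on that gene. Genes with
#'   no surviving hits are absent.
#' @examples
#' reg <- default_registry()
#' hits <- data.frame(gene_id = "g1", profile = "EntA", bitscore = 300)
#' apply_cutoffs(hits, reg)
#' @export
apply_cutoffs <- function(hits, registry) {
  stopifnot(is.data.frame(hits))
  registry <- as_profile_registry(registry)
  if (nrow(hits) == 0L) return(structure(list(), names = character(0)))
  unknown <- setdiff(unique(hits$profile), registry$profile)
  if (length(unknown) > 0L) {
    stop("profile(s) missing from registry: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  }
  cutoff <- registry$cutoff[match(hits$profile, registry$profile)]
  keep <- hits$bitscore >= cutoff
  sig <- hits[keep, c("gene_id", "profile"), drop = FALSE]
  if (nrow(sig) == 0L) return(structure(list(), names = character(0)))
  lapply(split(sig$profile, sig$gene_id), function(p) sort(unique(p)))
}

#' Evaluate a rule against the significant hits of one region
#'
#' Implements the two-scope semantics of the rule language. Outside
#' `cds()`, an identifier is true iff any gene in the region carries a
#' significant hit to that profile (region scope). Inside `cds()`, the
#' wrapped sub-expression must be satisfied by some single gene using only
#' that gene's own hits (gene scope) -- this is how "a gene containing at
#' least one condensation and one adenylation domain" is expressed as
#' `cds(Condensation and AMP-binding)`. `not`, `and` and `or` are ordinary
#' boolean connectives; negative constraints are region-scoped, so e.g. a
#' significant KtzT hit anywhere in the region vetoes the
#' ornithine-monooxygenase hydroxamate branch.
#'
#' The verdict also reports *triggering identifiers*: profile names that
#' occur positively (outside any `not`) and are true on a satisfied path of
#' the rule. Identifiers on vetoed branches never appear. When the rule is
#' not satisfied the triggering set is empty.
#'
#' @param rule A `rule_expr`.
#' @param region_hits Named list mapping `gene_id` to a character vector of
#'   significant profile names, as returned by [apply_cutoffs()] (restricted
#'   to the region's member genes).
#' @return A list with `satisfied` (logical) and `triggering` (sorted
#'   character vector).
#' @examples
#' rule <- parse_rule("cds(Condensation and AMP-binding) and (EntA and EntC)")
#' evaluate_rule(rule, list(g1 = c("AMP-binding", "Condensation"),
#'                          g2 = c("EntA", "EntC")))
#' @export
evaluate_rule <- function(rule, region_hits) {
  stopifnot(inherits(rule, "rule_expr"), is.list(region_hits))
  all_profiles <- unique(unlist(region_hits, use.names = FALSE))
  # eval_node returns list(value, triggers); triggers only meaningful when
  # value is TRUE and collect positively-occurring true identifiers.
  eval_node <- function(node, gene_profiles) {
    switch(node$kind,
      identifier = {
        v <- node$name %in% gene_profiles
        list(value = v, triggers = if (v) node$name else character(0))
      },
      "not" = {
        r <- eval_node(node$child, gene_profiles)
        list(value = !r$value, triggers = character(0))
      },
      "and" = {
        l <- eval_node(node$left, gene_profiles)
        r <- eval_node(node$right, gene_profiles)
        v <- l$value && r$value
        list(value = v,
             triggers = if (v) c(l$triggers, r$triggers) else character(0))
      },
      "or" = {
        l <- eval_node(node$left, gene_profiles)
        r <- eval_node(node$right, gene_profiles)
        v <- l$value || r$value
        trig <- c(if (l$value) l$triggers, if (r$value) r$triggers)
        list(value = v, triggers = if (v) trig else character(0))
      },
      cds = {
        # satisfied iff some single gene satisfies the child on its own hits
        trig <- character(0)
        v <- FALSE
        for (g in names(region_hits)) {
          r <- eval_node(node$child, region_hits[[g]])
          if (r$value) {
            v <- TRUE
            trig <- c(trig, r$triggers)
          }
        }
        list(value = v, triggers = if (v) trig else character(0))
      },
      stop("unknown rule node kind: ", node$kind))
  }
  res <- eval_node(rule, all_profiles)
  list(satisfied = res$value,
       triggering = if (res$value) sort(unique(res$triggers)) else character(0))
}
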