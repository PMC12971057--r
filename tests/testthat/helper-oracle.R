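`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracle for rule evaluation: direct recursive
# truth-value substitution over an AST, with cds() enumerated gene by gene.
# Kept free of the package's evaluator internals (no triggering logic).
oracle_eval <- function(node, gene_sets) {
  region_profiles <- unique(unlist(gene_sets, use.names = FALSE))
  sub <- function(n, profs) {
    switch(n$kind,
      identifier = n$name %in% profs,
      "not" = !sub(n$child, profs),
      "and" = sub(n$left, profs) && sub(n$right, profs),
      "or" = sub(n$left, profs) || sub(n$right, profs),
      cds = length(gene_sets) > 0L &&
        any(vapply(gene_sets, function(g) sub(n$child, g), logical(1))),
      stop("bad node"))
  }
  sub(node, region_profiles)
}

# Random rule *strings* (also exercises the parser). `in_cds` guards the
# no-nested-cds constraint.
rand_rule_string <- function(ids, depth = 3L, in_cds = FALSE) {
  if (depth <= 0L || stats::runif(1) < 0.3) {
    return(sample(ids, 1L))
  }
  choice <- sample(c("and", "or", "not", "cds"), 1L,
                   prob = c(0.32, 0.32, 0.2, if (in_cds) 0 else 0.16))
  switch(choice,
    "and" = sprintf("(%s and %s)",
                    rand_rule_string(ids, depth - 1L, in_cds),
                    rand_rule_string(ids, depth - 1L, in_cds)),
    "or" = sprintf("(%s or %s)",
                   rand_rule_string(ids, depth - 1L, in_cds),
                   rand_rule_string(ids, depth - 1L, in_cds)),
    "not" = sprintf("not %s", rand_rule_string(ids, depth - 1L, in_cds)),
    "cds" = sprintf("cds(%s)", rand_rule_string(ids, depth - 1L, TRUE)))
}

# Random region: 1-3 genes, each carrying a random subset of identifiers.
rand_region <- function(ids, n_genes = sample(1:3, 1L)) {
  sets <- lapply(seq_len(n_genes), function(i) {
    k <- sample(0:length(ids), 1L)
    if (k == 0L) character(0) else sample(ids, k)
  })
  names(sets) <- sprintf("g%d", seq_len(n_genes))
  sets
}

# A tiny hand-built genome: one contig, genes at given starts (1.2 kb
# each), used by region/classifier tests.
toy_contig <- function(starts, contig_id = "c1", length = 200000L,
                       gene_len = 1200L) {
  genes <- data.frame(
    gene_id = sprintf("%s_g%d", contig_id, seq_along(starts)),
    start = as.integer(starts), end = as.integer(starts + gene_len),
    strand = "+", translation = NA_character_, stringsAsFactors = FALSE)
  contig_record(contig_id, length, genes)
}

# Hit rows at 1.5x the registry cutoff for the given gene -> profiles map.
toy_hits <- function(gene_profiles, registry = default_registry()) {
  rows <- list()
  for (g in names(gene_profiles)) {
    for (p in gene_profiles[[g]]) {
      cut <- registry$cutoff[match(p, registry$profile)]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, profile = p, bitscore = cut * 1.5, evalue = 1e-30,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(0), profile = character(0),
                      bitscore = numeric(0), evalue = numeric(0)))
  }
  do.call(rbind, rows)
}
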