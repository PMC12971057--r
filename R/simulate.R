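# Deterministic synthetic genomes with planted metallophore clusters,
# decoys, cheaters and edge fragments, plus matching domain-hit tables and
# ground-truth labels. Gene sequences are filler; the hit tables carry the
# signal, so the engine never re-scans sequences in tests.

SYNTH_GENE_LEN <- 1200L
SYNTH_GENE_GAP <- 200L

#' Planted cluster templates
#'
#' Each template instantiates a characteristic locus archetype: an
#' enterobactin-like catechol cluster, a pyoverdine-like three-group hybrid
#' (chromophore + hydroxamate + beta-OHAsp), a Type II standalone
#' VibH-like/tandem-Cy trigger, a "cheater" that kept transporters and an
#' NRPS but no chelator genes, a hydroxamate locus vetoed by a piperazate
#' KtzT gene, a syringomycin-like locus excluded by the SBH_Asp
#' negative constraint, and a plain NRPS decoy. Expected verdicts are
#' stored with each template and re-validated against the rule and registry
#' at generation time. Transporter complements are chosen so the
#' transporter and chelator verdicts agree on every template except the
#' cheater.
#'
#' @return Named list of `cluster_template` lists with fields `name`,
#'   `slots` (list of per-gene profile vectors), `expected_chelator`,
#'   `expected_transporter`, `expected_groups`.
#' @export
cluster_templates <- function() {
  tpl <- function(name, slots, chel, trans, groups) {
    structure(list(name = name, slots = slots, expected_chelator = chel,
                   expected_transporter = trans, expected_groups = groups),
              class = "cluster_template")
  }
  list(
    enterobactin = tpl("enterobactin",
      list("EntC", "EntA", c("Condensation", "AMP-binding"),
           "PF00593", "PF01032", "PF01497"),
      TRUE, TRUE, "catechol"),
    pyoverdine = tpl("pyoverdine",
      list("PvdP", "Orn_monoox", "TBH_Asp",
           c("Condensation", "AMP-binding"), "PF00593", "PF01032"),
      TRUE, TRUE,
      c("beta-OHAsp", "hydroxamate", "pyoverdine-chromophore")),
    type2 = tpl("type2",
      list("Cy_tandem", "PF00593", "PF01497"),
      TRUE, TRUE, "NRPS-domain-marker"),
    cheater = tpl("cheater",
      list(c("Condensation", "AMP-binding"), "PF00593", "PF01032",
           "PF01497"),
      FALSE, TRUE, character(0)),
    himastatin_veto = tpl("himastatin_veto",
      list("Orn_monoox", "KtzT", c("Condensation", "AMP-binding")),
      FALSE, FALSE, character(0)),
    syringomycin_excl = tpl("syringomycin_excl",
      list("IBH_Asp", "SBH_Asp", c("Condensation", "AMP-binding")),
      FALSE, FALSE, character(0)),
    nrps_decoy = tpl("nrps_decoy",
      list(c("Condensation", "AMP-binding")),
      FALSE, FALSE, character(0))
  )
}

#' Specify a synthetic genome
#'
#' One planted cluster per contig. Interior contigs are 60 kb with the
#' cluster placed near 25 kb so the neighborhood extension stays inside the
#' contig; `truncate_at_edge` places the cluster 2 kb from the left contig
#' edge so the extension is clamped and the resulting region is partial.
#'
#' @param templates Character vector of template names, one per contig.
#' @param truncate_at_edge Logical vector (recycled) marking clusters to
#'   plant on a contig edge.
#' @param decoys Integer: filler genes (no significant hits; some carry
#'   subthreshold chelator hits at half the cutoff) scattered per contig.
#' @param seed Integer seed; fully determines the generated bytes.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(templates, truncate_at_edge = FALSE, decoys = 3L,
                        seed = 1L) {
  known <- names(cluster_templates())
  bad <- setdiff(templates, known)
  if (length(bad) > 0L) {
    stop("unknown template(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(templates = templates,
                 truncate_at_edge = rep_len(truncate_at_edge,
                                            length(templates)),
                 decoys = as.integer(decoys), seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic genome, hit table and truth labels
#'
#' Deterministically (given `spec$seed`) builds one contig per requested
#' template, plants the template's genes with hit bitscores at
#' `score_mult` (default 1.5) times each profile's registry cutoff,
#' scatters decoy genes (a third of which carry subthreshold hits at half
#' the cutoff), and emits ground truth: per planted cluster, the expected
#' verdict of all three classification methods, the expected chelator
#' groups, and the expected completeness. Expected verdicts are
#' re-validated against `rule` and `registry` at generation time;
#' regenerating with the same spec is byte-identical.
#'
#' @param spec A [genome_spec()].
#' @param registry A `profile_registry`.
#' @param rule A `rule_expr`.
#' @param dir If non-`NULL`, write `genome.gbk`, `hits.tsv` and
#'   `truth.tsv` into this directory.
#' @param score_mult Multiplier above the cutoff for planted hits.
#' @return A list with `contigs`, `hits`, `truth` (and `paths` when `dir`
#'   is given).
#' @export
synth_genome <- function(spec, registry = default_registry(),
                         rule = nrp_metallophore_rule(), dir = NULL,
                         score_mult = 1.5) {
  stopifnot(inherits(spec, "genome_spec"))
  registry <- as_profile_registry(registry)
  templates <- cluster_templates()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)

  contigs <- list()
  hit_rows <- list()
  truth_rows <- list()
  sub_pool <- c("EntA", "Orn_monoox", "PvdP", "IPL")

  for (k in seq_along(spec$templates)) {
    tmpl <- templates[[spec$templates[k]]]
    contig_id <- sprintf("ctg%03d", k)
    n_slot <- length(tmpl$slots)
    cluster_len <- n_slot * (SYNTH_GENE_LEN + SYNTH_GENE_GAP)
    if (spec$truncate_at_edge[k]) {
      cluster_start <- 2000L
      contig_len <- cluster_start + cluster_len + 25000L
    } else {
      cluster_start <- 25000L + sample.int(2000L, 1L)
      contig_len <- cluster_start + cluster_len + 25000L + 10000L
    }
    genes <- list()
    gmap <- list()  # planted gene -> profiles, for validation
    for (s in seq_len(n_slot)) {
      gid <- sprintf("%s_g%02d", contig_id, s)
      gstart <- cluster_start + (s - 1L) * (SYNTH_GENE_LEN + SYNTH_GENE_GAP)
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, start = gstart, end = gstart + SYNTH_GENE_LEN,
        strand = if (s %% 2L == 0L) "-" else "+",
        translation = paste(rep("MA", 10L), collapse = ""),
        stringsAsFactors = FALSE)
      profs <- tmpl$slots[[s]]
      gmap[[gid]] <- profs
      for (p in profs) {
        cutoff <- registry_lookup(registry, p, "cutoff")
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          gene_id = gid, profile = p, bitscore = cutoff * score_mult,
          evalue = 1e-50, stringsAsFactors = FALSE)
      }
    }
    cluster_end <- cluster_start + cluster_len - SYNTH_GENE_GAP

    # decoy genes in the right-hand tail of the contig
    if (spec$decoys > 0L) {
      tail_start <- cluster_end + 2L * SYNTH_GENE_GAP
      free <- contig_len - tail_start - SYNTH_GENE_LEN
      slots <- sort(sample.int(max(1L, free %/% (SYNTH_GENE_LEN + SYNTH_GENE_GAP)),
                               min(spec$decoys,
                                   max(1L, free %/% (SYNTH_GENE_LEN + SYNTH_GENE_GAP)))))
      for (d in seq_along(slots)) {
        gid <- sprintf("%s_d%02d", contig_id, d)
        gstart <- tail_start + (slots[d] - 1L) * (SYNTH_GENE_LEN + SYNTH_GENE_GAP)
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, start = gstart, end = gstart + SYNTH_GENE_LEN,
          strand = "+", translation = NA_character_,
          stringsAsFactors = FALSE)
        if (d %% 3L == 0L) {  # subthreshold decoy hit: never significant
          p <- sub_pool[1L + (d %/% 3L) %% length(sub_pool)]
          cutoff <- registry_lookup(registry, p, "cutoff")
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            gene_id = gid, profile = p, bitscore = cutoff * 0.5,
            evalue = 1e-3, stringsAsFactors = FALSE)
        }
      }
    }

    ctg <- contig_record(contig_id, contig_len, do.call(rbind, genes))
    contigs[[length(contigs) + 1L]] <- ctg

    # validate planted expectations against the actual rule + registry
    verdict <- evaluate_rule(rule, gmap)
    if (!identical(verdict$satisfied, tmpl$expected_chelator)) {
      stop(sprintf("template %s: planted chelator verdict %s != expected %s",
                   tmpl$name, verdict$satisfied, tmpl$expected_chelator),
           call. = FALSE)
    }
    fams <- intersect(TRANSPORTER_FAMILIES,
                      unlist(gmap, use.names = FALSE))
    trans <- length(fams) >= 2L
    if (!identical(trans, tmpl$expected_transporter)) {
      stop(sprintf("template %s: planted transporter verdict mismatch",
                   tmpl$name), call. = FALSE)
    }
    if (verdict$satisfied) {
      cats <- registry_lookup(registry, verdict$triggering, "category")
      groups <- sort(unique(cats[cats %in% CHELATOR_GROUPS]))
      if (!identical(groups, sort(tmpl$expected_groups))) {
        stop(sprintf("template %s: planted groups mismatch", tmpl$name),
             call. = FALSE)
      }
    }

    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      contig_id = contig_id, start = cluster_start, end = cluster_end,
      template = tmpl$name,
      is_metallophore = tmpl$expected_chelator,
      chelator = tmpl$expected_chelator,
      transporter = tmpl$expected_transporter,
      ensemble = tmpl$expected_chelator | tmpl$expected_transporter,
      groups = paste(sort(tmpl$expected_groups), collapse = ";"),
      complete = !spec$truncate_at_edge[k],
      stringsAsFactors = FALSE)
  }

  hits <- if (length(hit_rows) == 0L) empty_hits() else
    do.call(rbind, hit_rows)
  hits$ali_start <- 0L
  hits$ali_end <- 200L
  truth <- do.call(rbind, truth_rows)
  out <- list(contigs = contigs, hits = hits, truth = truth, spec = spec)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    gbk <- file.path(dir, "genome.gbk")
    htsv <- file.path(dir, "hits.tsv")
    ttsv <- file.path(dir, "truth.tsv")
    write_genbank(contigs, gbk)
    write_domain_hits(hits, htsv)
    utils::write.table(truth, ttsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- c(genbank = gbk, hits = htsv, truth = ttsv)
  }
  out
}

#' Generate a labeled multi-cluster benchmark
#'
#' Builds `n_clusters` planted clusters (one per contig) with template
#' counts proportional to `mix` (largest-remainder apportionment, so the
#' truth-summary statistics are identical across seeds at a given mix),
#' shuffles their order by `seed`, and marks an `edge_fraction` of them for
#' contig-edge truncation. Running [detect()] and [evaluate_detection()]
#' on the output reproduces generator-known confusion counts exactly on
#' clean settings.
#'
#' @param n_clusters Number of clusters (> 0).
#' @param mix Named numeric proportions over template names; must sum
#'   to 1. Default mixes all seven templates.
#' @param seed Integer seed.
#' @param edge_fraction Fraction of clusters planted on a contig edge.
#' @param ... Passed to [synth_genome()] (e.g. `registry`, `dir`).
#' @return As [synth_genome()].
#' @export
benchmark_set <- function(n_clusters,
                          mix = c(enterobactin = 0.25, pyoverdine = 0.15,
                                  type2 = 0.10, cheater = 0.10,
                                  himastatin_veto = 0.10,
                                  syringomycin_excl = 0.10,
                                  nrps_decoy = 0.20),
                          seed = 1L, edge_fraction = 0.2, ...) {
  if (n_clusters <= 0L) stop("n_clusters must be > 0", call. = FALSE)
  if (abs(sum(mix) - 1) > 1e-8) {
    stop("mix proportions must sum to 1", call. = FALSE)
  }
  # largest-remainder apportionment: exact counts at the stated mix
  raw <- mix * n_clusters
  counts <- floor(raw)
  rem <- n_clusters - sum(counts)
  if (rem > 0L) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  templates <- rep(names(mix), counts)
  n_edge <- floor(n_clusters * edge_fraction)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  templates <- sample(templates)
  edge <- logical(n_clusters)
  if (n_edge > 0L) edge[sample.int(n_clusters, n_edge)] <- TRUE
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  spec <- genome_spec(templates, truncate_at_edge = edge, seed = seed)
  synth_genome(spec, ...)
}
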