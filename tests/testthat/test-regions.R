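test_that("anchor genes need the single-gene NRPS core or a Type II marker", {
  reg <- default_registry()
  ctg <- toy_contig(c(1000, 3000, 5000, 7000))
  hits <- toy_hits(list(
    c1_g1 = c("Condensation", "AMP-binding"),  # anchor
    c1_g2 = "Condensation",                    # half a core: not an anchor
    c1_g3 = "AMP-binding",                     # other half: not an anchor
    c1_g4 = "Cy_tandem"))                      # Type II entry point
  sig <- apply_cutoffs(hits, reg)
  anchors <- find_anchor_genes(ctg$genes, sig)
  expect_identical(anchors, c("c1_g1", "c1_g4"))

  # chelator markers alone never anchor
  sig2 <- apply_cutoffs(toy_hits(list(c1_g1 = c("EntA", "EntC"))), reg)
  expect_length(find_anchor_genes(ctg$genes, sig2), 0L)
})

test_that("regions merge by distance, extend, clamp and stay disjoint", {
  reg <- default_registry()
  p <- region_params(merge_distance = 20000, neighborhood = 20000)

  # two anchors 5 kb apart -> one region
  ctg <- toy_contig(c(40000, 46200), length = 200000L)
  sig <- apply_cutoffs(toy_hits(list(
    c1_g1 = c("Condensation", "AMP-binding"),
    c1_g2 = c("Condensation", "AMP-binding"))), reg)
  regs <- build_regions(ctg, find_anchor_genes(ctg$genes, sig), p)
  expect_length(regs, 1L)
  expect_identical(regs[[1]]$start, 40000L - 20000L)
  expect_identical(regs[[1]]$end, 47400L + 20000L)
  expect_true(regs[[1]]$complete)
  expect_setequal(regs[[1]]$anchor_gene_ids, c("c1_g1", "c1_g2"))

  # two anchors 50 kb apart -> two disjoint regions
  ctg2 <- toy_contig(c(40000, 91200), length = 300000L)
  regs2 <- build_regions(ctg2, find_anchor_genes(ctg2$genes, sig), p)
  expect_length(regs2, 2L)
  expect_lte(regs2[[1]]$end, regs2[[2]]$start)

  # left clamping marks the region partial
  ctg3 <- toy_contig(1000, length = 100000L)
  sig3 <- apply_cutoffs(toy_hits(list(
    c1_g1 = c("Condensation", "AMP-binding"))), reg)
  regs3 <- build_regions(ctg3, find_anchor_genes(ctg3$genes, sig3), p)
  expect_identical(regs3[[1]]$start, 0L)
  expect_identical(regs3[[1]]$end, 2200L + 20000L)
  expect_false(regs3[[1]]$complete)

  # anchor ending exactly neighborhood bp before the contig end: complete
  ctg4 <- toy_contig(40000, length = 61200L)
  regs4 <- build_regions(ctg4, find_anchor_genes(ctg4$genes, sig3), p)
  expect_true(regs4[[1]]$complete)
  expect_identical(regs4[[1]]$end, 61200L)
})

test_that("region building is idempotent and monotone in merge_distance", {
  reg <- default_registry()
  set.seed(31)
  for (trial in 1:10) {
    n <- sample(2:6, 1L)
    starts <- sort(sample.int(150000L, n)) + 10000L
    ctg <- toy_contig(starts, length = 220000L)
    sig <- apply_cutoffs(toy_hits(stats::setNames(
      rep(list(c("Condensation", "AMP-binding")), n),
      ctg$genes$gene_id)), reg)
    anchors <- find_anchor_genes(ctg$genes, sig)
    prev_n <- Inf
    for (md in c(1000, 10000, 30000, 100000)) {
      regs <- build_regions(ctg, anchors, region_params(md, 20000))
      # disjoint, sorted, anchors partitioned
      if (length(regs) > 1L) {
        for (i in seq_len(length(regs) - 1L)) {
          expect_lte(regs[[i]]$end, regs[[i + 1L]]$start)
        }
      }
      expect_setequal(unlist(lapply(regs, `[[`, "anchor_gene_ids")),
                      anchors)
      expect_true(all(vapply(regs, function(r) {
        all(r$anchor_gene_ids %in% r$member_gene_ids)
      }, logical(1))))
      expect_lte(length(regs), prev_n)
      prev_n <- length(regs)
    }
    # idempotence: rebuilding from a region's own genes reproduces it
    regs <- build_regions(ctg, anchors, region_params(30000, 20000))
    for (r in regs) {
      sub <- ctg$genes[ctg$genes$gene_id %in% r$member_gene_ids, ,
                       drop = FALSE]
      sub_ctg <- contig_record(ctg$contig_id, ctg$length, sub)
      again <- build_regions(sub_ctg,
                             intersect(anchors, r$member_gene_ids),
                             region_params(30000, 20000))
      expect_length(again, 1L)
      expect_identical(again[[1]]$start, r$start)
      expect_identical(again[[1]]$end, r$end)
      expect_identical(again[[1]]$complete, r$complete)
    }
  }
})
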