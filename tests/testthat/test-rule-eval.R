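test_that("bitscore cutoffs are inclusive and registry-checked", {
  reg <- as_profile_registry(data.frame(
    profile = c("EntA", "EntC"), cutoff = c(150, 200),
    category = "catechol", role = "marker"))
  hits <- data.frame(
    gene_id = c("g1", "g1", "g2"), profile = c("EntA", "EntA", "EntC"),
    bitscore = c(100, 150, 350), evalue = 1e-10)
  sig <- apply_cutoffs(hits, reg)
  expect_identical(sig, list(g1 = "EntA", g2 = "EntC"))  # 150 >= 150 kept

  below <- data.frame(gene_id = "g1", profile = "EntA", bitscore = 149.99,
                      evalue = 1e-10)
  expect_length(apply_cutoffs(below, reg), 0L)

  unknown <- data.frame(gene_id = "g1", profile = "PqqE", bitscore = 500,
                        evalue = 0)
  expect_error(apply_cutoffs(unknown, reg), "PqqE")
})

test_that("rule semantics: region scope, gene scope, vetoes", {
  rule <- nrp_metallophore_rule()
  ev <- function(region) evaluate_rule(rule, region)

  # catechol markers on different genes + single-gene NRPS core
  v <- ev(list(g1 = "EntA", g2 = "EntC",
               g3 = c("Condensation", "AMP-binding")))
  expect_true(v$satisfied)
  expect_true(all(c("EntA", "EntC") %in% v$triggering))

  # hydroxamate branch vetoed region-wide by KtzT
  v <- ev(list(g1 = "Orn_monoox", g2 = "KtzT",
               g3 = c("Condensation", "AMP-binding")))
  expect_false(v$satisfied)
  expect_length(v$triggering, 0L)

  # MetRS-like vetoes the same branch; Lys_monoox rescues it
  expect_false(ev(list(g1 = "Orn_monoox", g2 = "MetRS-like",
                       g3 = c("Condensation", "AMP-binding")))$satisfied)
  expect_true(ev(list(g1 = "Orn_monoox", g2 = "KtzT", g4 = "Lys_monoox",
                      g3 = c("Condensation", "AMP-binding")))$satisfied)

  # VibH-like triggers standalone, without any NRPS core
  v <- ev(list(g1 = "VibH_like"))
  expect_true(v$satisfied)
  expect_identical(v$triggering, "VibH_like")

  # condensation and adenylation domains on *different* genes do not count
  expect_false(ev(list(g1 = "Condensation", g2 = "AMP-binding",
                       g3 = "EntA", g4 = "EntC"))$satisfied)

  # empty region
  expect_false(ev(stats::setNames(list(), character(0)))$satisfied)

  # EntA without EntC (3-hydroxyanthranilate look-alike) is not enough
  expect_false(ev(list(g1 = "EntA",
                       g3 = c("Condensation", "AMP-binding")))$satisfied)
})

test_that("evaluate agrees with brute-force substitution on random rules", {
  set.seed(11)
  ids <- sprintf("P%02d", 1:12)
  n_cases <- 0L
  for (r in 1:60) {
    ast <- parse_rule(rand_rule_string(ids, depth = 4L))
    for (a in 1:10) {
      region <- rand_region(ids)
      got <- evaluate_rule(ast, region)
      want <- oracle_eval(ast, region)
      expect_identical(got$satisfied, want,
                       label = sprintf("rule=%s region=%s", format(ast),
                                       paste(names(region), collapse = ",")))
      # triggering identifiers are positively-occurring and present
      if (got$satisfied) {
        pos <- list_identifiers(ast)$positive
        expect_true(all(got$triggering %in% pos))
        expect_true(all(got$triggering %in%
                          unlist(region, use.names = FALSE)))
      } else {
        expect_length(got$triggering, 0L)
      }
      n_cases <- n_cases + 1L
    }
  }
  expect_gte(n_cases, 500L)
})

test_that("adding hits is monotone in identifier polarity", {
  set.seed(23)
  ids <- sprintf("P%02d", 1:8)
  for (r in 1:40) {
    ast <- parse_rule(rand_rule_string(ids, depth = 3L))
    pol <- list_identifiers(ast)
    pos_only <- setdiff(pol$positive, pol$negated)
    neg_only <- setdiff(pol$negated, pol$positive)
    region <- rand_region(ids)
    before <- evaluate_rule(ast, region)$satisfied
    if (before && length(pos_only) > 0L) {
      region2 <- region
      region2[[1]] <- union(region2[[1]], sample(pos_only, 1L))
      expect_true(evaluate_rule(ast, region2)$satisfied)
    }
    if (!before && length(neg_only) > 0L) {
      region2 <- region
      region2[[1]] <- union(region2[[1]], sample(neg_only, 1L))
      expect_false(evaluate_rule(ast, region2)$satisfied)
    }
  }
})
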