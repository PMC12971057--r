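# Builds a single-region fixture from a gene -> profiles map and returns
# the three verdicts plus the chelator profile.
classify_fixture <- function(gene_profiles, registry = default_registry()) {
  starts <- 30000L + (seq_along(gene_profiles) - 1L) * 1400L
  ctg <- toy_contig(starts, length = 100000L)
  names(gene_profiles) <- ctg$genes$gene_id[seq_along(gene_profiles)]
  sig <- apply_cutoffs(toy_hits(gene_profiles, registry), registry)
  region <- structure(list(
    region_id = "r1", contig_id = "c1", start = 0L, end = 100000L,
    raw_start = 0, raw_end = 100000,
    anchor_gene_ids = names(gene_profiles)[1],
    member_gene_ids = ctg$genes$gene_id, complete = TRUE),
    class = "region")
  chel <- classify_chelator_rule(region, sig, registry = registry)
  trans <- classify_transporter_rule(region, sig)
  list(chelator = chel$satisfied, groups = chel$groups,
       triggering = chel$triggering, transporter = trans,
       ensemble = classify_ensemble(chel$satisfied, trans))
}

test_that("chelator rule verdicts and group profiles match the archetypes", {
  # enterobactin-like: catechol only
  v <- classify_fixture(list("EntA", "EntC",
                             c("Condensation", "AMP-binding")))
  expect_true(v$chelator)
  expect_identical(v$groups, "catechol")
  expect_setequal(v$triggering$catechol, c("EntA", "EntC"))

  # pyoverdine-like: the three-group combination
  v <- classify_fixture(list("PvdP", "Orn_monoox", "TBH_Asp",
                             c("Condensation", "AMP-binding")))
  expect_true(v$chelator)
  expect_identical(v$groups,
                   c("beta-OHAsp", "hydroxamate", "pyoverdine-chromophore"))

  # IBH_Asp with the SBH_Asp competing profile present: excluded
  v <- classify_fixture(list("IBH_Asp", "SBH_Asp",
                             c("Condensation", "AMP-binding")))
  expect_false(v$chelator)
  expect_identical(v$groups, character(0))

  # NRPS core alone
  v <- classify_fixture(list(c("Condensation", "AMP-binding")))
  expect_false(v$chelator)

  # graminine needs both GrbD and GrbE
  v <- classify_fixture(list("GrbD", c("Condensation", "AMP-binding")))
  expect_false(v$chelator)
  v <- classify_fixture(list("GrbD", "GrbE",
                             c("Condensation", "AMP-binding")))
  expect_true(v$chelator)
  expect_identical(v$groups, "graminine")

  # vetoed Orn_monoox never contributes to the profile even when another
  # branch fires
  v <- classify_fixture(list("Orn_monoox", "KtzT", "IPL",
                             c("Condensation", "AMP-binding")))
  expect_true(v$chelator)
  expect_identical(v$groups, "salicylate")

  # Type II marker profiles as their own group
  v <- classify_fixture(list("VibH_like"))
  expect_true(v$chelator)
  expect_identical(v$groups, "NRPS-domain-marker")
})

test_that("transporter rule counts distinct families, two of three", {
  v <- classify_fixture(list(c("Condensation", "AMP-binding"),
                             "PF00593", "PF01032"))
  expect_true(v$transporter)

  # one family on three genes is still one family
  v <- classify_fixture(list(c("Condensation", "AMP-binding"),
                             "PF01497", "PF01497", "PF01497"))
  expect_false(v$transporter)

  v <- classify_fixture(list(c("Condensation", "AMP-binding"),
                             "PF00593", "PF01032", "PF01497"))
  expect_true(v$transporter)
})

test_that("ensemble is the logical OR and the cheater disagrees as planted", {
  expect_true(classify_ensemble(TRUE, FALSE))
  expect_true(classify_ensemble(FALSE, TRUE))
  expect_true(classify_ensemble(TRUE, TRUE))
  expect_false(classify_ensemble(FALSE, FALSE))

  # cheater: transporters + NRPS fragment, no chelator biosynthesis
  v <- classify_fixture(list(c("Condensation", "AMP-binding"),
                             "PF00593", "PF01032", "PF01497"))
  expect_false(v$chelator)
  expect_true(v$transporter)
  expect_true(v$ensemble)
})

test_that("profile groups are witnessed by in-region significant hits", {
  set.seed(47)
  reg <- default_registry()
  markers <- reg$profile[reg$role == "marker"]
  for (trial in 1:20) {
    picks <- sample(markers, sample(1:4, 1L))
    gene_profiles <- c(as.list(picks),
                       list(c("Condensation", "AMP-binding")))
    v <- classify_fixture(gene_profiles)
    for (grp in v$groups) {
      wit <- v$triggering[[grp]]
      expect_gt(length(wit), 0L)
      expect_true(all(reg$category[match(wit, reg$profile)] == grp))
      expect_true(all(wit %in% c(unlist(gene_profiles))))
    }
    # determinism: identical inputs, identical verdicts
    v2 <- classify_fixture(gene_profiles)
    expect_identical(v, v2)
  }
})
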