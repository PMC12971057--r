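test_that("confusion tallies match a per-region brute force", {
  keys <- sprintf("r%d", 1:5)
  pred <- stats::setNames(rep(TRUE, 5), keys)
  cc <- confusion(pred, pred)
  expect_identical(unclass(cc)[c("tp", "fp", "fn", "tn")],
                   list(tp = 5L, fp = 0L, fn = 0L, tn = 0L))

  keys <- sprintf("r%d", 1:10)
  truth <- stats::setNames(c(rep(TRUE, 3), rep(FALSE, 7)), keys)
  pred <- stats::setNames(rep(FALSE, 10), keys)
  cc <- confusion(pred, truth)
  expect_identical(cc$fn, 3L)
  expect_identical(cc$tn, 7L)

  # random instances against an explicit per-region tally
  set.seed(13)
  for (trial in 1:10) {
    keys <- sprintf("r%d", 1:12)
    pred <- stats::setNames(sample(c(TRUE, FALSE), 12, TRUE), keys)
    truth <- stats::setNames(sample(c(TRUE, FALSE), 12, TRUE),
                             sample(keys))  # shuffled key order
    cc <- confusion(pred, truth)
    tally <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
    for (k in keys) {
      cell <- if (pred[[k]] && truth[[k]]) "tp"
        else if (pred[[k]]) "fp"
        else if (truth[[k]]) "fn" else "tn"
      tally[cell] <- tally[cell] + 1L
    }
    expect_identical(c(tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn),
                     tally)
    expect_identical(cc$tp + cc$fp + cc$fn + cc$tn, 12L)
  }

  expect_error(confusion(stats::setNames(TRUE, "a"),
                         stats::setNames(TRUE, "b")), "mismatch.*a.*b")
})

test_that("precision/recall/F1 follow the harmonic-mean identity", {
  m <- compute_metrics(list(tp = 140, fp = 5, fn = 40))
  expect_identical(round_half_up(m$precision, 2), 0.97)
  expect_identical(round_half_up(m$recall, 2), 0.78)
  expect_identical(round_half_up(m$f1, 2), 0.86)
  expect_false(m$degenerate)

  m <- compute_metrics(list(tp = 100, fp = 8, fn = 80))
  expect_identical(round_half_up(m$precision, 2), 0.93)
  expect_identical(round_half_up(m$recall, 2), 0.56)
  expect_identical(round_half_up(m$f1, 2), 0.69)

  expect_identical(round_half_up(f1_score(0.92, 0.88), 2), 0.90)

  m <- compute_metrics(list(tp = 9, fp = 0, fn = 0))
  expect_identical(c(m$precision, m$recall, m$f1), c(1, 1, 1))

  # harmonic-mean identity and [0,1] bounds on random counts
  set.seed(3)
  for (trial in 1:25) {
    cc <- list(tp = sample(0:50, 1), fp = sample(0:50, 1),
               fn = sample(0:50, 1))
    m <- compute_metrics(cc)
    expect_true(all(c(m$precision, m$recall, m$f1) >= 0))
    expect_true(all(c(m$precision, m$recall, m$f1) <= 1))
    if (m$precision + m$recall > 0) {
      expect_equal(m$f1, 2 * m$precision * m$recall /
                           (m$precision + m$recall))
    } else {
      expect_identical(m$f1, 0)
    }
  }

  # degenerate cases yield 0, never NaN
  m <- compute_metrics(list(tp = 0, fp = 0, fn = 0))
  expect_true(m$degenerate)
  expect_identical(c(m$precision, m$recall, m$f1), c(0, 0, 0))
  expect_error(compute_metrics(list(tp = -1, fp = 0, fn = 0)), "negative")
})

test_that("census percentages use half-up whole percent, one decimal < 10", {
  expect_identical(census_percent(3210, 20107), 16)
  expect_identical(census_percent(2485, 11704), 21)
  expect_identical(census_percent(725, 8403), 8.6)
  expect_identical(census_percent(176, 758), 23)
  expect_true(is.na(census_percent(0, 0)))

  df <- data.frame(
    chelator_rule = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    transporter_rule = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    complete = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  df$ensemble <- df$chelator_rule | df$transporter_rule
  cs <- census(df)
  # strata sum to totals and stored percentages recompute from counts
  for (m in unique(cs$method)) {
    sub <- cs[cs$method == m, ]
    expect_identical(sub$n[sub$stratum == "total"],
                     sum(sub$n[sub$stratum != "total"]))
    expect_identical(sub$positive[sub$stratum == "total"],
                     sum(sub$positive[sub$stratum != "total"]))
  }
  expect_true(all(mapply(function(p, n, pct) {
    identical(census_percent(p, n), pct)
  }, cs$positive, cs$n, cs$percent)))
})

test_that("combination counts key regions by their sorted group tuple", {
  counts <- combination_counts(list("hydroxamate", "catechol",
                                    c("hydroxamate", "catechol")))
  expect_identical(sort(names(counts)),
                   c("catechol", "catechol;hydroxamate", "hydroxamate"))
  expect_true(all(counts == 1L))

  expect_length(combination_counts(list()), 0L)

  # marker-only regions are their own class; alongside chelator groups the
  # marker is dropped from the key
  counts <- combination_counts(list("NRPS-domain-marker",
                                    c("NRPS-domain-marker", "catechol")))
  expect_setequal(names(counts), c("catechol", "NRPS-domain-marker"))

  # 50-region random instance equals a brute-force dictionary tally
  set.seed(17)
  groups <- c("catechol", "salicylate", "hydroxamate", "beta-OHAsp")
  profiles <- lapply(1:50, function(i) {
    k <- sample(0:3, 1)
    if (k == 0) character(0) else sample(groups, k)
  })
  counts <- combination_counts(profiles)
  dict <- list()
  for (p in profiles) {
    if (length(p) == 0) next
    key <- paste(sort(unique(p)), collapse = ";")
    dict[[key]] <- (dict[[key]] %||% 0L) + 1L
  }
  expect_identical(counts[sort(names(counts))],
                   unlist(dict)[sort(names(dict))])
  expect_identical(sum(counts),
                   sum(vapply(profiles, length, 1L) > 0L))
})
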