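test_that("confusion matrices tally co-assignments with correct marginals", {
  ids <- sprintf("i%d", 1:6)
  a1 <- stats::setNames(c("A", "A", "B", "B", "C", "C"), ids)
  a2 <- stats::setNames(c("A", "A", "B", "B", "C", "C"), ids)
  m <- build_confusion(a1, a2, categories = c("A", "B", "C"))
  expect_identical(unname(diag(m$counts)), c(2L, 2L, 2L))
  expect_identical(sum(m$counts) - sum(diag(m$counts)), 0L)

  # disjoint single-category annotations: one off-diagonal cell
  d <- build_confusion(rep("A", 4), rep("B", 4), categories = c("A", "B"))
  expect_identical(unname(d$counts["B", "A"]), 4L)
  expect_identical(sum(d$counts), 4L)

  # alignment is by item id, not position
  swapped <- build_confusion(a1, a2[rev(ids)], categories = c("A", "B", "C"))
  expect_identical(swapped$counts, m$counts)
  expect_error(build_confusion(a1, a2[-1]), class = "spatzone_alignment_error")
})

test_that("bundled study fixtures carry the published marginals", {
  fixtures <- zoning_confusion_matrices()
  expect_identical(unname(colSums(fixtures$set1$counts)), c(579, 253, 63, 191))
  expect_identical(unname(rowSums(fixtures$set1$counts)), c(587, 264, 63, 172))
  expect_equal(fixtures$set1$n, 1086)
  expect_equal(fixtures$set2$n, 908)
})

test_that("kappa handles the canonical hand cases", {
  # observed equals chance
  m <- confusion_matrix(matrix(c(25, 25, 25, 25), 2))
  expect_equal(cohens_kappa(m)$kappa, 0)
  # perfect agreement over >= 2 occupied categories
  d <- confusion_matrix(diag(c(7L, 3L, 5L, 2L)))
  expect_identical(cohens_kappa(d)$kappa, 1)
  expect_identical(cohens_kappa(d)$pr_a, 1)
  # kappa = 1 iff pr_a = 1
  near <- confusion_matrix(matrix(c(7, 1, 0, 5), 2))
  expect_lt(cohens_kappa(near)$kappa, 1)
  # degenerate marginals: every item in one cell
  expect_error(cohens_kappa(confusion_matrix(matrix(c(9, 0, 0, 0), 2))),
               class = "spatzone_degenerate_error")
  expect_error(cohens_kappa(confusion_matrix(matrix(0, 2, 2))),
               class = "spatzone_empty_input_error")
})

test_that("kappa is invariant under category permutation", {
  set.seed(3)
  l1 <- sample(event_types(), 80, TRUE)
  l2 <- sample(event_types(), 80, TRUE)
  k1 <- cohens_kappa(build_confusion(l1, l2, event_types()))$kappa
  k2 <- cohens_kappa(build_confusion(l1, l2, rev(event_types())))$kappa
  expect_equal(k1, k2, tolerance = 1e-14)
})

test_that("kappa and percentage agreement match brute-force oracles", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(10:150, 1)
    l1 <- sample(event_types(), n, TRUE)
    l2 <- ifelse(stats::runif(n) < 0.7, l1, sample(event_types(), n, TRUE))
    k <- cohens_kappa(build_confusion(l1, l2, event_types()))$kappa
    expect_equal(k, oracle_kappa(l1, l2, event_types()), tolerance = 1e-13)
    expect_equal(percentage_agreement(l1, l2, `==`), oracle_pct(l1, l2),
                 tolerance = 1e-13)
  }
})

test_that("percentage agreement bounds and errors", {
  expect_identical(percentage_agreement(c(a = "x", b = "y"), c(a = "x", b = "y")), 1)
  expect_identical(percentage_agreement(c("x", "y"), c("y", "x")), 0)
  expect_error(percentage_agreement(character(), character()),
               class = "spatzone_empty_input_error")
})

test_that("temporal comparator requires identity of all six attributes", {
  base <- do.call(event_predicate, c(list(id = "a", span = c(0L, 4L)),
                                     normal_attrs(loc = "Tokyo")))
  same <- base; same$id <- "b"
  expect_true(temporal_comparator(base, same))

  diff_dir <- same; diff_dir$etime_dir <- "BEFORE"
  expect_false(temporal_comparator(base, diff_dir))

  kind_mismatch <- same; kind_mismatch$stime <- time_point(symbol = "PAST")
  expect_false(temporal_comparator(base, kind_mismatch))

  info <- event_predicate("c", c(0L, 4L), "Event_Info")
  expect_error(temporal_comparator(base, info), class = "spatzone_domain_error")
})

test_that("exact spatial comparison is normalized set equality", {
  expect_true(spatial_exact_comparator("Tokyo", "Tokyo"))
  expect_true(spatial_exact_comparator("Tokyo", " tokyo "))
  expect_false(spatial_exact_comparator("Tokyo", "Japan"))
  expect_false(spatial_exact_comparator("Bangkok, Thailand", "Bangkok"))
  expect_true(spatial_exact_comparator(character(), character()))
  expect_true(spatial_exact_comparator(c("Tokyo", "Osaka"), c("Osaka", "Tokyo")))
})

test_that("approximate spatial comparison accepts partial and partitive matches", {
  g <- tiny_gazetteer()
  expect_true(spatial_approx_comparator("Bangkok, Thailand", "Bangkok", g))
  expect_true(spatial_approx_comparator("Tokyo", "Japan", g))
  expect_true(spatial_approx_comparator("Japan", "Tokyo", g)) # either direction
  expect_false(spatial_approx_comparator("Tokyo", "Hanoi", g))
  expect_false(spatial_approx_comparator("Tokyo", "Hanoi", NULL))
  expect_true(spatial_approx_comparator(character(), character(), g))
  expect_false(spatial_approx_comparator("Tokyo", character(), g))

  # strict variant: every location on each side must match something
  expect_true(spatial_approx_comparator(c("Tokyo", "Hanoi"), "Japan", g, mode = "some"))
  expect_false(spatial_approx_comparator(c("Tokyo", "Hanoi"), "Japan", g, mode = "all"))
  expect_true(spatial_approx_comparator(c("Tokyo", "Hanoi"),
                                        c("Japan", "Vietnam"), g, mode = "all"))
})

test_that("approximate agreement dominates exact agreement on random location sets", {
  g <- tiny_gazetteer()
  pool <- c("Japan", "Tokyo", "Thailand", "Bangkok", "Bangkok, Thailand",
            "Vietnam", "Hanoi")
  set.seed(99)
  for (i in 1:200) {
    a <- sample(pool, sample(0:2, 1))
    b <- sample(pool, sample(0:2, 1))
    if (spatial_exact_comparator(a, b)) {
      expect_true(spatial_approx_comparator(a, b, g))
      expect_true(spatial_approx_comparator(a, b, g, mode = "all"))
    }
  }
})

test_that("per-class stratification matches exhaustive per-class tallies", {
  ids <- sprintf("i%d", 1:12)
  cls <- rep(c("Event_Normal", "Event_Report", "Event_Info"), each = 4)
  l1 <- stats::setNames(c("a", "a", "a", "a", "b", "b", "b", "b", "c", "c", "c", "c"), ids)
  l2 <- stats::setNames(c("a", "a", "x", "x", "b", "b", "b", "x", "c", "x", "x", "x"), ids)
  res <- per_class_agreement(l1, l2, comparator = `==`, classes = cls)
  expect_equal(unname(res["Event_Normal"]), 2 / 4)
  expect_equal(unname(res["Event_Report"]), 3 / 4)
  expect_equal(unname(res["Event_Info"]), 1 / 4)
  expect_equal(unname(res["All classes"]), 6 / 12)
  # oracle check per stratum
  for (cl in unique(cls)) {
    idx <- cls == cl
    expect_equal(unname(res[cl]), oracle_pct(as.list(l1[idx]), as.list(l2[idx])))
  }

  ident <- per_class_agreement(l1, l1, comparator = `==`, classes = cls)
  expect_true(all(ident == 1))
})

test_that("confusion matrices round-trip through CSV", {
  fixtures <- zoning_confusion_matrices()
  tmp <- tempfile(fileext = ".csv")
  write_confusion_csv(fixtures$set1, tmp)
  back <- read_confusion_csv(tmp)
  expect_identical(unname(back$counts), unname(fixtures$set1$counts))
  expect_identical(back$categories, fixtures$set1$categories)
})
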