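test_that("threshold classifiers follow the published bands", {
  expect_identical(as.character(classify_enc(c(0.05, 0.12, 0.25))),
                   c("NORMAL", "LOW", "HIGH"))
  # boundary values go to the higher-risk side
  expect_identical(as.character(classify_enc(c(0.08, 0.18))), c("LOW", "HIGH"))
  expect_error(classify_enc(1.5), class = "qtp_validation_error")

  expect_identical(as.character(classify_nddn3(c(30, 23, 15))),
                   c("NORMAL", "LOW", "HIGH"))
  # the LOW band is inclusive on both sides
  expect_identical(as.character(classify_nddn3(c(21, 25))), c("LOW", "LOW"))
  expect_error(classify_nddn3(-1), class = "qtp_validation_error")
})

test_that("grade collapse maps the CIN ladder onto disease groups", {
  expect_identical(
    as.character(collapse_grade(c("NORMAL", "CIN1", "CIN2", "CIN3"))),
    c("NORMAL", "LOW", "HIGH", "HIGH")
  )
  expect_true(is.ordered(collapse_grade("CIN1")))
  expect_error(collapse_grade("CIN4"), class = "qtp_validation_error")
})

test_that("the packaged contingency table matches the published counts", {
  tab <- colposcopy_table()
  expect_identical(sum(tab), 46L)
  expect_identical(unname(colSums(tab)), c(13, 18, 9, 6))
  expect_identical(unname(rowSums(tab)), c(17, 5, 24))
})

test_that("colposcopy benchmark metrics reproduce the published percents", {
  tab <- colposcopy_table()
  hg <- diagnostic_metrics(tab, "high_grade")
  expect_identical(c(hg$sensitivity_pct, hg$specificity_pct), c(73, 58))
  expect_identical(c(hg$tp, hg$fn, hg$tn, hg$fp), c(11L, 4L, 18L, 13L))
  any <- diagnostic_metrics(tab, "any_lesion")
  expect_identical(c(any$sensitivity_pct, any$specificity_pct), c(75, 69))
  expect_identical(hg$tp + hg$fn + hg$tn + hg$fp, sum(tab))
})

test_that("metric identities: perfect table, truncation, and margin swap", {
  perfect <- contingency_table(matrix(
    c(10, 0, 0, 0, 5, 0, 0, 0, 3, 0, 0, 2), nrow = 3,
    dimnames = list(c("NORMAL", "LOW", "HIGH"),
                    c("NORMAL", "CIN1", "CIN2", "CIN3"))
  ))
  m <- diagnostic_metrics(perfect, "high_grade")
  expect_identical(c(m$sensitivity_pct, m$specificity_pct), c(100, 100))

  # truncation contract: printed percent = floor(100 * ratio)
  tab <- colposcopy_table()
  any <- diagnostic_metrics(tab, "any_lesion")
  expect_identical(any$sensitivity_pct, floor(100 * 25 / 33))
  expect_false(any$sensitivity_pct == round(100 * 25 / 33))

  # swapping the positive/negative roles swaps sensitivity and specificity:
  # rebuild the table so the old negatives play the positive part
  hg <- diagnostic_metrics(tab, "high_grade")
  swapped <- matrix(0L, 3, 4, dimnames = dimnames(tab))
  swapped["HIGH", "CIN2"] <- hg$tn     # new tp = old tn
  swapped["NORMAL", "CIN2"] <- hg$fp   # new fn = old fp
  swapped["HIGH", "NORMAL"] <- hg$fn   # new fp = old fn
  swapped["NORMAL", "NORMAL"] <- hg$tp # new tn = old tp
  sw <- diagnostic_metrics(contingency_table(swapped), "high_grade")
  expect_identical(sw$sensitivity_pct, hg$specificity_pct)
  expect_identical(sw$specificity_pct, hg$sensitivity_pct)

  # degenerate margins are errors
  empty_pos <- contingency_table(matrix(
    c(5, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 0), nrow = 3,
    dimnames = dimnames(tab)
  ))
  expect_error(diagnostic_metrics(empty_pos, "high_grade"),
               class = "qtp_insufficient_data_error")
})

test_that("ordinal Spearman reproduces the published coefficient", {
  tab <- colposcopy_table()
  expect_equal(round(spearman_ordinal(tab, collapse = TRUE), 2), 0.43)
  # the four-level coding gives a different value: the collapse matters
  expect_false(round(spearman_ordinal(tab, collapse = FALSE), 2) == 0.43)
  # perfectly concordant diagonal table
  diag3 <- contingency_table(matrix(
    c(8, 0, 0, 0, 6, 0, 0, 0, 5), nrow = 3,
    dimnames = list(c("NORMAL", "LOW", "HIGH"), c("NORMAL", "LOW", "HIGH"))
  ))
  expect_equal(spearman_ordinal(diag3), 1.0, tolerance = 1e-12)
})

test_that("ordinal Spearman matches the brute-force mid-rank oracle", {
  withr::with_seed(5, {
    for (k in 1:10) {
      m <- random_contingency()
      tab <- contingency_table(m)
      expect_equal(spearman_ordinal(tab, collapse = TRUE),
                   oracle_spearman(m, collapse = TRUE), tolerance = 1e-12)
      expect_equal(spearman_ordinal(tab, collapse = FALSE),
                   oracle_spearman(m, collapse = FALSE), tolerance = 1e-12)
    }
  })
})

test_that("ordinal Spearman is invariant under strictly increasing recoding", {
  tab <- colposcopy_table()
  # recoding the ordinal levels cannot change a rank correlation; verify by
  # expanding manually with stretched codes
  counts <- unclass(tab)
  x <- rep(c(1, 10, 100), rowSums(counts))
  code <- c(2, 5, 7, 7)  # collapsed histology, arbitrarily stretched
  y <- unlist(lapply(1:3, function(r) rep(code, counts[r, ])))
  expect_equal(spearman_ordinal(tab, collapse = TRUE), cor(rank(x), rank(y)),
               tolerance = 1e-12)
})

test_that("two-group LSD equals the pooled-variance t-test", {
  withr::with_seed(8, {
    df <- data.frame(v = c(rnorm(12), rnorm(15, 0.8)),
                     g = rep(c("a", "b"), c(12, 15)))
  })
  fit <- anova_lsd(df, v, g)
  tt <- t.test(v ~ g, data = df, var.equal = TRUE)
  expect_equal(tidy(fit)$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(abs(tidy(fit)$t), abs(unname(tt$statistic)), tolerance = 1e-12)
  expect_equal(glance(fit)$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("identical groups give F near zero and p near one", {
  df <- data.frame(v = rep(c(1, 2, 3, 4), 3), g = rep(c("a", "b", "c"), each = 4))
  fit <- anova_lsd(df, v, g)
  expect_lt(glance(fit)$f_statistic, 1e-20)
  expect_true(all(tidy(fit)$p_value > 1 - 1e-10))
  expect_error(anova_lsd(data.frame(v = 1:3, g = c("a", "a", "b")), v, g),
               class = "qtp_validation_error")
})

test_that("LSD detects 2-sd shifts and holds its size on equal pairs", {
  n <- 20
  reject <- matrix(0, 500, 3)
  withr::with_seed(123, {
    for (r in 1:500) {
      df <- data.frame(
        v = c(rnorm(n), rnorm(n), rnorm(n, 2)),  # a = b, c shifted 2 sd
        g = rep(c("a", "b", "c"), each = n)
      )
      p <- tidy(anova_lsd(df, v, g))$p_value
      reject[r, ] <- p < 0.05
    }
  })
  # pairs: (a,b), (a,c), (b,c)
  expect_lt(mean(reject[, 1]), 0.10)       # type I close to nominal
  expect_gt(mean(reject[, 2]), 0.95)       # shifted pairs essentially always found
  expect_gt(mean(reject[, 3]), 0.95)
})

test_that("depth evaluation reports both tasks per feature and depth", {
  feats <- tibble::tibble(
    specimen_id = rep(sprintf("s%d", 1:6), times = 3),
    depth_um = rep(c(0, 15, 30), each = 6),
    enc_ratio = rep(c(0.04, 0.05, 0.12, 0.13, 0.25, 0.30), 3),
    nddn3_um = rep(c(28, 30, 23, 22, 18, 15), 3),
    truth = rep(c("NORMAL", "NORMAL", "CIN1", "CIN1", "CIN2", "CIN3"), 3)
  )
  ev <- evaluate_depths(feats)
  expect_identical(nrow(ev), 3L * 2L * 2L)
  # identical frames at all depths give identical metrics
  expect_identical(length(unique(split(ev$sensitivity_pct, ev$depth_um))), 1L)
  # this synthetic layout classifies perfectly
  expect_true(all(ev$sensitivity_pct == 100) && all(ev$specificity_pct == 100))

  # a depth predicting all-NORMAL under mixed truth has zero sensitivity
  all_norm <- dplyr::mutate(feats[feats$depth_um == 0, ],
                            enc_ratio = 0.05, nddn3_um = 30)
  ev0 <- evaluate_depths(all_norm)
  expect_true(all(ev0$sensitivity_pct == 0))

  expect_error(evaluate_depths(dplyr::mutate(feats, truth = NA)),
               class = "qtp_validation_error")
})
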