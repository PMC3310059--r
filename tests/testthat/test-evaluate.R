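# Response evaluation: EULAR classification, cluster labelling, confusion
# arithmetic, reconstruction from printed percentages, cohort summaries,
# and the composed validation chain.

test_that("EULAR classification follows the DAS28 thresholds", {
  expect_equal(eular_response(5.3, 3.1), "good")
  expect_equal(eular_response(4.8, 4.7), "none")
  expect_equal(eular_response(6.0, 4.0), "moderate")
  # boundary behaviour: improvement exactly 1.2 is not good; attained > 5.1
  # with sub-1.2 improvement is none
  expect_equal(eular_response(4.5, 3.2), "good")
  expect_equal(eular_response(4.4, 3.2), "moderate")
  expect_equal(eular_response(6.0, 5.2), "none")
  expect_equal(eular_response(6.4, 5.2), "none")
  expect_equal(eular_response(6.6, 5.2), "moderate")
  expect_error(eular_response(11, 3), "\\[0, 10\\]")
  expect_error(eular_response(5, -1), "\\[0, 10\\]")
})

test_that("cluster labelling follows majority with max-accuracy fallback", {
  # decisive majorities
  m1 <- label_clusters(c(1, 1, 1, 1, 2, 2),
                       c("none", "none", "none", "good", "good", "good"))
  expect_equal(m1$mapping, c("1" = "none", "2" = "good"))
  expect_true(m1$majority_decisive)
  # cluster 1 tied, cluster 2 majority good: max(tp+tn) resolves
  m2 <- label_clusters(c(1, 1, 2, 2, 2),
                       c("none", "good", "none", "good", "good"))
  expect_equal(m2$mapping, c("1" = "none", "2" = "good"))
  expect_false(m2$majority_decisive)
  expect_equal(unname(m2$accuracy_counts), c(3, 2))
  # pure clusters: perfect accuracy
  m3 <- label_clusters(c(1, 1, 2), c("none", "none", "good"))
  cm3 <- confusion(c(1, 1, 2), m3, c("none", "none", "good"))
  expect_equal(cm3$tp + cm3$tn, 3)
  expect_error(label_clusters(c(1, 1, 1), c("none", "good", "none")),
               "empty")
  expect_error(label_clusters(c(1, 2), c("none", "none")), "both response")
})

test_that("confusion counts follow the non-responder-positive convention", {
  labels <- rep(c("none", "good"), c(24, 18))
  all_right <- rep(c(1, 2), c(24, 18))
  cm <- confusion(all_right, c("1" = "none", "2" = "good"), labels)
  expect_equal(unclass(cm)[c("tp", "fn", "tn", "fp")],
               list(tp = 24L, fn = 0L, tn = 18L, fp = 0L))
  swapped <- confusion(all_right, c("1" = "good", "2" = "none"), labels)
  expect_equal(unclass(swapped)[c("tp", "fn", "tn", "fp")],
               list(tp = 0L, fn = 24L, tn = 0L, fp = 18L))
  # constructed fixture: 17 of 24 NR correct, 11 of 18 R correct
  assign <- c(rep(1, 17), rep(2, 7), rep(2, 11), rep(1, 7))
  cmf <- confusion(assign, c("1" = "none", "2" = "good"), labels)
  expect_equal(unclass(cmf)[c("tp", "fn", "tn", "fp")],
               list(tp = 17L, fn = 7L, tn = 11L, fp = 7L))
  expect_error(confusion(c(1, 2), c("1" = "none", "2" = "good"),
                         c("none", "moderate")), "good")
})

test_that("sensitivity and specificity round half-up to integer percent", {
  cm <- confusion_matrix(17, 7, 11, 7)
  expect_equal(sensitivity(cm), 71)
  expect_equal(specificity(cm), 61)
  expect_equal(sensitivity(cm, digits = 2), 70.83)
  perfect <- confusion_matrix(24, 0, 18, 0)
  expect_equal(sensitivity(perfect), 100)
  expect_equal(specificity(perfect), 100)
  julia <- confusion_matrix(22, 2, 3, 15)
  expect_equal(sensitivity(julia), 92)
  expect_equal(specificity(julia), 17)
  expect_error(sensitivity(confusion_matrix(0, 0, 3, 1)), "undefined")
  expect_error(specificity(confusion_matrix(3, 1, 0, 0)), "undefined")
})

test_that("reconstruction inverts printed percentages", {
  r <- reconstruct_confusion(71, 61, 24, 18)
  expect_true(r$unique)
  expect_equal(r$matrices[[1]]$tp, 17L)
  expect_equal(r$matrices[[1]]$tn, 11L)
  r2 <- reconstruct_confusion(100, 100, 24, 18)
  expect_true(r2$unique)
  expect_equal(r2$matrices[[1]]$tp, 24L)
  r3 <- reconstruct_confusion(67, 33, 24, 18)
  expect_true(r3$unique)
  expect_equal(c(r3$matrices[[1]]$tp, r3$matrices[[1]]$tn), c(16L, 6L))
  # impossible pair -> empty, not an error
  r4 <- reconstruct_confusion(99, 99, 4, 4)
  expect_length(r4$matrices, 0)
  expect_false(r4$unique)
})

test_that("reconstruction composed with scoring is the identity", {
  set.seed(3)
  for (i in 1:20) {
    n_nr <- sample(5:30, 1); n_r <- sample(5:30, 1)
    tp <- sample(0:n_nr, 1); tn <- sample(0:n_r, 1)
    cm <- confusion_matrix(tp, n_nr - tp, tn, n_r - tn)
    s1 <- sensitivity(cm); s2 <- specificity(cm)
    rec <- reconstruct_confusion(s1, s2, n_nr, n_r)
    for (m in rec$matrices) {
      expect_equal(sensitivity(m), s1)
      expect_equal(specificity(m), s2)
    }
    expect_true(any(vapply(rec$matrices, function(m)
      m$tp == tp && m$tn == tn, logical(1))))
  }
})

test_that("Welch test from summaries matches t.test on raw data", {
  w <- welch_from_summary(2.0, 0.8, 18, 0.1, 1.0, 24)
  expect_equal(w$t, 6.84, tolerance = 0.001)
  expect_equal(w$df, 39.8, tolerance = 0.001)
  expect_lt(w$p, 1e-4)
  set.seed(10)
  a <- rnorm(12, 1); b <- rnorm(15)
  ref <- t.test(a, b)
  got <- welch_from_summary(mean(a), sd(a), 12, mean(b), sd(b), 15)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("cohort summary reproduces within-group percentages and the Welch p", {
  labels <- rep(c("good", "none"), c(18, 24))
  cov <- generate_covariates(labels, seed = 1)
  das <- generate_das28(labels, seed = 2)
  md <- data.frame(sample_id = sprintf("P%02d", 1:42), response = labels,
                   das, cov)
  s <- cohort_summary(md)
  expect_equal(s$good$n, 18); expect_equal(s$none$n, 24)
  expect_equal(s$good$pct_of_cohort, 43)
  expect_equal(s$none$pct_of_cohort, 57)
  expect_equal(s$good$female_pct, 89)
  expect_equal(s$none$female_pct, 58)
  expect_equal(s$good$rf_pct, 72)
  expect_equal(s$none$rf_pct, 79)
  expect_lt(s$das28_decrease_welch$p, 1e-4)
  expect_error(cohort_summary(md[md$response == "good", ]), "empty")
})

test_that("validate_signature recovers a strong synthetic signal perfectly", {
  co <- small_cohort(effect = 2, sd = 0.3, seed = 1)
  rep <- validate_signature(co$expr, co$metadata, signature_from_cohort(co),
                            cluster_config(seed = 5))
  expect_equal(rep$sensitivity, 100)
  expect_equal(rep$specificity, 100)
  expect_equal(rep$confusion$tp, 24L)
  expect_equal(rep$confusion$tn, 18L)
  expect_true(rep$mapping$usable)
})

test_that("scores are invariant to cluster index swaps", {
  labels <- rep(c("none", "good"), c(6, 6))
  assign <- c(1, 1, 1, 1, 2, 2, 2, 2, 2, 1, 2, 2)
  cm_a <- confusion(assign, label_clusters(assign, labels), labels)
  flipped <- 3 - assign
  cm_b <- confusion(flipped, label_clusters(flipped, labels), labels)
  expect_equal(sensitivity(cm_a), sensitivity(cm_b))
  expect_equal(specificity(cm_a), specificity(cm_b))
})

test_that("unusable signatures fail with a stage-tagged error", {
  co <- small_cohort(n_genes = 50, n_sig = 5, seed = 3)
  foreign <- gene_signature("foreign", c("NOT1", "NOT2", "NOT3"))
  expect_error(validate_signature(co$expr, co$metadata, foreign),
               "\\[map_signature\\]")
})
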