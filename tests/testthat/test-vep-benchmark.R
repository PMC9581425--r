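make_table <- function(m, inverse = character()) {
  vep_table(m, setNames(rep("inverse", length(inverse)), inverse))
}

test_that("orientation flips inverse columns exactly once", {
  m <- cbind(direct = c(1, 2, 3), inv = c(-3, -1, 2))
  rownames(m) <- paste0("T1:A", 1:3, "G")
  tab <- make_table(m, "inv")
  o <- orient_scores(tab)
  expect_equal(unname(o$scores[, "inv"]), c(3, 1, -2))
  expect_equal(unname(o$scores[, "direct"]), c(1, 2, 3))
  expect_true(all(o$orientation == "direct"))
  # re-application is the identity once flags are updated
  expect_identical(orient_scores(o)$scores, o$scores)
})

test_that("AUC equals brute-force pair counting and the trapezoidal ROC area", {
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1.0)
  expect_equal(roc_auc(c(0.5, 0.5), c(TRUE, FALSE))$auc, 0.5)

  set.seed(19)
  for (rep in 1:30) {
    n <- sample(4:30, 1)
    scores <- round(rnorm(n), sample(c(0, 1, 3), 1))  # induce ties sometimes
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, auc_oracle(scores, labels), tolerance = 1e-12)
    expect_equal(r$auc, trapezoid_area(r$fpr, r$tpr), tolerance = 1e-12)
    # curve is monotone from (0,0) to (1,1)
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(tail(r$fpr, 1), tail(r$tpr, 1)), c(1, 1))
    # complement and transform invariances
    expect_equal(r$auc + roc_auc(scores, !labels)$auc, 1, tolerance = 1e-12)
    expect_equal(roc_auc(qnorm(pnorm(scores)) * 3 + 1, labels)$auc, r$auc,
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE), stratum = "T9"), "T9")
})

test_that("AUC agrees with the field-standard ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- round(rnorm(60), 1)
  labels <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  ours <- roc_auc(scores, labels)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                              direction = "<", quiet = TRUE)))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("oriented AUC of an inverse predictor complements its raw AUC", {
  set.seed(33)
  raw <- rnorm(40) + rep(c(-1, 0), each = 20)  # inverse scale: pathogenic lower
  labels <- rep(c("pathogenic", "gnomad"), each = 20)
  naive <- roc_auc(raw, labels)$auc
  m <- cbind(DeepSequence = raw)
  rownames(m) <- paste0("T1:A", 1:40, "G")
  oriented <- orient_scores(make_table(m, "DeepSequence"))
  expect_equal(roc_auc(oriented$scores[, 1], labels)$auc, 1 - naive,
               tolerance = 1e-12)
})

test_that("stratified AUC recovers planted per-predictor effects and strata rules", {
  seqs <- setNames(lapply(c(61, 62), random_seq, n = 120), c("ND1", "OT1"))
  reg <- toy_registry(unlist(seqs), phenotype = c("neurodevelopmental", "other"),
                      family = c("alpha", "beta"))
  cat1 <- make_variant_catalog(9, reg, n_path_per_isotype = 40,
                               n_benign_per_isotype = 40)
  sm <- make_score_matrix(10, catalog = cat1,
                          predictors = data.frame(
                            name = c("strong", "null"), d = c(2, 0),
                            inverse = c(FALSE, FALSE), missing_rate = 0))
  o <- orient_scores(sm$table)
  g <- stratified_auc(o, cat1, "global")
  expect_equal(dim(g), c(2L, 1L))
  expect_gt(g["strong", "global"], 0.85)   # Phi(2/sqrt(2)) ~ 0.92
  expect_lt(abs(g["null", "global"] - 0.5), 0.12)

  by_iso <- stratified_auc(o, cat1, "isotype", min_pathogenic = 10)
  expect_setequal(colnames(by_iso), c("ND1", "OT1"))
  by_grp <- stratified_auc(o, cat1, "phenotype_group")
  expect_setequal(colnames(by_grp), c("neurodevelopmental", "other"))
  expect_true(all(by_grp["strong", ] > 0.8))

  # a raised pathogenic floor can empty the stratification
  expect_error(stratified_auc(o, cat1, "isotype", min_pathogenic = 100),
               "no strata")
  cmp <- phenotype_group_auc_test(by_grp)
  expect_true(cmp$p_value > 0 && cmp$p_value <= 1)
  expect_equal(nrow(cmp$pairs), 2)
})

test_that("the optimal threshold minimises distance to the ROC corner on the native scale", {
  # perfect separation: midpoint of the two boundary scores, distance 0
  sep <- optimal_native_threshold(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$threshold, 3.5)
  expect_equal(sep$distance, 0)
  expect_equal(sep$direction, "above")

  # inverse predictors report on the native scale with direction "below"
  inv <- optimal_native_threshold(c(-8, -7, -2, -1), c(TRUE, TRUE, FALSE, FALSE),
                                  orientation = "inverse")
  expect_equal(inv$threshold, -4.5)
  expect_equal(inv$direction, "below")

  # matches an exhaustive scan over all cut positions
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(6:25, 1)
    scores <- round(rnorm(n), 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    got <- optimal_native_threshold(scores, labels)
    n_pos <- sum(labels); n_neg <- sum(!labels)
    cands <- c(-Inf, sort(unique(scores)), Inf)
    dists <- vapply(cands, function(t) {
      sqrt((sum(!labels & scores >= t) / n_neg)^2 +
             (1 - sum(labels & scores >= t) / n_pos)^2)
    }, numeric(1))
    expect_equal(got$distance, min(dists), tolerance = 1e-12)
  }
  expect_error(optimal_native_threshold(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("missingness is reported per predictor", {
  m <- cbind(a = c(1, NA, 3, 4, 5, 6, 7, 8, 9, 10), b = 1:10)
  rownames(m) <- paste0("T1:A", 1:10, "G")
  mis <- missingness(make_table(m))
  expect_equal(unname(mis["a"]), 0.1)
  expect_equal(unname(mis["b"]), 0.0)
})
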