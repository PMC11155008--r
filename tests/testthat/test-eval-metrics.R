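# exhaustive pairwise-concordance AUC oracle
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

test_that("RECIST mapping is total, two-valued, and correct", {
  expect_equal(map_recist("CR"), "responsive")
  expect_equal(map_recist("PR"), "responsive")
  expect_equal(map_recist("SD"), "nonresponsive")
  expect_equal(map_recist("PD"), "nonresponsive")
  expect_setequal(unique(map_recist(c("CR", "PR", "SD", "PD"))),
                  c("responsive", "nonresponsive"))
  expect_error(map_recist("XX"), "unknown RECIST")
})

test_that("AUC equals the pairwise concordance oracle, ties count half", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  set.seed(42)
  for (rep in 1:5) {
    scores <- round(runif(20), 1)  # coarse grid forces ties
    labels <- rbinom(20, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_lt(abs(roc_auc(scores, labels) - auc_oracle(scores, labels)),
              1e-12)
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- runif(50)
  labels <- rbinom(50, 1, 0.5)
  labels[1:2] <- c(0, 1)
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(labels, scores, direction = "<", quiet = TRUE))
  ))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("AUC invariances: monotone transforms and label complement", {
  set.seed(9)
  scores <- rnorm(30)
  labels <- rbinom(30, 1, 0.4)
  labels[1:2] <- c(0, 1)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a, tolerance = 1e-12)
  expect_equal(roc_auc(3 * scores + 2, labels), a, tolerance = 1e-12)
  # flipping labels alone reverses the ranking
  expect_equal(roc_auc(scores, 1 - labels), 1 - a, tolerance = 1e-12)
  # flipping labels AND scores leaves it unchanged
  expect_equal(roc_auc(-scores, 1 - labels), a, tolerance = 1e-12)
})

test_that("bootstrap CI is seeded, ordered, and tight when separable", {
  set.seed(3)
  scores <- c(runif(100, 0.6, 1), runif(100, 0, 0.4))
  labels <- rep(c(1, 0), each = 100)
  ci <- bootstrap_auc_ci(scores, labels, n_boot = 500, seed = 11)
  expect_identical(bootstrap_auc_ci(scores, labels, n_boot = 500, seed = 11),
                   ci)
  expect_lte(ci[["lower"]], ci[["upper"]])
  expect_gte(ci[["lower"]], 0.95)
  expect_equal(ci[["upper"]], 1)
})

test_that("bootstrap CI covers a known AUC at roughly the nominal rate", {
  # binormal scores: positives N(mu, 1), negatives N(0, 1),
  # true AUC = pnorm(mu / sqrt(2))
  mu <- 1
  true_auc <- pnorm(mu / sqrt(2))
  set.seed(123)
  covered <- vapply(1:200, function(trial) {
    scores <- c(rnorm(20, mu), rnorm(20))
    labels <- rep(c(1, 0), each = 20)
    ci <- bootstrap_auc_ci(scores, labels, n_boot = 400,
                           seed = 1000 + trial)
    ci[["lower"]] <= true_auc && true_auc <= ci[["upper"]]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("confusion rates satisfy the exact accuracy decomposition", {
  set.seed(5)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.5)
  labels[1:2] <- c(0, 1)
  r <- confusion_and_rates(scores, labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  expect_equal(r$accuracy,
               (r$recall * n_pos + r$specificity * n_neg) / 40)
  expect_equal(sum(r$confusion), 40)

  perfect <- confusion_and_rates(labels, labels)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$confusion[1, 2] + perfect$confusion[2, 1], 0)

  all_pos <- confusion_and_rates(rep(1, 40), labels)
  expect_equal(all_pos$recall, 1)
  expect_equal(all_pos$specificity, 0)
})

test_that("a 32-patient test cohort reproduces the published row shape", {
  # 17 of one class, 15 of the other; 11 correct in each class
  labels <- rep(c(1, 0), c(15, 17))
  scores <- c(rep(0.9, 11), rep(0.1, 4),   # positives: 11 right, 4 wrong
              rep(0.1, 11), rep(0.9, 6))   # negatives: 11 right, 6 wrong
  r <- confusion_and_rates(scores, labels)
  expect_equal(r$accuracy, 22 / 32)
  expect_equal(round(r$accuracy, 3), 0.688)
  expect_equal(r$recall, 11 / 15)
  expect_equal(round(r$recall, 3), 0.733)
  expect_equal(round(11 / 17, 3), 0.647)
  expect_equal(r$specificity, 11 / 17)
})

test_that("metrics_report bundles rates, AUC, and CI consistently", {
  set.seed(8)
  scores <- runif(30)
  labels <- ifelse(rbinom(30, 1, 0.5) == 1, "responsive", "nonresponsive")
  labels[1:2] <- c("responsive", "nonresponsive")
  rep1 <- metrics_report(scores, labels, n_boot = 200, seed = 4)
  expect_s3_class(rep1, "metrics_report")
  expect_equal(rep1$auc,
               roc_auc(scores, as.integer(labels == "responsive")))
  expect_lte(rep1$auc_ci[["lower"]], rep1$auc)
  expect_gte(rep1$auc_ci[["upper"]], rep1$auc)
  expect_equal(rep1$n, 30)
  # positive-class orientation is configurable, flipping recall/specificity
  rep2 <- metrics_report(1 - scores, labels, positive = "nonresponsive",
                         n_boot = 0)
  expect_equal(rep2$auc, rep1$auc, tolerance = 1e-12)
})

test_that("roc_curve spans (0,0) to (1,1) and matches the AUC trapezoid", {
  set.seed(10)
  scores <- runif(25)
  labels <- rbinom(25, 1, 0.5)
  labels[1:2] <- c(0, 1)
  rc <- roc_curve(scores, labels)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_equal(rc$tpr[nrow(rc)], 1)
  trap <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
  expect_equal(trap, roc_auc(scores, labels), tolerance = 1e-12)
})
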