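test_that("biomarker selection walks the ranking and applies the SD filter", {
  genes <- sprintf("g%02d", 1:10)
  rk <- ranking_from_order(genes)
  set.seed(2)
  expr <- matrix(stats::rnorm(10 * 30, sd = 10), 10, 30,
                 dimnames = list(genes, sprintf("s%02d", 1:30)))
  expect_equal(select_biomarkers(rk, expr, top_k = 7, sd_threshold = 5),
               genes[1:7])

  # a low-variance gene in the middle of the ranking is skipped
  expr2 <- expr
  expr2["g02", ] <- 100   # constant: SD 0
  expect_equal(select_biomarkers(rk, expr2, top_k = 7, sd_threshold = 5),
               genes[c(1, 3:8)])

  expect_error(select_biomarkers(rk, expr * 0, top_k = 7, sd_threshold = 5),
               "0 gene")
})

test_that("k-means recovers well-separated groups deterministically", {
  set.seed(8)
  genes <- sprintf("b%d", 1:4)
  grp_truth <- rep(c(1, 2), each = 25)
  centers <- matrix(c(0, 10), 1)[, grp_truth] # 10-SD separation at sd = 1
  expr <- matrix(stats::rnorm(4 * 50, mean = rep(centers, each = 4)), 4, 50,
                 dimnames = list(genes, sprintf("s%02d", 1:50)))
  lab <- cluster_patients(expr, seed = 4)
  agreement <- max(mean(lab == grp_truth), mean(lab == 3 - grp_truth))
  expect_gt(agreement, 0.95)

  expect_identical(cluster_patients(expr, seed = 4), lab)

  # duplicated samples co-cluster
  expr_dup <- cbind(expr, expr)
  colnames(expr_dup) <- sprintf("d%03d", 1:100)
  lab_dup <- cluster_patients(expr_dup, seed = 4)
  expect_equal(unname(lab_dup[1:50]), unname(lab_dup[51:100]))
})

test_that("log-rank matches the hand-tabulated four-sample case", {
  # group 1: times 1 (event), 3 (event); group 2: times 2 (event), 4 (censored)
  # event-time tabulation (O - E and variance per time):
  #  t=1: at risk 4 (2+2), 1 event  -> E1 = 0.5,  V = 0.25
  #  t=2: at risk 3 (1+2), 1 event  -> E1 = 1/3,  V = 2/9
  #  t=3: at risk 2 (1+1), 1 event  -> E1 = 0.5,  V = 0.25
  # O1 = 2, E1 = 4/3, chisq = (2 - 4/3)^2 / (0.25 + 2/9 + 0.25)
  labels <- c(s1 = 1L, s2 = 2L, s3 = 1L, s4 = 2L)
  surv <- data.frame(sample = c("s1", "s2", "s3", "s4"),
                     time = c(1, 2, 3, 4), event = c(1, 1, 1, 0))
  res <- logrank_compare(labels, surv)
  expect_equal(res$chisq, (2 - 4 / 3)^2 / (0.25 + 2 / 9 + 0.25),
               tolerance = 1e-12)
  expect_false(res$degenerate)
  # group 1 dies earlier: its members are the high-risk group
  expect_equal(as.character(res$labels[c("s1", "s3")]),
               c("high_risk", "high_risk"))
})

test_that("identical survival in both groups gives statistic 0 and p = 1", {
  labels <- stats::setNames(rep(c(1L, 2L), each = 4), sprintf("s%d", 1:8))
  times <- rep(c(2, 5, 7, 9), 2)
  events <- rep(c(1, 0, 1, 1), 2)
  surv <- data.frame(sample = sprintf("s%d", 1:8), time = times,
                     event = events)
  res <- logrank_compare(labels, surv)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
})

test_that("single-group clusterings are flagged degenerate", {
  labels <- stats::setNames(rep(1L, 6), sprintf("s%d", 1:6))
  surv <- data.frame(sample = sprintf("s%d", 1:6), time = 1:6,
                     event = rep(1L, 6))
  res <- logrank_compare(labels, surv)
  expect_true(res$degenerate)
  expect_true(is.na(res$p_value))
})

test_that("high-risk labeling is independent of cluster index", {
  set.seed(14)
  n <- 40
  # group A dies fast, group B slowly
  times <- c(stats::rexp(n, 1 / 100), stats::rexp(n, 1 / 1000))
  surv <- data.frame(sample = sprintf("s%03d", 1:(2 * n)),
                     time = times, event = rep(1L, 2 * n))
  lab_a <- stats::setNames(rep(c(1L, 2L), each = n), surv$sample)
  lab_b <- stats::setNames(rep(c(2L, 1L), each = n), surv$sample)
  res_a <- logrank_compare(lab_a, surv)
  res_b <- logrank_compare(lab_b, surv)
  expect_identical(res_a$labels, res_b$labels)
  expect_equal(as.character(res_a$labels[1]), "high_risk")
})

test_that("log-rank detects a three-fold hazard difference", {
  set.seed(31)
  hits <- replicate(100, {
    n <- 100
    surv <- data.frame(sample = sprintf("s%03d", 1:(2 * n)),
                       time = c(stats::rexp(n, 3), stats::rexp(n, 1)),
                       event = 1L)
    labels <- stats::setNames(rep(c(1L, 2L), each = n), surv$sample)
    logrank_compare(labels, surv)$p_value < 0.01
  })
  expect_gte(sum(hits), 95)
})

test_that("end-to-end stratification separates risk groups on the fixture", {
  env <- get_fixture(1)
  sc <- fixture_scores(env$fx)
  fit <- rank_genes(env$D, sc$SM, sc$SE)
  res <- stratify_patients(fit$ranking, env$fx$tumor_expr,
                           env$fx$survival, seed = 3)
  expect_false(res$degenerate)
  expect_length(res$biomarkers, 7)
  expect_true(all(table(res$labels) > 0))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})
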