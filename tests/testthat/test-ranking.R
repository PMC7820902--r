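test_that("diffusion with beta = 1 leaves scores unchanged", {
  net <- pair_net()
  D <- compute_diffusion(normalize_adjacency(net), beta = 1)
  S <- column_normalize(as_scores(
    matrix(c(1, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))))
  W <- relevance_scores(D, S)
  expect_equal(unname(W[, 1]), c(1, 0))
})

test_that("relevance scores match hand multiplication and conserve mass", {
  D <- compute_diffusion(normalize_adjacency(pair_net()), beta = 0.5)
  S <- column_normalize(as_scores(
    matrix(c(1, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))))
  W <- relevance_scores(D, S)
  expect_equal(unname(W[, 1]), c(2 / 3, 1 / 3), tolerance = 1e-12)

  set.seed(5)
  net <- random_net(15, p = 0.3)
  Dn <- compute_diffusion(normalize_adjacency(net), beta = 0.48)
  M <- matrix(stats::runif(15 * 4), 15, 4,
              dimnames = list(net$genes, sprintf("s%d", 1:4)))
  Wn <- relevance_scores(Dn, column_normalize(as_scores(M)))
  expect_equal(unname(colSums(Wn)), rep(1, 4), tolerance = 1e-8)
})

test_that("gene-order mismatch is an error, not a silent realignment", {
  D <- compute_diffusion(normalize_adjacency(pair_net()), beta = 0.5)
  S <- column_normalize(as_scores(
    matrix(c(1, 0), 2, 1, dimnames = list(c("g2", "g1"), "s1"))))
  expect_error(relevance_scores(D, S), "gene order")
})

test_that("integration strategies obey min <= mean <= max and demote outliers", {
  set.seed(9)
  genes <- sprintf("g%d", 1:6)
  mk <- function(M) structure(M, source = "mutation",
                              class = c("relevance_score_matrix",
                                        "matrix", "array"))
  M <- mk(matrix(stats::runif(18), 6, 3,
                 dimnames = list(genes, c("s1", "s2", "s3"))))
  E <- mk(matrix(stats::runif(18), 6, 3,
                 dimnames = list(genes, c("s1", "s2", "s3"))))
  Wmin <- integrate_scores(M, E, "min")
  Wmean <- integrate_scores(M, E, "mean")
  Wmax <- integrate_scores(M, E, "max")
  expect_true(all(Wmin <= M + 1e-15 & Wmin <= E + 1e-15))
  expect_true(all(Wmin <= Wmean & Wmean <= Wmax))
  expect_equal(unclass_mat(Wmin), pmin(unclass_mat(M), unclass_mat(E)))

  # identical inputs: all strategies are the identity
  expect_equal(unclass_mat(integrate_scores(M, M, "min")), unclass_mat(M))
  expect_equal(unclass_mat(integrate_scores(M, M, "mean")), unclass_mat(M))
  expect_equal(unclass_mat(integrate_scores(M, M, "max")), unclass_mat(M))

  # a gene with high mutation but tiny expression relevance is demoted
  M2 <- mk(matrix(c(0.48, 0.1), 2, 1, dimnames = list(c("a", "b"), "s")))
  E2 <- mk(matrix(c(3.24e-6, 0.1), 2, 1, dimnames = list(c("a", "b"), "s")))
  expect_equal(integrate_scores(M2, E2, "min")["a", "s"], 3.24e-6)

  colnames(E) <- c("s1", "s2", "sX")
  expect_error(integrate_scores(M, E, "min"), "sample sets differ")
})

test_that("per-sample ranks follow the average-rank tie rule", {
  W <- matrix(c(0.5, 0.2, 0.3,
                0.4, 0.4, 0.1,
                0, 0, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  R <- per_sample_ranks(W)
  expect_equal(unname(R[, "s1"]), c(1, 3, 2))
  expect_equal(unname(R[, "s2"]), c(1.5, 1.5, 3))
  expect_equal(unname(R[, "s3"]), c(2, 2, 2))   # total tie: (n+1)/2
  expect_equal(unname(colSums(R)), rep(6, 3))   # n(n+1)/2 invariant
})

test_that("rank aggregation sums ranks and breaks ties lexicographically", {
  R <- matrix(c(1, 2, 3,
                3, 1, 2), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  agg <- aggregate_ranks(R)
  expect_equal(agg$gene, c("g2", "g1", "g3"))
  expect_equal(agg$score, c(3, 4, 5))
  # permuting sample columns changes nothing
  expect_equal(aggregate_ranks(R[, c(2, 1)])$gene, agg$gene)
  # identical rankings across samples reproduce the common order
  R2 <- cbind(s1 = c(g1 = 2, g2 = 1, g3 = 3), s2 = c(2, 1, 3))
  expect_equal(aggregate_ranks(R2)$gene, c("g2", "g1", "g3"))
})

test_that("frequency baseline counts mutated samples", {
  M <- matrix(0, 3, 10, dimnames = list(c("g1", "g2", "g3"),
                                        sprintf("s%d", 1:10)))
  M["g1", 1:3] <- 1
  M["g2", 5] <- 1
  fb <- frequency_baseline(as_scores(M))
  expect_equal(fb$gene[1:2], c("g1", "g2"))
  expect_equal(fb$score[1], 0.3)
  expect_error(frequency_baseline(column_normalize(as_scores(M))),
               "unnormalized")

  empty <- as_scores(M * 0)
  fb0 <- frequency_baseline(empty)
  expect_equal(fb0$gene, c("g1", "g2", "g3"))   # lexicographic fallback
  expect_true(all(fb0$score == 0))
})

test_that("min-source proportions count ties toward both layers", {
  genes <- c("a", "b")
  mk <- function(M, src) structure(M, source = src, strategy = NULL,
                                   class = c("relevance_score_matrix",
                                             "matrix", "array"))
  M <- mk(matrix(c(0.1, 0.5, 0.3, 0.3), 2, 2,
                 dimnames = list(genes, c("s1", "s2"))), "mutation")
  E <- mk(matrix(c(0.2, 0.4, 0.3, 0.6), 2, 2,
                 dimnames = list(genes, c("s1", "s2"))), "expression")
  W <- integrate_scores(M, E, "min")
  pr <- min_source_proportions(M, E, W, genes)
  # mins: s1 a<-M, s1 b<-E, s2 a tie, s2 b<-M => M: 3/4, E: 2/4
  expect_equal(unname(pr), c(0.75, 0.5))
  expect_gte(sum(pr), 1)

  expect_error(min_source_proportions(M, E, W, c("a", "zz")), "not in")
  Wmean <- integrate_scores(M, E, "mean")
  expect_error(min_source_proportions(M, E, Wmean, genes), "min-strategy")

  # identical parents: every cell is a tie, both proportions are 1
  prt <- min_source_proportions(M, M, integrate_scores(M, M, "min"), genes)
  expect_equal(unname(prt), c(1, 1))
  # one parent uniformly below the other: (1, 0)
  Mlo <- structure(unclass_mat(E) / 2, source = "mutation", strategy = NULL,
                   class = c("relevance_score_matrix", "matrix", "array"))
  pr_dom <- min_source_proportions(Mlo, E, integrate_scores(Mlo, E, "min"),
                                   genes)
  expect_equal(unname(pr_dom), c(1, 0))
})

test_that("brute-force cell counts confirm min-source proportions", {
  set.seed(21)
  genes <- sprintf("g%d", 1:8)
  mk <- function(M, src) structure(M, source = src, strategy = NULL,
                                   class = c("relevance_score_matrix",
                                             "matrix", "array"))
  M <- mk(matrix(stats::runif(40), 8, 5,
                 dimnames = list(genes, sprintf("s%d", 1:5))), "mutation")
  E <- mk(matrix(stats::runif(40), 8, 5,
                 dimnames = list(genes, sprintf("s%d", 1:5))), "expression")
  W <- integrate_scores(M, E, "min")
  top <- sample(genes, 4)
  pr <- min_source_proportions(M, E, W, top)
  nm <- 0; ne <- 0; total <- 0
  for (g in top) for (s in colnames(M)) {
    total <- total + 1
    if (W[g, s] == M[g, s]) nm <- nm + 1
    if (W[g, s] == E[g, s]) ne <- ne + 1
  }
  expect_equal(unname(pr), c(nm, ne) / total)
})
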