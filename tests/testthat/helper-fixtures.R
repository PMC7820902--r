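# Shared test fixtures, all built in code.

# three-gene network with edges g1->g2, g2->g1, g1->g3
tiny_net <- function() {
  interaction_network(data.frame(source = c("g1", "g2", "g1"),
                                 target = c("g2", "g1", "g3")))
}

# mutual pair g1 <-> g2
pair_net <- function() {
  interaction_network(data.frame(source = c("g1", "g2"),
                                 target = c("g2", "g1")))
}

# random directed graph on n nodes with edge probability p (no self-loops);
# resamples until at least one edge exists
random_net <- function(n, p = 0.3) {
  repeat {
    adj <- matrix(stats::runif(n * n) < p, n, n)
    diag(adj) <- FALSE
    if (any(adj)) break
  }
  idx <- which(adj, arr.ind = TRUE)
  genes <- sprintf("r%02d", seq_len(n))
  interaction_network(data.frame(source = genes[idx[, 2]],
                                 target = genes[idx[, 1]]))
}

# independent oracle for the diffusion matrix: truncated Neumann series
# beta * sum_k (1-beta)^k Anorm^k
neumann_diffusion <- function(adj, beta, tol = 1e-10) {
  A <- as.matrix(adj$matrix)
  n <- nrow(A)
  term <- diag(nrow = n)
  acc <- term
  k <- 0
  while ((1 - beta)^k >= tol) {
    k <- k + 1
    term <- (1 - beta) * (A %*% term)
    acc <- acc + term
  }
  beta * acc
}

# independent oracle for the partial AUC: explicit double loop over the
# first n negatives and all positives
brute_partial_auc <- function(genes_in_order, gold, n) {
  is_pos <- genes_in_order %in% gold
  T_gold <- sum(is_pos)
  neg_pos <- which(!is_pos)[seq_len(n)]
  total <- 0
  for (np in neg_pos) {
    for (pp in which(is_pos)) if (pp < np) total <- total + 1
  }
  total / (n * T_gold)
}

# ranking object from an ordered gene vector (best first)
ranking_from_order <- function(genes) {
  new_gene_ranking(stats::setNames(seq_along(genes), genes),
                   higher_is_better = FALSE)
}

# unnormalized omics matrix from a plain matrix
as_scores <- function(M, kind = "mutation") {
  minnetrank:::new_omics_score_matrix(M, kind = kind)
}

# one shared default fixture + diffusion, computed once per test run
fixture_env <- new.env()
get_fixture <- function(seed = 1) {
  key <- paste0("fx", seed)
  if (is.null(fixture_env[[key]])) {
    fx <- default_fixture(seed = seed)
    D <- compute_diffusion(normalize_adjacency(fx$network), beta = 0.48)
    fixture_env[[key]] <- list(fx = fx, D = D)
  }
  fixture_env[[key]]
}

# mutation + expression score matrices for a fixture
fixture_scores <- function(fx, scheme = "uniform") {
  w <- suppressWarnings(assign_variant_weights(fx$variants,
                                               weight_scheme(scheme)))
  samples <- sort(unique(fx$pairing$tumor))
  SM <- suppressMessages(build_mutation_scores(w, fx$network, samples))
  SE <- suppressMessages(compute_alfc(fx$tumor_expr, fx$normal_expr,
                                      fx$pairing, fx$network))
  list(SM = SM, SE = SE)
}

# strip class/attrs from an omics or relevance matrix for plain comparison
unclass_mat <- function(x) {
  attributes(x) <- list(dim = dim(x), dimnames = dimnames(x))
  x
}
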