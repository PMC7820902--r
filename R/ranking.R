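#' Construct a gene ranking
#'
#' A `gene_ranking` is a data.frame with columns `rank`, `gene`, `score`,
#' ordered best-first. For rank-sum aggregates the score is a sum of
#' per-sample ranks (lower is better); for centrality or frequency
#' baselines it is a metric value (higher is better). Ties are always
#' broken lexicographically by gene symbol so output files are
#' byte-reproducible.
#'
#' @param scores named numeric vector (names are gene symbols).
#' @param higher_is_better direction of the score.
#' @param rank_matrix optional genes x samples matrix of per-sample ranks
#'   kept for diagnostics.
#' @return a `gene_ranking` data.frame.
#' @export
new_gene_ranking <- function(scores, higher_is_better, rank_matrix = NULL) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  ord <- if (higher_is_better) order(-scores, names(scores))
         else order(scores, names(scores))
  out <- data.frame(rank = seq_along(scores),
                    gene = names(scores)[ord],
                    score = unname(scores[ord]),
                    stringsAsFactors = FALSE)
  structure(out,
            higher_is_better = higher_is_better,
            rank_matrix = rank_matrix,
            class = c("gene_ranking", "data.frame"))
}

#' Diffuse per-sample omics scores over the network
#'
#' Multiplies the diffusion matrix with a column-normalized gene x sample
#' score matrix: W = D S. Entry (i, k) is gene i's relevance score in
#' sample k — its diffused proximity to that sample's mutated or
#' differentially expressed genes. Column mass is conserved: because D is
#' column stochastic on non-isolated genes, a normalized input column sums
#' to 1 in the output too.
#'
#' @param D a `diffusion_matrix`.
#' @param S an `omics_score_matrix`, column-normalized, with gene order
#'   identical to `D` (no silent realignment is performed).
#' @return a `relevance_score_matrix`: numeric genes x samples matrix with
#'   attributes `source` (inherited from `S`'s kind) and `genes`.
#' @export
relevance_scores <- function(D, S) {
  stopifnot(inherits(D, "diffusion_matrix"),
            inherits(S, "omics_score_matrix"))
  if (!identical(D$genes, rownames(S)))
    stop("gene order of the diffusion matrix and score matrix differ; ",
         "build both against the same network")
  if (!isTRUE(attr(S, "normalized")))
    stop("score matrix must be column-normalized before diffusion")
  W <- D$matrix %*% unclass_matrix(S)
  structure(W, source = attr(S, "kind"), strategy = NULL,
            class = c("relevance_score_matrix", class(W)))
}

unclass_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x), dimnames = dimnames(x))
  x
}

#' Integrate mutation and expression relevance scores
#'
#' Combines the two diffused score matrices elementwise. The default
#' `"min"` strategy implements the "double high" requirement: a gene only
#' keeps a high integrated score in a sample if both its mutation and its
#' expression relevance are high, which suppresses single-omics outliers
#' such as isolated mutations without downstream expression change.
#' `"mean"` and `"max"` are the corresponding baselines.
#'
#' @param WM,WE `relevance_score_matrix` objects of identical shape, gene
#'   order and sample set.
#' @param strategy one of `"min"`, `"mean"`, `"max"`.
#' @return a `relevance_score_matrix` with `source = "integrated"` and the
#'   strategy recorded.
#' @export
integrate_scores <- function(WM, WE, strategy = c("min", "mean", "max")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(WM, "relevance_score_matrix"),
            inherits(WE, "relevance_score_matrix"))
  if (!identical(rownames(WM), rownames(WE)))
    stop("gene orders differ between the two relevance matrices")
  if (!identical(colnames(WM), colnames(WE))) {
    only_m <- setdiff(colnames(WM), colnames(WE))
    only_e <- setdiff(colnames(WE), colnames(WM))
    stop("sample sets differ: ",
         length(only_m), " only in first (", toString(utils::head(only_m, 5)),
         "); ", length(only_e), " only in second (",
         toString(utils::head(only_e, 5)), ")")
  }
  M <- unclass_matrix(WM)
  E <- unclass_matrix(WE)
  W <- switch(strategy,
              min = pmin(M, E),
              mean = (M + E) / 2,
              max = pmax(M, E))
  structure(W, source = "integrated", strategy = strategy,
            class = c("relevance_score_matrix", class(W)))
}

#' Per-sample gene rankings from relevance scores
#'
#' Within each sample (column), the gene with the largest score gets rank
#' 1. Tied scores receive the average of their rank positions, so each
#' column always sums to n(n+1)/2.
#'
#' @param W a `relevance_score_matrix` (or plain genes x samples matrix).
#' @return a genes x samples matrix of ranks.
#' @export
per_sample_ranks <- function(W) {
  stopifnot(is.matrix(W) || inherits(W, "relevance_score_matrix"))
  M <- unclass_matrix(W)
  if (length(M) == 0L) stop("empty score matrix")
  apply(M, 2, function(col) rank(-col, ties.method = "average"))
}

#' Aggregate per-sample rankings into a cohort-level ranking
#'
#' The aggregate score of a gene is the sum of its ranks across samples;
#' genes are ordered by ascending rank sum (consistently good genes come
#' first), ties broken lexicographically. The per-sample rank matrix is
#' retained on the result for diagnostics.
#'
#' @param rank_matrix genes x samples matrix from [per_sample_ranks()].
#' @return a `gene_ranking` with `score` = rank sum (lower is better).
#' @export
aggregate_ranks <- function(rank_matrix) {
  stopifnot(is.matrix(rank_matrix), ncol(rank_matrix) >= 1L)
  rs <- rowSums(rank_matrix)
  new_gene_ranking(rs, higher_is_better = FALSE, rank_matrix = rank_matrix)
}

#' Mutation-frequency baseline ranking
#'
#' Orders genes by the fraction of samples in which they are mutated —
#' the classic frequency-based driver criterion, used as a comparator for
#' the network-propagation rankings.
#'
#' @param SM an unnormalized mutation `omics_score_matrix` (entries > 0
#'   mark a mutated gene).
#' @return a `gene_ranking` with `score` = mutation frequency.
#' @export
frequency_baseline <- function(SM) {
  stopifnot(inherits(SM, "omics_score_matrix"))
  if (isTRUE(attr(SM, "normalized")))
    stop("frequency baseline needs the unnormalized mutation matrix")
  freq <- rowMeans(unclass_matrix(SM) > 0)
  new_gene_ranking(freq, higher_is_better = TRUE)
}

#' Which omics layer supplies the minimum score?
#'
#' Over all (gene, sample) cells restricted to `top_genes`, computes the
#' fraction of cells where the integrated min-score equals the mutation
#' relevance score and the fraction where it equals the expression
#' relevance score. Exact ties count toward both, so the two proportions
#' can sum to more than 1.
#'
#' @param WM,WE parent `relevance_score_matrix` objects.
#' @param W_min their elementwise-minimum integration.
#' @param top_genes character vector of genes to restrict to (must be a
#'   subset of the matrix gene order).
#' @return named numeric vector `c(mutation = ..., expression = ...)`.
#' @export
min_source_proportions <- function(WM, WE, W_min, top_genes) {
  stopifnot(identical(dim(WM), dim(W_min)),
            identical(dim(WE), dim(W_min)))
  if (!identical(attr(W_min, "strategy"), "min"))
    stop("W_min must be a min-strategy integration")
  missing <- setdiff(top_genes, rownames(W_min))
  if (length(missing) > 0L)
    stop("top_genes not in the gene order: ", toString(utils::head(missing, 5)))
  rows <- rownames(W_min) %in% top_genes
  m <- unclass_matrix(WM)[rows, , drop = FALSE]
  e <- unclass_matrix(WE)[rows, , drop = FALSE]
  w <- unclass_matrix(W_min)[rows, , drop = FALSE]
  c(mutation = mean(w == m), expression = mean(w == e))
}

#' Full propagation-and-ranking pipeline on score matrices
#'
#' Convenience wrapper running column normalization, diffusion,
#' integration (when both omics layers are supplied), per-sample ranking
#' and cohort-level aggregation. With both layers the analysis is
#' restricted to the samples present in both matrices; with a single layer
#' its full cohort is used.
#'
#' @param D a `diffusion_matrix`.
#' @param SM unnormalized mutation `omics_score_matrix`, or NULL.
#' @param SE unnormalized expression `omics_score_matrix`, or NULL.
#' @param strategy integration strategy passed to [integrate_scores()].
#' @return list of class `minnetrank_fit`: `ranking` (a `gene_ranking`),
#'   `W` (the scores the ranking is based on), and when both layers are
#'   present `WM` and `WE`.
#' @export
rank_genes <- function(D, SM = NULL, SE = NULL,
                       strategy = c("min", "mean", "max")) {
  strategy <- match.arg(strategy)
  if (is.null(SM) && is.null(SE))
    stop("at least one omics score matrix is required")
  if (!is.null(SM) && !is.null(SE)) {
    common <- intersect(colnames(SM), colnames(SE))
    if (length(common) == 0L)
      stop("mutation and expression cohorts share no samples")
    SM <- subset_samples(SM, common)
    SE <- subset_samples(SE, common)
    WM <- relevance_scores(D, column_normalize(SM))
    WE <- relevance_scores(D, column_normalize(SE))
    W <- integrate_scores(WM, WE, strategy)
    ranking <- aggregate_ranks(per_sample_ranks(W))
    out <- list(ranking = ranking, W = W, WM = WM, WE = WE)
  } else {
    S <- if (is.null(SE)) SM else SE
    W <- relevance_scores(D, column_normalize(S))
    ranking <- aggregate_ranks(per_sample_ranks(W))
    out <- list(ranking = ranking, W = W)
  }
  structure(out, class = "minnetrank_fit")
}
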