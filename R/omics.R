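#' Construct an omics score matrix
#'
#' Internal constructor shared by the mutation and expression builders:
#' a non-negative genes x samples matrix whose row order is the network
#' gene order, carrying `kind` ("mutation" or "expression") and a
#' `normalized` flag.
#'
#' @keywords internal
new_omics_score_matrix <- function(matrix, kind, normalized = FALSE) {
  stopifnot(is.matrix(matrix), kind %in% c("mutation", "expression"))
  if (any(matrix < 0)) stop("omics scores must be non-negative")
  structure(matrix, kind = kind, normalized = normalized,
            class = c("omics_score_matrix", class(matrix)))
}

#' Subset an omics score matrix to a set of samples
#' @keywords internal
subset_samples <- function(S, samples) {
  stopifnot(inherits(S, "omics_score_matrix"))
  missing <- setdiff(samples, colnames(S))
  if (length(missing) > 0L)
    stop("samples not in the score matrix: ",
         toString(utils::head(missing, 5)))
  new_omics_score_matrix(unclass_matrix(S)[, samples, drop = FALSE],
                         kind = attr(S, "kind"),
                         normalized = attr(S, "normalized"))
}

#' Gene x sample mutation score matrix
#'
#' Builds the mutation input to network propagation. Entry (i, k) is the
#' sum of the weights of sample k's variants in gene i; under the uniform
#' weighting scheme the sum is clipped at 1, reproducing the plain 0/1
#' mutated-or-not status. Variants in genes outside the interaction
#' network are dropped (their count is reported via a message), because a
#' gene absent from the network cannot take part in diffusion.
#'
#' @param variants a data.frame of weighted variant records as returned by
#'   [assign_variant_weights()] (columns `sample`, `gene`, `weight`).
#' @param net the `interaction_network` defining the gene universe.
#' @param samples character vector of cohort sample identifiers (columns of
#'   the result; samples without any network-mapped variant get all-zero
#'   columns).
#' @param cap optional upper clip for per-gene per-sample summed weights;
#'   defaults to 1 for the uniform scheme and no cap otherwise.
#' @return an unnormalized `omics_score_matrix` with `kind = "mutation"`.
#' @export
build_mutation_scores <- function(variants, net, samples, cap = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  if (length(samples) == 0L) stop("sample list is empty")
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  if (!is.data.frame(variants) || is.null(variants$weight))
    stop("variants must carry a weight column; ",
         "run assign_variant_weights() first")
  if (is.null(cap))
    cap <- if (identical(attr(variants, "scheme"), "uniform")) 1 else Inf

  unknown <- !(variants$sample %in% samples)
  if (any(unknown)) {
    warning(sum(unknown), " variant(s) reference samples outside the ",
            "cohort and were skipped")
    variants <- variants[!unknown, , drop = FALSE]
  }
  outside <- !(variants$gene %in% net$genes)
  if (any(outside)) {
    message(sum(outside), " variant(s) in genes outside the interaction ",
            "network dropped")
    variants <- variants[!outside, , drop = FALSE]
  }

  n <- length(net$genes)
  m <- length(samples)
  M <- matrix(0, n, m, dimnames = list(net$genes, samples))
  if (nrow(variants) > 0L) {
    agg <- stats::aggregate(weight ~ gene + sample, data = variants, FUN = sum)
    idx <- cbind(match(agg$gene, net$genes), match(agg$sample, samples))
    M[idx] <- pmin(agg$weight, cap)
  }
  new_omics_score_matrix(M, kind = "mutation")
}

#' Absolute log2 fold-change expression scores
#'
#' Computes the per-sample differential expression score ALFC_ik =
#' |log2((t_ik + delta) / (d_ik + delta))|, where t is tumor expression
#' and d is the paired normal sample's expression when a pairing is
#' available, or the mean of gene i's expression over all normal samples
#' for unpaired tumors. The absolute value captures up- and
#' down-regulation alike; the additive pseudocount `delta` keeps the ratio
#' finite for zero-expression genes. Genes outside the interaction network
#' are dropped; network genes missing from the expression data get
#' all-zero rows.
#'
#' @param tumor_expr,normal_expr non-negative numeric matrices, genes as
#'   rows (rownames = symbols), samples as columns.
#' @param pairing optional data.frame with columns `tumor`, `normal`
#'   mapping tumor samples to their matched normal.
#' @param net the `interaction_network` defining the gene universe.
#' @param pseudocount additive pseudocount delta > 0 (default 0.5).
#' @return an unnormalized `omics_score_matrix` with `kind = "expression"`.
#' @export
compute_alfc <- function(tumor_expr, normal_expr, pairing = NULL, net,
                         pseudocount = 0.5) {
  stopifnot(inherits(net, "interaction_network"),
            is.matrix(tumor_expr), is.matrix(normal_expr))
  if (ncol(tumor_expr) == 0L) stop("no tumor samples")
  if (ncol(normal_expr) == 0L)
    stop("no normal samples: ALFC needs paired or pooled normal expression")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  if (any(tumor_expr < 0) || any(normal_expr < 0))
    stop("expression values must be non-negative")

  common_genes <- intersect(rownames(tumor_expr), rownames(normal_expr))
  keep <- intersect(common_genes, net$genes)
  dropped <- setdiff(common_genes, net$genes)
  if (length(dropped) > 0L)
    message(length(dropped), " expressed gene(s) outside the interaction ",
            "network dropped")
  if (length(keep) == 0L)
    stop("no expressed gene is in the interaction network")

  tum <- tumor_expr[keep, , drop = FALSE]
  nor <- normal_expr[keep, , drop = FALSE]
  pooled_normal <- rowMeans(nor)

  pair_of <- character(0)
  if (!is.null(pairing)) {
    stopifnot(is.data.frame(pairing), ncol(pairing) >= 2)
    pair_of <- stats::setNames(as.character(pairing[[2]]),
                               as.character(pairing[[1]]))
    known <- names(pair_of) %in% colnames(tum)
    pair_of <- pair_of[known]
    bad <- !(pair_of %in% colnames(nor))
    if (any(bad))
      stop("paired normal sample(s) missing from normal_expr: ",
           toString(utils::head(pair_of[bad], 5)))
  }

  A <- matrix(0, length(net$genes), ncol(tum),
              dimnames = list(net$genes, colnames(tum)))
  for (s in colnames(tum)) {
    denom <- if (s %in% names(pair_of)) nor[, pair_of[[s]]] else pooled_normal
    A[keep, s] <- abs(log2((tum[, s] + pseudocount) / (denom + pseudocount)))
  }
  new_omics_score_matrix(A, kind = "expression")
}

#' Normalize each sample column to unit mass
#'
#' Divides every column by its sum so the scores form a per-sample
#' distribution over genes; this puts the mutation and expression layers
#' on the common scale the minimum integration requires. All-zero columns
#' are left untouched and their sample identifiers are reported on the
#' result (attribute `zero_columns`) — a sample with no network-mapped
#' signal is a data condition, not an error.
#'
#' @param S an unnormalized `omics_score_matrix`.
#' @return the column-normalized `omics_score_matrix`
#'   (`normalized = TRUE`).
#' @export
column_normalize <- function(S) {
  stopifnot(inherits(S, "omics_score_matrix"))
  if (isTRUE(attr(S, "normalized")))
    stop("score matrix is already normalized")
  M <- unclass_matrix(S)
  cs <- colSums(M)
  zero <- cs == 0
  scale <- ifelse(zero, 1, 1 / cs)
  M <- sweep(M, 2, scale, `*`)
  out <- new_omics_score_matrix(M, kind = attr(S, "kind"), normalized = TRUE)
  attr(out, "zero_columns") <- colnames(M)[zero]
  out
}
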