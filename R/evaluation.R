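#' Precision, recall and F1 curves against a gold-standard gene set
#'
#' For each cutoff i = 1..n, computes the precision |top-i ∩ gold| / i,
#' the recall |top-i ∩ gold| / T where T is the gold-set size, and their
#' harmonic mean F1 (0 when both are 0). The single summary figures
#' usually reported are the values at i = n.
#'
#' @param ranking a `gene_ranking`.
#' @param gold character vector of gold-standard (known driver) genes.
#' @param n top-gene cutoff (default 50).
#' @param restrict_gold if TRUE (default) T counts only gold genes present
#'   in the ranking's gene universe.
#' @return data.frame with columns `top`, `precision`, `recall`, `f1` and
#'   attribute `gold_size` (T).
#' @export
precision_recall_f1 <- function(ranking, gold, n = 50,
                                restrict_gold = TRUE) {
  stopifnot(inherits(ranking, "gene_ranking"))
  if (length(gold) == 0L) stop("gold-standard gene set is empty")
  if (n > nrow(ranking))
    stop("cutoff n = ", n, " exceeds ranking length ", nrow(ranking))
  if (restrict_gold) gold <- intersect(gold, ranking$gene)
  T_gold <- length(gold)
  hits <- cumsum(ranking$gene[seq_len(n)] %in% gold)
  precision <- hits / seq_len(n)
  recall <- if (T_gold > 0) hits / T_gold else rep(0, n)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(data.frame(top = seq_len(n), precision = precision,
                       recall = recall, f1 = f1),
            gold_size = T_gold)
}

#' Partial AUC of a ranking at the top n negatives
#'
#' Walks the ranking from the top; for each of the first `n` genes not in
#' the gold set (the negatives), counts the number of gold genes ranked
#' above it (T_i), and returns sum(T_i) / (n * T), where T is the gold-set
#' size. This truncated AUC rewards placing known drivers above the
#' highest-ranked non-drivers and is insensitive to the long tail of the
#' ranking.
#'
#' @inheritParams precision_recall_f1
#' @param n number of top negatives to walk (default 50).
#' @return a single number in [0, 1].
#' @export
partial_auc <- function(ranking, gold, n = 50, restrict_gold = TRUE) {
  stopifnot(inherits(ranking, "gene_ranking"))
  if (length(gold) == 0L) stop("gold-standard gene set is empty")
  if (restrict_gold) gold <- intersect(gold, ranking$gene)
  T_gold <- length(gold)
  if (T_gold == 0L)
    stop("no gold-standard gene is in the ranking's gene universe")
  is_pos <- ranking$gene %in% gold
  neg_idx <- which(!is_pos)
  if (length(neg_idx) < n)
    stop("ranking has only ", length(neg_idx), " negatives; need ", n)
  pos_above <- cumsum(is_pos)
  T_i <- pos_above[neg_idx[seq_len(n)]]
  sum(T_i) / (n * T_gold)
}

#' Robustness of the ranking under cohort subsampling
#'
#' Repeatedly reruns the full propagation-and-ranking pipeline on random
#' sample subsets of the cohort and summarizes how stable the evaluation
#' metrics are. For each subset size, `repeats` subsets are drawn
#' uniformly without replacement (child seeds are derived deterministically
#' from `seed` per size/repeat pair, so extending the size grid never
#' perturbs earlier draws); on each subset the ranking is recomputed and
#' the mean top-`top_n` precision P = mean(p_i, i = 1..top_n), the F1
#' score at `top_n`, and the partial AUC at `top_n` are recorded.
#'
#' @param D a `diffusion_matrix`.
#' @param SM,SE unnormalized mutation / expression `omics_score_matrix`
#'   objects covering the full cohort (`SE` may be NULL for a
#'   mutation-only analysis).
#' @param gold gold-standard gene set for the metrics.
#' @param sizes integer vector of subset sizes. The conventional grid is
#'   `robustness_size_grid(m)` = 10, 25, 50, 100, ... up to the cohort
#'   size m.
#' @param repeats subsets drawn per size (default 10).
#' @param seed master seed.
#' @param top_n evaluation cutoff (default 50; capped at the number of
#'   ranked genes).
#' @param strategy integration strategy for [rank_genes()].
#' @return data.frame of class `robustness_result`: one row per size with
#'   mean and SD of precision, F1 and partial AUC over the repeats, plus
#'   the number of repeats that produced a usable ranking.
#' @export
robustness_subsample <- function(D, SM, SE = NULL, gold, sizes,
                                 repeats = 10, seed = 1, top_n = 50,
                                 strategy = "min") {
  stopifnot(repeats >= 2)
  cohort <- if (is.null(SE)) colnames(SM)
            else intersect(colnames(SM), colnames(SE))
  m <- length(cohort)
  if (any(sizes > m))
    stop("subset size(s) exceed the cohort size ", m, ": ",
         toString(sizes[sizes > m]))
  rows <- lapply(seq_along(sizes), function(si) {
    size <- sizes[si]
    vals <- matrix(NA_real_, repeats, 3,
                   dimnames = list(NULL, c("precision", "f1", "auc")))
    for (r in seq_len(repeats)) {
      child <- (seed * 1009L + size * 131L + r) %% 2147483647L
      subset <- local({
        old <- .Random.seed_get()
        on.exit(.Random.seed_set(old))
        set.seed(child)
        sample(cohort, size)
      })
      fit <- tryCatch(
        rank_genes(D,
                   SM = subset_samples(SM, subset),
                   SE = if (is.null(SE)) NULL else subset_samples(SE, subset),
                   strategy = strategy),
        error = function(e) NULL)
      if (is.null(fit)) {
        warning("repeat ", r, " at size ", size,
                " produced no usable ranking; recorded as missing")
        next
      }
      k <- min(top_n, nrow(fit$ranking))
      curves <- precision_recall_f1(fit$ranking, gold, n = k)
      vals[r, "precision"] <- mean(curves$precision)
      vals[r, "f1"] <- curves$f1[k]
      vals[r, "auc"] <- tryCatch(partial_auc(fit$ranking, gold, n = k),
                                 error = function(e) NA_real_)
    }
    data.frame(size = size,
               mean_precision = mean(vals[, "precision"], na.rm = TRUE),
               sd_precision = stats::sd(vals[, "precision"], na.rm = TRUE),
               mean_f1 = mean(vals[, "f1"], na.rm = TRUE),
               sd_f1 = stats::sd(vals[, "f1"], na.rm = TRUE),
               mean_auc = mean(vals[, "auc"], na.rm = TRUE),
               sd_auc = stats::sd(vals[, "auc"], na.rm = TRUE),
               completed = sum(!is.na(vals[, "precision"])))
  })
  structure(do.call(rbind, rows),
            repeats = repeats, seed = seed,
            class = c("robustness_result", "data.frame"))
}

#' Conventional subset-size grid for the robustness protocol
#'
#' Returns sizes 10, 25, 50, 100, 150, ... in steps of 50 up to the cohort
#' size `m` (sizes larger than `m` are dropped).
#'
#' @param m total cohort size.
#' @return integer vector of subset sizes.
#' @export
robustness_size_grid <- function(m) {
  sizes <- c(10, 25, 50 * seq_len(ceiling(m / 50)))
  unique(sizes[sizes <= m])
}

# save/restore the global RNG state so simulators do not perturb callers
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
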