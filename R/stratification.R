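#' Select top-ranked high-variance biomarker genes
#'
#' Walks the cohort-level ranking best-first and keeps genes whose
#' expression standard deviation across tumor samples exceeds
#' `sd_threshold`, stopping once `top_k` genes are collected. Low-variance
#' genes carry little information for separating patients, so they are
#' skipped even when highly ranked. The SD is computed on the expression
#' matrix as supplied, so the threshold is on the data's own scale
#' (abundance-scale by convention).
#'
#' @param ranking a `gene_ranking`.
#' @param tumor_expr numeric matrix, genes x tumor samples.
#' @param top_k number of biomarkers to select (default 7).
#' @param sd_threshold minimum expression SD (default 5).
#' @return character vector of `top_k` gene symbols, in ranking order.
#' @export
select_biomarkers <- function(ranking, tumor_expr, top_k = 7,
                              sd_threshold = 5) {
  stopifnot(inherits(ranking, "gene_ranking"), is.matrix(tumor_expr))
  sds <- apply(tumor_expr, 1, stats::sd)
  chosen <- character(0)
  for (g in ranking$gene) {
    if (!g %in% rownames(tumor_expr)) next
    if (sds[[g]] > sd_threshold) chosen <- c(chosen, g)
    if (length(chosen) == top_k) break
  }
  if (length(chosen) < top_k)
    stop("only ", length(chosen), " gene(s) pass the SD threshold ",
         sd_threshold, "; ", top_k, " biomarkers requested")
  chosen
}

#' Cluster patients into two groups on biomarker expression
#'
#' Standardizes each biomarker gene to zero mean and unit SD across
#' samples (so high-variance genes do not dominate by scale alone) and
#' runs k-means with multiple random restarts, keeping the best solution
#' by within-cluster sum of squares. Deterministic under a fixed seed.
#'
#' @param expr numeric matrix, biomarker genes x samples.
#' @param k number of clusters (default 2).
#' @param seed RNG seed for the restarts.
#' @param restarts number of random starts (default 25).
#' @return integer vector of cluster labels (1..k) named by sample.
#' @export
cluster_patients <- function(expr, k = 2, seed = 1, restarts = 25) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2 * k)
  z <- t(apply(expr, 1, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  X <- t(z)   # samples as rows
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = restarts, iter.max = 100)
  stats::setNames(km$cluster, colnames(expr))
}

#' Log-rank comparison of two patient groups
#'
#' Joins the cluster labels with the survival table and tests whether the
#' two groups' survival curves differ (two-group log-rank chi-square on 1
#' degree of freedom). The group with the worse survival — smaller
#' Kaplan-Meier restricted mean up to the last time observed in both
#' groups, ties broken toward the group with more events — is labeled
#' `high_risk`; high-risk status is thus defined by survival, never by
#' cluster index.
#'
#' @param labels integer cluster labels named by sample (two clusters).
#' @param survival data.frame with columns `sample`, `time`, `event`.
#' @param biomarkers optional character vector recorded on the result.
#' @return object of class `stratification_result`: list with `labels`
#'   (factor high_risk/low_risk named by sample), `chisq`, `p_value`,
#'   `n_per_group`, `degenerate` flag, and `biomarkers`.
#' @export
logrank_compare <- function(labels, survival, biomarkers = NULL) {
  stopifnot(is.data.frame(survival),
            all(c("sample", "time", "event") %in% names(survival)))
  common <- intersect(names(labels), survival$sample)
  if (length(common) == 0L)
    stop("no overlap between clustered samples and the survival table")
  surv <- survival[match(common, survival$sample), ]
  grp <- labels[common]
  groups <- sort(unique(grp))
  if (length(groups) < 2L) {
    return(structure(list(labels = NULL, chisq = NA_real_,
                          p_value = NA_real_,
                          n_per_group = table(grp),
                          degenerate = TRUE, biomarkers = biomarkers),
                     class = "stratification_result"))
  }
  sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ grp)
  chisq <- unname(sd$chisq)
  p <- stats::pchisq(chisq, df = length(groups) - 1L, lower.tail = FALSE)

  # worse-survival group = smaller KM restricted mean up to the last
  # time observed in both groups
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ grp)
  tmax <- min(tapply(surv$time, grp, max))
  tab <- summary(fit, rmean = tmax)$table
  rmean_col <- grep("rmean", colnames(tab))[1]
  rmeans <- tab[, rmean_col]
  events <- tab[, "events"]
  ord <- order(rmeans, -events)
  high <- groups[ord[1]]
  risk <- factor(ifelse(grp == high, "high_risk", "low_risk"),
                 levels = c("high_risk", "low_risk"))
  names(risk) <- common
  structure(list(labels = risk, chisq = chisq, p_value = p,
                 n_per_group = table(risk), degenerate = FALSE,
                 biomarkers = biomarkers),
            class = "stratification_result")
}

#' @export
print.stratification_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Stratification degenerate: all samples fell in one group\n")
  } else {
    cat("Two-group survival stratification\n")
    if (!is.null(x$biomarkers))
      cat("  biomarkers:", toString(x$biomarkers), "\n")
    cat("  group sizes:", paste(names(x$n_per_group), x$n_per_group,
                                sep = "=", collapse = ", "), "\n")
    cat(sprintf("  log-rank chisq = %.4g, p = %.3g\n", x$chisq, x$p_value))
  }
  invisible(x)
}

#' Stratify tumors into survival risk groups from a gene ranking
#'
#' End-to-end stratification: select the `top_k` top-ranked genes with
#' expression SD above `sd_threshold` as biomarkers, cluster patients
#' into two groups by k-means on the standardized biomarker expression,
#' and test the groups' survival separation by log-rank.
#'
#' @inheritParams select_biomarkers
#' @inheritParams cluster_patients
#' @param survival data.frame with columns `sample`, `time`, `event`.
#' @return a `stratification_result` (see [logrank_compare()]).
#' @export
stratify_patients <- function(ranking, tumor_expr, survival, top_k = 7,
                              sd_threshold = 5, seed = 1, restarts = 25) {
  biomarkers <- select_biomarkers(ranking, tumor_expr, top_k = top_k,
                                  sd_threshold = sd_threshold)
  labels <- cluster_patients(tumor_expr[biomarkers, , drop = FALSE],
                             k = 2, seed = seed, restarts = restarts)
  logrank_compare(labels, survival, biomarkers = biomarkers)
}
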