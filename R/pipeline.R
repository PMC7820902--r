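#' Assemble a pipeline run configuration
#'
#' Collects input paths and all tunable parameters with their conventional
#' defaults: restart probability `beta = 0.48`, top 50 genes for
#' evaluation, 7 biomarkers with expression SD above 5 for stratification,
#' 10 robustness repeats, PrDSM threshold 0.308. Any field can be
#' overridden; the whole configuration round-trips through YAML via
#' [read_config()] / [write_config()].
#'
#' @param network,maf,tumor_expr,normal_expr input file paths (required
#'   for [run_pipeline()]).
#' @param pairing,gold,survival optional input file paths.
#' @param out_dir output directory.
#' @param beta restart probability in (0, 1].
#' @param weight_scheme variant weighting scheme name.
#' @param prdsm_threshold PrDSM deleteriousness cutoff.
#' @param strategy integration strategy: min, mean or max.
#' @param pseudocount ALFC additive pseudocount.
#' @param top_n evaluation cutoff.
#' @param top_k number of stratification biomarkers.
#' @param sd_threshold biomarker expression-SD cutoff.
#' @param repeats robustness repeats per subset size.
#' @param seed master seed; stages derive child seeds from it.
#' @return a named list of class `minnetrank_config`.
#' @export
minnetrank_config <- function(network = NULL, maf = NULL,
                              tumor_expr = NULL, normal_expr = NULL,
                              pairing = NULL, gold = NULL, survival = NULL,
                              out_dir = "minnetrank_out",
                              beta = 0.48, weight_scheme = "uniform",
                              prdsm_threshold = 0.308, strategy = "min",
                              pseudocount = 0.5, top_n = 50, top_k = 7,
                              sd_threshold = 5, repeats = 10, seed = 1) {
  cfg <- list(network = network, maf = maf, tumor_expr = tumor_expr,
              normal_expr = normal_expr, pairing = pairing, gold = gold,
              survival = survival, out_dir = out_dir, beta = beta,
              weight_scheme = weight_scheme,
              prdsm_threshold = prdsm_threshold, strategy = strategy,
              pseudocount = pseudocount, top_n = top_n, top_k = top_k,
              sd_threshold = sd_threshold, repeats = repeats, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "minnetrank_config")
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$beta) || cfg$beta <= 0 || cfg$beta > 1)
    stop("beta must lie in (0, 1]")
  if (!cfg$strategy %in% c("min", "mean", "max"))
    stop("strategy must be min, mean or max")
  if (!cfg$weight_scheme %in% c("uniform", "sift", "sift_prdsm",
                                "sift_prdsm_filtered", "sift_predcid"))
    stop("unknown weight scheme: ", cfg$weight_scheme)
  if (cfg$pseudocount <= 0) stop("pseudocount must be > 0")
  invisible(cfg)
}

#' Read a YAML run configuration
#' @param path YAML file; keys as in [minnetrank_config()].
#' @return a `minnetrank_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(minnetrank_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", toString(unknown))
  do.call(minnetrank_config, vals)
}

#' Write a run configuration as YAML
#' @param config a `minnetrank_config`.
#' @param path output YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' Run the full driver-gene prioritization pipeline
#'
#' Chains every stage on the configured inputs: load the network, compute
#' the diffusion matrix, weight the variants and build the mutation and
#' expression score matrices, diffuse and integrate them, aggregate the
#' per-sample rankings, and — when a gold-standard list or survival table
#' is configured — evaluate the ranking and stratify patients. All
#' artifacts are written under `config$out_dir` together with a
#' machine-readable manifest (configuration echo, input file hashes,
#' package version).
#'
#' @param config a `minnetrank_config` with at least `network`, `maf`,
#'   `tumor_expr` and `normal_expr` set.
#' @return invisibly, a list with the fitted objects (`fit`, `ranking`,
#'   `evaluation`, `stratification`) and the output paths.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  for (f in c("network", "maf", "tumor_expr", "normal_expr")) {
    if (is.null(config[[f]])) stop("config field '", f, "' is required")
    if (!file.exists(config[[f]]))
      stop("input stage: file for '", f, "' not found: ", config[[f]])
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  net <- stage("network", load_network(config$network))
  D <- stage("diffusion",
             compute_diffusion(normalize_adjacency(net), beta = config$beta))
  variants <- stage("mutation", read_maf(config$maf))
  scheme <- weight_scheme(config$weight_scheme,
                          prdsm_threshold = config$prdsm_threshold)
  weighted <- stage("mutation", assign_variant_weights(variants, scheme))
  samples_mut <- sort(unique(variants$sample))
  SM <- stage("mutation",
              build_mutation_scores(weighted, net, samples_mut))
  tumor <- stage("expression", read_expression_matrix(config$tumor_expr))
  normal <- stage("expression", read_expression_matrix(config$normal_expr))
  pairing <- if (!is.null(config$pairing))
    stage("expression", read_pairing(config$pairing)) else NULL
  SE <- stage("expression",
              compute_alfc(tumor, normal, pairing, net,
                           pseudocount = config$pseudocount))
  fit <- stage("ranking",
               rank_genes(D, SM, SE, strategy = config$strategy))

  ranking_path <- file.path(config$out_dir, "ranking.tsv")
  write_ranking(fit$ranking, ranking_path)
  utils::write.table(
    data.frame(gene = rownames(attr(fit$ranking, "rank_matrix")),
               apply(attr(fit$ranking, "rank_matrix"), 2, .fmt_num),
               check.names = FALSE),
    file.path(config$out_dir, "per_sample_ranks.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  evaluation <- NULL
  if (!is.null(config$gold)) {
    gold <- stage("evaluation", read_gene_list(config$gold))
    n_eval <- min(config$top_n, nrow(fit$ranking))
    curves <- stage("evaluation",
                    precision_recall_f1(fit$ranking, gold, n = n_eval))
    auc <- tryCatch(partial_auc(fit$ranking, gold, n = n_eval),
                    error = function(e) NA_real_)
    evaluation <- list(curves = curves, partial_auc = auc, top_n = n_eval)
    utils::write.table(
      data.frame(top = curves$top,
                 precision = .fmt_num(curves$precision),
                 recall = .fmt_num(curves$recall),
                 f1 = .fmt_num(curves$f1)),
      file.path(config$out_dir, "evaluation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  stratification <- NULL
  if (!is.null(config$survival)) {
    surv <- stage("stratification", read_survival(config$survival))
    stratification <- stage("stratification",
      stratify_patients(fit$ranking, tumor, surv, top_k = config$top_k,
                        sd_threshold = config$sd_threshold,
                        seed = config$seed))
    if (!stratification$degenerate)
      utils::write.table(
        data.frame(sample = names(stratification$labels),
                   group = as.character(stratification$labels)),
        file.path(config$out_dir, "risk_groups.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    config = unclass(config)[!vapply(config, is.null, logical(1))],
    inputs = lapply(
      Filter(Negate(is.null),
             config[c("network", "maf", "tumor_expr", "normal_expr",
                      "pairing", "gold", "survival")]),
      function(p) unname(tools::md5sum(p))),
    package_version = as.character(utils::packageVersion("minnetrank")))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(fit = fit, ranking = fit$ranking,
                 evaluation = evaluation,
                 stratification = stratification,
                 out_dir = config$out_dir))
}
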