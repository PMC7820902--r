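# Synthetic cohort generator. The simulated data emulate the statistical
# structure the ranking method assumes: driver genes are recurrently
# mutated, sit at highly connected network positions (as known cancer
# genes do), and their network neighbors shift expression downstream of
# the mutation. Background genes mutate sporadically and fluctuate around
# their baseline expression.

#' Simulate a directed gene-interaction network with hubs
#'
#' Grows a directed graph by preferential attachment: edge endpoints are
#' drawn with probability proportional to a base weight plus the degree
#' accumulated so far, and a designated hub set carries an elevated base
#' weight, giving hubs high incoming and outgoing degree — the position
#' known cancer genes occupy in curated interaction networks.
#'
#' @param n_genes number of genes (>= 10).
#' @param mean_degree target edges per gene; the graph has close to
#'   `n_genes * mean_degree` directed edges (duplicate draws are
#'   discarded).
#' @param hub_fraction fraction of genes designated as hubs.
#' @param seed RNG seed; the same seed reproduces the same edge set.
#' @return an `interaction_network` with the hub genes in attribute
#'   `hubs`.
#' @export
simulate_network <- function(n_genes, mean_degree = 4, hub_fraction = 0.05,
                             seed = 1) {
  if (n_genes < 10) stop("n_genes must be at least 10")
  stopifnot(mean_degree > 0, hub_fraction >= 0, hub_fraction <= 0.5)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)

  genes <- sprintf("g%04d", seq_len(n_genes))
  n_hubs <- max(1L, round(hub_fraction * n_genes))
  hubs <- sort(sample(genes, n_hubs))
  base_w <- stats::setNames(rep(1, n_genes), genes)
  base_w[hubs] <- 10
  deg <- stats::setNames(rep(0, n_genes), genes)

  m_target <- round(n_genes * mean_degree)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  src <- character(m_target)
  tgt <- character(m_target)
  got <- 0L
  for (iter in seq_len(60L)) {
    if (got >= m_target) break
    need <- m_target - got
    w <- base_w + 0.5 * deg
    s <- sample(genes, 2L * need, replace = TRUE, prob = w)
    t <- sample(genes, 2L * need, replace = TRUE, prob = w)
    ok <- s != t
    s <- s[ok]; t <- t[ok]
    for (e in seq_along(s)) {
      key <- paste0(s[e], ">", t[e])
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      got <- got + 1L
      src[got] <- s[e]
      tgt[got] <- t[e]
      deg[s[e]] <- deg[s[e]] + 1
      deg[t[e]] <- deg[t[e]] + 1
      if (got >= m_target) break
    }
  }
  if (got == 0L) stop("simulation produced no edges; increase mean_degree")
  net <- interaction_network(data.frame(source = src[seq_len(got)],
                                        target = tgt[seq_len(got)]))
  attr(net, "hubs") <- hubs
  net
}

#' Simulate a tumor cohort with planted driver genes
#'
#' Generates, from a network and a chosen driver set, everything the
#' ranking pipeline consumes: somatic variant calls, paired tumor/normal
#' expression, and survival times.
#'
#' Per sample, each planted driver mutates with probability
#' `driver_mut_prob` and each background gene with `mutation_rate_bg`;
#' variant classes are drawn from a fixed frequency table dominated by
#' missense calls, and missense/synonymous/frameshift variants carry a
#' uniform [0, 1] deleteriousness score standing in for SIFT / PrDSM /
#' PredCID predictions. Expression baselines are log-normal; the network
#' first-neighbors of a sample's mutated drivers are shifted by
#' `de_effect` on the log2 scale (direction fixed per gene), everything
#' else fluctuates with SD `noise_sd` — the downstream-of-mutation
#' structure is planted only one hop out, so recovering the drivers
#' themselves is left to the diffusion. Survival is exponential with a
#' three-fold hazard for samples carrying two or more mutated drivers,
#' with uniform censoring at rate `censor_rate`.
#'
#' @param net an `interaction_network`.
#' @param planted_drivers character vector of driver genes (subset of the
#'   network's genes).
#' @param n_samples cohort size.
#' @param mutation_rate_bg per-gene background mutation probability.
#' @param driver_mut_prob per-driver mutation probability.
#' @param de_effect mean absolute log2 expression shift planted in driver
#'   neighbors.
#' @param noise_sd log2-scale expression noise SD.
#' @param censor_rate probability a survival time is censored.
#' @param seed RNG seed.
#' @return list of class `cohort_fixture` with elements `network`,
#'   `planted_drivers`, `variants`, `tumor_expr`, `normal_expr`,
#'   `pairing`, `survival`, `seed`.
#' @export
simulate_cohort <- function(net, planted_drivers, n_samples = 100,
                            mutation_rate_bg = 0.01, driver_mut_prob = 0.4,
                            de_effect = 2, noise_sd = 0.5,
                            censor_rate = 0.2, seed = 1) {
  stopifnot(inherits(net, "interaction_network"))
  if (!all(planted_drivers %in% net$genes))
    stop("planted drivers must be network genes")
  probs <- c(mutation_rate_bg, driver_mut_prob, censor_rate)
  if (any(probs < 0 | probs > 1))
    stop("mutation_rate_bg, driver_mut_prob and censor_rate must lie in [0, 1]")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)

  genes <- net$genes
  n <- length(genes)
  samples <- sprintf("s%03d", seq_len(n_samples))
  normals <- sprintf("n%03d", seq_len(n_samples))
  drivers <- sort(planted_drivers)
  is_driver <- genes %in% drivers

  # mutation indicators, drivers recurrent, background sporadic
  p_mut <- ifelse(is_driver, driver_mut_prob, mutation_rate_bg)
  mut <- matrix(stats::rbinom(n * n_samples, 1, rep(p_mut, n_samples)),
                n, n_samples, dimnames = list(genes, samples))

  class_freq <- c(missense = 0.55, stop_gain = 0.08, stop_loss = 0.02,
                  frameshift = 0.10, nonframeshift = 0.05,
                  synonymous = 0.15, other = 0.05)
  hit <- which(mut == 1, arr.ind = TRUE)
  vclass <- sample(names(class_freq), nrow(hit), replace = TRUE,
                   prob = class_freq)
  score <- ifelse(vclass %in% c("missense", "synonymous", "frameshift"),
                  stats::runif(nrow(hit)), NA_real_)
  variants <- data.frame(sample = samples[hit[, 2]],
                         gene = genes[hit[, 1]],
                         variant_class = vclass,
                         score = score,
                         stringsAsFactors = FALSE)
  variants <- variants[order(variants$sample, variants$gene), ]
  rownames(variants) <- NULL

  # first neighbors (either direction) of each driver
  nbrs <- lapply(drivers, function(d) {
    e <- net$edges
    union(e$target[e$source == d], e$source[e$target == d])
  })
  names(nbrs) <- drivers

  baseline <- stats::rnorm(n, mean = 5, sd = 1.5)
  updown <- sample(c(-1, 1), n, replace = TRUE)   # DE direction per gene
  shift <- matrix(0, n, n_samples, dimnames = list(genes, samples))
  for (k in seq_len(n_samples)) {
    mutated_drivers <- drivers[mut[drivers, k] == 1]
    if (length(mutated_drivers) == 0L) next
    de_genes <- unique(unlist(nbrs[mutated_drivers]))
    idx <- match(de_genes, genes)
    shift[idx, k] <- updown[idx] * de_effect
  }
  noise_t <- matrix(stats::rnorm(n * n_samples, sd = noise_sd), n, n_samples)
  noise_n <- matrix(stats::rnorm(n * n_samples, sd = noise_sd), n, n_samples)
  tumor_expr <- 2^(baseline + shift + noise_t)
  normal_expr <- 2^(baseline + noise_n)
  dimnames(tumor_expr) <- list(genes, samples)
  dimnames(normal_expr) <- list(genes, normals)
  pairing <- data.frame(tumor = samples, normal = normals,
                        stringsAsFactors = FALSE)

  # survival: higher hazard with a heavier driver burden
  burden <- colSums(mut[drivers, , drop = FALSE])
  hazard <- (1 / 1000) * ifelse(burden >= 2, 3, 1)
  time <- stats::rexp(n_samples, rate = hazard)
  event <- rep(1L, n_samples)
  censored <- stats::runif(n_samples) < censor_rate
  time[censored] <- stats::runif(sum(censored), 0, time[censored])
  event[censored] <- 0L
  survival <- data.frame(sample = samples, time = time, event = event,
                         stringsAsFactors = FALSE)

  structure(list(network = net, planted_drivers = drivers,
                 variants = variants, tumor_expr = tumor_expr,
                 normal_expr = normal_expr, pairing = pairing,
                 survival = survival, seed = seed),
            class = "cohort_fixture")
}

#' Default synthetic cohort
#'
#' The standard test fixture: a 200-gene preferential-attachment network
#' whose 5 hub genes are the planted drivers, and a 100-sample cohort
#' simulated with the frozen default parameters of [simulate_cohort()].
#'
#' @param seed master seed; the network and cohort use child seeds derived
#'   from it.
#' @return a `cohort_fixture`.
#' @export
default_fixture <- function(seed = 1) {
  net <- simulate_network(n_genes = 200, mean_degree = 6,
                          hub_fraction = 0.025, seed = seed)
  simulate_cohort(net, planted_drivers = attr(net, "hubs"),
                  n_samples = 100, seed = seed + 1)
}

#' Write a cohort fixture to a directory of plain-text files
#'
#' Emits the edge list, MAF-lite variant table, tumor and normal
#' expression matrices, pairing table, survival table and the
#' planted-driver answer key, in the formats the loaders read back.
#'
#' @param fixture a `cohort_fixture`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(fixture, dir) {
  stopifnot(inherits(fixture, "cohort_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(fixture$network, file.path(dir, "network.tsv"))
  write_maf(fixture$variants, file.path(dir, "variants.maf.tsv"))
  write_expression_matrix(fixture$tumor_expr,
                          file.path(dir, "tumor_expr.tsv"))
  write_expression_matrix(fixture$normal_expr,
                          file.path(dir, "normal_expr.tsv"))
  write_pairing(fixture$pairing, file.path(dir, "pairing.tsv"))
  write_survival(fixture$survival, file.path(dir, "survival.tsv"))
  writeLines(fixture$planted_drivers,
             file.path(dir, "planted_drivers.txt"))
  invisible(dir)
}

#' Read a cohort fixture written by [write_cohort()]
#' @param dir directory containing the fixture files.
#' @return a `cohort_fixture` (with `seed = NA`).
#' @export
read_cohort <- function(dir) {
  structure(list(network = load_network(file.path(dir, "network.tsv")),
                 planted_drivers =
                   read_gene_list(file.path(dir, "planted_drivers.txt")),
                 variants = read_maf(file.path(dir, "variants.maf.tsv")),
                 tumor_expr =
                   read_expression_matrix(file.path(dir, "tumor_expr.tsv")),
                 normal_expr =
                   read_expression_matrix(file.path(dir, "normal_expr.tsv")),
                 pairing = read_pairing(file.path(dir, "pairing.tsv")),
                 survival = read_survival(file.path(dir, "survival.tsv")),
                 seed = NA_integer_),
            class = "cohort_fixture")
}
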