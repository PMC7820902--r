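#' Build an interaction network from a directed edge list
#'
#' Constructs the directed gene-interaction graph used for network
#' propagation. Duplicate edges are collapsed, self-loops are removed (with
#' a warning giving their count), and genes are ordered lexicographically so
#' that every matrix built downstream has a deterministic, platform-stable
#' axis order.
#'
#' @param edges a two-column data.frame (source, target) of gene symbols.
#' @return an object of class `interaction_network`: a list with elements
#'   `genes` (sorted unique symbols), `edges` (deduplicated data.frame with
#'   columns `source`, `target`), `in_degree`, `out_degree` (named integer
#'   vectors), and `graph` (the corresponding igraph object).
#' @export
interaction_network <- function(edges) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  edges <- data.frame(source = as.character(edges[[1]]),
                      target = as.character(edges[[2]]),
                      stringsAsFactors = FALSE)
  loops <- edges$source == edges$target
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) removed")
    edges <- edges[!loops, , drop = FALSE]
  }
  edges <- unique(edges)
  if (nrow(edges) == 0L)
    stop("network is empty after removing self-loops and duplicates")
  genes <- sort(unique(c(edges$source, edges$target)))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = genes)
  out_degree <- igraph::degree(g, mode = "out")[genes]
  in_degree <- igraph::degree(g, mode = "in")[genes]
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(genes = genes,
                 edges = edges,
                 in_degree = in_degree,
                 out_degree = out_degree,
                 graph = g),
            class = "interaction_network")
}

#' Load a directed interaction network from a TSV edge list
#'
#' Reads a tab-separated file with two columns, source and target gene
#' symbol. A header row is detected and skipped when its first field matches
#' a common column label (source/from/gene1, case-insensitive). Lines
#' starting with `#` are skipped; a line without exactly two non-empty
#' fields is a parse error reporting the offending line number.
#'
#' @param path path to the edge-list TSV.
#' @return an `interaction_network` (see [interaction_network()]).
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) == 0L) stop("network file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, function(f)
    length(f) < 2L || !nzchar(trimws(f[1])) || !nzchar(trimws(f[2])),
    logical(1)))
  if (length(bad) > 0L)
    stop("malformed edge at line ", lineno[bad[1]], " of ", path,
         ": expected two tab-separated gene symbols")
  src <- trimws(vapply(fields, `[`, character(1), 1L))
  tgt <- trimws(vapply(fields, `[`, character(1), 2L))
  header_labels <- c("source", "from", "gene1", "gene_a", "regulator")
  if (tolower(src[1]) %in% header_labels) {
    src <- src[-1]
    tgt <- tgt[-1]
  }
  if (length(src) == 0L) stop("network file has a header but no edges: ", path)
  interaction_network(data.frame(source = src, target = tgt))
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network:", length(x$genes), "genes,",
      nrow(x$edges), "directed edges\n")
  invisible(x)
}

#' Degree- and direction-aware normalized adjacency matrix
#'
#' With adjacency entries a_ij = 1 when an edge j -> i exists, the
#' normalized matrix has entries (a_ij + a_ji) / (deg_out_j + deg_in_j),
#' so each column mixes incoming and outgoing connectivity of its gene and
#' sums to 1 whenever that gene has at least one edge. Columns of isolated
#' genes are all zero.
#'
#' @param net an `interaction_network`.
#' @return an object of class `normalized_adjacency`: list with `matrix`
#'   (sparse `dgCMatrix`, genes x genes) and `genes` (axis order).
#' @export
normalize_adjacency <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  genes <- net$genes
  n <- length(genes)
  i <- match(net$edges$target, genes)   # a_ij = 1 for edge j -> i
  j <- match(net$edges$source, genes)
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n),
                            dimnames = list(genes, genes))
  S <- A + Matrix::t(A)
  degtot <- net$out_degree + net$in_degree
  scale <- ifelse(degtot > 0, 1 / degtot, 0)
  Anorm <- S %*% Matrix::Diagonal(n, x = scale)
  dimnames(Anorm) <- list(genes, genes)
  structure(list(matrix = methods::as(Anorm, "CsparseMatrix"), genes = genes),
            class = "normalized_adjacency")
}

#' Closed-form diffusion matrix of a random walk with restart
#'
#' Computes D = beta * (I - (1 - beta) * Anorm)^-1, the stationary
#' influence matrix of a random walk that restarts with probability `beta`
#' at each step. Entry (i, j) measures how much signal placed on gene j
#' ends up on gene i. Because the normalized adjacency is column
#' stochastic on non-isolated genes, each such column of D also sums to 1.
#' `beta = 1` means no diffusion (D is the identity); `beta = 0` is
#' rejected because the resolvent can be singular there.
#'
#' @param adj a `normalized_adjacency`.
#' @param beta restart probability in (0, 1]; default 0.48.
#' @param method `"direct"` (dense solve, default) or `"iterative"`
#'   (fixed-point iteration, for networks too large to invert densely).
#' @param tol convergence tolerance for the iterative method.
#' @param max_iter iteration cap for the iterative method.
#' @param cache_dir optional directory; when given, the result is cached in
#'   a file keyed by the network content hash and `beta`, and reloaded on
#'   subsequent calls with the same inputs.
#' @return an object of class `diffusion_matrix`: list with `matrix`
#'   (dense, genes x genes), `beta`, and `genes`.
#' @export
compute_diffusion <- function(adj, beta = 0.48,
                              method = c("direct", "iterative"),
                              tol = 1e-9, max_iter = 10000L,
                              cache_dir = NULL) {
  stopifnot(inherits(adj, "normalized_adjacency"))
  method <- match.arg(method)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1)
    stop("beta must be a single number in (0, 1]; got ", format(beta))
  cache_file <- NULL
  if (!is.null(cache_dir)) {
    key <- .network_hash(adj, beta)
    cache_file <- file.path(cache_dir, paste0("diffusion-", key, ".rds"))
    if (file.exists(cache_file)) {
      cached <- readRDS(cache_file)
      if (identical(cached$genes, adj$genes) && identical(cached$beta, beta))
        return(cached)
    }
  }
  n <- length(adj$genes)
  if (beta == 1) {
    D <- diag(nrow = n)
  } else if (method == "direct") {
    M <- diag(nrow = n) - (1 - beta) * as.matrix(adj$matrix)
    D <- tryCatch(beta * solve(M),
                  error = function(e)
                    stop("diffusion solve failed (beta = ", beta, ", n = ",
                         n, "): ", conditionMessage(e)))
  } else {
    # fixed point D <- beta I + (1 - beta) Anorm D, contraction for beta > 0
    A <- adj$matrix
    D <- diag(nrow = n) * beta
    bI <- D
    for (it in seq_len(max_iter)) {
      Dn <- as.matrix(bI + (1 - beta) * (A %*% D))
      delta <- max(abs(Dn - D))
      D <- Dn
      if (delta < tol) break
    }
    if (delta >= tol)
      stop("iterative diffusion did not converge within ", max_iter,
           " iterations (last delta ", format(delta), ")")
  }
  dimnames(D) <- list(adj$genes, adj$genes)
  out <- structure(list(matrix = D, beta = beta, genes = adj$genes),
                   class = "diffusion_matrix")
  if (!is.null(cache_file)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(out, cache_file)
  }
  out
}

.network_hash <- function(adj, beta) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(list(genes = adj$genes,
               i = adj$matrix@i, p = adj$matrix@p, x = adj$matrix@x,
               beta = beta),
          tf)
  unname(tools::md5sum(tf))
}

#' Network-centrality baseline rankings
#'
#' Ranks genes by total degree, by directed shortest-path betweenness, and
#' by the mean of the two after min-max rescaling each to [0, 1] (the two
#' centralities live on incomparable scales). These data-free baselines
#' serve as comparators for the diffusion-based rankings.
#'
#' @param net an `interaction_network`.
#' @return named list of three `gene_ranking` objects: `degree`,
#'   `betweenness`, `mean_of_both`.
#' @export
centrality_baselines <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  genes <- net$genes
  deg <- net$in_degree + net$out_degree
  btw <- igraph::betweenness(net$graph, directed = TRUE)[genes]
  rescale01 <- function(x) {
    r <- range(x)
    if (r[2] == r[1]) return(rep(0, length(x)))
    (x - r[1]) / (r[2] - r[1])
  }
  combined <- (rescale01(deg) + rescale01(btw)) / 2
  names(combined) <- genes
  list(degree = new_gene_ranking(deg, higher_is_better = TRUE),
       betweenness = new_gene_ranking(btw, higher_is_better = TRUE),
       mean_of_both = new_gene_ranking(combined, higher_is_better = TRUE))
}
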