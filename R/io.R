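# Readers and writers for the plain-text interchange formats: MAF-lite
# variant tables, expression matrices, sample pairings, survival tables,
# gene lists and ranking files. Numeric matrices are written with 17
# significant digits so a write/read round trip reproduces the doubles
# exactly.

#' Mapping from MAF Variant_Classification terms to the controlled
#' vocabulary
#'
#' Returns the shipped mapping table translating standard Mutation
#' Annotation Format terms (e.g. `Missense_Mutation`, `Frame_Shift_Del`,
#' `Silent`) to the package's variant classes. Terms not in the table map
#' to `other`.
#'
#' @return data.frame with columns `maf_term`, `variant_class`.
#' @export
variant_class_map <- function() {
  path <- system.file("extdata", "variant_class_map.tsv",
                      package = "minnetrank", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a MAF-lite somatic variant table
#'
#' Expects a TSV with at least `Tumor_Sample_Barcode`, `Hugo_Symbol` and
#' `Variant_Classification` (lower-case `sample`/`gene`/`variant_class`
#' synonyms are accepted), plus an optional `Weight_Score` column carrying
#' an external deleteriousness score in [0, 1]. Variant classification
#' terms are mapped through [variant_class_map()]; unknown terms become
#' `other`.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `sample`, `gene`, `variant_class`,
#'   `score`.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "#")
  pick <- function(options) {
    hit <- intersect(options, names(df))
    if (length(hit) == 0L)
      stop("MAF-lite file ", path, " lacks a column among: ",
           toString(options))
    df[[hit[1]]]
  }
  sample <- as.character(pick(c("Tumor_Sample_Barcode", "sample")))
  gene <- as.character(pick(c("Hugo_Symbol", "gene")))
  class_raw <- as.character(pick(c("Variant_Classification",
                                   "variant_class")))
  map <- variant_class_map()
  idx <- match(class_raw, map$maf_term)
  variant_class <- ifelse(is.na(idx), "other", map$variant_class[idx])
  score <- if ("Weight_Score" %in% names(df))
    as.numeric(df$Weight_Score)
  else if ("score" %in% names(df)) as.numeric(df$score)
  else NA_real_
  data.frame(sample = sample, gene = gene, variant_class = variant_class,
             score = score, stringsAsFactors = FALSE)
}

#' Write a variant table as MAF-lite
#' @param variants data.frame with `sample`, `gene`, `variant_class`,
#'   optional `score`.
#' @param path output TSV path.
#' @export
write_maf <- function(variants, path) {
  out <- data.frame(Tumor_Sample_Barcode = variants$sample,
                    Hugo_Symbol = variants$gene,
                    Variant_Classification = variants$variant_class,
                    Weight_Score = .fmt_num(variants$score))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene expression matrix
#'
#' TSV with gene symbols in the first column and one column per sample.
#'
#' @param path path to the TSV.
#' @return numeric matrix, genes as rownames, samples as colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene symbols in ", path)
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- genes
  M
}

#' Write a gene expression matrix
#' @param expr numeric matrix with gene rownames.
#' @param path output TSV path.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene = rownames(expr),
                   apply(expr, 2, .fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tumor-normal sample pairing table
#' @param path TSV with columns `tumor`, `normal` (header optional).
#' @return data.frame with columns `tumor`, `normal`.
#' @export
read_pairing <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          header = FALSE, comment.char = "#")
  if (tolower(df[1, 1]) %in% c("tumor", "tumor_sample")) df <- df[-1, ]
  data.frame(tumor = as.character(df[[1]]), normal = as.character(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Write a tumor-normal pairing table
#' @param pairing data.frame with columns `tumor`, `normal`.
#' @param path output TSV path.
#' @export
write_pairing <- function(pairing, path) {
  utils::write.table(pairing[, c("tumor", "normal")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table
#' @param path TSV with columns `sample`, `time`, `event` (event 1 =
#'   death/event, 0 = censored).
#' @return data.frame with those columns, validated.
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("sample", "time", "event")
  df$sample <- as.character(df$sample)
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  if (any(df$time < 0)) stop("negative survival times in ", path)
  if (!all(df$event %in% c(0L, 1L)))
    stop("event indicator must be 0 or 1 in ", path)
  df
}

#' Write a survival table
#' @param survival data.frame with columns `sample`, `time`, `event`.
#' @param path output TSV path.
#' @export
write_survival <- function(survival, path) {
  out <- data.frame(sample = survival$sample,
                    time = .fmt_num(survival$time),
                    event = survival$event)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#' @param path text file, one gene symbol per line; `#` comments skipped.
#' @return character vector of unique symbols.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Write an edge list TSV
#' @param net an `interaction_network`.
#' @param path output TSV path (columns `source`, `target`).
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a gene ranking TSV
#' @param ranking a `gene_ranking`.
#' @param path output TSV path (columns `rank`, `gene`, `score`).
#' @export
write_ranking <- function(ranking, path) {
  out <- data.frame(rank = ranking$rank, gene = ranking$gene,
                    score = .fmt_num(ranking$score))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene ranking TSV written by [write_ranking()]
#' @param path ranking TSV path.
#' @return a `gene_ranking` data.frame.
#' @export
read_ranking <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(data.frame(rank = as.integer(df$rank),
                       gene = as.character(df$gene),
                       score = as.numeric(df$score),
                       stringsAsFactors = FALSE),
            class = c("gene_ranking", "data.frame"))
}

# full-precision decimal formatting: doubles survive the round trip
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.finite(v) && v == round(v) && abs(v) < 1e15)
      return(format(v, scientific = FALSE))
    sprintf("%.17g", v)
  }, character(1))
  out
}
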