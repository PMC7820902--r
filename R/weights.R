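#' Variant classes recognized by the weighting schemes
#' @keywords internal
VARIANT_CLASSES <- c("missense", "stop_gain", "stop_loss", "frameshift",
                     "nonframeshift", "synonymous", "other")

#' Define a variant-type weighting scheme
#'
#' The weighting schemes decide how much each somatic variant contributes
#' to its gene's mutation score:
#' \describe{
#'   \item{uniform}{every non-synonymous variant weighs 1; synonymous
#'     variants are dropped. This reproduces the plain binary
#'     mutated-or-not analysis.}
#'   \item{sift}{missense variants weigh their SIFT score (taken as
#'     supplied by default; see `sift_transform`), truncating variants
#'     (stop-gain, stop-loss, frameshift, non-frameshift) weigh 1,
#'     synonymous variants are dropped.}
#'   \item{sift_prdsm}{as `sift`, but synonymous variants are kept with
#'     their PrDSM deleteriousness score as weight.}
#'   \item{sift_prdsm_filtered}{as `sift_prdsm`, but a synonymous variant
#'     is kept only when its PrDSM score exceeds `prdsm_threshold`
#'     (strict inequality); the default 0.308 is the published
#'     deleteriousness cutoff for synonymous variants.}
#'   \item{sift_predcid}{as `sift`, but frameshift variants weigh their
#'     PredCID score instead of 1.}
#' }
#'
#' SIFT scores are conventionally low for deleterious variants, yet the
#' schemes above consume them directly as weights; `sift_transform =
#' "one_minus"` is provided for users who prefer 1 - SIFT so that more
#' deleterious variants carry more weight.
#'
#' @param name scheme name, one of the five above.
#' @param prdsm_threshold PrDSM cutoff in [0, 1], consulted only by
#'   `sift_prdsm_filtered`.
#' @param sift_transform `"as_stated"` (use the SIFT score directly,
#'   default) or `"one_minus"`.
#' @param missing_score what to do when a variant's class requires an
#'   external score but none is present: `"warn"` (default; weight falls
#'   back to 1) or `"error"`.
#' @return an object of class `weight_scheme`.
#' @export
weight_scheme <- function(name = c("uniform", "sift", "sift_prdsm",
                                   "sift_prdsm_filtered", "sift_predcid"),
                          prdsm_threshold = 0.308,
                          sift_transform = c("as_stated", "one_minus"),
                          missing_score = c("warn", "error")) {
  name <- match.arg(name)
  sift_transform <- match.arg(sift_transform)
  missing_score <- match.arg(missing_score)
  stopifnot(is.numeric(prdsm_threshold), prdsm_threshold >= 0,
            prdsm_threshold <= 1)
  structure(list(name = name, prdsm_threshold = prdsm_threshold,
                 sift_transform = sift_transform,
                 missing_score = missing_score),
            class = "weight_scheme")
}

#' Assign per-variant weight coefficients
#'
#' Applies a [weight_scheme()] to a table of variant records, returning the
#' retained variants with a `weight` column in [0, 1]. Synonymous variants
#' are dropped or kept according to the scheme; variants whose class needs
#' an external deleteriousness score (missense under the SIFT schemes,
#' synonymous under the PrDSM schemes, frameshift under `sift_predcid`)
#' read it from the `score` column.
#'
#' @param variants data.frame with columns `sample`, `gene`,
#'   `variant_class` (values from the controlled vocabulary: missense,
#'   stop_gain, stop_loss, frameshift, nonframeshift, synonymous, other)
#'   and optionally `score` in [0, 1].
#' @param scheme a `weight_scheme` (or a scheme name, taken with its
#'   defaults).
#' @return the filtered data.frame with a `weight` column; the scheme name
#'   is recorded in attribute `scheme`.
#' @export
assign_variant_weights <- function(variants, scheme = weight_scheme()) {
  if (is.character(scheme)) scheme <- weight_scheme(scheme)
  stopifnot(inherits(scheme, "weight_scheme"), is.data.frame(variants))
  required <- c("sample", "gene", "variant_class")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0L)
    stop("variants table lacks column(s): ", toString(missing_cols))
  bad_class <- !(variants$variant_class %in% VARIANT_CLASSES)
  if (any(bad_class))
    stop("unrecognized variant class(es): ",
         toString(unique(variants$variant_class[bad_class])))
  if (is.null(variants$score)) variants$score <- NA_real_
  if (any(!is.na(variants$score) &
          (variants$score < 0 | variants$score > 1)))
    stop("variant scores must lie in [0, 1]")

  cls <- variants$variant_class
  score <- variants$score

  scored_weight <- function(idx, label) {
    w <- score[idx]
    nas <- is.na(w)
    if (any(nas)) {
      if (scheme$missing_score == "error")
        stop(sum(nas), " ", label, " variant(s) lack the score the '",
             scheme$name, "' scheme requires")
      warning(sum(nas), " ", label, " variant(s) lack a ", scheme$name,
              " score; weight 1 used")
      w[nas] <- 1
    }
    w
  }

  weight <- rep(1, nrow(variants))
  keep <- cls != "synonymous"

  if (scheme$name != "uniform") {
    mis <- which(cls == "missense")
    if (length(mis) > 0L) {
      w <- scored_weight(mis, "missense")
      if (scheme$sift_transform == "one_minus") w <- 1 - w
      weight[mis] <- w
    }
    if (scheme$name %in% c("sift_prdsm", "sift_prdsm_filtered")) {
      syn <- which(cls == "synonymous")
      if (length(syn) > 0L) {
        w <- scored_weight(syn, "synonymous")
        weight[syn] <- w
        keep[syn] <- if (scheme$name == "sift_prdsm_filtered")
          w > scheme$prdsm_threshold else TRUE
      }
    }
    if (scheme$name == "sift_predcid") {
      fs <- which(cls == "frameshift")
      if (length(fs) > 0L) weight[fs] <- scored_weight(fs, "frameshift")
    }
  }

  out <- variants[keep, , drop = FALSE]
  out$weight <- weight[keep]
  rownames(out) <- NULL
  attr(out, "scheme") <- scheme$name
  out
}
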