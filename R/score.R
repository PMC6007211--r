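# Exact-match evaluation scoring.

.trunc2 <- function(x) trunc(x * 100 + 1e-9) / 100
.round2 <- function(x) round(x + 1e-9, 2)

#' Score predicted records against gold annotations
#'
#' Exact-match set comparison on a component tuple. An instance counts as a
#' true positive only when every configured component matches; otherwise it
#' is a false positive (predicted only) or false negative (gold only).
#' Percentages are reported to two decimals: precision and recall are
#' truncated, the F-score (computed from the untruncated values) is rounded
#' (see the methods vignette on this mixed convention).
#'
#' @param gold,predicted Record tibbles or data.frames. A unified
#'   `entity_norm` column is derived from `gene_id`/`mirna_norm` when absent.
#' @param components Key columns compared (default: the identifier tuple
#'   pmid, expressed entity, level, disease).
#' @return An `exprel_score` list: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f`.
#' @export
score <- function(gold, predicted,
                  components = c("pmid", "entity_norm", "level", "doid")) {
  keyize <- function(x) {
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    if (!"entity_norm" %in% names(x) &&
        all(c("entity_kind", "gene_id", "mirna_norm") %in% names(x))) {
      x$entity_norm <- ifelse(x$entity_kind == "gene", x$gene_id, x$mirna_norm)
    }
    miss <- setdiff(components, names(x))
    if (length(miss)) stop("missing component column(s): ",
                           paste(miss, collapse = ", "))
    unique(do.call(paste, c(lapply(x[components], as.character), sep = "\x1f")))
  }
  gk <- keyize(gold); pk <- keyize(predicted)
  tp <- length(intersect(gk, pk))
  fp <- length(setdiff(pk, gk))
  fn <- length(setdiff(gk, pk))
  score_from_counts(tp, fp, fn)
}

#' Score report from raw counts
#'
#' @param tp,fp,fn True-positive, false-positive and false-negative counts.
#' @return An `exprel_score`.
#' @export
score_from_counts <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  f <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = .trunc2(p), recall = .trunc2(r),
                 f = .round2(f)),
            class = "exprel_score")
}

#' @export
print.exprel_score <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  P %.2f  R %.2f  F %.2f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f))
  invisible(x)
}
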