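# Confusion-matrix scoring of an inferred network against a gold standard.

#' Confusion counts over unordered gene pairs
#'
#' Compares an inferred network with a reference over all `C(N, 2)`
#' unordered gene pairs: TP are pairs present in both (correctly inferred
#' edges), TN pairs in neither (correctly removed), FP pairs only inferred
#' (wrongly added) and FN pairs only in the reference (wrongly removed).
#' Directed or duplicated reference edges are collapsed to unordered pairs
#' first, so the four counts always sum to `C(N, 2)`.
#'
#' @param inferred,truth [grn()] objects over the same gene set.
#' @return An object of class `"confusion_counts"`: list with `tp`, `tn`,
#'   `fp`, `fn`, `n_genes`.
#' @export
confusion_counts <- function(inferred, truth) {
  stopifnot(inherits(inferred, "grn"), inherits(truth, "grn"))
  if (!setequal(inferred$gene_ids, truth$gene_ids))
    stop_config("inferred and reference networks cover different gene sets")
  n <- length(inferred$gene_ids)
  total <- n * (n - 1) / 2
  key <- function(net) paste(net$edges$from, net$edges$to, sep = "\r")
  ki <- key(inferred)
  kt <- key(truth)
  tp <- sum(ki %in% kt)
  fp <- length(ki) - tp
  fn <- length(kt) - tp
  tn <- total - tp - fp - fn
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, n_genes = n),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d  (over %d gene pairs)\n",
              x$tp, x$tn, x$fp, x$fn, x$n_genes * (x$n_genes - 1) / 2))
  invisible(x)
}

#' Sensitivity, specificity and precision
#'
#' The three standard classification ratios over unordered gene pairs:
#' specificity `TN / (TN + FP)`, sensitivity `TP / (TP + FN)` and
#' precision `TP / (TP + FP)`. When no edges were inferred at all
#' (`TP + FP = 0`) precision is undefined and reported as `NA` with a
#' message, never silently as 0 or 1.
#'
#' @param counts A [confusion_counts()] object, or a list/vector with
#'   elements `tp`, `tn`, `fp`, `fn`.
#' @return Named numeric vector `c(specificity, sensitivity, precision)`.
#' @examples
#' classification_metrics(list(tp = 112, tn = 30602, fp = 138, fn = 273))
#' @export
classification_metrics <- function(counts) {
  cc <- lapply(counts[c("tp", "tn", "fp", "fn")], as.numeric)
  if (any(vapply(cc, function(v) length(v) != 1L || is.na(v) || v < 0, TRUE)))
    stop_config("counts must contain nonnegative tp, tn, fp, fn")
  specificity <- cc$tn / (cc$tn + cc$fp)
  sensitivity <- cc$tp / (cc$tp + cc$fn)
  if (cc$tp + cc$fp == 0) {
    message("no edges inferred: precision is undefined, reporting NA")
    precision <- NA_real_
  } else {
    precision <- cc$tp / (cc$tp + cc$fp)
  }
  c(specificity = specificity, sensitivity = sensitivity,
    precision = precision)
}
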