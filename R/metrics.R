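#' Confusion counts for deletion-pathogenicity calls
#'
#' \code{confusion_counts} constructs the container directly (counts may be
#' fractional, as fold-averaged and class-normalised counts are);
#' \code{confusion} tallies it from labels and calls. Pathogenic is the
#' positive class: TP/TN are correctly predicted pathogenic/benign variants,
#' FN/FP the respective misclassifications. VUS calls enter only the
#' missing count, never the confusion matrix.
#'
#' @param TP,TN,FP,FN Non-negative (possibly fractional) counts.
#' @param n_missing Number of unclassified (VUS) variants.
#' @return A \code{confusion_counts} object.
#' @export
confusion_counts <- function(TP, TN, FP, FN, n_missing = 0) {
  counts <- c(TP = as.numeric(TP), TN = as.numeric(TN),
              FP = as.numeric(FP), FN = as.numeric(FN))
  if (any(counts < 0) || n_missing < 0) stop("counts must be non-negative")
  structure(c(as.list(counts), list(n_missing = as.numeric(n_missing))),
            class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param labels True labels, \code{pathogenic}/\code{benign} (unlabeled
#'   rows are an error).
#' @param calls Predicted calls, \code{pathogenic}/\code{benign}/\code{VUS}.
#' @export
confusion <- function(labels, calls) {
  labels <- as.character(labels); calls <- as.character(calls)
  if (any(!labels %in% c("pathogenic", "benign")))
    stop("labels must be 'pathogenic' or 'benign'")
  if (any(!calls %in% c("pathogenic", "benign", "VUS")))
    stop("calls must be 'pathogenic', 'benign' or 'VUS'")
  if (length(labels) != length(calls)) stop("labels/calls length mismatch")
  confusion_counts(
    TP = sum(labels == "pathogenic" & calls == "pathogenic"),
    TN = sum(labels == "benign" & calls == "benign"),
    FP = sum(labels == "benign" & calls == "pathogenic"),
    FN = sum(labels == "pathogenic" & calls == "benign"),
    n_missing = sum(calls == "VUS"))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %.1f  TN %.1f  FP %.1f  FN %.1f  (missing %g)\n",
              x$TP, x$TN, x$FP, x$FN, x$n_missing))
  invisible(x)
}

#' Class-normalised confusion counts
#'
#' Rescales the benign row (TN, FP) by the ratio of class totals
#' \code{(TP + FN) / (TN + FP)}, so both classes have equal totals and
#' threshold-dependent metrics reflect balanced data. All ratio metrics
#' (PPV, NPV, sensitivity, specificity, accuracy, MCC, OPM) are invariant to
#' which class row is scaled; the benign-up direction matches how normalised
#' counts are conventionally displayed alongside the raw ones.
#'
#' @param counts A \code{confusion_counts} with both class totals positive.
#' @return Normalised \code{confusion_counts}.
#' @export
normalise_counts <- function(counts) {
  pos <- counts$TP + counts$FN
  neg <- counts$TN + counts$FP
  if (pos <= 0 || neg <= 0) stop("both class totals must be positive")
  s <- pos / neg
  confusion_counts(TP = counts$TP, TN = counts$TN * s,
                   FP = counts$FP * s, FN = counts$FN,
                   n_missing = counts$n_missing)
}

metric_ratio <- function(num, den, name) {
  if (den <= 0) {
    warning(name, " undefined (zero denominator); returning 0")
    return(0)
  }
  num / den
}

#' Performance metrics from confusion counts
#'
#' Computes the standard suite on the classified variants: PPV, NPV,
#' sensitivity, specificity, accuracy, the Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FN)(TP+FP)(TN+FN)(TN+FP)}}}
#' (0 when the denominator vanishes) and the composite overall performance
#' measure
#' \deqn{OPM = (PPV + NPV)(Sens + Spec)(Acc + (1 + MCC)/2)\,/\,8,}
#' which lies in [0, 1] and equals 1 only for a perfect classifier. Ratio
#' metrics with a zero denominator are reported as 0 with a warning. Full
#' precision is retained; rounding is a display concern.
#'
#' @param counts A \code{confusion_counts}.
#' @param normalise Also compute metrics on class-normalised counts
#'   (default TRUE; skipped when a class total is 0).
#' @return A \code{metrics_report}: list with \code{counts},
#'   \code{metrics} (named vector), \code{normalised_counts},
#'   \code{normalised_metrics}, \code{missing_fraction}.
#' @examples
#' del_metrics(confusion_counts(TP = 422, TN = 251, FP = 61, FN = 78))
#' @export
del_metrics <- function(counts, normalise = TRUE) {
  compute <- function(cc) {
    total <- cc$TP + cc$TN + cc$FP + cc$FN
    if (total <= 0) stop("no classified variants")
    PPV <- metric_ratio(cc$TP, cc$TP + cc$FP, "PPV")
    NPV <- metric_ratio(cc$TN, cc$TN + cc$FN, "NPV")
    sens <- metric_ratio(cc$TP, cc$TP + cc$FN, "sensitivity")
    spec <- metric_ratio(cc$TN, cc$TN + cc$FP, "specificity")
    acc <- (cc$TP + cc$TN) / total
    den <- sqrt(cc$TP + cc$FN) * sqrt(cc$TP + cc$FP) *
           sqrt(cc$TN + cc$FN) * sqrt(cc$TN + cc$FP)
    mcc <- if (den == 0) 0 else (cc$TP * cc$TN - cc$FP * cc$FN) / den
    opm <- (PPV + NPV) * (sens + spec) * (acc + (1 + mcc) / 2) / 8
    c(PPV = PPV, NPV = NPV, sensitivity = sens, specificity = spec,
      accuracy = acc, MCC = mcc, OPM = opm)
  }
  metrics <- compute(counts)
  norm_counts <- NULL
  norm_metrics <- NULL
  if (normalise && counts$TP + counts$FN > 0 && counts$TN + counts$FP > 0) {
    norm_counts <- normalise_counts(counts)
    norm_metrics <- compute(norm_counts)
  }
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  structure(list(counts = counts, metrics = metrics,
                 normalised_counts = norm_counts,
                 normalised_metrics = norm_metrics,
                 missing_fraction = counts$n_missing / (total + counts$n_missing)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  fmt <- function(v) formatC(round(v, digits), format = "f", digits = digits)
  for (nm in names(x$metrics)) {
    cat(sprintf("%-12s %s", nm, fmt(x$metrics[[nm]])))
    if (!is.null(x$normalised_metrics))
      cat(" (", fmt(x$normalised_metrics[[nm]]), ")", sep = "")
    cat("\n")
  }
  cc <- x$counts
  cat(sprintf("counts       TP %.1f TN %.1f FP %.1f FN %.1f", cc$TP, cc$TN, cc$FP, cc$FN))
  if (!is.null(x$normalised_counts)) {
    nc <- x$normalised_counts
    cat(sprintf("  (norm TN %.1f FP %.1f)", nc$TN, nc$FP))
  }
  cat("\n")
  if (x$missing_fraction > 0)
    cat(sprintf("missing      %g (%.1f%%)\n", cc$n_missing, 100 * x$missing_fraction))
  invisible(x)
}

#' Serialise a metrics report as JSON
#'
#' @param report A \code{metrics_report}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_metrics <- function(report, path) {
  out <- list(counts = unclass(report$counts),
              metrics = as.list(report$metrics),
              normalised_counts = if (!is.null(report$normalised_counts))
                unclass(report$normalised_counts),
              normalised_metrics = if (!is.null(report$normalised_metrics))
                as.list(report$normalised_metrics),
              missing_fraction = report$missing_fraction)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Threshold-independent area under the ROC curve computed from average
#' ranks, equivalent to the probability that a random pathogenic variant
#' scores above a random benign one, counting ties as one half.
#'
#' @param labels True labels (\code{pathogenic}/\code{benign}; both classes
#'   must be present).
#' @param scores Numeric scores, higher meaning more pathogenic.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(labels, scores) {
  labels <- as.character(labels)
  pos <- labels == "pathogenic"
  neg <- labels == "benign"
  if (!any(pos) || !any(neg)) stop("both classes must be present for AUC")
  r <- rank(scores)
  np <- sum(pos); nn <- sum(neg)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Evaluate three-state calls against binary truth
#'
#' Metrics are computed on the classified (non-VUS) subset only; the VUS
#' count and its fraction of all variants are reported alongside.
#'
#' @param labels True labels (\code{pathogenic}/\code{benign}).
#' @param calls Calls including possible \code{VUS}.
#' @return A \code{metrics_report} whose \code{missing_fraction} is
#'   n_VUS / n_total.
#' @export
evaluate_tristate <- function(labels, calls) {
  calls <- as.character(calls)
  if (all(calls == "VUS")) stop("all calls are VUS; metrics undefined")
  del_metrics(confusion(labels, calls))
}
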