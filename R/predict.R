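#' Bootstrap p-value against a null mean probability of 0.5
#'
#' Tests whether the mean of an ensemble's per-model probabilities differs
#' from 0.5 (no evidence for pathogenicity versus benignity). \code{B}
#' resamples of the probability vector are drawn with replacement; the
#' two-sided p-value doubles the smaller inclusive tail of the resampled
#' means around 0.5 and is capped at 1:
#' \deqn{p = \min(1,\; 2 \min(\#\{m^* \ge 0.5\}, \#\{m^* \le 0.5\}) / B)}
#' Degenerate inputs behave sensibly: all probabilities at 0.9 give p = 0,
#' all at exactly 0.5 give p = 1. The p-value is invariant to permutations
#' of \code{probs}.
#'
#' @param probs Numeric vector of per-model probabilities in [0, 1]
#'   (typically length 25).
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Optional seed (the caller's RNG stream is untouched).
#' @return The p-value in [0, 1].
#' @export
bootstrap_pvalue <- function(probs, B = 1000, seed = NULL) {
  if (B < 1) stop("B must be at least 1")
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  probs <- sort(probs)  # exact invariance to the order of the members
  n <- length(probs)
  means <- with_seed(seed,
    colMeans(matrix(probs[sample.int(n, n * B, replace = TRUE)], nrow = n)))
  ge <- sum(means >= 0.5)
  le <- sum(means <= 0.5)
  min(1, 2 * min(ge, le) / B)
}

#' Predict deletion pathogenicity from a fitted ensemble
#'
#' \code{type} selects the output:
#' \describe{
#'   \item{\code{"prob"}}{mean probability over the ensemble members.}
#'   \item{\code{"response"}}{binary call: pathogenic iff the mean
#'     probability exceeds 0.5 (exactly 0.5 is benign).}
#'   \item{\code{"members"}}{the full n x n_models probability matrix.}
#'   \item{\code{"tristate"}}{three-state classification: each variant's 25
#'     member probabilities are bootstrap-tested against 0.5
#'     (\code{\link{bootstrap_pvalue}}); variants whose test cannot reject
#'     the null (p >= \code{alpha}) are called VUS, the rest pathogenic or
#'     benign by the mean probability. \code{alpha >= 1} disables
#'     abstention, reducing exactly to the binary predictor.}
#' }
#' Bootstrap seeds are derived per variant from a hash of the variant id and
#' \code{seed}, so p-values do not depend on batch composition or order.
#'
#' @param object A \code{del_ensemble}.
#' @param newdata Feature table (must contain every training feature; a
#'   missing feature raises an error naming it).
#' @param type Output type (see above).
#' @param alpha Significance level for the VUS test (default 0.05).
#' @param B Bootstrap resamples (default 1000).
#' @param seed Global seed combined with each variant id.
#' @param ... Unused.
#' @return See \code{type}; for \code{"tristate"}, a
#'   \code{tristate_prediction} data frame with columns \code{variant_id},
#'   \code{mean_prob}, \code{p_value}, \code{call}.
#' @export
predict.del_ensemble <- function(object, newdata,
                                 type = c("tristate", "prob", "response", "members"),
                                 alpha = 0.05, B = 1000, seed = 1, ...) {
  type <- match.arg(type)
  x <- feature_matrix(newdata, object$features)
  members <- vapply(object$models, function(m)
    predict_learner(object$learner, m, x), numeric(nrow(x)))
  members <- matrix(members, nrow = nrow(x))
  if (type == "members") return(members)
  mean_prob <- rowMeans(members)
  if (type == "prob") return(mean_prob)
  binary <- ifelse(mean_prob > 0.5, "pathogenic", "benign")
  if (type == "response")
    return(factor(binary, levels = c("benign", "pathogenic")))
  ids <- newdata$variant_id %||% rownames(newdata) %||% as.character(seq_len(nrow(x)))
  p_value <- vapply(seq_len(nrow(members)), function(i)
    bootstrap_pvalue(members[i, ], B = B,
                     seed = variant_seed(ids[i], seed)), numeric(1))
  call <- if (alpha >= 1) binary else ifelse(p_value >= alpha, "VUS", binary)
  structure(data.frame(variant_id = ids, mean_prob = mean_prob,
                       p_value = p_value, call = call,
                       stringsAsFactors = FALSE),
            alpha = alpha, B = B,
            class = c("tristate_prediction", "data.frame"))
}

#' Re-threshold a tri-state prediction at a different significance level
#'
#' Uses the stored mean probabilities and p-values, so no refit or
#' re-bootstrap is needed.
#'
#' @param pred A \code{tristate_prediction}.
#' @param alpha New significance level (\code{alpha >= 1} disables
#'   abstention).
#' @return A \code{tristate_prediction} at the new level.
#' @export
reclassify_alpha <- function(pred, alpha) {
  binary <- ifelse(pred$mean_prob > 0.5, "pathogenic", "benign")
  pred$call <- if (alpha >= 1) binary else ifelse(pred$p_value >= alpha, "VUS", binary)
  attr(pred, "alpha") <- alpha
  pred
}

#' Coverage/performance trade-off over VUS significance levels
#'
#' Re-thresholds a tri-state prediction at each \code{alpha} and evaluates
#' the classified subset, tabulating how performance and the number of
#' unclassified (VUS) variants trade off as the threshold tightens from 1.0
#' (no abstention) downwards.
#'
#' @param pred A \code{tristate_prediction}.
#' @param labels True labels (\code{pathogenic}/\code{benign}), aligned with
#'   \code{pred}.
#' @param alphas Decreasing significance levels to evaluate.
#' @return Data frame with one row per alpha: \code{n_vus},
#'   \code{missing_fraction}, \code{coverage}, \code{accuracy}, \code{MCC},
#'   \code{OPM} (NA when everything is VUS).
#' @export
sweep_alpha <- function(pred, labels,
                        alphas = c(1, 0.5, 0.1, 0.05, 0.01, 0.001)) {
  rows <- lapply(alphas, function(a) {
    p <- reclassify_alpha(pred, a)
    n_vus <- sum(p$call == "VUS")
    if (n_vus == nrow(p)) {
      data.frame(alpha = a, n_vus = n_vus, missing_fraction = 1, coverage = 0,
                 accuracy = NA_real_, MCC = NA_real_, OPM = NA_real_)
    } else {
      rep <- evaluate_tristate(labels, p$call)
      data.frame(alpha = a, n_vus = n_vus,
                 missing_fraction = rep$missing_fraction,
                 coverage = 1 - rep$missing_fraction,
                 accuracy = rep$metrics[["accuracy"]],
                 MCC = rep$metrics[["MCC"]], OPM = rep$metrics[["OPM"]])
    }
  })
  do.call(rbind, rows)
}

#' Write batch predictions as CSV
#'
#' Columns: variant id, mean probability, bootstrap p-value, binary call and
#' three-state call.
#'
#' @param pred A \code{tristate_prediction}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_predictions <- function(pred, path) {
  out <- data.frame(variant_id = pred$variant_id,
                    mean_prob = pred$mean_prob,
                    p_value = pred$p_value,
                    binary_call = ifelse(pred$mean_prob > 0.5, "pathogenic", "benign"),
                    call = pred$call)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
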