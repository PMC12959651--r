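#' Feature filtering cascade
#'
#' Three deterministic stages reduce a redundant engineered feature set
#' before model selection; the cascade is fitted on training data only and
#' can be replayed on other tables via \code{\link{apply_filter}}:
#' \enumerate{
#'   \item \code{drop_rare_binary}: binary features whose minority class has
#'     fewer than \code{min_minority} observations (default 6, i.e. "5 or
#'     fewer" removed) are unstable and dropped. A constant binary column has
#'     minority count 0 and is dropped here.
#'   \item \code{drop_zero_variance}: numeric features with exactly zero
#'     variance are dropped (near-zero variance is left to the correlation
#'     stage).
#'   \item \code{drop_correlated}: numeric features are scanned in registry
#'     order (category, then name -- fully deterministic); a feature whose
#'     absolute Spearman rank correlation with an already-kept feature
#'     exceeds \code{threshold} (default 0.8) is dropped, keeping the
#'     earlier column. Ties in ranks use average ranks.
#' }
#' Sequence-segment columns bypass all stages and are not counted among the
#' filtered features. The cascade is idempotent: applied to its own output it
#' drops nothing.
#'
#' @param table A feature table (with registry attribute; see
#'   \code{\link{feature_registry}}).
#' @param min_minority Minimum minority-class count for binary features.
#' @param threshold Absolute Spearman correlation above which the later
#'   feature is dropped.
#' @return \code{filter_features}: list with \code{table} (filtered) and
#'   \code{report} (a \code{filter_report}: dropped lists per stage,
#'   \code{n_in}, \code{n_out}). The stage functions return
#'   \code{list(table, dropped)}.
#' @export
filter_features <- function(table, min_minority = 6, threshold = 0.8) {
  n_in <- length(model_feature_names(table))
  s1 <- drop_rare_binary(table, min_minority = min_minority)
  s2 <- drop_zero_variance(s1$table)
  s3 <- drop_correlated(s2$table, threshold = threshold)
  report <- structure(list(
    dropped_rare_binary = s1$dropped,
    dropped_zero_variance = s2$dropped,
    dropped_correlated = s3$dropped,
    n_in = n_in,
    n_out = length(model_feature_names(s3$table)),
    min_minority = min_minority,
    threshold = threshold
  ), class = "filter_report")
  stopifnot(report$n_out == report$n_in - length(report$dropped_rare_binary) -
              length(report$dropped_zero_variance) -
              nrow(report$dropped_correlated))
  list(table = s3$table, report = report)
}

drop_feature_cols <- function(table, drop) {
  regi <- attr(table, "registry")
  out <- table[, setdiff(names(table), drop), drop = FALSE]
  if (!is.null(regi))
    attr(out, "registry") <- regi[!regi$name %in% drop, , drop = FALSE]
  attr(out, "excluded") <- attr(table, "excluded")
  class(out) <- class(table)
  out
}

#' @rdname filter_features
#' @export
drop_rare_binary <- function(table, min_minority = 6) {
  regi <- feature_registry(table)
  bin <- regi$name[regi$type == "binary"]
  dropped <- bin[vapply(bin, function(nm) {
    x <- table[[nm]]
    min(sum(x == 0), sum(x == 1)) < min_minority
  }, logical(1))]
  list(table = drop_feature_cols(table, dropped), dropped = dropped)
}

#' @rdname filter_features
#' @export
drop_zero_variance <- function(table) {
  regi <- feature_registry(table)
  num <- regi$name[regi$type == "numeric"]
  dropped <- num[vapply(num, function(nm) var(table[[nm]]) == 0, logical(1))]
  list(table = drop_feature_cols(table, dropped), dropped = dropped)
}

#' @rdname filter_features
#' @export
drop_correlated <- function(table, threshold = 0.8) {
  regi <- feature_registry(table)
  num <- regi$name[regi$type == "numeric"]
  dropped <- data.frame(dropped = character(0), kept = character(0),
                        rho = numeric(0), stringsAsFactors = FALSE)
  if (length(num) >= 2) {
    rho <- suppressWarnings(cor(as.matrix(table[, num, drop = FALSE]),
                                method = "spearman"))
    rho[is.na(rho)] <- 0
    kept <- logical(length(num))
    for (j in seq_along(num)) {
      over <- which(kept & abs(rho[j, seq_along(num)]) > threshold)
      if (j > 1 && length(over)) {
        k <- over[1]
        dropped <- rbind(dropped, data.frame(
          dropped = num[j], kept = num[k], rho = rho[j, k],
          stringsAsFactors = FALSE))
      } else kept[j] <- TRUE
    }
  }
  list(table = drop_feature_cols(table, dropped$dropped), dropped = dropped)
}

#' Replay a fitted filter on another table
#'
#' Drops exactly the features recorded in a \code{filter_report}, so a
#' cascade fitted on training data is applied unchanged to evaluation data.
#'
#' @param table A feature table.
#' @param report A \code{filter_report} from \code{\link{filter_features}}.
#' @return The table without the dropped features.
#' @export
apply_filter <- function(table, report) {
  drop <- c(report$dropped_rare_binary, report$dropped_zero_variance,
            report$dropped_correlated$dropped)
  drop_feature_cols(table, drop)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Feature filter cascade:", x$n_in, "->", x$n_out, "features\n")
  cat("  rare binary (minority <", x$min_minority, "):",
      length(x$dropped_rare_binary), "dropped\n")
  cat("  zero variance:", length(x$dropped_zero_variance), "dropped\n")
  cat("  |Spearman rho| >", x$threshold, ":", nrow(x$dropped_correlated),
      "dropped\n")
  invisible(x)
}

#' Serialise a filter report as JSON
#'
#' @param report A \code{filter_report}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
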