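#' Build a position logo around deletion boundaries
#'
#' Collects, for one class of training deletions, the residues observed at
#' offsets -5..-1 (immediately N-terminal of the deletion start) and +1..+5
#' (immediately C-terminal of the deletion end), and summarises each offset as
#' a residue-frequency column with its information content in bits:
#' \deqn{info(o) = \log_2 20 - H(freq_o)}
#' where \eqn{H} is the Shannon entropy. The bit score of letter \eqn{a} at
#' offset \eqn{o} is \eqn{freq_o(a) \times info(o)}, the usual sequence-logo
#' letter height. Window positions beyond the protein termini simply do not
#' contribute; non-standard residues (X) are ignored. An offset with zero
#' observations gets uniform frequencies and information 0.
#'
#' Raw frequencies are used with no small-sample correction.
#'
#' Logos are fitted objects: build them on training variants only and reuse
#' them (via \code{\link{context_bitscores}}) on evaluation data.
#'
#' @param variants A \code{deletion_variants} data frame.
#' @param proteins Named sequence vector covering the variants' proteins.
#' @param class_tag Optional \code{"pathogenic"}/\code{"benign"}: restrict to
#'   variants with that label (at least one such variant required).
#' @param flank Window half-width in residues (default 5).
#' @return A \code{position_logo}: list with \code{freq} (20 x 2*flank
#'   matrix), \code{info} (bits per offset), \code{offsets}, \code{n_obs},
#'   \code{class_tag}.
#' @export
build_position_logo <- function(variants, proteins, class_tag = NULL, flank = 5) {
  v <- as.data.frame(variants)
  if (!is.null(class_tag)) v <- v[v$label == class_tag, , drop = FALSE]
  if (nrow(v) == 0) stop("no variants available for logo construction")
  offsets <- c(-flank:-1, 1:flank)
  counts <- matrix(0, nrow = 20, ncol = length(offsets),
                   dimnames = list(AA_STANDARD, as.character(offsets)))
  for (i in seq_len(nrow(v))) {
    seq <- proteins[[v$protein_id[i]]]
    if (is.null(seq) || is.na(seq)) stop("unknown protein: ", v$protein_id[i])
    L <- nchar(seq)
    for (k in seq_len(flank)) {
      pu <- v$start[i] - k
      if (pu >= 1) {
        a <- substr(seq, pu, pu)
        if (a %in% AA_STANDARD) counts[a, as.character(-k)] <- counts[a, as.character(-k)] + 1
      }
      pd <- v$end[i] + k
      if (pd <= L) {
        a <- substr(seq, pd, pd)
        if (a %in% AA_STANDARD) counts[a, as.character(k)] <- counts[a, as.character(k)] + 1
      }
    }
  }
  n_obs <- colSums(counts)
  freq <- counts
  info <- numeric(length(offsets))
  names(info) <- colnames(counts)
  for (j in seq_along(offsets)) {
    if (n_obs[j] == 0) {
      freq[, j] <- 1 / 20
      info[j] <- 0
    } else {
      p <- counts[, j] / n_obs[j]
      freq[, j] <- p
      nz <- p > 0
      info[j] <- log2(20) + sum(p[nz] * log2(p[nz]))
    }
  }
  structure(list(freq = freq, info = pmax(info, 0), offsets = offsets,
                 n_obs = n_obs, flank = flank, class_tag = class_tag),
            class = "position_logo")
}

#' @export
print.position_logo <- function(x, ...) {
  cat("Position logo", if (!is.null(x$class_tag)) paste0(" (", x$class_tag, ")"),
      ": offsets ", min(x$offsets), "..", max(x$offsets), "\n", sep = "")
  cat("Information content (bits):\n")
  print(round(x$info, 3))
  invisible(x)
}

# Letter bit scores: freq * column information.
logo_bits <- function(logo) sweep(logo$freq, 2, logo$info, "*")

#' Context bit-score features for deletions
#'
#' For each variant and each class logo, sums the logo bit scores of the
#' observed residues over the (at most \code{flank}) upstream offsets and,
#' separately, the downstream offsets. Positions beyond a terminus and
#' residues absent from a logo column contribute 0, so the four sums are
#' non-negative. A fifth, signed feature -- the pathogenic-minus-benign
#' difference of the total (up + down) sums -- summarises which class's
#' boundary context the variant resembles more; it can be switched off.
#'
#' @param variants A \code{deletion_variants} data frame.
#' @param proteins Named sequence vector.
#' @param logos List with elements \code{benign} and \code{pathogenic}, both
#'   \code{position_logo} objects built on training data.
#' @param include_diff Include the signed difference feature (default TRUE).
#' @return Numeric matrix with columns \code{ctx_up_benign},
#'   \code{ctx_down_benign}, \code{ctx_up_pathogenic},
#'   \code{ctx_down_pathogenic} and (optionally) \code{ctx_class_diff}.
#' @export
context_bitscores <- function(variants, proteins, logos, include_diff = TRUE) {
  stopifnot(all(c("benign", "pathogenic") %in% names(logos)))
  v <- as.data.frame(variants)
  bits <- lapply(logos, logo_bits)
  flank <- logos$benign$flank
  out <- matrix(0, nrow = nrow(v), ncol = 4,
                dimnames = list(NULL, c("ctx_up_benign", "ctx_down_benign",
                                        "ctx_up_pathogenic", "ctx_down_pathogenic")))
  for (i in seq_len(nrow(v))) {
    seq <- proteins[[v$protein_id[i]]]
    L <- nchar(seq)
    for (cl in c("benign", "pathogenic")) {
      b <- bits[[cl]]
      up <- down <- 0
      for (k in seq_len(flank)) {
        pu <- v$start[i] - k
        if (pu >= 1) {
          a <- substr(seq, pu, pu)
          if (a %in% AA_STANDARD) up <- up + b[a, as.character(-k)]
        }
        pd <- v$end[i] + k
        if (pd <= L) {
          a <- substr(seq, pd, pd)
          if (a %in% AA_STANDARD) down <- down + b[a, as.character(k)]
        }
      }
      out[i, paste0("ctx_up_", cl)] <- up
      out[i, paste0("ctx_down_", cl)] <- down
    }
  }
  if (include_diff) {
    diff <- (out[, "ctx_up_pathogenic"] + out[, "ctx_down_pathogenic"]) -
            (out[, "ctx_up_benign"] + out[, "ctx_down_benign"])
    out <- cbind(out, ctx_class_diff = diff)
  }
  out
}
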