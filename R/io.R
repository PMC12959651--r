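#' Read protein sequences from FASTA
#'
#' Reads a protein FASTA file into a named character vector of uppercase
#' amino-acid sequences. The identifier is the first whitespace-delimited
#' token of each header line. Coordinates used throughout the package are
#' 1-based positions into these sequences, with closed intervals.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercased sequence per protein id.
#'   An empty file yields an empty vector.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "mklv"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) return(setNames(character(0), character(0)))
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate protein id(s) in FASTA: ", paste(dup, collapse = ", "))
  setNames(toupper(as.character(set)), ids)
}

#' Parse HGVS-p deletion notation
#'
#' Supports only the sequence-retaining deletion forms \code{p.X#del} and
#' \code{p.X#_Y#del} (one- or three-letter residue codes, optional
#' parentheses). Anything else -- frameshifts, insertions, delins,
#' duplications -- is rejected with \code{NA} coordinates, since only
#' deletions that preserve the downstream sequence are modelled.
#'
#' @param x Character vector of HGVS-p strings.
#' @return Data frame with columns \code{start}, \code{end} (1-based, closed;
#'   \code{NA} where the form is unsupported).
#' @examples
#' parse_hgvs_del(c("p.A5del", "p.Ala5_Gly7del", "p.A5fs"))
#' @export
parse_hgvs_del <- function(x) {
  re <- "^p\\.\\(?([A-Za-z]{1,3})(\\d+)(?:_([A-Za-z]{1,3})(\\d+))?del\\)?$"
  m <- regmatches(x, regexec(re, x))
  start <- end <- rep(NA_integer_, length(x))
  for (i in seq_along(m)) {
    if (length(m[[i]]) == 0) next
    start[i] <- as.integer(m[[i]][3])
    end[i] <- if (nzchar(m[[i]][5])) as.integer(m[[i]][5]) else start[i]
  }
  data.frame(start = start, end = end)
}

# Normalise a clinical label string to pathogenic / benign / unlabeled.
normalise_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("pathogenic", "likely pathogenic", "likely_pathogenic", "p", "lp")] <- "pathogenic"
  x[x %in% c("benign", "likely benign", "likely_benign", "neutral", "b", "lb")] <- "benign"
  x[is.na(x) | x == "" | x == "na"] <- "unlabeled"
  bad <- setdiff(unique(x), c("pathogenic", "benign", "unlabeled"))
  if (length(bad)) stop("unrecognised label(s): ", paste(bad, collapse = ", "))
  x
}

#' Read a deletion-variant table
#'
#' Reads protein-level deletion variants from CSV/TSV. Coordinates may be
#' given either as 1-based closed \code{start}/\code{end} columns or as an
#' HGVS-p deletion string (column \code{hgvs}); genomic coordinates are not
#' parsed (pre-map nucleotide variants to protein coordinates upstream, e.g.
#' with TransVar or VEP, and supply the protein-level rows here).
#'
#' Validation rules, applied per record:
#' \itemize{
#'   \item \code{start <= end}, integer coordinates;
#'   \item deletion length \code{end - start + 1} at most 10 residues;
#'   \item \code{start > 1}: a deletion of the initiator residue would remove
#'     the start codon, so first-position deletions are rejected;
#'   \item when \code{proteins} is supplied, \code{end} must lie within the
#'     sequence and a supplied \code{deleted_seq} must match it.
#' }
#' Duplicate records (same \code{protein_id}, \code{start}, \code{end}) are
#' collapsed to one; duplicates carrying conflicting labels are dropped
#' entirely with a warning. Rejected rows are reported in the
#' \code{"rejected"} attribute with row numbers and reason codes.
#'
#' @param path Path to the table.
#' @param format \code{"csv"} or \code{"tsv"}.
#' @param col_map Optional named character vector mapping canonical column
#'   names (\code{protein_id}, \code{start}, \code{end}, \code{hgvs},
#'   \code{deleted_seq}, \code{label}, \code{source}) to the file's columns.
#' @param proteins Optional named sequence vector (see
#'   \code{\link{read_fasta}}) for coordinate/sequence validation.
#' @return A \code{deletion_variants} data frame with columns
#'   \code{protein_id}, \code{start}, \code{end}, \code{deleted_seq},
#'   \code{label}, \code{source}; attribute \code{"rejected"} lists dropped
#'   rows with reasons.
#' @seealso [write_variants()]
#' @export
read_variants <- function(path, format = c("csv", "tsv"), col_map = NULL,
                          proteins = NULL) {
  format <- match.arg(format)
  raw <- if (format == "csv") read.csv(path, stringsAsFactors = FALSE)
         else read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(raw))
        stop("mapped column not found: ", col_map[[canon]])
      names(raw)[names(raw) == col_map[[canon]]] <- canon
    }
  }
  if (!"protein_id" %in% names(raw)) stop("missing column: protein_id")
  n <- nrow(raw)
  if (!all(c("start", "end") %in% names(raw))) {
    if (!"hgvs" %in% names(raw))
      stop("need start/end columns or an hgvs column")
    coords <- parse_hgvs_del(raw$hgvs)
    raw$start <- coords$start
    raw$end <- coords$end
  }
  suppressWarnings({
    raw$start <- as.integer(raw$start)
    raw$end <- as.integer(raw$end)
  })
  raw$label <- if ("label" %in% names(raw)) normalise_label(raw$label) else "unlabeled"
  raw$source <- if ("source" %in% names(raw)) as.character(raw$source) else ""
  raw$deleted_seq <- if ("deleted_seq" %in% names(raw))
    toupper(as.character(raw$deleted_seq)) else NA_character_

  reason <- rep(NA_character_, n)
  bad_coord <- is.na(raw$start) | is.na(raw$end) | raw$start > raw$end | raw$start < 1
  reason[bad_coord] <- "malformed_coordinates"
  len <- raw$end - raw$start + 1L
  reason[is.na(reason) & len > 10] <- "too_long"
  reason[is.na(reason) & raw$start == 1] <- "first_position"
  if (!is.null(proteins)) {
    known <- raw$protein_id %in% names(proteins)
    plen <- rep(NA_integer_, n)
    plen[known] <- nchar(proteins[raw$protein_id[known]])
    out_of_range <- is.na(reason) & known & raw$end > plen
    reason[out_of_range] <- "beyond_protein_end"
    fill <- is.na(reason) & known
    expected <- substr(proteins[raw$protein_id[fill]], raw$start[fill], raw$end[fill])
    mism <- !is.na(raw$deleted_seq[fill]) & raw$deleted_seq[fill] != expected
    reason[which(fill)[mism]] <- "deleted_seq_mismatch"
    fill <- is.na(reason) & known
    raw$deleted_seq[fill] <-
      substr(proteins[raw$protein_id[fill]], raw$start[fill], raw$end[fill])
  }
  rejected <- data.frame(row = which(!is.na(reason)),
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  ok <- raw[is.na(reason), c("protein_id", "start", "end", "deleted_seq",
                             "label", "source"), drop = FALSE]

  # Duplicate collapse on (protein_id, start, end); conflicting labels drop
  # the variant altogether.
  key <- paste(ok$protein_id, ok$start, ok$end, sep = "\r")
  n_lab <- tapply(ok$label, key, function(l) length(unique(l)))
  conflict <- names(n_lab)[n_lab > 1]
  if (length(conflict)) {
    warning(length(conflict), " variant(s) dropped: conflicting labels across duplicate records")
    drop_rows <- which(key %in% conflict)
    rejected <- rbind(rejected, data.frame(row = drop_rows,
                                           reason = "conflicting_labels"))
    ok <- ok[!key %in% conflict, , drop = FALSE]
    key <- key[!key %in% conflict]
  }
  ok <- ok[!duplicated(key), , drop = FALSE]
  ok <- ok[order(ok$protein_id, ok$start, ok$end), , drop = FALSE]
  rownames(ok) <- NULL
  structure(ok, rejected = rejected,
            class = c("deletion_variants", "data.frame"))
}

#' Write a deletion-variant table in the canonical dialect
#'
#' Writes the validated columns as plain CSV (no quoting, no row names) in
#' deterministic (protein, start, end) order, so that
#' \code{write_variants(read_variants(f))} round-trips byte-for-byte.
#'
#' @param variants A \code{deletion_variants} data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_variants <- function(variants, path) {
  cols <- c("protein_id", "start", "end", "deleted_seq", "label", "source")
  out <- as.data.frame(variants)[, cols, drop = FALSE]
  out <- out[order(out$protein_id, out$start, out$end), , drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read annotation-interval tracks
#'
#' Reads a TSV of per-protein annotation intervals (columns
#' \code{protein_id}, \code{category}, \code{start}, \code{end}; 1-based,
#' closed). These stand in for externally computed tracks such as domains,
#' repeats, transmembrane segments, intrinsically disordered regions,
#' last-exon windows, secondary-structure classes or curated SwissProt
#' regions; the category vocabulary is open. Overlapping intervals within a
#' category are kept as-is (overlap flags use their union).
#'
#' @param path Path to the TSV.
#' @param proteins Optional named sequence vector; intervals exceeding a known
#'   protein's length raise an error, intervals on unknown proteins only a
#'   warning.
#' @return An \code{annotation_tracks} data frame.
#' @export
read_annotation_tracks <- function(path, proteins = NULL) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "category", "start", "end")
  if (!all(need %in% names(raw)))
    stop("annotation track file needs columns: ", paste(need, collapse = ", "))
  raw$start <- as.integer(raw$start)
  raw$end <- as.integer(raw$end)
  if (any(is.na(raw$start) | is.na(raw$end) | raw$start < 1 | raw$start > raw$end))
    stop("malformed interval(s) in annotation track file")
  if (!is.null(proteins)) {
    known <- raw$protein_id %in% names(proteins)
    if (any(!known))
      warning("intervals on unknown protein(s): ",
              paste(unique(raw$protein_id[!known]), collapse = ", "))
    over <- known & raw$end > nchar(proteins[raw$protein_id])
    if (any(over))
      stop("interval exceeds protein length for: ",
           paste(unique(raw$protein_id[over]), collapse = ", "))
  }
  raw <- raw[order(raw$protein_id, raw$category, raw$start, raw$end), , drop = FALSE]
  rownames(raw) <- NULL
  structure(raw[, need], class = c("annotation_tracks", "data.frame"))
}

#' Read numeric annotations (per-residue or per-protein)
#'
#' Reads a long-format TSV with columns \code{protein_id}, \code{name},
#' \code{position}, \code{value}. Rows with an empty/NA \code{position} are
#' per-protein scalars (gene-class flags, gene age, ...); rows with a
#' position are per-residue values (conservation, solvent accessibility,
#' substitution pathogenicity, ...). These carry externally computed numbers
#' into the feature builder; the package never recomputes them from primary
#' databases.
#'
#' @param path Path to the TSV.
#' @return A \code{numeric_annotations} data frame.
#' @export
read_numeric_annotations <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "name", "position", "value")
  if (!all(need %in% names(raw)))
    stop("numeric annotation file needs columns: ", paste(need, collapse = ", "))
  raw$position <- suppressWarnings(as.integer(raw$position))
  raw$value <- as.numeric(raw$value)
  if (any(is.na(raw$value))) stop("non-numeric value(s) in numeric annotation file")
  structure(raw[, need], class = c("numeric_annotations", "data.frame"))
}

#' Read a weighted protein-interaction edge list
#'
#' TSV with two node columns (protein ids) and an optional \code{weight}
#' column (e.g. interaction confidences).
#'
#' @param path Path to the TSV.
#' @return Data frame with columns \code{from}, \code{to}, \code{weight}.
#' @export
read_edges <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("edge list needs at least two columns")
  out <- data.frame(from = as.character(raw[[1]]), to = as.character(raw[[2]]),
                    weight = if (ncol(raw) >= 3) as.numeric(raw[[3]]) else 1,
                    stringsAsFactors = FALSE)
  out
}

#' Read amino-acid property scales
#'
#' \code{read_aaindex} parses the standard AAindex1 flat format (records
#' delimited by \code{//}; the two data lines after each \code{I} line hold
#' values for A R N D C Q E G H I and L K M F P S T W Y V). Scales with
#' missing (\code{NA}) values are dropped with a warning, since a property
#' scale must cover all 20 standard residues. \code{read_scale_tsv} reads a
#' simple two-column (amino acid, value) TSV as a single scale.
#'
#' @param path Path to the file.
#' @return For \code{read_aaindex}, a named list of scales (each a named
#'   numeric vector over the 20 amino acids); for \code{read_scale_tsv}, one
#'   such vector.
#' @export
read_aaindex <- function(path) {
  lines <- readLines(path)
  row1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  row2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  scales <- list()
  acc <- NULL
  i <- 1
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "H ")) acc <- trimws(sub("^H ", "", ln))
    if (startsWith(ln, "I ")) {
      v1 <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 1]), "\\s+")[[1]]))
      v2 <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 2]), "\\s+")[[1]]))
      if (length(v1) == 10 && length(v2) == 10 && !is.null(acc)) {
        sc <- setNames(c(v1, v2), c(row1, row2))[AA_STANDARD]
        if (anyNA(sc)) warning("scale ", acc, " dropped: missing values")
        else scales[[acc]] <- sc
      }
      i <- i + 2
    }
    i <- i + 1
  }
  scales
}

#' @rdname read_aaindex
#' @param name Scale name for \code{read_scale_tsv}.
#' @export
read_scale_tsv <- function(path, name = "scale") {
  raw <- read.delim(path, stringsAsFactors = FALSE, header = TRUE)
  sc <- setNames(as.numeric(raw[[2]]), toupper(as.character(raw[[1]])))
  missing <- setdiff(AA_STANDARD, names(sc))
  if (length(missing))
    stop("scale ", name, " missing amino acid(s): ", paste(missing, collapse = ", "))
  sc[AA_STANDARD]
}
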