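#' Fixed-length sequence segments around a deletion
#'
#' Extracts, per variant, three segments of exactly \code{pad_len} characters:
#' the deleted stretch (trimmed from the front if longer, right-padded with
#' \code{X} if shorter), the upstream flank (the residues immediately
#' N-terminal, left-padded on the distal side) and the downstream flank
#' (right-padded). These fixed-length strings are carried as sequence inputs
#' for sequence-aware models and bypass the numeric feature filters.
#'
#' @param variants A \code{deletion_variants} data frame.
#' @param proteins Named sequence vector.
#' @param pad_len Segment length (default 5).
#' @return Data frame with character columns \code{seg_deletion},
#'   \code{seg_upstream}, \code{seg_downstream}.
#' @examples
#' v <- data.frame(protein_id = "P1", start = 5, end = 6)
#' extract_segments(v, c(P1 = "MKLVNAQWERTY"))
#' @export
extract_segments <- function(variants, proteins, pad_len = 5) {
  v <- as.data.frame(variants)
  pad <- strrep("X", pad_len)
  up <- dn <- del <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    seq <- proteins[[v$protein_id[i]]]
    L <- nchar(seq)
    s <- v$start[i]; e <- v$end[i]
    u <- substr(seq, max(1, s - pad_len), s - 1)
    up[i] <- substr(paste0(pad, u), nchar(u) + 1, nchar(u) + pad_len)
    d <- substr(seq, e + 1, min(L, e + pad_len))
    dn[i] <- substr(paste0(d, pad), 1, pad_len)
    dl <- substr(seq, s, min(e, s + pad_len - 1))
    del[i] <- substr(paste0(dl, pad), 1, pad_len)
  }
  data.frame(seg_deletion = del, seg_upstream = up, seg_downstream = dn,
             stringsAsFactors = FALSE)
}

#' Average property of the deleted residues
#'
#' Arithmetic mean of a per-amino-acid property scale over the deleted
#' residues. Non-standard residues (X) are excluded from both numerator and
#' denominator; a deletion consisting only of non-standard residues yields
#' \code{NA} (feature unavailable).
#'
#' @param variants A \code{deletion_variants} data frame (with
#'   \code{deleted_seq} filled, or \code{proteins} supplied).
#' @param proteins Optional named sequence vector used to fill missing
#'   \code{deleted_seq}.
#' @param scale Named numeric vector over the 20 standard amino acids.
#' @return Numeric vector of means.
#' @export
content_average <- function(variants, proteins = NULL, scale) {
  v <- as.data.frame(variants)
  seqs <- v$deleted_seq
  if ((is.null(seqs) || anyNA(seqs)) && !is.null(proteins))
    seqs <- substr(proteins[v$protein_id], v$start, v$end)
  vapply(seqs, function(s) {
    aa <- strsplit(s, "")[[1]]
    aa <- aa[aa %in% AA_STANDARD]
    if (length(aa) == 0) NA_real_ else mean(scale[aa])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Positional descriptors of a deletion
#'
#' Length (\code{end - start + 1}), relative position (deletion midpoint
#' divided by protein length) and closest distance to a protein terminus
#' (\code{min(start - 1, L - end)}; 0 when the deletion touches the last
#' residue).
#'
#' @param variants A \code{deletion_variants} data frame.
#' @param proteins Named sequence vector.
#' @return Data frame with columns \code{pos_length},
#'   \code{pos_relative}, \code{pos_dist_terminus}, \code{pos_protein_length}.
#' @export
position_features <- function(variants, proteins) {
  v <- as.data.frame(variants)
  L <- nchar(proteins[v$protein_id])
  data.frame(
    pos_length = v$end - v$start + 1,
    pos_relative = ((v$start + v$end) / 2) / L,
    pos_dist_terminus = pmin(v$start - 1, L - v$end),
    pos_protein_length = as.numeric(L)
  )
}

#' Overlap flags between deletions and annotation categories
#'
#' For every annotation category present in \code{tracks} (or the explicit
#' \code{categories}), flags whether the deletion interval \code{[start,end]}
#' intersects any interval of that category on the same protein. Intervals
#' are 1-based and closed; adjacency is not overlap. Categories absent for a
#' protein give 0.
#'
#' @param variants A \code{deletion_variants} data frame.
#' @param tracks An \code{annotation_tracks} data frame.
#' @param categories Optional character vector fixing the flag set (and
#'   order).
#' @return Integer 0/1 matrix, one column per category.
#' @export
overlap_flags <- function(variants, tracks, categories = NULL) {
  v <- as.data.frame(variants)
  tr <- as.data.frame(tracks)
  if (is.null(categories)) categories <- sort(unique(tr$category))
  out <- matrix(0L, nrow = nrow(v), ncol = length(categories),
                dimnames = list(NULL, categories))
  if (nrow(tr) == 0 || length(categories) == 0) return(out)
  idx <- split(seq_len(nrow(tr)), paste(tr$protein_id, tr$category, sep = "\r"))
  for (i in seq_len(nrow(v))) {
    for (cat in categories) {
      rows <- idx[[paste(v$protein_id[i], cat, sep = "\r")]]
      if (is.null(rows)) next
      if (any(tr$start[rows] <= v$end[i] & tr$end[rows] >= v$start[i]))
        out[i, cat] <- 1L
    }
  }
  out
}

#' Find palindromic stretches in a protein sequence
#'
#' Returns the maximal substrings that read identically in both directions
#' (\code{s == reverse(s)}) and have length at least \code{min_len}, as
#' 1-based closed intervals. "Maximal" means not contained in a longer
#' palindromic substring. Implemented by centre expansion (odd and even
#' centres) followed by a containment filter.
#'
#' @param sequence A single sequence string.
#' @param min_len Minimum palindrome length (>= 2; default 5).
#' @return Data frame with columns \code{start}, \code{end}, ordered by
#'   start.
#' @examples
#' find_palindromes("MKAQAKM", min_len = 5)
#' @export
find_palindromes <- function(sequence, min_len = 5) {
  stopifnot(min_len >= 2)
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  if (n < min_len) return(data.frame(start = integer(0), end = integer(0)))
  ivs <- list()
  expand <- function(l, r) {
    while (l - 1 >= 1 && r + 1 <= n && s[l - 1] == s[r + 1]) {
      l <- l - 1; r <- r + 1
    }
    c(l, r)
  }
  for (i in seq_len(n)) ivs[[length(ivs) + 1]] <- expand(i, i)
  for (i in seq_len(n - 1)) if (s[i] == s[i + 1]) ivs[[length(ivs) + 1]] <- expand(i, i + 1)
  m <- unique(do.call(rbind, ivs))
  m <- m[m[, 2] - m[, 1] + 1 >= min_len, , drop = FALSE]
  if (nrow(m) == 0) return(data.frame(start = integer(0), end = integer(0)))
  keep <- vapply(seq_len(nrow(m)), function(i) {
    !any(m[, 1] <= m[i, 1] & m[, 2] >= m[i, 2] &
           (m[, 1] < m[i, 1] | m[, 2] > m[i, 2]))
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

#' Protein-interaction network centralities
#'
#' Computes six per-node centrality metrics on an undirected interaction
#' graph: degree, closeness (normalised, restricted to each node's reachable
#' component), betweenness, harmonic centrality (normalised), hub score
#' (principal-eigenvector HITS score, scaled to maximum 1) and Bonacich power
#' centrality with
#' attenuation \code{0.9 / lambda_max} (just inside the convergence radius of
#' the adjacency spectrum). Edge weights are ignored for the path-based
#' metrics; interaction confidences are similarities, not distances.
#' Isolated nodes get closeness and harmonic centrality 0 by convention.
#'
#' @param edges Data frame with columns \code{from}, \code{to} (and
#'   optionally \code{weight}, unused).
#' @param nodes Optional character vector of node ids to include even when
#'   isolated.
#' @return Data frame with columns \code{node}, \code{ppi_degree},
#'   \code{ppi_closeness}, \code{ppi_betweenness}, \code{ppi_harmonic},
#'   \code{ppi_hub}, \code{ppi_power}.
#' @export
network_centralities <- function(edges, nodes = NULL) {
  verts <- unique(c(as.character(edges$from), as.character(edges$to), nodes))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to)),
    directed = FALSE, vertices = data.frame(name = verts))
  g <- igraph::simplify(g)
  deg <- igraph::degree(g)
  clo <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  clo[!is.finite(clo)] <- 0
  btw <- igraph::betweenness(g, weights = NA)
  har <- igraph::harmonic_centrality(g, normalized = TRUE)
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  if (nrow(adj) > 0 && any(adj > 0)) {
    # dense symmetric eigendecomposition: deterministic, exact principal
    # vector (iterative HITS solvers wobble at ~1e-5)
    es <- eigen(adj, symmetric = TRUE)
    lam <- max(es$values)
    hub <- abs(es$vectors[, which.max(es$values)])
    hub <- setNames(hub / max(hub), rownames(adj))
  } else {
    lam <- 0
    hub <- setNames(rep(0, length(verts)), verts)
  }
  pow <- if (lam > 0)
    igraph::power_centrality(g, exponent = 0.9 / lam, rescale = FALSE)
  else setNames(rep(0, length(verts)), verts)
  data.frame(node = verts,
             ppi_degree = as.numeric(deg[verts]),
             ppi_closeness = as.numeric(clo[verts]),
             ppi_betweenness = as.numeric(btw[verts]),
             ppi_harmonic = as.numeric(har[verts]),
             ppi_hub = as.numeric(hub[verts]),
             ppi_power = as.numeric(pow[verts]),
             stringsAsFactors = FALSE)
}

#' Assemble the feature table for a set of deletion variants
#'
#' Builds one row per variant from four feature categories:
#' \describe{
#'   \item{context}{logo bit-score sums around the deletion boundary (see
#'     \code{\link{context_bitscores}}; requires \code{logos}) and the three
#'     fixed-length sequence segments (registered with type
#'     \code{"sequence"}; they are carried for sequence-aware models and are
#'     excluded from numeric-learner input and from filtering).}
#'   \item{content}{averages of each supplied property scale over the
#'     deleted residues, plus means of any per-residue numeric annotations
#'     (conservation, solvent accessibility, substitution pathogenicity,
#'     ...).}
#'   \item{position}{deletion length, relative position, distance to the
#'     nearest terminus, protein length, and 0/1 overlap flags for every
#'     annotation-track category; a \code{palindrome} track is computed from
#'     the sequences themselves.}
#'   \item{gene}{per-protein scalar annotations (gene-class flags, gene age,
#'     ...) and six interaction-network centralities when an edge list is
#'     given.}
#' }
#'
#' Rows with any unavailable feature (missing provider annotation, protein
#' absent from the interaction graph, all-X deletion) are excluded from the
#' returned table and reported -- with the reason -- in the
#' \code{"excluded"} attribute, mirroring a "prediction not possible" note.
#' The output is deterministic and independent of variant order up to row
#' order. The feature registry (name, category, type) is stored in the
#' \code{"registry"} attribute and drives downstream filtering.
#'
#' @param variants A \code{deletion_variants} data frame.
#' @param proteins Named sequence vector.
#' @param logos Optional list of \code{benign}/\code{pathogenic}
#'   \code{position_logo}s built on training data only.
#' @param scales Optional named list of property scales.
#' @param tracks Optional \code{annotation_tracks} data frame.
#' @param numeric_annotations Optional \code{numeric_annotations} data frame.
#' @param edges Optional interaction edge list.
#' @param include_segments Carry the sequence segments (default TRUE).
#' @param include_ctx_diff Include the signed context-difference feature.
#' @param palindrome_min_len Minimum palindrome length for the computed
#'   palindrome track.
#' @return A \code{feature_table} data frame: \code{variant_id},
#'   \code{protein_id}, \code{label}, then features; attributes
#'   \code{"registry"} and \code{"excluded"}.
#' @export
featurize <- function(variants, proteins, logos = NULL, scales = NULL,
                      tracks = NULL, numeric_annotations = NULL, edges = NULL,
                      include_segments = TRUE, include_ctx_diff = TRUE,
                      palindrome_min_len = 5) {
  v <- as.data.frame(variants)
  v <- v[order(v$protein_id, v$start, v$end), , drop = FALSE]
  unknown <- setdiff(unique(v$protein_id), names(proteins))
  if (length(unknown)) stop("unknown protein(s): ", paste(unknown, collapse = ", "))
  id <- paste(v$protein_id, v$start, v$end, sep = ":")
  n <- nrow(v)
  feats <- list()
  registry <- data.frame(name = character(0), category = character(0),
                         type = character(0), stringsAsFactors = FALSE)
  reg <- function(names, category, type)
    rbind(registry, data.frame(name = names, category = category, type = type,
                               stringsAsFactors = FALSE))

  # context
  if (!is.null(logos)) {
    ctx <- context_bitscores(v, proteins, logos, include_diff = include_ctx_diff)
    feats$ctx <- as.data.frame(ctx)
    registry <- reg(colnames(ctx), "context", "numeric")
  }
  if (include_segments) {
    segs <- extract_segments(v, proteins)
    feats$segs <- segs
    registry <- reg(names(segs), "context", "sequence")
  }

  # content
  if (!is.null(scales) && length(scales)) {
    sc <- vapply(scales, function(s) content_average(v, proteins, s),
                 numeric(n))
    sc <- matrix(sc, nrow = n,
                 dimnames = list(NULL, paste0("content_", names(scales))))
    feats$scales <- as.data.frame(sc)
    registry <- reg(colnames(sc), "content", "numeric")
  }
  residue_names <- character(0)
  scalar_names <- character(0)
  if (!is.null(numeric_annotations) && nrow(numeric_annotations)) {
    na_df <- as.data.frame(numeric_annotations)
    per_res <- na_df[!is.na(na_df$position), , drop = FALSE]
    per_prot <- na_df[is.na(na_df$position), , drop = FALSE]
    if (nrow(per_res)) {
      residue_names <- sort(unique(per_res$name))
      vals <- matrix(NA_real_, nrow = n, ncol = length(residue_names),
                     dimnames = list(NULL, paste0("content_", residue_names)))
      keyed <- split(per_res[, c("position", "value")],
                     paste(per_res$protein_id, per_res$name, sep = "\r"))
      for (j in seq_along(residue_names)) {
        for (i in seq_len(n)) {
          rec <- keyed[[paste(v$protein_id[i], residue_names[j], sep = "\r")]]
          if (is.null(rec)) next
          vv <- rec$value[match(v$start[i]:v$end[i], rec$position)]
          if (!anyNA(vv)) vals[i, j] <- mean(vv)
        }
      }
      feats$residue <- as.data.frame(vals)
      registry <- reg(colnames(vals), "content", "numeric")
    }
    if (nrow(per_prot)) {
      scalar_names <- sort(unique(per_prot$name))
      vals <- matrix(NA_real_, nrow = n, ncol = length(scalar_names),
                     dimnames = list(NULL, paste0("gene_", scalar_names)))
      key <- paste(per_prot$protein_id, per_prot$name, sep = "\r")
      for (j in seq_along(scalar_names)) {
        idx <- match(paste(v$protein_id, scalar_names[j], sep = "\r"), key)
        vals[, j] <- per_prot$value[idx]
      }
      feats$scalar <- as.data.frame(vals)
      is_bin <- apply(vals, 2, function(x) all(x %in% c(0, 1) | is.na(x)))
      registry <- reg(colnames(vals), "gene",
                      ifelse(is_bin, "binary", "numeric"))
    }
  }

  # position
  pos <- position_features(v, proteins)
  feats$pos <- pos
  registry <- reg(names(pos), "position", "numeric")
  pal <- do.call(rbind, lapply(names(proteins), function(p) {
    iv <- find_palindromes(proteins[[p]], min_len = palindrome_min_len)
    if (nrow(iv) == 0) return(NULL)
    data.frame(protein_id = p, category = "palindrome",
               start = iv$start, end = iv$end, stringsAsFactors = FALSE)
  }))
  tr <- if (!is.null(tracks)) rbind(as.data.frame(tracks)[, c("protein_id", "category", "start", "end")], pal)
        else pal
  if (!is.null(tr) && nrow(tr)) {
    ov <- overlap_flags(v, tr)
    colnames(ov) <- paste0("ovl_", colnames(ov))
    feats$ovl <- as.data.frame(ov)
    registry <- reg(colnames(ov), "position", "binary")
  }

  # gene: network centralities
  if (!is.null(edges)) {
    cent <- network_centralities(edges)
    m <- match(v$protein_id, cent$node)
    cc <- cent[m, -1, drop = FALSE]
    rownames(cc) <- NULL
    feats$ppi <- cc
    registry <- reg(names(cc), "gene", "numeric")
  }

  tab <- do.call(cbind, unname(feats))
  # category-then-name order within each category block, categories in the
  # canonical order context, content, position, gene
  cat_order <- c(context = 1, content = 2, position = 3, gene = 4)
  ord <- order(cat_order[registry$category], registry$name)
  registry <- registry[ord, , drop = FALSE]
  rownames(registry) <- NULL
  tab <- tab[, registry$name, drop = FALSE]

  numeric_cols <- registry$name[registry$type != "sequence"]
  bad <- !stats::complete.cases(tab[, numeric_cols, drop = FALSE])
  excluded <- data.frame(variant_id = character(0), reason = character(0))
  if (any(bad)) {
    reason <- vapply(which(bad), function(i) {
      miss <- numeric_cols[is.na(as.numeric(tab[i, numeric_cols]))]
      paste0("prediction not possible: missing ", paste(miss, collapse = ","))
    }, character(1))
    excluded <- data.frame(variant_id = id[bad], reason = reason,
                           stringsAsFactors = FALSE)
  }
  out <- cbind(data.frame(variant_id = id, protein_id = v$protein_id,
                          label = v$label, stringsAsFactors = FALSE), tab)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, registry = registry, excluded = excluded,
            class = c("feature_table", "data.frame"))
}

#' Feature registry of a feature table
#'
#' Returns the (name, category, type) registry attached by
#' \code{\link{featurize}} or \code{\link{simulate_feature_table}}; when
#' absent it is inferred (character columns are \code{sequence}, 0/1 columns
#' \code{binary}, the rest \code{numeric}; id/label columns are skipped).
#'
#' @param table A feature table.
#' @return Data frame with columns \code{name}, \code{category}, \code{type}.
#' @export
feature_registry <- function(table) {
  regi <- attr(table, "registry")
  meta <- c("variant_id", "protein_id", "label")
  cols <- setdiff(names(table), meta)
  if (!is.null(regi)) return(regi[regi$name %in% cols, , drop = FALSE])
  type <- vapply(cols, function(nm) {
    x <- table[[nm]]
    if (is.character(x) || is.factor(x)) "sequence"
    else if (all(x %in% c(0, 1))) "binary" else "numeric"
  }, character(1))
  data.frame(name = cols, category = "content", type = type,
             stringsAsFactors = FALSE)
}

# Numeric model-input columns (numeric + binary; never sequence/meta).
model_feature_names <- function(table) {
  regi <- feature_registry(table)
  regi$name[regi$type %in% c("numeric", "binary")]
}
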