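#' Simulation configuration
#'
#' Defaults emulate the statistical shape of curated short-deletion
#' datasets: about 57.7% pathogenic variants, class-conditional deletion
#' lengths with means 2.71 (pathogenic) and 4.11 (benign) residues -- both
#' classes mode at length 1 -- drawn from a geometric distribution truncated
#' at 10, and roughly 2 variants per protein. \code{effect} scales how
#' strongly pathogenic deletions prefer domains and conserved/buried
#' positions while benign ones prefer termini and disordered regions;
#' \code{effect = 0} makes placement class-independent.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Protein length range (residues).
#' @param n_variants Number of labeled deletions.
#' @param pathogenic_fraction Fraction of pathogenic variants.
#' @param pathogenic_mean_length,benign_mean_length Target mean deletion
#'   lengths (clipped to [1, 10]).
#' @param effect Class-separation strength for variant placement and
#'   annotation signal.
#' @param domain_coverage Fraction of each protein covered by domain
#'   intervals.
#' @param seed Seed for all randomness.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_proteins = 500, length_range = c(100, 800),
                       n_variants = 2000, pathogenic_fraction = 0.577,
                       pathogenic_mean_length = 2.71,
                       benign_mean_length = 4.11, effect = 1,
                       domain_coverage = 0.4, seed = 1) {
  stopifnot(pathogenic_fraction > 0, pathogenic_fraction < 1,
            length_range[1] >= 30, n_proteins >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# Geometric success parameter q for a 1..10 truncated geometric with the
# requested mean; mode is always at 1.
trunc_geom_q <- function(target_mean) {
  target_mean <- min(max(target_mean, 1), 10)
  if (target_mean <= 1 + 1e-9) return(1e-9)
  uniroot(function(q) {
    k <- 1:10; w <- q^(k - 1)
    sum(k * w) / sum(w) - target_mean
  }, c(1e-9, 1 - 1e-9))$root
}

sample_trunc_geom <- function(n, target_mean) {
  q <- trunc_geom_q(target_mean)
  k <- 1:10
  sample(k, n, replace = TRUE, prob = q^(k - 1))
}

SS_CLASSES <- c("ss_alpha", "ss_beta", "ss_Bbeta", "ss_bbeta", "ss_turncoil",
                "ss_Ghelix", "ss_pihelix", "ss_lowconf")

#' Simulate a proteome with annotations
#'
#' Generates random protein sequences (Swiss-Prot-like residue composition)
#' together with the annotation layers the feature builder consumes: domain
#' intervals covering about \code{domain_coverage} of each protein,
#' terminus-biased intrinsically disordered regions, occasional repeat and
#' transmembrane intervals, a last-exon window, an eight-class secondary
#' structure partition (low-confidence segments co-locating with disorder),
#' per-residue conservation / solvent accessibility / substitution
#' pathogenicity correlated with domain membership, per-gene class flags and
#' gene age, and a sparse random interaction network. Identical seeds give
#' byte-identical output.
#'
#' @param config A \code{sim_config}.
#' @return A \code{sim_proteome}: list with \code{proteins} (named sequence
#'   vector), \code{tracks}, \code{numeric_annotations}, \code{edges},
#'   \code{config}.
#' @export
simulate_proteome <- function(config = sim_config()) {
  cf <- config
  with_seed(cf$seed, {
    n <- cf$n_proteins
    ids <- sprintf("SIM%04d", seq_len(n))
    lens <- if (n) sample(cf$length_range[1]:cf$length_range[2], n, replace = TRUE) else integer(0)
    proteins <- setNames(vapply(lens, function(L)
      paste(sample(names(AA_BACKGROUND), L, replace = TRUE,
                   prob = AA_BACKGROUND), collapse = ""), character(1)), ids)
    tracks <- list()
    numeric_rows <- list()
    add_track <- function(p, cat, s, e)
      tracks[[length(tracks) + 1]] <<- data.frame(
        protein_id = p, category = cat, start = as.integer(s),
        end = as.integer(e), stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      L <- lens[i]; p <- ids[i]
      in_domain <- logical(L); in_idr <- logical(L)
      covered <- 0
      while (covered < cf$domain_coverage * L) {
        w <- sample(40:120, 1)
        # trim toward the remaining need so realised coverage stays close to
        # the configured fraction
        w <- min(w, max(15, ceiling(cf$domain_coverage * L - covered)))
        s <- sample(seq_len(max(1, L - w)), 1); e <- min(L, s + w - 1)
        add_track(p, "domain", s, e)
        in_domain[s:e] <- TRUE
        covered <- sum(in_domain)
      }
      # disorder: biased to termini
      for (side in c("N", "C")) {
        if (runif(1) < 0.6) {
          w <- sample(15:60, 1)
          if (side == "N") { s <- 1; e <- min(L, w) } else { s <- max(1, L - w + 1); e <- L }
          add_track(p, "idr", s, e); in_idr[s:e] <- TRUE
        }
      }
      if (runif(1) < 0.3) {
        w <- sample(10:40, 1); s <- sample(seq_len(max(1, L - w)), 1)
        add_track(p, "repeat", s, min(L, s + w - 1))
      }
      if (runif(1) < 0.2) {
        for (k in seq_len(sample(1:5, 1))) {
          s <- sample(seq_len(max(1, L - 21)), 1)
          add_track(p, "tm", s, min(L, s + 20))
        }
      }
      add_track(p, "last_exon", max(1, ceiling(0.9 * L) - 17), L)
      # secondary-structure partition
      pos <- 1
      while (pos <= L) {
        w <- sample(5:30, 1); e <- min(L, pos + w - 1)
        cls <- if (any(in_idr[pos:e]) && runif(1) < 0.7) "ss_lowconf"
               else sample(SS_CLASSES, 1, prob = c(30, 20, 2, 2, 30, 5, 1, 10))
        add_track(p, cls, pos, e)
        pos <- e + 1
      }
      cons <- 1.5 + cf$effect * in_domain + rnorm(L, 0, 0.5)
      sasa <- pmax(0, 60 - 25 * in_domain + rnorm(L, 0, 15))
      subst <- pmin(1, pmax(0, stats::plogis(cons - 2) + rnorm(L, 0, 0.1)))
      numeric_rows[[length(numeric_rows) + 1]] <- data.frame(
        protein_id = p,
        name = rep(c("conservation", "sasa", "subst_pathogenicity"), each = L),
        position = rep(seq_len(L), 3),
        value = c(cons, sasa, subst), stringsAsFactors = FALSE)
      flags <- rbinom(6, 1, c(0.15, 0.10, 0.15, 0.10, 0.03, 0.20))
      numeric_rows[[length(numeric_rows) + 1]] <- data.frame(
        protein_id = p,
        name = c("housekeeping", "haploinsufficient", "essential",
                 "redundant", "pseudogene", "duplicated", "gene_age"),
        position = NA_integer_,
        value = c(flags, sample(c(50, 100, 200, 400, 800, 1600), 1)),
        stringsAsFactors = FALSE)
    }
    n_edges <- 2 * n
    edges <- if (n >= 2) {
      from <- sample(ids, n_edges, replace = TRUE)
      to <- sample(ids, n_edges, replace = TRUE)
      keep <- from != to
      data.frame(from = from[keep], to = to[keep],
                 weight = round(runif(sum(keep), 0.4, 1), 3),
                 stringsAsFactors = FALSE)
    } else data.frame(from = character(0), to = character(0), weight = numeric(0))
    structure(list(
      proteins = proteins,
      tracks = structure(do.call(rbind, tracks) %||%
                           data.frame(protein_id = character(0), category = character(0),
                                      start = integer(0), end = integer(0)),
                         class = c("annotation_tracks", "data.frame")),
      numeric_annotations = structure(do.call(rbind, numeric_rows) %||%
                                        data.frame(protein_id = character(0), name = character(0),
                                                   position = integer(0), value = numeric(0)),
                                      class = c("numeric_annotations", "data.frame")),
      edges = edges,
      config = cf), class = "sim_proteome")
  })
}

#' Simulate labeled deletion variants over a simulated proteome
#'
#' Draws deletions with class-conditional truncated-geometric lengths
#' (configured means, mode at 1, maximum 10) and class-dependent placement:
#' with positive \code{effect}, pathogenic deletions concentrate in domains
#' and conserved positions while benign ones favour protein termini and
#' disordered regions; with \code{effect = 0} placement is
#' class-independent. No deletion starts at position 1 (removing the
#' initiator residue would abolish translation) and duplicates are
#' resampled away.
#'
#' @param proteome A \code{sim_proteome}.
#' @param config Defaults to the proteome's config.
#' @return A \code{deletion_variants} data frame with \code{deleted_seq}
#'   filled and \code{source = "simulated"}.
#' @export
simulate_variants <- function(proteome, config = proteome$config) {
  cf <- config
  prot <- proteome$proteins
  lens <- nchar(prot)
  tr <- as.data.frame(proteome$tracks)
  dom <- tr[tr$category == "domain", ]
  idr <- tr[tr$category == "idr", ]
  mark <- function(iv, L) {
    m <- logical(L)
    for (r in seq_len(nrow(iv))) m[iv$start[r]:iv$end[r]] <- TRUE
    m
  }
  with_seed(cf$seed + 1, {
    weights <- lapply(names(prot), function(p) {
      L <- lens[[p]]
      ind <- mark(dom[dom$protein_id == p, ], L)
      idi <- mark(idr[idr$protein_id == p, ], L)
      term <- pmax(0, 1 - pmin(seq_len(L) - 1, L - seq_len(L)) / 50)
      list(path = exp(cf$effect * (1.0 * ind)),
           ben = exp(cf$effect * (1.0 * idi + 1.0 * term - 1.0 * ind)))
    })
    names(weights) <- names(prot)
    seen <- character(0)
    rows <- vector("list", cf$n_variants)
    k <- 0; tries <- 0
    while (k < cf$n_variants && tries < 50 * cf$n_variants) {
      tries <- tries + 1
      p <- sample(names(prot), 1, prob = lens)
      lab <- if (runif(1) < cf$pathogenic_fraction) "pathogenic" else "benign"
      dl <- sample_trunc_geom(1, if (lab == "pathogenic") cf$pathogenic_mean_length
                                 else cf$benign_mean_length)
      L <- lens[[p]]
      if (L < dl + 2) next
      w <- if (lab == "pathogenic") weights[[p]]$path else weights[[p]]$ben
      starts <- 2:(L - dl + 1)
      s <- sample(starts, 1, prob = w[starts])
      key <- paste(p, s, s + dl - 1)
      if (key %in% seen) next
      seen <- c(seen, key)
      k <- k + 1
      rows[[k]] <- data.frame(protein_id = p, start = s, end = s + dl - 1,
                              deleted_seq = substr(prot[[p]], s, s + dl - 1),
                              label = lab, source = "simulated",
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows[seq_len(k)])
    out <- out[order(out$protein_id, out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
    structure(out, rejected = data.frame(row = integer(0), reason = character(0)),
              class = c("deletion_variants", "data.frame"))
  })
}

#' Write a simulated proteome in the package's file dialects
#'
#' Writes \code{proteins.fasta}, \code{tracks.tsv}, \code{numeric.tsv} and
#' \code{edges.tsv} into a directory, in exactly the formats the
#' corresponding readers accept (round-trip guarantee).
#'
#' @param proteome A \code{sim_proteome}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_proteome <- function(proteome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(paste0(">", names(proteome$proteins), "\n", proteome$proteins),
             file.path(dir, "proteins.fasta"))
  write.table(proteome$tracks, file.path(dir, "tracks.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(proteome$numeric_annotations, file.path(dir, "numeric.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(proteome$edges, file.path(dir, "edges.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Simulate a labeled feature table directly
#'
#' Bypasses sequence simulation and produces a ready feature table for
#' exercising the filtering and training stages: \code{n_informative}
#' numeric features whose class means differ by \code{effect} standard
#' deviations (alternating sign), the rest class-independent noise, plus
#' optional planted pathologies for filter tests -- redundant columns
#' (monotone transforms of earlier columns), constant columns, rare binary
#' columns and ordinary balanced binary columns. Rows are grouped into
#' proteins (all variants of a protein share its class) so protein-disjoint
#' splitting behaves as it does on real data.
#'
#' @param n_rows Number of variants.
#' @param n_features Number of base numeric features.
#' @param n_informative How many of them separate the classes.
#' @param effect Class-mean separation in standard deviations.
#' @param pathogenic_fraction Fraction of pathogenic rows.
#' @param n_proteins Number of proteins (default about n_rows / 8).
#' @param n_binary Balanced binary features (kept by the filter).
#' @param n_redundant Planted monotone-transform duplicates.
#' @param n_constant Planted constant columns.
#' @param n_rare_binary Planted binary columns with 5 positive rows.
#' @param seed Seed.
#' @return A \code{feature_table} with attributes \code{registry} and
#'   \code{informative}.
#' @export
simulate_feature_table <- function(n_rows = 1000, n_features = 50,
                                   n_informative = 5, effect = 1,
                                   pathogenic_fraction = 0.577,
                                   n_proteins = NULL, n_binary = 0,
                                   n_redundant = 0, n_constant = 0,
                                   n_rare_binary = 0, seed = 1) {
  stopifnot(n_informative <= n_features)
  n_proteins <- n_proteins %||% max(20, round(n_rows / 8))
  with_seed(seed, {
    prot_ids <- sprintf("SP%04d", seq_len(n_proteins))
    prot_class <- ifelse(runif(n_proteins) < pathogenic_fraction,
                         "pathogenic", "benign")
    if (length(unique(prot_class)) < 2)
      prot_class[1:2] <- c("pathogenic", "benign")
    row_prot <- sample(n_proteins, n_rows, replace = TRUE)
    label <- prot_class[row_prot]
    y <- as.integer(label == "pathogenic")
    num_names <- sprintf("f%03d", seq_len(n_features))
    x <- matrix(rnorm(n_rows * n_features), n_rows, n_features,
                dimnames = list(NULL, num_names))
    informative <- num_names[seq_len(n_informative)]
    for (j in seq_len(n_informative)) {
      sgn <- if (j %% 2 == 1) 1 else -1
      x[, j] <- x[, j] + sgn * effect * y
    }
    cols <- as.data.frame(x)
    registry <- data.frame(name = num_names, category = "content",
                           type = "numeric", stringsAsFactors = FALSE)
    if (n_binary > 0) {
      bn <- sprintf("bin%02d", seq_len(n_binary))
      for (nm in bn) cols[[nm]] <- rbinom(n_rows, 1, 0.3)
      registry <- rbind(registry, data.frame(name = bn, category = "gene",
                                             type = "binary"))
    }
    if (n_redundant > 0) {
      rn <- sprintf("dup%03d", seq_len(n_redundant))
      tf <- list(function(v) v^3, function(v) exp(v / 2),
                 function(v) 2 * v + 1, function(v) -v)
      for (j in seq_len(n_redundant)) {
        base <- num_names[(j - 1) %% n_features + 1]
        cols[[rn[j]]] <- tf[[(j - 1) %% 4 + 1]](cols[[base]])
      }
      registry <- rbind(registry, data.frame(name = rn, category = "content",
                                             type = "numeric"))
    }
    if (n_constant > 0) {
      cn <- sprintf("const%02d", seq_len(n_constant))
      for (nm in cn) cols[[nm]] <- 1
      registry <- rbind(registry, data.frame(name = cn, category = "content",
                                             type = "numeric"))
    }
    if (n_rare_binary > 0) {
      qn <- sprintf("rare%02d", seq_len(n_rare_binary))
      for (nm in qn) {
        v <- integer(n_rows)
        v[sample(n_rows, min(5, n_rows))] <- 1L
        cols[[nm]] <- v
      }
      registry <- rbind(registry, data.frame(name = qn, category = "gene",
                                             type = "binary"))
    }
    out <- cbind(data.frame(variant_id = sprintf("v%05d", seq_len(n_rows)),
                            protein_id = prot_ids[row_prot], label = label,
                            stringsAsFactors = FALSE), cols)
    structure(out, registry = registry, informative = informative,
              excluded = data.frame(variant_id = character(0), reason = character(0)),
              class = c("feature_table", "data.frame"))
  })
}
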