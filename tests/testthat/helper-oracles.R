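# Brute-force oracles, kept deliberately naive and independent of the
# package's implementations.

# All maximal palindromic substrings >= min_len: O(n^3) check of every
# substring, then discard intervals strictly contained in another hit.
oracle_palindromes <- function(sequence, min_len) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  hits <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (j - i + 1 < min_len) next
    sub <- s[i:j]
    if (all(sub == rev(sub))) hits[[length(hits) + 1]] <- c(i, j)
  }
  if (!length(hits)) return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, hits)
  keep <- vapply(seq_len(nrow(m)), function(k)
    !any(m[, 1] <= m[k, 1] & m[, 2] >= m[k, 2] &
           (m[, 1] < m[k, 1] | m[, 2] > m[k, 2])), logical(1))
  m <- m[keep, , drop = FALSE]
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

# Interval intersection by scanning every (variant, interval) pair.
oracle_overlap <- function(variants, tracks, categories) {
  out <- matrix(0L, nrow(variants), length(categories),
                dimnames = list(NULL, categories))
  for (i in seq_len(nrow(variants))) for (r in seq_len(nrow(tracks))) {
    if (tracks$protein_id[r] != variants$protein_id[i]) next
    lo <- max(variants$start[i], tracks$start[r])
    hi <- min(variants$end[i], tracks$end[r])
    if (lo <= hi && tracks$category[r] %in% categories)
      out[i, tracks$category[r]] <- 1L
  }
  out
}

# AUC by exhaustive pair counting with half-credit ties.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == "pathogenic"]
  neg <- scores[labels == "benign"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Shortest-path machinery on a tiny adjacency matrix: enumerate every simple
# path between each ordered pair by depth-first search.
oracle_all_paths <- function(adj, s, t) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    for (w in seq_len(n))
      if (adj[v, w] == 1 && !(w %in% path)) walk(c(path, w))
  }
  walk(s)
  paths
}

oracle_centralities <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  nsp <- matrix(0, n, n); diag(nsp) <- 1   # number of shortest paths
  through <- array(0, c(n, n, n))           # shortest paths via k (interior)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- oracle_all_paths(adj, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1)) - 1
    d[s, t] <- min(lens)
    sp <- paths[lens == min(lens)]
    nsp[s, t] <- length(sp)
    for (p in sp) for (k in setdiff(p, c(s, t)))
      through[s, t, k] <- through[s, t, k] + 1
  }
  degree <- rowSums(adj)
  # normalised closeness on a connected graph: (n-1) / sum of distances
  closeness <- vapply(seq_len(n), function(v) {
    reach <- setdiff(which(is.finite(d[v, ])), v)
    if (!length(reach)) return(0)
    (n - 1) / sum(d[v, reach])
  }, numeric(1))
  betweenness <- vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n))
      if (s < t && s != v && t != v && nsp[s, t] > 0)
        tot <- tot + through[s, t, v] / nsp[s, t]
    tot
  }, numeric(1))
  harmonic <- vapply(seq_len(n), function(v) {
    other <- setdiff(seq_len(n), v)
    sum(1 / d[v, other][is.finite(d[v, other])]) / (n - 1)
  }, numeric(1))
  ev <- eigen(adj, symmetric = TRUE)
  hub <- abs(ev$vectors[, which.max(ev$values)])
  hub <- hub / max(hub)
  lam <- max(ev$values)
  pow <- as.numeric(solve(diag(n) - (0.9 / lam) * adj, adj %*% rep(1, n)))
  pow <- pow * sqrt(n / sum(pow^2))  # scale: sum of squares equals n
  list(degree = degree, closeness = closeness, betweenness = betweenness,
       harmonic = harmonic, hub = hub, power = pow)
}

# Random deletion-variant table over a toy proteome.
random_variants <- function(proteins, n, seed) {
  set.seed(seed)
  ids <- sample(names(proteins), n, replace = TRUE)
  L <- nchar(proteins[ids])
  start <- pmax(2, floor(runif(n, 2, pmax(2, L - 10))))
  len <- sample(1:10, n, replace = TRUE)
  end <- pmin(L, start + len - 1)
  data.frame(protein_id = ids, start = start, end = end,
             deleted_seq = substr(proteins[ids], start, end),
             label = sample(c("pathogenic", "benign"), n, replace = TRUE),
             source = "test", stringsAsFactors = FALSE)
}

random_proteins <- function(n, len_range = c(30, 120), seed = 1) {
  set.seed(seed)
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  setNames(vapply(lens, function(L) paste(sample(aa, L, TRUE), collapse = ""),
                  character(1)),
           sprintf("TP%02d", seq_len(n)))
}
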