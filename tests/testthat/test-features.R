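mkv <- function(protein_id, start, end, label = "benign") {
  structure(data.frame(protein_id = protein_id, start = start, end = end,
                       deleted_seq = NA, label = label, source = "",
                       stringsAsFactors = FALSE),
            class = c("deletion_variants", "data.frame"))
}

test_that("segments pad and trim to five residues by the stated conventions", {
  proteins <- c(P1 = "MKLVNAQWERTY")
  s <- extract_segments(mkv("P1", 5, 6), proteins)
  expect_equal(s$seg_upstream, "XMKLV")
  expect_equal(s$seg_deletion, "NAXXX")
  expect_equal(s$seg_downstream, "QWERT")
  expect_equal(extract_segments(mkv("P1", 2, 2), proteins)$seg_upstream, "XXXXM")
  long <- extract_segments(mkv("P1", 2, 11), proteins)
  expect_equal(long$seg_deletion, "KLVNA")   # first five deleted residues
  expect_equal(long$seg_downstream, "YXXXX")
})

test_that("content averages exclude non-standard residues", {
  scale <- setNames(rep(0, 20), delpath:::AA_STANDARD)
  scale["A"] <- 1; scale["G"] <- 3
  v <- data.frame(protein_id = "P1", start = 2, end = 3, deleted_seq = "AG")
  expect_equal(content_average(v, scale = scale), 2)
  v$deleted_seq <- "AXG"
  expect_equal(content_average(v, scale = scale), 2)
  v$deleted_seq <- "A"
  expect_equal(content_average(v, scale = scale), 1)
  v$deleted_seq <- "XX"
  expect_true(is.na(content_average(v, scale = scale)))
})

test_that("position features match the stated conventions", {
  proteins <- c(P1 = strrep("A", 100))
  f <- position_features(mkv("P1", 5, 6), proteins)
  expect_equal(f$pos_length, 2)
  expect_equal(f$pos_relative, 0.055)
  expect_equal(f$pos_dist_terminus, 4)
  expect_equal(position_features(mkv("P1", 100, 100), proteins)$pos_dist_terminus, 0)
  expect_equal(position_features(mkv("P1", 48, 53), proteins)$pos_relative, 0.505)
})

test_that("overlap flags use closed intervals and ignore adjacency", {
  tracks <- data.frame(protein_id = "P1", category = c("domain", "idr"),
                       start = c(6, 30), end = c(20, 35))
  expect_equal(unname(overlap_flags(mkv("P1", 5, 6), tracks)[1, ]), c(1L, 0L))
  expect_equal(unname(overlap_flags(mkv("P1", 5, 6),
    data.frame(protein_id = "P1", category = "domain", start = 7, end = 40))[1, ]), 0L)
  # two categories, exactly the overlapping one is set
  expect_equal(unname(overlap_flags(mkv("P1", 32, 33), tracks)[1, ]), c(0L, 1L))
})

test_that("overlap flags equal the brute-force interval-intersection oracle", {
  set.seed(42)
  for (rep in 1:5) {
    v <- data.frame(protein_id = sample(c("P1", "P2"), 12, TRUE),
                    start = sample(2:80, 12), stringsAsFactors = FALSE)
    v$end <- v$start + sample(0:9, 12, TRUE)
    tracks <- data.frame(protein_id = sample(c("P1", "P2"), 15, TRUE),
                         category = sample(c("a", "b", "c"), 15, TRUE),
                         start = sample(1:85, 15), stringsAsFactors = FALSE)
    tracks$end <- tracks$start + sample(0:20, 15, TRUE)
    cats <- c("a", "b", "c")
    expect_equal(overlap_flags(v, tracks, categories = cats),
                 oracle_overlap(v, tracks, cats))
  }
})

test_that("palindrome finder returns maximal intervals at the stated examples", {
  expect_equal(find_palindromes("MKAQAKM", min_len = 5),
               data.frame(start = 1L, end = 7L))
  expect_equal(nrow(find_palindromes("ACDEF", min_len = 3)), 0)
  expect_equal(find_palindromes("AAAAA", min_len = 3),
               data.frame(start = 1L, end = 5L))
  expect_error(find_palindromes("AAAA", min_len = 1))
})

test_that("palindrome finder matches the all-substrings oracle", {
  set.seed(11)
  for (rep in 1:8) {
    n <- sample(10:50, 1)
    s <- paste(sample(c("A", "K", "Q", "M"), n, TRUE), collapse = "")
    for (ml in c(3, 5))
      expect_equal(find_palindromes(s, min_len = ml),
                   oracle_palindromes(s, min_len = ml), label = s)
  }
})

test_that("centralities agree with hand conventions on tiny graphs", {
  path <- data.frame(from = c("A", "B"), to = c("B", "C"))
  c1 <- network_centralities(path)
  b <- c1[c1$node == "B", ]
  expect_equal(b$ppi_degree, 2)
  expect_equal(b$ppi_betweenness, 1)
  expect_equal(b$ppi_closeness, 1)
  tri <- data.frame(from = c("A", "B", "C"), to = c("B", "C", "A"))
  expect_equal(network_centralities(tri)$ppi_betweenness, rep(0, 3))
  # isolated node: closeness and harmonic are zero by convention
  iso <- network_centralities(path, nodes = "Z")
  z <- iso[iso$node == "Z", ]
  expect_equal(c(z$ppi_closeness, z$ppi_harmonic, z$ppi_degree), c(0, 0, 0))
})

test_that("all six centralities equal brute-force oracles on random small graphs", {
  set.seed(5)
  done <- 0
  while (done < 4) {
    n <- sample(4:6, 1)
    adj <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.55) adj[i, j] <- adj[j, i] <- 1
    # use connected graphs so closeness conventions are unambiguous
    reach <- diag(n) + adj
    for (k in 1:n) reach <- 1 * ((reach %*% (diag(n) + adj)) > 0)
    if (!all(reach == 1)) next
    done <- done + 1
    nodes <- LETTERS[1:n]
    edges <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    el <- data.frame(from = nodes[edges[, 1]], to = nodes[edges[, 2]])
    got <- network_centralities(el, nodes = nodes)
    got <- got[match(nodes, got$node), ]
    want <- oracle_centralities(adj)
    expect_equal(got$ppi_degree, want$degree, tolerance = 1e-8)
    expect_equal(got$ppi_closeness, want$closeness, tolerance = 1e-8)
    expect_equal(got$ppi_betweenness, want$betweenness, tolerance = 1e-8)
    expect_equal(got$ppi_harmonic, want$harmonic, tolerance = 1e-8)
    expect_equal(got$ppi_hub / max(got$ppi_hub), want$hub, tolerance = 1e-6)
    expect_equal(got$ppi_power, want$power, tolerance = 1e-8)
  }
})

test_that("featurize assembles a deterministic, order-invariant table and reports exclusions", {
  proteins <- random_proteins(6, seed = 31)
  v <- random_variants(proteins, 30, seed = 4)
  v <- v[!duplicated(v[c("protein_id", "start", "end")]), ]
  scales <- list(hydro = setNames(rnorm(20), delpath:::AA_STANDARD))
  tracks <- data.frame(protein_id = names(proteins)[1:4], category = "domain",
                       start = 3, end = 25)
  # conservation present for all but the last protein -> its variants excluded
  covered <- names(proteins)[-6]
  nums <- do.call(rbind, lapply(covered, function(p) data.frame(
    protein_id = p, name = "conservation", position = seq_len(nchar(proteins[p])),
    value = runif(nchar(proteins[p])))))
  nums <- rbind(nums, data.frame(protein_id = names(proteins), name = "gene_age",
                                 position = NA, value = 100))
  edges <- data.frame(from = names(proteins)[c(1, 2, 3, 4, 5)],
                      to = names(proteins)[c(2, 3, 4, 5, 6)])
  logos <- list(benign = build_position_logo(v, proteins, "benign"),
                pathogenic = build_position_logo(v, proteins, "pathogenic"))
  tab <- featurize(v, proteins, logos = logos, scales = scales, tracks = tracks,
                   numeric_annotations = nums, edges = edges)
  expect_s3_class(tab, "feature_table")
  regi <- feature_registry(tab)
  expect_true(all(c("context", "content", "position", "gene") %in% regi$category))
  expect_false(any(duplicated(regi$name)))
  excl <- attr(tab, "excluded")
  has6 <- v$protein_id == names(proteins)[6]
  expect_equal(nrow(excl), sum(has6))
  expect_match(excl$reason, "prediction not possible")
  expect_false(any(tab$protein_id == names(proteins)[6]))
  expect_false(any(is.na(tab[, delpath:::model_feature_names(tab)])))

  # determinism and permutation invariance (up to row order)
  tab2 <- featurize(v[sample(nrow(v)), ], proteins, logos = logos,
                    scales = scales, tracks = tracks,
                    numeric_annotations = nums, edges = edges)
  expect_equal(as.data.frame(tab), as.data.frame(tab2))
})
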