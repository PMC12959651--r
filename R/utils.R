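# Internal helpers shared across modules.

# The 20 standard amino acids, alphabetical one-letter codes.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Approximate background amino-acid frequencies (UniProtKB/Swiss-Prot
# composition), used by the sequence simulator.
AA_BACKGROUND <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0581, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0474, Q = 0.0393, R = 0.0553,
  S = 0.0664, T = 0.0535, V = 0.0686, W = 0.0110, Y = 0.0292
)

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit seed derived from a variant id and a global seed, so
# bootstrap p-values do not depend on batch composition or row order.
variant_seed <- function(id, seed = 0L) {
  mod <- 2147480009  # prime below 2^31
  vapply(as.character(id), function(s) {
    h <- 0
    for (c in utf8ToInt(s)) h <- (h * 31 + c) %% mod
    as.integer((h + as.numeric(seed)) %% mod)
  }, integer(1), USE.NAMES = FALSE)
}

# Min-max scaling fitted on training columns; constant columns map to 0.
minmax_fit <- function(x) {
  rng <- apply(x, 2, range)
  list(min = rng[1, ], span = pmax(rng[2, ] - rng[1, ], 0))
}

minmax_apply <- function(x, fit) {
  out <- sweep(x, 2, fit$min, "-")
  span <- ifelse(fit$span > 0, fit$span, 1)
  out <- sweep(out, 2, span, "/")
  out[, fit$span == 0] <- 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
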