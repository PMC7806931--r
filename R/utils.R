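# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical key for an unordered gene pair
.pair_key <- function(a, b) {
  swap <- a > b
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "\r")
}

# Deterministic 31-bit seed for an unordered gene pair under a global seed,
# so per-pair permutation nulls are reproducible regardless of the order in
# which pairs are evaluated.
.pair_seed <- function(seed, a, b) {
  g <- sort(c(a, b))
  h <- 0
  for (ch in utf8ToInt(paste(g[1L], g[2L], sep = "|"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h + (seed %% 2147483647)) %% 2147483647)
}

# Evaluate expr under a temporary RNG state; the caller's RNG stream is
# restored afterwards so seeded helpers do not clobber outer streams.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# small order-independent hash of a configuration object, for output headers
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = " ")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
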