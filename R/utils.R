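# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL uses the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stable per-stage child seeds below 2^31 so pipeline stages are
# independently reproducible from one master seed.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, hmm = 211L, profiles = 307L,
               variability = 401L, associate = 503L, general = 601L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (abs(as.integer(seed)) %% 1000003L) * 1009L + offsets[[stage]]
}

# Cheap FNV-1a string hash (hex) for run metadata.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Upper-triangle (i < j) index pairs of an n x n matrix, column-major order
# matching which(upper.tri(x)).
upper_pairs <- function(n) {
  idx <- which(upper.tri(diag(n)))
  list(linear = idx,
       i = row(diag(n))[idx],
       j = col(diag(n))[idx])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
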