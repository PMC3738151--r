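# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' seeded package functions never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a per-stream seed from a master seed.
# Keeps results independent across streams (genome / tracks / qpcr / sampling)
# while everything traces back to one master seed. Stays below 2^31.
derive_seed <- function(master, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- fnv1a32(paste0("seed:", as.integer(master), ":", stream))
  as.integer(h %% 2147483647)
}

# 32-bit FNV-1a hash of a string, returned as a double in [0, 2^32).
# Used for provenance hashes and seed derivation; no external digest needed.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296 # products < 2^53: exact in doubles
  }
  h
}

# log(sum(exp(x))) computed stably.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Consistent formatting for floating-point output: 6 significant digits.
format_num <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.6g", x)
    out[is.na(x)] <- "NA"
    out
  } else {
    as.character(x)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
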