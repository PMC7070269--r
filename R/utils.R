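#' @keywords internal
"_PACKAGE"

# Evaluate expr with a temporary RNG state so generators are deterministic
# given `seed` without clobbering the caller's random stream.
local_seed <- function(seed, expr) {
  glob <- globalenv()
  had <- exists(".Random.seed", envir = glob, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = glob, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = glob)
    } else if (exists(".Random.seed", envir = glob, inherits = FALSE)) {
      rm(".Random.seed", envir = glob)
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Per-subject seeds derived from a cohort seed; keeps every derived seed a
# valid 32-bit integer and distinct across indices.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 2654435761) %% 2147483629)
}

# Half-up decimal rounding (R's round() is banker's); used wherever
# percentages are compared against printed tables.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Polynomial rolling hash of a string, hex-encoded; used to stamp configs
# and the feature-catalog version into serialized outputs so order
# mismatches fail loudly.
string_hash <- function(s) {
  bytes <- as.double(charToRaw(s))
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
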