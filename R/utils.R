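# Internal helpers shared across modules.

# Flip edge-end orientations ("+" <-> "-"). Vectorized.
flip_side <- function(x) chartr("+-", "-+", x)

# Orientation letters used inside sort keys; keys must contain only
# uppercase letters so that string comparison is collation-independent.
ori_letter <- function(x) chartr("+-", "PM", x)

is_side <- function(x) all(x %in% c("+", "-"))

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Round-trip-exact decimal rendering for coverages in graph dumps.
fmt_cov <- function(x) formatC(x, digits = 17, format = "g")

check_odd_k <- function(k) {
  if (length(k) != 1L || is.na(k) || k != as.integer(k)) {
    stop("k must be a single integer", call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 3L || k %% 2L == 0L) {
    stop("k must be odd and >= 3 (even k admits palindromic k-mers)",
         call. = FALSE)
  }
  k
}
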