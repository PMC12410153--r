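# Internal helpers shared across modules.

# Pearson correlation on pairwise-complete observations with explicit flags.
# Returns list(r, n, flag); flag is NA_character_ when the estimate is defined.
.pearson_flagged <- function(x, y, min_pairs = 3L) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_pairs) {
    return(list(r = NA_real_, n = n, flag = "insufficient_pairs"))
  }
  xs <- x[ok]
  ys <- y[ok]
  if (sd(xs) == 0 || sd(ys) == 0) {
    return(list(r = NA_real_, n = n, flag = "constant_input"))
  }
  list(r = cor(xs, ys), n = n, flag = NA_character_)
}

# Column-wise pairwise-complete Pearson correlation between matching columns
# of A and B (both n x m). Vectorised; columns with < min_pairs complete rows
# or zero variance yield NA. Returns list(r, n).
.colwise_cor <- function(A, B, min_pairs = 3L) {
  ok <- !is.na(A) & !is.na(B)
  Az <- ifelse(ok, A, 0)
  Bz <- ifelse(ok, B, 0)
  n <- colSums(ok)
  sa <- colSums(Az)
  sb <- colSums(Bz)
  saa <- colSums(Az * Az)
  sbb <- colSums(Bz * Bz)
  sab <- colSums(Az * Bz)
  cov_ab <- sab - sa * sb / n
  var_a <- saa - sa * sa / n
  var_b <- sbb - sb * sb / n
  den <- sqrt(pmax(var_a, 0) * pmax(var_b, 0))
  r <- ifelse(n >= min_pairs & den > 0, cov_ab / den, NA_real_)
  r <- pmin(pmax(r, -1), 1)
  list(r = as.numeric(r), n = as.integer(n))
}

.is_scale <- function(scale) {
  is.numeric(scale) && length(scale) == 2L && all(is.finite(scale)) &&
    scale[2] > scale[1]
}

.check_scale <- function(scale) {
  if (!.is_scale(scale)) {
    abort("`scale` must be a numeric (lo, hi) pair with hi > lo.",
          class = "sc_parameter_error")
  }
  as.numeric(scale)
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic child seeds: derive per-stage seeds from one master seed
# without consuming the global RNG stream. Kept below 2^31 - 1.
.child_seed <- function(seed, stage) {
  offsets <- c(panel = 11L, machine = 23L, schedule = 37L, bold = 53L,
               mantel = 71L, generic = 97L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else 97L
  (as.integer(seed) * 1009L + off * 9973L) %% 2147483629L
}
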