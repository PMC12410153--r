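# Independently coded brute-force oracles and small fixture builders.
# Everything here is deliberately naive (explicit loops, direct formulas) so
# it shares no code path with the package implementations it checks.

oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

# leave-one-out consistency by explicit loops over raters and items
oracle_loo_consistency <- function(arr) {
  n_feat <- dim(arr)[2]
  n_rat <- dim(arr)[3]
  out <- numeric(n_feat)
  for (f in seq_len(n_feat)) {
    rs <- c()
    for (r in seq_len(n_rat)) {
      x <- arr[, f, r]
      others <- arr[, f, -r, drop = FALSE]
      m <- apply(others, 1L, function(v) {
        v <- v[!is.na(v)]
        if (length(v)) mean(v) else NA_real_
      })
      ok <- !is.na(x) & !is.na(m)
      if (sum(ok) >= 3 && sd(x[ok]) > 0 && sd(m[ok]) > 0) {
        rs <- c(rs, oracle_pearson(x, m))
      }
    }
    out[f] <- if (length(rs)) mean(rs) else NA_real_
  }
  out
}

# split-group consistency by explicit enumeration of unordered disjoint pairs
oracle_group_consistency <- function(arr, g) {
  n_rat <- dim(arr)[3]
  n_feat <- dim(arr)[2]
  groups <- combn(n_rat, g, simplify = FALSE)
  seen <- character(0)
  sums <- numeric(n_feat)
  counts <- integer(n_feat)
  for (a in groups) {
    for (b in combn(setdiff(seq_len(n_rat), a), g, simplify = FALSE)) {
      key <- paste(sort(c(paste(a, collapse = ","), paste(b, collapse = ","))),
                   collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      for (f in seq_len(n_feat)) {
        ma <- apply(arr[, f, a, drop = FALSE], 1L, function(v) {
          v <- v[!is.na(v)]
          if (length(v)) mean(v) else NA_real_
        })
        mb <- apply(arr[, f, b, drop = FALSE], 1L, function(v) {
          v <- v[!is.na(v)]
          if (length(v)) mean(v) else NA_real_
        })
        ok <- !is.na(ma) & !is.na(mb)
        if (sum(ok) >= 3 && sd(ma[ok]) > 0 && sd(mb[ok]) > 0) {
          sums[f] <- sums[f] + oracle_pearson(ma, mb)
          counts[f] <- counts[f] + 1L
        }
      }
    }
  }
  ifelse(counts > 0, sums / counts, NA_real_)
}

oracle_welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

oracle_matrix_similarity <- function(A, B) {
  xs <- c(); ys <- c()
  for (i in seq_len(nrow(A) - 1)) {
    for (j in (i + 1):ncol(A)) {
      xs <- c(xs, A[i, j]); ys <- c(ys, B[i, j])
    }
  }
  oracle_pearson(xs, ys)
}

# all permutations of 1..n, iterative construction
oracle_permutations <- function(n) {
  perms <- list(1L)
  for (m in 2:n) {
    new <- list()
    for (p in perms) {
      for (pos in 0:(m - 1)) {
        new[[length(new) + 1L]] <- append(p, m, after = pos)
      }
    }
    perms <- new
  }
  perms
}

# direct discrete convolution of a boxcar with a kernel, index arithmetic only
oracle_convolve <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (u in seq_len(min(t, length(k)))) {
      acc <- acc + x[t - u + 1] * k[u]
    }
    out[t] <- acc
  }
  out
}

# panel builders ------------------------------------------------------------

make_panel <- function(values, scale = c(0, 10)) {
  # values: item x feature x rater array (dimnames added here)
  dn <- list(paste0("i", seq_len(dim(values)[1])),
             paste0("f", seq_len(dim(values)[2])),
             paste0("r", seq_len(dim(values)[3])))
  dimnames(values) <- dn
  rating_panel(values, scale = scale)
}

rand_panel <- function(n_items, n_features, n_raters, seed,
                       miss_rate = 0, scale = c(0, 10)) {
  set.seed(seed)
  arr <- array(runif(n_items * n_features * n_raters, scale[1], scale[2]),
               dim = c(n_items, n_features, n_raters))
  if (miss_rate > 0) {
    arr[runif(length(arr)) < miss_rate] <- NA_real_
  }
  make_panel(arr, scale = scale)
}

mean_matrix_of <- function(panel) mean_over_raters(panel)
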