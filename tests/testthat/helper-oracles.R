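# Independent brute-force oracles and small fixture builders.

# Naive double-loop normalized cross-correlation with overlap-only sums.
oracle_xcorr <- function(s1, s2, lag) {
  num <- d1 <- d2 <- 0
  for (i in seq_along(s1)) {
    j <- i + lag
    if (j >= 1 && j <= length(s2)) {
      num <- num + s1[i] * s2[j]
      d1 <- d1 + s1[i]^2
      d2 <- d2 + s2[j]^2
    }
  }
  num / sqrt(d1 * d2)
}

# Exhaustive double-loop lag search with the same tie-break convention
# (smaller |lag| first, then negative before positive).
oracle_best_lag <- function(s1, s2, max_lag) {
  lags <- seq(-max_lag, max_lag)
  coefs <- rep(NA_real_, length(lags))
  for (k in seq_along(lags)) {
    lag <- lags[k]
    n_overlap <- 0
    for (i in seq_along(s1))
      if (i + lag >= 1 && i + lag <= length(s2)) n_overlap <- n_overlap + 1
    if (n_overlap >= 3) coefs[k] <- oracle_xcorr(s1, s2, lag)
  }
  ord <- order(-coefs, abs(lags), lags, na.last = TRUE)
  best <- ord[1L]
  list(coef = coefs[best], lag = lags[best])
}

# A tiny striated mark: identical translated rows of a shared base profile,
# free of edge artifacts (rows are windows into a longer base sequence).
shifted_rows_mark <- function(base, shifts, P) {
  margin <- max(abs(shifts)) + 1L
  stopifnot(length(base) >= P + 2L * margin)
  m <- t(vapply(shifts, function(s) base[(1:P) + margin + s], numeric(P)))
  heightmap(m, dx = 3, dy = 3)
}

# Planar quad mesh z = a*x + b*y + c over [0, w] x [0, h], two triangles.
plane_mesh <- function(a = 0, b = 0, c = 0, w = 1000, h = 1000) {
  zf <- function(x, y) a * x + b * y + c
  v <- rbind(c(0, 0, zf(0, 0)), c(w, 0, zf(w, 0)),
             c(w, h, zf(w, h)), c(0, h, zf(0, h)))
  structure(list(v1 = rbind(v[1, ], v[1, ]),
                 v2 = rbind(v[2, ], v[3, ]),
                 v3 = rbind(v[3, ], v[4, ])),
            class = "stl_mesh")
}
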