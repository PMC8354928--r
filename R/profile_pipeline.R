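#' Split a height map into per-row striation profiles
#'
#' The scan grid is divided orthogonally to the cutting direction: each row
#' of the height map is one cross-section signal through the striation
#' pattern. In grid mode (`hm` a [heightmap()] whose row length equals
#' `points_per_signal`) the rows are used directly. In stream mode (`hm` a
#' plain numeric vector) the sequence is chopped into consecutive blocks of
#' `points_per_signal` points and the remainder is discarded, which is how a
#' flat point-cloud export is re-gridded.
#'
#' @param hm A [heightmap()] or a numeric vector (stream mode).
#' @param points_per_signal Samples per signal, `P`. Default for grid mode:
#'   the row length.
#' @param dx Sample spacing (um); taken from the height map in grid mode.
#' @return A `signal_set`: list with `signals` (an `S x P` matrix, one signal
#'   per row), `dx`, `detrended` flag and `offsets` (all zero until
#'   alignment).
#' @export
#' @examples
#' split_signals(seq_len(103), points_per_signal = 10)$signals |> dim()
split_signals <- function(hm, points_per_signal = NULL, dx = 3) {
  if (inherits(hm, "heightmap")) {
    if (is.null(points_per_signal)) points_per_signal <- ncol(hm$z)
    points_per_signal <- as.integer(points_per_signal)
    if (points_per_signal < 3L)
      stop("'points_per_signal' must be at least 3")
    if (points_per_signal == ncol(hm$z)) {
      m <- hm$z
    } else {
      m <- chop_stream(as.vector(t(hm$z)), points_per_signal)
    }
    dx <- hm$dx
  } else {
    v <- as.numeric(hm)
    if (is.null(points_per_signal))
      stop("'points_per_signal' is required in stream mode")
    points_per_signal <- as.integer(points_per_signal)
    if (points_per_signal < 3L)
      stop("'points_per_signal' must be at least 3")
    m <- chop_stream(v, points_per_signal)
  }
  if (nrow(m) < 2L)
    stop("fewer than 2 complete signals of length ", points_per_signal)
  new_signal_set(m, dx = dx, detrended = FALSE)
}

chop_stream <- function(v, p) {
  s <- length(v) %/% p
  if (s < 1L) return(matrix(numeric(0), nrow = 0L, ncol = p))
  matrix(v[seq_len(s * p)], nrow = s, ncol = p, byrow = TRUE)
}

new_signal_set <- function(m, dx, detrended, offsets = NULL) {
  if (!all(is.finite(m))) stop("signals contain non-finite values")
  if (is.null(offsets)) offsets <- integer(nrow(m))
  structure(list(signals = m, dx = dx, detrended = isTRUE(detrended),
                 offsets = as.integer(offsets)),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("<signal_set> S = %d signals x P = %d points, dx = %g um%s\n",
              nrow(x$signals), ncol(x$signals), x$dx,
              if (x$detrended) ", detrended" else ""))
  invisible(x)
}

#' Detrend a profile with a centered moving average
#'
#' Subtracts the centered moving average from the signal, discarding the
#' low-frequency form (tilt, bow, mounting misalignment) while retaining the
#' high-frequency striation content. At the edges the window shrinks
#' symmetrically (equal reach on both sides), so the moving average of any
#' affine signal equals the signal itself and affine inputs detrend to
#' exactly zero everywhere.
#'
#' @param s Numeric vector (one profile), or a `signal_set` to detrend every
#'   signal.
#' @param window Odd window width in samples, at least 3. Default 51
#'   (~153 um at 3 um/px): well above typical striation spacing, well below
#'   the mark-form wavelength.
#' @return Same shape as the input; a `signal_set` gains `detrended = TRUE`.
#' @export
#' @examples
#' detrend_signal(c(0, 0, 9, 0, 0), window = 3)  # -> 0 -3 6 -3 0
detrend_signal <- function(s, window = 51L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3, got ", window)
  if (inherits(s, "signal_set")) {
    m <- t(apply(s$signals, 1L, detrend_vec, window = window))
    return(new_signal_set(m, dx = s$dx, detrended = TRUE,
                          offsets = s$offsets))
  }
  if (!is.numeric(s) || length(s) < 3L)
    stop("signal must be numeric with at least 3 samples")
  detrend_vec(as.numeric(s), window)
}

detrend_vec <- function(v, window) {
  n <- length(v)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  h <- pmin(half, i - 1L, n - i)   # symmetric shrink at the edges
  avg <- (cs[i + h + 1L] - cs[i - h]) / (2 * h + 1)
  v - avg
}

#' Normalized cross-correlation of two profiles at a given lag
#'
#' Evaluates
#' \deqn{X(L) = \frac{\sum_i S_1[i]\, S_2[i+L]}
#'   {\sqrt{\sum_i S_1[i]^2 \sum_i S_2[i+L]^2}}}
#' where all three sums run over the overlap region only (indices where both
#' `i` and `i + L` are in range and both values are finite). Restricting the
#' denominators to the overlap keeps the self-comparison at lag 0 exactly 1
#' and avoids padding artifacts. Signals are expected to be detrended; no
#' mean subtraction is performed here.
#'
#' @param s1,s2 Numeric vectors (profiles on the same spacing). `NA` entries
#'   (invalidated samples) are excluded from the overlap.
#' @param lag Integer lag `L` applied to the index of `s2`. A positive `L`
#'   means `s2`'s features sit `L` samples later than `s1`'s.
#' @return The correlation coefficient, in `[-1, 1]`.
#' @export
#' @examples
#' s <- rnorm(100)
#' xcorr_at_lag(s, s, 0)   # exactly 1
xcorr_at_lag <- function(s1, s2, lag) {
  s1 <- as.numeric(s1); s2 <- as.numeric(s2)
  lag <- as.integer(lag)
  if (abs(lag) >= min(length(s1), length(s2)))
    stop("|lag| must be smaller than the signal length")
  lo <- max(1L, 1L - lag)
  hi <- min(length(s1), length(s2) - lag)
  if (hi - lo + 1L < 3L)
    stop("fewer than 3 overlapping samples at lag ", lag)
  x <- s1[lo:hi]
  y <- s2[(lo + lag):(hi + lag)]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L)
    stop("fewer than 3 finite overlapping samples at lag ", lag)
  x <- x[ok]; y <- y[ok]
  sxx <- sum(x * x); syy <- sum(y * y)
  if (sxx == 0 || syy == 0)
    stop("undefined correlation: all-zero overlap in one of the signals",
         " at lag ", lag)
  sum(x * y) / sqrt(sxx * syy)
}

#' Exhaustive lag search for the maximum cross-correlation
#'
#' Evaluates [xcorr_at_lag()] at every integer lag in
#' `[-max_lag, +max_lag]` and returns the maximum together with its lag.
#' Ties are broken toward the smaller `|lag|`, then toward the negative lag,
#' so the result is deterministic.
#'
#' @param s1,s2 Numeric vectors; `NA` samples are excluded from overlaps.
#' @param max_lag Positive integer, less than half the signal length.
#' @return A list with `coef` and `lag`.
#' @export
best_lag <- function(s1, s2, max_lag = 50L) {
  s1 <- as.numeric(s1); s2 <- as.numeric(s2)
  max_lag <- as.integer(max_lag)
  p <- min(length(s1), length(s2))
  if (max_lag < 1L || max_lag >= p / 2)
    stop("'max_lag' must satisfy 0 < max_lag < P/2 (P = ", p, ")")
  best <- best_lag_core(s1, s2, max_lag)
  if (is.na(best$coef))
    stop("no lag in [-", max_lag, ", ", max_lag,
         "] has a valid (>= 3 samples, non-zero) overlap")
  best
}

# ordered 0, -1, +1, -2, +2, ...: a strict improvement rule then realizes
# the tie-break (smaller |lag| first, negative before positive)
lag_order <- function(max_lag) {
  k <- seq_len(max_lag)
  c(0L, as.vector(rbind(-k, k)))
}

best_lag_core <- function(s1, s2, max_lag) {
  n1 <- length(s1); n2 <- length(s2)
  best_c <- NA_real_; best_l <- NA_integer_
  for (lag in lag_order(max_lag)) {
    lo <- max(1L, 1L - lag)
    hi <- min(n1, n2 - lag)
    if (hi - lo + 1L < 3L) next
    x <- s1[lo:hi]
    y <- s2[(lo + lag):(hi + lag)]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) next
    x <- x[ok]; y <- y[ok]
    sxx <- sum(x * x); syy <- sum(y * y)
    if (sxx == 0 || syy == 0) next
    co <- sum(x * y) / sqrt(sxx * syy)
    if (is.na(best_c) || co > best_c) {
      best_c <- co; best_l <- lag
    }
  }
  list(coef = best_c, lag = best_l)
}

#' Sequentially align the signals of a mark
#'
#' The second signal is shifted to the first at the maximum cross-correlation
#' coefficient; every further signal `j` is shifted to the running mean of
#' the already-aligned signals `1..j-1` (per-sample mean over the valid,
#' in-range contributions). The `S - 1` maximum coefficients and their lags
#' are recorded: their mean `X_max` is the within-mark quality measure (close
#' to 1 for a clean, consistent mark) and the mean absolute lag `L_Xmax`
#' measures the straightness of the mark (0 for perfectly straight
#' striations). Samples shifted out of range are invalidated (`NA`), never
#' wrapped: physical profiles are not periodic.
#'
#' @param ss A detrended `signal_set` (see [detrend_signal()]).
#' @param max_lag Lag search half-width in samples; default 50.
#' @return A list with `signals` (the aligned `signal_set`, `NA` marking
#'   invalidated samples, `offsets` holding the applied lag per signal) and
#'   `alignment` (class `alignment_result`: `step_coeffs`, `step_lags`,
#'   `x_max`, `l_xmax`).
#' @export
align_signals <- function(ss, max_lag = 50L) {
  if (!inherits(ss, "signal_set")) stop("expected a 'signal_set'")
  if (!ss$detrended)
    stop("signals must be detrended before alignment; see detrend_signal()")
  m <- ss$signals
  s_n <- nrow(m); p <- ncol(m)
  if (s_n < 2L) stop("alignment needs at least 2 signals")
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag >= p / 2)
    stop("'max_lag' must satisfy 0 < max_lag < P/2 (P = ", p, ")")
  aligned <- matrix(NA_real_, nrow = s_n, ncol = p)
  aligned[1L, ] <- m[1L, ]
  msum <- m[1L, ]
  mcnt <- rep(1L, p)
  coeffs <- numeric(s_n - 1L)
  lags <- integer(s_n - 1L)
  offsets <- integer(s_n)
  for (j in 2L:s_n) {
    ref <- msum / ifelse(mcnt > 0L, mcnt, NA_integer_)
    best <- best_lag_core(ref, m[j, ], max_lag)
    if (is.na(best$coef))
      stop("alignment failure at step ", j - 1L,
           ": no lag leaves >= 3 overlapping samples")
    lag <- best$lag
    coeffs[j - 1L] <- best$coef
    lags[j - 1L] <- lag
    offsets[j] <- lag
    lo <- max(1L, 1L - lag)
    hi <- min(p, p - lag)
    aligned[j, lo:hi] <- m[j, (lo + lag):(hi + lag)]
    msum[lo:hi] <- msum[lo:hi] + aligned[j, lo:hi]
    mcnt[lo:hi] <- mcnt[lo:hi] + 1L
  }
  out <- structure(list(signals = aligned, dx = ss$dx, detrended = TRUE,
                        offsets = offsets),
                   class = "signal_set")
  al <- structure(list(step_coeffs = coeffs, step_lags = lags,
                       x_max = mean(coeffs), l_xmax = mean(abs(lags))),
                  class = "alignment_result")
  list(signals = out, alignment = al)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> %d steps, X_max = %.4f, L_Xmax = %.3f samples\n",
    length(x$step_coeffs), x$x_max, x$l_xmax))
  invisible(x)
}

#' Average aligned signals into a mark signature
#'
#' The signature representing a mark is the per-sample mean of the aligned
#' signals over their valid contributions. Samples near the ends that are
#' covered by fewer than 90% of the signals (because shifting invalidated
#' them) are trimmed from both ends to bound edge bias; the per-sample
#' contribution count is kept as `coverage`.
#'
#' @param ss An aligned `signal_set` from [align_signals()].
#' @param min_coverage Minimum fraction of contributing signals a retained
#'   end sample needs. Default 0.9.
#' @return An object of class `stria_signature`: `values` (um), `coverage`,
#'   `dx`, and the index `span` retained from the original axis.
#' @export
build_signature <- function(ss, min_coverage = 0.9) {
  if (!inherits(ss, "signal_set")) stop("expected a 'signal_set'")
  m <- ss$signals
  cov <- colSums(!is.na(m))
  need <- ceiling(min_coverage * nrow(m))
  keep <- which(cov >= need)
  if (!length(keep))
    stop("degenerate signature: no sample reaches ", min_coverage,
         " coverage")
  first <- keep[1L]; last <- keep[length(keep)]
  if (last - first + 1L < 10L)
    stop("degenerate signature: only ", last - first + 1L,
         " samples survive coverage trimming")
  vals <- colMeans(m[, first:last, drop = FALSE], na.rm = TRUE)
  structure(list(values = vals, coverage = cov[first:last], dx = ss$dx,
                 span = c(first, last)),
            class = "stria_signature")
}

#' @export
print.stria_signature <- function(x, ...) {
  cat(sprintf("<stria_signature> %d samples, dx = %g um, rms = %.3g um\n",
              length(x$values), x$dx, sqrt(mean(x$values^2))))
  invisible(x)
}

#' Full preprocessing: height map to mark signature
#'
#' Runs the pipeline split -> detrend -> align -> average on one scanned
#' mark: the rows of the height map become `S` cross-section signals of `P`
#' points each, the centered moving average is subtracted from each, the
#' signals are sequentially aligned by normalized cross-correlation, and the
#' aligned signals are averaged into the mark's signature. Deterministic for
#' fixed input and parameters.
#'
#' @param hm A [heightmap()] (or numeric stream; see [split_signals()]).
#' @param points_per_signal Samples per signal; default the row length
#'   (1004 on the reference scanner grid).
#' @param window Detrending moving-average window (odd, samples).
#'   Default 51.
#' @param max_lag Alignment lag search half-width (samples). Default 50.
#' @param invert If `TRUE`, [invert_scan()] is applied first (for marks
#'   scanned directly rather than cast).
#' @return A list with `signature` (a `stria_signature`) and `alignment`
#'   (an `alignment_result` holding `x_max` and `l_xmax`).
#' @export
#' @examples
#' knife <- generate_knife(P = 200, seed = 1)
#' hm <- generate_mark(knife, material_presets()[["high-fidelity"]],
#'                     S = 20, seed = 1)
#' res <- mark_signature(hm, window = 31, max_lag = 20)
#' res$alignment$x_max
mark_signature <- function(hm, points_per_signal = NULL, window = 51L,
                           max_lag = 50L, invert = FALSE) {
  if (invert) {
    stopifnot_heightmap(hm)
    hm <- invert_scan(hm)
  }
  ss <- split_signals(hm, points_per_signal = points_per_signal)
  ss <- detrend_signal(ss, window = window)
  ar <- align_signals(ss, max_lag = max_lag)
  sig <- build_signature(ar$signals)
  list(signature = sig, alignment = ar$alignment)
}

#' Write / read a mark signature as delimited text
#'
#' One `value coverage` pair per line after `#` header lines carrying `dx`
#' and, when an alignment result is supplied, `x_max` and `l_xmax`.
#'
#' @param sig A `stria_signature`.
#' @param path Output path.
#' @param alignment Optional `alignment_result` whose summary metrics are
#'   stored in the header.
#' @export
write_signature <- function(sig, path, alignment = NULL) {
  if (!inherits(sig, "stria_signature")) stop("expected a 'stria_signature'")
  hdr <- c("# striamark signature",
           sprintf("# dx %.17g", sig$dx),
           sprintf("# n %d", length(sig$values)))
  if (!is.null(alignment))
    hdr <- c(hdr,
             sprintf("# x_max %.17g", alignment$x_max),
             sprintf("# l_xmax %.17g", alignment$l_xmax))
  writeLines(c(hdr, sprintf("%.17g %d", sig$values,
                            as.integer(sig$coverage))), path)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  get_hdr <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\b"), hdr, value = TRUE)
    if (!length(m)) return(NA_real_)
    as.numeric(trimws(sub(paste0("^#\\s*", key, "\\s*"), "", m[1L])))
  }
  parts <- strsplit(trimws(body), "\\s+")
  vals <- as.numeric(vapply(parts, `[`, "", 1L))
  cov <- as.integer(vapply(parts, `[`, "", 2L))
  if (any(!is.finite(vals))) stop("unparseable signature file: ", path)
  sig <- structure(list(values = vals, coverage = cov,
                        dx = get_hdr("dx"), span = c(1L, length(vals))),
                   class = "stria_signature")
  attr(sig, "x_max") <- get_hdr("x_max")
  attr(sig, "l_xmax") <- get_hdr("l_xmax")
  sig
}
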