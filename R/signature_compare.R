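#' Compare two mark signatures
#'
#' The between-mark similarity score `X_C` is the maximum normalized
#' cross-correlation between two signatures over an exhaustive integer-lag
#' search (same search and tie-breaking as [best_lag()]). Signatures of
#' unequal length are compared over their common span, left-aligned, since
#' coverage trimming makes lengths differ by at most twice the lag window.
#'
#' @param a,b `stria_signature` objects on the same spacing.
#' @param max_lag Lag search half-width (samples). Default 50.
#' @param label Ground-truth label to attach: `"KM"` (known match, same
#'   knife), `"KNM"` (known non-match) or `"unknown"`.
#' @return An object of class `comparison_result`: list with `x_c`, `lag`,
#'   `label` and `pair` (the two mark labels, if any).
#' @export
compare_signatures <- function(a, b, max_lag = 50L,
                               label = c("unknown", "KM", "KNM")) {
  if (!inherits(a, "stria_signature") || !inherits(b, "stria_signature"))
    stop("expected two 'stria_signature' objects")
  label <- match.arg(label)
  if (is.finite(a$dx) && is.finite(b$dx) &&
      abs(a$dx - b$dx) > 1e-9 * max(a$dx, b$dx))
    stop("signatures have incompatible sample spacing: ",
         a$dx, " vs ", b$dx, " um")
  p <- min(length(a$values), length(b$values))
  max_lag <- as.integer(max_lag)
  if (p - max_lag < 10L)
    stop("signatures too short for max_lag = ", max_lag,
         ": overlap would fall below 10 samples")
  va <- a$values[seq_len(p)]
  vb <- b$values[seq_len(p)]
  best <- best_lag_core(va, vb, max_lag)
  if (is.na(best$coef))
    stop("no valid lag: signatures have a zero or empty overlap")
  structure(list(x_c = best$coef, lag = best$lag, label = label,
                 pair = c(attr(a, "mark_id") %||% "",
                          attr(b, "mark_id") %||% "")),
            class = "comparison_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> X_C = %.4f at lag %d (%s)\n",
              x$x_c, x$lag, x$label))
  invisible(x)
}

#' Build the known-match / known-non-match comparison set of a study
#'
#' In the reference design every knife cuts two marks, `A` and `B`. The
#' known matches (KM) are the two marks of each knife. The known non-matches
#' (KNM) pair marks across knives; because the study design does not
#' enumerate which cross-knife pairs to use, the default scheme is a
#' deterministic cyclic derangement — mark `A` of knife `i` against mark `B`
#' of knife `i + 1` (wrapping) — yielding exactly one KNM per knife.
#' `"all-knm"` instead uses every cross-knife pair.
#'
#' @param signatures List of `stria_signature` objects.
#' @param knife Character/factor vector: knife id per signature.
#' @param mark Character vector: mark id per signature (e.g. `"A"`, `"B"`).
#' @param material Single material name for the whole set (or vector).
#' @param pairing `"cyclic"` (default) or `"all-knm"`.
#' @param max_lag Passed to [compare_signatures()].
#' @return A data frame with one row per comparison: `material`, `knife_a`,
#'   `mark_a`, `knife_b`, `mark_b`, `label`, `x_c`, `lag`.
#' @export
km_knm_matrix <- function(signatures, knife, mark, material = "",
                          pairing = c("cyclic", "all-knm"), max_lag = 50L) {
  pairing <- match.arg(pairing)
  knife <- as.character(knife)
  mark <- as.character(mark)
  n <- length(signatures)
  stopifnot(length(knife) == n, length(mark) == n)
  material <- rep_len(as.character(material), n)
  knives <- unique(knife)
  if (length(knives) < 2L)
    stop("known non-matches require at least 2 knives")
  per_knife <- split(seq_len(n), knife)
  short <- names(per_knife)[lengths(per_knife) < 2L]
  if (length(short))
    stop("knife ", short[1L], " has fewer than 2 marks; ",
         "known matches need two marks per knife")
  rows <- list()
  add <- function(i, j, lab) {
    cr <- compare_signatures(signatures[[i]], signatures[[j]],
                             max_lag = max_lag, label = lab)
    rows[[length(rows) + 1L]] <<- data.frame(
      material = material[i], knife_a = knife[i], mark_a = mark[i],
      knife_b = knife[j], mark_b = mark[j], label = lab,
      x_c = cr$x_c, lag = cr$lag, stringsAsFactors = FALSE)
  }
  for (k in knives) {
    idx <- per_knife[[k]]
    cmb <- utils::combn(idx, 2L)
    for (c_i in seq_len(ncol(cmb))) add(cmb[1L, c_i], cmb[2L, c_i], "KM")
  }
  if (pairing == "cyclic") {
    nk <- length(knives)
    for (ki in seq_len(nk)) {
      i <- per_knife[[knives[ki]]][1L]                      # mark A
      nxt <- per_knife[[knives[ki %% nk + 1L]]]
      j <- nxt[min(2L, length(nxt))]                        # mark B
      add(i, j, "KNM")
    }
  } else {
    for (ki in seq_along(knives)[-length(knives)]) {
      for (kj in (ki + 1L):length(knives)) {
        for (i in per_knife[[knives[ki]]])
          for (j in per_knife[[knives[kj]]]) add(i, j, "KNM")
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize one material's comparison study
#'
#' Means and standard deviations of the per-mark quality metrics (`X_max`,
#' `L_Xmax`) and of the comparison scores `X_C` split by KM/KNM, together
#' with the two-sided Mann-Whitney U p-value for the KM vs KNM score
#' separation — the practical criterion for a usable test material.
#'
#' @param results Data frame from [km_knm_matrix()] (needs `label`, `x_c`).
#' @param alignments Optional list of `alignment_result` objects (one per
#'   mark) supplying `x_max` / `l_xmax`.
#' @param material Material name for the summary row.
#' @return An object of class `material_summary`: a list of `(mean, sd, n)`
#'   triples plus `separation_p`, printable as a one-line report.
#' @export
summarize_material <- function(results, alignments = NULL, material = "") {
  km <- results$x_c[results$label == "KM"]
  knm <- results$x_c[results$label == "KNM"]
  if (!length(km) || !length(knm))
    stop("need at least one KM and one KNM result")
  stat3 <- function(v) c(mean = mean(v), sd = if (length(v) > 1L) sd(v)
                         else NA_real_, n = length(v))
  xm <- lm <- c(mean = NA_real_, sd = NA_real_, n = 0)
  if (!is.null(alignments)) {
    xm <- stat3(vapply(alignments, function(a) a$x_max, 0))
    lm <- stat3(vapply(alignments, function(a) a$l_xmax, 0))
  }
  sep <- mann_whitney_u(km, knm)
  structure(list(material = material,
                 x_max_stats = xm, l_xmax_stats = lm,
                 xc_km_stats = stat3(km), xc_knm_stats = stat3(knm),
                 separation_p = sep$p.value,
                 xc_km = km, xc_knm = knm),
            class = "material_summary")
}

#' @export
print.material_summary <- function(x, ...) {
  f <- function(s) sprintf("%.3f +/- %.3f (n=%d)", s["mean"], s["sd"],
                           as.integer(s["n"]))
  cat(sprintf("<material_summary> %s\n", x$material))
  if (x$x_max_stats["n"] > 0) {
    cat("  X_max :", f(x$x_max_stats), "\n")
    cat("  L_Xmax:", f(x$l_xmax_stats), "\n")
  }
  cat("  X_C KM :", f(x$xc_km_stats), "\n")
  cat("  X_C KNM:", f(x$xc_knm_stats), "\n")
  cat(sprintf("  KM vs KNM Mann-Whitney p = %.3g%s\n", x$separation_p,
              if (x$separation_p < SIGNIFICANCE_LEVEL) " *" else ""))
  invisible(x)
}

#' Pairwise material comparison on a chosen metric
#'
#' Two-sided Mann-Whitney U p-values for every pair of materials on the raw
#' per-mark or per-pair values of one metric. P-values are reported raw; an
#' optional Holm adjustment is available.
#'
#' @param values_by_material Named list of numeric vectors: the raw metric
#'   values (e.g. all `x_max` per mark, or all KM `x_c`) per material.
#' @param adjust If `TRUE`, Holm-adjust the upper triangle of p-values.
#' @return A symmetric matrix of p-values with unit diagonal.
#' @export
compare_materials <- function(values_by_material, adjust = FALSE) {
  if (length(values_by_material) < 2L)
    stop("need at least 2 materials with raw values")
  if (is.null(names(values_by_material)) ||
      any(!nzchar(names(values_by_material))))
    stop("'values_by_material' must be a named list")
  bad <- names(values_by_material)[
    !vapply(values_by_material, function(v) is.numeric(v) && length(v) >= 2L,
            TRUE)]
  if (length(bad))
    stop("missing or degenerate raw values for material ", bad[1L])
  nms <- names(values_by_material)
  k <- length(nms)
  p <- matrix(1, k, k, dimnames = list(nms, nms))
  ut <- which(upper.tri(p), arr.ind = TRUE)
  pv <- apply(ut, 1L, function(ij)
    mann_whitney_u(values_by_material[[ij[1L]]],
                   values_by_material[[ij[2L]]])$p.value)
  if (adjust) pv <- stats::p.adjust(pv, method = "holm")
  p[ut] <- pv
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  p
}
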