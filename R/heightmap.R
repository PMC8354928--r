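#' Construct a height map
#'
#' A height map is the digital form of a scanned mark or cast: a regular grid
#' of surface heights in micrometres. Rows run along the cut direction, so
#' each row is one cross-section profile of the striation pattern; columns
#' run orthogonally to the cut (the profile axis).
#'
#' @param z Numeric matrix of heights (um), `S` rows by `P` columns. All
#'   values must be finite; at least 2 rows and 2 columns.
#' @param dx Column spacing (um), default 3 (a typical tool-mark scanner
#'   lateral resolution).
#' @param dy Row spacing (um), default 3.
#' @param kind Either `"cast"` (a silicone replica, the mirrored negative of
#'   the original surface) or `"direct-scan"`.
#' @param label Free-text mark identifier.
#'
#' @return An object of class `heightmap`: a list with elements `z`, `dx`,
#'   `dy`, `kind` and `label`.
#' @seealso [invert_scan()], [read_heightmap()], [mark_signature()]
#' @export
#' @examples
#' hm <- heightmap(matrix(rnorm(12), 3, 4))
#' dim(hm$z)
heightmap <- function(z, dx = 3, dy = 3, kind = c("cast", "direct-scan"),
                      label = "") {
  kind <- match.arg(kind)
  z <- as.matrix(z)
  storage.mode(z) <- "double"
  if (nrow(z) < 2L || ncol(z) < 2L)
    stop("height map must have at least 2 rows and 2 columns, got ",
         nrow(z), " x ", ncol(z))
  if (!all(is.finite(z)))
    stop("height map contains non-finite heights")
  if (!is.numeric(dx) || length(dx) != 1L || !is.finite(dx) || dx <= 0)
    stop("'dx' must be a single positive number (um)")
  if (!is.numeric(dy) || length(dy) != 1L || !is.finite(dy) || dy <= 0)
    stop("'dy' must be a single positive number (um)")
  structure(list(z = z, dx = as.numeric(dx), dy = as.numeric(dy),
                 kind = kind, label = as.character(label)[1L]),
            class = "heightmap")
}

#' @export
print.heightmap <- function(x, ...) {
  cat(sprintf("<heightmap> %d x %d points, dx = %g um, dy = %g um, kind = %s",
              nrow(x$z), ncol(x$z), x$dx, x$dy, x$kind))
  if (nzchar(x$label)) cat(", label =", x$label)
  cat("\n")
  invisible(x)
}

#' @export
dim.heightmap <- function(x) dim(x$z)

stopifnot_heightmap <- function(hm) {
  if (!inherits(hm, "heightmap"))
    stop("expected a 'heightmap' object; see heightmap()")
  invisible(hm)
}

#' Invert a scan between surface and cast convention
#'
#' A cast is the mirrored negative of the surface it was taken from: peaks
#' become valleys and the profile axis is reflected. Direct scans of a mark
#' are therefore inverted before they are compared with scans of casts.
#' Heights are negated and the column axis mirrored; the `kind` flag is
#' toggled. Applying the operation twice returns the original grid.
#'
#' @param hm A [heightmap()].
#' @return A `heightmap` with negated, column-mirrored heights.
#' @export
#' @examples
#' hm <- heightmap(matrix(1:6, 2, 3))
#' invert_scan(invert_scan(hm))$z == hm$z
invert_scan <- function(hm) {
  stopifnot_heightmap(hm)
  z <- -hm$z[, ncol(hm$z):1L, drop = FALSE]
  heightmap(z, dx = hm$dx, dy = hm$dy,
            kind = if (hm$kind == "cast") "direct-scan" else "cast",
            label = hm$label)
}
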