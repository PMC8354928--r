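#' Read a surface scan into a height map
#'
#' Supported formats:
#' \describe{
#'   \item{`grid-text`}{Plain delimited text: `#`-prefixed header lines
#'     carrying `dx`, `dy`, `kind` and `label`, then one row of
#'     whitespace-separated heights (um) per line. Human-inspectable and
#'     exactly round-tripping.}
#'   \item{`stl`}{A triangulated surface mesh (binary or ASCII STL, the
#'     export format of 3D tool-mark scanners). The mesh is resampled onto a
#'     regular grid at spacing `dx`/`dy` via [resample_mesh_to_grid()];
#'     STL stores no physical units, so coordinates are taken as um.}
#'   \item{`raster16`}{A single-channel 16-bit TIFF whose integer counts map
#'     to heights as `offset + count * scale`. The scale factor is not stored
#'     in the raster and must be supplied.}
#' }
#'
#' @param path Path to the file.
#' @param format One of `"grid-text"`, `"stl"`, `"raster16"`. Defaults to a
#'   guess from the file extension.
#' @param dx,dy Grid spacing (um) for formats that do not carry it
#'   (`stl` resampling target, `raster16`). Default 3.
#' @param scale Height per count (um) for `raster16`; required there.
#' @param offset Height of count 0 (um) for `raster16`; default 0.
#' @param kind,label Metadata for formats that do not carry it.
#' @return A [heightmap()]. The row axis is the cut direction; columns are
#'   the striation cross-section axis.
#' @export
read_heightmap <- function(path,
                           format = c("grid-text", "stl", "raster16"),
                           dx = 3, dy = 3, scale = NULL, offset = 0,
                           kind = "cast", label = "") {
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     stl = "stl",
                     tif = , tiff = "raster16",
                     "grid-text")
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  switch(format,
    "grid-text" = read_grid_text(path),
    "stl" = resample_mesh_to_grid(read_stl(path), dx = dx, dy = dy,
                                  kind = kind, label = label),
    "raster16" = {
      if (is.null(scale))
        stop("'scale' (um per count) is required for raster16 input")
      img <- tiff::readTIFF(path)
      if (length(dim(img)) != 2L)
        stop("raster16 input must be single-channel: ", path)
      counts <- round(img * 65535)
      heightmap(offset + counts * scale, dx = dx, dy = dy,
                kind = kind, label = label)
    })
}

#' Write a height map
#'
#' `grid-text` writes full-precision decimals and round-trips exactly.
#' `raster16` quantizes heights to 16-bit counts `round((z - offset)/scale)`,
#' bounding the round-trip error by `scale / 2`; the caller must keep `scale`
#' and `offset` to read the raster back.
#'
#' @param hm A [heightmap()].
#' @param path Output path.
#' @param format `"grid-text"` (default) or `"raster16"`.
#' @param scale Height per count (um), required for `raster16`.
#' @param offset Height of count 0 (um) for `raster16`. Default: the minimum
#'   height, so counts start at 0. Returned invisibly for re-reading.
#' @return Invisibly, a list with the `scale` and `offset` used (raster16) or
#'   the path (grid-text).
#' @export
write_heightmap <- function(hm, path, format = c("grid-text", "raster16"),
                            scale = NULL, offset = NULL) {
  stopifnot_heightmap(hm)
  format <- match.arg(format)
  if (format == "grid-text") {
    hdr <- c("# striamark heightmap",
             sprintf("# dx %.17g", hm$dx),
             sprintf("# dy %.17g", hm$dy),
             paste("# kind", hm$kind),
             paste("# label", hm$label))
    rows <- apply(hm$z, 1L, function(r) paste(sprintf("%.17g", r),
                                              collapse = " "))
    ok <- tryCatch({
      writeLines(c(hdr, rows), path)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("cannot write grid-text file: ", path)
    return(invisible(list(path = path)))
  }
  if (is.null(scale) || !is.finite(scale) || scale <= 0)
    stop("'scale' (um per count) must be a positive number for raster16")
  if (is.null(offset)) offset <- min(hm$z)
  counts <- round((hm$z - offset) / scale)
  if (any(counts < 0) || any(counts > 65535))
    stop("heights do not fit the 16-bit range at scale ", scale,
         " and offset ", offset)
  tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16L)
  invisible(list(scale = scale, offset = offset))
}

read_grid_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr & nzchar(trimws(lines))]
  get_hdr <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, "\\b"), hdr, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(paste0("^#\\s*", key, "\\s*"), "", m[1L]))
  }
  if (!length(body)) stop("grid-text file has no data rows: ", path)
  split_rows <- lapply(body, function(l) strsplit(trimws(l), "[ \t,;]+")[[1L]])
  lens <- lengths(split_rows)
  if (length(unique(lens)) != 1L)
    stop("ragged grid-text file ", path, ": data line ",
         which(lens != lens[1L])[1L], " has ", lens[lens != lens[1L]][1L],
         " values, expected ", lens[1L])
  vals <- suppressWarnings(lapply(split_rows, as.numeric))
  bad <- which(vapply(vals, function(v) any(!is.finite(v)), logical(1L)))
  if (length(bad))
    stop("non-finite or unparseable height in ", path, " at data line ",
         bad[1L])
  z <- do.call(rbind, vals)
  heightmap(z,
            dx = as.numeric(get_hdr("dx", "3")),
            dy = as.numeric(get_hdr("dy", "3")),
            kind = match.arg(get_hdr("kind", "cast"),
                             c("cast", "direct-scan")),
            label = get_hdr("label", ""))
}

#' Read a triangulated surface mesh (STL)
#'
#' Reads binary or ASCII STL. STL files carry no units; coordinates are
#' returned as-is (the scan pipeline treats them as um).
#'
#' @param path Path to the `.stl` file.
#' @return An object of class `stl_mesh`: a list of three `n x 3` matrices
#'   `v1`, `v2`, `v3` holding the triangle vertices.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  size <- file.info(path)$size
  raw <- readBin(path, "raw", n = size)
  is_binary <- FALSE
  if (size >= 84) {
    n_tri <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
    if (!is.na(n_tri) && n_tri >= 0 && size == 84 + 50 * n_tri)
      is_binary <- TRUE
  }
  if (is_binary) {
    n_tri <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
    if (n_tri == 0L) stop("STL file contains no facets: ", path)
    # 50-byte records: 12 floats (normal + 3 vertices) + 2 attribute bytes
    idx <- outer(seq_len(48L), 84 + 50 * (seq_len(n_tri) - 1L), "+")
    vals <- readBin(raw[as.vector(idx)], "numeric", size = 4L,
                    n = 12L * n_tri, endian = "little")
    m <- matrix(vals, nrow = 12L)
    if (!all(is.finite(m[4:12, ])))
      stop("non-finite vertex coordinate in STL facet ",
           which(!apply(is.finite(m[4:12, , drop = FALSE]), 2L, all))[1L])
    mesh <- list(v1 = t(m[4:6, , drop = FALSE]),
                 v2 = t(m[7:9, , drop = FALSE]),
                 v3 = t(m[10:12, , drop = FALSE]))
  } else {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (!length(vlines) || length(vlines) %% 3L != 0L)
      stop("malformed ASCII STL (", length(vlines),
           " vertex lines, not a multiple of 3): ", path)
    nums <- suppressWarnings(vapply(strsplit(trimws(vlines), "\\s+"),
      function(p) as.numeric(p[2:4]), numeric(3L)))
    if (any(!is.finite(nums)))
      stop("unparseable vertex line in ASCII STL near line ",
           grep("^\\s*vertex\\s", lines)[which(!apply(
         is.finite(nums), 2L, all))[1L]])
    v <- t(nums)
    i <- seq(1L, nrow(v), by = 3L)
    mesh <- list(v1 = v[i, , drop = FALSE], v2 = v[i + 1L, , drop = FALSE],
                 v3 = v[i + 2L, , drop = FALSE])
  }
  structure(mesh, class = "stl_mesh")
}

write_stl_ascii <- function(mesh, path) {
  # fixture helper: emit a minimal ASCII STL (normals recomputed are not
  # needed by the reader, so zeros are written)
  n <- nrow(mesh$v1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid striamark", con)
  for (i in seq_len(n)) {
    writeLines(c("  facet normal 0 0 0", "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g",
                         c(mesh$v1[i, 1], mesh$v2[i, 1], mesh$v3[i, 1]),
                         c(mesh$v1[i, 2], mesh$v2[i, 2], mesh$v3[i, 2]),
                         c(mesh$v1[i, 3], mesh$v2[i, 3], mesh$v3[i, 3])),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid striamark", con)
  invisible(path)
}

write_stl_binary <- function(mesh, path) {
  n <- nrow(mesh$v1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(as.integer(n), con, size = 4L, endian = "little")
  for (i in seq_len(n)) {
    writeBin(c(0, 0, 0, mesh$v1[i, ], mesh$v2[i, ], mesh$v3[i, ]), con,
             size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
  invisible(path)
}

#' Resample a triangulated mesh onto a regular height grid
#'
#' Projects the mesh onto the x-y plane and interpolates the height linearly
#' within the containing triangle at each grid node (exact for any affine
#' surface). Nodes outside the mesh footprint are invalid; after
#' interpolation the grid is trimmed to a full rectangle by repeatedly
#' dropping the boundary row or column with the most invalid nodes, because
#' the profile pipeline requires rectangular grids.
#'
#' @param mesh An `stl_mesh` from [read_stl()].
#' @param dx,dy Target grid spacing (um).
#' @param kind,label Metadata for the resulting [heightmap()].
#' @return A [heightmap()].
#' @details A mesh that folds over itself (two triangles projecting onto the
#'   same x-y point with different heights) is not a height field and raises
#'   a geometry error.
#' @export
resample_mesh_to_grid <- function(mesh, dx = 3, dy = 3,
                                  kind = "cast", label = "") {
  if (!inherits(mesh, "stl_mesh")) stop("expected an 'stl_mesh' object")
  v1 <- mesh$v1; v2 <- mesh$v2; v3 <- mesh$v3
  xs_all <- c(v1[, 1], v2[, 1], v3[, 1])
  ys_all <- c(v1[, 2], v2[, 2], v3[, 2])
  gx <- seq(min(xs_all), max(xs_all) + dx / 2, by = dx)
  gx <- gx[gx <= max(xs_all) + 1e-9]
  gy <- seq(min(ys_all), max(ys_all) + dy / 2, by = dy)
  gy <- gy[gy <= max(ys_all) + 1e-9]
  z <- matrix(NA_real_, nrow = length(gy), ncol = length(gx))
  eps <- 1e-9 * max(1, diff(range(xs_all)), diff(range(ys_all)))
  ztol <- 1e-6
  for (t in seq_len(nrow(v1))) {
    ax <- v1[t, 1]; ay <- v1[t, 2]; az <- v1[t, 3]
    bx <- v2[t, 1]; by <- v2[t, 2]; bz <- v2[t, 3]
    cx <- v3[t, 1]; cy <- v3[t, 2]; cz <- v3[t, 3]
    det <- (by - cy) * (ax - cx) + (cx - bx) * (ay - cy)
    if (abs(det) < eps^2) next  # degenerate in projection
    ci <- which(gx >= min(ax, bx, cx) - eps & gx <= max(ax, bx, cx) + eps)
    ri <- which(gy >= min(ay, by, cy) - eps & gy <= max(ay, by, cy) + eps)
    if (!length(ci) || !length(ri)) next
    px <- rep(gx[ci], each = length(ri))
    py <- rep(gy[ri], times = length(ci))
    l1 <- ((by - cy) * (px - cx) + (cx - bx) * (py - cy)) / det
    l2 <- ((cy - ay) * (px - cx) + (ax - cx) * (py - cy)) / det
    l3 <- 1 - l1 - l2
    tol <- 1e-9
    inside <- l1 >= -tol & l2 >= -tol & l3 >= -tol
    if (!any(inside)) next
    zi <- l1 * az + l2 * bz + l3 * cz
    rows <- rep(ri, times = length(ci))[inside]
    cols <- rep(ci, each = length(ri))[inside]
    zv <- zi[inside]
    lin <- cbind(rows, cols)
    old <- z[lin]
    clash <- !is.na(old) & abs(old - zv) > ztol
    if (any(clash))
      stop("mesh folds over itself: grid node (row ", rows[clash][1L],
           ", col ", cols[clash][1L], ") receives heights ",
           signif(old[clash][1L], 6), " and ", signif(zv[clash][1L], 6))
    z[lin] <- zv
  }
  # trim to the largest full rectangle, greedily from the boundary
  while (anyNA(z)) {
    if (nrow(z) < 2L || ncol(z) < 2L)
      stop("mesh footprint leaves no usable rectangular grid")
    na_top <- sum(is.na(z[1L, ])); na_bot <- sum(is.na(z[nrow(z), ]))
    na_lef <- sum(is.na(z[, 1L])); na_rig <- sum(is.na(z[, ncol(z)]))
    frac <- c(na_top / ncol(z), na_bot / ncol(z),
              na_lef / nrow(z), na_rig / nrow(z))
    if (max(frac) == 0)
      stop("mesh footprint has interior holes; cannot form a full grid")
    side <- which.max(frac)
    z <- switch(side,
                z[-1L, , drop = FALSE],
                z[-nrow(z), , drop = FALSE],
                z[, -1L, drop = FALSE],
                z[, -ncol(z), drop = FALSE])
  }
  heightmap(z, dx = dx, dy = dy, kind = kind, label = label)
}

#' Read / write an 8-bit grayscale image
#'
#' Images are integer brightness matrices in `[0, 255]`, the input of
#' [image_contrast()]. Multi-channel PNGs are averaged to grayscale.
#'
#' @param path PNG path.
#' @return For `read_image`, an integer matrix of class `gray_image`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L)
    img <- rowMeans(img[, , seq_len(min(3L, dim(img)[3L])), drop = FALSE],
                    dims = 2L)
  gray_image(round(img * 255))
}

#' @param img A `gray_image` or integer matrix in `[0, 255]`.
#' @rdname read_image
#' @export
write_image <- function(img, path) {
  img <- gray_image(img)
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' Validate and classify a grayscale image matrix
#'
#' @param b Matrix of integer brightness values in `[0, 255]`.
#' @return The matrix with class `gray_image`.
#' @export
gray_image <- function(b) {
  b <- as.matrix(b)
  storage.mode(b) <- "double"
  if (any(!is.finite(b)) || any(b < 0) || any(b > 255) ||
      any(b != round(b)))
    stop("image must hold integer brightness values in [0, 255]")
  structure(b, class = "gray_image")
}
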