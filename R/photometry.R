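#' Image contrast of a grayscale image
#'
#' A high number of distinct brightness values corresponds to a detailed,
#' high-contrast representation of a mark, so contrast is quantified as the
#' sample standard deviation of all pixel brightness values,
#' \deqn{IC = \sqrt{\sum_i (b_i - \bar b)^2 / (n - 1)}.}
#'
#' @param img A [gray_image()] or numeric matrix of brightness values in
#'   `[0, 255]`, at least 2 pixels.
#' @return The contrast IC (brightness counts).
#' @export
#' @examples
#' image_contrast(matrix(c(0, 0, 255, 255), 2, 2))  # 147.224
image_contrast <- function(img) {
  b <- if (inherits(img, "gray_image")) as.numeric(unclass(img))
       else as.numeric(gray_image(img))
  if (length(b) < 2L)
    stop("contrast is undefined for a single-pixel image")
  sd(b)
}

#' Material optics: reflection degree and light reflectance value
#'
#' @param tau Degree of reflection, in `[0, 1]`.
#' @param lrv Light reflectance value, in `[0, 100]`: the percentage of
#'   incident light a surface reflects (100 = ideally white, 0 = ideally
#'   black).
#' @return A list of class `material_optics`.
#' @export
material_optics <- function(tau, lrv) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) ||
      tau < 0 || tau > 1)
    stop("'tau' (degree of reflection) must lie in [0, 1]")
  if (!is.numeric(lrv) || length(lrv) != 1L || !is.finite(lrv) ||
      lrv < 0 || lrv > 100)
    stop("'lrv' must lie in [0, 100]")
  structure(list(tau = tau, lrv = lrv), class = "material_optics")
}

#' Illumination geometry for oblique-light rendering
#'
#' @param azimuth Degrees in the surface plane; 0 points along the profile
#'   axis, i.e. perpendicular to the grooves — the standard orientation for
#'   examining striated marks.
#' @param elevation Degrees above the surface plane, in `(0, 90)`. Grazing
#'   light (a few degrees) maximizes striation shadows.
#' @param intensity Incident intensity `I_I`, arbitrary linear units.
#' @return A list of class `illumination_config`.
#' @export
illumination_config <- function(azimuth = 0, elevation = 5, intensity = 1) {
  if (!is.finite(elevation) || elevation <= 0 || elevation >= 90)
    stop("'elevation' must lie strictly between 0 and 90 degrees")
  if (!is.finite(intensity) || intensity < 0)
    stop("'intensity' must be nonnegative")
  structure(list(azimuth = azimuth, elevation = elevation,
                 intensity = intensity), class = "illumination_config")
}

#' Reflected intensity under oblique illumination
#'
#' The reflected intensity of a facet illuminated with intensity `I_I` at
#' incidence angle `lambda` (measured from the facet plane) is
#' \deqn{I_R = I_I \cdot |\sin \lambda| \cdot \tau} with `tau` the degree of
#' reflection. At grazing incidence (`lambda = 0`) every material reflects
#' nothing, which is why dark and bright materials differ most under steep
#' local incidence.
#'
#' @param incident Incident intensity `I_I` (>= 0), recyclable vector.
#' @param incidence_angle Angle `lambda` in degrees, recyclable vector.
#' @param optics A [material_optics()].
#' @return Reflected intensity, same units as `incident`.
#' @export
#' @examples
#' reflected_intensity(200, 30, material_optics(0.5, 50))  # 50
reflected_intensity <- function(incident, incidence_angle, optics) {
  if (!inherits(optics, "material_optics"))
    optics <- do.call(material_optics, as.list(optics))
  if (any(incident < 0)) stop("incident intensity must be nonnegative")
  incident * abs(sin(incidence_angle * pi / 180)) * optics$tau
}

#' Render a height map under oblique illumination
#'
#' A minimal physically-motivated shading model for what a striated surface
#' looks like under the oblique light of a comparison microscope: per-pixel
#' surface normals come from central-difference height gradients, the
#' incidence angle is the angle between the incoming ray and the local
#' tangent plane, and each pixel's brightness is
#' `base + gain * I_R`, clamped and rounded to `[0, 255]`. The base
#' brightness maps the material's LRV (`255 * lrv / 100`); the gain is
#' calibrated so that a 45-degree facet at `tau = 1`, `I_I = 1` adds 64
#' counts. Facets facing away from the light receive no illumination
#' (`lambda = 0`); cast shadows are not modelled. Deterministic.
#'
#' @param hm A [heightmap()].
#' @param illum An [illumination_config()].
#' @param optics A [material_optics()].
#' @param clamp If `FALSE`, return the raw numeric brightness matrix without
#'   rounding or clamping (useful to verify linearity in `I_I`).
#' @return A [gray_image()] (or numeric matrix when `clamp = FALSE`).
#' @export
render_oblique <- function(hm, illum = illumination_config(),
                           optics = material_optics(0.8, 20),
                           clamp = TRUE) {
  stopifnot_heightmap(hm)
  if (!inherits(illum, "illumination_config"))
    stop("'illum' must be an illumination_config()")
  if (!inherits(optics, "material_optics"))
    stop("'optics' must be a material_optics()")
  z <- hm$z
  gx <- central_diff_cols(z) / hm$dx   # dz/dx along the profile axis
  gy <- central_diff_rows(z) / hm$dy   # dz/dy along the cut direction
  # unit normal (-gx, -gy, 1)/|.|
  nn <- sqrt(gx^2 + gy^2 + 1)
  az <- illum$azimuth * pi / 180
  el <- illum$elevation * pi / 180
  lx <- cos(el) * cos(az); ly <- cos(el) * sin(az); lz <- sin(el)
  sin_lambda <- (-gx * lx - gy * ly + lz) / nn
  sin_lambda[sin_lambda < 0] <- 0   # facing away from the light
  lambda <- asin(pmin(1, sin_lambda)) * 180 / pi
  i_r <- reflected_intensity(illum$intensity, lambda, optics)
  base <- 255 * optics$lrv / 100
  gain <- 64 / sin(45 * pi / 180)
  bright <- base + gain * i_r
  if (!clamp) return(bright)
  b <- round_half_away(bright)
  b[b < 0] <- 0; b[b > 255] <- 255
  gray_image(b)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

central_diff_cols <- function(z) {
  p <- ncol(z)
  g <- matrix(0, nrow(z), p)
  if (p >= 3L)
    g[, 2:(p - 1)] <- (z[, 3:p] - z[, 1:(p - 2)]) / 2
  g[, 1] <- z[, 2] - z[, 1]
  g[, p] <- z[, p] - z[, p - 1]
  g
}

central_diff_rows <- function(z) t(central_diff_cols(t(z)))

#' Group comparison and LRV correlation of image-contrast values
#'
#' Compares contrast values between groups (e.g. cast colours) with
#' pairwise two-sided Mann-Whitney U tests, and — when light reflectance
#' values are supplied — tests the linear correlation of IC with LRV
#' (Pearson).
#'
#' @param ic Numeric vector of contrast values.
#' @param group Factor/character vector of group labels, same length.
#' @param lrv Optional numeric vector of LRVs, same length.
#' @return A list with `pairwise_p` (symmetric matrix from
#'   [compare_materials()]) and, when `lrv` is given, `pearson`
#'   (`estimate`, `statistic`, `p.value`).
#' @export
contrast_by_group <- function(ic, group, lrv = NULL) {
  ic <- as.numeric(ic)
  group <- as.character(group)
  stopifnot(length(ic) == length(group))
  groups <- split(ic, group)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L))
    stop("every group needs at least 2 values")
  out <- list(pairwise_p = compare_materials(groups))
  if (!is.null(lrv)) {
    stopifnot(length(lrv) == length(ic))
    out$pearson <- test_battery(ic, lrv, test = "pearson")
  }
  out
}
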