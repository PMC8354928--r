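#' Synthetic material model
#'
#' Bundles the parameters with which the generator emulates how a test
#' material records and degrades a knife's striation pattern: lateral
#' jitter of the striations from row to row (how "straight" the mark is),
#' per-point height noise (how faithfully fine detail is reproduced),
#' low-order surface form, grain-like dot artifacts (casting material
#' filling chondrocyte lacunae on cartilage casts), and the optical and
#' elastic constants used by the rendering and indentation modules. The
#' preset parameter values are engineering constants of the generator, not
#' measured material properties.
#'
#' @param name Material name.
#' @param lag_sd Per-row lateral jitter standard deviation (samples).
#' @param lag_walk `"iid"` (independent per-row shifts) or `"random-walk"`
#'   (progressive drift).
#' @param noise_sd Per-point height noise standard deviation (um).
#' @param form_amplitude Amplitude of the smooth tilt + bow form term (um).
#' @param dot_density Expected dots per mm^2 of surface.
#' @param dot_diameter_mean,dot_diameter_sd Dot diameter distribution (um),
#'   truncated to positive values. Defaults 26.3 and 5.1, the scale of
#'   chondrocyte lacunae.
#' @param dot_height Dot bump height (um).
#' @param tau Degree of reflection, `[0, 1]`.
#' @param lrv Light reflectance value, `[0, 100]`.
#' @param E Young's modulus (MPa); documentation field for the indentation
#'   module, `NA` when not applicable.
#' @return A list of class `material_model`.
#' @seealso [material_presets()], [generate_mark()]
#' @export
material_model <- function(name = "custom", lag_sd = 0, lag_walk = c("iid",
                           "random-walk"), noise_sd = 0, form_amplitude = 0,
                           dot_density = 0, dot_diameter_mean = 26.3,
                           dot_diameter_sd = 5.1, dot_height = 4,
                           tau = 0.5, lrv = 20, E = NA_real_) {
  lag_walk <- match.arg(lag_walk)
  for (v in c(lag_sd, noise_sd, form_amplitude, dot_density,
              dot_diameter_mean, dot_diameter_sd, dot_height))
    if (!is.finite(v) || v < 0)
      stop("material parameters must be nonnegative")
  if (tau < 0 || tau > 1) stop("'tau' must lie in [0, 1]")
  if (lrv < 0 || lrv > 100) stop("'lrv' must lie in [0, 100]")
  structure(list(name = name, lag_sd = lag_sd, lag_walk = lag_walk,
                 noise_sd = noise_sd, form_amplitude = form_amplitude,
                 dot_density = dot_density,
                 dot_diameter_mean = dot_diameter_mean,
                 dot_diameter_sd = dot_diameter_sd, dot_height = dot_height,
                 tau = tau, lrv = lrv, E = E),
            class = "material_model")
}

#' Named synthetic material presets
#'
#' Four generator presets spanning the fidelity range observed across
#' cartilage-analogue test materials: `"high-fidelity"` (an agarose-like
#' material: very straight marks, little noise), `"medium-fidelity"`,
#' `"low-fidelity"` (a gelatine-like material: strong jitter and noise) and
#' `"cartilage-like"` (medium fidelity with dot artifacts enabled). The `E`
#' fields carry representative printed moduli of such materials for use as
#' simulation inputs; all other values are invented generator constants and
#' are not measurements.
#'
#' @return Named list of [material_model()] objects.
#' @export
#' @examples
#' names(material_presets())
material_presets <- function() {
  list(
    "high-fidelity" = material_model("high-fidelity", lag_sd = 0.6,
      noise_sd = 0.1, form_amplitude = 2, tau = 0.35, lrv = 15, E = 1.39),
    "medium-fidelity" = material_model("medium-fidelity", lag_sd = 2.5,
      noise_sd = 0.35, form_amplitude = 3, tau = 0.5, lrv = 30, E = 2.69),
    "low-fidelity" = material_model("low-fidelity", lag_sd = 5,
      noise_sd = 0.8, form_amplitude = 4, tau = 0.6, lrv = 60, E = 0.12),
    "cartilage-like" = material_model("cartilage-like", lag_sd = 2,
      noise_sd = 0.3, form_amplitude = 3, dot_density = 5,
      dot_diameter_mean = 26.3, dot_diameter_sd = 5.1, dot_height = 4,
      tau = 0.35, lrv = 20))
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, a, b = 0L) {
  as.integer((as.numeric(seed) %% 1e6 * 1009 + a * 1311 + b * 17 + 1) %%
               2147483629)
}

#' Generate a synthetic knife edge profile
#'
#' The individualizing damage along a knife's cutting edge is modelled as a
#' stationary Gaussian profile: white noise smoothed to a given correlation
#' length (moving-average kernel of width `correlation_length / dx`,
#' applied circularly so the length is preserved), centered, and rescaled
#' to the requested amplitude. Each seed yields an independent "knife".
#'
#' @param P Profile length in samples. Default 1004.
#' @param amplitude_sd Target standard deviation of the profile (um).
#'   Default 1.5.
#' @param correlation_length Striation correlation length (um), at least
#'   `dx`. Default 30.
#' @param dx Sample spacing (um). Default 3.
#' @param seed Integer seed.
#' @param knife_id Identifier carried through to study manifests.
#' @return A list of class `knife_profile`: `values`, `dx`,
#'   `correlation_length`, `amplitude_sd`, `knife_id`.
#' @export
generate_knife <- function(P = 1004L, amplitude_sd = 1.5,
                           correlation_length = 30, dx = 3, seed = 1L,
                           knife_id = "") {
  if (amplitude_sd <= 0 || dx <= 0)
    stop("'amplitude_sd' and 'dx' must be positive")
  if (correlation_length < dx)
    stop("'correlation_length' must be at least dx (", dx, " um)")
  P <- as.integer(P)
  if (P < 8L) stop("'P' must be at least 8")
  w <- max(1L, round(correlation_length / dx))
  v <- withr::with_seed(as.integer(seed), {
    raw <- rnorm(P + 2L * w)
    sm <- as.numeric(stats::filter(raw, rep(1 / w, w), sides = 2L))
    sm[(w + 1L):(w + P)]
  })
  v <- v - mean(v)
  v <- v * amplitude_sd / sd(v)
  structure(list(values = v, dx = dx,
                 correlation_length = correlation_length,
                 amplitude_sd = amplitude_sd, knife_id = knife_id),
            class = "knife_profile")
}

#' Generate a synthetic striated mark
#'
#' Emulates the scan of a cast of a striated cut mark: every row of the
#' height map carries the knife's edge profile, laterally shifted by an
#' integer jitter drawn per the material's jitter model, with iid Gaussian
#' height noise, a smooth mark-level form term (tilt plus a single-period
#' bow), and — for dot-forming materials — radially symmetric grain-like
#' bumps whose centers follow a spatial Poisson process and whose diameters
#' are truncated-normal. Samples shifted past the profile ends are filled
#' by extending the edge value (profiles are not periodic). Deterministic
#' per seed; the marks carry `kind = "cast"` because dots appear as
#' elevations on casts.
#'
#' @param knife A [generate_knife()] profile.
#' @param mat A [material_model()].
#' @param S Number of rows (signals). Default 261.
#' @param dy Row spacing (um). Default 3.
#' @param seed Integer seed.
#' @param label Mark label.
#' @return A [heightmap()] with an attached `dots` attribute (data frame of
#'   dot centers, diameters and heights).
#' @export
generate_mark <- function(knife, mat, S = 261L, dy = 3, seed = 1L,
                          label = "") {
  if (!inherits(knife, "knife_profile")) stop("expected a 'knife_profile'")
  if (!inherits(mat, "material_model")) stop("expected a 'material_model'")
  S <- as.integer(S)
  if (S < 2L) stop("'S' must be at least 2")
  P <- length(knife$values)
  dx <- knife$dx
  out <- withr::with_seed(as.integer(seed), {
    shifts <- if (mat$lag_sd > 0) {
      raw <- rnorm(S, 0, mat$lag_sd)
      if (mat$lag_walk == "random-walk") raw <- cumsum(raw)
      as.integer(round(raw))
    } else integer(S)
    idx_base <- seq_len(P)
    z <- matrix(0, nrow = S, ncol = P)
    for (j in seq_len(S)) {
      idx <- pmin(pmax(idx_base + shifts[j], 1L), P)  # edge extension
      z[j, ] <- knife$values[idx]
    }
    if (mat$noise_sd > 0)
      z <- z + matrix(rnorm(S * P, 0, mat$noise_sd), S, P)
    if (mat$form_amplitude > 0) {
      x <- (idx_base - 1) / (P - 1)
      phase <- runif(1)
      slope <- runif(1, -1, 1)
      form <- mat$form_amplitude * (slope * (x - 0.5) +
                                      sin(2 * pi * (x + phase)))
      z <- sweep(z, 2L, form, `+`)
    }
    dots <- data.frame(row_um = numeric(0), col_um = numeric(0),
                       diameter = numeric(0), height = numeric(0))
    if (mat$dot_density > 0) {
      area_mm2 <- (S * dy) * (P * dx) / 1e6
      n_dots <- rpois(1L, mat$dot_density * area_mm2)
      if (n_dots > 0) {
        rows_um <- runif(n_dots, 0, S * dy)
        cols_um <- runif(n_dots, 0, P * dx)
        diam <- vapply(seq_len(n_dots), function(i) {
          d <- rnorm(1L, mat$dot_diameter_mean, mat$dot_diameter_sd)
          while (d <= 0) d <- rnorm(1L, mat$dot_diameter_mean,
                                    mat$dot_diameter_sd)
          d
        }, 0)
        for (i in seq_len(n_dots)) {
          r <- diam[i] / 2
          jr <- which(abs(seq_len(S) * dy - dy / 2 - rows_um[i]) <= r)
          ir <- which(abs(idx_base * dx - dx / 2 - cols_um[i]) <= r)
          if (!length(jr) || !length(ir)) next
          dist <- sqrt(outer((jr * dy - dy / 2 - rows_um[i])^2,
                             (ir * dx - dx / 2 - cols_um[i])^2, `+`))
          bump <- mat$dot_height * 0.5 * (1 + cos(pi * pmin(dist / r, 1)))
          bump[dist > r] <- 0
          z[jr, ir] <- z[jr, ir] + bump
        }
        dots <- data.frame(row_um = rows_um, col_um = cols_um,
                           diameter = diam, height = mat$dot_height)
      }
    }
    list(z = z, dots = dots)
  })
  hm <- heightmap(out$z, dx = dx, dy = dy, kind = "cast", label = label)
  attr(hm, "dots") <- out$dots
  hm
}

#' Generate a whole known-match / known-non-match study
#'
#' The reference study design: `n_knives` independent synthetic knives each
#' cut `marks_per_knife` marks into the same material, with independent
#' jitter, noise and dots per mark. Per-knife and per-mark sub-seeds are
#' derived deterministically from `seed`, so a study is a pure function of
#' its configuration.
#'
#' @param n_knives Number of knives. Default 10.
#' @param marks_per_knife Marks cut per knife. Default 2.
#' @param S,P Rows and columns of each mark's grid. Defaults 261 and 1004
#'   (the reference scanner grid of 262,044 points).
#' @param dx,dy Grid spacing (um). Default 3.
#' @param material A [material_model()]. Default: the `"high-fidelity"`
#'   preset.
#' @param amplitude_sd,correlation_length Knife profile parameters, passed
#'   to [generate_knife()].
#' @param seed Study seed.
#' @return A list of class `mark_study`: `marks` (list of [heightmap()]s),
#'   `manifest` (data frame with `mark_id`, `knife_id`, `mark`, `material`,
#'   `seed`), and the configuration.
#' @export
#' @examples
#' st <- generate_study(n_knives = 2, S = 12, P = 120, seed = 1)
#' st$manifest
generate_study <- function(n_knives = 10L, marks_per_knife = 2L, S = 261L,
                           P = 1004L, dx = 3, dy = 3,
                           material = material_presets()[["high-fidelity"]],
                           amplitude_sd = 1.5, correlation_length = 30,
                           seed = 0L) {
  n_knives <- as.integer(n_knives)
  marks_per_knife <- as.integer(marks_per_knife)
  if (n_knives < 1L || marks_per_knife < 1L)
    stop("'n_knives' and 'marks_per_knife' must be at least 1")
  if (!inherits(material, "material_model"))
    stop("'material' must be a material_model()")
  marks <- list()
  manifest <- list()
  for (k in seq_len(n_knives)) {
    knife_id <- sprintf("K%02d", k)
    knife <- generate_knife(P = P, amplitude_sd = amplitude_sd,
                            correlation_length = correlation_length,
                            dx = dx, seed = derive_seed(seed, k),
                            knife_id = knife_id)
    for (m in seq_len(marks_per_knife)) {
      mark_seed <- derive_seed(seed, k, m)
      mark_id <- paste0(knife_id, "_", LETTERS[m])
      hm <- generate_mark(knife, material, S = S, dy = dy,
                          seed = mark_seed, label = mark_id)
      marks[[mark_id]] <- hm
      manifest[[mark_id]] <- data.frame(
        mark_id = mark_id, knife_id = knife_id, mark = LETTERS[m],
        material = material$name, seed = mark_seed,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(marks = marks, manifest = do.call(rbind, manifest),
                 material = material, seed = seed),
            class = "mark_study")
}

#' @export
print.mark_study <- function(x, ...) {
  cat(sprintf("<mark_study> %d marks from %d knives, material %s, seed %d\n",
              nrow(x$manifest), length(unique(x$manifest$knife_id)),
              x$material$name, x$seed))
  invisible(x)
}

#' Run the full comparison pipeline on a generated study
#'
#' Computes every mark's signature (see [mark_signature()]), builds the
#' KM/KNM comparison set, and returns the comparison table, the per-mark
#' alignment metrics and the material summary.
#'
#' @param study A `mark_study` from [generate_study()].
#' @param window,max_lag Pipeline parameters, see [mark_signature()].
#' @param pairing KNM pairing scheme, see [km_knm_matrix()].
#' @return A list with `results` (comparison data frame), `alignments`
#'   (named list of `alignment_result`), `per_mark` (data frame of `x_max`,
#'   `l_xmax` per mark) and `summary` (a [summarize_material()] object).
#' @export
run_km_knm_study <- function(study, window = 51L, max_lag = 50L,
                             pairing = c("cyclic", "all-knm")) {
  if (!inherits(study, "mark_study")) stop("expected a 'mark_study'")
  pairing <- match.arg(pairing)
  sigs <- list()
  aligns <- list()
  for (id in study$manifest$mark_id) {
    ms <- mark_signature(study$marks[[id]], window = window,
                         max_lag = max_lag)
    attr(ms$signature, "mark_id") <- id
    sigs[[id]] <- ms$signature
    aligns[[id]] <- ms$alignment
  }
  results <- km_knm_matrix(sigs, knife = study$manifest$knife_id,
                           mark = study$manifest$mark,
                           material = study$material$name,
                           pairing = pairing, max_lag = max_lag)
  per_mark <- data.frame(
    mark_id = names(aligns),
    x_max = vapply(aligns, function(a) a$x_max, 0),
    l_xmax = vapply(aligns, function(a) a$l_xmax, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  list(results = results, alignments = aligns, per_mark = per_mark,
       summary = summarize_material(results, aligns,
                                    material = study$material$name))
}
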