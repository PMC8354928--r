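test_that("grid-text files round-trip exactly with their metadata", {
  withr::with_seed(11, {
    hm <- heightmap(matrix(rnorm(40 * 25), 40, 25), dx = 3, dy = 2.5,
                    kind = "direct-scan", label = "mark 7")
  })
  path <- withr::local_tempfile(fileext = ".txt")
  write_heightmap(hm, path)
  back <- read_heightmap(path)
  expect_identical(back$z, hm$z)
  expect_identical(back$dx, hm$dx)
  expect_identical(back$dy, hm$dy)
  expect_identical(back$kind, hm$kind)
  expect_identical(back$label, hm$label)
})

test_that("grid-text reader reports malformed input precisely", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# dx 3", "1 2 3", "4 5"), path)
  expect_error(read_heightmap(path), "ragged")
  writeLines(c("1 2 3", "4 NaN 6"), path)
  expect_error(read_heightmap(path), "non-finite")
  writeLines(c("# dx 3", "# only headers"), path)
  expect_error(read_heightmap(path), "no data rows")
})

test_that("a trivial zero grid reads as an all-zero height map", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0 0 0", "0 0 0 0", "0 0 0 0"), path)
  hm <- read_heightmap(path)
  expect_identical(dim(hm), c(3L, 4L))
  expect_true(all(hm$z == 0))
})

test_that("raster16 round-trip error is bounded by half the height scale", {
  withr::with_seed(12, {
    hm <- heightmap(matrix(rnorm(30 * 20, sd = 5), 30, 20))
  })
  path <- withr::local_tempfile(fileext = ".tif")
  meta <- write_heightmap(hm, path, format = "raster16", scale = 0.01)
  back <- read_heightmap(path, format = "raster16", scale = 0.01,
                         offset = meta$offset)
  expect_lte(max(abs(back$z - hm$z)), 0.005)
  expect_error(read_heightmap(path, format = "raster16"), "scale")
})

test_that("degenerate grids are rejected", {
  expect_error(heightmap(matrix(1, 1, 5)), "at least 2")
  expect_error(heightmap(matrix(numeric(0), 0, 0)), "at least 2")
  expect_error(heightmap(matrix(c(1, Inf, 2, 3), 2, 2)), "non-finite")
})

test_that("STL meshes round-trip through both encodings", {
  mesh <- plane_mesh(a = 0.05, b = -0.02, c = 4, w = 300, h = 150)
  fa <- withr::local_tempfile(fileext = ".stl")
  fb <- withr::local_tempfile(fileext = ".stl")
  striamark:::write_stl_ascii(mesh, fa)
  striamark:::write_stl_binary(mesh, fb)
  ma <- read_stl(fa)
  mb <- read_stl(fb)
  ga <- resample_mesh_to_grid(ma, dx = 3, dy = 3)
  gb <- resample_mesh_to_grid(mb, dx = 3, dy = 3)
  # binary stores float32; both resampled grids match the analytic plane
  expect_equal(ga$z, gb$z, tolerance = 1e-4)
})

test_that("mesh resampling is exact on affine surfaces", {
  # flat plane z = 5 over 1 mm x 1 mm at the scanner spacing
  flat <- resample_mesh_to_grid(plane_mesh(c = 5), dx = 3, dy = 3)
  expect_lt(max(abs(flat$z - 5)), 1e-6)
  # plane z = x: each column equals its x coordinate
  px <- resample_mesh_to_grid(plane_mesh(a = 1, w = 120, h = 60),
                              dx = 3, dy = 3)
  expect_equal(px$z[1, ], px$z[nrow(px$z), ], tolerance = 1e-9)
  expect_equal(diff(px$z[1, ]), rep(3, ncol(px$z) - 1), tolerance = 1e-9)
  # tilted plane z = 0.1 x + 0.2 y against the closed form
  tl <- resample_mesh_to_grid(plane_mesh(a = 0.1, b = 0.2, w = 90, h = 90),
                              dx = 3, dy = 3)
  xs <- (seq_len(ncol(tl$z)) - 1) * 3
  ys <- (seq_len(nrow(tl$z)) - 1) * 3
  expect_lt(max(abs(tl$z - outer(0.2 * ys, 0.1 * xs, `+`))), 1e-9)
})

test_that("a folded mesh is rejected as not a height field", {
  mesh <- plane_mesh(c = 0, w = 90, h = 90)
  over <- plane_mesh(c = 7, w = 90, h = 90)  # same footprint, other height
  fold <- structure(list(v1 = rbind(mesh$v1, over$v1),
                         v2 = rbind(mesh$v2, over$v2),
                         v3 = rbind(mesh$v3, over$v3)),
                    class = "stl_mesh")
  expect_error(resample_mesh_to_grid(fold, 3, 3), "folds over itself")
})

test_that("invert_scan negates, mirrors and toggles the kind flag", {
  hm <- heightmap(rbind(c(1, 2, 3), c(4, 5, 6)), kind = "cast")
  inv <- invert_scan(hm)
  expect_equal(inv$z[1, ], c(-3, -2, -1))
  expect_identical(inv$kind, "direct-scan")
  expect_equal(invert_scan(inv)$z, hm$z)
  expect_identical(invert_scan(inv)$kind, "cast")
  # mean height changes sign
  expect_equal(mean(inv$z), -mean(hm$z))
})

test_that("the signature is invariant under double inversion of the scan", {
  knife <- generate_knife(P = 240, seed = 5)
  hm <- generate_mark(knife, material_presets()[["high-fidelity"]],
                      S = 16, seed = 6)
  a <- mark_signature(hm, window = 31, max_lag = 20)
  b <- mark_signature(invert_scan(invert_scan(hm)), window = 31,
                      max_lag = 20)
  expect_identical(a$signature$values, b$signature$values)
})

test_that("gray images round-trip through 8-bit PNG", {
  withr::with_seed(13, {
    img <- gray_image(matrix(sample(0:255, 200, replace = TRUE), 10, 20))
  })
  path <- withr::local_tempfile(fileext = ".png")
  write_image(img, path)
  expect_identical(unclass(read_image(path)), unclass(img))
  expect_error(gray_image(matrix(c(-1, 4, 5, 6), 2, 2)), "\\[0, 255\\]")
  expect_error(gray_image(matrix(c(0.5, 4, 5, 6), 2, 2)), "integer")
})
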