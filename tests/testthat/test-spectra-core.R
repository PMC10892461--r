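test_that("spectra_set normalizes axis direction and enforces invariants", {
  grid_desc <- seq(9000, 4000, by = -6)
  m <- matrix(runif(3 * length(grid_desc), 0.1, 1), nrow = 3)
  s <- toy_set(m, kind = "reflectance", grid = grid_desc, n_levels = 3)
  expect_false(is.unsorted(s$grid, strictly = TRUE))
  expect_true(attr(s, "descending_input"))
  # values follow the axis flip
  expect_equal(s$intensities[1, ], rev(m[1, ]), ignore_attr = TRUE)

  expect_error(toy_set(m[, 1:10], grid = c(4000, 4006, 4003), n_levels = 3),
               "monotonic")
  expect_error(spectra_set(1:5, matrix(1, 2, 4),
                           toy_set(matrix(1, 2, 5), n_levels = 2)$samples,
                           "absorbance"),
               "columns")
  dup <- toy_set(matrix(1, 2, 5), n_levels = 2)$samples
  dup$level_id <- c(1L, 1L); dup$replicate_id <- c(1L, 1L)
  expect_error(spectra_set(1:5, matrix(1, 2, 5), dup, "absorbance"),
               "unique")
})

test_that("CSV write/read round trip is lossless and errors name the id", {
  set.seed(7)
  m <- matrix(10^rnorm(4 * 30), nrow = 4)
  s <- toy_set(m, kind = "reflectance", n_levels = 4)
  sp <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, sp, mp)
  s2 <- read_spectra(sp, mp, kind = "reflectance")
  expect_identical(s2$intensities, s$intensities)
  expect_identical(s2$grid, s$grid)
  expect_equal(s2$samples$level_id, s$samples$level_id)

  meta <- read.csv(mp)
  meta <- meta[meta$sample_id != "s02", ]
  mp2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(meta, mp2, row.names = FALSE)
  expect_error(read_spectra(sp, mp2), "s02")
})

test_that("JCAMP-DX single-spectrum blocks are read", {
  path <- withr::local_tempfile(fileext = ".jdx")
  grid <- seq(9000, 4000, by = -250)
  y <- round(sin(seq_along(grid)) + 2, 4)
  lines <- c("##TITLE=s01", "##JCAMP-DX=4.24", "##XUNITS=1/CM",
             "##XFACTOR=1", "##YFACTOR=0.0001",
             paste0("##FIRSTX=", grid[1]), paste0("##LASTX=", grid[21]),
             paste0("##NPOINTS=", 21),
             "##XYDATA=(X++(Y..Y))",
             vapply(seq(1, 21, by = 7), function(i) {
               paste(c(grid[i], round(y[i:(i + 6)] * 1e4)), collapse = " ")
             }, ""),
             "##END=")
  writeLines(lines, path)
  mp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(sample_id = "s01", level_id = 1, replicate_id = 1,
                       state = "dry", casein_conc = 0.6, nitrate_conc = 0.1,
                       water_content = NA),
            mp, row.names = FALSE)
  s <- read_spectra(path, mp, format = "jcamp", kind = "absorbance")
  expect_equal(length(s$grid), 21)
  expect_true(attr(s, "descending_input"))
  expect_equal(as.numeric(s$intensities), rev(y), tolerance = 1e-12)
})

test_that("to_absorbance applies log10(1/R) and rejects non-positive R", {
  g <- seq(4000, by = 6, length.out = 20)
  s1 <- toy_set(matrix(1, 2, 20), kind = "reflectance", grid = g,
                n_levels = 2)
  expect_equal(as.numeric(to_absorbance(s1)$intensities), rep(0, 40))
  s2 <- toy_set(matrix(0.1, 2, 20), kind = "reflectance", grid = g,
                n_levels = 2)
  a2 <- to_absorbance(s2)
  expect_equal(as.numeric(a2$intensities), rep(1, 40))
  expect_identical(a2$kind, "absorbance")
  expect_error(to_absorbance(a2), "reflectance")
  # monotone decreasing in reflectance
  r <- seq(0.05, 1, length.out = 20)
  sm <- toy_set(rbind(r, r), kind = "reflectance", grid = g, n_levels = 2)
  expect_true(all(diff(to_absorbance(sm)$intensities[1, ]) < 0))
  # construction already rejects non-positive reflectance, naming the point
  expect_error(toy_set(matrix(c(0.5, 0, rep(0.5, 38)), 2, 20),
                       kind = "reflectance", grid = g, n_levels = 2),
               "cm-1")
})

test_that("SG second derivative is exact on polynomials and matches the
          local-polyfit oracle", {
  g <- seq(4000, by = 6, length.out = 120)
  for (w in c(11, 17)) {
    half <- (w - 1) / 2
    quad <- outer(c(1, 2), g^2 / 1e4) + 3   # a * nu^2 / 1e4 + 3
    s <- toy_set(quad, grid = g, n_levels = 2)
    d2 <- second_derivative(s, w, 2)
    expect_equal(length(d2$grid), 120 - 2 * half)
    expect_equal(d2$intensities[1, ], rep(2e-4, ncol(d2$intensities)),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(d2$intensities[2, ], rep(4e-4, ncol(d2$intensities)),
                 tolerance = 1e-10, ignore_attr = TRUE)
    lin <- outer(c(1, -2), g / 100)
    dl <- second_derivative(toy_set(lin, grid = g, n_levels = 2), w, 2)
    expect_lt(max(abs(dl$intensities)), 1e-12)
  }
  set.seed(11)
  y <- rnorm(120)
  s <- toy_set(rbind(y, y), grid = g, n_levels = 2)
  d2 <- second_derivative(s, 17, 2)
  oracle <- sg_d2_oracle(g, y, 17)
  expect_equal(d2$intensities[1, ], oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
  # linearity
  y2 <- rnorm(120)
  da <- second_derivative(toy_set(rbind(y, y2), grid = g, n_levels = 2),
                          11, 2)$intensities
  dc <- second_derivative(toy_set(rbind(3 * y - 5 * y2, y), grid = g,
                                  n_levels = 2), 11, 2)$intensities
  expect_equal(dc[1, ], 3 * da[1, ] - 5 * da[2, ], tolerance = 1e-10)
})

test_that("SG second derivative validates window, polyorder and grid", {
  g <- seq(4000, by = 6, length.out = 40)
  s <- toy_set(matrix(rnorm(80), 2), grid = g, n_levels = 2)
  expect_error(second_derivative(s, 10, 2), "odd")
  expect_error(second_derivative(s, 3, 3), "exceed")
  expect_error(second_derivative(s, 41, 2), "grid length")
  gn <- c(seq(4000, by = 6, length.out = 20),
          seq(4140, by = 9, length.out = 20))
  expect_error(second_derivative(toy_set(matrix(rnorm(80), 2), grid = gn,
                                         n_levels = 2), 11, 2),
               "uniform")
})

test_that("restrict_region keeps the closed interval, composes, errors on
          empty overlap", {
  g <- seq(4000, 9000, by = 6)
  s <- toy_set(matrix(rnorm(2 * length(g)), 2), grid = g, n_levels = 2)
  r <- restrict_region(s, 4000, 7500)
  expect_true(all(r$grid <= 7500) && all(r$grid >= 4000))
  expect_true(max(r$grid) + 6 > 7500)  # boundary point retained
  expect_equal(restrict_region(s, 4000, 9000)$intensities, s$intensities)
  # nested restriction equals the inner one
  expect_equal(restrict_region(restrict_region(s, 4200, 8000), 5000, 6000),
               restrict_region(s, 5000, 6000))
  expect_error(restrict_region(s, 100, 200), "overlap")
  expect_error(restrict_region(s, 5000, 4000), "lo must be below hi")
})

test_that("replicate variability equals per-column sd/mean with undefined
          flags", {
  g <- seq(4000, by = 6, length.out = 50)
  base <- sin(g / 200)
  ident <- toy_set(matrix(rep(base, 20), 20, byrow = TRUE), grid = g,
                   n_levels = 20)
  v <- replicate_variability(ident)
  expect_equal(v$cv[!is.na(v$cv)],
               rep(0, sum(!is.na(v$cv))), ignore_attr = TRUE)

  two <- toy_set(rbind(rep(1, 50), rep(3, 50)), grid = g, n_levels = 2)
  v2 <- replicate_variability(two)
  expect_equal(v2$cv, rep(sqrt(2) / 2, 50), ignore_attr = TRUE)

  set.seed(5)
  m <- matrix(rnorm(20 * 50, mean = 2), 20)
  s <- toy_set(m, grid = g, n_levels = 20)
  v3 <- replicate_variability(s)
  expect_equal(v3$cv, apply(m, 2, sd) / colMeans(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(replicate_variability(toy_set(m[1, , drop = FALSE],
                                             grid = g)),
               "at least 2")
})

test_that("average_replicates collapses levels to per-group means", {
  g <- seq(4000, by = 6, length.out = 30)
  set.seed(3)
  m <- matrix(rnorm(9 * 6 * 30), 54)
  s <- toy_set(m, grid = g, n_levels = 9, n_reps = 6)
  a <- average_replicates(s)
  expect_equal(n_spectra(a), 9)
  expect_equal(a$samples$n_averaged, rep(6L, 9))
  for (l in c(1, 5, 9))
    expect_equal(a$intensities[l, ],
                 colMeans(m[s$samples$level_id == l, ]),
                 tolerance = 1e-14, ignore_attr = TRUE)
  single <- toy_set(m[1:9, ], grid = g, n_levels = 9)
  expect_equal(average_replicates(single)$intensities, single$intensities,
               ignore_attr = TRUE)
})
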