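make_toy_series <- function(dynamic, levels = seq_len(nrow(dynamic)),
                            grid = seq(4000, by = 6,
                                       length.out = ncol(dynamic))) {
  dynamic <- sweep(dynamic, 2, colMeans(dynamic))
  structure(list(grid = grid, dynamic = dynamic, levels = levels,
                 reference = colMeans(dynamic), analyte = "casein"),
            class = "perturbation_series")
}

test_that("make_series centers columns and orders by concentration", {
  g <- seq(4000, by = 6, length.out = 40)
  set.seed(1)
  m <- matrix(rnorm(9 * 40), 9)
  s <- toy_set(m, grid = g, n_levels = 9)
  ser <- make_series(s, "casein")
  expect_lt(max(abs(colMeans(ser$dynamic))),
            1e-12 * max(abs(ser$dynamic)))
  expect_equal(ser$levels, sort(s$samples$casein_conc))
  expect_equal(ser$reference, colMeans(m), ignore_attr = TRUE)
  # nitrate ordering permutes the rows to ascending nitrate
  ser2 <- make_series(s, "nitrate")
  expect_equal(ser2$levels, sort(s$samples$nitrate_conc))

  ident <- toy_set(rbind(m[1, ], m[1, ]), grid = g, n_levels = 2)
  expect_equal(max(abs(make_series(ident)$dynamic)), 0)
  expect_error(make_series(toy_set(m, grid = g, n_levels = 3, n_reps = 3)),
               "average")
  expect_error(make_series(toy_set(m[1, , drop = FALSE], grid = g)),
               "at least 2")
})

test_that("synchronous map matches the hand example and the summation
          oracle", {
  a <- make_toy_series(matrix(c(1, -1), 2, 1))
  b <- make_toy_series(matrix(c(2, -2), 2, 1), levels = a$levels)
  expect_equal(as.numeric(synchronous(a, b)), 4)

  set.seed(2)
  A <- matrix(rnorm(9 * 40), 9)
  B <- matrix(rnorm(9 * 25), 9)
  sa <- make_toy_series(A)
  sb <- make_toy_series(B, levels = sa$levels)
  expect_lt(max(abs(synchronous(sa, sb) - sync_oracle(sa$dynamic,
                                                      sb$dynamic))),
            1e-12)
  # homo-spectral: symmetric, diagonal = per-wavenumber variance
  phi <- synchronous(sa, sa)
  expect_equal(phi, t(phi))
  expect_equal(diag(phi), apply(sa$dynamic, 2, var), ignore_attr = TRUE)
  # positive semidefinite
  ev <- eigen(phi, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(abs(phi)))
})

test_that("asynchronous map matches the Hilbert-Noda oracle with the
          expected symmetries", {
  set.seed(3)
  A <- matrix(rnorm(9 * 30), 9)
  B <- matrix(rnorm(9 * 20), 9)
  sa <- make_toy_series(A)
  sb <- make_toy_series(B, levels = sa$levels)
  psi <- asynchronous(sa, sb)
  expect_lt(max(abs(psi - async_oracle(sa$dynamic, sb$dynamic))), 1e-12)
  # homo-spectral: antisymmetric with zero diagonal
  ph <- asynchronous(sa, sa)
  expect_equal(ph, -t(ph))
  expect_equal(max(abs(diag(ph))), 0)
  # fully in-phase series: every trace shares one level pattern, so the
  # asynchronous (out-of-phase) map vanishes identically
  s <- rnorm(9)
  sa1 <- make_toy_series(outer(s, rnorm(30)))
  sb1 <- make_toy_series(outer(s, rnorm(20)), levels = sa1$levels)
  expect_lt(max(abs(asynchronous(sa1, sb1))),
            1e-12 * max(abs(synchronous(sa1, sb1))))
})

test_that("2D maps are bilinear, swap-transpose, and ignore level-constant
          offsets", {
  set.seed(4)
  A <- matrix(rnorm(7 * 15), 7); A2 <- matrix(rnorm(7 * 15), 7)
  B <- matrix(rnorm(7 * 12), 7)
  sa <- make_toy_series(A); sb <- make_toy_series(B, levels = sa$levels)
  sa2 <- make_toy_series(A2)
  smix <- make_toy_series(2 * A - 3 * A2)
  expect_equal(synchronous(smix, sb),
               2 * synchronous(sa, sb) - 3 * synchronous(sa2, sb),
               tolerance = 1e-12)
  expect_equal(asynchronous(smix, sb),
               2 * asynchronous(sa, sb) - 3 * asynchronous(sa2, sb),
               tolerance = 1e-12)
  expect_equal(synchronous(sb, sa), t(synchronous(sa, sb)))
  expect_equal(asynchronous(sb, sa), -t(asynchronous(sa, sb)))
  # adding a level-independent constant spectrum changes nothing
  shift <- make_toy_series(A + matrix(rnorm(15), 7, 15, byrow = TRUE))
  expect_equal(synchronous(shift, sb), synchronous(sa, sb),
               tolerance = 1e-10)
  expect_equal(asynchronous(shift, sb), asynchronous(sa, sb),
               tolerance = 1e-10)
  # misalignment guards
  expect_error(synchronous(sa, make_toy_series(B[1:6, ])), "level counts")
  expect_error(synchronous(sa, make_toy_series(B, levels = rev(sa$levels))),
               "misaligned")
})

test_that("the five NIR analysis regions partition the working grid", {
  g <- restrict_region(
    second_derivative(toy_set(matrix(1:2 %o% nir_grid()^0, 2),
                              grid = nir_grid(), n_levels = 2), 11, 2),
    4000, 7500)$grid
  reg <- split_nir_regions(g)
  expect_equal(nrow(reg), 5)
  covered <- unlist(mapply(seq, reg$start, reg$end, SIMPLIFY = FALSE))
  expect_equal(sort(covered), seq_along(g))   # disjoint and exhaustive
  expect_equal(anyDuplicated(covered), 0)
  # snapped bounds close to the nominal boundaries
  expect_lt(max(abs(reg$hi_cm[1] - 7500)), 6)
  expect_lt(abs(reg$lo_cm[5] - min(g)), 1e-9)

  # grid exactly at the boundaries puts edges on those points
  ge <- seq(4000, 7500, by = 5)
  rege <- split_nir_regions(ge)
  expect_true(all(c(7500, 6890, 4000) %in%
                    c(rege$hi_cm, rege$lo_cm)))
  expect_error(split_nir_regions(seq(5000, 6000, by = 5)), "cover")
  expect_error(split_nir_regions(sample(g)), "ascending")
})

test_that("hotspot extraction keys on the synchronous map per region", {
  g1 <- seq(4010, 7500, by = 6)
  g2 <- seq(800, 4000, by = 4)
  sync <- matrix(0, length(g1), length(g2))
  i_star <- which.min(abs(g1 - 5000))
  j_star <- which.min(abs(g2 - 1650))
  sync[i_star, j_star] <- 1
  map <- structure(list(axis1 = g1, axis2 = g2, sync = sync,
                        async = sync * 0, m = 9), class = "twod_map")
  hs <- twod_hotspots(map, c(1500, 1700), q = 0.001)
  expect_true(i_star %in% hs)
  # only regions containing signal contribute beyond ties at zero
  expect_equal(twod_hotspots(map, c(1500, 1700), q = 1), seq_along(g1))
  expect_error(twod_hotspots(map, list(), q = 0.25), "at least one")
  expect_error(twod_hotspots(map, c(100, 200)), "overlap")
})

test_that("hotspots recover the generator's casein band centers", {
  prep <- tiny_d2_set(n_levels = 9, n_reps = 1, seed = 9)
  mir <- generate_mir_set(design_spec(n_levels = 9, n_replicates = 1,
                                      noise_sd = 0, scatter_sd = 0,
                                      baseline_sd = 0, seed = 10))
  nir_ser <- make_series(average_replicates(prep$d2), "casein")
  mir_ser <- make_series(average_replicates(
    second_derivative(mir$set, 17, 2)), "casein")
  map <- twod_map(nir_ser, mir_ser)
  hs <- twod_hotspots(map, c(1500, 1700), q = 0.25)
  truth <- prep$truth$band_centers$casein
  in_grid <- truth$center >= min(prep$d2$grid) &
    truth$center <= max(prep$d2$grid)
  idx <- vapply(truth$center[in_grid],
                function(ct) which.min(abs(prep$d2$grid - ct)), 0L)
  expect_true(all(idx %in% hs))
})
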