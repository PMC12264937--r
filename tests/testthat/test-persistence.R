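test_that("facet barcodes record birth and covering death", {
  two <- rips_filtration(point_cloud(rbind(c(0, 0, 0), c(1.7, 0, 0))), 2, 3)
  bc <- facet_barcode(two, 1)
  expect_equal(bc$dimension, c(0L, 0L, 1L))
  expect_equal(bc$birth, c(0, 0, 1.7))
  expect_equal(bc$death, c(1.7, 1.7, Inf))

  # equilateral triangle: edges are covered at their own entry value, so no
  # dim-1 facet episode persists (tolerance absorbs floating-point ties)
  tri <- rips_filtration(point_cloud(rbind(c(0, 0, 0), c(1, 0, 0),
                                           c(0.5, sqrt(3) / 2, 0))), 3, 3)
  bt <- facet_barcode(tri, 2)
  d0 <- bt[bt$dimension == 0, ]
  expect_equal(nrow(d0), 3L)
  expect_equal(d0$death, rep(1, 3), tolerance = 1e-9)
  d1 <- bt[bt$dimension == 1, ]
  expect_true(all(d1$death - d1$birth < 1e-9))
  d2 <- bt[bt$dimension == 2, ]
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$birth, 1, tolerance = 1e-9)
  expect_equal(d2$death, Inf)

  expect_error(facet_barcode(two, 2), "max_dim")
})

test_that("C60 facet barcode matches the fullerene bond structure", {
  filt <- rips_filtration(make_c60(), 3, 3)
  bc <- facet_barcode(filt, 2)
  d0 <- bc[bc$dimension == 0, ]
  expect_equal(nrow(d0), 60L)
  expect_equal(d0$death, rep(1.367, 60), tolerance = 1e-3)
  d1 <- bc[bc$dimension == 1, ]
  dbl <- d1[abs(d1$birth - 1.367) < 1e-3, ]
  sgl <- d1[abs(d1$birth - 1.453) < 1e-3, ]
  expect_equal(nrow(dbl), 30L)
  expect_equal(nrow(sgl), 60L)
  expect_equal(dbl$death, rep(2.443, 30), tolerance = 1e-3)
  phi <- (1 + sqrt(5)) / 2
  expect_equal(sgl$death, rep(phi * 1.453, 60), tolerance = 1e-9)
})

test_that("facet persistence Betti numbers count bars alive on [r, r']", {
  filt <- rips_filtration(make_c60(), 3, 3)
  bc <- facet_barcode(filt, 2)
  expect_equal(facet_persistence_betti(bc, 1, 1.4, 2.0), 30L)
  expect_equal(facet_persistence_betti(bc, 0, 1.0, 1.5), 0L)
  tri <- rips_filtration(point_cloud(rbind(c(0, 0, 0), c(1, 0, 0),
                                           c(0.5, sqrt(3) / 2, 0))), 3, 3)
  expect_equal(facet_persistence_betti(facet_barcode(tri, 2), 2, 1, 1), 1L)
  expect_error(facet_persistence_betti(bc, 0, 2, 1), "r must not exceed")
  # non-increasing in r'
  for (rp in c(1.5, 2.0, 2.5)) {
    expect_lte(facet_persistence_betti(bc, 1, 1.4, rp),
               facet_persistence_betti(bc, 1, 1.4, 1.5))
  }
})

test_that("grid summaries divide Betti numbers by the scale", {
  filt <- rips_filtration(make_c60(), 3, 3)
  bc <- facet_barcode(filt, 2)
  s1 <- summarize_on_grid(bc, 1.0)
  expect_equal(unname(s1$beta["dim0", 1]), 60L)
  expect_equal(unname(s1$beta_rate["dim0", 1]), 60)
  # at r = 2.0 all 90 bond bars are still facets (single bonds die at the
  # pentagon diagonal 2.351 A); by 2.4 only the 30 double-bond bars remain
  s2 <- summarize_on_grid(bc, 2.0)
  expect_equal(unname(s2$beta["dim1", 1]), 90L)
  expect_equal(unname(s2$beta_rate["dim1", 1]), 45)
  s3 <- summarize_on_grid(bc, 2.4)
  expect_equal(unname(s3$beta["dim1", 1]), 30L)
  expect_equal(unname(s3$beta_rate["dim1", 1]), 12.5)
  empty <- bc[bc$dimension > 99, ]
  attr(empty, "cap") <- attr(bc, "cap")
  expect_true(all(summarize_on_grid(empty, c(1, 2))$beta == 0L))
  expect_error(summarize_on_grid(bc, c(-1, 1)), "positive")
})

test_that("reduced homology ranks match known complexes", {
  hollow <- make_complex_from_facets(list(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(reduced_homology_rank(hollow, 1), 1L)
  expect_equal(reduced_homology_rank(hollow, 0), 0L)
  expect_equal(reduced_homology_rank(make_complex_from_facets(list(1, 2)), 0), 1L)
  full <- make_complex_from_facets(list(c(1, 2, 3)))
  expect_equal(reduced_homology_rank(full, 1), 0L)
  expect_equal(reduced_homology_rank(full, 0), 0L)
  # boundary of the 3-simplex is a 2-sphere
  sphere <- make_complex_from_facets(utils::combn(4, 3, simplify = FALSE))
  expect_equal(reduced_homology_rank(sphere, 2), 1L)
  expect_equal(reduced_homology_rank(sphere, 1), 0L)
})

test_that("persistent homology ranks track merging and cycles", {
  two <- rips_filtration(point_cloud(rbind(c(0, 0, 0), c(1, 0, 0))), 2, 3)
  expect_equal(persistent_homology_rank(two, 0, 0.5, 1.5), 0L)
  expect_equal(persistent_homology_rank(two, 0, 0.5, 0.5), 1L)
  square <- rips_filtration(point_cloud(rbind(c(0, 0, 0), c(1, 0, 0),
                                              c(1, 1, 0), c(0, 1, 0))),
                            2, 1.2)  # diagonal sqrt(2) beyond the cap
  expect_equal(persistent_homology_rank(square, 1, 1, 1.2), 1L)
})

test_that("persistent graded Betti numbers follow the multiscale Hochster formula", {
  iso2 <- rips_filtration(point_cloud(rbind(c(0, 0, 0), c(9, 0, 0))), 2, 3)
  expect_equal(persistent_graded_betti(iso2, 1, 1, 0.5, 0.5), 1L)
  # static hollow triangle: edges present, the 2-face genuinely absent
  hollow <- filtration(vertices = 1:3,
                       simplices = list(1, 2, 3, c(1, 2), c(2, 3), c(1, 3)),
                       values = c(0, 0, 0, 1, 1, 1), max_dim = 2, cap = 3)
  expect_equal(persistent_graded_betti(hollow, 1, 2, 1, 1), 1L)
  expect_equal(persistent_graded_betti(hollow, 1, 1, 1, 1), 0L)
  two <- rips_filtration(point_cloud(rbind(c(0, 0, 0), c(1, 0, 0))), 1, 3)
  expect_equal(persistent_graded_betti(two, 1, 1, 0.5, 1.5), 0L)
})

test_that("diagonal graded Betti numbers match the static Hochster evaluation", {
  set.seed(71)
  for (rep in 1:6) {
    n <- sample(4:6, 1)
    filt <- random_filtration(n)
    r <- stats::quantile(filt$values, stats::runif(1, 0.3, 0.9))
    cx <- complex_at(filt, r)
    for (i in 1:(n - 1)) {
      for (j in 1:min(3, n - i)) {
        expect_equal(persistent_graded_betti(filt, i, j, r, r),
                     hochster_static(cx, i, j),
                     info = sprintf("n=%d i=%d j=%d", n, i, j))
      }
    }
  }
})

test_that("persistent h- and f-vectors reduce to the classical ones at r = r'", {
  hollow <- filtration(vertices = 1:3,
                       simplices = list(1, 2, 3, c(1, 2), c(2, 3), c(1, 3)),
                       values = c(0, 0, 0, 1, 1, 1), max_dim = 2, cap = 3)
  expect_equal(persistent_h_vector(hollow, 1, 1), c(1, 1, 1))
  expect_equal(persistent_f_vector(hollow, 1, 1), c(3, 3))
  tri <- rips_filtration(point_cloud(rbind(c(0, 0, 0), c(1, 0, 0),
                                           c(0.5, sqrt(3) / 2, 0))), 2, 3)
  expect_equal(persistent_h_vector(tri, 1, 1), c(1, 0, 0, 0))
  expect_equal(persistent_f_vector(tri, 1, 1), c(3, 3, 1))
  iso3 <- rips_filtration(point_cloud(rbind(c(0, 0, 0), c(9, 0, 0),
                                            c(0, 9, 0))), 2, 3)
  expect_equal(persistent_h_vector(iso3, 0.5, 0.5), c(1, 2))
  expect_equal(persistent_f_vector(iso3, 0.5, 0.5), c(3))
  expect_equal(persistent_f_vector(iso3, 0.5, 0.5),
               f_vector(complex_at(iso3, 0.5)))
})

test_that("the boundary relation ties graded Betti numbers to homology ranks", {
  set.seed(81)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    filt <- random_filtration(n)
    rs <- sort(stats::runif(2, 0.2, max(filt$values)))
    for (i in 1:(n - 1)) {
      j <- n - i
      if (j < 1) next
      expect_equal(persistent_graded_betti(filt, i, j, rs[1], rs[2]),
                   persistent_homology_rank(filt, n - i - 1L, rs[1], rs[2]),
                   info = sprintf("n=%d i=%d", n, i))
    }
  }
})

test_that("barcode counts equal brute-force snapshot facet intersections", {
  set.seed(91)
  for (rep in 1:5) {
    filt <- random_filtration(sample(5:8, 1))
    bc <- facet_barcode(filt, 2)
    grid <- stats::quantile(filt$values[filt$values > 0], c(0.2, 0.5, 0.8))
    for (a in seq_along(grid)) for (b in a:length(grid)) {
      for (i in 0:2) {
        expect_equal(facet_persistence_betti(bc, i, grid[a], grid[b]),
                     snapshot_facet_betti(filt, i, grid[a], grid[b]))
      }
    }
  }
})

test_that("barcodes export as TSV with inf deaths", {
  two <- rips_filtration(point_cloud(rbind(c(0, 0, 0), c(1.7, 0, 0))), 2, 3)
  bc <- facet_barcode(two, 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  barcode_to_tsv(bc, path)
  tab <- utils::read.delim(path, colClasses = "character")
  expect_equal(nrow(tab), 3L)
  expect_true("inf" %in% tab$death)
})
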