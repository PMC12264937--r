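test_that("pair enumeration reproduces the interaction-type counts", {
  expect_equal(nrow(enumerate_pairs("ES", FALSE)), 40L)
  es <- enumerate_pairs("ES", TRUE)
  expect_equal(nrow(es), 138L)
  expect_equal(sum(es$interaction == "P-L"), 40L)
  expect_equal(sum(es$interaction == "M-P"), 28L)
  expect_equal(sum(es$interaction == "M-L"), 70L)
  cs <- enumerate_pairs("CS", TRUE)
  expect_equal(nrow(cs), 138L)
  expect_setequal(unique(cs$side_a[cs$interaction == "P-L"]),
                  c("H", "U", "N", "P"))
  # deterministic ordering
  expect_identical(es, enumerate_pairs("ES", TRUE))
})

test_that("atom grouping selects by element, category and role", {
  at <- rbind(
    data.frame(element = rep("C", 5), x = 1:5, y = 0, z = 0,
               residue = c("GLY", "GLY", "ALA", "SER", "LYS"),
               role = "protein"),
    data.frame(element = c("C", "C", "C", "O"), x = 0, y = 1:4, z = 0,
               residue = "", role = "ligand"),
    data.frame(element = "Zn", x = 0, y = 0, z = 2, residue = "",
               role = "metal"))
  mc <- molecular_complex(at, "grp")
  g <- group_atoms(mc, list(side_a = "C", side_b = "C", interaction = "P-L"), "ES")
  expect_equal(nrow(g$a$coords), 5L)
  expect_equal(nrow(g$b$coords), 3L)
  gh <- group_atoms(mc, list(side_a = "H", side_b = "O", interaction = "P-L"), "CS")
  expect_equal(nrow(gh$a$coords), 3L)  # GLY, GLY, ALA
  expect_equal(nrow(gh$b$coords), 1L)
  gm <- group_atoms(mc, list(side_a = "Mg", side_b = "O", interaction = "M-L"), "ES")
  expect_equal(nrow(gm$a$coords), 0L)
  expect_equal(nrow(gm$b$coords), 1L)
})

test_that("pair feature segments have fixed layout and zero-fill", {
  grid <- seq(1, 12, 0.5)
  emptyc <- point_cloud(matrix(numeric(0), ncol = 3))
  seg <- pair_features(emptyc, emptyc, grid)
  expect_equal(length(seg), 23 * 4 * 2)
  expect_true(all(seg == 0))

  c60 <- make_c60()
  seg2 <- pair_features(c60, emptyc, 1.0)
  # rips_union: all 60 vertices are facets below bond length; bipartite:
  # all 60 vertices isolated
  expect_equal(seg2, c(60, 0, 60, 0, 60, 0, 60, 0))
})

test_that("fast facet statistics agree with the generic barcode route", {
  set.seed(101)
  grid <- c(0.4, 0.8, 1.2, 1.6)
  for (rep in 1:5) {
    a <- point_cloud(random_points(sample(3:6, 1)))
    b <- point_cloud(random_points(sample(2:5, 1)))
    seg <- pair_features(a, b, grid)
    # generic route: full filtrations + barcode counting
    rips <- facet_barcode(rips_filtration(
      point_cloud(rbind(a$coords, b$coords)), 2, max(grid)), 1)
    bip <- facet_barcode(bipartite_filtration(a, b, max(grid)), 1)
    expected <- c(
      as.vector(vapply(grid, function(r) {
        b0 <- facet_persistence_betti(rips, 0, r, r)
        b1 <- facet_persistence_betti(rips, 1, r, r)
        c(b0, b1, b0 / r, b1 / r)
      }, numeric(4))),
      as.vector(vapply(grid, function(r) {
        b0 <- facet_persistence_betti(bip, 0, r, r)
        b1 <- facet_persistence_betti(bip, 1, r, r)
        c(b0, b1, b0 / r, b1 / r)
      }, numeric(4))))
    expect_equal(seg, expected)
  }
})

test_that("feature vectors have schema-determined length and offsets", {
  expect_equal(feature_schema("ES", FALSE)$length, 7360L)
  expect_equal(feature_schema("ES", TRUE)$length, 40L * 184L + 98L * 232L)
  expect_equal(feature_schema("CS", TRUE)$length, 30096L)

  mc <- pocket_atoms(make_synthetic_pocket(30, 8, FALSE, 5))
  v <- featurize_complex(mc, "ES")
  expect_equal(length(v), 7360L)
  expect_true(all(is.finite(v)) && all(v >= 0))

  mcm <- pocket_atoms(make_synthetic_pocket(30, 8, TRUE, 5))
  vm <- featurize_complex(mcm, "ES")
  expect_equal(length(vm), 30096L)

  # no ligand -> error
  noL <- molecular_complex(mc$atoms[mc$atoms$role == "protein", ], "p")
  expect_error(featurize_complex(noL, "ES"), "no ligand")
})

test_that("features are invariant to atom order and rigid motions", {
  mc <- pocket_atoms(make_synthetic_pocket(25, 8, FALSE, 9))
  v <- featurize_complex(mc, "ES")
  perm <- sample(nrow(mc$atoms))
  vperm <- featurize_complex(
    molecular_complex(mc$atoms[perm, ], mc$identifier), "ES")
  expect_equal(vperm, v, ignore_attr = TRUE)

  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- mc$atoms
  xyz <- as.matrix(rot[, c("x", "y", "z")]) %*% R
  rot$x <- xyz[, 1] + 5; rot$y <- xyz[, 2] - 2; rot$z <- xyz[, 3] + 1
  vrot <- featurize_complex(molecular_complex(rot, mc$identifier), "ES")
  expect_equal(vrot, v, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("removing one element touches only that element's pair blocks", {
  mc <- pocket_atoms(make_synthetic_pocket(30, 10, FALSE, 13))
  stopifnot(any(mc$atoms$element == "N" & mc$atoms$role == "protein"))
  v <- featurize_complex(mc, "ES")
  drop <- mc$atoms[!(mc$atoms$element == "N" & mc$atoms$role == "protein"), ]
  v2 <- featurize_complex(molecular_complex(drop, "dropN"), "ES")
  touched <- grepl("^P-L\\.N\\.", names(v))
  expect_equal(v2[!touched], v[!touched], ignore_attr = TRUE)
  # with the protein side empty there are no cross edges left
  expect_true(all(v2[touched & grepl("\\.b1(_rate)?$", names(v)) &
                       grepl("\\.bipartite\\.", names(v))] == 0))
  # a pair absent on both sides contributes an all-zero block
  absent <- mc$atoms$element == "I"
  stopifnot(!any(absent))
  expect_true(all(v[grepl("^P-L\\.[CNOS]\\.I\\.", names(v)) &
                      grepl("\\.b1(_rate)?$", names(v)) &
                      grepl("\\.bipartite\\.", names(v))] == 0))
})

test_that("rate features equal the Betti features divided by r", {
  mc <- pocket_atoms(make_synthetic_pocket(20, 6, FALSE, 17))
  v <- featurize_complex(mc, "ES")
  nm <- names(v)
  for (d in c("b0", "b1")) {
    base <- v[grepl(paste0("\\.", d, "$"), nm)]
    rate <- v[grepl(paste0("\\.", d, "_rate$"), nm)]
    r <- as.numeric(sub(".*\\.r([0-9.]+)\\..*", "\\1",
                        nm[grepl(paste0("\\.", d, "$"), nm)]))
    expect_equal(unname(rate), unname(base / r))
    expect_true(all(base == floor(base)))  # integer counts
  }
})

test_that("feature CSV round trips with its schema sidecar", {
  schema <- feature_schema("ES", FALSE)
  mc <- pocket_atoms(make_synthetic_pocket(15, 6, FALSE, 23))
  v <- featurize_complex(mc, "ES")
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(rbind(v, v), path, schema, ids = c("a", "b"))
  expect_true(file.exists(paste0(path, ".schema.json")))
  back <- read_feature_csv(path, schema)
  expect_equal(back$ids, c("a", "b"))
  expect_equal(unname(back$x[1, ]), as.numeric(v))
  expect_error(read_feature_csv(path, feature_schema("ES", TRUE)),
               "column count")
})
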