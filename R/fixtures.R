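# Deterministic synthetic inputs: parametric C60 fullerene, random
# binding-pocket-like complexes, labeled regression datasets.

# run code under a locally seeded RNG without touching the global stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Parametric C60 fullerene point cloud
#'
#' Builds the 60-atom truncated icosahedron by truncating a regular
#' icosahedron: with pentagon-edge (single bond) length `s` and
#' hexagon-hexagon (double bond) length `d`, the icosahedron edge is
#' `a = 2 s + d` and each edge carries two atoms at fractions `t` and
#' `1 - t` with `t = s / a`. The 12 pentagons (around the truncated
#' vertices) then have side exactly `s` and the 30 edge-centre segments
#' length exactly `d`. Defaults are the fullerene bond lengths 1.453 and
#' 1.367 Angstrom.
#'
#' @param single_bond pentagon-edge bond length (A)
#' @param double_bond hexagon-hexagon bond length (A)
#' @return a `point_cloud` of 60 carbon atoms, with attributes `pentagons`
#'   (12 index vectors of length 5) and `hexagons` (20 index vectors of
#'   length 6) identifying the faces
#' @export
make_c60 <- function(single_bond = 1.453, double_bond = 1.367) {
  if (single_bond <= 0 || double_bond <= 0) stop("bond lengths must be positive")
  phi <- (1 + sqrt(5)) / 2
  base <- rbind(
    c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi), c(0, -1, -phi),
    c(1, phi, 0), c(1, -phi, 0), c(-1, phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  a <- 2 * single_bond + double_bond
  ico <- base * (a / 2)  # icosahedron edge length 2 before scaling
  DI <- as.matrix(stats::dist(ico))
  edges <- which(upper.tri(DI) & abs(DI - a) < 1e-9 * a, arr.ind = TRUE)
  stopifnot(nrow(edges) == 30L)
  t <- single_bond / a
  pts <- matrix(0, nrow = 60L, ncol = 3L)
  # atom 2k-1 sits nearer edge endpoint u, atom 2k nearer endpoint v
  for (k in seq_len(nrow(edges))) {
    u <- ico[edges[k, 1L], ]; v <- ico[edges[k, 2L], ]
    pts[2L * k - 1L, ] <- u + t * (v - u)
    pts[2L * k, ] <- v + t * (u - v)
  }
  pentagons <- lapply(seq_len(12L), function(w) {
    near_u <- which(edges[, 1L] == w)
    near_v <- which(edges[, 2L] == w)
    c(2L * near_u - 1L, 2L * near_v)
  })
  stopifnot(all(lengths(pentagons) == 5L))
  adj <- abs(DI - a) < 1e-9 * a
  faces <- list()
  for (i in 1:10) for (j in (i + 1):11) for (k in (j + 1):12) {
    if (adj[i, j] && adj[j, k] && adj[i, k]) faces[[length(faces) + 1L]] <- c(i, j, k)
  }
  stopifnot(length(faces) == 20L)
  hexagons <- lapply(faces, function(f) {
    es <- which(edges[, 1L] %in% f & edges[, 2L] %in% f)
    sort(c(2L * es - 1L, 2L * es))
  })
  pc <- point_cloud(pts, rep("C", 60L))
  attr(pc, "pentagons") <- pentagons
  attr(pc, "hexagons") <- hexagons
  pc
}

.sample_in_ball <- function(n, radius, r_min = 0) {
  dir <- matrix(stats::rnorm(3 * n), ncol = 3L)
  dir <- dir / sqrt(rowSums(dir^2))
  rad <- (stats::runif(n, (r_min / radius)^3, 1))^(1 / 3) * radius
  dir * rad
}

#' Random binding-pocket-like molecular complex
#'
#' Emulates a pocket: ligand atoms inside a 5 A ball at the origin (the
#' first ligand atom pinned to the origin so every generated atom respects
#' the collection cutoffs), protein atoms in a shell 3-11.9 A out with
#' elements from {C, N, O, S} and residues from the 20 standard codes, and
#' optionally one metal atom within 14.5 A with element frequencies
#' following the typical metalloprotein abundances (Zn most common).
#' Deterministic per seed.
#'
#' @param n_protein,n_ligand atom counts (`n_ligand >= 1`)
#' @param with_metal add a metal atom?
#' @param seed integer seed
#' @return a `molecular_complex`
#' @export
make_synthetic_pocket <- function(n_protein, n_ligand, with_metal = FALSE,
                                  seed = 1L) {
  if (n_ligand < 1L) stop("need at least one ligand atom")
  if (n_protein < 0L) stop("n_protein must be >= 0")
  .with_seed(seed, {
    lig_xyz <- rbind(c(0, 0, 0),
                     if (n_ligand > 1L) .sample_in_ball(n_ligand - 1L, 5))
    lig <- data.frame(
      element = sample(.LIGAND_ELEMENTS, n_ligand, replace = TRUE,
                       prob = c(.40, .12, .20, .03, .02, .05, .05, .02, .01, .10)),
      x = lig_xyz[, 1L], y = lig_xyz[, 2L], z = lig_xyz[, 3L],
      residue = "", role = "ligand", stringsAsFactors = FALSE)
    rows <- lig
    if (n_protein > 0L) {
      pro_xyz <- .sample_in_ball(n_protein, 11.9, r_min = 3)
      pro <- data.frame(
        element = sample(.PROTEIN_ELEMENTS, n_protein, replace = TRUE,
                         prob = c(.62, .16, .20, .02)),
        x = pro_xyz[, 1L], y = pro_xyz[, 2L], z = pro_xyz[, 3L],
        residue = sample(unlist(.RESIDUE_CATEGORIES), n_protein, replace = TRUE),
        role = "protein", stringsAsFactors = FALSE)
      rows <- rbind(rows, pro)
    }
    if (with_metal) {
      m_xyz <- .sample_in_ball(1L, 14.5, r_min = 3)
      met <- data.frame(
        element = sample(.METAL_ELEMENTS, 1L,
                         prob = c(1389, 614, 319, 516, 48, 60, 63)),
        x = m_xyz[1L], y = m_xyz[2L], z = m_xyz[3L],
        residue = "", role = "metal", stringsAsFactors = FALSE)
      rows <- rbind(rows, met)
    }
    molecular_complex(rows, sprintf("synthetic-pocket-%d", seed))
  })
}

#' Synthetic regression dataset with known sparse linear signal
#'
#' Generates seeded pockets of varying sizes, featurizes them, and builds
#' labels as a fixed sparse linear combination of informative features plus
#' Gaussian noise. The informative features are the highest-variance
#' columns of the feature matrix (large, smoothly varying count features);
#' generating weights, indices and noise level are recorded in the
#' metadata.
#'
#' @param n_samples number of complexes (>= 10)
#' @param seed integer seed
#' @param sigma label noise standard deviation (default 0.5)
#' @param scheme featurization scheme
#' @param n_informative number of informative features (default 12)
#' @return list with `x` (feature matrix), `y` (labels), and `meta`
#'   (weights, indices, sigma, seed, schema_id)
#' @export
make_regression_dataset <- function(n_samples, seed = 1L, sigma = 0.5,
                                    scheme = "ES", n_informative = 12L) {
  if (n_samples < 10L) stop("need at least 10 samples")
  .with_seed(seed, {
    np <- sample(20:60, n_samples, replace = TRUE)
    nl <- sample(5:15, n_samples, replace = TRUE)
    pocket_seeds <- sample.int(2^30, n_samples)
    noise <- stats::rnorm(n_samples, 0, 1)
    x <- t(vapply(seq_len(n_samples), function(i) {
      mc <- make_synthetic_pocket(np[i], nl[i], FALSE, pocket_seeds[i])
      as.numeric(featurize_complex(pocket_atoms(mc), scheme))
    }, numeric(feature_schema(scheme, FALSE)$length)))
    vars <- apply(x, 2L, stats::var)
    idx <- order(vars, decreasing = TRUE)[seq_len(n_informative)]
    w <- sample(c(-1, 1), n_informative, replace = TRUE) *
      stats::runif(n_informative, 0.5, 1.5)
    # scale each informative column's contribution to unit sd
    sds <- sqrt(vars[idx])
    y <- as.vector(x[, idx, drop = FALSE] %*% (w / sds)) + sigma * noise
    list(x = x, y = y,
         meta = list(weights = w, indices = idx, sigma = sigma, seed = seed,
                     schema_id = feature_schema(scheme, FALSE)$schema_id))
  })
}
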