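# Shared generators and independent oracles for the property tests.

# random point set in a box, scaled so pairwise distances spread over [0, ~2]
random_points <- function(n) {
  matrix(stats::runif(3 * n, 0, 1.2), ncol = 3)
}

# random Rips filtration with the full flag complex visible (max_dim = n - 1)
random_filtration <- function(n, cap = 3) {
  rips_filtration(point_cloud(random_points(n)), max_dim = n - 1L, cap = cap)
}

# random abstract complex: downward closure of random facets
random_complex <- function(n, n_facets = NULL) {
  if (is.null(n_facets)) n_facets <- sample(2:4, 1)
  facs <- lapply(seq_len(n_facets), function(i) {
    sample(n, sample(seq_len(min(n, 4)), 1))
  })
  facs <- c(facs, as.list(seq_len(n)))  # keep every vertex present
  make_complex_from_facets(facs)
}

# induced subcomplex of cx on vertex index set w (labels preserved as indices)
induced_subcomplex <- function(cx, w) {
  keep <- Filter(function(f) all(f %in% w), cx$faces)
  make_complex_from_facets(keep)
}

# Hochster's formula at a single scale, by the static route:
# j = 1: sum over |W| = i+1 of (#components - 1)
# j >= 2: sum over |W| = i+j of dim H~_{j-1}(Delta_W)
hochster_static <- function(cx, i, j) {
  n <- length(cx$vertices)
  if (i + j > n) return(0L)
  total <- 0L
  for (w in utils::combn(n, i + j, simplify = FALSE)) {
    sub <- induced_subcomplex(cx, w)
    total <- total + reduced_homology_rank(sub, j - 1L)
  }
  total
}

# coefficients 0..maxdeg of (h_0 + h_1 s + ... + h_d s^d) / (1 - s)^d
hilbert_series_coeffs <- function(h, d, maxdeg) {
  denom <- vapply(0:maxdeg, function(t) choose(t + d - 1, d - 1), 0)
  vapply(0:maxdeg, function(t) {
    js <- 0:min(t, length(h) - 1L)
    sum(h[js + 1L] * denom[t - js + 1L])
  }, 0)
}

# brute-force facet persistence Betti number by snapshot intersection
snapshot_facet_betti <- function(filt, i, r, r_prime) {
  fr <- facets(complex_at(filt, r))
  frp <- facets(complex_at(filt, r_prime))
  key <- function(f) paste(f, collapse = ",")
  kr <- vapply(Filter(function(f) length(f) == i + 1L, fr), key, "")
  krp <- vapply(Filter(function(f) length(f) == i + 1L, frp), key, "")
  length(intersect(kr, krp))
}

# connected components of an undirected graph given as an edge matrix
graph_components <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- comp[edges[k, 1]]; b <- comp[edges[k, 2]]
      if (a != b) {
        comp[comp == max(a, b)] <- min(a, b)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# fixed-column PDB record for fixtures
pdb_line <- function(record, serial, name, resname, chain, resseq, x, y, z,
                     element = "", altloc = " ") {
  paste0(sprintf("%-6s", record), sprintf("%5d", serial), " ",
         sprintf("%-4s", name), altloc, sprintf("%3s", resname), " ",
         chain, sprintf("%4d", resseq), "    ",
         sprintf("%8.3f%8.3f%8.3f", x, y, z),
         sprintf("%6.2f%6.2f", 1, 0), "          ",
         sprintf("%2s", element))
}

# minimal V2000 SDF block
sdf_text <- function(atoms) {
  # atoms: data.frame(element, x, y, z)
  n <- nrow(atoms)
  c("fixture", "  psrt", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L),
    vapply(seq_len(n), function(k) {
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              atoms$x[k], atoms$y[k], atoms$z[k], atoms$element[k])
    }, ""),
    "M  END", "$$$$")
}
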