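# Element-specific (ES) and category-specific (CS) persistent
# commutative-algebra featurization of binding pockets.

.GRID_PL    <- seq(1, 12, by = 0.5)   # 23 points, protein-ligand pairs
.GRID_METAL <- seq(1, 15, by = 0.5)   # 29 points, metal-involving pairs
.STATS <- c("b0", "b1", "b0_rate", "b1_rate")
.CONSTRUCTIONS <- c("rips_union", "bipartite")

#' Enumerate atom-pair specifications for a featurization scheme
#'
#' Element-specific (ES): 4 protein elements (C, N, O, S) crossed with 10
#' ligand elements give 40 protein-ligand (P-L) pairs; with metals, 7 metal
#' elements add 28 metal-protein (M-P) and 70 metal-ligand (M-L) pairs for
#' 138 in total. Category-specific (CS) replaces the protein-side element
#' tags with the 4 residue categories (H, U, N, P), with identical counts.
#' Ordering is the deterministic side-A-major product order, P-L then M-P
#' then M-L.
#'
#' @param scheme `"ES"` or `"CS"`
#' @param has_metal include metal-involving pairs?
#' @return data frame with columns `side_a`, `side_b`, `interaction`
#' @export
enumerate_pairs <- function(scheme = c("ES", "CS"), has_metal = FALSE) {
  scheme <- match.arg(scheme)
  ptags <- if (scheme == "ES") .PROTEIN_ELEMENTS else names(.RESIDUE_CATEGORIES)
  pl <- expand.grid(side_b = .LIGAND_ELEMENTS, side_a = ptags,
                    stringsAsFactors = FALSE)[, c("side_a", "side_b")]
  pl$interaction <- "P-L"
  out <- pl
  if (has_metal) {
    mp <- expand.grid(side_b = ptags, side_a = .METAL_ELEMENTS,
                      stringsAsFactors = FALSE)[, c("side_a", "side_b")]
    mp$interaction <- "M-P"
    ml <- expand.grid(side_b = .LIGAND_ELEMENTS, side_a = .METAL_ELEMENTS,
                      stringsAsFactors = FALSE)[, c("side_a", "side_b")]
    ml$interaction <- "M-L"
    out <- rbind(pl, mp, ml)
  }
  rownames(out) <- NULL
  out
}

# protein atoms matching a side tag under a scheme (element filter applied)
.protein_side <- function(at, tag, scheme) {
  pr <- at[at$role == "protein" & at$element %in% .PROTEIN_ELEMENTS, ,
           drop = FALSE]
  if (scheme == "ES") {
    pr[pr$element == tag, , drop = FALSE]
  } else {
    pr[residue_category(pr$residue) == tag, , drop = FALSE]
  }
}

#' Extract the two point clouds of an atom-pair specification
#'
#' @param mc a pocket-filtered `molecular_complex`
#' @param spec one row of [enumerate_pairs()] output (or an equivalent list
#'   with `side_a`, `side_b`, `interaction`)
#' @param scheme `"ES"` or `"CS"`
#' @return list of two `point_cloud`s (`a`, `b`); either may be empty
#' @export
group_atoms <- function(mc, spec, scheme = c("ES", "CS")) {
  scheme <- match.arg(scheme)
  at <- mc$atoms
  pick <- function(rows) point_cloud(as.matrix(rows[, c("x", "y", "z")]),
                                     rows$element)
  if (spec$interaction == "P-L") {
    a <- .protein_side(at, spec$side_a, scheme)
    b <- at[at$role == "ligand" & at$element == spec$side_b, , drop = FALSE]
  } else if (spec$interaction == "M-P") {
    a <- at[at$role == "metal" & at$element == spec$side_a, , drop = FALSE]
    b <- .protein_side(at, spec$side_b, scheme)
  } else if (spec$interaction == "M-L") {
    a <- at[at$role == "metal" & at$element == spec$side_a, , drop = FALSE]
    b <- at[at$role == "ligand" & at$element == spec$side_b, , drop = FALSE]
  } else {
    stop("unknown interaction class: ", spec$interaction)
  }
  list(a = pick(a), b = pick(b))
}

# diagonal facet persistence Betti numbers (dims 0 and 1) of the Rips
# complex of one cloud, on a grid, straight from the distance matrix:
# a vertex is a facet at r until its nearest neighbor arrives; an edge is a
# facet from its length until some third point is within that scale of both
# endpoints (the cheapest covering triangle).
.facet_stats_rips <- function(coords, grid) {
  n <- nrow(coords)
  cap <- max(grid)
  if (n == 0L) return(list(b0 = rep(0L, length(grid)),
                           b1 = rep(0L, length(grid))))
  if (n == 1L) return(list(b0 = rep(1L, length(grid)),
                           b1 = rep(0L, length(grid))))
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  vdeath <- apply(D, 1L, min)
  eidx <- which(upper.tri(D) & D <= cap, arr.ind = TRUE)
  ebirth <- numeric(0)
  edeath <- numeric(0)
  if (nrow(eidx) > 0L) {
    ebirth <- D[eidx]
    edeath <- vapply(seq_len(nrow(eidx)), function(k) {
      i <- eidx[k, 1L]; j <- eidx[k, 2L]
      leg <- pmax(D[i, ], D[j, ])
      leg[c(i, j)] <- Inf
      min(leg)
    }, 0)
  }
  list(b0 = vapply(grid, function(r) sum(vdeath > r), 0L),
       b1 = vapply(grid, function(r) sum(ebirth <= r & edeath > r), 0L))
}

# same statistics for the bipartite construction: vertices die at their
# first cross-edge; cross edges never acquire cofaces, so every present
# edge is a facet.
.facet_stats_bipartite <- function(ca, cb, grid) {
  na <- nrow(ca); nb <- nrow(cb)
  if (na == 0L || nb == 0L) {
    return(list(b0 = rep(na + nb, length(grid)),
                b1 = rep(0L, length(grid))))
  }
  CD <- .cross_dist(ca, cb)
  vdeath <- c(apply(CD, 1L, min), apply(CD, 2L, min))
  dists <- as.vector(CD)
  list(b0 = vapply(grid, function(r) sum(vdeath > r), 0L),
       b1 = vapply(grid, function(r) sum(dists <= r), 0L))
}

#' Per-pair feature segment
#'
#' For one atom-pair grouping, computes the diagonal facet persistence
#' Betti numbers in dimensions 0 and 1 and their average rates, at every
#' grid scale, for two constructions: the Vietoris-Rips complex of the
#' pooled cloud (`rips_union`) and the bipartite cross-distance complex.
#' Layout: constructions in order, grid-major within a construction, the
#' four statistics (`b0`, `b1`, `b0/r`, `b1/r`) per grid point.
#'
#' @param a,b `point_cloud`s for the two sides (either may be empty)
#' @param grid strictly increasing positive scales
#' @param constructions subset of `c("rips_union", "bipartite")`
#' @return numeric vector of length `length(grid) * 4 * length(constructions)`
#' @export
pair_features <- function(a, b, grid, constructions = .CONSTRUCTIONS) {
  if (any(grid <= 0) || any(diff(grid) <= 0)) {
    stop("grid must be positive and strictly increasing")
  }
  segs <- lapply(constructions, function(con) {
    st <- if (con == "rips_union") {
      .facet_stats_rips(rbind(a$coords, b$coords), grid)
    } else if (con == "bipartite") {
      .facet_stats_bipartite(a$coords, b$coords, grid)
    } else {
      stop("unknown construction: ", con)
    }
    as.vector(rbind(st$b0, st$b1, st$b0 / grid, st$b1 / grid))
  })
  unlist(segs)
}

#' Feature schema for a scheme
#'
#' @param scheme `"ES"` or `"CS"`
#' @param has_metal include metal-involving pairs?
#' @return list with the pair table, grids, statistics, constructions,
#'   total vector length, and a `schema_id` string
#' @export
feature_schema <- function(scheme = c("ES", "CS"), has_metal = FALSE) {
  scheme <- match.arg(scheme)
  pairs <- enumerate_pairs(scheme, has_metal)
  seg_len <- function(inter) {
    g <- if (inter == "P-L") .GRID_PL else .GRID_METAL
    length(g) * length(.STATS) * length(.CONSTRUCTIONS)
  }
  total <- sum(vapply(pairs$interaction, seg_len, 0))
  list(scheme = scheme, has_metal = has_metal, pairs = pairs,
       grid_pl = .GRID_PL, grid_metal = .GRID_METAL,
       stats = .STATS, constructions = .CONSTRUCTIONS,
       length = as.integer(total),
       schema_id = sprintf("psrt-%s%s-v1-L%d", scheme,
                           if (has_metal) "-metal" else "", as.integer(total)))
}

#' Featurize a binding-pocket complex
#'
#' Concatenates [pair_features()] segments over the pair enumeration of the
#' scheme, in order. Protein-ligand pairs use the 1-12 A grid; metal-protein
#' and metal-ligand pairs use the 1-15 A grid (matching the pocket
#' collection cutoffs). Absent atom groups contribute all-zero blocks at
#' their fixed offsets, so the vector length depends only on
#' `(scheme, has_metal)`.
#'
#' @param mc a pocket-filtered `molecular_complex` with ligand atoms
#' @param scheme `"ES"` or `"CS"`
#' @param has_metal `NULL` (auto-detect from the atoms) or logical
#' @return named numeric `feature_vector` with attribute `schema_id`
#' @export
featurize_complex <- function(mc, scheme = c("ES", "CS"), has_metal = NULL) {
  scheme <- match.arg(scheme)
  if (!any(mc$atoms$role == "ligand")) stop("no ligand atoms in complex")
  if (is.null(has_metal)) has_metal <- any(mc$atoms$role == "metal")
  schema <- feature_schema(scheme, has_metal)
  segs <- lapply(seq_len(nrow(schema$pairs)), function(k) {
    spec <- schema$pairs[k, ]
    grid <- if (spec$interaction == "P-L") schema$grid_pl else schema$grid_metal
    cl <- group_atoms(mc, spec, scheme)
    pair_features(cl$a, cl$b, grid, schema$constructions)
  })
  v <- unlist(segs)
  names(v) <- feature_names(schema)
  structure(v, schema_id = schema$schema_id)
}

#' Feature names for a schema
#' @param schema output of [feature_schema()]
#' @return character vector of length `schema$length`
#' @export
feature_names <- function(schema) {
  unlist(lapply(seq_len(nrow(schema$pairs)), function(k) {
    spec <- schema$pairs[k, ]
    grid <- if (spec$interaction == "P-L") schema$grid_pl else schema$grid_metal
    tag <- sprintf("%s.%s.%s", spec$interaction, spec$side_a, spec$side_b)
    unlist(lapply(schema$constructions, function(con) {
      as.vector(vapply(grid, function(r) {
        sprintf("%s.%s.r%.1f.%s", tag, con, r, schema$stats)
      }, character(length(schema$stats))))
    }))
  }))
}

#' Write a feature matrix as CSV with a schema-hash column
#'
#' @param x feature matrix (rows = complexes) or a single feature vector
#' @param path output CSV path; a JSON sidecar `<path>.schema.json`
#'   documents the pair order, grids, statistics and constructions
#' @param schema output of [feature_schema()]
#' @param ids optional row identifiers
#' @return `path`, invisibly
#' @export
write_feature_csv <- function(x, path, schema, ids = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != schema$length) stop("feature width does not match schema")
  if (is.null(ids)) ids <- sprintf("complex%d", seq_len(nrow(x)))
  df <- data.frame(id = ids, schema_id = schema$schema_id, x,
                   check.names = FALSE)
  colnames(df) <- c("id", "schema_id", feature_names(schema))
  utils::write.csv(df, path, row.names = FALSE)
  side <- schema
  side$pairs <- as.list(as.data.frame(t(as.matrix(schema$pairs))))
  jsonlite::write_json(
    list(schema_id = schema$schema_id, scheme = schema$scheme,
         has_metal = schema$has_metal, length = schema$length,
         pairs = schema$pairs, grid_pl = schema$grid_pl,
         grid_metal = schema$grid_metal, stats = schema$stats,
         constructions = schema$constructions),
    paste0(path, ".schema.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_csv()]
#' @param path CSV path
#' @param schema optional schema to validate width and id against
#' @return list with `ids`, `schema_id`, and numeric matrix `x`
#' @export
read_feature_csv <- function(path, schema = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.null(schema)) {
    if (ncol(x) != schema$length) stop("column count does not match schema")
    if (!all(df$schema_id == schema$schema_id)) stop("schema_id mismatch")
  }
  list(ids = df$id, schema_id = df$schema_id[1L], x = x)
}
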