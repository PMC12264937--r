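#' Labeled 3D point cloud
#'
#' @param coords numeric matrix with 3 columns (x, y, z in Angstrom), or an
#'   object coercible to one
#' @param labels optional character vector of per-point tags (element symbols
#'   or residue categories); defaults to `"X"`
#' @return an object of class `point_cloud`: list with `coords` and `labels`
#' @export
point_cloud <- function(coords, labels = NULL) {
  coords <- as.matrix(coords)
  if (length(coords) == 0L) coords <- matrix(numeric(0), ncol = 3L)
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  if (nrow(coords) > 0L && !all(is.finite(coords))) {
    stop("non-finite coordinates")
  }
  if (is.null(labels)) labels <- rep("X", nrow(coords))
  if (length(labels) != nrow(coords)) stop("length(labels) != number of points")
  structure(list(coords = coords, labels = as.character(labels)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("point cloud:", nrow(x$coords), "points,",
      length(unique(x$labels)), "distinct labels\n")
  invisible(x)
}

.simplex_sort_key <- function(s) paste(sprintf("%06d", s), collapse = ",")

new_filtration <- function(vertices, simplices, values, max_dim, cap) {
  keys <- vapply(simplices, .simplex_sort_key, "")
  ord <- order(values, lengths(simplices), keys)
  structure(list(vertices = vertices,
                 simplices = simplices[ord],
                 values = values[ord],
                 max_dim = as.integer(max_dim),
                 cap = cap),
            class = "filtration")
}

#' Construct a filtration from explicit simplices and values
#'
#' General constructor for a filtered complex given by a monotone function:
#' every face of a listed simplex must be listed with a value no larger.
#' `max_dim` asserts through which dimension the simplex list is complete
#' (a hand-built complex with no 2-faces is complete through dimension 2,
#' even though no 2-simplex is listed); cofacet-based operations rely on it.
#'
#' @param vertices vertex labels (length n); simplices index into them
#' @param simplices list of integer vertex-index vectors
#' @param values numeric filtration values, one per simplex
#' @param max_dim dimension through which the list is complete
#' @param cap largest tracked scale
#' @return a `filtration`
#' @export
filtration <- function(vertices, simplices, values, max_dim, cap) {
  if (length(simplices) != length(values)) stop("one value per simplex")
  simplices <- lapply(simplices, function(s) sort(as.integer(s)))
  keys <- vapply(simplices, .face_key, "")
  if (anyDuplicated(keys)) stop("duplicate simplices")
  n <- length(vertices)
  if (any(unlist(simplices) < 1L) || any(unlist(simplices) > n)) {
    stop("simplex vertex out of range")
  }
  if (!all(as.character(seq_len(n)) %in% keys[lengths(simplices) == 1L])) {
    stop("every vertex must appear as a 0-simplex")
  }
  val <- stats::setNames(values, keys)
  for (s in seq_along(simplices)) {
    sx <- simplices[[s]]
    if (length(sx) == 1L) next
    for (drop in seq_along(sx)) {
      fk <- .face_key(sx[-drop])
      if (!fk %in% keys) stop("missing face: ", fk)
      if (val[[fk]] > values[s] + 1e-12) {
        stop("non-monotone filtration at simplex ", keys[s])
      }
    }
  }
  if (any(values > cap)) stop("simplex value exceeds cap")
  new_filtration(vertices, simplices, values, max_dim, cap)
}

#' @export
print.filtration <- function(x, ...) {
  cat("filtration:", length(x$vertices), "vertices,",
      length(x$simplices), "simplices, max dimension", x$max_dim,
      ", cap", x$cap, "\n")
  invisible(x)
}

#' Vietoris-Rips filtration of a point cloud
#'
#' Every vertex enters at scale 0; a simplex on a vertex set `U` (with at
#' most `max_dim + 1` vertices) enters at the diameter of `U` (maximum
#' pairwise distance), provided that value does not exceed `cap`. The
#' resulting filtration function is monotone by construction.
#'
#' @param points a `point_cloud` (or bare coordinate matrix)
#' @param max_dim largest simplex dimension to include (>= 0)
#' @param cap largest tracked filtration scale (> 0), in Angstrom
#' @return a `filtration`
#' @export
rips_filtration <- function(points, max_dim, cap) {
  if (!inherits(points, "point_cloud")) points <- point_cloud(points)
  if (nrow(points$coords) < 1L) stop("need at least one point")
  if (max_dim < 0L) stop("max_dim must be >= 0")
  if (cap <= 0) stop("cap must be positive")
  n <- nrow(points$coords)
  D <- as.matrix(stats::dist(points$coords))
  simplices <- lapply(seq_len(n), function(i) i)
  values <- rep(0, n)
  if (max_dim >= 1L && n >= 2L) {
    # neighbor lists under the cap, then incremental clique expansion
    nbr <- lapply(seq_len(n), function(i) which(D[i, ] <= cap & seq_len(n) > i))
    frontier <- list()
    fvals <- numeric(0)
    for (i in seq_len(n)) {
      for (j in nbr[[i]]) {
        frontier[[length(frontier) + 1L]] <- c(i, j)
        fvals <- c(fvals, D[i, j])
      }
    }
    simplices <- c(simplices, frontier)
    values <- c(values, fvals)
    dim_k <- 1L
    while (dim_k < max_dim && length(frontier) > 0L) {
      nxt <- list()
      nvals <- numeric(0)
      for (s in seq_along(frontier)) {
        sx <- frontier[[s]]
        cand <- Reduce(intersect, lapply(sx, function(v) {
          which(D[v, ] <= cap & seq_len(n) > max(sx))
        }))
        for (w in cand) {
          val <- max(fvals[s], D[sx, w])
          if (val <= cap) {
            nxt[[length(nxt) + 1L]] <- c(sx, w)
            nvals <- c(nvals, val)
          }
        }
      }
      simplices <- c(simplices, nxt)
      values <- c(values, nvals)
      frontier <- nxt
      fvals <- nvals
      dim_k <- dim_k + 1L
    }
  }
  labs <- if (all(points$labels == "X")) {
    as.character(seq_len(n))
  } else {
    paste0(points$labels, seq_len(n))
  }
  new_filtration(labs, simplices, values, max_dim, cap)
}

#' Bipartite distance filtration between two point clouds
#'
#' Vertices of both clouds enter at 0; edges connect only vertices from
#' different clouds, at their pairwise distance, up to `cap`. No simplex of
#' dimension 2 or higher exists in a bipartite complex, so the filtration is
#' complete through dimension 2 by construction.
#'
#' @param set_a,set_b `point_cloud` objects (either may be empty)
#' @param cap largest tracked scale (> 0)
#' @return a `filtration`
#' @export
bipartite_filtration <- function(set_a, set_b, cap) {
  if (cap <= 0) stop("cap must be positive")
  na <- nrow(set_a$coords)
  nb <- nrow(set_b$coords)
  n <- na + nb
  simplices <- lapply(seq_len(n), function(i) i)
  values <- rep(0, n)
  if (na > 0L && nb > 0L) {
    CD <- .cross_dist(set_a$coords, set_b$coords)
    hit <- which(CD <= cap, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      edges <- lapply(seq_len(nrow(hit)), function(k) {
        c(hit[k, 1L], na + hit[k, 2L])
      })
      simplices <- c(simplices, edges)
      values <- c(values, CD[hit])
    }
  }
  labs <- c(if (na > 0L) paste0("A:", set_a$labels, seq_len(na)),
            if (nb > 0L) paste0("B:", set_b$labels, seq_len(nb)))
  new_filtration(labs, simplices, values, max_dim = 2L, cap = cap)
}

.cross_dist <- function(a, b) {
  # Euclidean distances between rows of a (na x 3) and rows of b (nb x 3)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Snapshot of a filtration at a scale
#'
#' Returns the subcomplex of simplices with filtration value at or below `r`
#' (closed threshold). Snapshots are nested: `r <= r'` implies the faces at
#' `r` are a subset of the faces at `r'`.
#'
#' @param filt a `filtration`
#' @param r scale in `[0, cap]`
#' @return a `simplicial_complex` on the filtration's vertex labels
#' @export
complex_at <- function(filt, r) {
  if (r > filt$cap) stop("r exceeds the filtration cap")
  if (r < 0) stop("r must be non-negative")
  keep <- filt$values <= r
  faces <- .sort_faces(filt$simplices[keep])
  new_simplicial_complex(filt$vertices, faces)
}

#' Restrict a filtration to a vertex subset
#'
#' Keeps exactly the simplices whose vertex set lies in `w`, with values
#' unchanged (the induced filtration on the full subcomplex). Commutes with
#' [complex_at()].
#'
#' @param filt a `filtration`
#' @param w integer vertex indices (into `filt$vertices`)
#' @return a `filtration` on the sub-vertex-set, reindexed 1..length(w)
#' @export
restrict_filtration <- function(filt, w) {
  w <- sort(unique(as.integer(w)))
  if (length(w) == 0L || any(w < 1L) || any(w > length(filt$vertices))) {
    stop("unknown vertex in restriction set")
  }
  remap <- integer(length(filt$vertices))
  remap[w] <- seq_along(w)
  keep <- vapply(filt$simplices, function(s) all(s %in% w), TRUE)
  simplices <- lapply(filt$simplices[keep], function(s) remap[s])
  new_filtration(filt$vertices[w], simplices, filt$values[keep],
                 filt$max_dim, filt$cap)
}

#' Read a labeled XYZ point cloud
#'
#' Accepts standard XYZ (atom count line, comment line, then
#' `element x y z` records) or a bare list of `element x y z` lines.
#'
#' @param path file path
#' @return a `point_cloud`
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty XYZ file")
  first <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (!is.na(first) && length(strsplit(trimws(lines[1L]), "\\s+")[[1L]]) == 1L) {
    lines <- lines[-(1:2)]  # count + comment header
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < first) stop("XYZ header count exceeds record count")
    lines <- lines[seq_len(first)]
  } else {
    lines <- lines[nzchar(trimws(lines))]
  }
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) < 4L)
  if (length(bad) > 0L) stop("XYZ line ", bad[1L], ": expected 'element x y z'")
  labels <- vapply(parts, `[[`, "", 1L)
  coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(coords)) stop("XYZ: non-numeric coordinate")
  point_cloud(coords, labels)
}

#' Write a labeled XYZ point cloud
#' @param points a `point_cloud`
#' @param path output path
#' @param comment comment line
#' @return `path`, invisibly
#' @export
write_xyz <- function(points, path, comment = "") {
  n <- nrow(points$coords)
  rec <- sprintf("%s %.6f %.6f %.6f", points$labels,
                 points$coords[, 1L], points$coords[, 2L], points$coords[, 3L])
  writeLines(c(as.character(n), comment, rec), path)
  invisible(path)
}

#' Export a filtration as TSV (one simplex per row)
#' @param filt a `filtration`
#' @param path output path
#' @return `path`, invisibly
#' @export
filtration_to_tsv <- function(filt, path) {
  df <- data.frame(
    simplex = vapply(filt$simplices, function(s)
      paste(filt$vertices[s], collapse = " "), ""),
    value = filt$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
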