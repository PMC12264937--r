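# Facet persistence barcodes, persistent graded Betti numbers (multiscale
# Hochster formula), persistent h-/f-vectors.

#' Facet persistence barcode of a filtration
#'
#' A simplex `sigma` is a facet of the snapshot at scale `r` when it is
#' present (`g(sigma) <= r`) and no coface is. Its facet ideal therefore
#' lives on the half-open interval from `birth = g(sigma)` to
#' `death = min g(tau)` over cofacets `tau` (one dimension up); if no
#' cofacet exists within the cap the death is `+Inf`. A bar is emitted only
#' when `death > birth`: a simplex covered at its own entry value is never a
#' facet of any snapshot.
#'
#' @param filt a `filtration` whose `max_dim` is at least `up_to_dim + 1`
#'   (so cofacets of the top tracked dimension are visible)
#' @param up_to_dim largest facet dimension to report
#' @return a `facet_barcode`: data frame with columns `dimension`, `birth`,
#'   `death` and a list column `witness` (the facet's vertex indices),
#'   with attributes `cap` and `vertices`
#' @export
facet_barcode <- function(filt, up_to_dim) {
  if (filt$max_dim < up_to_dim + 1L) {
    stop("filtration max_dim must be at least up_to_dim + 1 for cofacet visibility")
  }
  keys <- vapply(filt$simplices, .face_key, "")
  dims <- lengths(filt$simplices) - 1L
  # min cofacet value per simplex: scan each simplex's boundary
  death <- rep(Inf, length(keys))
  names(death) <- keys
  for (s in which(dims >= 1L & dims <= up_to_dim + 1L)) {
    sx <- filt$simplices[[s]]
    v <- filt$values[s]
    for (drop in seq_along(sx)) {
      fk <- .face_key(sx[-drop])
      if (v < death[[fk]]) death[[fk]] <- v
    }
  }
  sel <- which(dims <= up_to_dim)
  birth <- filt$values[sel]
  dth <- unname(death[keys[sel]])
  keep <- dth > birth
  bars <- data.frame(dimension = dims[sel][keep],
                     birth = birth[keep],
                     death = dth[keep])
  bars$witness <- filt$simplices[sel][keep]
  bars <- bars[order(bars$dimension, bars$birth, bars$death), , drop = FALSE]
  rownames(bars) <- NULL
  structure(bars, cap = filt$cap, vertices = filt$vertices,
            class = c("facet_barcode", "data.frame"))
}

#' Facet persistence Betti number from a barcode
#'
#' Counts the `i`-dimensional facet ideals alive at both scales, i.e. bars
#' of dimension `i` with `birth <= r` and `death > r_prime`. Equals the
#' cardinality of the intersection of the facet sets of the two snapshots.
#'
#' @param bc a `facet_barcode`
#' @param i facet dimension
#' @param r,r_prime scales with `r <= r_prime <= cap`
#' @return non-negative integer
#' @export
facet_persistence_betti <- function(bc, i, r, r_prime) {
  if (r > r_prime) stop("r must not exceed r_prime")
  if (r_prime > attr(bc, "cap")) stop("r_prime exceeds the barcode cap")
  sum(bc$dimension == i & bc$birth <= r & bc$death > r_prime)
}

#' Grid summary of facet persistence Betti numbers and their rates
#'
#' For each grid scale `r`, reports the diagonal facet persistence Betti
#' numbers `beta_i^{r,r}` per dimension together with their average rates
#' `beta_i^{r,r} / r`; optionally the f-vector rates `f^{r,r} / r` when the
#' per-scale f-vectors are supplied.
#'
#' @param bc a `facet_barcode`
#' @param grid strictly increasing positive scales
#' @param dims facet dimensions to summarize (default 0:1)
#' @param f_by_r optional list of f-vectors, one per grid point
#' @return a `persistence_summary`: list with `grid`, `beta` (matrix, one
#'   row per dimension), `beta_rate`, and `f_rate` (list or NULL)
#' @export
summarize_on_grid <- function(bc, grid, dims = 0:1, f_by_r = NULL) {
  if (any(grid <= 0)) stop("grid values must be positive (rates divide by r)")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  beta <- vapply(grid, function(r) {
    vapply(dims, function(i) facet_persistence_betti(bc, i, r, r), 0L)
  }, integer(length(dims)))
  beta <- matrix(beta, nrow = length(dims),
                 dimnames = list(paste0("dim", dims), NULL))
  f_rate <- NULL
  if (!is.null(f_by_r)) {
    if (length(f_by_r) != length(grid)) stop("f_by_r must align with grid")
    f_rate <- lapply(seq_along(grid), function(t) f_by_r[[t]] / grid[t])
  }
  structure(list(grid = grid, dims = dims, beta = beta,
                 beta_rate = sweep(beta, 2L, grid, "/"),
                 f_rate = f_rate),
            class = "persistence_summary")
}

# boundary matrix from p-faces (columns) to (p-1)-faces (rows)
.boundary_matrix <- function(faces_p, faces_pm1) {
  if (length(faces_p) == 0L) {
    return(matrix(0, nrow = length(faces_pm1), ncol = 0L))
  }
  idx <- stats::setNames(seq_along(faces_pm1),
                         vapply(faces_pm1, .face_key, ""))
  M <- matrix(0, nrow = length(faces_pm1), ncol = length(faces_p))
  for (cidx in seq_along(faces_p)) {
    sx <- faces_p[[cidx]]
    for (k in seq_along(sx)) {
      M[idx[[.face_key(sx[-k])]], cidx] <- (-1)^(k - 1L)
    }
  }
  M
}

#' Reduced simplicial homology rank over an exact field
#'
#' Computes `dim` of the p-th reduced homology of a complex from boundary
#' matrix ranks over a large prime field (exact arithmetic; the augmentation
#' map is included for p = 0, so a single connected component contributes
#' nothing in degree 0).
#'
#' @param cx a `simplicial_complex` with at most 20 vertices
#' @param p homology degree (>= 0)
#' @return non-negative integer
#' @export
reduced_homology_rank <- function(cx, p) {
  if (length(cx$vertices) > 20L) stop("brute-force guard: more than 20 vertices")
  if (p < 0L) stop("p must be >= 0")
  card <- lengths(cx$faces)
  faces_p <- cx$faces[card == p + 1L]
  if (length(faces_p) == 0L) return(0L)
  if (p == 0L) {
    rank_dp <- 1L  # augmentation map onto k
  } else {
    faces_pm1 <- cx$faces[card == p]
    rank_dp <- .rank_modp(.boundary_matrix(faces_p, faces_pm1))
  }
  faces_pp1 <- cx$faces[card == p + 2L]
  rank_dpp1 <- .rank_modp(.boundary_matrix(faces_pp1, faces_p))
  length(faces_p) - rank_dp - rank_dpp1
}

# p-simplices of the filtration alive at scale r
.filt_faces_at <- function(filt, p, r) {
  filt$simplices[lengths(filt$simplices) == p + 1L & filt$values <= r]
}

#' Rank of the map on reduced homology induced by a filtration inclusion
#'
#' For scales `r <= r_prime`, computes the rank of
#' `H~_p(Delta^r) -> H~_p(Delta^r')` as
#' `rank [ B_p(Delta^r') | Z_p(Delta^r) ] - rank B_p(Delta^r')`,
#' where `Z_p` is the cycle space at the earlier scale (including the
#' augmentation for p = 0) and `B_p` the boundary space at the later one,
#' both expressed in the p-chain basis of the later snapshot.
#'
#' @param filt a `filtration` with `max_dim >= p + 1` and at most 20 vertices
#' @param p homology degree
#' @param r,r_prime scales with `r <= r_prime`
#' @return non-negative integer
#' @export
persistent_homology_rank <- function(filt, p, r, r_prime) {
  if (r > r_prime) stop("r must not exceed r_prime")
  if (length(filt$vertices) > 20L) stop("brute-force guard: more than 20 vertices")
  if (filt$max_dim < p + 1L) stop("filtration max_dim too low for degree p")
  faces_p_r <- .filt_faces_at(filt, p, r)
  if (length(faces_p_r) == 0L) return(0L)
  faces_p_rp <- .filt_faces_at(filt, p, r_prime)
  # cycle space at r
  if (p == 0L) {
    d_r <- matrix(1, nrow = 1L, ncol = length(faces_p_r))
  } else {
    d_r <- .boundary_matrix(faces_p_r, .filt_faces_at(filt, p - 1L, r))
  }
  Z <- .kernel_modp(d_r)
  if (ncol(Z) == 0L) return(0L)
  # embed into the p-chain basis at r_prime
  keys_rp <- vapply(faces_p_rp, .face_key, "")
  pos <- match(vapply(faces_p_r, .face_key, ""), keys_rp)
  Zemb <- matrix(0, nrow = length(faces_p_rp), ncol = ncol(Z))
  Zemb[pos, ] <- Z
  B <- .boundary_matrix(.filt_faces_at(filt, p + 1L, r_prime), faces_p_rp)
  .rank_modp(cbind(B, Zemb)) - .rank_modp(B)
}

#' Persistent Stanley-Reisner graded Betti number
#'
#' Multiscale Hochster formula: the persistent graded Betti number at
#' homological index `i` and degree offset `j` (total degree `i + j`) is the
#' sum, over all vertex subsets `W` of size `i + j`, of the rank of the map
#' on (j-1)-st reduced homology induced by the inclusion of the restricted
#' snapshots `Delta_W^r -> Delta_W^{r'}`. At `r = r_prime` this reduces to
#' the classical Hochster formula.
#'
#' @param filt a `filtration`
#' @param i homological index (>= 1)
#' @param j degree offset (>= 1); the total degree is `i + j`
#' @param r,r_prime scales with `r <= r_prime`
#' @param guard maximum vertex count for the subset enumeration (default 12)
#' @return non-negative integer
#' @export
persistent_graded_betti <- function(filt, i, j, r, r_prime, guard = 12L) {
  n <- length(filt$vertices)
  if (n > guard) stop("brute-force guard: more than ", guard, " vertices")
  if (i < 1L || j < 1L) stop("require i >= 1 and j >= 1")
  if (i + j > n) return(0L)
  subsets <- utils::combn(n, i + j, simplify = FALSE)
  total <- 0L
  for (w in subsets) {
    total <- total + persistent_homology_rank(
      restrict_filtration(filt, w), j - 1L, r, r_prime)
  }
  total
}

# binomial with the convention C(a, 0) = 1 (any a, including negative) and
# C(a, b) = 0 whenever b > 0 and a < b
.bin0 <- function(a, b) {
  if (b == 0L) return(1)
  if (a < b) return(0)
  choose(a, b)
}

# persistent graded Betti number indexed by total degree jt; beta_{0,0} = 1
.pgb_total <- function(filt, i, jt, r, r_prime, guard) {
  if (i == 0L) return(as.integer(jt == 0L))
  if (jt - i < 1L) return(0L)
  persistent_graded_betti(filt, i, jt - i, r, r_prime, guard)
}

#' Persistent h-vector
#'
#' `h_m^{r,r'} = sum_{j=0}^m C(n-d+m-j-1, m-j) sum_{i=0}^j (-1)^i
#' beta_{i,j}^{r,r'}`, where the second Betti index is the total degree
#' (`beta_{0,0} = 1`), `n` is the vertex count and `d` the Krull dimension
#' of the snapshot at `r_prime`. At `r = r_prime` this reproduces the
#' classical h-vector of the snapshot.
#'
#' @inheritParams persistent_graded_betti
#' @return numeric vector `(h_0, ..., h_d)`
#' @export
persistent_h_vector <- function(filt, r, r_prime, guard = 12L) {
  if (r > r_prime) stop("r must not exceed r_prime")
  n <- length(filt$vertices)
  if (n > guard) stop("brute-force guard: more than ", guard, " vertices")
  d <- complex_dim(complex_at(filt, r_prime)) + 1L
  # alternating sums S_j = sum_i (-1)^i beta_{i,j} per total degree j
  S <- vapply(0:d, function(jt) {
    sum(vapply(0:jt, function(i) {
      (-1)^i * .pgb_total(filt, i, jt, r, r_prime, guard)
    }, 0))
  }, 0)
  vapply(0:d, function(m) {
    sum(vapply(0:m, function(j) {
      .bin0(n - d + m - j - 1L, m - j) * S[j + 1L]
    }, 0))
  }, 0)
}

#' Persistent f-vector
#'
#' `f_{m-1}^{r,r'} = sum_{i=0}^m C(d-i, m-i) h_i^{r,r'}`. At `r = r_prime`
#' it coincides with the classical f-vector of the snapshot at `r`.
#'
#' @inheritParams persistent_graded_betti
#' @return numeric vector `(f_0, ..., f_{d-1})`
#' @export
persistent_f_vector <- function(filt, r, r_prime, guard = 12L) {
  h <- persistent_h_vector(filt, r, r_prime, guard)
  d <- length(h) - 1L
  vapply(1:d, function(m) {
    sum(vapply(0:m, function(i) .bin0(d - i, m - i) * h[i + 1L], 0))
  }, 0)
}

#' Export a facet barcode as TSV
#'
#' Columns: dimension, birth, death (`inf` for unbounded bars), and the
#' witness facet's vertex labels.
#'
#' @param bc a `facet_barcode`
#' @param path output path
#' @return `path`, invisibly
#' @export
barcode_to_tsv <- function(bc, path) {
  labs <- attr(bc, "vertices")
  df <- data.frame(
    dimension = bc$dimension,
    birth = bc$birth,
    death = ifelse(is.infinite(bc$death), "inf",
                   format(bc$death, digits = 12)),
    witness = vapply(bc$witness, function(w)
      paste(labs[w], collapse = " "), ""))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
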