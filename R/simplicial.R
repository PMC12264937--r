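# canonical key for a sorted integer face
.face_key <- function(idx) paste(idx, collapse = ",")

.key_to_face <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1]])

# all non-empty subsets of a sorted integer vector
.subsets_nonempty <- function(idx) {
  n <- length(idx)
  if (n > 16L) stop("face too large for subset enumeration (", n, " vertices)")
  out <- vector("list", 2L^n - 1L)
  k <- 0L
  for (m in seq_len(2L^n - 1L)) {
    k <- k + 1L
    out[[k]] <- idx[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
  }
  out
}

.sort_faces <- function(faces) {
  if (length(faces) == 0L) return(faces)
  lens <- lengths(faces)
  keys <- vapply(faces, function(f) paste(sprintf("%06d", f), collapse = ","), "")
  faces[order(lens, keys)]
}

#' Construct a simplicial complex as the downward closure of a facet list
#'
#' An abstract simplicial complex is a family of non-empty vertex subsets
#' (faces) closed under taking subsets, with every vertex a face. This
#' constructor takes any collection of candidate faces, absorbs duplicates and
#' dominated sets, and returns the downward closure of the inclusion-maximal
#' members.
#'
#' @param facet_list list of vertex subsets (vectors of labels). Labels may be
#'   integers or character; they are sorted and mapped to 1-based indices.
#' @return an object of class `simplicial_complex` with components
#'   `vertices` (sorted labels), `faces` (list of sorted integer index
#'   vectors, canonically ordered), and `face_keys` (character keys for fast
#'   membership tests).
#' @examples
#' cx <- make_complex_from_facets(list(c(1, 2, 3)))
#' length(cx$faces)  # 7: the full 2-simplex
#' @export
make_complex_from_facets <- function(facet_list) {
  if (length(facet_list) == 0L) stop("empty complex")
  facet_list <- lapply(facet_list, unique)
  if (any(lengths(facet_list) == 0L)) stop("empty complex")
  vertices <- sort(unique(unlist(facet_list)))
  facet_idx <- lapply(facet_list, function(f) sort(match(f, vertices)))
  # drop duplicates and dominated sets
  keys <- vapply(facet_idx, .face_key, "")
  facet_idx <- facet_idx[!duplicated(keys)]
  maximal <- vapply(seq_along(facet_idx), function(i) {
    !any(vapply(seq_along(facet_idx), function(j) {
      i != j && length(facet_idx[[i]]) <= length(facet_idx[[j]]) &&
        all(facet_idx[[i]] %in% facet_idx[[j]])
    }, TRUE))
  }, TRUE)
  facet_idx <- facet_idx[maximal]
  all_faces <- unlist(lapply(facet_idx, .subsets_nonempty), recursive = FALSE)
  all_keys <- vapply(all_faces, .face_key, "")
  faces <- .sort_faces(all_faces[!duplicated(all_keys)])
  new_simplicial_complex(vertices, faces)
}

new_simplicial_complex <- function(vertices, faces) {
  structure(
    list(vertices = vertices, faces = faces,
         face_keys = vapply(faces, .face_key, "")),
    class = "simplicial_complex")
}

#' @export
print.simplicial_complex <- function(x, ...) {
  cat("simplicial complex on", length(x$vertices), "vertices,",
      length(x$faces), "faces, dimension", complex_dim(x), "\n")
  invisible(x)
}

#' Dimension of a simplicial complex
#'
#' The dimension is the maximum face cardinality minus one.
#' @param cx a `simplicial_complex`
#' @return integer dimension
#' @export
complex_dim <- function(cx) max(lengths(cx$faces)) - 1L

.is_face <- function(cx, idx) .face_key(sort(idx)) %in% cx$face_keys

#' Facets (inclusion-maximal faces) of a complex
#'
#' @param cx a `simplicial_complex`
#' @return list of faces (integer index vectors) that are inclusion-maximal
#' @export
facets <- function(cx) {
  keep <- vapply(seq_along(cx$faces), function(i) {
    f <- cx$faces[[i]]
    bigger <- cx$faces[lengths(cx$faces) == length(f) + 1L]
    !any(vapply(bigger, function(g) all(f %in% g), TRUE))
  }, TRUE)
  cx$faces[keep]
}

#' f-vector of a simplicial complex
#'
#' Entry `i` of the f-vector counts the (i-1)-dimensional faces, i.e. the
#' faces with `i` vertices; the implicit empty face (f_{-1} = 1) is not
#' stored but honoured by [h_from_f()].
#'
#' @param cx a `simplicial_complex`
#' @return integer vector `(f_0, ..., f_{d-1})` of length `dim + 1`
#' @export
f_vector <- function(cx) {
  tabulate(lengths(cx$faces), nbins = complex_dim(cx) + 1L)
}

#' h-vector from an f-vector
#'
#' Computes the h-vector, the coefficient vector of the numerator of the
#' Hilbert series of the Stanley-Reisner ring written over `(1-s)^d`:
#' `h_j = sum_{i=0}^{j} (-1)^(j-i) C(d-i, j-i) f_{i-1}`, with `f_{-1} = 1`.
#'
#' @param f integer f-vector `(f_0, ..., f_{d-1})`
#' @param d the Krull dimension, which must equal `length(f)`
#' @return integer vector `(h_0, ..., h_d)`
#' @export
h_from_f <- function(f, d) {
  if (d != length(f)) stop("d must equal length(f)")
  fx <- c(1, f)  # fx[i+1] = f_{i-1}
  vapply(0:d, function(j) {
    sum(vapply(0:j, function(i) {
      (-1)^(j - i) * choose(d - i, j - i) * fx[i + 1L]
    }, 0))
  }, 0)
}

#' f-vector from an h-vector
#'
#' Inverse of [h_from_f()]: `f_{j-1} = sum_{i=0}^{j} C(d-i, j-i) h_i`.
#'
#' @param h integer h-vector of length `d + 1`
#' @param d the Krull dimension
#' @return integer vector `(f_0, ..., f_{d-1})`
#' @export
f_from_h <- function(h, d) {
  if (length(h) != d + 1L) stop("length(h) must equal d + 1")
  vapply(1:d, function(j) {
    sum(vapply(0:j, function(i) choose(d - i, j - i) * h[i + 1L], 0))
  }, 0)
}

#' Hilbert function of the Stanley-Reisner ring by direct monomial count
#'
#' Counts, for each degree `t`, the monomials of degree `t` whose support is
#' a face of the complex (the dimension of the degree-`t` graded piece of
#' `k[Delta]`). A monomial with support exactly a face of cardinality `c`
#' corresponds to a composition of `t` into `c` positive parts, so the count
#' is a sum of binomials over faces; this serves as the brute-force oracle
#' for the rational form of the Hilbert series.
#'
#' @param cx a `simplicial_complex`
#' @param max_degree highest degree to report (>= 0)
#' @return integer vector of length `max_degree + 1` (degrees 0..max_degree)
#' @export
hilbert_dimensions <- function(cx, max_degree) {
  if (max_degree < 0) stop("max_degree must be >= 0")
  card <- lengths(cx$faces)
  vapply(0:max_degree, function(t) {
    if (t == 0L) return(1)
    sum(choose(t - 1L, card - 1L))
  }, 0)
}

#' Minimal generators of the Stanley-Reisner ideal
#'
#' The Stanley-Reisner ideal of a complex is generated by the squarefree
#' monomials of its non-faces; the minimal generating set corresponds to the
#' inclusion-minimal non-faces (every proper subset is a face). The full
#' simplex has the zero ideal (no generators).
#'
#' @param cx a `simplicial_complex`
#' @return a `squarefree_monomial_ideal`
#' @export
stanley_reisner_generators <- function(cx) {
  n <- length(cx$vertices)
  if (n > 20L) stop("brute-force guard: complex has more than 20 vertices")
  gens <- list()
  max_size <- min(n, complex_dim(cx) + 2L)
  for (k in seq_len(max_size)) {
    cand <- utils::combn(n, k, simplify = FALSE)
    for (s in cand) {
      if (!.is_face(cx, s)) {
        proper_ok <- k == 1L ||
          all(vapply(utils::combn(s, k - 1L, simplify = FALSE),
                     function(p) .is_face(cx, p), TRUE))
        if (proper_ok) gens[[length(gens) + 1L]] <- s
      }
    }
  }
  new_squarefree_ideal(cx$vertices, gens)
}

new_squarefree_ideal <- function(ambient, generators) {
  structure(list(ambient = ambient, generators = .sort_faces(generators)),
            class = "squarefree_monomial_ideal")
}

#' @export
print.squarefree_monomial_ideal <- function(x, ...) {
  if (length(x$generators) == 0L) {
    cat("(0)\n")
  } else {
    mons <- vapply(x$generators, function(g)
      paste0("x", g, collapse = "*"), "")
    cat("(", paste(mons, collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

#' Facet prime ideal of a facet
#'
#' For a facet `sigma`, the associated prime monomial ideal is generated by
#' the single variables not in `sigma`. The Stanley-Reisner ideal is the
#' intersection of these ideals over all facets.
#'
#' @param facet vertex index vector; must be a facet of `cx`
#' @param cx a `simplicial_complex`
#' @return a `squarefree_monomial_ideal` generated by single variables
#' @export
facet_prime_ideal <- function(facet, cx) {
  facet <- sort(as.integer(facet))
  fkeys <- vapply(facets(cx), .face_key, "")
  if (!(.face_key(facet) %in% fkeys)) stop("not a facet of the complex")
  outside <- setdiff(seq_along(cx$vertices), facet)
  new_squarefree_ideal(cx$vertices, as.list(outside))
}

#' Verify the primary decomposition of the Stanley-Reisner ideal
#'
#' Brute-force check that the Stanley-Reisner ideal equals the intersection
#' of the facet prime ideals: for every squarefree monomial (non-empty
#' vertex subset S), membership in I(Delta) (S is a non-face) must coincide
#' with membership in every facet ideal (S is contained in no facet). True
#' for every valid complex; `FALSE` signals an implementation bug.
#'
#' @param cx a `simplicial_complex` with at most 20 vertices
#' @return logical
#' @export
check_primary_decomposition <- function(cx) {
  n <- length(cx$vertices)
  if (n > 20L) stop("brute-force guard: complex has more than 20 vertices")
  fac <- facets(cx)
  for (m in seq_len(2L^n - 1L)) {
    s <- which(bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    in_ideal <- !.is_face(cx, s)
    in_all_primes <- !any(vapply(fac, function(sig) all(s %in% sig), TRUE))
    if (in_ideal != in_all_primes) return(FALSE)
  }
  TRUE
}

#' Krull dimension of the Stanley-Reisner ring
#'
#' Equals `dim(Delta) + 1`.
#' @param cx a `simplicial_complex`
#' @return integer
#' @export
krull_dimension <- function(cx) complex_dim(cx) + 1L

#' Serialize a complex to JSON
#'
#' The document stores vertex labels and facets (as labels), so the complex
#' can be reconstructed with [make_complex_from_facets()].
#'
#' @param cx a `simplicial_complex`
#' @param path optional file path; if `NULL` the JSON string is returned
#' @return the JSON string (invisibly when written to a file)
#' @export
complex_to_json <- function(cx, path = NULL) {
  doc <- list(vertices = cx$vertices,
              facets = lapply(facets(cx), function(f) cx$vertices[f]))
  js <- jsonlite::toJSON(doc, auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a complex from JSON written by [complex_to_json()]
#' @param path file path or JSON string
#' @return a `simplicial_complex`
#' @export
complex_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  make_complex_from_facets(lapply(doc$facets, unlist))
}
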