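# Exact rank / kernel computations over GF(p) for a single large prime.
# p is chosen so that (p-1)^2 < 2^53: modular products stay exact in doubles.
# Boundary matrices of small complexes have tiny torsion primes (2, 3, ...),
# so ranks over this field agree with ranks over the rationals.

.PSRT_PRIME <- 67108859

.mod_inv <- function(a, p = .PSRT_PRIME) {
  # Fermat: a^(p-2) mod p by square-and-multiply
  a <- a %% p
  e <- p - 2
  res <- 1
  while (e > 0) {
    if (e %% 2 == 1) res <- (res * a) %% p
    a <- (a * a) %% p
    e <- e %/% 2
  }
  res
}

# Reduced row echelon form; returns list(mat, pivots, rank)
.rref_modp <- function(M, p = .PSRT_PRIME) {
  if (is.null(dim(M)) || nrow(M) == 0L || ncol(M) == 0L) {
    return(list(mat = M, pivots = integer(0), rank = 0L))
  }
  M <- M %% p
  nr <- nrow(M); nc <- ncol(M)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(nc)) {
    if (row > nr) break
    piv <- which(M[row:nr, col] != 0)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) M[c(row, piv), ] <- M[c(piv, row), ]
    M[row, ] <- (M[row, ] * .mod_inv(M[row, col], p)) %% p
    other <- which(M[, col] != 0)
    other <- other[other != row]
    if (length(other) > 0L) {
      M[other, ] <- (M[other, , drop = FALSE] -
                       outer(M[other, col], M[row, ])) %% p
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(mat = M, pivots = pivots, rank = length(pivots))
}

.rank_modp <- function(M, p = .PSRT_PRIME) .rref_modp(M, p)$rank

# Basis of the null space (columns) of M over GF(p)
.kernel_modp <- function(M, p = .PSRT_PRIME) {
  if (is.null(dim(M)) || nrow(M) == 0L) {
    # zero map: everything is in the kernel
    nc <- if (is.null(dim(M))) length(M) else ncol(M)
    return(diag(1, nc))
  }
  nc <- ncol(M)
  if (nc == 0L) return(matrix(0, nrow = 0L, ncol = 0L))
  rr <- .rref_modp(M, p)
  free <- setdiff(seq_len(nc), rr$pivots)
  K <- matrix(0, nrow = nc, ncol = length(free))
  for (k in seq_along(free)) {
    fc <- free[k]
    K[fc, k] <- 1
    if (length(rr$pivots) > 0L) {
      K[rr$pivots, k] <- (p - rr$mat[seq_along(rr$pivots), fc]) %% p
    }
  }
  K
}
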