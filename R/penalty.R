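#' Second-order random-walk penalty matrix
#'
#' Builds the T x T penalty matrix \eqn{P = D_2' D_2}, where \eqn{D_2} is the
#' (T-2) x T second-difference operator. \eqn{u'Pu} is the quadratic penalty of
#' the second-order random-walk (RW2) smoothing prior used for the nonlinear
#' components of the country time trends. \eqn{P} annihilates constants and
#' linear trends (\eqn{P 1 = 0}, \eqn{P t = 0}) and has rank T - 2; its
#' interior rows carry the band (1, -4, 6, -4, 1).
#'
#' @param T integer number of time points, at least 3.
#' @return A symmetric T x T numeric matrix.
#' @examples
#' P <- rw2_penalty_matrix(6)
#' max(P)          # 6
#' range(P %*% rep(1, 6))  # both 0
#' @export
rw2_penalty_matrix <- function(T) {
  if (length(T) != 1L || !is.finite(T) || T != round(T) || T < 3)
    stop("T must be a single integer >= 3: the RW2 penalty is undefined otherwise")
  T <- as.integer(T)
  D2 <- second_difference_operator(T)
  P <- crossprod(D2)
  # crossprod of an integer-valued banded matrix; symmetrise exactly
  (P + t(P)) / 2
}

#' Second-difference operator
#'
#' The (T-2) x T banded matrix with rows (1, -2, 1) such that
#' \code{D2 %*% u} is the vector of second differences of \code{u}.
#'
#' @param T integer number of time points, at least 3.
#' @return A (T-2) x T numeric matrix.
#' @export
second_difference_operator <- function(T) {
  T <- as.integer(T)
  D2 <- matrix(0, T - 2L, T)
  for (r in seq_len(T - 2L)) D2[r, r:(r + 2L)] <- c(1, -2, 1)
  D2
}

# Eigendecomposition of P with its two-dimensional null space (constants and
# linear trends) identified; cached by callers that need repeated constrained
# draws. `nonnull` indexes eigenvalues above tol.
rw2_penalty_eigen <- function(T, tol = 1e-9) {
  P <- rw2_penalty_matrix(T)
  e <- eigen(P, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  list(values = e$values, vectors = e$vectors, nonnull = which(keep), T = T)
}
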