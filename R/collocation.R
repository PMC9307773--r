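#' Orthogonal collocation grid on the unit interval
#'
#' Builds the node set, differentiation matrices and quadrature weights used
#' to discretize both the biofilm depth coordinate and the column height.
#' Interior nodes are the roots of the shifted Legendre polynomial of degree
#' `n_interior` on (0, 1); both endpoints are appended, so the grid carries
#' `n_interior + 2` points in total. Differentiation matrices come from
#' barycentric Lagrange differentiation (stable for the node counts used
#' here, n <= ~30), and the quadrature weights integrate the Lagrange basis
#' exactly, so polynomials up to the grid's exactness degree are integrated
#' without error.
#'
#' @param n_interior Number of interior collocation points (>= 1).
#' @return An object of class `colloc_grid`: a list with
#'   \describe{
#'     \item{nodes}{ordered points in \[0, 1\], first = 0, last = 1}
#'     \item{d1}{first-derivative matrix (n x n)}
#'     \item{d2}{second-derivative matrix (n x n)}
#'     \item{quad_weights}{quadrature weights, summing to 1}
#'     \item{n}{total number of nodes}
#'   }
#' @examples
#' g <- colloc_grid(3)
#' # derivative of x^2 is 2x at every node:
#' g$d1 %*% g$nodes^2
#' @export
colloc_grid <- function(n_interior) {
  if (!is.numeric(n_interior) || length(n_interior) != 1L || n_interior < 1 ||
      n_interior != round(n_interior)) {
    stop("`n_interior` must be a single integer >= 1", call. = FALSE)
  }
  n_interior <- as.integer(n_interior)
  xi <- if (n_interior == 1L) 0.5 else sort(pracma::gaussLegendre(n_interior, 0, 1)$x)
  x <- c(0, xi, 1)
  n <- length(x)

  # barycentric weights; scaled to avoid under/overflow at larger n
  wb <- vapply(seq_len(n), function(j) 1 / prod(x[j] - x[-j]), numeric(1))
  wb <- wb / max(abs(wb))

  d1 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d1[i, j] <- (wb[j] / wb[i]) / (x[i] - x[j])
    }
  }
  diag(d1) <- -rowSums(d1)
  # the interpolant's derivative lives in the same polynomial space, so the
  # second-derivative matrix is exactly d1 applied twice
  d2 <- d1 %*% d1

  # quadrature weights: integrate each Lagrange basis polynomial with a
  # Gauss-Legendre rule of sufficient order (exact, avoids Vandermonde solves)
  m <- ceiling(n / 2) + 1L
  gq <- pracma::gaussLegendre(m, 0, 1)
  basis <- .lagrange_eval(x, wb, gq$x)   # m x n, basis[q, j] = L_j(y_q)
  qw <- as.numeric(crossprod(basis, gq$w))

  structure(
    list(nodes = x, d1 = d1, d2 = d2, quad_weights = qw, n = n),
    class = "colloc_grid"
  )
}

# Evaluate all Lagrange basis polynomials over nodes x (barycentric weights wb)
# at query points y. Returns length(y) x length(x) matrix.
.lagrange_eval <- function(x, wb, y) {
  out <- matrix(0, length(y), length(x))
  for (q in seq_along(y)) {
    d <- y[q] - x
    hit <- which(abs(d) < .Machine$double.eps)
    if (length(hit)) {
      out[q, hit[1]] <- 1
    } else {
      t <- wb / d
      out[q, ] <- t / sum(t)
    }
  }
  out
}

#' Integrate node samples over \[0, 1\]
#'
#' Applies the grid's quadrature weights to values sampled at the collocation
#' nodes. Exact for polynomials within the grid's degree of exactness; this is
#' the rule behind the depth-averaged biofilm reaction rate.
#'
#' @param grid A [colloc_grid()] object.
#' @param values Numeric vector, one entry per node.
#' @return A scalar, `sum(quad_weights * values)`.
#' @examples
#' g <- colloc_grid(3)
#' integrate_profile(g, g$nodes^3)  # exactly 1/4
#' @export
integrate_profile <- function(grid, values) {
  stopifnot(inherits(grid, "colloc_grid"))
  if (length(values) != grid$n) {
    stop("`values` must have one entry per node (", grid$n, ")", call. = FALSE)
  }
  sum(grid$quad_weights * values)
}
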