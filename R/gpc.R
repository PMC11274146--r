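#' Orthonormal Legendre polynomial on an interval
#'
#' Returns the degree-`d` Legendre polynomial rescaled to be orthonormal with
#' respect to the *uniform probability density* on `[a, b]`:
#' \deqn{\int_a^b \phi_m(x)\phi_n(x)\,\frac{dx}{b-a} = \delta_{mn}.}
#' Degree 0 is the constant 1; degree 1 on `[-1, 1]` is `sqrt(3) * x`.
#'
#' @param degree Nonnegative integer.
#' @param interval Length-2 numeric `c(a, b)`, `a < b`.
#' @param center Optional anchor used as the interval midpoint in the affine
#'   map (defaults to `(a + b) / 2`); exposed so cut lines can pass through
#'   the reference point bit-exactly.
#' @return A vectorized function of `x`.
#' @export
legendre_orthonormal_1d <- function(degree, interval, center = NULL) {
  stopifnot(degree >= 0, length(interval) == 2)
  if (!(interval[1] < interval[2])) stop("degenerate interval: need a < b")
  force(degree)
  function(x) legendre_design(x, degree, interval, center)[, degree + 1L]
}

# Columns 0..max_degree of orthonormal Legendre values at x, via the
# three-term recurrence (n+1) P_{n+1} = (2n+1) t P_n - n P_{n-1} on t in
# [-1, 1], then phi_n = sqrt(2n+1) P_n.
legendre_design <- function(x, max_degree, interval, center = NULL) {
  a <- interval[1]; b <- interval[2]
  if (is.null(center)) center <- (a + b) / 2
  t <- (x - center) / ((b - a) / 2)
  out <- matrix(0, length(x), max_degree + 1L)
  out[, 1L] <- 1
  if (max_degree >= 1) out[, 2L] <- t
  if (max_degree >= 2) {
    for (n in 1:(max_degree - 1L)) {
      out[, n + 2L] <- ((2 * n + 1) * t * out[, n + 1L] - n * out[, n]) / (n + 1)
    }
  }
  sweep(out, 2, sqrt(2 * (0:max_degree) + 1), "*")
}

#' Total-degree multi-index set
#'
#' All multi-indices `d` over `n_vars` variables with `sum(d) <= p`, in
#' graded order (total degree ascending) and, within a degree, lexicographic
#' with the first variable's degree descending.  The count is
#' `choose(n_vars + p, p)`.
#'
#' @param n_vars Number of variables (>= 1).
#' @param p Maximum total degree (>= 0).
#' @return Integer matrix, one row per multi-index; the first row is all
#'   zeros.
#' @export
total_degree_multi_indices <- function(n_vars, p) {
  stopifnot(n_vars >= 1, p >= 0)
  per_degree <- function(d, k) {
    if (k == 1L) return(matrix(d, 1L, 1L))
    blocks <- lapply(d:0, function(first) {
      cbind(first, per_degree(d - first, k - 1L))
    })
    do.call(rbind, blocks)
  }
  out <- do.call(rbind, lapply(0:p, per_degree, k = n_vars))
  dimnames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' Tensor-product Gauss-Legendre quadrature on a box
#'
#' Builds the `n_gl`-point Gauss-Legendre rule per dimension (odd `n_gl`
#' only, so every 1-D rule contains the interval midpoint) and tensorizes.
#' Weights are normalized to sum to 1, absorbing the uniform probability
#' density on the box, so `sum(f(nodes) * weights)` estimates `E[f]`.
#'
#' @param n_gl Odd number of points per dimension.
#' @param box List of `c(a, b)` intervals (or a `d x 2` matrix).
#' @param center Optional numeric vector of per-dimension anchors through
#'   which the middle node passes bit-exactly (defaults to the midpoints).
#' @return List with `nodes` (matrix `n_gl^d x d`, first column cycling
#'   fastest), `weights` (sums to 1), `box`, `n_gl`, `center`.
#' @export
gl_rule <- function(n_gl, box, center = NULL) {
  if (n_gl %% 2 == 0) {
    stop("unsupported rule: n_gl must be odd so component functions share the center point")
  }
  box <- as_box(box)
  d <- nrow(box)
  if (is.null(center)) center <- rowMeans(box)
  ref <- gl_reference_1d(n_gl)
  axes <- lapply(seq_len(d), function(k) {
    center[k] + ref$t * (box[k, 2] - box[k, 1]) / 2
  })
  nodes <- as.matrix(do.call(expand.grid, axes))
  dimnames(nodes) <- NULL
  w <- Reduce(function(acc, k) as.vector(outer(acc, ref$w)), seq_len(d)[-1],
              init = ref$w)
  list(nodes = nodes, weights = w, box = box, n_gl = n_gl, center = center)
}

# Symmetrized 1-D Gauss-Legendre rule on [-1, 1] with probability weights
# (sum 1); the middle node of an odd rule is exactly 0.
gl_reference_1d <- function(n_gl) {
  if (n_gl == 1L) return(list(t = 0, w = 1))
  gl <- pracma::gaussLegendre(n_gl, -1, 1)
  t <- (gl$x - rev(gl$x)) / 2
  t[(n_gl + 1L) / 2L] <- 0
  w <- (gl$w + rev(gl$w)) / 2
  list(t = t, w = w / sum(w))
}

as_box <- function(box) {
  if (is.list(box)) box <- do.call(rbind, box)
  box <- matrix(as.numeric(box), ncol = 2)
  if (any(box[, 1] >= box[, 2])) stop("degenerate interval: need a < b")
  box
}

#' Fit a gPC expansion from model values at quadrature nodes
#'
#' Computes the spectral projection coefficients
#' \deqn{\alpha_n = \sum_j F(\tilde x_j)\,\Phi_n(\tilde x_j)\,w_j}
#' for every total-degree basis term and every output column in one matrix
#' product, so arbitrarily many voxels are fitted in a single pass.  Values
#' may be real or complex; fitting real and imaginary parts separately is
#' identical to fitting the complex values (the projection is linear).
#'
#' @param values_at_nodes Matrix `n_nodes x n_outputs` (or a vector for one
#'   output), rows aligned with `rule$nodes`.
#' @param rule A quadrature rule from [gl_rule()].
#' @param basis Multi-index matrix from [total_degree_multi_indices()]
#'   (default: total degree <= `p`).
#' @param p Total degree used when `basis` is not supplied.
#' @param subset Optional integer vector naming which coordinates of the full
#'   parameter vector this expansion spans (bookkeeping for HDMR).
#' @return A `gpc_expansion`: list with `coefficients`
#'   (`n_basis x n_outputs`), `basis`, `box`, `center`, `subset`, `degree`.
#' @export
fit_gpc <- function(values_at_nodes, rule, basis = NULL, p = 2, subset = NULL) {
  if (is.null(dim(values_at_nodes))) {
    values_at_nodes <- matrix(values_at_nodes, ncol = 1)
  }
  if (nrow(values_at_nodes) != nrow(rule$nodes)) {
    stop("corrupted evaluation table: values are not row-aligned with rule nodes")
  }
  d <- ncol(rule$nodes)
  if (is.null(basis)) basis <- total_degree_multi_indices(d, p)
  phi <- basis_matrix(rule$nodes, basis, rule$box, rule$center)
  coef <- t(phi * rule$weights) %*% values_at_nodes
  structure(
    list(coefficients = coef, basis = basis, box = rule$box,
         center = rule$center, subset = subset, degree = max(rowSums(basis))),
    class = "gpc_expansion"
  )
}

# Joint basis values Phi_n(points): product of 1-D orthonormal Legendre
# polynomials per the multi-index rows.
basis_matrix <- function(points, basis, box, center = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = nrow(as_box(box)))
  box <- as_box(box)
  d <- ncol(points)
  if (is.null(center)) center <- rowMeans(box)
  maxdeg <- max(basis)
  per_dim <- lapply(seq_len(d), function(k) {
    legendre_design(points[, k], maxdeg, box[k, ], center[k])
  })
  phi <- matrix(1, nrow(points), nrow(basis))
  for (n in seq_len(nrow(basis))) {
    for (k in seq_len(d)) {
      dk <- basis[n, k]
      if (dk > 0) phi[, n] <- phi[, n] * per_dim[[k]][, dk + 1L]
    }
  }
  phi
}

#' Evaluate a gPC expansion at points
#'
#' @param expansion A `gpc_expansion`.
#' @param points Matrix of points (columns = the expansion's own variables).
#'   Points outside the expansion box are evaluated anyway with an
#'   extrapolation warning.
#' @param outputs Optional integer vector restricting which output columns
#'   are evaluated.
#' @return Matrix `n_points x n_outputs` (complex if the coefficients are).
#' @export
evaluate_gpc <- function(expansion, points, outputs = NULL) {
  box <- expansion$box
  if (is.null(dim(points))) points <- matrix(points, ncol = nrow(box))
  out_of_box <- any(sweep(points, 2, box[, 1], "<")) ||
    any(sweep(points, 2, box[, 2], ">"))
  if (out_of_box) {
    warning("evaluating gPC expansion outside its box (extrapolation)")
  }
  phi <- basis_matrix(points, expansion$basis, box, expansion$center)
  coef <- expansion$coefficients
  if (!is.null(outputs)) coef <- coef[, outputs, drop = FALSE]
  phi %*% coef
}

#' Closed-form mean and variance of a gPC expansion
#'
#' With an orthonormal basis under the uniform probability measure, the mean
#' is the constant-term coefficient and the variance is the sum of squared
#' moduli of all higher coefficients - no sampling involved.
#'
#' @param expansion A `gpc_expansion`.
#' @return List with `mean` (complex or real vector per output) and
#'   `variance` (real vector per output).
#' @export
gpc_moments <- function(expansion) {
  coef <- expansion$coefficients
  stopifnot(all(expansion$basis[1, ] == 0))
  list(
    mean = coef[1, ],
    variance = colSums(Mod(coef[-1, , drop = FALSE])^2)
  )
}
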