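#' Least-squares gPC baseline surrogate
#'
#' Fits a full-dimensional total-degree Legendre expansion by ordinary least
#' squares over a (typically Latin hypercube) training design - the
#' regression-based polynomial-chaos comparison surrogate.  The solve uses a
#' QR orthogonal decomposition per output column (real and imaginary parts of
#' complex observables are fitted separately, which is exact by linearity),
#' with a rank check on the design matrix.
#'
#' At total degree 2 over 12 inputs the basis has 91 terms; the conventional
#' 300-point Latin hypercube training budget keeps the system comfortably
#' overdetermined.
#'
#' @param train_x A `sample_design` (or point matrix), `n_train` rows.
#' @param train_y Matrix `n_train x n_outputs` of observable values (real or
#'   complex), rows aligned with `train_x`.
#' @param space A `param_space` supplying the box (or pass `box`).
#' @param p Total polynomial degree (default 2).
#' @param box Optional explicit `d x 2` box matrix.
#' @return An `ls_gpc` (also a `gpc_expansion`, so [evaluate_gpc()] and
#'   [gpc_moments()] apply): coefficients, basis, box, plus `n_train` and the
#'   training residual norm.
#' @export
fit_ls_gpc <- function(train_x, train_y, space = NULL, p = 2, box = NULL) {
  pts <- if (is.matrix(train_x)) train_x else design_matrix(train_x)
  if (is.null(dim(train_y))) train_y <- matrix(train_y, ncol = 1)
  stopifnot(nrow(pts) == nrow(train_y))
  if (is.null(box)) box <- param_box(space)
  basis <- total_degree_multi_indices(ncol(pts), p)
  if (nrow(pts) < nrow(basis)) {
    stop("training set smaller than the basis (", nrow(basis),
         " terms): system underdetermined")
  }
  phi <- basis_matrix(pts, basis, box)
  dec <- qr(phi)
  if (dec$rank < ncol(phi)) {
    stop("rank-deficient design matrix (rank ", dec$rank, " < ", ncol(phi),
         "): degenerate training set")
  }
  coef <- if (is.complex(train_y)) {
    qr.coef(dec, Re(train_y)) + 1i * qr.coef(dec, Im(train_y))
  } else {
    qr.coef(dec, train_y)
  }
  if (is.null(dim(coef))) coef <- matrix(coef, ncol = 1)
  resid <- sqrt(sum(Mod(train_y - phi %*% coef)^2))
  structure(
    list(coefficients = coef, basis = basis, box = as_box(box),
         center = rowMeans(as_box(box)), subset = seq_len(ncol(pts)),
         degree = p, n_train = nrow(pts), residual_norm = resid),
    class = c("ls_gpc", "gpc_expansion")
  )
}

#' Evaluate a least-squares gPC surrogate
#'
#' @param surrogate An `ls_gpc`.
#' @param points Input point matrix.
#' @param outputs Optional output subset.
#' @return Matrix `n_points x n_outputs`.
#' @export
evaluate_ls_gpc <- function(surrogate, points, outputs = NULL) {
  evaluate_gpc(surrogate, points, outputs)
}

#' @export
print.ls_gpc <- function(x, ...) {
  cat("<ls_gpc> degree ", x$degree, ", ", nrow(x$basis), " terms, ",
      x$n_train, " training points, residual norm ",
      signif(x$residual_norm, 4), "\n", sep = "")
  invisible(x)
}
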