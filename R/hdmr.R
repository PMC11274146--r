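#' Build an adaptive CUT-HDMR surrogate of a deterministic forward model
#'
#' Approximates a vector-valued observable \eqn{y = F(x)} over the parameter
#' box by a cut-type high-dimensional model representation truncated at
#' second order,
#' \deqn{F(x) \approx F_0 + \sum_i F_i(x_i) + \sum_{i<j} F_{ij}(x_i, x_j),}
#' with every component function represented by a generalized polynomial
#' chaos (gPC) expansion fitted by tensor Gauss-Legendre quadrature on the
#' line (plane) through the reference point.
#'
#' The construction is iterative: after the zeroth- and all first-order
#' components are fitted, each dimension receives an importance weight
#' \eqn{\eta_i = \lVert E[F_i] \rVert_2 / \lVert F_0 \rVert_2}
#' and only dimensions with \eqn{\eta_i > } `tol` (strict) enter the
#' important set from which second-order pairs are generated.  First-order
#' components of unimportant dimensions are still retained in the final
#' expansion - they are already paid for.
#'
#' All model calls go through a cache keyed on the exact input vector, so the
#' shared center point and the line nodes embedded in every plane are never
#' recomputed; the resulting unique-evaluation count obeys
#' \eqn{N_{cp} = 1 + N(N_{GL}-1) + |pairs| (N_{GL}-1)^2}
#' (see [count_collocation_points()]).
#'
#' @param model Function mapping a length-`N` numeric vector inside the
#'   parameter box to a fixed-length real or complex observable vector
#'   (voxels, field components, ...).  Must be deterministic.
#' @param space A `param_space` from [head_tissue_space()] (or compatible).
#' @param p Total polynomial degree of each component gPC (default 2).
#' @param n_gl Odd number of Gauss-Legendre points per dimension (default 3).
#' @param tol Importance tolerance \eqn{\xi} (default `1e-2`); dimensions
#'   with weight exactly equal to `tol` are excluded.
#' @param max_order 1 or 2: truncation order of the expansion.
#' @param weight `"mean"` for the norm-of-mean weight above (the default), or
#'   `"variance"` to rank dimensions by
#'   \eqn{\sqrt{\sum_{voxels} Var[F_i]} / \lVert F_0\rVert_2}, which also
#'   sees odd (zero-mean) dependence.
#' @return An `hdmr_surrogate`: list with `f0`, `first_order` (list of
#'   `gpc_expansion`, one per dimension), `second_order` (named list over
#'   selected pairs), `eta`, `important` (pre-selection set S), `ledger`
#'   (tibble of per-component new-point counts plus the deduplicated total
#'   and the evaluated points), `space` and the build settings.
#' @seealso [evaluate_hdmr()], [importance_weights()], [tidy.hdmr_surrogate()]
#' @export
build_hdmr <- function(model, space, p = 2, n_gl = 3, tol = 1e-2,
                       max_order = 2, weight = c("mean", "variance")) {
  weight <- match.arg(weight)
  stopifnot(max_order %in% c(1, 2))
  if (n_gl %% 2 == 0) stop("n_gl must be odd (component functions share the center point)")
  box <- param_box(space)
  ref <- reference_point(space)
  n_dims <- nrow(box)

  cache <- new.env(parent = emptyenv())
  order_of_first_eval <- character(0)
  evals_new <- 0L
  eval_model <- function(x) {
    key <- paste(sprintf("%.17g", x), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- unname(model(x))
    if (any(!is.finite(Mod(val)))) {
      stop("model evaluation returned non-finite values at input [",
           paste(signif(x, 6), collapse = ", "), "]")
    }
    cache[[key]] <- val
    evals_new <<- evals_new + 1L
    order_of_first_eval[[evals_new]] <<- key
    val
  }
  eval_rows <- function(pts) {
    vals <- lapply(seq_len(nrow(pts)), function(r) eval_model(pts[r, ]))
    do.call(rbind, vals)
  }

  ledger_rows <- list()
  note <- function(component, subset, before) {
    ledger_rows[[length(ledger_rows) + 1L]] <<- tibble::tibble(
      component = component, order = length(subset),
      subset = paste(subset, collapse = ","), new_points = evals_new - before
    )
  }

  # zeroth order: the observable at the anchor
  before <- evals_new
  f0 <- eval_model(ref)
  note("F0", integer(0), before)
  n_outputs <- length(f0)

  # first order: gPC on the line through the anchor, model minus F0
  first_order <- vector("list", n_dims)
  for (i in seq_len(n_dims)) {
    before <- evals_new
    rule <- gl_rule(n_gl, box[i, , drop = FALSE], center = ref[i])
    pts <- matrix(ref, nrow = n_gl, ncol = n_dims, byrow = TRUE)
    pts[, i] <- rule$nodes[, 1]
    vals <- eval_rows(pts)
    vals <- sweep_off(vals, f0)
    first_order[[i]] <- fit_gpc(vals, rule, p = p, subset = i)
    note(paste0("F", i), i, before)
  }

  eta <- importance_weights(f0, first_order, weight = weight)
  important <- which(eta > tol)

  second_order <- list()
  if (max_order == 2 && length(important) >= 2) {
    pairs <- utils::combn(important, 2)
    for (c_idx in seq_len(ncol(pairs))) {
      i <- pairs[1, c_idx]; j <- pairs[2, c_idx]
      before <- evals_new
      rule <- gl_rule(n_gl, box[c(i, j), , drop = FALSE], center = ref[c(i, j)])
      pts <- matrix(ref, nrow = nrow(rule$nodes), ncol = n_dims, byrow = TRUE)
      pts[, i] <- rule$nodes[, 1]
      pts[, j] <- rule$nodes[, 2]
      vals <- eval_rows(pts)
      # subtract all lower-order contributions at the nodes
      vals <- sweep_off(vals, f0)
      vals <- vals - evaluate_gpc(first_order[[i]], rule$nodes[, 1])
      vals <- vals - evaluate_gpc(first_order[[j]], rule$nodes[, 2])
      second_order[[paste0(i, ",", j)]] <-
        fit_gpc(vals, rule, p = p, subset = c(i, j))
      note(paste0("F", i, ",", j), c(i, j), before)
    }
  }

  ledger <- dplyr::bind_rows(ledger_rows)
  pts_mat <- do.call(rbind, lapply(order_of_first_eval, function(k) {
    as.numeric(strsplit(k, ",", fixed = TRUE)[[1]])
  }))
  structure(
    list(
      space = space, f0 = f0, first_order = first_order,
      second_order = second_order, eta = eta, important = important,
      tol = tol, p = p, n_gl = n_gl, max_order = max_order, weight = weight,
      n_outputs = n_outputs, complex_output = is.complex(f0),
      ledger = structure(ledger, unique_points = pts_mat, total = evals_new)
    ),
    class = "hdmr_surrogate"
  )
}

# rows minus a fixed vector, preserving complex type
sweep_off <- function(values, v) {
  values - matrix(v, nrow = nrow(values), ncol = length(v), byrow = TRUE)
}

#' Importance weights of the input dimensions
#'
#' \eqn{\eta_i = \lVert E[F_i(x_i)] \rVert_2 / \lVert F_0 \rVert_2}, with the
#' per-output means taken coefficient-wise from the fitted gPC components
#' ([gpc_moments()]) and the norms over all output entries.  The ratio of L2
#' norms is the vector-output generalization of the scalar mean ratio; a
#' dimension the model does not depend on gets exactly 0.
#'
#' @param f0 Zeroth-order observable vector (the model at the anchor).
#' @param first_order List of fitted first-order `gpc_expansion`s.
#' @param weight `"mean"` (mean-ratio, the default) or `"variance"`.
#' @return Numeric vector of weights, one per dimension.
#' @export
importance_weights <- function(f0, first_order, weight = c("mean", "variance")) {
  weight <- match.arg(weight)
  denom <- sqrt(sum(Mod(f0)^2))
  if (denom == 0) stop("degenerate model: all-zero reference output")
  vapply(first_order, function(comp) {
    mom <- gpc_moments(comp)
    num <- if (weight == "mean") sqrt(sum(Mod(mom$mean)^2)) else sqrt(sum(mom$variance))
    num / denom
  }, numeric(1))
}

#' Evaluate a CUT-HDMR surrogate
#'
#' Sums \eqn{F_0 + \sum_i F_i(x_i) + \sum_{i<j} F_{ij}(x_i,x_j)} for every
#' point, as one matrix product over all retained components.  At the
#' reference point all components of order >= 1 vanish and the result is
#' exactly `f0`.
#'
#' @param surrogate An `hdmr_surrogate`.
#' @param points Matrix of input points (rows) or a single vector.
#' @param outputs Optional integer vector restricting the output entries
#'   (e.g. a few voxels) - the coefficient matrices are subset before the
#'   product, so evaluation cost scales with `length(outputs)`.
#' @return Matrix `n_points x n_outputs` (complex if the model is).
#' @export
evaluate_hdmr <- function(surrogate, points, outputs = NULL) {
  box <- param_box(surrogate$space)
  if (is.null(dim(points))) points <- matrix(points, ncol = nrow(box))
  if (any(sweep(points, 2, box[, 1], "<")) || any(sweep(points, 2, box[, 2], ">"))) {
    warning("evaluating HDMR surrogate outside the parameter box (extrapolation)")
  }
  comps <- c(surrogate$first_order, surrogate$second_order)
  phi_blocks <- vector("list", length(comps))
  coef_blocks <- vector("list", length(comps))
  for (k in seq_along(comps)) {
    comp <- comps[[k]]
    phi_blocks[[k]] <- basis_matrix(points[, comp$subset, drop = FALSE],
                                    comp$basis, comp$box, comp$center)
    cf <- comp$coefficients
    if (!is.null(outputs)) cf <- cf[, outputs, drop = FALSE]
    coef_blocks[[k]] <- cf
  }
  f0 <- if (is.null(outputs)) surrogate$f0 else surrogate$f0[outputs]
  out <- do.call(cbind, phi_blocks) %*% do.call(rbind, coef_blocks)
  out + matrix(f0, nrow = nrow(points), ncol = length(f0), byrow = TRUE)
}

#' Collocation-point budget of a CUT-HDMR build
#'
#' Number of unique deterministic-model evaluations needed when points shared
#' between component functions (the center point, and plane nodes lying on
#' the lines) are counted once:
#' \deqn{N_{cp} = 1 + N\,(N_{GL}-1) + |pairs|\,(N_{GL}-1)^2.}
#' The first-order term always spans all `n_dims` dimensions (every line is
#' evaluated before selection); the pair term applies only at `max_order = 2`.
#'
#' @param n_dims Number of input dimensions N.
#' @param selected_pairs Number of second-order pairs retained.
#' @param n_gl Odd Gauss-Legendre points per dimension.
#' @param max_order 1 or 2.
#' @return Integer count.
#' @examples
#' count_collocation_points(12, 0, 3, max_order = 1)   # 25
#' count_collocation_points(12, 66, 3, max_order = 2)  # 289
#' count_collocation_points(12, 66, 5, max_order = 2)  # 1105
#' @export
count_collocation_points <- function(n_dims, selected_pairs = 0, n_gl = 3,
                                     max_order = 2) {
  stopifnot(selected_pairs <= n_dims * (n_dims - 1) / 2)
  total <- 1 + n_dims * (n_gl - 1)
  if (max_order == 2) total <- total + selected_pairs * (n_gl - 1)^2
  as.integer(total)
}

#' Per-dimension variances of the first-order components
#'
#' Variance of each \eqn{F_i} over its own variable, read off the gPC
#' coefficients - the cut variances reused by the sensitivity module.
#'
#' @param surrogate An `hdmr_surrogate`.
#' @return Real matrix `n_dims x n_outputs`.
#' @export
hdmr_first_order_variances <- function(surrogate) {
  do.call(rbind, lapply(surrogate$first_order, function(comp) {
    gpc_moments(comp)$variance
  }))
}

#' @export
print.hdmr_surrogate <- function(x, ...) {
  cat("<hdmr_surrogate> order-", x$max_order, " CUT-HDMR, p = ", x$p,
      ", n_gl = ", x$n_gl, "\n", sep = "")
  cat("  dimensions: ", length(x$first_order),
      " (important: ", length(x$important), ")",
      "  pairs: ", length(x$second_order), "\n", sep = "")
  cat("  outputs: ", x$n_outputs,
      if (x$complex_output) " (complex)" else " (real)",
      "   unique model evaluations: ", attr(x$ledger, "total"), "\n", sep = "")
  invisible(x)
}

#' Plan the collocation points of an HDMR build for an external simulator
#'
#' Emits the full request list of input vectors (deduplicated, center first)
#' that a `max_order`/`n_gl` build will need, so the corresponding
#' deterministic simulations can be run elsewhere and fed back through
#' [tabulated_model()].  Because importance selection happens only after the
#' first-order values exist, the plan conservatively includes all pairs of
#' `dims` (default: all dimensions).
#'
#' @inheritParams build_hdmr
#' @param dims Dimensions assumed important for pair planning.
#' @return A tibble: one row per unique input vector, columns = parameter
#'   symbols plus a `point_id`.
#' @export
hdmr_plan <- function(space, n_gl = 3, max_order = 2, dims = NULL) {
  box <- param_box(space)
  ref <- reference_point(space)
  n <- nrow(box)
  if (is.null(dims)) dims <- seq_len(n)
  seen <- new.env(parent = emptyenv())
  rows <- list()
  add <- function(x) {
    key <- paste(sprintf("%.17g", x), collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      rows[[length(rows) + 1L]] <<- x
    }
  }
  add(ref)
  for (i in seq_len(n)) {
    nodes <- gl_rule(n_gl, box[i, , drop = FALSE], center = ref[i])$nodes[, 1]
    for (v in nodes) { x <- ref; x[i] <- v; add(x) }
  }
  if (max_order == 2 && length(dims) >= 2) {
    pairs <- utils::combn(dims, 2)
    for (c_idx in seq_len(ncol(pairs))) {
      i <- pairs[1, c_idx]; j <- pairs[2, c_idx]
      nodes <- gl_rule(n_gl, box[c(i, j), , drop = FALSE], center = ref[c(i, j)])$nodes
      for (r in seq_len(nrow(nodes))) {
        x <- ref; x[i] <- nodes[r, 1]; x[j] <- nodes[r, 2]; add(x)
      }
    }
  }
  pts <- do.call(rbind, rows)
  colnames(pts) <- space$symbol
  out <- tibble::as_tibble(as.data.frame(pts))
  tibble::add_column(out, point_id = seq_len(nrow(out)), .before = 1)
}

#' Wrap precomputed simulation results as a forward model
#'
#' Turns a filled evaluation table (the plan from [hdmr_plan()] plus one
#' observable vector per row) into a deterministic model function that looks
#' results up by exact input vector, erroring on any unplanned point.
#'
#' @param plan Tibble from [hdmr_plan()] (or any table whose non-`point_id`
#'   columns are the input coordinates).
#' @param values Matrix with one row per plan row: the observable vectors.
#' @return A function usable as the `model` argument of [build_hdmr()].
#' @export
tabulated_model <- function(plan, values) {
  pts <- as.matrix(plan[setdiff(names(plan), "point_id")])
  stopifnot(nrow(pts) == nrow(values))
  lookup <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(pts))) {
    lookup[[paste(sprintf("%.17g", pts[r, ]), collapse = ",")]] <- values[r, ]
  }
  function(x) {
    key <- paste(sprintf("%.17g", x), collapse = ",")
    val <- lookup[[key]]
    if (is.null(val)) {
      stop("input vector not in the evaluation table: [",
           paste(signif(x, 6), collapse = ", "), "]")
    }
    val
  }
}
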