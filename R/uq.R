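# Normalize the three evaluator flavours (HDMR surrogate, gPC/LS-gPC
# expansion, plain function of one input vector) to a batched interface.
as_evaluator <- function(evaluator) {
  if (inherits(evaluator, "batched_evaluator")) {
    evaluator
  } else if (inherits(evaluator, "hdmr_surrogate")) {
    function(points, outputs = NULL) evaluate_hdmr(evaluator, points, outputs)
  } else if (inherits(evaluator, "gpc_expansion")) {
    function(points, outputs = NULL) evaluate_gpc(evaluator, points, outputs)
  } else if (is.function(evaluator)) {
    function(points, outputs = NULL) {
      rows <- lapply(seq_len(nrow(points)), function(r) {
        v <- evaluator(points[r, ])
        if (is.null(outputs)) v else v[outputs]
      })
      do.call(rbind, rows)
    }
  } else {
    stop("evaluator must be an hdmr_surrogate, a gpc_expansion, or a function")
  }
}

#' Monte Carlo mean and variance of an observable
#'
#' Draws uniform points over the parameter box, evaluates the model or
#' surrogate, and accumulates the element-wise running mean and second
#' moment; the variance is the second moment minus the squared mean (for
#' complex observables, of the modulus).  Checkpoints of the running
#' statistics are recorded every `checkpoint_every` samples for convergence
#' plots.
#'
#' @param evaluator An `hdmr_surrogate`, a fitted gPC expansion, or a
#'   function of a single input vector (the brute-force path).
#' @param space A `param_space`.
#' @param n Sample size (>= 2).  The surrogate-assisted convention is
#'   10,000; brute-force comparisons use 5,000.
#' @param seed Master seed; the MC stream is split off via [child_seed()].
#' @param checkpoint_every Cadence of convergence checkpoints (default 50).
#' @param outputs Optional output subset (e.g. a few voxels).
#' @param trace_outputs Outputs to record in the convergence trace; defaults
#'   to all when at most 20 outputs are evaluated, otherwise none.
#' @param chunk_size Points evaluated per internal batch.
#' @return An `mc_statistics`: list with `mean`, `variance` (clamped to be
#'   nonnegative; estimates below -1e-12 of scale would error), `n`, `seed`
#'   and a `trace` tibble (`n`, `output`, `mean`, `variance`).
#' @export
mc_statistics <- function(evaluator, space, n = 10000, seed = 1L,
                          checkpoint_every = 50, outputs = NULL,
                          trace_outputs = NULL, chunk_size = 500) {
  stopifnot(n >= 2)
  ev <- as_evaluator(evaluator)
  design <- sample_uniform(space, n, seed = child_seed(seed, "mc"))
  pts <- design_matrix(design)
  chunk_size <- max(chunk_size, checkpoint_every)

  s1 <- NULL; s2 <- NULL; seen <- 0L
  trace <- list()
  done_to <- 0L
  while (seen < n) {
    take <- min(chunk_size, n - seen)
    vals <- ev(pts[seen + seq_len(take), , drop = FALSE], outputs)
    if (is.null(s1)) {
      s1 <- vals[1, ] * 0; s2 <- numeric(ncol(vals))
      if (is.null(trace_outputs)) {
        trace_outputs <- if (ncol(vals) <= 20) seq_len(ncol(vals)) else integer(0)
      }
    }
    # per-sample accumulation inside the chunk so checkpoints land exactly
    cum1 <- apply(vals, 2, cumsum)
    cum2 <- apply(Mod(vals)^2, 2, cumsum)
    if (take == 1) { cum1 <- matrix(cum1, 1); cum2 <- matrix(cum2, 1) }
    marks <- seq(done_to + checkpoint_every, seen + take, by = checkpoint_every)
    marks <- marks[marks > seen]
    for (m in marks) {
      s1_m <- s1 + cum1[m - seen, ]
      s2_m <- s2 + cum2[m - seen, ]
      if (length(trace_outputs) > 0) {
        mu <- s1_m / m
        va <- pmax(Re(s2_m / m) - Mod(mu)^2, 0)
        trace[[length(trace) + 1L]] <- tibble::tibble(
          n = m, output = trace_outputs,
          mean = if (is.complex(mu)) Mod(mu[trace_outputs]) else mu[trace_outputs],
          variance = va[trace_outputs]
        )
      }
    }
    if (length(marks) > 0) done_to <- max(marks)
    s1 <- s1 + cum1[take, ]
    s2 <- s2 + cum2[take, ]
    seen <- seen + take
  }
  mu <- s1 / n
  va <- Re(s2 / n) - Mod(mu)^2
  scale <- max(abs(va), 1)
  if (any(va < -1e-12 * scale)) stop("variance estimate significantly negative")
  va <- pmax(va, 0)
  structure(
    list(mean = mu, variance = va, n = n, seed = seed,
         trace = dplyr::bind_rows(trace)),
    class = "mc_statistics"
  )
}

#' @export
print.mc_statistics <- function(x, ...) {
  cat("<mc_statistics> n = ", x$n, ", ", length(x$mean), " outputs\n", sep = "")
  invisible(x)
}

#' Cut-based Sobol sensitivity indices
#'
#' For each requested dimension k, a Monte Carlo run varies only \eqn{x_k}
#' over its range while every other coordinate is pinned to its nominal
#' value; the index is that cut variance over the full-space variance,
#' \eqn{S_k = Var_{x_k}[y] / Var[y]}, per output entry.  The denominator
#' comes from a separate full-space MC run on its own child stream.
#'
#' @param evaluator As in [mc_statistics()].
#' @param space A `param_space`.
#' @param k Dimensions to assess (default: all).
#' @param n Samples per cut (and for the full-variance run).
#' @param seed Master seed (split per dimension and for the full run).
#' @param outputs Optional output subset.
#' @return A `sobol_cut` matrix `length(k) x n_outputs` (rownames = parameter
#'   symbols) with the full-space variance attached as attribute
#'   `full_variance`.  Outputs with zero full variance are flagged `NA` with
#'   a warning.
#' @export
sobol_cut <- function(evaluator, space, k = NULL, n = 10000, seed = 1L,
                      outputs = NULL) {
  ev <- as_evaluator(evaluator)
  box <- param_box(space)
  ref <- reference_point(space)
  if (is.null(k)) k <- seq_len(nrow(box))
  stopifnot(all(k >= 1), all(k <= nrow(box)))

  full <- mc_statistics(evaluator, space, n = n,
                        seed = child_seed(seed, "sobol_full"),
                        outputs = outputs, trace_outputs = integer(0))
  denom <- full$variance

  num <- matrix(NA_real_, length(k), length(denom))
  for (row in seq_along(k)) {
    kk <- k[row]
    set.seed(child_seed(seed, paste0("sobol_dim", kk)))
    draws <- stats::runif(n, box[kk, 1], box[kk, 2])
    pts <- matrix(ref, n, nrow(box), byrow = TRUE)
    pts[, kk] <- draws
    vals <- ev(pts, outputs)
    mu <- colMeans(vals)
    num[row, ] <- pmax(colMeans(Mod(vals)^2) - Mod(mu)^2, 0)
  }
  zero <- denom == 0
  if (any(zero)) warning(sum(zero), " outputs have zero full variance; Sobol index undefined (NA)")
  s <- sweep(num, 2, ifelse(zero, NA_real_, denom), "/")
  rownames(s) <- space$symbol[k]
  structure(s, full_variance = denom, n = n, class = c("sobol_cut", "matrix"))
}

#' Tissue-averaged Sobol indices
#'
#' Averages per-voxel Sobol indices over all voxels of each tissue type:
#' \eqn{S^t_v = N_t^{-1} \sum_{i \in t} S_{v,i}}.
#'
#' @param per_voxel Matrix `n_inputs x n_voxels` (e.g. a `sobol_cut`).
#' @param labels Integer tissue label per voxel column.
#' @param tissue_names Optional names for the label levels.
#' @return A tibble with one row per (input, tissue): columns `input`,
#'   `tissue`, `n_voxels`, `sobol`.  Tissues with zero voxels are absent.
#' @export
tissue_averaged_sobol <- function(per_voxel, labels,
                                  tissue_names = NULL) {
  stopifnot(ncol(per_voxel) == length(labels))
  inputs <- rownames(per_voxel)
  if (is.null(inputs)) inputs <- paste0("x", seq_len(nrow(per_voxel)))
  levs <- sort(unique(labels))
  out <- purrr::map_dfr(levs, function(t) {
    cols <- labels == t
    tibble::tibble(
      input = inputs,
      tissue = if (is.null(tissue_names)) as.character(t) else tissue_names[t],
      n_voxels = sum(cols),
      sobol = unname(rowMeans(per_voxel[, cols, drop = FALSE]))
    )
  })
  class(out) <- c("sensitivity_table", class(out))
  out
}

#' Surrogate validation error report
#'
#' Per-voxel relative error averaged over the test points,
#' \eqn{err_i = N_{test}^{-1} \sum_n |y_{ni} - y'_{ni}| / |y_{ni}|},
#' summarized as the maximum and mean over voxels.  Voxels whose typical
#' magnitude falls below `guard` times the volume's median are excluded from
#' `err_max` (their relative errors are amplified noise) and reported
#' separately; `err_ave` is reported both with and without the guard.
#'
#' @param truth Matrix `n_test x n_voxels` of reference values (real or
#'   complex).
#' @param predicted Same shape, surrogate predictions.
#' @param threshold Exceedance level for the reported voxel fraction
#'   (default 0.01, i.e. 1%).
#' @param guard Near-zero guard factor (default `1e-3`).
#' @return An `error_report`: list with `per_voxel` errors, `err_max`,
#'   `err_ave`, `err_ave_guarded`, `threshold_exceedance`, `n_test`,
#'   `n_voxels`, `excluded` (indices of guarded-out voxels).
#' @export
relative_error_report <- function(truth, predicted, threshold = 0.01,
                                  guard = 1e-3) {
  if (is.null(dim(truth))) truth <- matrix(truth, nrow = 1)
  if (is.null(dim(predicted))) predicted <- matrix(predicted, nrow = 1)
  if (!all(dim(truth) == dim(predicted))) stop("shape mismatch between truth and predictions")
  rel <- Mod(truth - predicted) / Mod(truth)
  per_voxel <- colMeans(rel)
  typ <- apply(Mod(truth), 2, stats::median)
  excluded <- which(typ < guard * stats::median(typ))
  kept <- setdiff(seq_along(per_voxel), excluded)
  structure(
    list(
      per_voxel = per_voxel,
      err_max = max(per_voxel[kept]),
      err_ave = mean(per_voxel),
      err_ave_guarded = mean(per_voxel[kept]),
      threshold = threshold,
      threshold_exceedance = mean(per_voxel[kept] > threshold),
      n_test = nrow(truth), n_voxels = ncol(truth),
      excluded = excluded
    ),
    class = "error_report"
  )
}

#' @export
print.error_report <- function(x, ...) {
  cat("<error_report> ", x$n_voxels, " voxels x ", x$n_test, " test points\n",
      "  err_ave = ", sprintf("%.3f%%", 100 * x$err_ave),
      "  err_max = ", sprintf("%.3f%%", 100 * x$err_max),
      "  (", length(x$excluded), " near-zero voxels guarded out of err_max)\n",
      "  voxels above ", sprintf("%g%%", 100 * x$threshold), ": ",
      sprintf("%.3f%%", 100 * x$threshold_exceedance), "\n", sep = "")
  invisible(x)
}
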