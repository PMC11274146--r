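#' Uncertain dielectric-property space of the six head tissues
#'
#' The twelve uncertain inputs are the relative permittivity \eqn{\epsilon_r}
#' and conductivity \eqn{\sigma} (S/m) of white matter, grey matter,
#' cerebrospinal fluid (CSF), bone, scalp and eye humor.  Each is modelled as
#' an independent uniform random variable spanning +/-20% of its nominal
#' value.  The input vector is frozen in the order
#' \eqn{[\epsilon_{r1} \dots \epsilon_{r6}, \sigma_1 \dots \sigma_6]} so that
#' designs, caches and sensitivity tables stay index-compatible everywhere in
#' the package.
#'
#' @details
#' Ranges are regenerated as exactly `nominal * c(0.8, 1.2)`; the conventional
#' rounded brackets (kept in `printed_lower` / `printed_upper` for reference)
#' are not always centred on the nominal (bone conductivity is the example:
#' nominal 0.083, printed bracket \[0.07, 0.10\]).  The +/-20% rule governs.
#'
#' @param tissues Optional tibble overriding the default tissue table; must
#'   have columns `tissue`, `eps_r`, `sigma`, `density`.
#' @return A `param_space` tibble with one row per random variable and columns
#'   `name`, `symbol`, `tissue`, `property`, `nominal`, `lower`, `upper`,
#'   `printed_lower`, `printed_upper`, `distribution`.  The tissue density
#'   table (label, tissue, density in kg/m^3) is attached as attribute
#'   `densities`, and the reference point (the nominal vector) as attribute
#'   `reference`.
#' @examples
#' space <- head_tissue_space()
#' reference_point(space)
#' @export
head_tissue_space <- function(tissues = NULL) {
  if (is.null(tissues)) {
    tissues <- tibble::tibble(
      tissue  = c("white_matter", "grey_matter", "csf", "bone", "scalp", "eye_humor"),
      eps_r   = c(43.8, 60.0, 72.7, 13.4, 49.8, 69.0),
      sigma   = c(0.413, 0.692, 2.220, 0.083, 0.641, 1.520),
      density = c(1041, 1045, 1007, 1908, 1109, 1005),
      printed_eps_lower   = c(35.04, 48.00, 58.16, 10.72, 39.84, 55.20),
      printed_eps_upper   = c(52.56, 72.00, 87.24, 16.08, 59.76, 82.80),
      printed_sigma_lower = c(0.33, 0.55, 1.78, 0.07, 0.51, 1.22),
      printed_sigma_upper = c(0.50, 0.83, 2.66, 0.10, 0.77, 1.82)
    )
  }
  nt <- nrow(tissues)
  params <- tibble::tibble(
    name = c(paste0(tissues$tissue, "_eps_r"), paste0(tissues$tissue, "_sigma")),
    symbol = c(paste0("eps_r", seq_len(nt)), paste0("sigma", seq_len(nt))),
    tissue = rep(tissues$tissue, 2),
    property = rep(c("eps_r", "sigma"), each = nt),
    nominal = c(tissues$eps_r, tissues$sigma),
    distribution = "uniform"
  )
  params$lower <- 0.8 * params$nominal
  params$upper <- 1.2 * params$nominal
  if (all(c("printed_eps_lower", "printed_sigma_lower") %in% names(tissues))) {
    params$printed_lower <- c(tissues$printed_eps_lower, tissues$printed_sigma_lower)
    params$printed_upper <- c(tissues$printed_eps_upper, tissues$printed_sigma_upper)
  } else {
    params$printed_lower <- params$lower
    params$printed_upper <- params$upper
  }
  new_param_space(
    params,
    densities = tibble::tibble(
      label = seq_len(nt), tissue = tissues$tissue, density = tissues$density
    )
  )
}

new_param_space <- function(params, densities) {
  stopifnot(all(params$lower < params$nominal), all(params$nominal < params$upper))
  out <- tibble::new_tibble(params, class = "param_space")
  attr(out, "densities") <- densities
  attr(out, "reference") <- stats::setNames(params$nominal, params$symbol)
  out
}

#' Anchor point of the parameter space
#'
#' Returns the nominal vector: the reference point through which every
#' CUT-HDMR line and plane passes, and at which all component functions of
#' order one and above vanish.
#'
#' @param space A `param_space`.
#' @return Named numeric vector of length `nrow(space)`.
#' @export
reference_point <- function(space) {
  attr(space, "reference")
}

#' Tissue density table attached to a parameter space
#'
#' @param space A `param_space`.
#' @return Tibble with columns `label`, `tissue`, `density` (kg/m^3).
#' @export
tissue_densities <- function(space) {
  attr(space, "densities")
}

#' Per-parameter sampling box
#'
#' @param space A `param_space`.
#' @return A `n x 2` matrix of `lower`, `upper` bounds, rownames = symbols.
#' @export
param_box <- function(space) {
  m <- cbind(lower = space$lower, upper = space$upper)
  rownames(m) <- space$symbol
  m
}

#' @export
print.param_space <- function(x, ...) {
  cat("<param_space> ", nrow(x), " uniform random variables (+/-20% of nominal)\n",
      sep = "")
  NextMethod()
}

#' Deterministic child seeds for independent random streams
#'
#' One top-level integer seed is expanded into per-purpose child seeds by a
#' fixed string hash, so Monte Carlo draws, Latin hypercube designs and test
#' points never share a random stream.  The result is always in
#' `[1, 2^31 - 2]`.
#'
#' @param seed Integer master seed.
#' @param purpose Character tag naming the stream (e.g. `"mc"`, `"lhs"`).
#' @return Integer child seed.
#' @export
child_seed <- function(seed, purpose) {
  stopifnot(length(seed) == 1, is.finite(seed))
  h <- as.double(seed) %% 2147483399
  for (ch in utf8ToInt(as.character(purpose))) {
    h <- (h * 31 + ch) %% 2147483399
  }
  as.integer(h + 1)
}

#' Draw independent uniform samples over the parameter box
#'
#' @param space A `param_space`.
#' @param n Number of points (>= 1).
#' @param seed Integer seed; identical seeds give identical designs.
#' @return A `sample_design` tibble (`n` rows, one column per parameter
#'   symbol) with attributes `seed` and `scheme`.
#' @export
sample_uniform <- function(space, n, seed = 1L) {
  if (n < 1) stop("invalid design size: n must be >= 1")
  box <- param_box(space)
  set.seed(child_seed(seed, "uniform"))
  u <- matrix(stats::runif(n * nrow(box)), nrow = n)
  pts <- sweep(u, 2, box[, 2] - box[, 1], "*")
  pts <- sweep(pts, 2, box[, 1], "+")
  new_sample_design(pts, space, seed, "uniform_random")
}

#' Latin hypercube design over the parameter box
#'
#' One point per equal-probability stratum per coordinate, with strata
#' randomly permuted across coordinates (via [lhs::randomLHS()]).
#'
#' @inheritParams sample_uniform
#' @export
sample_lhs <- function(space, n = 300, seed = 1L) {
  if (n < 1) stop("invalid design size: n must be >= 1")
  box <- param_box(space)
  set.seed(child_seed(seed, "lhs"))
  u <- lhs::randomLHS(n, nrow(box))
  pts <- sweep(u, 2, box[, 2] - box[, 1], "*")
  pts <- sweep(pts, 2, box[, 1], "+")
  new_sample_design(pts, space, seed, "latin_hypercube")
}

new_sample_design <- function(points, space, seed, scheme) {
  colnames(points) <- space$symbol
  out <- tibble::new_tibble(as.data.frame(points), class = "sample_design")
  attr(out, "seed") <- seed
  attr(out, "scheme") <- scheme
  out
}

#' Matrix view of a sample design
#' @param design A `sample_design` (or any data frame of points).
#' @return Numeric matrix, one row per point.
#' @export
design_matrix <- function(design) {
  as.matrix(as.data.frame(design))
}

#' Write / read a parameter space as JSON
#'
#' The on-disk form carries every per-parameter field plus the tissue density
#' table, and survives a round trip bit-exactly (numbers are serialized at
#' full precision).
#'
#' @param space A `param_space`.
#' @param path File path (`.json`).
#' @return `write_param_space` returns `path` invisibly; `read_param_space`
#'   returns the reconstructed `param_space`.
#' @export
write_param_space <- function(space, path) {
  params <- as.data.frame(space)
  num_cols <- vapply(params, is.numeric, logical(1))
  params[num_cols] <- lapply(params[num_cols], function(x) sprintf("%.17g", x))
  payload <- list(
    parameters = params,
    tissues = as.data.frame(tissue_densities(space))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_param_space
#' @export
read_param_space <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- tibble::as_tibble(payload$parameters)
  for (col in c("nominal", "lower", "upper", "printed_lower", "printed_upper")) {
    if (col %in% names(params)) params[[col]] <- as.numeric(params[[col]])
  }
  tissues <- tibble::as_tibble(payload$tissues)
  tissues$density <- as.numeric(tissues$density)
  tissues$label <- as.integer(tissues$label)
  new_param_space(params, densities = tissues)
}

#' Write a sample design as CSV (header = parameter symbols)
#' @param design A `sample_design`.
#' @param path File path.
#' @export
write_design <- function(design, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(design)), path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  tibble::new_tibble(readr::read_csv(path, show_col_types = FALSE),
                     class = "sample_design")
}
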