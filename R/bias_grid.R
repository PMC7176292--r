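#' Mollifier kernel profile
#'
#' Tabulated 1D deposition kernel over bin offsets \code{-alpha..alpha}: a
#' quartic bump \eqn{w(r) \propto (1-(r/\alpha)^2)^2} with compact support,
#' normalized to unit mass. Two-dimensional grids use the product form.
#'
#' @param alpha positive integer half-width in bins.
#' @return numeric vector of length \code{2*alpha + 1} summing to 1.
#' @export
mollifier_profile <- function(alpha) {
  alpha <- as.integer(alpha)
  if (length(alpha) != 1L || is.na(alpha) || alpha < 1L)
    stop("'alpha' must be a positive integer")
  mollifier_profile_cpp(alpha)
}

#' Create an empty adaptive-bias grid
#'
#' Discretizes CV space into cells that accumulate mollified sampling weight
#' S. The bias potential of a cell is \eqn{V = b \, k_B T \, \log(c S + 1)},
#' evaluated lazily, and deposits are scaled down as V approaches the
#' fill-limit \code{flim} (overfill protection) so the bias can never drive
#' the system over unphysical barriers.
#'
#' Defaults follow the binding-simulation configuration: bias fraction
#' \code{b = 0.9}, deposition rate \code{c = 0.005} per step, kernel
#' half-width \code{alpha = 20} bins, and \code{kT = 0.6163} kcal/mol
#' (310 K).
#'
#' @param bins integer vector (length 1 or 2): cells per dimension.
#' @param range numeric \code{c(lo, hi)} or a list of such pairs, CV units
#'   (Angstrom or radians).
#' @param periodic logical per dimension; periodic dimensions wrap.
#' @param b bias fraction in (0, 1).
#' @param c deposition rate per time step (> 0).
#' @param alpha mollifier half-width in bins (positive integer); the kernel
#'   must fit in the grid (\code{bins >= 2*alpha + 1}).
#' @param flim fill-limit, kcal/mol (> 0).
#' @param kT thermal energy, kcal/mol (> 0).
#' @return an object of class \code{bias_grid}.
#' @examples
#' g <- make_grid(c(480, 480), list(c(0, 60), c(0, 60)))
#' bin_width(g) # 0.125 Angstrom per dimension
#' @export
make_grid <- function(bins, range, periodic = FALSE, b = 0.9, c = 0.005,
                      alpha = 20L, flim = 15, kT = 0.6163) {
  bins <- as.integer(bins)
  ndim <- length(bins)
  if (ndim < 1L || ndim > 2L) stop("grids must be 1D or 2D")
  if (!is.list(range)) range <- list(range)
  if (length(range) == 1L && ndim == 2L) range <- rep(range, 2L)
  if (length(range) != ndim) stop("'range' must give (lo, hi) per dimension")
  lo <- vapply(range, function(r) r[[1]], numeric(1))
  hi <- vapply(range, function(r) r[[2]], numeric(1))
  periodic <- rep_len(as.logical(periodic), ndim)
  alpha <- as.integer(alpha)
  if (any(hi <= lo)) stop("each range must have hi > lo")
  if (any(bins < 2L)) stop("need at least 2 bins per dimension")
  if (length(alpha) != 1L || is.na(alpha) || alpha < 1L)
    stop("'alpha' must be a positive integer")
  if (any(alpha >= bins / 2))
    stop("kernel wider than grid: need bins >= 2*alpha + 1")
  if (!is.numeric(b) || b <= 0 || b >= 1) stop("'b' must lie in (0, 1)")
  if (!is.numeric(c) || c <= 0) stop("'c' must be positive")
  if (!is.numeric(flim) || flim <= 0) stop("'flim' must be positive")
  if (!is.numeric(kT) || kT <= 0) stop("'kT' must be positive")
  structure(list(
    bins = bins, lo = as.double(lo), hi = as.double(hi),
    periodic = periodic, b = as.double(b), c = as.double(c),
    alpha = alpha, flim = as.double(flim), kT = as.double(kT),
    weight = numeric(prod(bins)), step_count = 0L
  ), class = "bias_grid")
}

#' Grid bin widths
#' @param grid a \code{bias_grid} or \code{fes_landscape}.
#' @return numeric vector of per-dimension cell widths.
#' @export
bin_width <- function(grid) (grid$hi - grid$lo) / grid$bins

#' @export
print.bias_grid <- function(x, ...) {
  cat(sprintf("mABP bias grid: %s cells over [%s]\n",
              paste(x$bins, collapse = " x "),
              paste(sprintf("%g..%g%s", x$lo, x$hi,
                            ifelse(x$periodic, " (periodic)", "")),
                    collapse = ", ")))
  cat(sprintf("  b = %g, c = %g/step, alpha = %d bins, flim = %g kcal/mol, kT = %g kcal/mol\n",
              x$b, x$c, x$alpha, x$flim, x$kT))
  cat(sprintf("  deposits: %d, total weight: %.4g, max bias: %.4g kcal/mol\n",
              x$step_count, sum(x$weight), max(grid_bias_values(x))))
  invisible(x)
}

# cell-center coordinates along dimension d
grid_centers <- function(grid, d = 1L) {
  h <- bin_width(grid)[d]
  grid$lo[d] + (seq_len(grid$bins[d]) - 0.5) * h
}

# V per cell, lazily from weight, hard-capped at the fill limit
grid_bias_values <- function(grid) {
  pmin(grid$b * grid$kT * log1p(grid$c * grid$weight), grid$flim)
}

as_cv_matrix <- function(cv, ndim) {
  if (is.null(dim(cv))) {
    if (length(cv) == ndim) cv <- matrix(cv, nrow = 1L)
    else if (ndim == 1L) cv <- matrix(cv, ncol = 1L)
    else stop("CV values must be a vector of length ", ndim,
              " or a matrix with ", ndim, " columns")
  }
  cv <- as.matrix(cv)
  storage.mode(cv) <- "double"
  if (ncol(cv) != ndim) stop("CV dimensionality does not match grid")
  if (any(!is.finite(cv))) stop("non-finite CV value")
  cv
}

#' Deposit bias at CV points
#'
#' Adds one mollifier kernel of (at most) unit mass centered on the cell
#' containing each CV point, in order. Each deposit is scaled by the
#' overfill factor \eqn{g = \mathrm{clip}(1 - V_{center}/f_{lim}, 0, 1)}
#' evaluated at the pre-deposit center cell; together with the hard cap on
#' the evaluated bias, the cell bias never exceeds \code{flim} anywhere.
#' Points beyond the range of a
#' non-periodic dimension are clamped to the edge cell and counted in the
#' \code{"n_clamped"} attribute.
#'
#' @param grid a \code{bias_grid}.
#' @param cv a CV point (vector) or one point per row (matrix).
#' @return the updated grid; attributes \code{"g"} (applied scales) and
#'   \code{"n_clamped"}.
#' @export
deposit <- function(grid, cv) {
  stopifnot(inherits(grid, "bias_grid"))
  pts <- as_cv_matrix(cv, length(grid$bins))
  grid$weight <- grid$weight + 0 # force a copy: C++ mutates in place
  res <- grid_deposit_cpp(grid, pts)
  grid$step_count <- grid$step_count + nrow(pts)
  attr(grid, "g") <- res$g
  attr(grid, "n_clamped") <- res$n_clamped
  grid
}

#' Bias potential and force at CV points
#'
#' Multilinear interpolation of the cell-centered bias V and the analytic
#' gradient of that interpolant, both continuous within cells. Outside the
#' range of a non-periodic dimension the edge value is returned with zero
#' outward gradient. The evaluated bias is capped at \code{flim}
#' everywhere.
#'
#' @param grid a \code{bias_grid}.
#' @param cv a CV point or matrix of points (rows).
#' @return list with \code{energy} (kcal/mol) and \code{gradient}
#'   (kcal/mol per CV unit, one row per point).
#' @export
bias_potential_and_force <- function(grid, cv) {
  stopifnot(inherits(grid, "bias_grid"))
  pts <- as_cv_matrix(cv, length(grid$bins))
  res <- grid_bias_eval_cpp(grid, pts)
  list(energy = res$value, gradient = res$gradient)
}

#' Free-energy estimate from a bias grid
#'
#' Converts the accumulated bias into a free-energy landscape. At
#' stationary growth of the log-form bias the deposited potential tracks
#' \eqn{V = \frac{b}{1+b}(C - F)}, so the estimator used is
#' \eqn{\hat F = -\frac{1+b}{b} V}, shifted so the minimum over visited
#' cells is zero. Cells never reached by any kernel mass are marked
#' unvisited and excluded from the shift.
#'
#' @param grid a \code{bias_grid} with nonzero total weight.
#' @return an object of class \code{fes_landscape}.
#' @export
free_energy_estimate <- function(grid) {
  stopifnot(inherits(grid, "bias_grid"))
  if (all(grid$weight == 0)) stop("no sampling: the grid is empty")
  V <- grid_bias_values(grid)
  visited <- grid$weight > 0
  F <- -(1 + grid$b) / grid$b * V
  F[visited] <- F[visited] - min(F[visited])
  F[!visited] <- NA_real_
  structure(list(
    bins = grid$bins, lo = grid$lo, hi = grid$hi, periodic = grid$periodic,
    F = F, visited = visited, replicate_count = 1L, kT = grid$kT
  ), class = "fes_landscape")
}

#' @export
print.fes_landscape <- function(x, ...) {
  cat(sprintf("free-energy landscape: %s cells, %.1f%% visited, %d replicate(s)\n",
              paste(x$bins, collapse = " x "),
              100 * mean(x$visited), x$replicate_count))
  if (any(x$visited))
    cat(sprintf("  F range (visited): 0..%.3g kcal/mol\n",
                max(x$F[x$visited])))
  invisible(x)
}

#' Write / read a bias-grid checkpoint
#'
#' Versioned `.mabp` checkpoint: a one-line JSON header (dimensions, bins,
#' ranges, periodicity, biasing parameters, step count) followed by the
#' weight block as little-endian float64.
#'
#' @param grid a \code{bias_grid}.
#' @param path file path.
#' @return \code{write_checkpoint}: the path, invisibly.
#' @export
write_checkpoint <- function(grid, path) {
  stopifnot(inherits(grid, "bias_grid"))
  hdr <- jsonlite::toJSON(list(
    format = "mabp-checkpoint", version = 1L,
    ndim = length(grid$bins), bins = grid$bins, lo = grid$lo, hi = grid$hi,
    periodic = grid$periodic, b = grid$b, c = grid$c, alpha = grid$alpha,
    flim = grid$flim, kT = grid$kT, step_count = grid$step_count,
    n_weights = length(grid$weight), storage = "float64le"
  ), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  writeBin(grid$weight, con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_checkpoint
#' @return \code{read_checkpoint}: the restored \code{bias_grid}.
#' @export
read_checkpoint <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- jsonlite::fromJSON(readLines(con, n = 1L))
  if (!identical(hdr$format, "mabp-checkpoint"))
    stop("not a mabp checkpoint: ", path)
  w <- readBin(con, "double", n = hdr$n_weights, size = 8L, endian = "little")
  if (length(w) != hdr$n_weights) stop("truncated checkpoint: ", path)
  structure(list(
    bins = as.integer(hdr$bins), lo = as.double(hdr$lo),
    hi = as.double(hdr$hi), periodic = as.logical(hdr$periodic),
    b = hdr$b, c = hdr$c, alpha = as.integer(hdr$alpha), flim = hdr$flim,
    kT = hdr$kT, weight = w, step_count = as.integer(hdr$step_count)
  ), class = "bias_grid")
}

#' Write / read a free-energy landscape as TSV
#'
#' Tab-separated export with one row per cell: cell-center CV coordinates,
#' free energy (kcal/mol, NA for unvisited cells) and a visited flag.
#' Contour levels (default 1, 3 and 5 kcal/mol, the figure convention) are
#' recorded in a comment header.
#'
#' @param fes a \code{fes_landscape}.
#' @param path file path.
#' @param contour_levels numeric levels recorded in the header comment.
#' @return \code{write_fes}: the path, invisibly.
#' @export
write_fes <- function(fes, path, contour_levels = c(1, 3, 5)) {
  stopifnot(inherits(fes, "fes_landscape"))
  ndim <- length(fes$bins)
  if (ndim == 1L) {
    df <- data.frame(cv1 = grid_centers(fes, 1L), F_kcal_per_mol = fes$F,
                     visited = as.integer(fes$visited))
  } else {
    cc <- expand.grid(cv1 = grid_centers(fes, 1L), cv2 = grid_centers(fes, 2L))
    df <- data.frame(cv1 = cc$cv1, cv2 = cc$cv2, F_kcal_per_mol = fes$F,
                     visited = as.integer(fes$visited))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# mabp-fes v1 bins=%s lo=%s hi=%s periodic=%s kT=%.10g replicates=%d",
            paste(fes$bins, collapse = ","), paste(fes$lo, collapse = ","),
            paste(fes$hi, collapse = ","),
            paste(as.integer(fes$periodic), collapse = ","),
            fes$kT, fes$replicate_count),
    sprintf("# contour_levels_kcal_per_mol=%s",
            paste(contour_levels, collapse = ","))
  ), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fes
#' @return \code{read_fes}: the restored \code{fes_landscape}.
#' @export
read_fes <- function(path) {
  lines <- readLines(path, n = 1L)
  if (!grepl("^# mabp-fes v1 ", lines))
    stop("not a mabp FES file: ", path)
  kv <- regmatches(lines, gregexpr("[a-zA-Z_]+=[^ ]+", lines))[[1]]
  meta <- list()
  for (p in kv) {
    s <- strsplit(p, "=", fixed = TRUE)[[1]]
    meta[[s[1]]] <- strsplit(s[2], ",", fixed = TRUE)[[1]]
  }
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(
    bins = as.integer(meta$bins), lo = as.double(meta$lo),
    hi = as.double(meta$hi), periodic = as.logical(as.integer(meta$periodic)),
    F = df$F_kcal_per_mol, visited = df$visited == 1L,
    replicate_count = as.integer(meta$replicates), kT = as.double(meta$kT)
  ), class = "fes_landscape")
}
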