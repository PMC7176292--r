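#' Seeded Langevin dynamics on a toy system
#'
#' BAOAB-discretized Langevin dynamics with total force
#' \eqn{-\nabla U - \nabla V(\mathrm{cv}) \cdot \nabla \mathrm{cv} - \nabla U_{restraint}};
#' in biased runs one overfill-protected deposit is made per step
#' (the deposition rate c is defined per time step). All randomness comes
#' from R's RNG seeded with \code{seed}, so identical configuration and
#' seed give bit-identical output.
#'
#' @param system a \code{toy_system}.
#' @param grid a \code{bias_grid} whose dimensionality matches the system's
#'   CVs (2D for \code{host_guest}, 1D/2D matching coordinates otherwise).
#' @param n_steps number of dynamics steps.
#' @param stride save every \code{stride} steps.
#' @param seed integer RNG seed.
#' @return list with \code{trajectory} (a \code{trajectory} object) and the
#'   updated \code{grid}.
#' @export
run_mabp <- function(system, grid, n_steps, stride = 10L, seed = 1L) {
  stopifnot(inherits(system, "toy_system"), inherits(grid, "bias_grid"))
  run_dynamics(system, grid, n_steps, stride, seed, deposit = TRUE)
}

#' Unbiased reference dynamics
#'
#' Same integrator and seed handling as \code{\link{run_mabp}} with no bias
#' and no deposits; marginals converge to the Boltzmann distribution of the
#' toy potential.
#'
#' @inheritParams run_mabp
#' @return a \code{trajectory} object.
#' @export
run_unbiased <- function(system, n_steps, stride = 10L, seed = 1L) {
  stopifnot(inherits(system, "toy_system"))
  run_dynamics(system, NULL, n_steps, stride, seed, deposit = FALSE)$trajectory
}

run_dynamics <- function(system, grid, n_steps, stride, seed, deposit) {
  n_steps <- as.integer(n_steps)
  stride <- as.integer(stride)
  if (n_steps < 1L) stop("'n_steps' must be positive")
  if (stride < 1L) stop("'stride' must be positive")
  if (!is.null(grid)) {
    nd_cv <- if (system$kind == "host_guest") 2L
             else if (system$kind == "mueller_brown") 2L else 1L
    if (length(grid$bins) != nd_cv)
      stop("CV dimensionality (", nd_cv, ") does not match grid (",
           length(grid$bins), "D)")
    grid$weight <- grid$weight + 0 # private copy: the core mutates in place
  }
  set.seed(as.integer(seed))

  if (system$kind == "host_guest") {
    nf <- 3L * system$hg$nlig
    noise <- matrix(rnorm(n_steps * nf), n_steps, nf)
    res <- run_hostguest_cpp(system$hg, grid, deposit, n_steps, stride,
                             noise, system$x0)
    cv_trace <- res$cv_trace
    monitor <- res$monitor
  } else {
    nd <- length(system$x0)
    noise <- matrix(rnorm(n_steps * nd), n_steps, nd)
    res <- run_langevin_cpp(system$pot_id, system$pars, system$x0,
                            system$kT, system$friction, system$dt,
                            n_steps, stride, noise, grid, deposit)
    cv_trace <- res$frames
    if (system$kind == "cosine_well")
      cv_trace <- cv_trace %% (2 * pi)
    monitor <- NULL
  }
  if (res$blowup)
    stop(sprintf("numerical blow-up at step %d (|coordinate| > 1e3); %s",
                 res$steps_done,
                 "check dt/friction or the bias configuration"))

  keep <- seq_len(res$n_saved)
  traj <- structure(list(
    frames = res$frames[keep, , drop = FALSE],
    cv_trace = cv_trace[keep, , drop = FALSE],
    monitor = if (!is.null(monitor)) monitor[keep],
    stride = stride, dt = system$dt,
    metadata = list(kind = system$kind, seed = as.integer(seed),
                    n_steps = n_steps, biased = deposit,
                    n_clamped = res$n_clamped)
  ), class = "trajectory")

  if (!is.null(grid)) {
    grid$step_count <- grid$step_count + if (deposit) res$steps_done else 0L
    list(trajectory = traj, grid = grid)
  } else {
    list(trajectory = traj, grid = NULL)
  }
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames (stride %d, dt %g ps) from '%s' run, seed %d\n",
              nrow(x$frames), x$stride, x$dt, x$metadata$kind, x$metadata$seed))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a \code{trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$frames)

#' Write / read a toy trajectory as XYZ
#'
#' Plain multi-frame XYZ (atom count, comment, then \code{name x y z}
#' records), the sidecar CV trace going through
#' \code{\link{write_cv_trace}}.
#'
#' @param traj a \code{trajectory} (frames with 3 columns per atom).
#' @param path file path.
#' @param names atom names (recycled).
#' @return \code{write_xyz}: the path, invisibly.
#' @export
write_xyz <- function(traj, path, names = NULL) {
  fr <- traj$frames
  if (ncol(fr) %% 3L != 0L) {
    # 1D/2D CV-space toys: zero-pad to one 3D pseudo-atom per frame
    pad <- 3L - ncol(fr) %% 3L
    fr <- cbind(fr, matrix(0, nrow(fr), pad))
  }
  na <- ncol(fr) %/% 3L
  if (is.null(names)) names <- sprintf("L%d", seq_len(na))
  names <- rep_len(names, na)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(fr))) {
    writeLines(c(as.character(na), sprintf("frame %d", i)), con)
    xyz <- matrix(fr[i, ], ncol = 3L, byrow = TRUE)
    writeLines(sprintf("%s %.6f %.6f %.6f", names, xyz[, 1], xyz[, 2], xyz[, 3]),
               con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @return \code{read_xyz}: a list with \code{frames} (matrix, 3 columns
#'   per atom) and \code{names}.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("empty XYZ file: ", path)
  na <- as.integer(lines[1L])
  per <- na + 2L
  nfr <- length(lines) %/% per
  frames <- matrix(NA_real_, nfr, 3L * na)
  nm <- character(na)
  for (i in seq_len(nfr)) {
    block <- lines[((i - 1L) * per + 3L):((i - 1L) * per + 2L + na)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    nm <- vapply(parts, `[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[i, ] <- as.vector(t(xyz))
  }
  list(frames = frames, names = nm)
}

#' Write / read a CV trace table
#'
#' Tab-separated sidecar for a trajectory: time (ps), CV values, and the
#' monitored distance when present.
#'
#' @param traj a \code{trajectory}.
#' @param path file path.
#' @return \code{write_cv_trace}: the path, invisibly.
#' @export
write_cv_trace <- function(traj, path) {
  cv <- traj$cv_trace
  df <- data.frame(time_ps = seq_len(nrow(cv)) * traj$stride * traj$dt)
  for (d in seq_len(ncol(cv))) df[[paste0("cv", d)]] <- cv[, d]
  if (!is.null(traj$monitor)) df$monitor_A <- traj$monitor
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cv_trace
#' @return \code{read_cv_trace}: a data frame with \code{time_ps},
#'   \code{cv*} and optionally \code{monitor_A} columns.
#' @export
read_cv_trace <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}
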