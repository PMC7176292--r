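#' Analytic toy systems
#'
#' Desk-scale physics substrates for the sampler. Each system carries an
#' analytic potential (kcal/mol), thermostat parameters and a default CV
#' grid; the free energy along the declared CVs is computable in closed
#' form or by dense quadrature, so biased runs can be checked against an
#' exact answer.
#'
#' \describe{
#'   \item{\code{toy_harmonic}}{1D harmonic well U = k x^2 / 2.}
#'   \item{\code{toy_double_well}}{1D quartic double well U = h (x^2 - 1)^2
#'     (barrier h kcal/mol between minima at x = -1, +1).}
#'   \item{\code{toy_mueller_brown}}{the classic four-Gaussian 2D surface,
#'     scaled by \code{scale} to desk-scale barriers.}
#'   \item{\code{toy_cosine_well}}{1D periodic well U = A (1 - cos x) on
#'     [0, 2*pi), the dihedral-mode stand-in.}
#' }
#'
#' @param k,h,scale,amplitude potential parameters (kcal/mol).
#' @param kT thermal energy, kcal/mol.
#' @param friction Langevin friction, 1/ps.
#' @param dt time step, ps.
#' @param x0 initial coordinate(s).
#' @return an object of class \code{toy_system}.
#' @name toy_systems
NULL

new_toy <- function(kind, pot_id, pars, x0, kT, friction, dt, grid_args) {
  structure(list(kind = kind, pot_id = pot_id, pars = as.double(pars),
                 x0 = as.double(x0), kT = kT, friction = friction, dt = dt,
                 grid_args = grid_args),
            class = "toy_system")
}

#' @rdname toy_systems
#' @export
toy_harmonic <- function(k = 1, kT = 0.6, friction = 5, dt = 0.01, x0 = 0) {
  new_toy("harmonic", 1L, k, x0, kT, friction, dt,
          list(bins = 480L, range = c(-6, 6), periodic = FALSE,
               b = 0.9, c = 0.005, alpha = 20L, kT = kT))
}

#' @rdname toy_systems
#' @export
toy_double_well <- function(h = 2, kT = 0.6, friction = 10, dt = 0.01, x0 = -1) {
  new_toy("double_well", 2L, h, x0, kT, friction, dt,
          list(bins = 480L, range = c(-2, 2), periodic = FALSE,
               b = 0.9, c = 0.005, alpha = 20L, kT = kT))
}

#' @rdname toy_systems
#' @export
toy_mueller_brown <- function(scale = 0.05, kT = 0.6, friction = 10,
                              dt = 0.005, x0 = c(-0.558, 1.442)) {
  new_toy("mueller_brown", 3L, scale, x0, kT, friction, dt,
          list(bins = c(96L, 96L), range = list(c(-1.75, 1.25), c(-0.5, 2.25)),
               periodic = FALSE, b = 0.9, c = 0.05, alpha = 4L, kT = kT))
}

#' @rdname toy_systems
#' @export
toy_cosine_well <- function(amplitude = 2, kT = 0.6, friction = 5,
                            dt = 0.01, x0 = 0) {
  new_toy("cosine_well", 4L, amplitude, x0, kT, friction, dt,
          list(bins = 300L, range = c(0, 2 * pi), periodic = TRUE,
               b = 0.8, c = 0.1, alpha = 5L, kT = kT))
}

#' Host-guest binding toy
#'
#' A 3D stand-in for receptor-ligand binding: a four-particle ligand (two
#' labelled groups of two atoms, mirroring the decomposition of a ligand
#' into flexible and rigid moieties) diffusing above two fixed receptor
#' reference points. A designed binding pocket (per-atom Gaussian wells at
#' a constructed bound pose) sits behind a Gaussian entrance barrier on the
#' anchor atom; an optional decoy well on the ligand centroid provides a
#' spurious-escape channel that high fill-limits can populate. The ligand
#' is confined by a flat-bottom cylinder, a CV cap and a half-space wall
#' standing in for the receptor body. The two CVs are the RMS distances of
#' the two ligand groups to the reference points; the monitored distance
#' (anchor atom to its pocket site) starts at 11 Angstrom (unbound).
#'
#' @param pocket_depth per-atom pocket well depth, kcal/mol.
#' @param pocket_width pocket well width, Angstrom.
#' @param barrier_height entrance barrier height, kcal/mol.
#' @param decoy_depth decoy well depth, kcal/mol (0 disables).
#' @param cylinder_radius flat-bottom cylinder radius, Angstrom.
#' @param cv_cap maximal allowable CV value, Angstrom.
#' @param kT,friction,dt thermostat parameters (kcal/mol, 1/ps, ps).
#' @return an object of class \code{toy_system} (kind \code{"host_guest"}).
#' @export
toy_host_guest <- function(pocket_depth = 1.5, pocket_width = 0.9,
                           barrier_height = 5, decoy_depth = 1.2,
                           cylinder_radius = 4, cv_cap = 12,
                           kT = 0.6, friction = 5, dt = 0.01) {
  pose <- rbind(c(-1, 0, 1), c(0, 0, 1), c(1, 0, 1), c(2, 0, 1))
  start <- rbind(c(-1, 0, 12), c(0, 0, 12), c(1, 0, 12), c(2, 0, 12))
  refA <- c(-2, 0, 0)
  refB <- c(2, 0, 0)
  bonds <- rbind(c(0, 1, 1, 100), c(1, 2, 1, 100), c(2, 3, 1, 100),
                 c(0, 2, 2, 20), c(1, 3, 2, 20))
  hg <- list(
    nlig = 4L, bonds = bonds, pocket = pose,
    pocket_eps = pocket_depth, pocket_w = pocket_width,
    barrier_B = barrier_height, barrier_r0 = 5, barrier_sigma = 1,
    decoy_eps = decoy_depth, decoy_w = 2, decoy_pos = c(4, 0, 8),
    wall_k = 10, wall_z = 0,
    refA = refA, refB = refB, g1 = 0:1, g2 = 2:3,
    cyl_x = 0, cyl_y = 0, cyl_R = cylinder_radius, k_cyl = 10,
    cv_cap = cv_cap, k_cap = 10,
    kT = kT, gamma = friction, dt = dt
  )
  sys <- new_toy("host_guest", NA_integer_, numeric(0), as.vector(t(start)),
                 kT, friction, dt,
                 list(bins = c(28L, 28L), range = list(c(0, 14), c(0, 14)),
                      periodic = FALSE, b = 0.9, c = 100, alpha = 3L, kT = kT))
  sys$hg <- hg
  sys$pose <- pose
  sys$pose_cv <- c(rms_distance_cv(pose[1:2, , drop = FALSE], refA),
                   rms_distance_cv(pose[3:4, , drop = FALSE], refB))
  sys
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("toy system '%s': kT = %g kcal/mol, friction = %g/ps, dt = %g ps\n",
              x$kind, x$kT, x$friction, x$dt))
  invisible(x)
}

#' Default CV grid for a toy system
#'
#' @param system a \code{toy_system}.
#' @param flim fill-limit, kcal/mol.
#' @param ... overrides passed to \code{\link{make_grid}}.
#' @return a \code{bias_grid} matching the system's CV space.
#' @export
system_grid <- function(system, flim = 6, ...) {
  stopifnot(inherits(system, "toy_system"))
  args <- utils::modifyList(system$grid_args, list(flim = flim, ...))
  do.call(make_grid, args)
}

#' Analytic potential of a toy system
#'
#' @param system a \code{toy_system} with an analytic CV-space potential
#'   (all kinds except \code{host_guest}).
#' @param x CV points (vector for 1D, or matrix with one point per row).
#' @return potential energies, kcal/mol.
#' @export
system_potential <- function(system, x) {
  stopifnot(inherits(system, "toy_system"))
  if (system$kind == "host_guest")
    stop("the host-guest potential is defined on atomic coordinates, not CVs")
  nd <- if (system$kind == "mueller_brown") 2L else 1L
  pts <- as_cv_matrix(x, nd)
  pot_energy_cpp(system$pot_id, system$pars, pts)
}

#' Analytic free-energy reference on a grid
#'
#' For the analytic toys every coordinate is a CV, so the free energy along
#' the CVs equals the potential itself (min-shifted over the requested
#' cells). Used as the exact oracle for recovery tests.
#'
#' @param system a \code{toy_system} (not \code{host_guest}).
#' @param grid a \code{bias_grid} or \code{fes_landscape} supplying cell
#'   geometry.
#' @return numeric vector of min-shifted free energies at cell centers.
#' @export
analytic_fes <- function(system, grid) {
  nd <- length(grid$bins)
  pts <- if (nd == 1L) matrix(grid_centers(grid, 1L), ncol = 1L)
         else as.matrix(expand.grid(grid_centers(grid, 1L),
                                    grid_centers(grid, 2L)))
  u <- system_potential(system, pts)
  u - min(u)
}
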