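#' Atom group
#'
#' A labelled set of unique 0-based atom indices, the building block of
#' collective-variable definitions (e.g. the flexible and rigid moieties of
#' a ligand, or the receptor C-alpha sets defining reference points).
#'
#' @param indices integer vector of 0-based atom indices.
#' @param label text label.
#' @param n_atoms optional total atom count to validate against.
#' @return an object of class \code{atom_group}.
#' @export
atom_group <- function(indices, label = "group", n_atoms = NULL) {
  indices <- as.integer(indices)
  if (length(indices) == 0L) stop("atom group must be non-empty")
  if (anyNA(indices) || any(indices < 0L)) stop("atom indices must be >= 0")
  if (anyDuplicated(indices)) stop("atom indices must be unique")
  if (!is.null(n_atoms) && any(indices >= n_atoms))
    stop("atom index out of range for structure with ", n_atoms, " atoms")
  structure(list(indices = indices, label = as.character(label)),
            class = "atom_group")
}

#' Center of geometry of a dynamic reference selection
#'
#' Reference points for the binding CVs are single centers of geometry of
#' receptor atom selections, recomputed from the current coordinates at
#' every evaluation (dynamic references).
#'
#' @param coords numeric n x 3 matrix of coordinates (Angstrom).
#' @param group an \code{atom_group} (0-based indices into \code{coords}),
#'   or NULL to use all atoms.
#' @return length-3 numeric center of geometry.
#' @export
center_of_geometry <- function(coords, group = NULL) {
  coords <- as.matrix(coords)
  if (!is.null(group)) coords <- coords[group$indices + 1L, , drop = FALSE]
  colMeans(coords)
}

#' RMS distance of an atom group to a single reference point
#'
#' The binding CV: \eqn{\mathrm{cv} = \sqrt{\frac{1}{n}\sum_i \|x_i - r\|^2}}.
#' A single reference point admits no superposition, so no fitting is
#' performed. Invariant under rigid transformations applied jointly to the
#' group and the reference.
#'
#' @param group_coords n x 3 matrix of group coordinates (Angstrom).
#' @param reference length-3 reference point (Angstrom).
#' @return non-negative CV value in Angstrom; 0 iff all atoms coincide with
#'   the reference.
#' @export
rms_distance_cv <- function(group_coords, reference) {
  gc <- as.matrix(group_coords)
  if (nrow(gc) == 0L) stop("atom group must be non-empty")
  d <- sweep(gc, 2L, as.numeric(reference))
  sqrt(mean(rowSums(d^2)))
}

#' Gradient of the RMS-distance CV
#'
#' Per-atom derivatives \eqn{\partial\mathrm{cv}/\partial x_i = (x_i - r)/(n\,\mathrm{cv})}
#' for the ligand group; because the reference is the center of geometry of
#' a receptor selection (m atoms), each receptor atom carries the
#' equal-and-opposite distributed contribution
#' \eqn{-\frac{1}{m}\sum_i \partial\mathrm{cv}/\partial x_i}, so the total
#' gradient sums to zero. At cv = 0 the CV is singular and the zero vector
#' is returned.
#'
#' @param group_coords n x 3 ligand group coordinates.
#' @param reference length-3 reference point (the receptor selection's
#'   center of geometry).
#' @param n_ref number of receptor atoms defining the reference (their
#'   shared distributed gradient is returned as one row each).
#' @return list with \code{cv}, \code{group} (n x 3 per-atom gradients) and
#'   \code{reference_each} (1 x 3: the gradient carried by each of the
#'   \code{n_ref} receptor atoms).
#' @export
rms_distance_gradient <- function(group_coords, reference, n_ref = 1L) {
  gc <- as.matrix(group_coords)
  n <- nrow(gc)
  cv <- rms_distance_cv(gc, reference)
  if (cv < .Machine$double.eps^0.5) {
    return(list(cv = cv, group = matrix(0, n, 3),
                reference_each = matrix(0, 1, 3)))
  }
  g <- sweep(gc, 2L, as.numeric(reference)) / (n * cv)
  list(cv = cv, group = g,
       reference_each = matrix(-colSums(g) / n_ref, 1, 3))
}

#' Torsion angle of four points
#'
#' Standard signed dihedral mapped to [0, 2*pi); a periodic CV. The planar
#' cis arrangement gives 0 and trans gives pi.
#'
#' @param p1,p2,p3,p4 length-3 coordinate triples.
#' @return angle in radians in [0, 2*pi).
#' @export
dihedral_cv <- function(p1, p2, p3, p4) {
  b1 <- as.numeric(p2) - as.numeric(p1)
  b2 <- as.numeric(p3) - as.numeric(p2)
  b3 <- as.numeric(p4) - as.numeric(p3)
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("degenerate dihedral: three consecutive points are collinear")
  ang <- atan2(sqrt(sum(b2^2)) * sum(b1 * n2), sum(n1 * n2))
  ang %% (2 * pi)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Binding-simulation restraints
#'
#' Flat-bottom restraints used in ligand-binding runs: a cylindrical wall
#' (default radius 18 Angstrom) around an axis through the dynamically
#' computed receptor center (the geometric center of the two CV reference
#' points, axis defaulting to the membrane normal +z), combined with a
#' maximal allowable CV value (default 22 Angstrom) that prevents the
#' ligand from diffusing away into periodic images. Both are half-harmonic:
#' zero strictly inside, \eqn{\frac{1}{2} k (\cdot)^2} outside, continuous
#' at the boundary.
#'
#' @param cylinder_radius Angstrom (default 18).
#' @param cylinder_axis unit 3-vector (default +z).
#' @param cv_cap Angstrom (default 22).
#' @param k_cyl,k_cap force constants, kcal/mol/A^2 (default 10).
#' @return an object of class \code{restraint_set}.
#' @export
restraint_set <- function(cylinder_radius = 18, cylinder_axis = c(0, 0, 1),
                          cv_cap = 22, k_cyl = 10, k_cap = 10) {
  axis <- as.numeric(cylinder_axis)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("cylinder axis must be a nonzero vector")
  structure(list(cylinder_radius = cylinder_radius, cylinder_axis = axis / nrm,
                 cv_cap = cv_cap, k_cyl = k_cyl, k_cap = k_cap),
            class = "restraint_set")
}

#' Restraint energy and forces
#'
#' @param ligand_cog length-3 ligand center of geometry (Angstrom).
#' @param cv_values numeric pair of CV values (Angstrom).
#' @param restraints a \code{restraint_set}.
#' @param origin length-3 cylinder origin (the receptor center; default the
#'   coordinate origin).
#' @return list with total \code{energy} (kcal/mol), \code{force_cog}
#'   (kcal/mol/A on the ligand center of geometry, radial term) and
#'   \code{dE_dcv} (derivative with respect to each CV, cap term).
#' @export
restraint_energy_force <- function(ligand_cog, cv_values, restraints,
                                   origin = c(0, 0, 0)) {
  stopifnot(inherits(restraints, "restraint_set"))
  cog <- as.numeric(ligand_cog)
  ax <- restraints$cylinder_axis
  rel <- cog - as.numeric(origin)
  radial <- rel - sum(rel * ax) * ax
  rho <- sqrt(sum(radial^2))
  energy <- 0
  force <- c(0, 0, 0)
  if (rho > restraints$cylinder_radius) {
    dr <- rho - restraints$cylinder_radius
    energy <- energy + 0.5 * restraints$k_cyl * dr^2
    force <- -restraints$k_cyl * dr * radial / rho
  }
  dE_dcv <- numeric(length(cv_values))
  over <- cv_values > restraints$cv_cap
  if (any(over)) {
    ex <- cv_values[over] - restraints$cv_cap
    energy <- energy + sum(0.5 * restraints$k_cap * ex^2)
    dE_dcv[over] <- restraints$k_cap * ex
  }
  list(energy = energy, force_cog = force, dE_dcv = dE_dcv)
}
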