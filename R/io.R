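#' Read a PDB structure into an atom table
#'
#' Thin wrapper over \code{bio3d::read.pdb} returning a plain atom table.
#' Alternate locations are resolved by keeping the highest-occupancy
#' altloc of each atom (ties go to the first record), which is logged.
#' PDB serials are 1-based; the \code{index0} column gives the 0-based
#' index used by CV definitions.
#'
#' @param path path to a PDB file (ATOM/HETATM records).
#' @return data frame with columns \code{serial, name, altloc, resid,
#'   chain, resno, x, y, z, occupancy, index0}.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  bad <- which(rec & nchar(lines) < 54L)
  if (length(bad) > 0L)
    stop("malformed ATOM/HETATM record at line ",
         paste(bad, collapse = ", "), " of ", path)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("failed to parse ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  at$occupancy <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    best <- idx[which.max(at$occupancy[idx])]
    keep[setdiff(idx, best)] <- FALSE
  }
  if (any(!keep))
    message("read_structure: dropped ", sum(!keep),
            " lower-occupancy altloc record(s)")
  at <- at[keep, , drop = FALSE]
  data.frame(serial = at$eleno, name = at$elety,
             altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
             resid = at$resid, chain = at$chain, resno = at$resno,
             x = at$x, y = at$y, z = at$z, occupancy = at$occupancy,
             index0 = seq_len(nrow(at)) - 1L,
             stringsAsFactors = FALSE)
}

#' Write an atom table (or a single pose) as PDB
#'
#' @param coords n x 3 coordinate matrix, Angstrom.
#' @param path file path.
#' @param name atom names (recycled).
#' @param resid residue name (recycled).
#' @param chain chain identifier (recycled).
#' @param resno residue numbers (recycled).
#' @return the path, invisibly.
#' @export
write_structure <- function(coords, path, name = "CA", resid = "LIG",
                            chain = "A", resno = 1L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  bio3d::write.pdb(file = path, xyz = as.vector(t(coords)),
                   type = rep("ATOM", n), eleno = seq_len(n),
                   elety = rep_len(name, n), resid = rep_len(resid, n),
                   chain = rep_len(chain, n), resno = rep_len(resno, n),
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' Generate deterministic synthetic fixtures
#'
#' Writes toy-system configurations and planted-truth datasets for
#' exercising the pipeline. Outputs are a pure function of \code{kind},
#' \code{params} and \code{seed} (byte-identical on repeat).
#'
#' \describe{
#'   \item{\code{double_well}, \code{mueller_brown}, \code{cosine_well}}{a
#'     YAML run configuration for the analytic toy.}
#'   \item{\code{host_guest}}{a PDB with the labelled ligand groups and
#'     receptor reference dummy C-alpha atoms, plus a YAML run config.}
#'   \item{\code{planted_traj}}{an XYZ trajectory with planted pose
#'     clusters, a CV trace placing them inside a declared region, a
#'     monitored-distance series with a planted binding/unbinding
#'     schedule, and a JSON truth sidecar.}
#'   \item{\code{planted_fes}}{a 2D landscape TSV with planted Gaussian
#'     minima and a JSON truth sidecar.}
#' }
#'
#' @param kind fixture kind (see details).
#' @param dir output directory (created if needed).
#' @param params named list of overrides (cluster counts, event counts,
#'   minima positions, run lengths, ...).
#' @param seed integer seed.
#' @return invisibly, a list with the written \code{files} and the planted
#'   \code{truth} (where applicable).
#' @export
generate_fixture <- function(kind = c("double_well", "mueller_brown",
                                      "cosine_well", "host_guest",
                                      "planted_traj", "planted_fes"),
                             dir = ".", params = list(), seed = 1L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default

  if (kind %in% c("double_well", "mueller_brown", "cosine_well")) {
    cfgfile <- file.path(dir, paste0(kind, ".yaml"))
    cfg <- list(
      system = switch(kind,
        double_well = list(kind = "double_well", h = p("h", 2)),
        mueller_brown = list(kind = "mueller_brown", scale = p("scale", 0.05)),
        cosine_well = list(kind = "cosine_well", amplitude = p("amplitude", 2))),
      grid = list(flim = p("flim", 6)),
      run = list(n_steps = p("n_steps", 200000L), stride = p("stride", 10L),
                 seed = as.integer(seed))
    )
    yaml::write_yaml(cfg, cfgfile)
    return(invisible(list(files = cfgfile, truth = NULL)))
  }

  if (kind == "host_guest") {
    sys <- toy_host_guest()
    lig <- matrix(sys$x0, ncol = 3L, byrow = TRUE)
    # receptor reference dummies: 4 C-alpha atoms ringed around each point
    ring <- function(center) {
      offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
      sweep(offs, 2L, center, `+`)
    }
    recA <- ring(sys$hg$refA)
    recB <- ring(sys$hg$refB)
    coords <- rbind(lig, recA, recB)
    n <- nrow(coords)
    pdbfile <- file.path(dir, "host_guest.pdb")
    bio3d::write.pdb(
      file = pdbfile, xyz = as.vector(t(coords)),
      type = c(rep("HETATM", 4L), rep("ATOM", 8L)),
      eleno = seq_len(n),
      elety = c("LG1", "LG2", "LG3", "LG4", rep("CA", 8L)),
      resid = c(rep("LIG", 4L), rep("GLY", 8L)),
      chain = c(rep("L", 4L), rep("A", 4L), rep("B", 4L)),
      resno = c(rep(1L, 4L), 1:4, 1:4),
      o = rep(1, n), b = rep(0, n))
    cfgfile <- file.path(dir, "host_guest.yaml")
    yaml::write_yaml(list(
      system = list(kind = "host_guest"),
      structure = basename(pdbfile),
      groups = list(cv1 = list(chain = "L", atoms = c("LG1", "LG2")),
                    cv2 = list(chain = "L", atoms = c("LG3", "LG4")),
                    refA = list(chain = "A", atoms = "CA"),
                    refB = list(chain = "B", atoms = "CA")),
      grid = list(flim = p("flim", 10)),
      run = list(n_steps = p("n_steps", 2000000L), stride = p("stride", 10L),
                 seed = as.integer(seed))
    ), cfgfile)
    return(invisible(list(files = c(pdbfile, cfgfile), truth = NULL)))
  }

  if (kind == "planted_traj") {
    n_clusters <- p("n_clusters", 2L)
    per <- p("frames_per_cluster", 100L)
    sigma <- p("sigma", 0.1)
    sep <- p("separation", 5)
    n_atoms <- p("n_atoms", 4L)
    n_events <- p("n_events", 7L)
    base <- matrix(rep(seq_len(n_atoms), each = 3L) +
                     rep(c(0, 0.3, 0.6), n_atoms), ncol = 3L, byrow = TRUE)
    frames <- NULL
    labels <- integer(0)
    for (kcl in seq_len(n_clusters)) {
      ctr <- base + matrix(rep(c((kcl - 1L) * sep, 0, 0), each = n_atoms),
                           ncol = 3L)
      blob <- t(vapply(seq_len(per), function(i)
        as.vector(t(ctr + matrix(rnorm(3L * n_atoms, sd = sigma), ncol = 3L))),
        numeric(3L * n_atoms)))
      frames <- rbind(frames, blob)
      labels <- c(labels, rep(kcl, per))
    }
    traj <- structure(list(
      frames = frames,
      cv_trace = cbind(2 + labels * 0.1 + rnorm(nrow(frames), sd = 0.02),
                       2 + rnorm(nrow(frames), sd = 0.02)),
      monitor = NULL, stride = 1L, dt = 1,
      metadata = list(kind = "planted", seed = as.integer(seed),
                      n_steps = nrow(frames), biased = FALSE)
    ), class = "trajectory")
    xyzfile <- file.path(dir, "planted_traj.xyz")
    cvfile <- file.path(dir, "planted_traj_cv.tsv")
    write_xyz(traj, xyzfile)
    write_cv_trace(traj, cvfile)
    # telegraph distance series: n_events excursions below 4 A separated by
    # returns above 10 A, starting (and ending) unbound
    seg <- p("segment_length", 20L)
    dist <- rep(12, seg)
    for (e in seq_len(n_events)) {
      dist <- c(dist, rep(3, seg), rep(12, seg))
    }
    dist <- dist + runif(length(dist), -0.5, 0.5)
    evfile <- file.path(dir, "planted_events.tsv")
    write.table(data.frame(time_ps = seq_along(dist) * 10, distance_A = dist),
                evfile, sep = "\t", quote = FALSE, row.names = FALSE)
    truth <- list(n_clusters = n_clusters, frames_per_cluster = per,
                  n_binding = n_events, n_unbinding = n_events)
    truthfile <- file.path(dir, "planted_traj_truth.json")
    jsonlite::write_json(truth, truthfile, auto_unbox = TRUE, digits = NA)
    return(invisible(list(files = c(xyzfile, cvfile, evfile, truthfile),
                          truth = truth)))
  }

  # planted_fes
  minima <- p("minima", list(c(1.5, 1.5), c(4, 4), c(1.5, 4.5)))
  depths <- p("depths", rep(4, length(minima)))
  width <- p("width", 0.5)
  bins <- p("bins", c(60L, 60L))
  rng <- p("range", c(0, 6))
  g <- make_grid(bins, list(rng, rng), alpha = 2L)
  cx <- grid_centers(g, 1L)
  cy <- grid_centers(g, 2L)
  cc <- expand.grid(x = cx, y = cy)
  F <- rep(0, nrow(cc))
  for (i in seq_along(minima)) {
    F <- F - depths[[i]] * exp(-((cc$x - minima[[i]][1])^2 +
                                 (cc$y - minima[[i]][2])^2) / (2 * width^2))
  }
  F <- F - min(F)
  fes <- structure(list(bins = g$bins, lo = g$lo, hi = g$hi,
                        periodic = g$periodic, F = F,
                        visited = rep(TRUE, length(F)),
                        replicate_count = 1L, kT = 0.6),
                   class = "fes_landscape")
  fesfile <- file.path(dir, "planted_fes.tsv")
  write_fes(fes, fesfile)
  truth <- list(minima = minima, depths = depths)
  truthfile <- file.path(dir, "planted_fes_truth.json")
  jsonlite::write_json(truth, truthfile, auto_unbox = TRUE, digits = NA)
  invisible(list(files = c(fesfile, truthfile), truth = truth))
}
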