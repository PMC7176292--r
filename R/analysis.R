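same_geometry <- function(a, b) {
  identical(a$bins, b$bins) && isTRUE(all.equal(a$lo, b$lo)) &&
    isTRUE(all.equal(a$hi, b$hi)) && identical(a$periodic, b$periodic)
}

#' Average free-energy landscapes over replicates
#'
#' Cell-wise mean of F over the replicates that visited each cell; the
#' visited mask is the union, and the result is re-shifted so the minimum
#' over visited cells is zero.
#'
#' @param landscapes list of \code{fes_landscape} objects with identical
#'   grid geometry (a single landscape is returned unchanged).
#' @return the averaged \code{fes_landscape}.
#' @export
average_landscapes <- function(landscapes) {
  if (inherits(landscapes, "fes_landscape")) landscapes <- list(landscapes)
  if (length(landscapes) < 1L) stop("need at least one landscape")
  ref <- landscapes[[1L]]
  for (l in landscapes)
    if (!same_geometry(ref, l)) stop("landscapes have mismatched grid geometry")
  Fsum <- numeric(length(ref$F))
  count <- integer(length(ref$F))
  for (l in landscapes) {
    v <- l$visited
    Fsum[v] <- Fsum[v] + l$F[v]
    count[v] <- count[v] + 1L
  }
  visited <- count > 0L
  Fm <- ifelse(visited, Fsum / pmax(count, 1L), NA_real_)
  Fm[visited] <- Fm[visited] - min(Fm[visited])
  structure(list(bins = ref$bins, lo = ref$lo, hi = ref$hi,
                 periodic = ref$periodic, F = Fm, visited = visited,
                 replicate_count = sum(vapply(landscapes,
                                              function(l) l$replicate_count,
                                              integer(1))),
                 kT = ref$kT),
            class = "fes_landscape")
}

#' Axis-aligned basin region in CV space
#'
#' A labelled closed box, as used to delimit landscape basins (e.g. the
#' S1/S2/S3 dihedral states) and to extract frames. On a periodic
#' dimension \code{lo > hi} denotes the wrap-around interval.
#'
#' @param lo,hi numeric bounds per dimension.
#' @param label text label.
#' @return an object of class \code{basin_region}.
#' @export
basin_region <- function(lo, hi, label = "basin") {
  lo <- as.numeric(lo)
  hi <- as.numeric(hi)
  if (length(lo) != length(hi)) stop("'lo' and 'hi' must have equal length")
  structure(list(lo = lo, hi = hi, label = as.character(label)),
            class = "basin_region")
}

#' @export
print.basin_region <- function(x, ...) {
  cat(sprintf("basin '%s': [%s]\n", x$label,
              paste(sprintf("%g..%g", x$lo, x$hi), collapse = ", ")))
  invisible(x)
}

# logical membership of points (rows) in a closed box; wrap-aware
region_contains <- function(region, pts, periodic = NULL) {
  pts <- as.matrix(pts)
  nd <- length(region$lo)
  if (ncol(pts) != nd) stop("point dimensionality does not match region")
  if (is.null(periodic)) periodic <- rep(FALSE, nd)
  inside <- rep(TRUE, nrow(pts))
  for (d in seq_len(nd)) {
    lo <- region$lo[d]; hi <- region$hi[d]
    if (lo > hi) {
      if (!periodic[d]) stop("lo > hi on a non-periodic dimension")
      inside <- inside & (pts[, d] >= lo | pts[, d] <= hi)
    } else {
      inside <- inside & pts[, d] >= lo & pts[, d] <= hi
    }
  }
  inside
}

# neighbor linear indices of each cell (4-neighborhood in 2D)
grid_neighbors <- function(fes, cell) {
  nd <- length(fes$bins)
  if (nd == 1L) {
    n <- fes$bins[1L]
    out <- c(cell - 1L, cell + 1L)
    if (fes$periodic[1L]) out <- ((out - 1L) %% n) + 1L
    out[out >= 1L & out <= n]
  } else {
    nx <- fes$bins[1L]; ny <- fes$bins[2L]
    i <- ((cell - 1L) %% nx) + 1L
    j <- ((cell - 1L) %/% nx) + 1L
    res <- integer(0)
    for (s in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ii <- i + s[1L]; jj <- j + s[2L]
      if (fes$periodic[1L]) ii <- ((ii - 1L) %% nx) + 1L
      if (fes$periodic[2L]) jj <- ((jj - 1L) %% ny) + 1L
      if (ii >= 1L && ii <= nx && jj >= 1L && jj <= ny)
        res <- c(res, ii + nx * (jj - 1L))
    }
    res
  }
}

#' Detect energetic minima as basin regions
#'
#' Finds visited cells lying at or below all their visited neighbors with
#' F below \code{depth_threshold}, expands each into the connected region
#' with \code{F < F_min + basin_width}, and returns the regions' bounding
#' boxes sorted by depth (shallower regions that merge into an already
#' claimed region are dropped).
#'
#' @param fes a \code{fes_landscape}.
#' @param depth_threshold only minima with F at or below this value
#'   (kcal/mol above the global minimum) are reported.
#' @param basin_width basin expansion window above the local minimum,
#'   kcal/mol (default 1).
#' @return list of \code{basin_region} objects (possibly empty), labelled
#'   \code{S1, S2, ...} by increasing depth rank.
#' @export
find_minima <- function(fes, depth_threshold = 3, basin_width = 1) {
  stopifnot(inherits(fes, "fes_landscape"))
  if (!any(fes$visited)) stop("landscape has no visited cells")
  ncell <- length(fes$F)
  cand <- integer(0)
  for (cell in which(fes$visited)) {
    if (fes$F[cell] > depth_threshold) next
    nb <- grid_neighbors(fes, cell)
    nb <- nb[fes$visited[nb]]
    if (length(nb) == 0L || all(fes$F[cell] <= fes$F[nb]))
      cand <- c(cand, cell)
  }
  if (length(cand) == 0L) return(list())
  cand <- cand[order(fes$F[cand])]
  claimed <- logical(ncell)
  h <- bin_width(fes)
  nd <- length(fes$bins)
  basins <- list()
  for (cell in cand) {
    if (claimed[cell]) next
    lim <- fes$F[cell] + basin_width
    member <- logical(ncell)
    queue <- cell
    member[cell] <- TRUE
    while (length(queue) > 0L) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      for (nb in grid_neighbors(fes, cur)) {
        if (!member[nb] && fes$visited[nb] && fes$F[nb] < lim) {
          member[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    claimed <- claimed | member
    cells <- which(member)
    if (nd == 1L) {
      ctr <- grid_centers(fes, 1L)[cells]
      reg <- basin_region(min(ctr) - h / 2, max(ctr) + h / 2)
    } else {
      nx <- fes$bins[1L]
      ii <- ((cells - 1L) %% nx) + 1L
      jj <- ((cells - 1L) %/% nx) + 1L
      cx <- grid_centers(fes, 1L)
      cy <- grid_centers(fes, 2L)
      reg <- basin_region(c(min(cx[ii]) - h[1] / 2, min(cy[jj]) - h[2] / 2),
                          c(max(cx[ii]) + h[1] / 2, max(cy[jj]) + h[2] / 2))
    }
    reg$depth <- fes$F[cell]
    reg$minimum <- if (nd == 1L) grid_centers(fes, 1L)[cell]
                   else c(grid_centers(fes, 1L)[((cell - 1L) %% fes$bins[1L]) + 1L],
                          grid_centers(fes, 2L)[((cell - 1L) %/% fes$bins[1L]) + 1L])
    basins[[length(basins) + 1L]] <- reg
  }
  for (i in seq_along(basins)) basins[[i]]$label <- paste0("S", i)
  basins
}

#' Extract trajectory frames inside a basin region
#'
#' Returns exactly the frames whose CV values lie inside the closed box
#' (wrap-aware on periodic CVs if \code{periodic} is given). An empty
#' result is a warning, not an error.
#'
#' @param traj a \code{trajectory} with a CV trace.
#' @param region a \code{basin_region} matching the CV dimensionality.
#' @param periodic logical per CV dimension (default non-periodic).
#' @return the sub-\code{trajectory} of matching frames; frame indices in
#'   attribute \code{"indices"}.
#' @export
extract_frames <- function(traj, region, periodic = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(region, "basin_region"))
  if (is.null(traj$cv_trace)) stop("trajectory has no CV trace")
  idx <- which(region_contains(region, traj$cv_trace, periodic))
  if (length(idx) == 0L)
    warning("no frames inside region '", region$label, "'")
  out <- traj
  out$frames <- traj$frames[idx, , drop = FALSE]
  out$cv_trace <- traj$cv_trace[idx, , drop = FALSE]
  if (!is.null(traj$monitor)) out$monitor <- traj$monitor[idx]
  attr(out, "indices") <- idx
  out
}

#' DBSCAN pose clustering
#'
#' Density-based clustering of ligand poses with the standard DBSCAN
#' semantics: a core point has at least \code{min_pts} neighbors within
#' \code{eps} (counting itself); clusters are the connected components of
#' core points plus their border points; everything else is noise
#' (label 0). The pairwise metric is ligand-atom RMSD without re-fitting
#' (frames are assumed receptor-aligned upstream). The representative pose
#' is the medoid of the largest cluster.
#'
#' @param frames a \code{trajectory} or a numeric matrix (one frame per
#'   row, 3 columns per atom).
#' @param eps neighborhood radius, Angstrom RMSD (default 0.7).
#' @param min_pts minimum neighborhood size for a core point (default 25).
#' @return an object of class \code{cluster_result}: per-frame
#'   \code{labels} (0 = noise), \code{n_clusters}, \code{representative}
#'   (frame index of the largest cluster's medoid, NA if all noise),
#'   \code{medoid_distance} per frame, and the parameters.
#' @export
cluster_poses <- function(frames, eps = 0.7, min_pts = 25L) {
  if (inherits(frames, "trajectory")) frames <- frames$frames
  frames <- as.matrix(frames)
  n <- nrow(frames)
  if (n < 1L) stop("need at least one frame")
  if (ncol(frames) %% 3L != 0L) stop("frames must have 3 columns per atom")
  m <- ncol(frames) %/% 3L
  d <- as.matrix(stats::dist(frames)) / sqrt(m) # per-atom RMSD
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nbrs[[i]]
    while (length(queue) > 0L) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nbrs[[j]])
      }
    }
  }
  rep_idx <- NA_integer_
  med_dist <- rep(NA_real_, n)
  if (cl > 0L) {
    sizes <- tabulate(labels, nbins = cl)
    big <- which.max(sizes)
    members <- which(labels == big)
    sums <- colSums(d[members, members, drop = FALSE])
    rep_idx <- members[which.min(sums)]
    med_dist <- d[, rep_idx]
  }
  structure(list(labels = labels, n_clusters = cl, core = core,
                 representative = rep_idx, medoid_distance = med_dist,
                 eps = eps, min_pts = as.integer(min_pts)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("DBSCAN poses: %d cluster(s), %d/%d noise (eps = %g A, min_pts = %d)\n",
              x$n_clusters, sum(x$labels == 0L), length(x$labels),
              x$eps, x$min_pts))
  invisible(x)
}

#' Write a cluster report as TSV
#'
#' @param clusters a \code{cluster_result}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_cluster_report <- function(clusters, path) {
  df <- data.frame(frame_id = seq_along(clusters$labels),
                   cluster = clusters$labels,
                   distance_to_medoid = clusters$medoid_distance)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Boltzmann occupancy of a basin on a 1D landscape
#'
#' Cell-wise Boltzmann weighting of the free-energy profile:
#' \eqn{\mathrm{occ} = \sum_{basin} e^{-F/kT} / \sum_{all} e^{-F/kT}}.
#' Intended for fully visited periodic dihedral profiles; unvisited cells
#' inside the basin are an error.
#'
#' @param fes a 1D \code{fes_landscape}.
#' @param basin a 1D \code{basin_region} (wrap-aware: \code{lo > hi} on a
#'   periodic profile denotes the wrap-around interval).
#' @param kT thermal energy, kcal/mol (default the landscape's).
#' @return occupancy fraction in [0, 1].
#' @export
basin_occupancy <- function(fes, basin, kT = fes$kT) {
  stopifnot(inherits(fes, "fes_landscape"), inherits(basin, "basin_region"))
  if (length(fes$bins) != 1L) stop("basin occupancy is defined on 1D landscapes")
  centers <- grid_centers(fes, 1L)
  inb <- region_contains(basin, matrix(centers, ncol = 1L), fes$periodic)
  if (any(inb & !fes$visited))
    stop("unvisited cells inside basin '", basin$label, "'")
  w <- ifelse(fes$visited, exp(-fes$F / kT), 0)
  sum(w[inb]) / sum(w)
}
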