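# Independent brute-force oracles used to cross-check the implementation.

# O(n^2) DBSCAN by explicit connected components of the core-point graph
# (deliberately different algorithm shape from cluster_poses' queue
# expansion): border points join the lowest-labelled adjacent core cluster.
brute_dbscan <- function(frames, eps, min_pts) {
  frames <- as.matrix(frames)
  n <- nrow(frames)
  m <- ncol(frames) / 3
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      d[i, j] <- sqrt(sum((frames[i, ] - frames[j, ])^2) / m)
  core <- vapply(seq_len(n), function(i) sum(d[i, ] <= eps) >= min_pts,
                 logical(1))
  # connected components among cores (union-find)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in which(core)) for (j in which(core))
    if (d[i, j] <= eps) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  labels <- integer(n)
  roots <- unique(vapply(which(core), find, integer(1)))
  for (k in seq_along(roots))
    labels[core][vapply(which(core), find, integer(1)) == roots[k]] <- k
  for (i in which(!core)) {
    adj <- which(core & d[i, ] <= eps)
    if (length(adj) > 0) labels[i] <- min(labels[adj])
  }
  labels
}

# labels equal up to a permutation of cluster ids (noise label 0 fixed)
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!all((a == 0) == (b == 0))) return(FALSE)
  for (k in unique(a[a != 0]))
    if (length(unique(b[a == k])) != 1) return(FALSE)
  for (k in unique(b[b != 0]))
    if (length(unique(a[b == k])) != 1) return(FALSE)
  TRUE
}

# explicit state-machine replay of the two-threshold hysteresis rule
brute_hysteresis <- function(d, bound = 4, unbound = 10, init = "unbound") {
  state <- init
  n_bind <- 0L
  n_unbind <- 0L
  states <- character(length(d))
  for (i in seq_along(d)) {
    if (state == "unbound" && d[i] < bound) {
      state <- "bound"; n_bind <- n_bind + 1L
    } else if (state == "bound" && d[i] > unbound) {
      state <- "unbound"; n_unbind <- n_unbind + 1L
    }
    states[i] <- state
  }
  list(states = states, n_binding = n_bind, n_unbinding = n_unbind)
}

# central finite difference gradient of f at x (vector argument)
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# independent torsion formula: angle between bond-plane normals with the
# sign taken from a triple product, then mapped to [0, 2*pi)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3],
                         a[1]*b[2]-a[2]*b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosang <- sum(n1*n2) / sqrt(sum(n1^2) * sum(n2^2))
  cosang <- max(-1, min(1, cosang))
  ang <- acos(cosang)
  if (sum(cr(n1, n2) * b2) < 0) ang <- -ang
  ang %% (2 * pi)
}

# kernel-sum histogram: expected weight field for a list of deposit centers
# with no overfill scaling (flim effectively infinite)
brute_kernel_hist <- function(centers, bins, lo, hi, alpha, periodic) {
  prof <- mollifier_profile(alpha)
  S <- numeric(bins)
  h <- (hi - lo) / bins
  for (x in centers) {
    ci <- floor((x - lo) / h)
    for (k in -alpha:alpha) {
      i <- ci + k
      if (periodic) i <- ((i %% bins) + bins) %% bins
      else if (i < 0 || i >= bins) next
      S[i + 1] <- S[i + 1] + prof[k + alpha + 1]
    }
  }
  S
}

# toy host-guest energy recomputed in R from the system definition, used to
# finite-difference-check the compiled forces
r_hostguest_energy <- function(sys, x) {
  hg <- sys$hg
  n <- hg$nlig
  xm <- matrix(x, ncol = 3, byrow = TRUE)
  U <- 0
  for (b in seq_len(nrow(hg$bonds))) {
    i <- hg$bonds[b, 1] + 1; j <- hg$bonds[b, 2] + 1
    r <- sqrt(sum((xm[i, ] - xm[j, ])^2))
    U <- U + 0.5 * hg$bonds[b, 4] * (r - hg$bonds[b, 3])^2
  }
  for (i in seq_len(n)) {
    r2 <- sum((xm[i, ] - hg$pocket[i, ])^2)
    U <- U - hg$pocket_eps * exp(-r2 / (2 * hg$pocket_w^2))
  }
  cog <- colMeans(xm)
  pc <- colMeans(hg$pocket)
  r <- sqrt(sum((cog - pc)^2))
  U <- U + hg$barrier_B * exp(-(r - hg$barrier_r0)^2 / (2 * hg$barrier_sigma^2))
  if (hg$decoy_eps > 0) {
    r2 <- sum((cog - hg$decoy_pos)^2)
    U <- U - hg$decoy_eps * exp(-r2 / (2 * hg$decoy_w^2))
  }
  U <- U + sum(ifelse(xm[, 3] < hg$wall_z,
                      0.5 * hg$wall_k * (xm[, 3] - hg$wall_z)^2, 0))
  rho <- sqrt((cog[1] - hg$cyl_x)^2 + (cog[2] - hg$cyl_y)^2)
  if (rho > hg$cyl_R) U <- U + 0.5 * hg$k_cyl * (rho - hg$cyl_R)^2
  cv1 <- rms_distance_cv(xm[hg$g1 + 1, , drop = FALSE], hg$refA)
  cv2 <- rms_distance_cv(xm[hg$g2 + 1, , drop = FALSE], hg$refB)
  for (cv in c(cv1, cv2))
    if (cv > hg$cv_cap) U <- U + 0.5 * hg$k_cap * (cv - hg$cv_cap)^2
  U
}
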