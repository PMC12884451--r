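# Water-structure analysis: exclusive water-to-indole assignment,
# coordination-number curves, 3D water-oxygen density grids on a regular
# lattice, difference-density maps with isocontour region extraction, and
# quantification of sub-Angstrom water shifts upon forced hole transfer.

#' Assign each water to its single closest indole (exclusive assignment)
#'
#' @param frame a [quad_frame()].
#' @param mode `"whole-indole"` (distance to the nearest of the 9 ring
#'   atoms) or `"NH-only"` (distance to NE1).
#' @return data.frame with one row per water: `water` (index),
#'   `nearest_site`, `distance` (A). Exact ties go to the site earliest in
#'   the fixed order 124A, 122A, 122D, 124D.
#' @export
assign_waters_exclusive <- function(frame,
                                    mode = c("whole-indole", "NH-only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(frame, "quad_frame"), length(frame$sites) >= 1)
  w <- frame$waters
  if (nrow(w) == 0)
    return(data.frame(water = integer(0), nearest_site = character(0),
                      distance = numeric(0)))
  dmat <- vapply(QUAD_SITES, function(lbl) {
    s <- frame$sites[[lbl]]
    ref <- if (mode == "NH-only") matrix(s$nh, 1, 3) else s$atoms
    d2 <- outer(rowSums(w^2), rowSums(ref^2), "+") - 2 * w %*% t(ref)
    sqrt(pmax(apply(d2, 1, min), 0))
  }, numeric(nrow(w)))
  dmat <- matrix(dmat, nrow = nrow(w),
                 dimnames = list(NULL, QUAD_SITES))
  nearest <- apply(dmat, 1, which.min)   # which.min: first of tied minima,
  data.frame(water = seq_len(nrow(w)),   # i.e. earliest in site order
             nearest_site = QUAD_SITES[nearest],
             distance = dmat[cbind(seq_len(nrow(w)), nearest)])
}

#' Exclusive water coordination-number curve
#'
#' For each cutoff r, the mean (over frames) number of waters that are both
#' assigned to `site` by the exclusive rule and within r of it. In
#' `"NH-only"` mode both the assignment and the counting distance are to
#' NE1 instead of the whole indole.
#'
#' @param traj a [quad_trajectory()] (or list of frames).
#' @param site site label.
#' @param cutoffs ascending cutoff radii (A); must be non-empty.
#' @param mode `"whole-indole"` or `"NH-only"`.
#' @return a `coordination_curve`: data.frame with `cutoff` and `n_water`
#'   (monotonically non-decreasing), with attributes `site` and `mode`.
#' @export
coordination_curve <- function(traj, site, cutoffs = seq(2.5, 5, by = 0.1),
                               mode = c("whole-indole", "NH-only")) {
  mode <- match.arg(mode)
  frames <- if (inherits(traj, "quad_trajectory")) traj$frames else traj
  if (length(cutoffs) == 0) stop("empty cutoff list")
  stopifnot(length(frames) >= 1, site %in% QUAD_SITES,
            !is.unsorted(cutoffs))
  counts <- vapply(frames, function(f) {
    a <- assign_waters_exclusive(f, mode = mode)
    d <- a$distance[a$nearest_site == site]
    vapply(cutoffs, function(r) sum(d <= r), numeric(1))
  }, numeric(length(cutoffs)))
  counts <- matrix(counts, nrow = length(cutoffs))
  res <- data.frame(cutoff = cutoffs, n_water = rowMeans(counts))
  attr(res, "site") <- site
  attr(res, "mode") <- mode
  class(res) <- c("coordination_curve", "data.frame")
  res
}

# --- rigid-body superposition (Kabsch) -------------------------------------

# Least-squares rotation + translation mapping P onto Q (both n x 3).
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  if (min(sv$d) < 1e-10 && sum(sv$d > 1e-10) < 2)
    stop("degenerate superposition: reference atoms are rank-deficient")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, cp = cp, cq = cq)
}

apply_fit <- function(X, fit) {
  sweep(sweep(X, 2, fit$cp) %*% t(fit$R), 2, -fit$cq)
}

frame_quad_atoms <- function(f) {
  do.call(rbind, lapply(f$sites[QUAD_SITES], function(s) s$atoms))
}

# Canonical pose of a frame's quadruplex: principal axes of the heavy
# atoms, signs fixed so the 124A NE1 has non-negative coordinates (ties
# broken by 122D NE1). Makes density grids independent of the global
# orientation of the input trajectory.
canonical_pose <- function(frame) {
  X <- frame_quad_atoms(frame)
  ctr <- colMeans(X)
  ev <- eigen(stats::cov(X))
  R <- ev$vectors  # columns: principal axes, decreasing variance
  ref1 <- frame$sites[["124A"]]$nh - ctr
  ref2 <- frame$sites[["122D"]]$nh - ctr
  for (k in 1:3) {
    s <- sum(ref1 * R[, k])
    if (abs(s) < 1e-8) s <- sum(ref2 * R[, k])
    if (s < 0) R[, k] <- -R[, k]
  }
  list(R = R, ctr = ctr)
}

apply_pose <- function(X, pose) {
  sweep(X, 2, pose$ctr) %*% pose$R
}

#' 3D water-oxygen density map
#'
#' Frames are least-squares superposed onto the first frame's quadruplex
#' heavy atoms (all four indoles), then water oxygens are binned on a
#' regular lattice. Voxel value = occupancy count / (n_frames x voxel
#' volume), i.e. molecules per cubic Angstrom; the integral over the grid
#' recovers the mean in-grid water count per frame. A boolean mask marks
#' voxels within `mask_radius` of any NE1.
#'
#' @param traj a [quad_trajectory()] or list of frames (>= 1; the study's
#'   maps use hundreds).
#' @param spacing lattice spacing (A), default 0.1.
#' @param mask_radius NH mask radius (A), default 4.
#' @param padding extra margin (A) beyond the NH mask bounding box.
#' @param superpose superpose frames before binning (default TRUE; set
#'   FALSE when frames are already aligned).
#' @return a `density_grid`: list with `origin`, `spacing`, `shape`,
#'   `values` (3D array, molecules/A^3), `rho0`, `mask` (3D logical),
#'   `nh_positions`, `n_frames`.
#' @export
density_map <- function(traj, spacing = 0.1, mask_radius = 4,
                        padding = 1, superpose = TRUE) {
  frames <- if (inherits(traj, "quad_trajectory")) traj$frames else traj
  stopifnot(length(frames) >= 1, spacing > 0)
  # grids live in the canonical (principal-axes) pose of the first
  # frame's quadruplex, so the lattice does not depend on the global
  # orientation of the input
  pose <- canonical_pose(frames[[1]])
  ref <- apply_pose(frame_quad_atoms(frames[[1]]), pose)
  nh <- apply_pose(t(vapply(frames[[1]]$sites[QUAD_SITES],
                            function(s) s$nh, numeric(3))), pose)
  rownames(nh) <- QUAD_SITES
  lo <- apply(nh, 2, min) - mask_radius - padding
  hi <- apply(nh, 2, max) + mask_radius + padding
  origin <- floor(lo / spacing) * spacing
  shape <- pmax(ceiling((hi - origin) / spacing), 1)
  values <- array(0, dim = shape)
  for (f in frames) {
    w <- f$waters
    if (superpose) {
      fit <- kabsch(frame_quad_atoms(f), ref)
      if (nrow(w) > 0) w <- apply_fit(w, fit)
    } else if (nrow(w) > 0) {
      w <- apply_pose(w, pose)
    }
    if (nrow(w) == 0) next
    ijk <- floor(sweep(w, 2, origin) / spacing) + 1
    keep <- ijk[, 1] >= 1 & ijk[, 1] <= shape[1] &
            ijk[, 2] >= 1 & ijk[, 2] <= shape[2] &
            ijk[, 3] >= 1 & ijk[, 3] <= shape[3]
    ijk <- ijk[keep, , drop = FALSE]
    if (nrow(ijk) > 0) {
      lin <- ijk[, 1] + shape[1] * (ijk[, 2] - 1) +
        shape[1] * shape[2] * (ijk[, 3] - 1)
      tab <- table(lin)
      values[as.integer(names(tab))] <-
        values[as.integer(names(tab))] + as.integer(tab)
    }
  }
  values <- values / (length(frames) * spacing^3)
  grid <- structure(list(
    origin = origin, spacing = spacing, shape = shape, values = values,
    rho0 = quad_constants$rho0_water, nh_positions = nh,
    n_frames = length(frames), pose = pose), class = "density_grid")
  grid$mask <- grid_nh_mask(grid, mask_radius)
  grid
}

grid_axes <- function(grid) {
  lapply(1:3, function(k)
    grid$origin[k] + (seq_len(grid$shape[k]) - 0.5) * grid$spacing)
}

grid_nh_mask <- function(grid, mask_radius) {
  ax <- grid_axes(grid)
  mask <- array(FALSE, dim = grid$shape)
  for (i in seq_len(nrow(grid$nh_positions))) {
    p <- grid$nh_positions[i, ]
    dx2 <- (ax[[1]] - p[1])^2; dy2 <- (ax[[2]] - p[2])^2
    dz2 <- (ax[[3]] - p[3])^2
    mask <- mask | (outer(outer(dx2, dy2, "+"), dz2, "+") <= mask_radius^2)
  }
  mask
}

#' Map world coordinates into a grid's canonical frame
#'
#' Density grids are built in the canonical (principal-axes) pose of the
#' reference quadruplex; use this to compare world-coordinate positions
#' (e.g. planted water locations) with grid features such as isocontour
#' region centroids.
#'
#' @param grid a `density_grid`.
#' @param points n x 3 matrix (or length-3 vector) of world coordinates.
#' @return coordinates in the grid frame (same shape as the input).
#' @export
to_grid_frame <- function(grid, points) {
  one <- is.null(dim(points))
  if (one) points <- matrix(points, 1, 3)
  out <- apply_pose(points, grid$pose)
  if (one) out[1, ] else out
}

#' Integrate a density grid
#'
#' @param grid a `density_grid`.
#' @param masked integrate only over the NH mask.
#' @return integral of rho dV (mean molecules per frame inside the grid).
#' @export
grid_integral <- function(grid, masked = FALSE) {
  v <- if (masked) grid$values[grid$mask] else grid$values
  sum(v) * grid$spacing^3
}

congruent <- function(a, b) {
  identical(a$shape, b$shape) && a$spacing == b$spacing &&
    max(abs(a$origin - b$origin)) < 1e-9
}

#' Difference density map with isocontour regions
#'
#' Voxelwise `final - initial`, plus connected regions (26-neighbor
#' connectivity) exceeding `+iso_factor * rho0` (excess hydration in the
#' final state) or below `-iso_factor * rho0` (excess in the initial
#' state), reported with centroid, peak value and volume. Only voxels
#' inside the NH mask are eligible for regions.
#'
#' @param final,initial congruent `density_grid`s.
#' @param iso_factor isocontour threshold in units of rho0 (default 2.5).
#' @param min_volume drop regions smaller than this volume (A^3); default 0.
#' @return a `density_grid` (the difference; negative values allowed) with
#'   attribute `regions`: data.frame `sign`, `n_voxels`, `volume`,
#'   `peak`, `cx`, `cy`, `cz`.
#' @export
difference_map <- function(final, initial, iso_factor = 2.5,
                           min_volume = 0) {
  if (!congruent(final, initial))
    stop("density grids are not congruent (origin/spacing/shape differ)")
  diff <- final
  diff$values <- final$values - initial$values
  thr <- iso_factor * final$rho0
  pos <- extract_regions(diff, diff$values >= thr & diff$mask, "+",
                         min_volume)
  neg <- extract_regions(diff, diff$values <= -thr & diff$mask, "-",
                         min_volume)
  attr(diff, "regions") <- rbind(pos, neg)
  attr(diff, "iso_factor") <- iso_factor
  diff
}

# Label connected components (26-connectivity) among flagged voxels.
extract_regions <- function(grid, flag, sign_label, min_volume) {
  idx <- which(flag)
  empty <- data.frame(sign = character(0), n_voxels = integer(0),
                      volume = numeric(0), peak = numeric(0),
                      cx = numeric(0), cy = numeric(0), cz = numeric(0))
  if (length(idx) == 0) return(empty)
  sh <- grid$shape
  ar <- arrayInd(idx, sh)
  key <- function(m) (m[, 1] + 1) + (sh[1] + 2) * (m[, 2] + 1) +
    (sh[1] + 2) * (sh[2] + 2) * (m[, 3] + 1)  # padded code, no wraparound
  codes <- key(ar)
  lookup <- seq_along(idx)
  names(lookup) <- as.character(codes)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    nb <- key(sweep(ar, 2, -offs[r, ]))
    hit <- match(as.character(nb), names(lookup))
    has <- which(!is.na(hit))
    if (length(has) > 0)
      edges <- rbind(edges, cbind(has, hit[has]))
  }
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_along(idx), seq_along(idx))), directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(idx)]
  ax <- grid_axes(grid)
  vals <- grid$values[idx]
  res <- do.call(rbind, lapply(split(seq_along(idx), comp), function(ii) {
    w <- abs(vals[ii])
    data.frame(sign = sign_label, n_voxels = length(ii),
               volume = length(ii) * grid$spacing^3,
               peak = vals[ii][which.max(w)],
               cx = sum(ax[[1]][ar[ii, 1]] * w) / sum(w),
               cy = sum(ax[[2]][ar[ii, 2]] * w) / sum(w),
               cz = sum(ax[[3]][ar[ii, 3]] * w) / sum(w))
  }))
  rownames(res) <- NULL
  res[res$volume >= min_volume, , drop = FALSE]
}

#' Measure the water shift toward a site between two states
#'
#' Signed displacement of the nearest-water density centroid, projected on
#' the unit vector pointing from the initial centroid to the site's NE1;
#' positive values mean motion toward the site. Accepts either two
#' congruent density grids (peak-centroid displacement) or two
#' trajectories/frame lists (per-frame nearest-water averaging, the more
#' precise estimator for synthetic data).
#'
#' @param initial,final `density_grid`s or [quad_trajectory()]s / frame
#'   lists for the two states.
#' @param site site label the shift is measured toward.
#' @param peak_radius radius (A) around the density peak used for the
#'   centroid in grid mode.
#' @return signed displacement in Angstrom.
#' @export
measure_shift <- function(initial, final, site, peak_radius = 0.8) {
  stopifnot(site %in% QUAD_SITES)
  if (inherits(initial, "density_grid")) {
    stopifnot(inherits(final, "density_grid"))
    if (!congruent(initial, final)) stop("grids are not congruent")
    nh <- initial$nh_positions[site, ]
    c0 <- nearest_peak_centroid(initial, nh, peak_radius)
    c1 <- nearest_peak_centroid(final, nh, peak_radius, near = c0)
    u <- nh - c0$centroid
    u <- u / sqrt(sum(u^2))
    return(sum((c1$centroid - c0$centroid) * u))
  }
  f0 <- if (inherits(initial, "quad_trajectory")) initial$frames else initial
  f1 <- if (inherits(final, "quad_trajectory")) final$frames else final
  nh <- f0[[1]]$sites[[site]]$nh
  nearest_mean <- function(frames) {
    pos <- vapply(frames, function(f) {
      d2 <- rowSums(sweep(f$waters, 2, f$sites[[site]]$nh)^2)
      f$waters[which.min(d2), ]
    }, numeric(3))
    rowMeans(pos)
  }
  m0 <- nearest_mean(f0); m1 <- nearest_mean(f1)
  u <- nh - m0
  u <- u / sqrt(sum(u^2))
  sum((m1 - m0) * u)
}

# Density centroid within peak_radius of the strongest voxel near a point.
nearest_peak_centroid <- function(grid, nh, peak_radius, near = NULL) {
  ax <- grid_axes(grid)
  idx <- which(grid$mask & grid$values > 0)
  if (length(idx) == 0)
    stop("no density within the NH mask near the requested site")
  ar <- arrayInd(idx, grid$shape)
  pts <- cbind(ax[[1]][ar[, 1]], ax[[2]][ar[, 2]], ax[[3]][ar[, 3]])
  d_nh <- sqrt(rowSums(sweep(pts, 2, nh)^2))
  ok <- d_nh <= 4
  if (!any(ok))
    stop("no density within 4 A of site NE1")
  cand <- if (is.null(near)) which(ok) else
    which(ok & sqrt(rowSums(sweep(pts, 2, near$centroid)^2)) <=
            peak_radius + 0.5)
  if (length(cand) == 0) cand <- which(ok)
  # the nearest water's peak: among voxels carrying substantial density,
  # take the one closest to the NH (not the globally strongest peak)
  strong <- cand[grid$values[idx[cand]] >= 0.3 * max(grid$values[idx[cand]])]
  peak <- strong[which.min(d_nh[strong])]
  sel <- which(sqrt(rowSums(sweep(pts, 2, pts[peak, ])^2)) <= peak_radius)
  w <- grid$values[idx[sel]]
  list(centroid = colSums(pts[sel, , drop = FALSE] * w) / sum(w),
       peak = pts[peak, ])
}

#' Radial distribution function of water oxygens around a site's NH
#'
#' Standard shell-volume normalized g(r) relative to the bulk density rho0.
#'
#' @param traj a [quad_trajectory()] or frame list.
#' @param site site label (distances measured to NE1).
#' @param r_max maximal radius (A).
#' @param dr shell width (A).
#' @param rho0 bulk density (molecules/A^3).
#' @return data.frame with `r` (shell centers) and `g`.
#' @export
water_rdf <- function(traj, site, r_max = 6, dr = 0.1,
                      rho0 = quad_constants$rho0_water) {
  frames <- if (inherits(traj, "quad_trajectory")) traj$frames else traj
  edges <- seq(0, r_max, by = dr)
  counts <- numeric(length(edges) - 1)
  for (f in frames) {
    d <- sqrt(rowSums(sweep(f$waters, 2, f$sites[[site]]$nh)^2))
    h <- findInterval(d[d < r_max], edges, rightmost.closed = TRUE)
    tab <- table(h)
    counts[as.integer(names(tab))] <-
      counts[as.integer(names(tab))] + as.integer(tab)
  }
  shell_v <- 4 / 3 * pi * diff(edges^3)
  data.frame(r = edges[-1] - dr / 2,
             g = counts / (length(frames) * shell_v * rho0))
}

#' Write a density grid in OpenDX scalar-field format
#'
#' @param grid a `density_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  sh <- grid$shape
  n <- prod(sh)
  hdr <- c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            sh[1], sh[2], sh[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %g 0 0", grid$spacing),
    sprintf("delta 0 %g 0", grid$spacing),
    sprintf("delta 0 0 %g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            sh[1], sh[2], sh[3]),
    sprintf(
      "object 3 class array type double rank 0 items %d data follows", n)
  )
  # DX expects z fastest
  v <- aperm(grid$values, c(3, 2, 1))
  vals <- as.vector(v)
  pad <- ceiling(length(vals) / 3) * 3 - length(vals)
  vals <- c(vals, rep(NA, pad))
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  body <- apply(m, 1, function(r)
    paste(format(r[!is.na(r)], digits = 8), collapse = " "))
  writeLines(c(hdr, body,
               'attribute "dep" string "positions"',
               'object "density" class field'), path)
  invisible(path)
}
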