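# Distance-based observables: shortest inter-site distances, per-frame
# distance tables, conformer classifiers, frame selection, 2D structural
# maps. All distances are between C/N heavy atoms, disregarding hydrogens.

site_coords <- function(x) {
  if (inherits(x, "indole_site")) return(x$atoms)
  if (is.matrix(x)) return(x)
  if (is.numeric(x) && length(x) == 3) return(matrix(x, 1, 3))
  stop("cannot interpret object as an atom group")
}

#' Minimum inter-site distance
#'
#' Shortest Euclidean distance over all cross pairs of atoms between two
#' sites or atom groups. For [indole_site()] arguments this uses the
#' package-wide convention: C/N ring heavy atoms only, no hydrogens.
#'
#' @param a,b an [indole_site()], an (n x 3) coordinate matrix, or a single
#'   xyz point.
#' @return the minimum distance in Angstrom (symmetric in its arguments).
#' @export
#' @examples
#' tpl <- indole_template()
#' min_site_distance(tpl, tpl + 5)  # < 5: closest-atom, not centroid
min_site_distance <- function(a, b) {
  A <- site_coords(a); B <- site_coords(b)
  if (nrow(A) == 0 || nrow(B) == 0)
    stop("empty atom set in min_site_distance")
  # squared cross-distance matrix without forming explicit loops
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(min(d2), 0))
}

#' Per-frame distance table of the quadruplex
#'
#' Computes the six pairwise shortest indole-indole distances (two sides,
#' two interfacial edges, two diagonals) plus, when the corresponding atom
#' groups are present in `frame$groups`, auxiliary dmpA-124A, dmpA-122D and
#' SAL-122 shortest distances.
#'
#' @param frame a [quad_frame()].
#' @return data.frame with columns `pair`, `a`, `b`, `d_min` (Angstrom) and
#'   `kind` (`side`/`edge`/`diagonal`/`aux`).
#' @export
distance_table <- function(frame) {
  stopifnot(inherits(frame, "quad_frame"))
  res <- QUAD_PAIR_KIND
  res$d_min <- mapply(function(a, b)
    min_site_distance(frame$sites[[a]], frame$sites[[b]]),
    res$a, res$b)
  aux <- list(
    c("dmpA", "124A"), c("dmpA", "122D"),
    c("SAL_A", "122A"), c("SAL_D", "122D")
  )
  for (ax in aux) {
    if (!is.null(frame$groups[[ax[1]]])) {
      res <- rbind(res, data.frame(
        a = ax[1], b = ax[2], kind = "aux",
        d_min = min_site_distance(frame$groups[[ax[1]]],
                                  frame$sites[[ax[2]]])))
    }
  }
  res$pair <- paste(res$a, res$b, sep = "-")
  res[, c("pair", "a", "b", "d_min", "kind")]
}

#' Classify the Re-chromophore conformer from the dmpA-124A distance
#'
#' The dmp ligand of the Re complex sits either close to the proximal
#' tryptophan ("in", distance distribution peaking at 3-4 A) or away from it
#' ("out", peaking at 5-6 A).
#'
#' @param d_dmpA_124A shortest dmpA-124A distance, Angstrom (vectorized).
#' @param cutoff decision boundary; default 4.5 A, the midpoint of the two
#'   peaks. `in` iff `d < cutoff` (strict).
#' @return character vector, `"in"` or `"out"`.
#' @export
classify_re_conformer <- function(d_dmpA_124A, cutoff = 4.5) {
  stopifnot(all(d_dmpA_124A > 0))
  ifelse(d_dmpA_124A < cutoff, "in", "out")
}

#' Classify the quadruplex shape from its two side lengths
#'
#' A side is "short" below `short_cutoff` (default 4 A, the same criterion
#' used to select nearly-rhombic subpopulations). Both sides short is
#' rhombic; one short side gives a trapezoid named by the (124A-122A,
#' 122D-124D) ordering. Frames with both sides long are still labeled by
#' the shorter/longer ordering and flagged via the `both_long` attribute.
#'
#' @param side_AA 124A-122A shortest distance (Angstrom, vectorized).
#' @param side_DD 122D-124D shortest distance.
#' @param short_cutoff threshold below which a side counts as short.
#' @return character vector with levels `rhombic`, `trapezoid_shortlong`,
#'   `trapezoid_longshort`; attribute `both_long` is a logical vector.
#' @export
#' @examples
#' classify_quad_shape(3.5, 6.0)  # "trapezoid_shortlong"
classify_quad_shape <- function(side_AA, side_DD, short_cutoff = 4.0) {
  stopifnot(all(side_AA > 0), all(side_DD > 0),
            length(side_AA) == length(side_DD))
  a_short <- side_AA < short_cutoff
  d_short <- side_DD < short_cutoff
  out <- ifelse(a_short & d_short, "rhombic",
         ifelse(side_AA <= side_DD, "trapezoid_shortlong",
                "trapezoid_longshort"))
  attr(out, "both_long") <- !a_short & !d_short
  out
}

#' Predicate constructor for frame selection
#'
#' @param pair a pair string `"A-B"` naming two sites/groups whose shortest
#'   distance the predicate tests (e.g. `"124A-122A"`, `"SAL_A-122A"`).
#' @param op comparison operator, `"<"`, `"<="`, `">"` or `">="`.
#' @param value threshold in Angstrom.
#' @return a `frame_predicate` object for [select_frames()].
#' @export
distance_predicate <- function(pair, op, value) {
  stopifnot(op %in% c("<", "<=", ">", ">="), value > 0)
  structure(list(pair = pair, op = op, value = value),
            class = "frame_predicate")
}

frame_group <- function(frame, name) {
  if (name %in% names(frame$sites)) return(frame$sites[[name]])
  if (name %in% names(frame$groups)) return(frame$groups[[name]])
  stop("frame has no site or group named '", name, "'")
}

#' Select frames satisfying a conjunction of distance predicates
#'
#' Reproduces subpopulation filters such as "both sides < 4 A and both
#' SAL-122 distances > 3.5 A". Every predicate must be computable on every
#' frame; referencing an absent atom group is an error.
#'
#' @param traj a [quad_trajectory()].
#' @param predicates list of [distance_predicate()] objects (empty list
#'   selects everything).
#' @return list with `frames` (the selected [quad_trajectory()], or NULL if
#'   empty), `index` (selected 0-based frame indices) and `counts`
#'   (data.frame of per-predicate pass counts).
#' @export
select_frames <- function(traj, predicates = list()) {
  stopifnot(inherits(traj, "quad_trajectory"))
  n <- length(traj$frames)
  keep <- rep(TRUE, n)
  counts <- data.frame(predicate = character(0), n_pass = integer(0))
  for (p in predicates) {
    nm <- strsplit(p$pair, "-", fixed = TRUE)[[1]]
    if (length(nm) != 2) stop("malformed pair: ", p$pair)
    d <- vapply(traj$frames, function(f)
      min_site_distance(frame_group(f, nm[1]), frame_group(f, nm[2])),
      numeric(1))
    pass <- do.call(p$op, list(d, p$value))
    counts <- rbind(counts, data.frame(
      predicate = paste(p$pair, p$op, p$value), n_pass = sum(pass)))
    keep <- keep & pass
  }
  sel <- which(keep)
  list(
    frames = if (length(sel) > 0) quad_trajectory(traj$frames[sel]) else NULL,
    index = vapply(traj$frames[sel], function(f) f$index, numeric(1)),
    counts = counts
  )
}

#' 2D structural map (joint histogram of two distance series)
#'
#' The canonical use correlates the 124A-122A and 122D-124D shortest
#' distances over a trajectory; any equal-length paired series works.
#'
#' @param x_distances,y_distances equal-length numeric vectors (Angstrom).
#' @param bin_width bin width in Angstrom (shared by both axes).
#' @param x_range,y_range optional c(lo, hi); defaults snap to bin edges
#'   covering the data.
#' @return list with `counts` (matrix, rows = x bins), `x_edges`, `y_edges`.
#'   `sum(counts)` equals the number of frames.
#' @export
structural_map_2d <- function(x_distances, y_distances, bin_width = 0.1,
                              x_range = NULL, y_range = NULL) {
  if (length(x_distances) != length(y_distances))
    stop("x and y distance series differ in length")
  stopifnot(bin_width > 0, length(x_distances) > 0)
  edges <- function(v, rg) {
    if (is.null(rg)) rg <- range(v)
    lo <- floor(rg[1] / bin_width) * bin_width
    hi <- ceiling(rg[2] / bin_width + 1e-9) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    seq(lo, hi, by = bin_width)
  }
  xe <- edges(x_distances, x_range); ye <- edges(y_distances, y_range)
  xi <- pmin(pmax(findInterval(x_distances, xe,
                               rightmost.closed = TRUE), 1), length(xe) - 1)
  yi <- pmin(pmax(findInterval(y_distances, ye,
                               rightmost.closed = TRUE), 1), length(ye) - 1)
  counts <- matrix(0L, length(xe) - 1, length(ye) - 1)
  for (k in seq_along(xi)) counts[xi[k], yi[k]] <- counts[xi[k], yi[k]] + 1L
  list(counts = counts, x_edges = xe, y_edges = ye)
}

#' Distance time series over a trajectory
#'
#' @param traj a [quad_trajectory()].
#' @param a,b site or group names (as in [distance_predicate()] pairs).
#' @return numeric vector of per-frame shortest distances.
#' @export
distance_series <- function(traj, a, b) {
  vapply(traj$frames, function(f)
    min_site_distance(frame_group(f, a), frame_group(f, b)), numeric(1))
}
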