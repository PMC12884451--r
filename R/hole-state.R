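# Per-fragment charge/spin time-series analysis: localization statistics,
# delocalization episodes, complete-transfer detection, fluctuation
# correlations. Conservation of total charge and spin is asserted on
# construction of the container.

#' Charge/spin series container
#'
#' @param times time stamps in fs (need not be uniform).
#' @param charge,spin numeric matrices `n_frames x n_fragments` with
#'   fragment column names (the four indole labels plus e.g. `dmpA`,
#'   `ReCO3`).
#' @param method_tag provenance tag (e.g. `"CAM-B3LYP"`, `"PBE0"`,
#'   `"synthetic"`).
#' @param tol conservation tolerance: per-frame charge and spin sums must be
#'   constant within `tol` (default 1e-3).
#' @return a `charge_series` object.
#' @export
charge_series <- function(times, charge, spin = NULL,
                          method_tag = "unknown", tol = 1e-3) {
  stopifnot(is.matrix(charge), length(times) == nrow(charge))
  if (is.null(colnames(charge))) stop("charge matrix needs fragment names")
  if (is.null(spin)) spin <- matrix(0, nrow(charge), ncol(charge),
                                    dimnames = dimnames(charge))
  check_conserved <- function(m, what) {
    s <- rowSums(m)
    if (diff(range(s)) > tol)
      stop("per-frame ", what, " sum varies by ",
           format(diff(range(s))), " (> ", tol, "): not conserved")
  }
  check_conserved(charge, "charge")
  check_conserved(spin, "spin")
  structure(list(times = as.numeric(times), charge = charge, spin = spin,
                 method_tag = method_tag),
            class = "charge_series")
}

series_indoles <- function(series) {
  intersect(QUAD_SITES, colnames(series$charge))
}

#' Read a charge/spin series from long-format CSV
#'
#' Expected columns: `frame`, `time`, `fragment`, `charge`, `spin`
#' (optionally `method`).
#'
#' @param path CSV path.
#' @return a [charge_series()].
#' @export
read_charge_series <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time", "fragment", "charge")
  if (!all(need %in% names(d)))
    stop("charge-series CSV must have columns ",
         paste(need, collapse = ", "))
  frags <- unique(d$fragment)
  frames <- sort(unique(d$frame))
  shape <- function(col) {
    m <- matrix(NA_real_, length(frames), length(frags),
                dimnames = list(NULL, frags))
    m[cbind(match(d$frame, frames), match(d$fragment, frags))] <- d[[col]]
    m
  }
  times <- d$time[match(frames, d$frame)]
  charge_series(times, shape("charge"),
                if ("spin" %in% names(d)) shape("spin") else NULL,
                method_tag = if ("method" %in% names(d)) d$method[1]
                             else "unknown")
}

#' Write a charge/spin series as long-format CSV
#'
#' @param series a [charge_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_charge_series <- function(series, path) {
  frags <- colnames(series$charge)
  n <- nrow(series$charge)
  d <- data.frame(
    frame = rep(seq_len(n), times = length(frags)),
    time = rep(series$times, times = length(frags)),
    fragment = rep(frags, each = n),
    charge = as.vector(series$charge),
    spin = as.vector(series$spin),
    method = series$method_tag)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Localization summary of a charge series
#'
#' The dominant site is the indole with the largest mean charge; the series
#' is "localized" when that mean carries at least `localized_fraction` of
#' the total mean indole hole charge (operationalizing the >= 90%
#' localization criterion).
#'
#' @param series a [charge_series()] with >= 10 frames.
#' @param localized_fraction threshold fraction (default 0.9).
#' @return list with `per_fragment` (data.frame: fragment, mean, median,
#'   sd), `dominant_site`, `localized`, `dominant_fraction`, `tie`.
#' @export
localization_summary <- function(series, localized_fraction = 0.9) {
  stopifnot(inherits(series, "charge_series"))
  if (nrow(series$charge) < 10)
    stop("need >= 10 frames for a localization summary")
  ind <- series_indoles(series)
  if (length(ind) == 0) stop("series contains no indole fragments")
  per <- data.frame(
    fragment = colnames(series$charge),
    mean = colMeans(series$charge),
    median = apply(series$charge, 2, median),
    sd = apply(series$charge, 2, sd),
    row.names = NULL)
  mi <- per$mean[match(ind, per$fragment)]
  best <- which.max(mi)  # first of ties: fixed site order
  tie <- sum(abs(mi - max(mi)) < 1e-12) > 1
  total <- sum(mi)
  frac <- mi[best] / total
  list(per_fragment = per, dominant_site = ind[best],
       localized = frac >= localized_fraction,
       dominant_fraction = frac, tie = tie)
}

#' Detect partial delocalization episodes
#'
#' An episode is a maximal run of frames in which a given non-dominant
#' indole carries at least `partner_threshold` charge, lasting at least
#' `min_duration`. Episodes are labeled by the geometric class of the
#' (dominant, partner) pair: interfacial edge, short/long diagonal, or
#' intramolecular side.
#'
#' @param series a [charge_series()].
#' @param partner_threshold charge threshold (e), default 0.2 (a package
#'   convention; the underlying studies do not quantify "partial").
#' @param min_duration minimal episode duration in fs (default 5),
#'   computed from time stamps (cadence need not be uniform).
#' @return data.frame: `start_frame`, `end_frame`, `start_time`,
#'   `end_time`, `duration`, `hot_site`, `partner`, `max_partner_charge`,
#'   `pair_kind`.
#' @export
detect_delocalization <- function(series, partner_threshold = 0.2,
                                  min_duration = 5) {
  stopifnot(inherits(series, "charge_series"))
  dom <- localization_summary_safe(series)
  ind <- series_indoles(series)
  out <- list()
  for (p in setdiff(ind, dom)) {
    above <- series$charge[, p] >= partner_threshold
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      t0 <- series$times[starts[k]]; t1 <- series$times[ends[k]]
      dur <- t1 - t0 + median(diff(series$times))
      if (dur >= min_duration) {
        out[[length(out) + 1L]] <- data.frame(
          start_frame = starts[k], end_frame = ends[k],
          start_time = t0, end_time = t1, duration = dur,
          hot_site = dom, partner = p,
          max_partner_charge = max(series$charge[starts[k]:ends[k], p]),
          pair_kind = pair_kind(dom, p))
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      start_time = numeric(0), end_time = numeric(0),
                      duration = numeric(0), hot_site = character(0),
                      partner = character(0),
                      max_partner_charge = numeric(0),
                      pair_kind = character(0)))
  res <- do.call(rbind, out)
  res[order(res$start_frame), ]
}

# dominant site without the >= 10 frame restriction used by the summary
localization_summary_safe <- function(series) {
  ind <- series_indoles(series)
  mi <- colMeans(series$charge[, ind, drop = FALSE])
  ind[which.max(mi)]
}

#' Detect complete hole-transfer events
#'
#' An event occurs when the per-frame dominant indole changes and the new
#' site stays dominant for at least `persistence`. Transient excursions
#' shorter than `persistence` (e.g. a transfer followed by back-transfer
#' within tens of fs) are not counted.
#'
#' @param series a [charge_series()].
#' @param persistence minimal residence time in fs (default 50).
#' @return data.frame: `frame`, `time`, `from`, `to`.
#' @export
detect_transfer <- function(series, persistence = 50) {
  stopifnot(inherits(series, "charge_series"))
  ind <- series_indoles(series)
  dom <- ind[apply(series$charge[, ind, drop = FALSE], 1, which.max)]
  r <- rle(dom)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  dt <- median(diff(series$times))
  established <- r$values[1]
  out <- list()
  for (k in seq_along(r$values)) {
    dur <- series$times[ends[k]] - series$times[starts[k]] + dt
    if (r$values[k] != established && dur >= persistence) {
      out[[length(out) + 1L]] <- data.frame(
        frame = starts[k], time = series$times[starts[k]],
        from = established, to = r$values[k])
      established <- r$values[k]
    }
  }
  if (length(out) == 0)
    return(data.frame(frame = integer(0), time = numeric(0),
                      from = character(0), to = character(0)))
  do.call(rbind, out)
}

#' Pearson correlation of mean-removed charge fluctuations
#'
#' @param series a [charge_series()] with >= 10 frames.
#' @param fragment_a,fragment_b fragment names.
#' @return Pearson r in `[-1, 1]`.
#' @export
fluctuation_correlation <- function(series, fragment_a, fragment_b) {
  stopifnot(inherits(series, "charge_series"),
            nrow(series$charge) >= 10)
  a <- series$charge[, fragment_a]
  b <- series$charge[, fragment_b]
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero variance in fragment ", if (sd(a) == 0) fragment_a
         else fragment_b)
  cor(a - mean(a), b - mean(b))
}
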