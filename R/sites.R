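# Domain containers: indole sites, frames, trajectories.

#' Construct an indole site
#'
#' An indole site is one tryptophan side chain reduced to its nine C/N
#' heavy ring atoms (CG, CD1, CD2, NE1, CE2, CE3, CZ2, CZ3, CH2). All
#' distances in this package are measured between these atoms, disregarding
#' hydrogens, CB and backbone.
#'
#' @param chain chain identifier.
#' @param resno residue number.
#' @param atoms numeric matrix (n x 3) of coordinates with rownames from the
#'   allowed atom-name set; at least 5 atoms, NE1 exactly once.
#' @param label site label, e.g. `"124A"`; default `paste0(resno, chain)`.
#' @return object of class `indole_site` with fields `chain`, `resno`,
#'   `label`, `atoms` and `nh` (the NE1 position).
#' @export
#' @examples
#' tpl <- indole_template()
#' site <- indole_site("A", 122, tpl)
indole_site <- function(chain, resno, atoms, label = paste0(resno, chain)) {
  stopifnot(is.matrix(atoms), ncol(atoms) == 3)
  nm <- rownames(atoms)
  if (is.null(nm)) stop("indole atoms must carry atom-name rownames")
  bad <- setdiff(nm, INDOLE_ATOMS)
  if (length(bad) > 0)
    stop("disallowed indole atom name(s): ", paste(bad, collapse = ", "))
  if (sum(nm == "NE1") != 1) stop("indole site must contain NE1 exactly once")
  if (nrow(atoms) < 5) stop("indole site needs >= 5 atoms, got ", nrow(atoms))
  structure(list(chain = chain, resno = resno, label = label,
                 atoms = atoms, nh = atoms["NE1", ]),
            class = "indole_site")
}

#' Idealized indole heavy-atom template
#'
#' Planar indole built from a regular pentagon and hexagon fused along the
#' CD2-CE2 bond (bond length 1.40 A), adequate for all distance analyses in
#' the package (rigid planar rings).
#'
#' @return 9 x 3 matrix of coordinates (z = 0) with indole atom rownames;
#'   NE1 at the origin and the ring centroid on the +x axis.
#' @export
indole_template <- function() {
  hex_c <- c(-1.4 * cos(pi / 6), 0)
  hexv <- function(deg) hex_c + 1.4 * c(cos(deg * pi / 180),
                                        sin(deg * pi / 180))
  pen_c <- c(0.7 / tan(36 * pi / 180), 0)
  penv <- function(deg) pen_c + (0.7 / sin(36 * pi / 180)) *
    c(cos(deg * pi / 180), sin(deg * pi / 180))
  xy <- rbind(
    CD2 = hexv(-30), CE2 = hexv(30), CZ2 = hexv(90),
    CH2 = hexv(150), CZ3 = hexv(210), CE3 = hexv(270),
    NE1 = penv(72), CD1 = penv(0), CG = penv(-72)
  )
  # shift NE1 to origin, rotate ring centroid onto +x
  xy <- sweep(xy, 2, xy["NE1", ])
  ctr <- colMeans(xy)
  th <- atan2(ctr[2], ctr[1])
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  xy <- xy %*% rot
  m <- cbind(xy, 0)
  colnames(m) <- c("x", "y", "z")
  m[INDOLE_ATOMS, ]
}

#' Construct a trajectory frame
#'
#' @param index 0-based frame index.
#' @param time time stamp (ps).
#' @param state redox state label, one of
#'   `"GS", "MLCT", "124A+", "122A+", "122D+", "124D+"`.
#' @param sites named list of the four [indole_site()] objects
#'   (`124A`, `122A`, `122D`, `124D`).
#' @param waters numeric matrix (n x 3) of water oxygen coordinates.
#' @param groups optional named list of auxiliary atom-group matrices
#'   (e.g. `dmpA`, `SAL_A`).
#' @return object of class `quad_frame`.
#' @export
quad_frame <- function(index, time, state, sites, waters = NULL,
                       groups = list()) {
  if (!state %in% STATE_LABELS)
    stop("unknown state label: ", state)
  if (!identical(sort(names(sites)), sort(QUAD_SITES)))
    stop("frame must carry exactly the four sites ",
         paste(QUAD_SITES, collapse = ", "))
  sites <- sites[QUAD_SITES]
  if (is.null(waters)) waters <- matrix(numeric(0), 0, 3)
  structure(list(index = index, time = time, state = state,
                 sites = sites, waters = waters, groups = groups),
            class = "quad_frame")
}

#' Construct a trajectory (ordered list of frames)
#'
#' @param frames list of [quad_frame()] objects.
#' @return object of class `quad_trajectory`.
#' @export
quad_trajectory <- function(frames) {
  stopifnot(length(frames) >= 1)
  structure(list(frames = frames), class = "quad_trajectory")
}

#' @export
length.quad_trajectory <- function(x) length(x$frames)

#' @export
print.quad_trajectory <- function(x, ...) {
  st <- vapply(x$frames, function(f) f$state, character(1))
  cat("quad_trajectory:", length(x$frames), "frames;",
      "states:", paste(rle(st)$values, "x", rle(st)$lengths,
                       collapse = ", "), "\n")
  invisible(x)
}

#' Extract quadruplex indole sites from an atom table
#'
#' Collects the four Trp side chains (residues 122/124 on chains A and D by
#' default) as [indole_site()] objects, plus water oxygens as a coordinate
#' matrix. Uses the requested model only.
#'
#' @param atoms atom table from [read_pdb()] / [read_mmcif()].
#' @param model model number to use (default 1).
#' @param state state label to tag the frame with.
#' @param site_selectors named list mapping site labels to `list(chain, resno)`.
#' @return a [quad_frame()].
#' @export
frame_from_atoms <- function(atoms, model = 1, state = "GS",
                             site_selectors = default_site_selectors()) {
  d <- atoms[atoms$model == model, , drop = FALSE]
  if (nrow(d) == 0) stop("model ", model, " not present")
  sites <- lapply(names(site_selectors), function(lbl) {
    sel <- site_selectors[[lbl]]
    rows <- d$chain == sel$chain & d$resno == sel$resno &
      d$atom %in% INDOLE_ATOMS
    if (!any(rows))
      stop("site ", lbl, " (chain ", sel$chain, " resno ", sel$resno,
           ") not found")
    m <- as.matrix(d[rows, c("x", "y", "z")])
    rownames(m) <- d$atom[rows]
    indole_site(sel$chain, sel$resno, m, label = lbl)
  })
  names(sites) <- names(site_selectors)
  wrow <- d$resname == "HOH" & d$atom %in% c("O", "OW", "OH2")
  waters <- as.matrix(d[wrow, c("x", "y", "z")])
  quad_frame(index = model - 1L, time = model - 1L, state = state,
             sites = sites, waters = waters)
}

default_site_selectors <- function() {
  list(`124A` = list(chain = "A", resno = 124),
       `122A` = list(chain = "A", resno = 122),
       `122D` = list(chain = "D", resno = 122),
       `124D` = list(chain = "D", resno = 124))
}

#' Read a multi-model PDB trajectory
#'
#' Model k becomes frame index k - 1 (0-based internally, 1-based in files
#' and reports).
#'
#' @param path multi-model PDB file.
#' @param states either a single state label for all frames or a vector of
#'   labels, one per model.
#' @inheritParams frame_from_atoms
#' @return a [quad_trajectory()].
#' @export
read_trajectory_pdb <- function(path, states = "GS",
                                site_selectors = default_site_selectors()) {
  atoms <- read_pdb(path)
  models <- sort(unique(atoms$model))
  if (length(states) == 1) states <- rep(states, length(models))
  stopifnot(length(states) == length(models))
  frames <- lapply(seq_along(models), function(k) {
    f <- frame_from_atoms(atoms, model = models[k], state = states[k],
                          site_selectors = site_selectors)
    f$index <- k - 1L
    f
  })
  quad_trajectory(frames)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a [quad_trajectory()].
#' @param path output path.
#' @return `path`, invisibly. State labels are recorded as REMARK lines.
#' @export
write_trajectory_pdb <- function(traj, path) {
  rows <- list()
  for (k in seq_along(traj$frames)) {
    f <- traj$frames[[k]]
    at <- frame_to_atoms(f)
    at$model <- k
    rows[[k]] <- at
  }
  atoms <- new_atom_table(do.call(rbind, rows))
  write_pdb(atoms, path)
  states <- vapply(traj$frames, function(f) f$state, character(1))
  body <- readLines(path, warn = FALSE)
  writeLines(c(sprintf("REMARK 900 QUADHOP STATES %s",
                       paste(states, collapse = " ")), body), path)
  invisible(path)
}

#' Read back a trajectory written by [write_trajectory_pdb()]
#'
#' @param path the file.
#' @return a [quad_trajectory()] with per-frame states restored from the
#'   REMARK header when present.
#' @export
read_trajectory_quadhop <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  states <- "GS"
  if (grepl("^REMARK 900 QUADHOP STATES ", first))
    states <- strsplit(sub("^REMARK 900 QUADHOP STATES ", "", first),
                       " ")[[1]]
  read_trajectory_pdb(path, states = states)
}

# Flatten one frame back to atom-table rows (sites as TRP ATOM records,
# waters as HOH HETATM oxygens).
frame_to_atoms <- function(f) {
  rows <- list()
  for (lbl in names(f$sites)) {
    s <- f$sites[[lbl]]
    rows[[length(rows) + 1L]] <- data.frame(
      record = "ATOM", serial = 0L, atom = rownames(s$atoms), altloc = "",
      resname = "TRP", chain = s$chain, resno = s$resno,
      x = s$atoms[, 1], y = s$atoms[, 2], z = s$atoms[, 3],
      occupancy = 1, element = substr(rownames(s$atoms), 1, 1),
      model = 1L, stringsAsFactors = FALSE)
  }
  for (gl in names(f$groups)) {
    g <- f$groups[[gl]]
    rows[[length(rows) + 1L]] <- data.frame(
      record = "HETATM", serial = 0L,
      atom = rownames(g) %||% paste0("C", seq_len(nrow(g))), altloc = "",
      resname = substr(toupper(gl), 1, 3), chain = "X",
      resno = 900L + match(gl, names(f$groups)),
      x = g[, 1], y = g[, 2], z = g[, 3], occupancy = 1,
      element = "C", model = 1L, stringsAsFactors = FALSE)
  }
  if (nrow(f$waters) > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      record = "HETATM", serial = 0L, atom = "O", altloc = "",
      resname = "HOH", chain = "W", resno = seq_len(nrow(f$waters)),
      x = f$waters[, 1], y = f$waters[, 2], z = f$waters[, 3],
      occupancy = 1, element = "O", model = 1L, stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  d$serial <- seq_len(nrow(d))
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
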