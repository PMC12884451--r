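# Minimal structure I/O. No structural-biology parser exists in the
# installed R stack, so fixed-column PDB v3.3, a restricted mmCIF atom_site
# loop, and XYZ are implemented here directly. All readers return an "atom
# table": a data.frame with one row per atom and columns
#   record, serial, atom, altloc, resname, chain, resno, x, y, z,
#   occupancy, element, model
# Coordinates are Angstrom; model is the 1-based model number (frame).

ATOM_TABLE_COLS <- c("record", "serial", "atom", "altloc", "resname",
                     "chain", "resno", "x", "y", "z", "occupancy",
                     "element", "model")

new_atom_table <- function(df) {
  for (nm in setdiff(ATOM_TABLE_COLS, names(df))) {
    df[[nm]] <- switch(nm,
      record = "ATOM", altloc = "", occupancy = 1, model = 1L,
      element = substr(df$atom, 1, 1), serial = seq_len(nrow(df)),
      stop("missing column: ", nm))
  }
  df <- df[ATOM_TABLE_COLS]
  class(df) <- c("atom_table", "data.frame")
  df
}

#' Read a PDB file into an atom table
#'
#' Parses ATOM/HETATM records of a (possibly multi-model) PDB v3.3 file.
#' For crystal-style input with alternate locations, only the highest
#' occupancy altloc of each atom is kept (ties resolved to altloc "A").
#'
#' @param path path to a PDB file.
#' @param keep_altlocs keep all alternate locations instead of filtering.
#' @return a data.frame of class `atom_table` (one row per atom; `model`
#'   numbers frames of multi-model files, 1-based).
#' @seealso [write_pdb()], [read_mmcif()], [read_xyz()]
#' @export
read_pdb <- function(path, keep_altlocs = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty PDB file: ", path)
  model <- 1L
  seen_model <- FALSE
  models <- integer(length(lines))
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  is_model <- startsWith(lines, "MODEL")
  cur <- 1L
  for (i in which(is_model | is_atom)) {
    if (is_model[i]) {
      cur <- suppressWarnings(as.integer(substr(lines[i], 11, 14)))
      if (is.na(cur)) cur <- if (seen_model) max(models) + 1L else 1L
      seen_model <- TRUE
    } else {
      models[i] <- cur
    }
  }
  al <- lines[is_atom]
  if (length(al) == 0) stop("no ATOM/HETATM records in ", path)
  fx <- function(a, b) trimws(substr(al, a, b))
  df <- data.frame(
    record    = fx(1, 6),
    serial    = suppressWarnings(as.integer(fx(7, 11))),
    atom      = fx(13, 16),
    altloc    = fx(17, 17),
    resname   = fx(18, 20),
    chain     = fx(22, 22),
    resno     = suppressWarnings(as.integer(fx(23, 26))),
    x         = as.numeric(fx(31, 38)),
    y         = as.numeric(fx(39, 46)),
    z         = as.numeric(fx(47, 54)),
    occupancy = suppressWarnings(as.numeric(fx(55, 60))),
    element   = fx(77, 78),
    model     = models[is_atom],
    stringsAsFactors = FALSE
  )
  df$occupancy[is.na(df$occupancy)] <- 1
  df$element[df$element == ""] <- substr(df$atom[df$element == ""], 1, 1)
  if (!keep_altlocs) df <- resolve_altlocs(df)
  new_atom_table(df)
}

# Keep the highest-occupancy altloc per (model, chain, resno, atom);
# ties go to altloc "A" (then lexicographic).
resolve_altlocs <- function(df) {
  if (all(df$altloc == "")) return(df)
  key <- paste(df$model, df$chain, df$resno, df$resname, df$atom, sep = "|")
  ord <- order(key, -df$occupancy, df$altloc != "A", df$altloc)
  df <- df[ord, ]
  df <- df[!duplicated(paste(df$model, df$chain, df$resno, df$resname,
                             df$atom, sep = "|")), ]
  df[order(df$model, df$chain, df$resno, df$serial), ]
}

#' Write an atom table as a (multi-model) PDB file
#'
#' @param atoms atom table (see [read_pdb()]); rows with `model > 1` are
#'   wrapped in MODEL/ENDMDL blocks.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  fmt <- function(d) {
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            d$record, d$serial %% 100000L,
            ifelse(nchar(d$atom) < 4, paste0(" ", d$atom), d$atom),
            d$altloc, d$resname, d$chain, d$resno %% 10000L,
            d$x, d$y, d$z, d$occupancy, 0, d$element)
  }
  models <- sort(unique(atoms$model))
  out <- character(0)
  multi <- length(models) > 1
  for (m in models) {
    d <- atoms[atoms$model == m, , drop = FALSE]
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    out <- c(out, fmt(d))
    out <- c(out, if (multi) "ENDMDL" else "TER")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Read a restricted mmCIF file into an atom table
#'
#' Supports the `_atom_site` loop produced by [write_mmcif()] and by common
#' deposition software (whitespace-delimited values, no multi-line strings).
#'
#' @param path path to an mmCIF file.
#' @param keep_altlocs keep all alternate locations instead of filtering.
#' @return an `atom_table` data.frame.
#' @export
read_mmcif <- function(path, keep_altlocs = FALSE) {
  lines <- readLines(path, warn = FALSE)
  i <- which(trimws(lines) == "loop_")
  hdr_start <- NA_integer_
  for (j in i) {
    k <- j + 1L
    if (k <= length(lines) && startsWith(trimws(lines[k]), "_atom_site.")) {
      hdr_start <- k
      break
    }
  }
  if (is.na(hdr_start)) stop("no _atom_site loop in ", path)
  k <- hdr_start
  fields <- character(0)
  while (k <= length(lines) && startsWith(trimws(lines[k]), "_atom_site.")) {
    fields <- c(fields, sub("^_atom_site\\.", "", trimws(lines[k])))
    k <- k + 1L
  }
  rows <- character(0)
  while (k <= length(lines)) {
    ln <- trimws(lines[k])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        ln == "loop_" || startsWith(ln, "data_")) break
    rows <- c(rows, ln)
    k <- k + 1L
  }
  if (length(rows) == 0) stop("empty _atom_site loop in ", path)
  mat <- do.call(rbind, strsplit(rows, "[ \t]+"))
  if (ncol(mat) != length(fields))
    stop("malformed _atom_site loop in ", path)
  colnames(mat) <- fields
  g <- function(nm, alt = NULL, default = NA_character_) {
    if (nm %in% fields) return(mat[, nm])
    if (!is.null(alt) && alt %in% fields) return(mat[, alt])
    rep(default, nrow(mat))
  }
  undot <- function(v, default) ifelse(v %in% c(".", "?", NA), default, v)
  df <- data.frame(
    record    = undot(g("group_PDB"), "ATOM"),
    serial    = as.integer(undot(g("id"), NA)),
    atom      = undot(g("auth_atom_id", "label_atom_id"), ""),
    altloc    = undot(g("label_alt_id"), ""),
    resname   = undot(g("auth_comp_id", "label_comp_id"), ""),
    chain     = undot(g("auth_asym_id", "label_asym_id"), ""),
    resno     = as.integer(undot(g("auth_seq_id", "label_seq_id"), NA)),
    x         = as.numeric(mat[, "Cartn_x"]),
    y         = as.numeric(mat[, "Cartn_y"]),
    z         = as.numeric(mat[, "Cartn_z"]),
    occupancy = as.numeric(undot(g("occupancy"), "1")),
    element   = undot(g("type_symbol"), ""),
    model     = as.integer(undot(g("pdbx_PDB_model_num"), "1")),
    stringsAsFactors = FALSE
  )
  df$element[df$element == ""] <- substr(df$atom[df$element == ""], 1, 1)
  if (!keep_altlocs) df <- resolve_altlocs(df)
  new_atom_table(df)
}

#' Write an atom table as mmCIF
#'
#' @param atoms atom table.
#' @param path output path.
#' @param entry_id data block name.
#' @return `path`, invisibly.
#' @export
write_mmcif <- function(atoms, path, entry_id = "synthetic") {
  hdr <- c(
    paste0("data_", entry_id),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.pdbx_PDB_model_num"
  )
  body <- sprintf("%-6s %d %s %s %s %s %s %s %d %.3f %.3f %.3f %.2f %d",
                  atoms$record, seq_len(nrow(atoms)), atoms$element,
                  atoms$atom, ifelse(atoms$altloc == "", ".", atoms$altloc),
                  atoms$resname, atoms$chain, atoms$chain, atoms$resno,
                  atoms$x, atoms$y, atoms$z, atoms$occupancy, atoms$model)
  writeLines(c(hdr, body, "#"), path)
  invisible(path)
}

#' Read an (multi-frame) XYZ file
#'
#' @param path path to an XYZ file; repeated blocks become models 1, 2, ...
#' @return an `atom_table` with `atom`/`element` set to the XYZ symbol and
#'   comment lines returned in `attr(, "comments")`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(); comments <- character(0); i <- 1L; m <- 0L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed XYZ count line at line ", i)
    m <- m + 1L
    comments <- c(comments, lines[i + 1L])
    block <- lines[(i + 2L):(i + 1L + n)]
    sp <- do.call(rbind, strsplit(trimws(block), "[ \t]+"))
    out[[m]] <- data.frame(
      record = "ATOM", serial = seq_len(n), atom = sp[, 1], altloc = "",
      resname = "UNK", chain = "X", resno = seq_len(n),
      x = as.numeric(sp[, 2]), y = as.numeric(sp[, 3]),
      z = as.numeric(sp[, 4]), occupancy = 1, element = sp[, 1],
      model = m, stringsAsFactors = FALSE
    )
    i <- i + 2L + n
  }
  res <- new_atom_table(do.call(rbind, out))
  attr(res, "comments") <- comments
  res
}

#' Write an atom table as (multi-frame) XYZ
#'
#' @param atoms atom table.
#' @param path output path.
#' @param comments optional per-model comment lines.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(atoms, path, comments = NULL) {
  models <- sort(unique(atoms$model))
  out <- character(0)
  for (k in seq_along(models)) {
    d <- atoms[atoms$model == models[k], , drop = FALSE]
    cm <- if (!is.null(comments)) comments[k] else paste("frame", models[k])
    out <- c(out, as.character(nrow(d)), cm,
             sprintf("%-2s %12.6f %12.6f %12.6f", d$element, d$x, d$y, d$z))
  }
  writeLines(out, path)
  invisible(path)
}

#' Fetch a structure from the RCSB PDB (online helper)
#'
#' Convenience downloader for interactive use; every analysis in the package
#' and every test works from local files or synthetic structures, so nothing
#' depends on network access.
#'
#' @param id 4-character PDB accession, e.g. `"6MJS"`.
#' @param dest destination file; defaults to `<id>.pdb` in `tempdir()`.
#' @param format `"pdb"` or `"cif"`.
#' @return the destination path.
#' @export
fetch_structure <- function(id, dest = NULL,
                            format = c("pdb", "cif")) {
  format <- match.arg(format)
  if (is.null(dest)) dest <- file.path(tempdir(), paste0(id, ".", format))
  url <- sprintf("https://files.rcsb.org/download/%s.%s",
                 toupper(id), format)
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  dest
}
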