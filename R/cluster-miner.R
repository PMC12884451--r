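# Tryptophan-cluster mining in protein structures: linkage graph at a
# distance cutoff, connected components, intramolecular / interfacial /
# dimer classification, the tight-quadruplex test, size census over a
# structure set, and cofactor proximity.

# Extract per-Trp indole coordinate matrices from an atom table (first
# model, altlocs already resolved by the readers).
trp_indoles <- function(atoms) {
  d <- atoms[atoms$model == min(atoms$model) & atoms$resname == "TRP" &
               atoms$atom %in% INDOLE_ATOMS, , drop = FALSE]
  if (nrow(d) == 0) return(list())
  key <- paste(d$chain, d$resno)
  ord <- order(d$chain, d$resno)
  d <- d[ord, ]; key <- key[ord]
  sp <- split(seq_len(nrow(d)), factor(key, levels = unique(key)))
  lapply(sp, function(ii) {
    m <- as.matrix(d[ii, c("x", "y", "z")])
    rownames(m) <- d$atom[ii]
    attr(m, "chain") <- d$chain[ii[1]]
    attr(m, "resno") <- d$resno[ii[1]]
    m
  })
}

#' Find tryptophan clusters in a structure
#'
#' Builds a graph whose nodes are the tryptophan residues of the first
#' model; two tryptophans are linked when the minimal distance between
#' their indole C/N atoms is within `link_cutoff` (inclusive, "within
#' 10 A"). Clusters are connected components of size >= `min_size`, with
#' members ordered by (chain, residue number).
#'
#' @param structure an `atom_table` ([read_pdb()]/[read_mmcif()] output) or
#'   a file path (format detected from the extension).
#' @param link_cutoff linkage distance in Angstrom (default 10, inclusive).
#' @param min_size minimal reported cluster size (default 2; singletons are
#'   returned separately in the `singletons` attribute for diagnostics).
#' @param structure_id identifier stored on the clusters (defaults to the
#'   file base name or `"structure"`).
#' @return list of `trp_cluster` objects; each has `structure_id`,
#'   `members` (data.frame chain/resno), `size`, `span_chains`,
#'   `classification` (`intramolecular` iff one chain else `interfacial`),
#'   `dimer_link` (interfacial and exactly two chains),
#'   `pairwise_min_distances` (symmetric matrix, zero diagonal),
#'   `tight_quadruplex` (size 4 and all six pairwise minima < 5 A).
#' @export
find_clusters <- function(structure, link_cutoff = 10, min_size = 2,
                          structure_id = NULL) {
  if (is.character(structure)) {
    if (is.null(structure_id))
      structure_id <- sub("\\.(pdb|cif|mmcif|ent)$", "",
                          basename(structure), ignore.case = TRUE)
    structure <- if (grepl("\\.(cif|mmcif)$", structure,
                           ignore.case = TRUE))
      read_mmcif(structure) else read_pdb(structure)
  }
  if (is.null(structure_id)) structure_id <- "structure"
  ind <- trp_indoles(structure)
  n <- length(ind)
  if (n == 0) return(structure(list(), singletons = character(0)))
  dmat <- matrix(0, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dmat[i, j] <- dmat[j, i] <- min_site_distance(ind[[i]], ind[[j]])
    }
  }
  adj <- dmat <= link_cutoff & !diag(n)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  chains <- vapply(ind, function(m) attr(m, "chain"), character(1))
  resnos <- vapply(ind, function(m) attr(m, "resno"), numeric(1))
  clusters <- list()
  singles <- character(0)
  for (cid in sort(unique(comp))) {
    mem <- which(comp == cid)
    mem <- mem[order(chains[mem], resnos[mem])]
    if (length(mem) < max(min_size, 2)) {
      if (length(mem) == 1)
        singles <- c(singles, paste0(chains[mem], resnos[mem]))
      next
    }
    if (length(mem) < min_size) next
    pm <- dmat[mem, mem, drop = FALSE]
    lab <- paste0(chains[mem], resnos[mem])
    dimnames(pm) <- list(lab, lab)
    span <- unique(chains[mem])
    cl <- structure(list(
      structure_id = structure_id,
      members = data.frame(chain = chains[mem], resno = resnos[mem]),
      size = length(mem),
      span_chains = span,
      classification = if (length(span) == 1) "intramolecular"
                       else "interfacial",
      dimer_link = length(span) == 2,
      pairwise_min_distances = pm,
      tight_quadruplex = length(mem) == 4 && all(pm[upper.tri(pm)] < 5)
    ), class = "trp_cluster")
    clusters[[length(clusters) + 1L]] <- cl
  }
  structure(clusters, singletons = singles)
}

#' Tight-quadruplex test on a 4-tryptophan cluster
#'
#' TRUE iff all six pairwise minimal indole-indole distances are strictly
#' below `cutoff` ("below 5 A"); failing pairs are reported.
#'
#' @param cluster a `trp_cluster` of size 4.
#' @param cutoff distance threshold (A), default 5 (strict).
#' @return list with `tight` (logical) and `failing_pairs` (data.frame
#'   pair/distance).
#' @export
tight_quadruplex_check <- function(cluster, cutoff = 5) {
  if (cluster$size != 4)
    stop("tight-quadruplex test requires a cluster of size 4, got ",
         cluster$size)
  pm <- cluster$pairwise_min_distances
  ut <- which(upper.tri(pm), arr.ind = TRUE)
  d <- pm[ut]
  bad <- d >= cutoff
  list(tight = !any(bad),
       failing_pairs = data.frame(
         pair = paste(rownames(pm)[ut[bad, 1]], rownames(pm)[ut[bad, 2]],
                      sep = "-"),
         distance = d[bad]))
}

#' Cluster size census over a structure set
#'
#' Per-size cluster counts (reported both per cluster and per structure
#' id), with the size-4 bin split into intramolecular vs interfacial and
#' the interfacial count further split by the dimer flag - the reporting
#' granularity of the published PDB-wide tryptophan census. A structure
#' contributing two disjoint size-4 clusters is counted twice in the
#' per-cluster histogram and once in the per-id tally.
#'
#' @param clusters list of `trp_cluster`s (possibly from many structures;
#'   concatenate the [find_clusters()] outputs).
#' @return list with `histogram` (data.frame size / n_clusters /
#'   n_structures), `size4` (list: n, intramolecular, interfacial, dimers).
#' @export
size_distribution <- function(clusters) {
  if (length(clusters) == 0)
    return(list(histogram = data.frame(size = integer(0),
                                       n_clusters = integer(0),
                                       n_structures = integer(0)),
                size4 = list(n = 0L, intramolecular = 0L,
                             interfacial = 0L, dimers = 0L)))
  sizes <- vapply(clusters, function(c) c$size, numeric(1))
  ids <- vapply(clusters, function(c) c$structure_id, character(1))
  us <- sort(unique(sizes))
  hist <- data.frame(
    size = us,
    n_clusters = vapply(us, function(s) sum(sizes == s), numeric(1)),
    n_structures = vapply(us, function(s)
      length(unique(ids[sizes == s])), numeric(1)))
  s4 <- clusters[sizes == 4]
  cls <- vapply(s4, function(c) c$classification, character(1))
  list(histogram = hist,
       size4 = list(n = length(s4),
                    intramolecular = sum(cls == "intramolecular"),
                    interfacial = sum(cls == "interfacial"),
                    dimers = sum(vapply(s4, function(c) c$dimer_link,
                                        logical(1)))))
}

#' Distances from a cluster to recognized redox cofactors
#'
#' For every het-group with a recognized cofactor residue name (FAD, FMN,
#' HEM/HEC, FE/FES/SF4, NAD/NAI/NAP) in the structure, the minimal
#' heavy-atom distance to any indole atom of the cluster.
#'
#' @param structure the `atom_table` the cluster came from.
#' @param cluster a `trp_cluster`.
#' @return data.frame: `resname`, `chain`, `resno`, `d_min` (A); empty when
#'   no cofactors are present.
#' @export
cofactor_proximity <- function(structure, cluster) {
  d <- structure[structure$model == min(structure$model), , drop = FALSE]
  cof <- d[d$resname %in% COFACTOR_RESNAMES & d$element != "H", ,
           drop = FALSE]
  empty <- data.frame(resname = character(0), chain = character(0),
                      resno = numeric(0), d_min = numeric(0))
  if (nrow(cof) == 0) return(empty)
  sel <- d$resname == "TRP" & d$atom %in% INDOLE_ATOMS &
    paste(d$chain, d$resno) %in%
      paste(cluster$members$chain, cluster$members$resno)
  cl_xyz <- as.matrix(d[sel, c("x", "y", "z")])
  key <- paste(cof$resname, cof$chain, cof$resno)
  out <- lapply(split(seq_len(nrow(cof)), factor(key, unique(key))),
                function(ii) {
    xyz <- as.matrix(cof[ii, c("x", "y", "z")])
    data.frame(resname = cof$resname[ii[1]], chain = cof$chain[ii[1]],
               resno = cof$resno[ii[1]],
               d_min = min_site_distance(cl_xyz, xyz))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan a directory of structures for tryptophan clusters
#'
#' @param dir directory containing `.pdb` / `.cif` files.
#' @param ids optional character vector (or path to a text file, one id per
#'   line) restricting the scan; ids are matched to file base names.
#' @param link_cutoff,min_size passed to [find_clusters()].
#' @return list of `trp_cluster`s across all structures.
#' @export
mine_structures <- function(dir, ids = NULL, link_cutoff = 10,
                            min_size = 2) {
  files <- list.files(dir, pattern = "\\.(pdb|cif|mmcif|ent)$",
                      full.names = TRUE, ignore.case = TRUE)
  if (!is.null(ids)) {
    if (length(ids) == 1 && file.exists(ids)) ids <- readLines(ids)
    base <- sub("\\.[^.]*$", "", basename(files))
    files <- files[base %in% ids]
  }
  out <- list()
  for (f in files) {
    cl <- tryCatch(find_clusters(f, link_cutoff, min_size),
                   error = function(e) {
                     warning("skipping ", f, ": ", conditionMessage(e))
                     list()
                   })
    out <- c(out, cl)
  }
  out
}
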