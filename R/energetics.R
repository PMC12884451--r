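# Electrostatic potentials at indoles from point-charge environments, with
# component partitioning; distributions of potential differences; and
# linear-response reaction free energies / reorganization energies from
# vertical energy-gap ensembles.

ENV_COMPONENTS <- c("protein", "ReA-", "ReD", "solvent", "counterion",
                    "oxidized_indole", "other")

#' Charged environment container
#'
#' @param coords numeric matrix (n x 3), Angstrom.
#' @param charge partial charges (e).
#' @param component per-particle tag; one of `protein`, `ReA-`, `ReD`,
#'   `solvent`, `counterion`, `oxidized_indole`, `other`.
#' @return a `charged_environment` object.
#' @export
charged_environment <- function(coords, charge, component = "other") {
  stopifnot(is.matrix(coords), ncol(coords) == 3,
            length(charge) == nrow(coords))
  if (length(component) == 1) component <- rep(component, nrow(coords))
  bad <- setdiff(unique(component), ENV_COMPONENTS)
  if (length(bad) > 0)
    stop("unknown component tag(s): ", paste(bad, collapse = ", "))
  structure(list(coords = coords, charge = as.numeric(charge),
                 component = component), class = "charged_environment")
}

#' Read a charged environment from CSV
#'
#' Expected columns `x, y, z, charge, component`.
#'
#' @param path CSV path.
#' @return a [charged_environment()].
#' @export
read_environment_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  charged_environment(as.matrix(d[, c("x", "y", "z")]), d$charge,
                      d$component)
}

#' Electrostatic potential at an indole site from a point-charge environment
#'
#' Vacuum Coulomb potential, no cutoff: the site potential is the unweighted
#' mean over the site's heavy atoms of `sum_k q_k K / r_k` with
#' K = 14.3996 V A / e. Per-component potentials are computed by restricting
#' the sum to each tag; they add up to the total exactly. The evaluated
#' site's own atoms must not be part of the environment; any environment
#' particle closer than 0.5 A to a site atom is treated as mis-tagged input
#' and rejected.
#'
#' @param site an [indole_site()] (or an n x 3 coordinate matrix; a flag for
#'   NE1-only evaluation is provided instead of charge-weighting).
#' @param env a [charged_environment()].
#' @param components tags to include (default: all present).
#' @param nh_only evaluate at NE1 only instead of averaging over all heavy
#'   atoms.
#' @return a `potential_record`: list with `phi_total` (V),
#'   `phi_by_component` (named, V), `site` label.
#' @export
site_potential <- function(site, env, components = NULL, nh_only = FALSE) {
  stopifnot(inherits(env, "charged_environment"))
  pts <- if (inherits(site, "indole_site")) {
    if (nh_only) matrix(site$nh, 1, 3) else site$atoms
  } else site_coords(site)
  lbl <- if (inherits(site, "indole_site")) site$label else "site"
  keep <- if (is.null(components)) rep(TRUE, nrow(env$coords))
          else env$component %in% components
  coords <- env$coords[keep, , drop = FALSE]
  q <- env$charge[keep]
  comp <- env$component[keep]
  if (nrow(coords) == 0)
    return(structure(list(site = lbl, phi_total = 0,
                          phi_by_component = numeric(0)),
                     class = "potential_record"))
  d2 <- outer(rowSums(pts^2), rowSums(coords^2), "+") - 2 * pts %*% t(coords)
  r <- sqrt(pmax(d2, 0))
  if (min(r) < 0.5)
    stop("environment particle within 0.5 A of a site atom (overlap; ",
         "is the site's own charge set excluded?)")
  inv <- quad_constants$k_coulomb / r        # atoms x particles
  per_particle <- colMeans(inv)              # mean over site atoms
  phi_comp <- vapply(split(per_particle * q, comp), sum, numeric(1))
  structure(list(site = lbl, phi_total = sum(per_particle * q),
                 phi_by_component = phi_comp),
            class = "potential_record")
}

#' Per-frame potential difference between oxidized and neutral indoles
#'
#' Delta-phi = phi(oxidized indole) - phi(neutral indole_i), per frame, with
#' summary statistics. Positive values favor transfer toward indole_i (a
#' larger driving force). Both inputs must be per-frame potential vectors
#' computed with the same environment-exclusion convention (canonically:
#' everything except the oxidized indole).
#'
#' @param records_oxidized,records_neutral numeric vectors of per-frame
#'   potentials (V), or lists of `potential_record`s.
#' @return list with `delta` (per-frame, V), `summary` (mean, median, q25,
#'   q75).
#' @export
delta_phi <- function(records_oxidized, records_neutral) {
  as_phi <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, function(r) r$phi_total, numeric(1))
  }
  a <- as_phi(records_oxidized); b <- as_phi(records_neutral)
  if (length(a) != length(b))
    stop("frame mismatch between oxidized and neutral potential records")
  d <- a - b
  list(delta = d,
       summary = c(mean = mean(d), median = median(d),
                   q25 = unname(quantile(d, 0.25)),
                   q75 = unname(quantile(d, 0.75))))
}

#' Linear-response reaction free energy and reorganization energy
#'
#' Two-ensemble linear-response (Marcus-picture) estimator from vertical
#' energy gaps dE = E(product) - E(reactant) sampled in the reactant (A)
#' and product (B) ensembles:
#' dG = (⟨dE⟩_A + ⟨dE⟩_B) / 2, lambda = (⟨dE⟩_A - ⟨dE⟩_B) / 2.
#' Uncertainty is estimated by block bootstrap (serial correlation safe).
#'
#' @param gaps_A,gaps_B [gap_samples()] (or bare numeric vectors) for the
#'   two endpoint ensembles.
#' @param n_boot bootstrap replicates (default 200).
#' @param block_frac block length as a fraction of the series (default
#'   0.05).
#' @param conf confidence level for the reported interval.
#' @param kT thermal energy (meV), carried through to the result.
#' @return a `free_energy_result`: list with `dG`, `lambda_est` (meV),
#'   `dG_se`, `dG_ci`, `lambda_se`, `n_A`, `n_B`, `kT`, `warning`.
#'   A non-positive lambda estimate flags inconsistent ensembles (warning
#'   recorded, result still returned).
#' @export
linear_response_dG <- function(gaps_A, gaps_B, n_boot = 200,
                               block_frac = 0.05, conf = 0.95,
                               kT = kT_meV()) {
  va <- if (inherits(gaps_A, "gap_samples")) gaps_A$values else
    as.numeric(gaps_A)
  vb <- if (inherits(gaps_B, "gap_samples")) gaps_B$values else
    as.numeric(gaps_B)
  if (length(va) == 0 || length(vb) == 0) stop("empty gap ensemble")
  est <- function(a, b) c(dG = (mean(a) + mean(b)) / 2,
                          lambda = (mean(a) - mean(b)) / 2)
  e0 <- est(va, vb)
  block_boot <- function(v) {
    L <- max(1L, round(length(v) * block_frac))
    nb <- ceiling(length(v) / L)
    starts <- sample.int(length(v) - L + 1L, nb, replace = TRUE)
    idx <- as.vector(outer(0:(L - 1L), starts, "+"))[seq_along(v)]
    v[idx]
  }
  boots <- t(vapply(seq_len(n_boot), function(i)
    est(block_boot(va), block_boot(vb)), numeric(2)))
  alpha <- (1 - conf) / 2
  warn <- if (e0["lambda"] <= 0)
    "non-positive reorganization energy: inconsistent ensembles" else NULL
  if (!is.null(warn)) warning(warn)
  structure(list(
    dG = unname(e0["dG"]), lambda_est = unname(e0["lambda"]),
    dG_se = sd(boots[, "dG"]), lambda_se = sd(boots[, "lambda"]),
    dG_ci = unname(quantile(boots[, "dG"], c(alpha, 1 - alpha))),
    n_A = length(va), n_B = length(vb), kT = kT,
    estimator = "two-ensemble linear response", warning = warn),
    class = "free_energy_result")
}

#' Node free energies from a step table (least-squares potential)
#'
#' An ensemble-derived step table need not close around cycles; this
#' extracts the best-fitting node potential G (minimizing the squared
#' mismatch G_j - G_i - dG(i->j) over all directed entries), i.e. the
#' gradient part of the table with the circulating part removed. For the
#' reference table the ranking is 122D < 124A < 122A < 124D - the
#' thermodynamic ordering of the four hole states.
#'
#' @param dg 4 x 4 antisymmetric step matrix (meV) with site dimnames.
#' @param reference site whose free energy is pinned to 0.
#' @return named vector of free energies (meV).
#' @export
node_free_energies <- function(dg, reference = "124A") {
  m <- dg[QUAD_SITES, QUAD_SITES]
  m[is.na(m)] <- 0
  # least-squares solution for antisymmetric input: column means
  g <- colMeans(m)
  g - g[reference]
}

#' Assemble and audit a 4 x 4 step free-energy table
#'
#' Builds the antisymmetric step matrix over the four quadruplex sites from
#' directed results and checks (a) antisymmetry dG(i->j) = -dG(j->i) and
#' (b) cycle closure: dG summed around every directed 3-site cycle. Residuals
#' are reported, not judged: ensemble-derived tables close only
#' approximately.
#'
#' @param results either a list of `free_energy_result`-like lists each with
#'   `from`, `to`, `dG`, or a 4 x 4 numeric matrix with site dimnames.
#' @param tol_antisym tolerance for the antisymmetry flag (meV).
#' @return list with `table` (4 x 4 matrix, NA diagonal/missing),
#'   `antisymmetric` (logical), `antisym_residuals`, `cycles` (data.frame
#'   of 3-cycles and residuals).
#' @export
dg_table <- function(results, tol_antisym = 1e-9) {
  m <- matrix(NA_real_, 4, 4, dimnames = list(QUAD_SITES, QUAD_SITES))
  if (is.matrix(results)) {
    m[rownames(results), colnames(results)] <- results
    diag(m) <- NA
  } else {
    if (length(results) == 0) stop("no free-energy results supplied")
    for (r in results) {
      if (!is.na(m[r$from, r$to]) && abs(m[r$from, r$to] - r$dG) > 1e-9)
        stop("conflicting duplicate entry for ", r$from, " -> ", r$to)
      m[r$from, r$to] <- r$dG
    }
  }
  anti <- m + t(m)
  have <- !is.na(anti)
  res_anti <- data.frame(
    pair = character(0), residual = numeric(0))
  for (i in 1:3) for (j in (i + 1):4) {
    if (have[i, j])
      res_anti <- rbind(res_anti, data.frame(
        pair = paste(QUAD_SITES[i], QUAD_SITES[j], sep = "-"),
        residual = anti[i, j]))
  }
  cyc <- utils::combn(4, 3)
  cycles <- do.call(rbind, lapply(seq_len(ncol(cyc)), function(k) {
    i <- cyc[1, k]; j <- cyc[2, k]; l <- cyc[3, k]
    r <- m[i, j] + m[j, l] + m[l, i]
    data.frame(cycle = paste(QUAD_SITES[c(i, j, l, i)], collapse = "->"),
               residual = r)
  }))
  list(table = m,
       antisymmetric = all(abs(res_anti$residual) <= tol_antisym,
                           na.rm = TRUE),
       antisym_residuals = res_anti,
       cycles = cycles)
}
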