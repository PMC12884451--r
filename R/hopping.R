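# Four-site hole-transfer network: nonadiabatic Marcus rates, the
# feasibility graph under thermodynamic and kinetic thresholds,
# master-equation population dynamics, and an adiabaticity diagnostic.

#' Nonadiabatic Marcus rate
#'
#' k = (2 pi / hbar) H_ab^2 (4 pi lambda kT)^(-1/2)
#'     exp(-(dG + lambda)^2 / (4 lambda kT)),
#' with all energies in meV and the result in 1/s. At dG = -lambda the
#' exponent vanishes (activationless maximum).
#'
#' @param H_ab electronic coupling (meV), >= 0. Vectorized.
#' @param dG reaction free energy (meV).
#' @param lambda reorganization energy (meV), > 0.
#' @param T_K temperature (K), > 0.
#' @return rate in 1/s (0 when `H_ab` is 0).
#' @export
#' @examples
#' marcus_rate(31, -320, 800, 298)
marcus_rate <- function(H_ab, dG, lambda = 800, T_K = 298) {
  if (any(lambda <= 0)) stop("lambda must be positive")
  if (any(T_K <= 0)) stop("temperature must be positive")
  kT <- kT_meV(T_K)
  pref <- 2 * pi / quad_constants$hbar_meV_s
  pref * H_ab^2 / sqrt(4 * pi * lambda * kT) *
    exp(-(dG + lambda)^2 / (4 * lambda * kT))
}

#' Read a step table (free energies or couplings) from CSV
#'
#' Layout mirrors the published tables: a `from` column of oxidized-site
#' labels and one column per destination site (`124A`, `122A`, `122D`,
#' `124D`, optionally `ReA-`); empty cells on the diagonal.
#'
#' @param path CSV path.
#' @return numeric matrix with site dimnames (NA diagonal).
#' @export
read_step_table <- function(path) {
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("from" %in% names(d))
  m <- as.matrix(d[, setdiff(names(d), "from"), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- d$from
  m
}

#' Reference reaction free energies of the quadruplex steps (meV)
#'
#' The MM/MD-ensemble reaction free energies of the twelve directed
#' hole-transfer steps of the azurin-dimer tryptophan quadruplex, shipped
#' with the package as delimited text and used as the canonical worked
#' example.
#'
#' @return 4 x 4 numeric matrix (meV), NA diagonal.
#' @export
reference_dg_table <- function() {
  read_step_table(system.file("extdata", "dg_steps_mev.csv",
                              package = "quadhop", mustWork = TRUE))
}

#' Reference median electronic couplings of the quadruplex steps (meV)
#'
#' Median H_ab values for the directed steps, including the column toward
#' the reduced Re chromophore (`ReA-`).
#'
#' @param include_re keep the `ReA-` column (default FALSE).
#' @return numeric matrix (meV), NA diagonal.
#' @export
reference_coupling_table <- function(include_re = FALSE) {
  m <- read_step_table(system.file("extdata", "hab_median_mev.csv",
                                   package = "quadhop", mustWork = TRUE))
  if (!include_re) m <- m[, QUAD_SITES]
  m
}

#' Build the hole-hopping network with feasibility flags
#'
#' Constructs the directed 4-node network from a free-energy table and a
#' coupling table, flags each edge as thermodynamically feasible
#' (`dG < dG_max`, strict) and kinetically feasible (`H_ab > H_min`,
#' strict), and attaches Marcus rates. In symmetric-coupling mode the
#' geometric mean of the two directional couplings is used for both
#' directions, which makes detailed balance exact for an antisymmetric
#' free-energy table; in asymmetric mode the directional medians are used
#' and the detailed-balance residual is reported.
#'
#' @param dg 4 x 4 free-energy matrix (meV) with site dimnames.
#' @param hab 4 x 4 coupling matrix (meV).
#' @param dG_max thermodynamic threshold (meV); default +70 (the stricter
#'   of the two published presets; use `+100` for the permissive one).
#' @param H_min kinetic threshold (meV); default 0.2.
#' @param lambda reorganization energy (meV), default 800.
#' @param T_K temperature (K), default 298.
#' @param symmetric_coupling use the symmetrized coupling (default TRUE).
#' @return a `hop_network`: list with `edges` (data.frame: from, to, dG,
#'   H_ab, rate, feasible_thermo, feasible_kinetic, feasible), `lambda`,
#'   `T_K`, `kT`, `balance_residual` (max |log| deviation from detailed
#'   balance over edge pairs).
#' @export
feasibility_graph <- function(dg, hab, dG_max = 70, H_min = 0.2,
                              lambda = 800, T_K = 298,
                              symmetric_coupling = TRUE) {
  stopifnot(all(QUAD_SITES %in% rownames(dg)),
            all(QUAD_SITES %in% colnames(dg)))
  miss <- is.na(dg[QUAD_SITES, QUAD_SITES]) & !diag(4)
  if (any(miss)) stop("missing free-energy entries for pair(s): ",
                      paste(which(miss), collapse = ", "))
  if (!all(QUAD_SITES %in% rownames(hab)) ||
      any(is.na(hab[QUAD_SITES, QUAD_SITES]) & !diag(4)))
    stop("coupling table does not cover all ordered site pairs")
  dg <- dg[QUAD_SITES, QUAD_SITES]
  hab <- hab[QUAD_SITES, QUAD_SITES]
  h_use <- if (symmetric_coupling) sqrt(hab * t(hab)) else hab
  edges <- do.call(rbind, lapply(seq_len(4), function(i) {
    do.call(rbind, lapply(setdiff(seq_len(4), i), function(j) {
      data.frame(from = QUAD_SITES[i], to = QUAD_SITES[j],
                 dG = dg[i, j], H_ab = h_use[i, j],
                 H_ab_directional = hab[i, j])
    }))
  }))
  edges$rate <- marcus_rate(edges$H_ab, edges$dG, lambda, T_K)
  edges$feasible_thermo <- edges$dG < dG_max
  edges$feasible_kinetic <- edges$H_ab_directional > H_min
  edges$feasible <- edges$feasible_thermo & edges$feasible_kinetic
  kT <- kT_meV(T_K)
  lr <- vapply(seq_len(nrow(edges)), function(k) {
    rev <- which(edges$from == edges$to[k] & edges$to == edges$from[k])
    if (edges$rate[k] <= 0 || edges$rate[rev] <= 0) return(NA_real_)
    log(edges$rate[k] / edges$rate[rev]) - (-edges$dG[k] / kT)
  }, numeric(1))
  structure(list(edges = edges, lambda = lambda, T_K = T_K, kT = kT,
                 dG_max = dG_max, H_min = H_min,
                 symmetric_coupling = symmetric_coupling,
                 balance_residual = if (all(is.na(lr))) NA_real_
                                    else max(abs(lr), na.rm = TRUE)),
            class = "hop_network")
}

#' Terminal states of the feasible sub-network
#'
#' Nodes belonging to terminal (no-outgoing-edge) strongly connected
#' components of the feasible edge set: every feasible directed path
#' eventually ends in one of these.
#'
#' @param network a `hop_network`.
#' @return character vector of site labels.
#' @export
terminal_states <- function(network) {
  fe <- network$edges[network$edges$feasible, c("from", "to")]
  g <- igraph::graph_from_data_frame(
    fe, directed = TRUE,
    vertices = data.frame(name = QUAD_SITES))
  sc <- igraph::components(g, mode = "strong")
  cond <- igraph::contract(g, sc$membership)
  cond <- igraph::simplify(cond)
  outdeg <- igraph::degree(cond, mode = "out")
  terminal_comps <- which(outdeg == 0)
  QUAD_SITES[sc$membership %in% terminal_comps]
}

#' Master-equation population dynamics on the hopping network
#'
#' Solves dp/dt = K p with K[j, i] = rate(i -> j) for i != j and columns
#' summing to zero (population conserving). Propagation uses the matrix
#' exponential via eigen-decomposition (with a scaling-and-squaring series
#' fallback for defective K); the stationary distribution comes from the
#' null space of K with a residual check.
#'
#' @param network a `hop_network` (all 12 directed rates are used,
#'   regardless of feasibility flags, unless `feasible_only = TRUE`).
#' @param p0 initial distribution over the four sites (named or in site
#'   order); must sum to 1 within 1e-9.
#' @param t_grid times (s) at which to report populations.
#' @param feasible_only zero the rates of infeasible edges.
#' @return list with `times`, `p` (length(t_grid) x 4 matrix),
#'   `stationary` (named), `stationary_residual` (max |K p_st|), `K`.
#' @export
master_equation <- function(network, p0, t_grid = 10^seq(-14, -8, by = 1),
                            feasible_only = FALSE) {
  if (is.null(names(p0))) names(p0) <- QUAD_SITES
  p0 <- p0[QUAD_SITES]
  if (abs(sum(p0) - 1) > 1e-9)
    stop("p0 must be normalized (sums to ", format(sum(p0)), ")")
  ed <- network$edges
  if (feasible_only) ed$rate[!ed$feasible] <- 0
  K <- matrix(0, 4, 4, dimnames = list(QUAD_SITES, QUAD_SITES))
  for (k in seq_len(nrow(ed))) K[ed$to[k], ed$from[k]] <- ed$rate[k]
  diag(K) <- -colSums(K)
  if (!all(is.finite(K))) stop("non-finite rates in the network")
  p <- t(vapply(t_grid, function(t) as.numeric(expm_mult(K * t, p0)),
                numeric(4)))
  colnames(p) <- QUAD_SITES
  stationary <- stationary_state(K, p0)
  resid <- max(abs(K %*% stationary))
  scale <- max(abs(K))
  if (scale > 0 && resid / scale > 1e-10)
    warning("stationary-state residual ", format(resid / scale),
            " exceeds 1e-10 (relative)")
  list(times = t_grid, p = p, stationary = stationary,
       stationary_residual = resid, K = K)
}

# Stationary distribution of a rate matrix. For an irreducible network the
# null vector is obtained from a bordered linear solve (replace one balance
# equation with the normalization), which resolves populations down to the
# ~1e-9 Boltzmann weights of strongly uphill states; for reducible networks
# (zero-rate edges) the long-time limit of p(t) from p0 is used instead.
stationary_state <- function(K, p0) {
  st <- tryCatch({
    A <- rbind(K[-1, , drop = FALSE], rep(1, ncol(K)))
    x <- solve(A, c(rep(0, nrow(K) - 1), 1))
    if (any(x < -1e-9)) stop("negative population")
    x
  }, error = function(e) NULL)
  if (is.null(st)) {
    ev <- eigen(K, only.values = TRUE)$values
    nz <- abs(Re(ev))[abs(Re(ev)) > 1e-6 * max(abs(Re(ev)), 1e-300)]
    if (length(nz) == 0) {
      st <- as.numeric(p0)
    } else {
      t_inf <- 50 / min(nz)
      st <- as.numeric(expm_mult(K * t_inf, p0))
    }
  }
  st <- pmax(st, 0)
  st <- st / sum(st)
  names(st) <- rownames(K)
  st
}

# exp(A) %*% v by eigen-decomposition, falling back to scaling and
# squaring of the truncated series when A is (near-)defective.
expm_mult <- function(A, v) {
  eg <- tryCatch(eigen(A), error = function(e) NULL)
  if (!is.null(eg) && abs(det(eg$vectors)) > 1e-12) {
    co <- solve(eg$vectors, v)
    out <- Re(eg$vectors %*% (exp(eg$values) * co))
    return(pmax(out, 0) / sum(pmax(out, 0)) * sum(v))
  }
  expm_series(A) %*% v
}

expm_series <- function(A) {
  nrm <- max(abs(A))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^s
  X <- diag(nrow(A)); term <- diag(nrow(A))
  for (k in 1:20) {
    term <- term %*% As / k
    X <- X + term
  }
  for (i in seq_len(s)) X <- X %*% X
  X
}

#' Landau-Zener-type adiabaticity index
#'
#' kappa = 2 pi H_ab^2 / (hbar nu_eff sqrt(4 pi lambda kT)); transfer is
#' classified adiabatic when kappa >= 1. This is the Marcus rate divided by
#' the effective nuclear attempt frequency at zero activation energy - a
#' package convention for the usual "is the electronic transition faster
#' than nuclear motion" diagnostic.
#'
#' @param H_ab electronic coupling (meV), > 0.
#' @param lambda reorganization energy (meV), > 0; default 800.
#' @param nu_eff_inv inverse effective nuclear frequency (fs), > 0; the
#'   published assumption is > 100 fs.
#' @param T_K temperature (K).
#' @return list with `kappa` and `classification`
#'   (`"adiabatic"`/`"nonadiabatic"`).
#' @export
adiabaticity_index <- function(H_ab, lambda = 800, nu_eff_inv = 100,
                               T_K = 298) {
  stopifnot(H_ab >= 0, lambda > 0, nu_eff_inv > 0, T_K > 0)
  kT <- kT_meV(T_K)
  nu_eff <- 1 / (nu_eff_inv * 1e-15)  # 1/s
  kappa <- 2 * pi * H_ab^2 /
    (quad_constants$hbar_meV_s * nu_eff * sqrt(4 * pi * lambda * kT))
  list(kappa = kappa,
       classification = ifelse(kappa >= 1, "adiabatic", "nonadiabatic"))
}

#' Export a hopping network as DOT graph text
#'
#' @param network a `hop_network`.
#' @param path output path; NULL returns the text.
#' @param feasible_only draw only feasible edges.
#' @return the DOT text, invisibly when written to file.
#' @export
network_dot <- function(network, path = NULL, feasible_only = TRUE) {
  ed <- network$edges
  if (feasible_only) ed <- ed[ed$feasible, ]
  lines <- c("digraph hopnet {",
             sprintf('  "%s";', QUAD_SITES),
             sprintf('  "%s" -> "%s" [label="%g meV"];',
                     ed$from, ed$to, ed$dG),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
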