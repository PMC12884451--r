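# Tryptophan-cluster mining: planted recovery, oracle equivalence,
# monotone coarsening, the tight-quadruplex rule, census counting and
# cofactor proximity.

test_that("planted single-chain and cross-chain clusters are recovered", {
  st <- gen_planted_pdb(list(list(chain = "A", n_trp = 4,
                                  pairwise_distance = 6)), seed = 1)
  cl <- find_clusters(st)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 4)
  expect_equal(cl[[1]]$classification, "intramolecular")
  expect_false(cl[[1]]$dimer_link)
  expect_false(cl[[1]]$tight_quadruplex)  # 6 A spacing is not "all < 5 A"
  expect_true(all(cl[[1]]$pairwise_min_distances[
    upper.tri(cl[[1]]$pairwise_min_distances)] >= 6 - 0.06))

  # an all-short quadruplex (every pair < 5 A) is tight
  tight_quad <- gen_quadruplex(quad_spec(side_AA = 3.6, side_DD = 3.6,
                                         edge_AD = 3.7, edge_DA = 3.7,
                                         diag_short = 3.7,
                                         diag_long = 4.6), seed = 30)
  cl_t <- find_clusters(tight_quad)
  expect_true(cl_t[[1]]$tight_quadruplex)

  st2 <- gen_planted_pdb(list(
    list(chain = "A", n_trp = 2, pairwise_distance = 6, group = 1),
    list(chain = "B", n_trp = 2, pairwise_distance = 6, group = 1)),
    decoys = 3, seed = 2)
  cl2 <- find_clusters(st2)
  expect_length(cl2, 1)
  expect_equal(cl2[[1]]$size, 4)
  expect_equal(cl2[[1]]$classification, "interfacial")
  expect_true(cl2[[1]]$dimer_link)
  expect_setequal(cl2[[1]]$span_chains, c("A", "B"))
  expect_length(attr(cl2, "singletons"), 3)
})

test_that("components match a brute-force union-find over the distance
           matrix", {
  for (seed in c(3, 4, 5)) {
    st <- gen_random_trp_structure(n_trp = 18, box = 45, seed = seed)
    cl <- find_clusters(st, link_cutoff = 10, min_size = 2)
    ind <- quadhop:::trp_indoles(st)
    n <- length(ind)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j)
        adj[i, j] <- brute_min_distance(ind[[i]], ind[[j]]) <= 10
    }
    comp <- union_find_components(adj)
    sizes_oracle <- sort(unname(table(comp)[table(comp) >= 2]))
    sizes_pkg <- sort(vapply(cl, function(c) c$size, numeric(1)))
    expect_equal(as.integer(sizes_pkg), as.integer(sizes_oracle))
    # membership agreement, not just sizes
    key <- vapply(ind, function(m)
      paste0(attr(m, "chain"), attr(m, "resno")), character(1))
    oracle_sets <- lapply(split(key, comp), sort)
    oracle_sets <- Filter(function(s) length(s) >= 2, oracle_sets)
    pkg_sets <- lapply(cl, function(c)
      sort(paste0(c$members$chain, c$members$resno)))
    expect_setequal(vapply(pkg_sets, paste, character(1), collapse = ","),
                    vapply(oracle_sets, paste, character(1),
                           collapse = ","))
  }
})

test_that("raising the linkage cutoff never shrinks clusters", {
  st <- gen_random_trp_structure(n_trp = 15, box = 40, seed = 6)
  for (pair in list(c(6, 10), c(10, 14))) {
    cl_small <- find_clusters(st, link_cutoff = pair[1])
    cl_big <- find_clusters(st, link_cutoff = pair[2])
    # every small-cutoff cluster is contained in one big-cutoff cluster
    big_sets <- lapply(cl_big, function(c)
      paste0(c$members$chain, c$members$resno))
    for (c in cl_small) {
      mem <- paste0(c$members$chain, c$members$resno)
      expect_true(any(vapply(big_sets, function(b) all(mem %in% b),
                             logical(1))))
    }
  }
})

test_that("clustering is invariant to rigid motion", {
  st <- gen_random_trp_structure(n_trp = 12, box = 35, seed = 7)
  cl0 <- find_clusters(st)
  set.seed(8)
  st2 <- transform_atoms(st, random_rigid())
  cl1 <- find_clusters(st2)
  expect_equal(vapply(cl1, function(c) c$size, numeric(1)),
               vapply(cl0, function(c) c$size, numeric(1)))
})

test_that("the tight-quadruplex rule is strict at 5 A", {
  # the crystal-interface geometry: all pairs short except the 5.4 A
  # long diagonal -> not a tight quadruplex, that pair reported
  fr <- attr(fixture_quad(), "frame")
  atoms <- fixture_quad()
  cl <- find_clusters(atoms)[[1]]
  expect_equal(cl$size, 4)
  chk <- tight_quadruplex_check(cl)
  expect_false(chk$tight)
  expect_equal(nrow(chk$failing_pairs), 1L)
  expect_equal(chk$failing_pairs$distance, 5.4, tolerance = 0.05)
  # an infinite cutoff always passes; wrong size is rejected
  expect_true(tight_quadruplex_check(cl, cutoff = Inf)$tight)
  small <- cl; small$size <- 3
  expect_error(tight_quadruplex_check(small), "size 4")
})

test_that("size census splits the 4-Trp bin by class and dimer flag", {
  st_a <- gen_planted_pdb(list(list(chain = "A", n_trp = 4,
                                    pairwise_distance = 6)), seed = 9)
  st_b <- gen_planted_pdb(list(
    list(chain = "A", n_trp = 2, pairwise_distance = 6, group = 1),
    list(chain = "B", n_trp = 2, pairwise_distance = 6, group = 1)),
    seed = 10)
  st_c <- gen_planted_pdb(list(list(chain = "C", n_trp = 3,
                                    pairwise_distance = 7)), seed = 11)
  cl <- c(find_clusters(st_a, structure_id = "s1"),
          find_clusters(st_b, structure_id = "s2"),
          find_clusters(st_c, structure_id = "s3"))
  cen <- size_distribution(cl)
  expect_equal(cen$histogram$n_clusters[cen$histogram$size == 4], 2)
  expect_equal(cen$size4$intramolecular, 1)
  expect_equal(cen$size4$interfacial, 1)
  expect_equal(cen$size4$dimers, 1)
  expect_equal(cen$histogram$n_clusters[cen$histogram$size == 3], 1)
  # one structure with two disjoint 4-clusters counts twice per cluster,
  # once per id
  st_d <- gen_planted_pdb(list(
    list(chain = "A", n_trp = 4, pairwise_distance = 6),
    list(chain = "A", n_trp = 4, pairwise_distance = 6)), seed = 12)
  cl_d <- find_clusters(st_d, structure_id = "s4")
  cen_d <- size_distribution(cl_d)
  expect_equal(cen_d$histogram$n_clusters[cen_d$histogram$size == 4], 2)
  expect_equal(cen_d$histogram$n_structures[cen_d$histogram$size == 4], 1)
  # empty input
  cen0 <- size_distribution(list())
  expect_equal(nrow(cen0$histogram), 0L)
})

test_that("cofactor proximity matches planted distances and brute force", {
  st <- gen_planted_pdb(list(list(chain = "A", n_trp = 4,
                                  pairwise_distance = 6)),
                        cofactors = list(list(resname = "FAD",
                                              chain = "X",
                                              distance = 12)),
                        seed = 13)
  cl <- find_clusters(st)[[1]]
  cp <- cofactor_proximity(st, cl)
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$resname, "FAD")
  expect_equal(cp$d_min, 12, tolerance = 0.05)
  # brute-force check
  ind <- quadhop:::trp_indoles(st)
  cluster_xyz <- do.call(rbind, ind)
  fad <- as.matrix(st[st$resname == "FAD", c("x", "y", "z")])
  expect_equal(cp$d_min, brute_min_distance(cluster_xyz, fad),
               tolerance = 1e-9)
  # no het groups -> empty
  st0 <- gen_planted_pdb(list(list(chain = "A", n_trp = 2,
                                   pairwise_distance = 6)), seed = 14)
  cl0 <- find_clusters(st0)[[1]]
  expect_equal(nrow(cofactor_proximity(st0, cl0)), 0L)
})

test_that("directory mining honors an id list", {
  dir <- withr::local_tempdir()
  gen_planted_pdb(list(list(chain = "A", n_trp = 4,
                            pairwise_distance = 6)), seed = 15,
                  path = file.path(dir, "aaaa.cif"))
  gen_planted_pdb(list(list(chain = "A", n_trp = 3,
                            pairwise_distance = 6)), seed = 16,
                  path = file.path(dir, "bbbb.cif"))
  all_cl <- mine_structures(dir)
  expect_length(all_cl, 2)
  only_a <- mine_structures(dir, ids = "aaaa")
  expect_length(only_a, 1)
  expect_equal(only_a[[1]]$size, 4)
})
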