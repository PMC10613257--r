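test_that("hydrogen-bond detector applies the heavy-atom criterion", {
  two <- function(d) build_toy(rbind(
    atom_df(1, "GLY", "N", "N", 0, 0, 0),
    atom_df(1, "GLY", "CA", "C", 1.5, 0, 0),
    atom_df(5, "GLY", "O", "O", 0, d, 0)))
  e <- detect_hbonds(two(2.9))
  expect_equal(nrow(e), 1)
  expect_equal(e$distance, 2.9, tolerance = 1e-9)
  expect_match(e$detail, "bb")
  expect_equal(nrow(detect_hbonds(two(4.0))), 0)
})

test_that("adjacent-residue backbone contacts are not hydrogen bonds", {
  s <- build_toy(rbind(
    atom_df(1, "GLY", "O", "O", 0, 0, 0),
    atom_df(2, "SER", "N", "N", 2.9, 0, 0),     # i,i+1 backbone: excluded
    atom_df(2, "SER", "OG", "O", 0, 2.9, 0)))   # side chain: kept
  e <- detect_hbonds(s)
  expect_equal(nrow(e), 1)
  expect_match(e$detail, "OG")
})

test_that("hydrophobic detector uses apolar side-chain carbons only", {
  pair <- function(d, resn_b = "PRO", atom_b = "CG") build_toy(rbind(
    atom_df(1, "ALA", "CB", "C", 0, 0, 0),
    atom_df(5, resn_b, atom_b, "C", d, 0, 0)))
  expect_equal(nrow(detect_hydrophobic(pair(4.0))), 1)
  expect_equal(nrow(detect_hydrophobic(pair(5.0))), 0)
  # Ser side-chain carbons are not apolar; Lys CD is
  expect_equal(nrow(detect_hydrophobic(pair(4.0, "SER", "CB"))), 0)
  expect_equal(nrow(detect_hydrophobic(pair(4.0, "LYS", "CD"))), 1)
  expect_equal(nrow(detect_hydrophobic(pair(4.0, "LYS", "NZ"))), 0)
  # backbone carbons never count
  s <- build_toy(rbind(atom_df(1, "ALA", "CB", "C", 0, 0, 0),
                       atom_df(5, "LEU", "CA", "C", 4, 0, 0)))
  expect_equal(nrow(detect_hydrophobic(s)), 0)
})

test_that("sequence-adjacent residues never form hydrophobic edges", {
  s <- build_toy(rbind(atom_df(1, "ALA", "CB", "C", 0, 0, 0),
                       atom_df(2, "PRO", "CG", "C", 4, 0, 0)))
  expect_equal(nrow(detect_hydrophobic(s)), 0)
})

test_that("pi-pi detector measures ring centroid separation", {
  ring_df <- function(res, resn, cen) {
    ring <- RING_SETS[[resn]]
    th <- 2 * pi * (seq_along(ring) - 1) / length(ring)
    do.call(rbind, lapply(seq_along(ring), function(q) {
      atom_df(res, resn, ring[q], substr(ring[q], 1, 1),
              cen[1] + 1.39 * cos(th[q]), cen[2] + 1.39 * sin(th[q]), cen[3])
    }))
  }
  stack <- function(dz) build_toy(rbind(ring_df(1, "PHE", c(0, 0, 0)),
                                        ring_df(5, "PHE", c(0, 0, dz))))
  e <- detect_pipi(stack(4.0))
  expect_equal(nrow(e), 1)
  expect_equal(e$distance, 4.0, tolerance = 1e-9)
  expect_equal(e$angle, 0, tolerance = 1e-6)  # parallel planes
  expect_equal(nrow(detect_pipi(stack(7.5))), 0)
  # an incomplete ring has no usable centroid
  broken <- build_toy(rbind(ring_df(1, "PHE", c(0, 0, 0)),
                            ring_df(5, "PHE", c(0, 0, 4))[1:3, ]))
  expect_equal(nrow(detect_pipi(broken)), 0)
})

test_that("all detectors equal their all-pairs oracles on random structures", {
  for (seed in 1:10) {
    s <- random_toy_structure(n_res = 20, seed = seed)
    expect_identical(edge_key(detect_hbonds(s)), edge_key(oracle_hbonds(s)),
                     label = paste("hbond seed", seed))
    expect_identical(edge_key(detect_hydrophobic(s)),
                     edge_key(oracle_hydrophobic(s)),
                     label = paste("hydrophobic seed", seed))
    expect_identical(edge_key(detect_pipi(s)), edge_key(oracle_pipi(s)),
                     label = paste("pipi seed", seed))
  }
})

test_that("edge sets are invariant under rigid motion and monotone in cutoffs", {
  set.seed(42)
  for (seed in 1:5) {
    s <- random_toy_structure(n_res = 20, seed = seed)
    ref <- edge_key(detect_hbonds(s))
    tr <- random_rigid()
    expect_identical(edge_key(detect_hbonds(transform_structure(s, tr$R, tr$t))),
                     ref, label = paste("rigid seed", seed))
    # monotone: smaller cutoff yields a subset
    for (f in list(detect_hbonds, detect_hydrophobic, detect_pipi)) {
      lo <- edge_key(f(s, 3.0))
      hi <- edge_key(f(s, 5.0))
      expect_true(all(sub("[0-9.]+$", "", lo) %in% sub("[0-9.]+$", "", hi)))
    }
  }
})

test_that("build_graph merges duplicates and keeps typed edges", {
  # two residues linked by two separate N/O atom pairs: one merged hbond edge
  s <- build_toy(rbind(
    atom_df(1, "ASN", "OD1", "O", 0, 0, 0),
    atom_df(1, "ASN", "ND2", "N", 0, 2.0, 0),
    atom_df(5, "SER", "OG", "O", 2.9, 0, 0),
    atom_df(5, "SER", "N", "N", 2.9, 2.0, 0)))
  expect_gte(nrow(detect_hbonds(s)), 2)
  g <- build_graph(s, include_zinc = FALSE)
  hb <- g$edges[g$edges$kind == "hbond" & g$edges$res_a == "1" &
                  g$edges$res_b == "5", ]
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)  # shortest kept
})

test_that("a contact-free structure yields nodes but no edges", {
  s <- build_toy(rbind(atom_df(1, "GLY", "CA", "C", 0, 0, 0),
                       atom_df(2, "GLY", "CA", "C", 50, 0, 0)))
  g <- build_graph(s, include_zinc = FALSE)
  expect_equal(length(g$nodes), 2)
  expect_equal(nrow(g$edges), 0)
  p <- shortest_path(g, 1, 2)
  expect_false(p$found)
  expect_error(shortest_path(g, 77, 2), "not in graph")
})

test_that("the planted path is recovered exactly on the synthetic enzyme", {
  gen <- make_enzyme(enzyme_spec(seed = 2))
  g <- build_graph(gen$structure)
  # the graph's residue-residue edges are exactly the planted ones
  rr <- g$edges[g$edges$kind != "metal", ]
  expect_identical(
    sort(paste(rr$res_a, rr$res_b, rr$kind)),
    sort(paste(gen$truth$planted_edges$res_a, gen$truth$planted_edges$res_b,
               gen$truth$planted_edges$kind)))
  p <- shortest_path(g, gen$truth$path_nodes[1])
  expect_true(p$found)
  expect_identical(p$path, gen$truth$path_nodes)
  expect_equal(p$n_hops, length(gen$truth$path_nodes) - 1)
})

test_that("equal-length paths break ties lexicographically", {
  g <- structure(list(
    nodes = c("1", "2", "3", "4"),
    edges = data.frame(res_a = c("1", "1", "2", "3"),
                       res_b = c("2", "3", "4", "4"),
                       kind = "hbond", distance = 3.0, detail = "",
                       angle = NA_real_, stringsAsFactors = FALSE),
    chain = "A", zinc_site = NULL,
    cutoffs = c(hbond = 3.5, hydrophobic = 4.5, pipi = 6, coordination = 2.8)),
    class = "interaction_graph")
  p <- shortest_path(g, "1", "4")
  # enumerate every simple path with igraph as the oracle
  ig <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = FALSE)
  all_p <- igraph::all_simple_paths(ig, "1", "4")
  lens <- vapply(all_p, length, integer(1))
  shortest <- lapply(all_p[lens == min(lens)],
                     function(v) names(igraph::V(ig))[as.integer(v)])
  keys <- vapply(shortest, paste, character(1), collapse = ",")
  expect_identical(paste(p$path, collapse = ","), min(keys))
})

test_that("distance_to_node measures atom-to-point separations", {
  s <- build_toy(rbind(atom_df(799, "ALA", "CA", "C", 26.1, 0, 0)))
  expect_equal(distance_to_node(s, 799, "CA", c(0, 0, 0)), 26.1)
  expect_equal(distance_to_node(s, 799, "CA", c(26.1, 0, 0)), 0)
  expect_error(distance_to_node(s, 799, "CB", c(0, 0, 0)), "not found")
})

test_that("the distal site sits across the planted path from the zinc", {
  gen <- make_enzyme(enzyme_spec(seed = 3))
  d <- distance_to_node(gen$structure, as.integer(gen$truth$path_nodes[1]),
                        "CA", gen$truth$zinc_coord)
  expect_gt(d, 26)  # distal means distal
})
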