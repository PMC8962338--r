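test_that("bond adjacency matrix has the line-graph structure and weights", {
  expect_equal(bond_adjacency(parse_smiles("CC"), "none"),
               matrix(0, 1, 1))
  expect_equal(bond_adjacency(parse_smiles("CCC"), "none"),
               matrix(c(0, 1, 1, 0), 2, 2))
  # CCO weighted by atomic weight: w = p_i/d_i + p_j/d_j
  g <- parse_smiles("CCO")
  aw <- assign_properties(g, "Ato")
  B <- bond_adjacency(g, "Ato")
  expect_equal(diag(B), c(aw[1] / 1 + aw[2] / 2, aw[2] / 2 + aw[3] / 1))
  expect_true(isSymmetric(B))
  expect_error(bond_adjacency(g, "Nope"))
})

test_that("spectral moments match trivial closed forms", {
  g <- parse_smiles("CCC")
  B <- bond_adjacency(g, "none")
  expect_equal(spectral_moment(B, 0), 2)
  expect_equal(spectral_moment(B, 2), 2)
  # single weighted bond: first moment is the bond weight
  g2 <- parse_smiles("CC")
  B2 <- bond_adjacency(g2, "Ato")
  expect_equal(spectral_moment(B2, 1), diag(B2)[1])
})

test_that("spectral moments equal naive closed-walk sums (oracle)", {
  for (smi in oracle_panel()) {
    g <- parse_smiles(smi)
    for (prop in c("none", "Ato")) {
      B <- bond_adjacency(g, prop)
      for (k in 0:6) {
        expect_equal(spectral_moment(B, k), oracle_closed_walks(B, k),
                     tolerance = 1e-9, info = paste(smi, prop, k))
      }
    }
  }
})

test_that("subgraph enumeration is exact and correctly classified", {
  expect_length(enumerate_subgraphs(parse_smiles("CCCC"), "P", 2), 2L)
  expect_length(enumerate_subgraphs(parse_smiles("C1CCCCC1"), "Ch", 6), 1L)
  # neopentane: four ways to pick 3 of the 4 star edges, all clusters
  neo <- parse_smiles("CC(C)(C)C")
  expect_length(enumerate_subgraphs(neo, "C", 3), 4L)
  expect_length(enumerate_subgraphs(neo, "P", 3), 0L)
  # counts match the brute-force subset oracle across the panel
  for (smi in oracle_panel()) {
    g <- parse_smiles(smi)
    for (o in 1:5) {
      mine <- enumerate_subgraphs(g, "all", o)
      theirs <- oracle_edge_subsets(g$bonds, o)
      expect_equal(length(mine), length(theirs), info = paste(smi, o))
      expect_setequal(vapply(mine, function(x) paste(sort(x), collapse = ","), ""),
                      vapply(theirs, function(x) paste(x, collapse = ","), ""))
    }
  }
})

test_that("connectivity indices reproduce hand values", {
  expect_equal(connectivity_index(parse_smiles("CC"), "P", 1), 1.0)
  expect_equal(connectivity_index(parse_smiles("CCCC"), "P", 1),
               2 / sqrt(2) + 0.5, tolerance = 1e-12)
  expect_equal(connectivity_index(parse_smiles("C1CCCCC1"), "Ch", 6), 0.125)
  # neopentane third-order cluster: 4 stars, each (4*1*1*1)^(-1/2)
  expect_equal(connectivity_index(parse_smiles("CC(C)(C)C"), "C", 3), 2.0)
})

test_that("connectivity indices agree with the brute-force oracle", {
  for (smi in oracle_panel()) {
    g <- parse_smiles(smi)
    dv <- ptml:::valence_delta(g)
    for (o in 1:6) {
      for (s in c("P", "C", "PC", "Ch")) {
        expect_equal(connectivity_index(g, s, o, "simple"),
                     oracle_connectivity(g, s, o, g$degree),
                     tolerance = 1e-9, info = paste(smi, s, o, "simple"))
        expect_equal(connectivity_index(g, s, o, "valence"),
                     oracle_connectivity(g, s, o, dv),
                     tolerance = 1e-9, info = paste(smi, s, o, "valence"))
      }
    }
  }
})

test_that("edge connectivity indices match hand values and the oracle", {
  expect_equal(edge_connectivity_index(parse_smiles("CCC"), "P", 1), 1.0)
  expect_equal(edge_connectivity_index(parse_smiles("CCCC"), "P", 1),
               sqrt(2), tolerance = 1e-12)
  expect_equal(edge_connectivity_index(parse_smiles("c1ccccc1"), "Ch", 6),
               0.125)
  # a single-bond molecule has an edgeless line graph
  expect_equal(edge_connectivity_index(parse_smiles("CC"), "P", 1), 0)
  for (smi in oracle_panel()) {
    g <- parse_smiles(smi)
    for (o in 1:5) {
      for (s in c("P", "C", "PC", "Ch")) {
        expect_equal(edge_connectivity_index(g, s, o),
                     oracle_edge_connectivity(g, s, o),
                     tolerance = 1e-9, info = paste(smi, s, o))
      }
    }
  }
})

test_that("subgraph types partition all connected subgraphs at fixed order", {
  for (smi in c("CC(C)CC1CCC1C", "Cc1ccccc1CC(C)O")) {
    g <- parse_smiles(smi)
    for (o in 2:5) {
      all_idx <- sum(vapply(enumerate_subgraphs(g, "all", o), function(bi) {
        atoms <- unique(as.vector(g$bonds[bi, c("i", "j")]))
        prod(g$degree[atoms])^(-0.5)
      }, numeric(1)))
      by_type <- sum(vapply(c("P", "C", "PC", "Ch"), function(s) {
        connectivity_index(g, s, o)
      }, numeric(1)))
      expect_equal(by_type, all_idx, tolerance = 1e-12, info = paste(smi, o))
    }
  }
})

test_that("indices are invariant under atom relabeling", {
  pairs <- list(c("CCO", "OCC"), c("CC(C)C", "C(C)(C)C"),
                c("Cc1ccccc1", "c1ccccc1C"), c("CCN(C)C", "N(C)(C)CC"))
  specs <- c("X(P)2", "Xv(P)1", "e(P)2", "NSM(Ato)3", "SM(Hyd)2")
  for (p in pairs) {
    v1 <- compute_descriptors(p[1], specs)
    v2 <- compute_descriptors(p[2], specs)
    expect_equal(unname(v1), unname(v2), tolerance = 1e-12,
                 info = paste(p, collapse = " vs "))
  }
})

test_that("pendant atoms only add first-order path subgraphs", {
  chain <- c("CC", "CCC", "CCCC", "CCCCC")
  counts <- vapply(chain, function(s) {
    length(enumerate_subgraphs(parse_smiles(s), "P", 1))
  }, integer(1))
  expect_true(all(diff(counts) > 0))
})

test_that("size normalization divides by nB and rejects nB = 0", {
  expect_equal(normalize_descriptor(10, 5), 2)
  expect_equal(normalize_descriptor(0, 7), 0)
  expect_error(normalize_descriptor(1, 0), "nB")
  b <- parse_smiles("CCCC")
  expect_equal(calc_descriptor(b, "NX(P)1"),
               connectivity_index(b, "P", 1) / 3)
})

test_that("the Model-1 block yields 15 finite values and honors its specs", {
  m1 <- model_descriptor_set(1)
  expect_equal(nrow(m1), 15L)
  v <- compute_descriptors("O=C(NCCO)Nc1ccc(Cl)cc1", m1$spec)
  expect_equal(ncol(v), 15L)
  expect_true(all(is.finite(v)))
  # a one-bond molecule: NSM(Hyd)1 is the Hyd bond weight over nB = 1
  g <- parse_smiles("CO")
  B <- bond_adjacency(g, "Hyd")
  expect_equal(calc_descriptor(g, "NSM(Hyd)1"), diag(B)[1])
})
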