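test_that("influence zones follow the decaying-spreading contract", {
  # two disconnected pairs: a seed's zone stays in its component
  net <- signaling_network(mk_edges(c("A", "C"), c("B", "D"),
                                    "undirected"))
  iz <- influence_zone(mk_weighted(net, c(1, 1)), "A")
  expect_equal(iz[["C"]], 0); expect_equal(iz[["D"]], 0)
  expect_gt(iz[["A"]], iz[["B"]])

  # symmetric star: equal influence at all leaves, seed maximal
  star <- signaling_network(mk_edges(rep("H", 4), paste0("L", 1:4),
                                     "undirected"))
  izs <- influence_zone(mk_weighted(star, rep(1, 4)), "H")
  expect_equal(length(unique(round(izs[paste0("L", 1:4)], 12))), 1)
  expect_equal(max(izs), izs[["H"]])

  # 5-node line graph vs independent linear-operator summation
  line <- signaling_network(mk_edges(paste0("n", 1:4), paste0("n", 2:5),
                                     "undirected"))
  wl <- mk_weighted(line, rep(1, 4))
  izl <- influence_zone(wl, "n1", lambda = 0.5)
  W <- matrix(0, 5, 5, dimnames = list(paste0("n", 1:5), paste0("n", 1:5)))
  for (k in 1:4) { W[k, k + 1] <- 1; W[k + 1, k] <- 1 }
  expect_equal(unname(izl), unname(operator_influence(W, 1, 0.5)),
               tolerance = 1e-5)

  # an isolated node's zone (and centrality) is itself alone
  Wi <- rbind(cbind(W, 0), 0)
  M <- oncorewire:::influence_matrix(Wi)
  expect_equal(unname(M[6, 6]), 1)
  expect_equal(sum(M[, 6]), 1)     # exerts nothing beyond itself
  expect_equal(sum(M[6, ]), 1)     # receives nothing: centrality 1
})

test_that("a clique is one module and a bridged barbell is recovered exactly", {
  k4 <- signaling_network(mk_clique(paste0("C", 1:4)))
  land <- detect_modules(mk_weighted(k4, rep(1, 6)))
  expect_equal(ncol(land$assignment), 1)
  expect_equal(unname(land$assignment[, 1]), rep(1, 4))

  bb <- mk_barbell()
  wbb <- mk_weighted(bb, c(rep(1, 20), 0.4))   # bridge <= half clique weight
  land2 <- detect_modules(wbb)
  da <- discrete_assignment(land2)
  expect_equal(ncol(land2$assignment), 2)
  expect_length(unique(da[paste0("A", 1:5)]), 1)
  expect_length(unique(da[paste0("B", 1:5)]), 1)
  expect_false(da[["A1"]] == da[["B1"]])
  # bridge endpoints belong non-trivially to both modules
  expect_true(all(land2$assignment["A1", ] > 0.01))
  expect_true(all(land2$assignment["B1", ] > 0.01))

  # planted-partition recovery across clique sizes
  for (k in 4:6) {
    a <- paste0("A", 1:k); b <- paste0("B", 1:k)
    net <- signaling_network(rbind(mk_clique(a), mk_clique(b),
                                   mk_edges("A1", "B1", "undirected")))
    w <- mk_weighted(net, c(rep(1, k * (k - 1)), 0.5))
    dak <- discrete_assignment(detect_modules(w))
    expect_length(unique(dak[a]), 1)
    expect_length(unique(dak[b]), 1)
    expect_false(dak[["A1"]] == dak[["B1"]])
  }
})

test_that("landscape invariants hold on random networks", {
  set.seed(41)
  for (rep in 1:5) {
    rw <- random_typed_network(sample(15:35, 1))
    land <- suppressWarnings(detect_modules(rw))
    A <- land$assignment
    expect_equal(unname(rowSums(A)), rep(1, nrow(A)), tolerance = 1e-9)
    expect_gte(ncol(A), 1)
    expect_true(all(A >= 0))
    da <- discrete_assignment(land)
    expect_setequal(unique(da), colnames(A))      # no empty module
    expect_true(all(land$centrality >= 0))
    # each module id is a node that discretely belongs to it
    for (m in colnames(A)) expect_equal(da[[m]], m)
  }
})

test_that("relabeling nodes permutes the landscape (equivariance)", {
  set.seed(42)
  rw <- random_typed_network(12)
  land1 <- suppressWarnings(detect_modules(rw))
  perm <- setNames(sprintf("Q%02d", seq_along(rw$network$nodes)),
                   sample(rw$network$nodes))
  e2 <- rw$network$edges
  e2$source <- unname(perm[e2$source]); e2$target <- unname(perm[e2$target])
  rw2 <- mk_weighted(signaling_network(e2), rw$weights)
  land2 <- suppressWarnings(detect_modules(rw2))
  A1 <- land1$assignment; A2 <- land2$assignment
  expect_equal(dim(A1), dim(A2))
  expect_equal(unname(colnames(A2)), unname(perm[colnames(A1)])[
    order(unname(perm[colnames(A1)]))])
  expect_equal(unname(A2[perm[rownames(A1)],
                         perm[colnames(A1)][order(perm[colnames(A1)])]]),
               unname(A1[, order(perm[colnames(A1)])]),
               tolerance = 1e-9)
})

test_that("community centrality ranks organizers: star center above leaves", {
  star <- signaling_network(mk_edges(rep("H", 5), paste0("L", 1:5),
                                     "undirected"))
  ws <- mk_weighted(star, rep(1, 5))
  cc <- community_centrality(w = ws)
  expect_true(all(cc["H"] > cc[paste0("L", 1:5)]))
  # equals direct summation of all influence zones at each node
  zones <- vapply(names(cc), function(s) influence_zone(ws, s),
                  numeric(6))
  expect_equal(unname(cc), unname(rowSums(zones)), tolerance = 1e-5)
  # a stored landscape returns its centrality directly
  land <- detect_modules(ws)
  expect_equal(community_centrality(land), land$centrality)
})

test_that("discrete assignment takes the argmax with lexicographic ties", {
  land <- structure(list(
    assignment = matrix(c(0.7, 0.5, 0.3, 0.5), 2, 2,
                        dimnames = list(c("n1", "n2"), c("BAX", "CDK1"))),
    centrality = c(n1 = 1, n2 = 1)),
    class = "module_landscape")
  da <- discrete_assignment(land)
  expect_equal(unname(da), c("BAX", "BAX"))   # 0.7 argmax; 0.5/0.5 tie

  set.seed(43)
  rw <- random_typed_network(25)
  land2 <- suppressWarnings(detect_modules(rw))
  da2 <- discrete_assignment(land2)
  A <- land2$assignment[, sort(colnames(land2$assignment)), drop = FALSE]
  oracle <- apply(A, 1, function(r) colnames(A)[which.max(r)])
  expect_identical(unname(da2), unname(oracle))
})

test_that("modules are named for their highest-centrality member", {
  land <- structure(list(
    assignment = matrix(c(0.9, 0.8, 0.1, 0.2), 2, 2,
                        dimnames = list(c("A", "B"), c("A", "Z"))),
    centrality = c(A = 3, B = 1)),
    class = "module_landscape")
  land$assignment <- land$assignment / rowSums(land$assignment)
  expect_warning(nm <- name_modules(land), "empty discrete membership")
  expect_equal(unname(nm["A"]), "A")

  # centrality tie -> lexicographically smallest symbol
  land2 <- structure(list(
    assignment = matrix(c(1, 1), 2, 1,
                        dimnames = list(c("B", "A"), "B")),
    centrality = c(B = 2, A = 2)),
    class = "module_landscape")
  expect_equal(unname(name_modules(land2)), "A")
})

test_that("overlap metrics are entropy-based effective counts and weighted degrees", {
  land <- structure(list(
    assignment = matrix(c(1, 0.5, 0, 0.5), 2, 2,
                        dimnames = list(c("A", "B"), c("M1", "M2")))),
    class = "module_landscape")
  net <- signaling_network(mk_edges("A", "B", "undirected"))
  w <- mk_weighted(net, 2.5)
  land$assignment <- land$assignment  # rows (1,0) and (0.5,0.5)
  om <- overlap_metrics(land, w)
  expect_equal(om$modular_overlap, c(1, 2), tolerance = 1e-12)
  expect_equal(om$effective_degree, c(2.5, 2.5))

  # random rows vs independent entropy computation
  set.seed(44)
  rw <- random_typed_network(18)
  land2 <- suppressWarnings(detect_modules(rw))
  om2 <- overlap_metrics(land2, rw)
  ent <- apply(land2$assignment, 1, function(p) {
    p <- p[p > 0]; exp(-sum(p * log(p)))
  })
  expect_equal(om2$modular_overlap, unname(ent), tolerance = 1e-12)
  W <- oncorewire:::weight_matrix(rw)
  expect_equal(om2$effective_degree, unname(rowSums(W)[om2$node]),
               tolerance = 1e-12)
})

test_that("strengthening a module's internal links never weakens member assignment", {
  bb <- mk_barbell()
  base_w <- c(rep(1, 20), 0.4)
  landA <- detect_modules(mk_weighted(bb, base_w))
  modA <- discrete_assignment(landA)[["A2"]]
  sA0 <- landA$assignment[paste0("A", 1:5), modA]
  stronger <- base_w; stronger[1:10] <- 1.4   # clique A internal edges
  landB <- detect_modules(mk_weighted(bb, stronger))
  modB <- discrete_assignment(landB)[["A2"]]
  sA1 <- landB$assignment[paste0("A", 1:5), modB]
  expect_true(all(sA1 >= sA0 - 1e-9))
})

test_that("module matching reports identity, merges and splits", {
  bb <- mk_barbell()
  w2mod <- mk_weighted(bb, c(rep(1, 20), 0.4))
  land2 <- detect_modules(w2mod)
  m_id <- match_modules(land2, land2)
  expect_equal(m_id$jaccard, rep(1, 2))
  expect_equal(m_id$annotation, rep("stable", 2))
  expect_equal(m_id$module_a, m_id$module_b)

  # one-module landscape (full clique on the same nodes) as the merged state
  all_nodes <- c(paste0("A", 1:5), paste0("B", 1:5))
  full <- signaling_network(mk_clique(all_nodes))
  w1mod <- mk_weighted(full, rep(1, 45))
  land1 <- detect_modules(w1mod)
  expect_equal(ncol(land1$assignment), 1)
  m_merge <- match_modules(land2, land1)
  expect_equal(m_merge$annotation, rep("merge", 2))
  expect_length(unique(m_merge$module_b), 1)
  m_split <- match_modules(land1, land2)
  expect_equal(m_split$annotation, "split")

  # disjoint node sets are an error
  other <- signaling_network(mk_clique(paste0("Z", 1:4)))
  land_z <- detect_modules(mk_weighted(other, rep(1, 6)))
  expect_error(match_modules(land2, land_z), "share no nodes")
})
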