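test_that("link weights are the log of endpoint abundance products", {
  net <- signaling_network(mk_edges(c("A", "B"), c("B", "C"),
                                    "activating"))
  ab <- c(A = 10, B = 10, C = 1)
  w <- compute_link_weights(net, ab)
  expect_equal(w$weights, c(2, 1))
  expect_equal(compute_link_weights(net, c(A = 1, B = 1, C = 1))$weights,
               c(0, 0))

  # brute-force oracle on a random network
  set.seed(12)
  rw <- random_typed_network(40, n_extra = 60)
  ab2 <- setNames(runif(length(rw$network$nodes), 0.5, 20),
                  rw$network$nodes)
  w2 <- compute_link_weights(rw$network, ab2)
  oracle <- vapply(seq_len(nrow(rw$network$edges)), function(k)
    log10(ab2[[rw$network$edges$source[k]]] *
            ab2[[rw$network$edges$target[k]]]), numeric(1))
  expect_equal(w2$weights, oracle, tolerance = 1e-12)

  expect_error(compute_link_weights(net, c(A = 1, B = 2)), "gene.*C")
})

test_that("raising an abundance never lowers an incident weight (monotonicity)", {
  set.seed(13)
  rw <- random_typed_network(20)
  ab <- setNames(runif(20, 1, 10), rw$network$nodes)
  w0 <- compute_link_weights(rw$network, ab)$weights
  for (g in sample(names(ab), 5)) {
    ab2 <- ab; ab2[g] <- ab2[g] * 1.5
    w1 <- compute_link_weights(rw$network, ab2)$weights
    expect_true(all(w1 >= w0 - 1e-12))
  }
})

test_that("the weight multiset is invariant under node relabeling", {
  set.seed(14)
  rw <- random_typed_network(15)
  ab <- setNames(runif(15, 1, 10), rw$network$nodes)
  w0 <- compute_link_weights(rw$network, ab)$weights
  perm <- setNames(sample(rw$network$nodes), rw$network$nodes)
  e2 <- rw$network$edges
  e2$source <- unname(perm[e2$source]); e2$target <- unname(perm[e2$target])
  ab2 <- setNames(ab, unname(perm[names(ab)]))
  w1 <- compute_link_weights(signaling_network(e2), ab2)$weights
  expect_equal(sort(w0), sort(w1), tolerance = 1e-12)
})

test_that("weight summaries compute quartiles, bins and the cumulative curve", {
  net4 <- signaling_network(mk_edges(paste0("n", 1:4), paste0("m", 1:4),
                                     "undirected"))
  s <- summarize_weights(mk_weighted(net4, c(1, 2, 3, 4)))
  expect_equal(s$median, 2.5); expect_equal(s$min, 1); expect_equal(s$max, 4)
  expect_lte(s$q1, s$median); expect_lte(s$median, s$q3)

  s2 <- summarize_weights(mk_weighted(net4, rep(3, 4)))
  expect_equal(s2$sd, 0); expect_equal(s2$iqr, 0)
  expect_equal(unname(s2$bin_fractions["strong"]), 1)  # 3 > 2.7

  # boundary convention: weak < 2, medium [2, 2.7], strong > 2.7
  s3 <- summarize_weights(mk_weighted(net4, c(1.9, 2.0, 2.5, 2.8)))
  expect_equal(unname(s3$bin_fractions), c(0.25, 0.5, 0.25))
  expect_equal(sum(s3$bin_fractions), 1)
  expect_true(all(diff(s3$cumulative$cumulative) >= 0))
  expect_equal(tail(s3$cumulative$cumulative, 1), 1)

  net1 <- signaling_network(mk_edges("a", "b", "undirected"))
  expect_error(summarize_weights(mk_weighted(net1, 1)), ">= 2 edges")
})

test_that("paired Wilcoxon matches exact enumeration and handles degeneracy", {
  # forced toy case: all three differences negative
  res <- paired_wilcoxon(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 0.25)

  # full-enumeration oracle across sizes, with and without ties
  set.seed(15)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    x <- round(runif(n, 0, 10), sample(c(0, 1), 1))  # coarse -> ties
    y <- round(runif(n, 0, 10), 1)
    if (all(x == y)) next
    expect_equal(paired_wilcoxon(x, y)$p.value, enum_wilcoxon_p(x, y),
                 tolerance = 1e-12, label = sprintf("rep %d", rep))
  }

  # tie-free exact branch agrees with the reference implementation
  set.seed(16)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(paired_wilcoxon(x, y)$p.value,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)

  # one-sign shifts: p decreases with n
  ps <- vapply(c(6, 8, 10), function(n) {
    x <- seq_len(n)
    paired_wilcoxon(x, x + 0.5)$p.value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))

  expect_error(paired_wilcoxon(1:5, 1:5), "degenerate")
  expect_error(paired_wilcoxon(1:4, 1:5), "aligned")
})

test_that("large-n Wilcoxon uses the tie-corrected normal approximation", {
  set.seed(17)
  x <- rnorm(40); y <- x + rnorm(40, 0.3)
  res <- paired_wilcoxon(x, y)
  expect_match(res$method, "normal")
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE,
                     correct = TRUE)$p.value
  expect_equal(res$p.value, ref, tolerance = 1e-9)
})

test_that("extreme strata have forced sizes, nesting and deterministic ties", {
  nodes <- sprintf("e%02d", 1:10)
  net <- signaling_network(mk_edges(nodes, paste0("x", 1:10), "undirected"))
  w <- mk_weighted(net, 1:10)
  ex <- extreme_links(w, 0.1, 0.01)
  expect_equal(ex$edges$weight[ex$top_decile], 10)
  expect_equal(ex$edges$weight[ex$bottom_decile], 1)

  set.seed(18)
  big <- random_typed_network(60, n_extra = 40)
  ex2 <- extreme_links(big, 0.10, 0.01)
  expect_equal(length(ex2$top_decile), floor(0.10 * length(big$weights)))
  expect_equal(length(ex2$top_percentile), floor(0.01 * length(big$weights)))
  expect_true(all(ex2$top_percentile %in% ex2$top_decile))
  expect_true(all(ex2$bottom_percentile %in% ex2$bottom_decile))
  expect_length(intersect(ex2$top_decile, ex2$bottom_decile), 0)

  # tie-break oracle: (weight desc, source, target) ordering
  wt <- c(5, 5, 5, 1, 2, 3, 4, 4, 4, 5)
  w3 <- mk_weighted(net, wt)
  ex3 <- extreme_links(w3, 0.2, 0.1)
  e <- ex3$edges
  oracle <- order(-e$weight, e$source, e$target)[1:2]
  expect_equal(ex3$top_decile, oracle)

  expect_error(extreme_links(w, 0.6), "fractions")
})

test_that("module representation ratios equal exhaustive per-edge counts", {
  nodes <- paste0("v", 1:8)
  net <- signaling_network(rbind(mk_clique(nodes[1:4]),
                                 mk_clique(nodes[5:8]),
                                 mk_edges("v1", "v5", "undirected")))
  w <- mk_weighted(net, c(rep(4, 6), rep(1, 6), 2.5))
  ex <- extreme_links(w, 0.4, 0.1)
  assign <- setNames(rep(c("M1", "M2"), each = 4), nodes)
  rep_tab <- module_representation(ex, assign)
  # brute-force oracle
  e <- ex$edges
  internal <- assign[e$source] == assign[e$target]
  for (m in c("M1", "M2")) {
    in_m <- internal & assign[e$source] == m
    for (s in c("top_decile", "bottom_decile")) {
      expect_equal(rep_tab[[s]][rep_tab$module == m],
                   sum(which(in_m) %in% ex[[s]]) / sum(in_m))
    }
  }
  # module with 4 internal edges and 2 in the top stratum -> 0.5
  expect_equal(rep_tab$top_decile[rep_tab$module == "M1"],
               sum(ex$top_decile %in% which(in_m <- internal &
                                              assign[e$source] == "M1")) /
                 6)

  # empty module warns and reports 0
  assign2 <- assign; assign2["v1"] <- "M3"
  expect_warning(rep2 <- module_representation(ex, assign2), "M3")
  expect_equal(rep2$top_decile[rep2$module == "M3"], 0)
})
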