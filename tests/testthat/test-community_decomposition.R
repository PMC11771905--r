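test_that("modularity matches hand-derived values", {
  g <- two_triangle_graph()
  all_one <- stats::setNames(rep(1, 6), igraph::V(g)$name)
  expect_equal(modularity_q(g, all_one), 0)

  tri <- igraph::make_graph(~ a - b, b - c, a - c)
  singletons <- stats::setNames(1:3, c("a", "b", "c"))
  expect_equal(modularity_q(tri, singletons), -1 / 3)

  split_tri <- stats::setNames(c(1, 1, 1, 2, 2, 2),
                               c("a", "b", "c", "d", "e", "f"))
  expect_equal(modularity_q(g, split_tri), 5 / 14)

  expect_error(modularity_q(g, stats::setNames(1, "a")), "missing")
})

test_that("modularity agrees with the igraph implementation", {
  for (seed in 81:85) {
    g <- rand_named_gnp(12, 0.3, seed)
    if (igraph::ecount(g) == 0) next
    memb <- sample(1:3, 12, replace = TRUE)
    expect_equal(modularity_q(g, stats::setNames(memb, igraph::V(g)$name)),
                 igraph::modularity(g, memb), tolerance = 1e-12)
  }
})

test_that("a clique is indivisible under the leading-eigenvector split", {
  k4 <- igraph::make_full_graph(4)
  k4 <- igraph::set_vertex_attr(k4, "name", value = letters[1:4])
  sp <- lev_split(k4)
  expect_false(sp$divisible)
})

test_that("the two-triangle graph splits exactly into its triangles", {
  g <- two_triangle_graph()
  sp <- lev_split(g)
  expect_true(sp$divisible)
  sides <- split(names(sp$sign_vector), sp$sign_vector)
  expect_equal(set_list_key(sides),
               set_list_key(list(c("a", "b", "c"), c("d", "e", "f"))))
  expect_equal(sp$delta_q, 5 / 14, tolerance = 1e-12)
  expect_lt(sp$residual, 1e-8)

  # brute force over all bisections confirms this is the best split
  nodes <- igraph::V(g)$name
  best <- -Inf
  for (mask in 1:(2^6 - 2)) {
    memb <- stats::setNames(as.integer(intToBits(mask))[1:6], nodes)
    best <- max(best, modularity_q(g, memb))
  }
  expect_equal(sp$delta_q, best, tolerance = 1e-12)
})

test_that("planted partitions are recovered", {
  gen <- gen_graph("planted_partition", n = 8, blocks = 2, p_in = 0.9,
                   p_out = 0.05, seed = 13)
  sp <- lev_split(gen$graph)
  expect_true(sp$divisible)
  sides <- split(names(sp$sign_vector), sp$sign_vector)
  truth <- split(names(gen$truth), gen$truth)
  expect_equal(set_list_key(sides), set_list_key(truth))
})

test_that("the KL-refined split is non-negative in gain and single-move stable", {
  for (seed in 86:95) {
    g <- rand_named_gnp(sample(5:10, 1), 0.4, seed)
    if (igraph::ecount(g) < 2) next
    sp <- lev_split(g, refine = "kl")
    expect_lt(sp$residual, 1e-8)
    if (!sp$divisible) next
    expect_gte(sp$delta_q, 0)
    memb <- stats::setNames(as.integer(sp$sign_vector > 0),
                            names(sp$sign_vector))
    q0 <- modularity_q(g, memb)
    for (v in names(memb)) { # Kernighan-Lin style single-move audit
      flipped <- memb
      flipped[v] <- 1 - flipped[v]
      if (length(unique(flipped)) < 2) next
      expect_lte(modularity_q(g, flipped), q0 + 1e-12)
    }
  }
})

test_that("triangle enumeration matches brute force", {
  tri <- igraph::make_graph(~ a - b, b - c, a - c)
  expect_equal(length(find_triangles(tri)), 1)
  path <- igraph::make_graph(~ a - b, b - c, c - d)
  expect_equal(length(find_triangles(path)), 0)
  k4 <- igraph::set_vertex_attr(igraph::make_full_graph(4), "name",
                                value = letters[1:4])
  expect_equal(length(find_triangles(k4)), choose(4, 3))
  for (seed in 96:100) {
    g <- rand_named_gnp(sample(6:15, 1), 0.3, seed)
    expect_equal(set_list_key(find_triangles(g)),
                 set_list_key(bf_triangles(g)))
  }
  # member-subset restriction
  g2 <- two_triangle_graph()
  expect_equal(length(find_triangles(g2, c("a", "b", "c"))), 1)
  expect_equal(length(find_triangles(g2, c("a", "b", "d"))), 0)
})

test_that("dotted-path labels follow the child-index grammar", {
  expect_equal(community_label(integer(0)), "C")
  expect_equal(community_label(2), "C2")
  expect_equal(community_label(c(2, 3)), "C2.3")
  expect_equal(community_label(c(2, 3, 4, 1)), "C2.3.4.1")
})

test_that("a lone triangle is a root motif leaf", {
  tri <- igraph::make_graph(~ x - y, y - z, x - z)
  tree <- recursive_decompose(tri)
  expect_equal(tree$root$label, "C")
  expect_true(tree$root$is_motif_leaf)
  expect_equal(tree$max_level, 0)
  lp <- label_paths(tree)
  expect_equal(lp$leaf_label, "C")
  expect_equal(lp$members, "x,y,z")
})

test_that("two joined triangles decompose into labelled motif leaves", {
  tree <- recursive_decompose(two_triangle_graph())
  expect_equal(length(tree$root$children), 2)
  expect_equal(vapply(tree$root$children, `[[`, "", "label"), c("C1", "C2"))
  expect_true(all(vapply(tree$root$children, `[[`, TRUE, "is_motif_leaf")))
  expect_equal(length(tree$motif_leaves), 2)
  expect_equal(tree$max_level, 1)
})

test_that("decomposition trees are nested partitions at every level", {
  graphs <- list(
    gen_graph("ba", n = 60, m = 2, seed = 17)$graph,
    gen_graph("planted_partition", n = 10, blocks = 3, p_in = 0.8,
              p_out = 0.05, seed = 18)$graph,
    gen_graph("hierarchical", clique_size = 4, levels = 3)$graph,
    gen_graph("modular", supers = 4, tri_per = 4, seed = 20)$graph)
  for (g in graphs) for (scope in c("local", "global")) {
    tree <- recursive_decompose(g, scope = scope)
    expect_setequal(unlist(level_partition(tree, tree$max_level)),
                    igraph::V(g)$name)
    prev <- level_partition(tree, 0)
    for (lev in seq_len(tree$max_level)) {
      cur <- level_partition(tree, lev)
      # refinement: every current community lies inside one previous one
      for (comm in cur) {
        inside <- vapply(prev, function(p) all(comm %in% p), TRUE)
        expect_equal(sum(inside), 1)
      }
      prev <- cur
    }
  }
})

test_that("global-scope recursion only accepts modularity-increasing splits", {
  graphs <- list(
    gen_graph("ba", n = 60, m = 2, seed = 17)$graph,
    gen_graph("modular", supers = 4, tri_per = 4, seed = 20)$graph)
  for (g in graphs) {
    tree <- recursive_decompose(g, scope = "global")
    q_of_level <- function(lev) {
      parts <- level_partition(tree, lev)
      memb <- stats::setNames(rep(seq_along(parts), lengths(parts)),
                              unlist(parts))
      modularity_q(g, memb)
    }
    qs <- vapply(0:tree$max_level, q_of_level, 0)
    expect_true(all(diff(qs) >= -1e-12)) # Q never decreases down the tree
    expect_gte(qs[length(qs)], 0)        # leaf partition beats the root Q = 0
  }
})

test_that("local-scope recursion reaches the planted triangle motifs", {
  gen <- gen_graph("modular", supers = 4, tri_per = 4, p_super = 0.08,
                   p_out = 0.005, seed = 26)
  tree <- recursive_decompose(gen$graph)
  expect_gt(length(tree$motif_leaves), 0)
  # motif leaves are overwhelmingly the planted triangle blocks (cross-block
  # chance triangles can occasionally surface as leaves)
  truth_blocks <- split(names(gen$truth), gen$truth)
  keys <- set_list_key(truth_blocks)
  leaf_keys <- vapply(tree$motif_leaves,
                      function(l) paste(sort(l$members), collapse = "|"), "")
  expect_gte(mean(leaf_keys %in% keys), 0.8)
})

test_that("four planted blocks are recovered with KL refinement", {
  gen <- gen_graph("planted_partition", n = 8, blocks = 4, p_in = 0.9,
                   p_out = 0.02, seed = 19)
  tree <- recursive_decompose(gen$graph, scope = "global", refine = "kl")
  truth <- split(names(gen$truth), gen$truth)
  tab <- tree_table(tree)
  comms <- lapply(strsplit(tab$members, ","), sort)
  for (b in truth)
    expect_true(paste(sort(b), collapse = "|") %in% set_list_key(comms))
})

test_that("disconnected graphs decompose component-wise under the root", {
  g <- igraph::make_graph(~ a - b, b - c, a - c, d - e, e - f, d - f)
  g <- igraph::delete_edges(g, character(0)) # no-op, keeps names
  tree <- recursive_decompose(g)
  expect_equal(length(tree$root$children), 2)
  expect_equal(length(tree$motif_leaves), 2)
})

test_that("max_level truncates recursion", {
  g <- gen_graph("hierarchical", clique_size = 4, levels = 3)$graph
  tree <- recursive_decompose(g, max_level = 1)
  expect_lte(tree$max_level, 1)
})

test_that("communities without triangles are kept but flagged", {
  g <- igraph::make_graph(~ a - b, b - c, a - c, c - d, d - e)
  tree <- recursive_decompose(g)
  tab <- tree_table(tree)
  expect_true(any(!tab$has_motif))
  expect_setequal(unlist(strsplit(tab$members[tab$label == "C"], ",")),
                  c("a", "b", "c", "d", "e"))
})
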