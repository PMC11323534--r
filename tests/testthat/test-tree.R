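test_that("Newick parsing counts nodes, round-trips, rejects bad input", {
  tr <- parse_newick("((A,B),C);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(tr$Nnode, 2)
  expect_equal(tr$node.label[1], "N1")

  rt <- parse_newick(write_newick(tr))
  expect_true(ape::all.equal.phylo(tr, rt, use.edge.length = FALSE))

  expect_error(parse_newick("(A,B"), "parse error")
  expect_error(parse_newick(""), "parse error")
  expect_error(parse_newick("((A,B),A);"), "duplicate")
  expect_error(parse_newick(), "exactly one")
})

test_that("constant characters reconstruct with zero events", {
  tr <- parse_newick("((A,B),(C,D));")
  all1 <- setNames(rep(1, 4), c("A", "B", "C", "D"))
  h1 <- sankoff_reconstruct(tr, all1)
  expect_equal(h1$total_cost, 0)
  expect_equal(h1$n_gains + h1$n_losses, 0)
  expect_true(all(h1$node_states == 1))
  h0 <- sankoff_reconstruct(tr, all1 * 0)
  expect_equal(h0$total_cost, 0)
  expect_true(all(h0$node_states == 0))
})

test_that("a single presence maps to one gain on that leaf's branch", {
  # caterpillar: for leaf A, any root-present alternative costs >= 3 losses
  tr <- parse_newick("(((A,B),C),D);")
  st <- setNames(c(1, 0, 0, 0), c("A", "B", "C", "D"))
  h <- sankoff_reconstruct(tr, st, gain_cost = 2, loss_cost = 1)
  expect_equal(h$total_cost, 2)
  expect_equal(h$n_gains, 1)
  expect_equal(h$n_losses, 0)
  ev <- h$events[h$events$event == "gain", ]
  expect_equal(ev$child_id, "A")
  expect_equal(count_parsimony_optima(tr, st, 2, 1), 1)
})

test_that("DP cost equals the brute-force minimum on generated trees", {
  for (n in 4:6) {
    th <- gen_tree_history(n_leaves = n, n_characters = 1, seed = n)
    tr <- th$tree
    lab <- all_labelings(n)
    for (i in seq_len(nrow(lab))) {
      st <- setNames(lab[i, ], tr$tip.label)
      for (costs in list(c(2, 1), c(1, 1), c(1, 3))) {
        h <- sankoff_reconstruct(tr, st, costs[1], costs[2])
        bf <- brute_force_parsimony(tr, st, costs[1], costs[2])
        expect_equal(h$total_cost, bf$min_cost)
        expect_equal(count_parsimony_optima(tr, st, costs[1], costs[2]),
                     bf$n_optima)
      }
    }
  }
})

test_that("polytomies are handled and still match the oracle", {
  tr <- parse_newick("(A,B,C,(D,E));")
  expect_equal(tr$Nnode, 2)
  lab <- all_labelings(5)
  for (i in seq_len(nrow(lab))) {
    st <- setNames(lab[i, ], tr$tip.label)
    h <- sankoff_reconstruct(tr, st)
    bf <- brute_force_parsimony(tr, st)
    expect_equal(h$total_cost, bf$min_cost)
  }
})

test_that("cost symmetry: swapping costs and inverting states mirrors events", {
  set.seed(17)
  th <- gen_tree_history(n_leaves = 8, n_characters = 5,
                         events_per_character = 2, seed = 23)
  for (ch in rownames(th$states)) {
    st <- th$states[ch, ]
    h1 <- sankoff_reconstruct(th$tree, st, 2, 1)
    h2 <- sankoff_reconstruct(th$tree, 1 - st, 1, 2, tie_break = "present")
    expect_equal(h2$total_cost, h1$total_cost)
    expect_equal(h2$n_gains, h1$n_losses)
    expect_equal(h2$n_losses, h1$n_gains)
    expect_equal(h2$node_states, 1 - h1$node_states)
  }
})

test_that("raising the gain cost never yields more gains", {
  th <- gen_tree_history(n_leaves = 10, n_characters = 8,
                         events_per_character = 2, seed = 31)
  for (ch in rownames(th$states)) {
    st <- th$states[ch, ]
    gains <- vapply(c(0.5, 1, 2, 4, 8), function(g)
      sankoff_reconstruct(th$tree, st, gain_cost = g, loss_cost = 1)$n_gains,
      0)
    expect_true(all(diff(gains) <= 0))
  }
})

test_that("symmetric-cost minima agree with phangorn's Sankoff", {
  skip_if_not_installed("phangorn")
  th <- gen_tree_history(n_leaves = 12, n_characters = 6,
                         events_per_character = 2, seed = 41)
  cost <- matrix(c(0, 1, 1, 0), 2, 2)
  for (ch in rownames(th$states)) {
    st <- th$states[ch, ]
    h <- sankoff_reconstruct(th$tree, st, gain_cost = 1, loss_cost = 1)
    dat <- phangorn::phyDat(matrix(st, ncol = 1,
                                   dimnames = list(names(st), NULL)),
                            type = "USER", levels = c(0, 1))
    ps <- phangorn::sankoff(th$tree, dat, cost = cost)
    expect_equal(h$total_cost, unname(as.numeric(ps)))
  }
})

test_that("missing leaf states are reported by name", {
  tr <- parse_newick("((A,B),C);")
  expect_error(sankoff_reconstruct(tr, c(A = 1, B = 0)), "C")
})

test_that("event summaries conserve per-history totals", {
  th <- gen_tree_history(n_leaves = 10, n_characters = 12,
                         events_per_character = 2, seed = 53)
  histories <- lapply(rownames(th$states), function(ch)
    sankoff_reconstruct(th$tree, th$states[ch, ]))
  names(histories) <- rownames(th$states)
  summ <- summarize_events(histories)
  expect_equal(sum(summ$gains), sum(vapply(histories, `[[`, 0, "n_gains")))
  expect_equal(sum(summ$losses), sum(vapply(histories, `[[`, 0, "n_losses")))
  # one isolated gain shows up at exactly its node
  tr <- parse_newick("(((A,B),C),D);")
  h <- sankoff_reconstruct(tr, setNames(c(1, 0, 0, 0), c("A", "B", "C", "D")))
  s1 <- summarize_events(list(cl = h))
  expect_equal(s1$gains[s1$node_id == "A"], 1)
  expect_equal(sum(s1$gains), 1)

  other <- gen_tree_history(n_leaves = 10, seed = 99)$tree
  h_other <- sankoff_reconstruct(other, setNames(rep(1, 10),
                                                 other$tip.label))
  expect_error(summarize_events(c(histories, list(x = h_other))),
               "mismatched")
})
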