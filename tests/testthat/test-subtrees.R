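test_that("hand-checked extraction on a 4-tip tree", {
  tr <- toy_tree()
  st <- states_1site(tr, c(R = "A", N1 = "K", L1 = "K", L2 = "C",
                           N2 = "A", L3 = "A", L4 = "A"))
  out <- extract_subtrees(tr, st)
  expect_equal(nrow(out$subtrees), 1)
  expect_equal(out$subtrees$A, "A")
  expect_equal(out$subtrees$B, "K")
  expect_equal(out$subtrees$gain_branch, "N1")
  br <- out$branches[order(out$branches$branch), ]
  expect_equal(br$branch, c("L1", "L2"))
  expect_equal(br$s, c(0, 1))
  expect_equal(br$age, c(0, 0))
  expect_equal(br$length, c(1, 1))
})

test_that("fully conserved sites carry no subtrees", {
  tr <- toy_tree()
  st <- states_1site(tr, c(R = "A", N1 = "A", L1 = "A", L2 = "A",
                           N2 = "A", L3 = "A", L4 = "A"))
  expect_equal(nrow(extract_subtrees(tr, st)$subtrees), 0)
})

test_that("a nested gain spawns its own subtree and truncates the outer one", {
  tr <- read_tree_text(
    "(((L1:1,L2:1)N2:1,(L3:1,L4:1)N3:1)N1:1,(L5:1,L6:1)N4:1)R;")
  st <- states_1site(tr, c(R = "A", N1 = "K", N2 = "K", L1 = "K", L2 = "K",
                           N3 = "D", L3 = "D", L4 = "D",
                           N4 = "A", L5 = "A", L6 = "A"))
  out <- extract_subtrees(tr, st)
  expect_equal(nrow(out$subtrees), 2)
  bsub <- out$branches[out$branches$B == "K", ]
  dsub <- out$branches[out$branches$B == "D", ]
  expect_setequal(bsub$branch, c("N2", "N3", "L1", "L2"))
  expect_equal(bsub$s[bsub$branch == "N3"], 1)   # lost to D
  expect_false(any(c("L3", "L4") %in% bsub$branch))  # no descent past a loss
  expect_setequal(dsub$branch, c("L3", "L4"))
  expect_equal(dsub$s, c(0, 0))
  # ages: distance from the gain node to the branch's parent
  expect_equal(bsub$age[bsub$branch %in% c("N2", "N3")], c(0, 0))
  expect_equal(bsub$age[bsub$branch %in% c("L1", "L2")], c(1, 1))
})

test_that("subtree count equals internal-branch state changes and extraction is exact on true states", {
  set.seed(11)
  tr <- fix_tree()
  aln <- simulate_alignment(tr, 12, landscape_spec("gamma", alpha = 1),
                            change_process("static"), seed = 12)
  out <- extract_subtrees(tr, aln$states)
  tt <- c(tr$tip.label, tr$node.label)
  internal <- !(tt[tr$edge[, 2]] %in% tr$tip.label)
  n_changes <- sum(vapply(seq_len(ncol(aln$states)), function(s) {
    sum(aln$states[tt[tr$edge[internal, 1]], s] !=
        aln$states[tt[tr$edge[internal, 2]], s])
  }, 0))
  expect_equal(nrow(out$subtrees), n_changes)

  # per-branch consistency: s = 1 exactly when the child's state differs
  for (i in sample(nrow(out$branches), 50)) {
    row <- out$branches[i, ]
    expect_equal(row$s,
                 as.numeric(aln$states[row$branch, row$site] != row$B))
  }

  # ages are bounded by the subtree depth and non-negative
  expect_true(all(out$branches$age >= 0))
  depth <- max(ape::node.depth.edgelength(tr))
  expect_true(all(out$branches$age <= depth))
})

test_that("branch lengths are re-estimated as per-site substitution frequencies", {
  tr <- toy_tree()
  nn <- c(tr$tip.label, tr$node.label)
  # 100 sites, all identical except 5 sites differing on branch R -> N1
  m <- matrix("A", length(nn), 100, dimnames = list(nn, 1:100))
  m[c("N1", "L1", "L2"), 1:5] <- "C"
  out <- rescale_branch_lengths(tr, m)
  child <- nn[tr$edge[, 2]]
  expect_equal(out$edge.length[child == "N1"], 0.05)
  expect_equal(sum(out$edge.length), 0.05)

  same <- matrix("A", length(nn), 10, dimnames = list(nn, 1:10))
  expect_equal(rescale_branch_lengths(tr, same)$edge.length, rep(0, 6))
  expect_error(rescale_branch_lengths(tr, m[, 0, drop = FALSE]), "sites")

  # on simulated data the re-estimated lengths track true event counts
  set.seed(13)
  big <- fix_tree()
  aln <- simulate_alignment(big, 200, landscape_spec("flat"),
                            change_process("static"), seed = 14)
  resc <- rescale_branch_lengths(big, aln$states)
  ev <- do.call(rbind, lapply(aln$histories, `[[`, "events"))
  tt <- c(big$tip.label, big$node.label)
  true_counts <- table(factor(ev$branch, levels = tt[big$edge[, 2]]))
  expect_gt(cor(resc$edge.length, as.numeric(true_counts) / 200), 0.9)
})

test_that("pooling collapses identical subtrees and conserves totals", {
  tr <- toy_tree()
  st <- states_1site(tr, c(R = "A", N1 = "K", L1 = "K", L2 = "C",
                           N2 = "A", L3 = "A", L4 = "A"))
  one <- extract_subtrees(tr, st)
  pooled <- pool_subtrees(list(one, one))
  expect_equal(length(pooled), 1)
  expect_equal(unclass(pooled)[[1]]$count, 2)
  expect_equal(n_subtrees(pooled), 2)

  st2 <- states_1site(tr, c(R = "A", N1 = "A", L1 = "A", L2 = "A",
                            N2 = "K", L3 = "K", L4 = "K"))
  two <- extract_subtrees(tr, st2)
  pooled2 <- pool_subtrees(list(one, two))
  expect_equal(length(pooled2), 2)
  expect_equal(n_subtrees(pooled2), 2)
})

test_that("missing or invalid states are refused with a useful message", {
  tr <- toy_tree()
  st <- states_1site(tr, c(R = "A", N1 = "K", L1 = "K", L2 = "C",
                           N2 = "A", L3 = "A", L4 = "A"))
  st_bad <- st[rownames(st) != "N2", , drop = FALSE]
  expect_error(extract_subtrees(tr, st_bad), "N2")
  st_na <- st; st_na["L3", 1] <- NA
  expect_error(extract_subtrees(tr, st_na), "L3")
})
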