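# Shared fixtures, memoized per test run.  Heavy objects (the pooled
# fixture subtree list and the ABC reference tables) are built once and
# reused across test files.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

fix_tree <- function() memo("tree", model_tree())

# Pooled subtree list defining the ABC study conditions (500 subtrees
# extracted from static gamma simulations on the model tree).
fix_subtrees <- function() memo("subtrees",
  fixture_subtree_list(n = 500, alpha = 1, seed = 101L))

fix_ref <- function(model) memo(paste0("ref_", model), {
  simulate_reference(fix_subtrees(), prior_spec(model), n_sims = 3000,
                     seed = if (model == "two_param") 202L else 203L)
})

read_tree_text <- function(text) {
  f <- tempfile(fileext = ".nwk")
  writeLines(text, f)
  on.exit(unlink(f))
  read_tree(f)
}

# 4-tip tree used for hand-checked subtree extraction.
toy_tree <- function() read_tree_text("((L1:1,L2:1)N1:1,(L3:1,L4:1)N2:1)R;")

# Build a 1-site node-state matrix from a named vector of states.
states_1site <- function(tree, states_named) {
  nn <- c(tree$tip.label, tree$node.label)
  matrix(unname(states_named[nn]), ncol = 1, dimnames = list(nn, "1"))
}

# Grid-search binomial MLE oracle: maximizes the log likelihood of
# s ~ intercept + slope * age with offset log(length) by iterative grid
# refinement; independent of glm's IRLS path.
grid_mle_slope <- function(br, span = 20, levels = 8, n_grid = 41) {
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * br$age + log(br$length)
    sum(br$s * eta - log1p(exp(eta)))
  }
  c0 <- 0; c1 <- 0; w <- span
  for (l in seq_len(levels)) {
    g0 <- seq(c0 - w, c0 + w, length.out = n_grid)
    g1 <- seq(c1 - w, c1 + w, length.out = n_grid)
    ll <- outer(g0, g1, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    c0 <- g0[best[1]]; c1 <- g1[best[2]]
    w <- w / 8
  }
  c1
}

# A subtree_list with a single shape: the whole tree hanging below its root
# (the root plays the role of the gain node).
whole_tree_shape <- function(tr) {
  tr2 <- ape::reorder.phylo(tr, "cladewise")
  depth <- ape::node.depth.edgelength(tr2)
  ne <- nrow(tr2$edge)
  loc <- integer(max(tr2$edge))
  root <- setdiff(tr2$edge[, 1], tr2$edge[, 2])
  loc[root] <- 1L
  nxt <- 1L
  parent <- child <- integer(ne)
  len <- age <- numeric(ne)
  for (e in seq_len(ne)) {
    p <- tr2$edge[e, 1]; cc <- tr2$edge[e, 2]
    nxt <- nxt + 1L
    loc[cc] <- nxt
    parent[e] <- loc[p] - 1L
    child[e] <- loc[cc] - 1L
    len[e] <- tr2$edge.length[e]
    age[e] <- depth[p]
  }
  structure(list(root = list(
    shape = list(parent = parent, child = child, len = len, age = age),
    count = 1L, gain_branch = "root")), class = "subtree_list")
}

# Wrap per-allele branch tables as a subtree_set for allele_scan().
synthetic_subtree_set <- function(branch_tables) {
  branches <- do.call(rbind, lapply(seq_along(branch_tables), function(i) {
    b <- branch_tables[[i]]
    data.frame(site = as.character(i), subtree = i, gain_branch = "root",
               A = "A", B = "L", branch = paste0(i, "_", seq_len(nrow(b))),
               length = b$length, age = b$age, s = b$s,
               stringsAsFactors = FALSE)
  }))
  subtrees <- data.frame(
    site = as.character(seq_along(branch_tables)),
    subtree = seq_along(branch_tables), gain_branch = "root",
    A = "A", B = "L",
    n_branches = vapply(branch_tables, nrow, 0L),
    n_losses = vapply(branch_tables, function(b) sum(b$s), 0),
    stringsAsFactors = FALSE)
  structure(list(branches = branches, subtrees = subtrees, shapes = list()),
            class = "subtree_set")
}
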