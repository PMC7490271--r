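# Substitution subtrees: for every gain A -> B on an internal branch, the
# contiguous segment of the phylogeny whose internal nodes all carry B.
# Within it, each member branch is scored with s = 1 if the child node no
# longer carries B (the allele was lost on that branch), else 0, and with
# its age = path distance from the gain node to the branch's parent node.

tip_set <- function(tree) tree$tip.label

tree_tables <- function(tree) {
  nn <- node_names(tree)
  parent <- nn[tree$edge[, 1]]
  child <- nn[tree$edge[, 2]]
  list(nn = nn, parent = parent, child = child, len = tree$edge.length,
       children = split(seq_len(nrow(tree$edge)), parent),
       is_tip = setNames(nn %in% tree$tip.label, nn))
}

check_states <- function(states, nn) {
  if (is.data.frame(states)) states <- as.matrix(states)
  if (is.null(rownames(states))) stop("node-state matrix must have node row names")
  missing <- setdiff(nn, rownames(states))
  if (length(missing))
    stop("missing states for node(s): ", paste(head(missing, 5), collapse = ", "))
  bad <- which(is.na(states) | !(states %in% AMINO_ACIDS), arr.ind = TRUE)
  if (nrow(bad))
    stop("missing or invalid state at node ", rownames(states)[bad[1, 1]],
         ", site ", colnames(states)[bad[1, 2]])
  states[nn, , drop = FALSE]
}

#' Re-estimate branch lengths from per-site substitution frequencies
#'
#' Sets each branch length to the fraction of sites whose state differs
#' between the branch's parent and child nodes, i.e. the average frequency
#' of amino-acid substitutions per site on that branch.
#'
#' @param tree Rooted `phylo` with named internal nodes.
#' @param states Character matrix of per-node, per-site amino-acid states
#'   (rows named by node).
#' @return The tree with re-estimated `edge.length`.
#' @export
rescale_branch_lengths <- function(tree, states) {
  tt <- tree_tables(tree)
  states <- check_states(states, tt$nn)
  if (ncol(states) == 0) stop("no scored sites")
  diff_frac <- vapply(seq_len(nrow(tree$edge)), function(e) {
    mean(states[tt$parent[e], ] != states[tt$child[e], ])
  }, 0)
  tree$edge.length <- diff_frac
  tree
}

#' Extract all substitution subtrees for every site
#'
#' A gain is any internal branch (child node internal) whose child state
#' differs from its parent state; the subtree is enumerated by descent from
#' the gain node, stopping below any branch whose child no longer carries
#' the gained allele.  Terminal branches are included as member branches;
#' gains on terminal branches have no observable descendants and are
#' ignored.
#'
#' @inheritParams rescale_branch_lengths
#' @param site_class Optional named vector of per-site selection-class
#'   labels (e.g. "omega<1"), named by site.
#' @return An object of class `subtree_set`: `branches` is a data frame
#'   with one row per (subtree, member branch) observation (columns site,
#'   subtree, gain_branch, A, B, branch, length, age, s); `subtrees`
#'   summarizes each subtree; `shapes` holds, per subtree, the member
#'   fragment in local preorder indexing for re-simulation.
#' @export
extract_subtrees <- function(tree, states, site_class = NULL) {
  tt <- tree_tables(tree)
  states <- check_states(states, tt$nn)
  sites <- colnames(states)
  if (is.null(sites)) sites <- as.character(seq_len(ncol(states)))
  elen_by_child <- setNames(tt$len, tt$child)

  rows <- list()
  subs <- list()
  shapes <- list()
  id <- 0L
  for (si in seq_len(ncol(states))) {
    st <- states[, si]
    gains <- which(st[tt$parent] != st[tt$child] & !tt$is_tip[tt$child])
    for (g in gains) {
      id <- id + 1L
      gain_node <- tt$child[g]
      B <- st[[gain_node]]
      A <- st[[tt$parent[g]]]
      # BFS from the gain node through B-carrying nodes
      loc_name <- gain_node
      loc_parent <- integer(0); loc_child <- integer(0)
      loc_len <- numeric(0); loc_age <- numeric(0)
      br_name <- character(0); br_s <- numeric(0)
      queue <- list(list(node = gain_node, idx = 1L, depth = 0))
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (e in tt$children[[cur$node]]) {
          m <- tt$child[e]
          lost <- st[[m]] != B
          loc_name <- c(loc_name, m)
          mi <- length(loc_name)
          loc_parent <- c(loc_parent, cur$idx)
          loc_child <- c(loc_child, mi)
          loc_len <- c(loc_len, tt$len[e])
          loc_age <- c(loc_age, cur$depth)
          br_name <- c(br_name, m)
          br_s <- c(br_s, as.numeric(lost))
          if (!lost && !tt$is_tip[[m]])
            queue <- c(queue, list(list(node = m, idx = mi,
                                        depth = cur$depth + tt$len[e])))
        }
      }
      rows[[id]] <- data.frame(
        site = sites[si], subtree = id, gain_branch = gain_node,
        A = A, B = B, branch = br_name, length = loc_len, age = loc_age,
        s = br_s, stringsAsFactors = FALSE)
      subs[[id]] <- data.frame(
        site = sites[si], subtree = id, gain_branch = gain_node,
        A = A, B = B, n_branches = length(br_name), n_losses = sum(br_s),
        stringsAsFactors = FALSE)
      shapes[[id]] <- list(parent = loc_parent - 1L, child = loc_child - 1L,
                           len = loc_len, age = loc_age, count = 1L)
    }
  }
  branches <- if (id) do.call(rbind, rows) else
    data.frame(site = character(), subtree = integer(),
               gain_branch = character(), A = character(), B = character(),
               branch = character(), length = numeric(), age = numeric(),
               s = numeric(), stringsAsFactors = FALSE)
  subtrees <- if (id) do.call(rbind, subs) else
    data.frame(site = character(), subtree = integer(),
               gain_branch = character(), A = character(), B = character(),
               n_branches = integer(), n_losses = numeric(),
               stringsAsFactors = FALSE)
  if (!is.null(site_class)) subtrees$class <- unname(site_class[subtrees$site])
  structure(list(branches = branches, subtrees = subtrees, shapes = shapes),
            class = "subtree_set")
}

#' @export
print.subtree_set <- function(x, ...) {
  cat("Substitution subtrees:", nrow(x$subtrees), "subtrees,",
      nrow(x$branches), "branch observations\n")
  invisible(x)
}

shape_signature <- function(gain_branch, shape) {
  paste(gain_branch,
        paste(shape$parent, shape$child,
              formatC(shape$len, digits = 10, format = "g"), collapse = ";"),
        sep = "|")
}

#' Pool identical substitution subtrees into (shape, count) entries
#'
#' Subtrees sharing the gain branch and an identical member-branch fragment
#' (topology and lengths) collapse to one entry with a multiplicity; this is
#' the input the ABC reference simulator consumes.
#'
#' @param sets A `subtree_set` or list of them.
#' @return An object of class `subtree_list`: a list of entries, each with
#'   `shape` (local fragment), `count`, and `gain_branch`, deterministically
#'   ordered by signature.
#' @export
pool_subtrees <- function(sets) {
  if (inherits(sets, "subtree_set")) sets <- list(sets)
  entries <- list()
  for (s in sets) {
    for (i in seq_along(s$shapes)) {
      sig <- shape_signature(s$subtrees$gain_branch[i], s$shapes[[i]])
      if (is.null(entries[[sig]])) {
        entries[[sig]] <- list(shape = s$shapes[[i]], count = 1L,
                               gain_branch = s$subtrees$gain_branch[i])
      } else {
        entries[[sig]]$count <- entries[[sig]]$count + 1L
      }
    }
  }
  # radix sort: deterministic ordering independent of the session locale
  if (length(entries))
    entries <- entries[order(names(entries), method = "radix")]
  structure(entries, class = "subtree_list")
}

#' @export
print.subtree_list <- function(x, ...) {
  cat("Pooled subtree list:", length(x), "distinct shapes,",
      n_subtrees(x), "subtrees\n")
  invisible(x)
}

#' Total number of subtrees in a pooled list
#' @param x A `subtree_list`.
#' @return Integer count.
#' @export
n_subtrees <- function(x)
  sum(vapply(unclass(x), function(e) as.numeric(e$count), 0))
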