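# File formats: newick trees, per-node state TSVs, FASTA leaf alignments.
# All times and lengths are in dS units; sites are 1-based; a branch is
# named by its child node.

#' Read a rooted newick tree
#'
#' Wraps [ape::read.tree()]; requires branch lengths on every edge and
#' assigns deterministic names (`n1`, `n2`, ... in preorder) to unnamed
#' internal nodes.
#'
#' @param path Path to a newick file.
#' @return A rooted `phylo` object with named internal nodes.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(ape::read.tree(path), error = function(e)
    stop("malformed newick in ", path, ": ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed newick in ", path)
  if (!ape::is.rooted(tree)) stop("tree in ", path, " is not rooted")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree in ", path, " is missing branch lengths")
  name_internal_nodes(tree)
}

#' Assign deterministic preorder names to unnamed internal nodes
#' @param tree A `phylo` object.
#' @return The tree with complete `node.label`.
#' @export
name_internal_nodes <- function(tree) {
  n_int <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", n_int)
  need <- !nzchar(lab) | is.na(lab)
  if (any(need)) {
    auto <- paste0("n", seq_len(n_int))
    taken <- c(tree$tip.label, lab[!need])
    auto <- setdiff(auto, taken)[seq_len(sum(need))]
    lab[need] <- auto
  }
  tree$node.label <- lab
  tree
}

#' Write a tree to newick
#' @param tree A `phylo` object.
#' @param path Output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read per-site node states
#'
#' Expects a TSV with header columns `node`, `site`, `state` (one-letter
#' amino acids) and validates that every tree node appears for every site.
#'
#' @param path Path to the TSV.
#' @param tree Optional `phylo`; if given, completeness against the tree's
#'   nodes is checked.
#' @return Character matrix, nodes x sites.
#' @export
read_states <- function(path, tree = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character")
  req <- c("node", "site", "state")
  if (!all(req %in% names(df)))
    stop("state TSV must have columns node, site, state")
  bad <- !(df$state %in% AMINO_ACIDS)
  if (any(bad))
    stop("invalid residue '", df$state[which(bad)[1]], "' at node ",
         df$node[which(bad)[1]])
  nodes <- unique(df$node)
  sites <- unique(df$site)
  m <- matrix(NA_character_, length(nodes), length(sites),
              dimnames = list(nodes, sites))
  m[cbind(match(df$node, nodes), match(df$site, sites))] <- df$state
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing state for node ", nodes[miss[1]], ", site ", sites[miss[2]])
  }
  if (!is.null(tree)) {
    missing <- setdiff(node_names(tree), nodes)
    if (length(missing))
      stop("states missing for tree node(s): ",
           paste(head(missing, 5), collapse = ", "))
  }
  m
}

output_header <- function() {
  paste0("# spfldyn ", as.character(utils::packageVersion("spfldyn")))
}

write_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- output_header()
  if (!is.null(seed)) hdr <- paste0(hdr, " seed=", seed)
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-site node states as TSV
#' @param states Character matrix, nodes x sites.
#' @param path Output path.
#' @param seed Optional seed recorded in the header comment.
#' @export
write_states <- function(states, path, seed = NULL) {
  df <- data.frame(node = rep(rownames(states), ncol(states)),
                   site = rep(colnames(states), each = nrow(states)),
                   state = as.vector(states))
  write_tsv(df, path, seed)
}

#' Write the leaf rows of a state matrix as FASTA
#' @param states Character matrix, nodes x sites.
#' @param tree The tree whose tips select the leaf rows.
#' @param path Output path.
#' @export
write_leaf_fasta <- function(states, tree, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tip in tree$tip.label) {
    writeLines(paste0(">", tip), con)
    writeLines(paste(states[tip, ], collapse = ""), con)
  }
  invisible(path)
}

#' Write the event log of simulated histories as TSV
#' @param histories List of `site_history` objects.
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @export
write_events <- function(histories, path, seed = NULL) {
  ev <- do.call(rbind, lapply(seq_along(histories), function(i) {
    e <- histories[[i]]$events
    if (!nrow(e)) return(NULL)
    cbind(site = i, e[, c("branch", "offset", "from", "to", "type")])
  }))
  if (is.null(ev))
    ev <- data.frame(site = integer(), branch = character(),
                     offset = numeric(), from = character(),
                     to = character(), type = character())
  write_tsv(ev, path, seed)
}

#' Write a subtree branch table as TSV
#' @param subtrees A `subtree_set`.
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @export
write_subtrees <- function(subtrees, path, seed = NULL) {
  write_tsv(subtrees$branches, path, seed)
}
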