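# Forward-time Markov simulation of one amino-acid site along a rooted
# phylogeny.  Branch lengths are in dS units: the expected time for one
# substitution at a neutral site.  The fixation kernel is the standard
# mutation-selection multiplier g(S) = S / (1 - exp(-S)) applied to a
# uniform mutation kernel, with S the difference in log fitness; on a flat
# landscape the total exit rate equals mu, so the neutral normalization of
# branch lengths holds by construction.

#' Mutation rate model
#'
#' @param mu Total mutation rate from the resident allele to the 19
#'   alternatives, per dS.  The default 1 makes branch lengths equal to
#'   expected neutral substitutions.
#' @return An object of class `rate_model`.
#' @export
rate_model <- function(mu = 1) {
  if (!is.finite(mu) || mu <= 0) stop("mu must be positive")
  structure(list(mu = mu), class = "rate_model")
}

#' Fixation-rate multiplier g(S)
#'
#' The relative fixation rate of a mutation with scaled selection
#' coefficient `S` (difference in log fitness), `g(S) = S / (1 - exp(-S))`,
#' extended by continuity with `g(0) = 1`.  Satisfies the detailed-balance
#' identity `g(S) / g(-S) = exp(S)`.
#'
#' @param S Numeric vector of selection coefficients.
#' @return Numeric vector of rate multipliers.
#' @export
fixation_factor <- function(S) {
  stopifnot(is.numeric(S), all(is.finite(S)))
  cpp_fix_factor(as.numeric(S))
}

#' Per-target substitution rates away from the resident allele
#'
#' Rate to allele j is `(mu/19) * g(logf[j] - logf[resident])`; the rate to
#' the resident itself is 0.
#'
#' @param logf Log-fitness vector (length 20).
#' @param resident One-letter code or index of the resident allele.
#' @param model A [rate_model()].
#' @return Named numeric vector of 20 non-negative rates.
#' @export
substitution_rates <- function(logf, resident, model = rate_model()) {
  stopifnot(length(logf) == 20)
  if (!all(is.finite(logf))) stop("non-finite log fitness")
  i <- if (is.character(resident)) aa_index(resident) else as.integer(resident)
  stopifnot(i >= 1, i <= 20)
  r <- model$mu / 19 * fixation_factor(logf - logf[i])
  r[i] <- 0
  names(r) <- AMINO_ACIDS
  r
}

#' Stationary allele distribution of a static landscape
#'
#' Under the g(S) kernel with uniform mutation the chain satisfies detailed
#' balance with `pi` proportional to `exp(logf)`.
#'
#' @param logf Log-fitness vector (length 20, or any length for reduced
#'   test chains).
#' @return Probability vector.
#' @export
stationary_distribution <- function(logf) {
  w <- exp(logf - max(logf))
  w / sum(w)
}

# ---- tree plumbing ---------------------------------------------------------

node_names <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab) || any(!nzchar(lab)))
    stop("tree must have non-empty internal node labels; see read_tree()")
  c(tree$tip.label, lab)
}

# Order edges so every parent appears before its children; returns the edge
# index permutation and the root node id.
edges_preorder <- function(edge) {
  nodes <- unique(as.vector(edge))
  root <- setdiff(edge[, 1], edge[, 2])
  if (length(root) != 1) stop("tree must have exactly one root")
  ne <- nrow(edge)
  ord <- integer(ne)
  seen <- c(root)
  remaining <- seq_len(ne)
  pos <- 0L
  while (length(remaining)) {
    ready <- remaining[edge[remaining, 1] %in% seen]
    if (!length(ready)) stop("edge list is not a connected rooted tree")
    ord[pos + seq_along(ready)] <- ready
    pos <- pos + length(ready)
    seen <- c(seen, edge[ready, 2])
    remaining <- setdiff(remaining, ready)
  }
  list(order = ord, root = root)
}

#' Simulate one amino-acid site along a rooted phylogeny
#'
#' Runs a forward-time Markov jump process for a single site.  On a static
#' landscape the process is simulated exactly (Gillespie); in random mode,
#' landscape-change events arrive as a Poisson process of rate `lambda` per
#' dS and trigger a reshuffle/redraw; in allele_linear mode time advances in
#' steps of `dt`, the resident's log fitness drifts by `k * dt` per step and
#' at most one substitution is drawn per step.  Children of a split inherit
#' the landscape state at the split point and evolve independently.
#'
#' @param tree A rooted `phylo` tree with branch lengths in dS and named
#'   internal nodes (see [read_tree()]), or a compatible list with fields
#'   `edge`, `edge.length`, `tip.label`, `node.label`.
#' @param spec A [landscape_spec()].
#' @param proc A [change_process()].
#' @param model A [rate_model()].
#' @param root_state Optional one-letter code fixing the root allele;
#'   default draws from the stationary distribution `pi` proportional to
#'   `exp(logf)` of the initial landscape.
#' @param logf0 Optional initial landscape; default [draw_landscape()].
#' @return An object of class `site_history` with elements `node_state`
#'   (named character vector over all nodes), `events` (data frame with
#'   branch, offset, from, to, type), `landscapes` (one row per landscape
#'   change), `logf0`, `root_state`, and the inputs.
#' @export
simulate_site <- function(tree, spec, proc, model = rate_model(),
                          root_state = NULL, logf0 = NULL) {
  if (is.null(tree$edge) || nrow(tree$edge) == 0) stop("empty tree")
  nn <- node_names(tree)
  eo <- edges_preorder(tree$edge)
  ord <- eo$order
  parent <- tree$edge[ord, 1]
  child <- tree$edge[ord, 2]
  elen <- tree$edge.length[ord]
  if (is.null(elen) || anyNA(elen)) stop("tree must have branch lengths")
  if (is.null(logf0)) logf0 <- draw_landscape(spec)
  shape_code <- match(spec$shape, c("flat", "rugged", "gamma")) - 1L
  mode_code <- match(proc$mode, c("static", "random", "allele_linear")) - 1L
  rs <- if (is.null(root_state)) -1L else aa_index(root_state) - 1L
  res <- cpp_sim_site(parent - 1L, child - 1L, elen,
                      length(nn), eo$root - 1L, as.numeric(logf0),
                      shape_code, spec$alpha, mode_code, proc$lambda,
                      proc$k, proc$dt, model$mu, rs)
  node_state <- setNames(AMINO_ACIDS[res$state + 1L], nn)
  ev <- data.frame(
    branch = nn[child[res$edge + 1L]],
    edge = res$edge + 1L,
    offset = res$offset,
    from = AMINO_ACIDS[res$from + 1L],
    to = AMINO_ACIDS[res$to + 1L],
    type = c("substitution", "landscape")[res$type + 1L],
    stringsAsFactors = FALSE)
  structure(list(
    tree = tree, edge_order = ord, parent = parent, child = child,
    edge_length = elen, root = eo$root,
    node_state = node_state, events = ev,
    landscapes = res$landscapes, logf0 = as.numeric(logf0),
    root_state = node_state[nn[eo$root]],
    spec = spec, proc = proc, model = model), class = "site_history")
}

#' @export
print.site_history <- function(x, ...) {
  nsub <- sum(x$events$type == "substitution")
  cat("Site history:", length(x$node_state), "nodes,", nsub,
      "substitutions,", sum(x$events$type == "landscape"),
      "landscape changes; root allele", x$root_state, "\n")
  invisible(x)
}

#' Replay a site history's events from the root
#'
#' Recomputes the allele at every node by applying the recorded substitution
#' events along each branch in order; used to verify internal consistency.
#'
#' @param history A `site_history`.
#' @return Named character vector of node states.
#' @export
replay_history <- function(history) {
  nn <- names(history$node_state)
  state <- setNames(rep(NA_character_, length(nn)), nn)
  state[history$root] <- history$root_state
  subs <- history$events[history$events$type == "substitution", ]
  for (i in seq_along(history$parent)) {
    p <- history$parent[i]; ch <- history$child[i]
    s <- state[p]
    ev <- subs[subs$edge == i, ]
    if (nrow(ev)) {
      ev <- ev[order(ev$offset), ]
      for (j in seq_len(nrow(ev))) {
        stopifnot(ev$from[j] == s)
        s <- ev$to[j]
      }
    }
    state[ch] <- s
  }
  state
}

#' Simulate an alignment of independent sites
#'
#' Sites are i.i.d. given their specs.  Each site uses its own RNG substream
#' derived from `(seed, site)`, so results are reproducible and independent
#' of evaluation order.
#'
#' @param tree Rooted `phylo` with named internal nodes.
#' @param n_sites Number of sites.
#' @param spec A [landscape_spec()] (or list of one per site).
#' @param proc A [change_process()] (or list of one per site).
#' @param model A [rate_model()].
#' @param seed Integer master seed.
#' @return A list of class `site_alignment`: `histories` (list of
#'   `site_history`), `states` (character matrix, nodes x sites), `tree`.
#' @export
simulate_alignment <- function(tree, n_sites, spec, proc,
                               model = rate_model(), seed = 1L) {
  stopifnot(n_sites >= 1)
  specs <- if (inherits(spec, "landscape_spec")) rep(list(spec), n_sites) else spec
  procs <- if (inherits(proc, "change_process")) rep(list(proc), n_sites) else proc
  stopifnot(length(specs) == n_sites, length(procs) == n_sites)
  histories <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    set.seed(site_seed(seed, i))
    histories[[i]] <- simulate_site(tree, specs[[i]], procs[[i]], model)
  }
  states <- do.call(cbind, lapply(histories, `[[`, "node_state"))
  colnames(states) <- as.character(seq_len(n_sites))
  structure(list(histories = histories, states = states, tree = tree,
                 seed = seed), class = "site_alignment")
}

site_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 1009L + i * 7L
}

#' @export
print.site_alignment <- function(x, ...) {
  cat("Simulated alignment:", ncol(x$states), "sites,",
      nrow(x$states), "nodes (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# ---- single-lineage experiments -------------------------------------------

#' A single-lineage "tree" for fitness-trajectory experiments
#'
#' Builds an unbranched chain of `n_seg` equal segments of total length
#' `t_max` dS, usable with [simulate_site()].
#'
#' @param t_max Total lineage length in dS.
#' @param n_seg Number of segments.
#' @return A `phylo`-compatible path tree.
#' @export
lineage_tree <- function(t_max, n_seg = 1) {
  stopifnot(t_max > 0, n_seg >= 1)
  # nodes: tip = 1, root = 2, chain 2 -> 3 -> ... -> (n_seg + 1) -> 1
  if (n_seg == 1) {
    edge <- matrix(c(2L, 1L), 1, 2)
    node.label <- "p1"
  } else {
    inner <- 2L + seq_len(n_seg - 1L)
    edge <- cbind(c(2L, inner), c(inner, 1L))
    node.label <- paste0("p", seq_len(n_seg))
  }
  structure(list(edge = edge, edge.length = rep(t_max / n_seg, n_seg),
                 tip.label = "lineage", Nnode = n_seg,
                 node.label = node.label), class = "phylo")
}

# Per-history piecewise state/landscape reconstruction along a path.
lineage_timeline <- function(h) {
  if (any(duplicated(h$parent))) stop("history was not simulated on a path tree")
  t0 <- cumsum(c(0, h$edge_length))[seq_along(h$edge_length)]
  ev <- h$events
  ev$time <- t0[ev$edge] + ev$offset
  ev[order(ev$time), , drop = FALSE]
}

#' Mean log fitness of the original resident allele over time
#'
#' For replicate single-lineage histories, tracks the log fitness of the
#' allele that was resident at the root and averages it across replicates at
#' each grid time.  Also reports the mean across-allele landscape fitness as
#' a reference (the level the resident's fitness decays towards under random
#' landscape changes).
#'
#' @param histories List of `site_history` objects simulated on a path tree
#'   (see [lineage_tree()]).
#' @param grid Numeric vector of times (dS) at which to evaluate.
#' @return Data frame with `time`, `mean_logf`, `landscape_mean`.
#' @export
fitness_trajectory <- function(histories, grid) {
  if (!length(histories)) stop("empty input")
  acc <- matrix(0, length(grid), 2)
  for (h in histories) {
    tl <- lineage_timeline(h)
    focal <- aa_index(h$root_state)
    logf <- h$logf0
    res <- focal
    k <- if (h$proc$mode == "allele_linear") h$proc$k else 0
    t_prev <- 0
    li <- 0L
    vals <- numeric(length(grid))
    means <- numeric(length(grid))
    gi <- 1L
    step_to <- function(t_new) {
      # advance drift on the resident between events
      if (k != 0) logf[res] <<- logf[res] + k * (t_new - t_prev)
      t_prev <<- t_new
    }
    events <- rbind(tl[, c("time", "type", "to")],
                    data.frame(time = Inf, type = "end", to = NA))
    for (e in seq_len(nrow(events))) {
      t_ev <- events$time[e]
      while (gi <= length(grid) && grid[gi] <= t_ev) {
        dtg <- grid[gi] - t_prev
        f_focal <- logf[focal] + if (k != 0 && res == focal) k * dtg else 0
        vals[gi] <- f_focal
        means[gi] <- mean(logf) + if (k != 0) k * dtg / 20 else 0
        gi <- gi + 1L
      }
      if (!is.finite(t_ev)) break
      step_to(t_ev)
      if (events$type[e] == "substitution") {
        res <- aa_index(events$to[e])
      } else {
        li <- li + 1L
        logf <- h$landscapes[li, ]
      }
    }
    acc[, 1] <- acc[, 1] + vals
    acc[, 2] <- acc[, 2] + means
  }
  data.frame(time = grid, mean_logf = acc[, 1] / length(histories),
             landscape_mean = acc[, 2] / length(histories))
}

#' Survival of the ancestral allele over time
#'
#' Fraction of replicate lineages whose root allele is still resident at
#' each grid time.
#'
#' @inheritParams fitness_trajectory
#' @return Data frame with `time`, `surviving`.
#' @export
ancestral_survival <- function(histories, grid) {
  if (!length(histories)) stop("empty input")
  surv <- numeric(length(grid))
  for (h in histories) {
    tl <- lineage_timeline(h)
    subs <- tl[tl$type == "substitution", , drop = FALSE]
    state_at <- function(t) {
      past <- subs$to[subs$time <= t]
      if (length(past)) past[length(past)] else h$root_state
    }
    surv <- surv + vapply(grid, function(t) state_at(t) == h$root_state, TRUE)
  }
  data.frame(time = grid, surviving = surv / length(histories))
}
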