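#' Parse a rooted phylogeny from Newick
#'
#' Thin validating wrapper around [ape::read.tree()]. The tree is taken as
#' rooted as written; polytomies are permitted; branch lengths are kept but
#' unused by parsimony. Internal nodes receive deterministic identifiers
#' `N1`, `N2`, ... in ape's cladewise (preorder) numbering, with `N1` the
#' root; existing internal labels are preserved as attribute
#' `original_node_labels`.
#'
#' @param text Newick string (one tree, terminated by `;`).
#' @param file alternatively, path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object with node labels set.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  if (!nzchar(trimws(text))) stop("parse error: empty Newick input")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("parse error: invalid Newick: ", substr(text, 1, 60))
  if (inherits(tr, "multiPhylo"))
    stop("parse error: expected a single tree")
  if (anyDuplicated(tr$tip.label))
    stop("parse error: duplicate leaf names: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!is.null(tr$node.label))
    attr(tr, "original_node_labels") <- tr$node.label
  tr$node.label <- paste0("N", seq_len(tr$Nnode))
  tr
}

#' Write a phylogeny to Newick
#'
#' @param tree a `phylo` object.
#' @param file optional output path; when `NULL` the Newick string is
#'   returned.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = file); invisible(file) }
}

node_ids <- function(tree) {
  c(tree$tip.label, tree$node.label)
}

transition_cost <- function(gain_cost, loss_cost) {
  ## rows = parent state (0/1), cols = child state (0/1)
  matrix(c(0, loss_cost, gain_cost, 0), 2, 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

#' Ancestral gain/loss reconstruction by asymmetric Wagner parsimony
#'
#' Minimum-cost ancestral presence/absence assignment for one gene cluster
#' on a rooted tree, by Sankoff dynamic programming over states \{0, 1\}:
#' post-order cost accumulation, root state by arg-min of root costs, and
#' pre-order traceback. A 0 -> 1 change on a branch costs `gain_cost`, a
#' 1 -> 0 change `loss_cost`; asymmetric defaults (gain 2, loss 1) make
#' gains rarer than losses. All ties resolve toward `tie_break`
#' (default: absence), which biases reconstructions toward later gains.
#' No event is placed above the root.
#'
#' @param tree a rooted `phylo` (see [parse_newick()]); polytomies allowed.
#' @param states named vector of 0/1 leaf states covering every tip.
#' @param gain_cost,loss_cost positive branch-change costs.
#' @param tie_break `"absent"` or `"present"`: state preferred when both
#'   are equally parsimonious.
#' @return List of class `event_history`: `node_states` (named 0/1 over
#'   tips then internal nodes), `events` (data frame `parent_id`,
#'   `child_id`, `event` in gain/loss/none, one row per branch in
#'   cladewise order), `total_cost`, `n_gains`, `n_losses`, plus the cost
#'   parameters and the tree.
#' @export
sankoff_reconstruct <- function(tree, states, gain_cost = 2, loss_cost = 1,
                                tie_break = c("absent", "present")) {
  stopifnot(inherits(tree, "phylo"))
  tie_break <- match.arg(tie_break)
  if (gain_cost <= 0 || loss_cost <= 0) stop("costs must be positive")
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stop("missing leaf state(s): ", paste(miss, collapse = ", "))
  s <- as.integer(states[tree$tip.label] > 0)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  trans <- transition_cost(gain_cost, loss_cost)
  cost <- matrix(0, ntip + nnode, 2L)
  cost[seq_len(ntip), ] <- Inf
  cost[cbind(seq_len(ntip), s + 1L)] <- 0
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(post))) {
    u <- post[e, 1L]; v <- post[e, 2L]
    for (st in 1:2)
      cost[u, st] <- cost[u, st] + min(trans[st, ] + cost[v, ])
  }
  root <- ntip + 1L
  pick <- function(costs) {
    # arg-min over the two states with deterministic tie-break
    if (tie_break == "absent") {
      if (costs[1L] <= costs[2L]) 0L else 1L
    } else {
      if (costs[2L] <= costs[1L]) 1L else 0L
    }
  }
  assign_state <- integer(ntip + nnode)
  assign_state[seq_len(ntip)] <- s
  assign_state[root] <- pick(cost[root, ])
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(pre))) {
    u <- pre[e, 1L]; v <- pre[e, 2L]
    if (v <= ntip) next  # leaf states are observed
    assign_state[v] <- pick(trans[assign_state[u] + 1L, ] + cost[v, ])
  }
  ids <- node_ids(tree)
  ps <- assign_state[pre[, 1L]]
  cs <- assign_state[pre[, 2L]]
  event <- ifelse(ps == cs, "none", ifelse(cs == 1L, "gain", "loss"))
  events <- data.frame(parent_id = ids[pre[, 1L]],
                       child_id = ids[pre[, 2L]],
                       event = event, stringsAsFactors = FALSE)
  n_gains <- sum(event == "gain")
  n_losses <- sum(event == "loss")
  total <- cost[root, assign_state[root] + 1L]
  stopifnot(isTRUE(all.equal(total,
                             gain_cost * n_gains + loss_cost * n_losses)))
  names(assign_state) <- ids
  structure(list(tree = tree, node_states = assign_state, events = events,
                 total_cost = total, n_gains = n_gains, n_losses = n_losses,
                 gain_cost = gain_cost, loss_cost = loss_cost,
                 tie_break = tie_break),
            class = "event_history")
}

#' @export
print.event_history <- function(x, ...) {
  cat("event_history:", x$n_gains, "gain(s),", x$n_losses,
      "loss(es), cost", x$total_cost,
      sprintf("(gain %g / loss %g)\n", x$gain_cost, x$loss_cost))
  invisible(x)
}

#' Number of minimum-cost ancestral assignments
#'
#' Counts, by a second dynamic-programming pass, how many complete
#' ancestral assignments attain the global parsimony minimum. A count of 1
#' certifies that the [sankoff_reconstruct()] solution is the unique
#' optimum (used to gate planted-history recovery checks).
#'
#' @inheritParams sankoff_reconstruct
#' @return Integer: the number of distinct optimal ancestral assignments.
#' @export
count_parsimony_optima <- function(tree, states, gain_cost = 2,
                                   loss_cost = 1) {
  stopifnot(inherits(tree, "phylo"))
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stop("missing leaf state(s): ", paste(miss, collapse = ", "))
  s <- as.integer(states[tree$tip.label] > 0)
  ntip <- length(tree$tip.label)
  trans <- transition_cost(gain_cost, loss_cost)
  cost <- matrix(0, ntip + tree$Nnode, 2L)
  cnt <- matrix(1, ntip + tree$Nnode, 2L)
  cost[seq_len(ntip), ] <- Inf
  cost[cbind(seq_len(ntip), s + 1L)] <- 0
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(post))) {
    u <- post[e, 1L]; v <- post[e, 2L]
    for (st in 1:2) {
      w <- trans[st, ] + cost[v, ]
      m <- min(w)
      cost[u, st] <- cost[u, st] + m
      cnt[u, st] <- cnt[u, st] * sum(cnt[v, w == m])
    }
  }
  root <- ntip + 1L
  m <- min(cost[root, ])
  sum(cnt[root, cost[root, ] == m])
}

#' Per-node gain/loss totals across clusters
#'
#' Aggregates the per-branch events of many single-cluster reconstructions
#' into counts of gains and losses on the branch subtending each node (the
#' per-node event bars of a gene-content evolution figure).
#'
#' @param histories named list (cluster id -> [sankoff_reconstruct()]
#'   result); all histories must share one tree.
#' @return Data frame: `node_id`, `gains`, `losses`, one row per non-root
#'   node (tips first, then internal nodes in cladewise order).
#' @export
summarize_events <- function(histories) {
  if (length(histories) == 0L) stop("no histories supplied")
  ref <- histories[[1L]]$tree
  ref_str <- ape::write.tree(ref)
  for (h in histories) {
    if (!identical(ape::write.tree(h$tree), ref_str))
      stop("histories reconstructed on mismatched trees")
  }
  ids <- node_ids(ref)
  root_id <- ref$node.label[1L]
  out <- data.frame(node_id = setdiff(ids, root_id),
                    gains = 0L, losses = 0L, stringsAsFactors = FALSE)
  for (h in histories) {
    ev <- h$events
    i <- match(ev$child_id, out$node_id)
    out$gains[i] <- out$gains[i] + (ev$event == "gain")
    out$losses[i] <- out$losses[i] + (ev$event == "loss")
  }
  out
}
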