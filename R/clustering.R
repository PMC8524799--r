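#' Pick the seed node of a new cluster
#'
#' Among the still-unassigned nodes, returns the one with the largest
#' degree in the full graph; ties are broken by the smallest input-order
#' index, so the procedure is deterministic.
#'
#' @param g a [social_graph()].
#' @param unassigned non-empty character vector of unassigned node ids.
#' @return A single node id.
#' @export
seed_node <- function(g, unassigned) {
  unassigned <- as.character(unassigned)
  if (length(unassigned) == 0) stop_precondition("no unassigned nodes left")
  idx <- sort(check_ids(g, unassigned))
  deg <- rowSums(g$adj)[idx]
  g$ids[idx[which.max(deg)]]  # which.max -> first (= smallest index) on ties
}

#' Cost of adding a node to a growing cluster
#'
#' The greedy clustering objective for one candidate: a convex combination
#' `a * attribute_term + (1 - a) * structure_distance(v, s)`. The attribute
#' term is the generalization-loss factor the grown cluster `s + v` would
#' have — numerical interval widths over global ranges plus categorical
#' subtree heights over hierarchy heights — normalized by the attribute
#' count so that, like the structure distance, it lies in \[0, 1\].
#' With `a = 1` the cost ignores the edge set entirely; with `a = 0` it is
#' exactly the mean normalized graph distance from `v` to the cluster.
#'
#' @param v candidate node id, not in `s`.
#' @param s non-empty character vector, the current cluster members.
#' @param g a [social_graph()].
#' @param records node-record table covering `v` and `s`.
#' @param schema an [attribute_schema()].
#' @param ranges global numeric ranges from [global_ranges()].
#' @param a attribute weight in \[0, 1\].
#' @return Non-negative real cost.
#' @export
candidate_cost <- function(v, s, g, records, schema, ranges, a) {
  s <- as.character(s)
  if (length(s) == 0) stop_precondition("cluster s must be non-empty")
  if (as.character(v) %in% s) stop_precondition("node %s already in cluster", v)
  if (a < 0 || a > 1) stop_parameter("weight a must lie in [0, 1]")
  grown <- records[match(c(s, as.character(v)), records$id), , drop = FALSE]
  p_plus_q <- length(schema$numerical) + length(schema$categorical)
  attr_term <- (attr_loss_factor(grown, schema, ranges) +
                  cate_loss_factor(grown, schema)) / p_plus_q
  a * attr_term + (1 - a) * structure_distance(g, v, s)
}

#' Greedy k-anonymous clustering of an attributed social graph
#'
#' Repeatedly opens a new cluster at the unassigned node of maximum degree
#' and grows it to exactly `k` members, each time adding the unassigned
#' node of minimal [candidate_cost()]; once fewer than `k` nodes remain
#' unassigned, each leftover is appended (in input order) to the existing
#' cluster it is cheapest to join, so no undersized cluster is ever
#' emitted. The result is a disjoint cover of the node set with every
#' cluster of size at least `k`, deterministic for a fixed input order
#' (all ties break toward the smallest input-order index).
#'
#' @param g a [social_graph()].
#' @param records node-record table; its id set must equal the graph's.
#' @param schema an [attribute_schema()].
#' @param k minimum cluster size, an integer with `2 <= k <= n`.
#' @param a attribute weight in \[0, 1\]: 1 clusters on attributes alone,
#'   0 on graph distance alone.
#' @return A list of character id vectors (the partition).
#' @export
greedy_k_cluster <- function(g, records, schema, k, a) {
  n <- n_nodes(g)
  if (length(k) != 1 || is.na(k) || k != as.integer(k)) {
    stop_parameter("k must be a single integer")
  }
  k <- as.integer(k)
  if (k < 2) stop_parameter("k must be at least 2 (k = 1 anonymity is vacuous)")
  if (k > n) stop_parameter("k = %d exceeds the number of nodes (%d)", k, n)
  if (length(a) != 1 || is.na(a) || a < 0 || a > 1) {
    stop_parameter("weight a must lie in [0, 1]")
  }
  records <- validate_records(records, schema)
  if (!setequal(records$id, g$ids) || nrow(records) != n) {
    stop_input("record ids must match the graph's node ids exactly")
  }
  records <- records[match(g$ids, records$id), , drop = FALSE]
  ranges <- global_ranges(records, schema)
  D <- node_distance_matrix(g)
  deg <- rowSums(g$adj)
  p_plus_q <- length(schema$numerical) + length(schema$categorical)
  num_attrs <- schema$numerical
  cat_attrs <- names(schema$categorical)
  num_vals <- lapply(stats::setNames(num_attrs, num_attrs),
                     function(x) records[[x]])
  cat_vals <- lapply(stats::setNames(cat_attrs, cat_attrs),
                     function(x) records[[x]])
  gr_width <- vapply(num_attrs, function(x) interval_size(ranges[[x]]), numeric(1))

  unassigned <- rep(TRUE, n)
  clusters <- list()        # member index vectors
  states <- list()          # incremental generalization state per cluster

  new_state <- function(i) {
    list(
      lo = vapply(num_attrs, function(x) num_vals[[x]][i], numeric(1)),
      hi = vapply(num_attrs, function(x) num_vals[[x]][i], numeric(1)),
      lca = vapply(cat_attrs, function(x) cat_vals[[x]][i], character(1)),
      sumD = D[, i]
    )
  }
  grow_state <- function(st, i) {
    for (x in num_attrs) {
      st$lo[[x]] <- min(st$lo[[x]], num_vals[[x]][i])
      st$hi[[x]] <- max(st$hi[[x]], num_vals[[x]][i])
    }
    for (x in cat_attrs) {
      st$lca[[x]] <- hier_lca(schema$categorical[[x]],
                              c(st$lca[[x]], cat_vals[[x]][i]))
    }
    st$sumD <- st$sumD + D[, i]
    st
  }
  # cost of adding each candidate index to the cluster in state st; must
  # agree with candidate_cost() (checked in the test suite)
  grown_cost <- function(st, size, cand) {
    attr_term <- numeric(length(cand))
    if (p_plus_q > 0) {
      for (x in num_attrs) {
        if (gr_width[[x]] > 0) {
          v <- num_vals[[x]][cand]
          attr_term <- attr_term +
            (pmax(st$hi[[x]], v) - pmin(st$lo[[x]], v)) / gr_width[[x]]
        }
      }
      for (x in cat_attrs) {
        h <- schema$categorical[[x]]
        v <- cat_vals[[x]][cand]
        lca_h <- vapply(unique(v), function(val) {
          h$subtree_height[[hier_lca(h, c(st$lca[[x]], val))]]
        }, numeric(1))
        attr_term <- attr_term + lca_h[match(v, unique(v))] / h$height
      }
      attr_term <- attr_term / p_plus_q
    }
    a * attr_term + (1 - a) * st$sumD[cand] / size
  }

  while (sum(unassigned) >= k) {
    seed <- match(seed_node(g, g$ids[unassigned]), g$ids)
    unassigned[seed] <- FALSE
    members <- seed
    st <- new_state(seed)
    while (length(members) < k) {
      cand <- which(unassigned)
      cost <- grown_cost(st, length(members), cand)
      pick <- cand[which.min(cost)]   # first minimum = smallest input index
      unassigned[pick] <- FALSE
      members <- c(members, pick)
      st <- grow_state(st, pick)
    }
    clusters[[length(clusters) + 1L]] <- members
    states[[length(states) + 1L]] <- st
  }

  for (i in which(unassigned)) {      # leftovers, in input order
    cost <- vapply(seq_along(clusters), function(ci) {
      grown_cost(states[[ci]], length(clusters[[ci]]), i)
    }, numeric(1))
    ci <- which.min(cost)
    clusters[[ci]] <- c(clusters[[ci]], i)
    states[[ci]] <- grow_state(states[[ci]], i)
  }

  lapply(clusters, function(m) g$ids[m])
}

#' Check k-anonymity of a partition
#'
#' @param partition list of id vectors.
#' @param k required minimum cluster size.
#' @return `TRUE` iff every cluster has at least `k` members.
#' @export
assert_k_anonymous <- function(partition, k) {
  all(lengths(partition) >= k)
}
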