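# Independent naive re-implementations of the distance and loss
# definitions, used as oracles. Deliberately written as direct nested-loop
# transcriptions of the formulas, sharing no code with the package
# implementations they check.

# All-pairs shortest-path edge counts by Floyd-Warshall on the adjacency
# matrix (Inf where unreachable, 0 on the diagonal).
naive_path_lengths <- function(adj) {
  n <- nrow(adj)
  L <- matrix(Inf, n, n)
  L[adj == 1] <- 1
  diag(L) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (L[i, k] + L[k, j] < L[i, j]) L[i, j] <- L[i, k] + L[k, j]
      }
    }
  }
  L
}

# Normalized node distance: d / mn with d the edge count and mn = d + 1
# the node count of the shortest path; 1 when unreachable.
naive_distance_matrix <- function(adj) {
  L <- naive_path_lengths(adj)
  D <- ifelse(is.infinite(L), 1, L / (L + 1))
  diag(D) <- 0
  D
}

# Lowest common ancestor by intersecting full root paths, walking the
# parent map directly.
naive_lca <- function(h, values) {
  path_up <- function(v) {
    p <- v
    while (!is.na(h$parent[[v]])) {
      v <- h$parent[[v]]
      p <- c(p, v)
    }
    p
  }
  paths <- lapply(unique(values), path_up)
  common <- Reduce(intersect, paths)
  common[which.max(h$depth[common])]
}

# Generalization loss straight from its definition: size-weighted sum of
# per-cluster numeric interval ratios and categorical subtree-height
# ratios over n * (p + q).
naive_gloss <- function(partition, records, schema) {
  n <- nrow(records)
  p <- length(schema$numerical)
  q <- length(schema$categorical)
  acc <- 0
  for (s in partition) {
    rows <- records[match(s, records$id), , drop = FALSE]
    attr_term <- 0
    for (a in schema$numerical) {
      g_lo <- min(records[[a]]); g_hi <- max(records[[a]])
      if (g_hi > g_lo) {
        attr_term <- attr_term + (max(rows[[a]]) - min(rows[[a]])) / (g_hi - g_lo)
      }
    }
    cate_term <- 0
    for (a in names(schema$categorical)) {
      h <- schema$categorical[[a]]
      anc <- naive_lca(h, rows[[a]])
      cate_term <- cate_term + h$subtree_height[[anc]] / h$height
    }
    acc <- acc + length(s) * (attr_term + cate_term)
  }
  acc / (n * (p + q))
}

# Structure loss straight from its definition: intra and pairwise inter
# losses over n (n - 1) / 4, counting edges by looping over node pairs.
naive_sloss <- function(adj, ids, partition) {
  n <- nrow(adj)
  idx <- lapply(partition, function(s) match(s, ids))
  m <- length(idx)
  total <- 0
  for (j in seq_len(m)) {
    b <- idx[[j]]
    e <- 0
    if (length(b) >= 2) {
      for (x in seq_along(b)) {
        for (y in seq_along(b)) {
          if (x < y && adj[b[x], b[y]] == 1) e <- e + 1
        }
      }
      total <- total + 2 * e * (1 - e / choose(length(b), 2))
    }
  }
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i < j) {
        e <- 0
        for (x in idx[[i]]) for (y in idx[[j]]) if (adj[x, y] == 1) e <- e + 1
        total <- total + 2 * e * (1 - e / (length(idx[[i]]) * length(idx[[j]])))
      }
    }
  }
  total / (n * (n - 1) / 4)
}

# --- fixture builders -------------------------------------------------

# Seeded random graph as a social_graph, edge probability p.
random_graph <- function(n, p = 0.3, seed = 1, ids = as.character(seq_len(n))) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj), arr.ind = TRUE)
  on <- up[stats::runif(nrow(up)) < p, , drop = FALSE]
  adj[on] <- 1L
  adj[on[, c(2, 1), drop = FALSE]] <- 1L
  social_graph(adj, ids)
}

# Seeded random partition of ids into blocks of size >= min_size.
random_partition <- function(ids, min_size = 1, seed = 1) {
  set.seed(seed)
  n <- length(ids)
  m <- max(1, sample.int(max(1, n %/% min_size), 1))
  repeat {
    assign <- sample.int(m, n, replace = TRUE)
    sizes <- tabulate(assign, m)
    keep <- sizes > 0
    if (all(sizes[keep] >= min_size)) {
      return(split(ids, assign)[as.character(which(keep))])
    }
  }
}

# Minimal schema: one numeric attribute plus one categorical with a
# two-level tree (root -> {u, v} -> leaves), used for small instances.
toy_hierarchy <- function() {
  hierarchy(list(all = list(
    east = list(A = list(), B = list()),
    west = list(C = list(), D = list())
  )))
}

toy_schema <- function() {
  attribute_schema(numerical = "x", categorical = list(city = toy_hierarchy()))
}

# Seeded random records for ids under toy_schema.
toy_records <- function(ids, seed = 1) {
  set.seed(seed)
  data.frame(id = ids,
             x = round(stats::runif(length(ids), 0, 100)),
             city = sample(c("A", "B", "C", "D"), length(ids), replace = TRUE),
             stringsAsFactors = FALSE)
}

# The 60-patient benchmark with seeded synthetic edges (mean degree 4).
benchmark_instance <- function(seed = 1) {
  recs <- table3_records()
  sch <- table3_schema()
  edges <- synth_edges(60, 4, "er", seed = seed, node_ids = recs$id)
  list(graph = social_graph_from_edges(edges, recs$id),
       records = recs, schema = sch)
}
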