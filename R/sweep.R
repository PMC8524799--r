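with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Seeded synthetic edge generator
#'
#' Generates a reproducible random edge list over `n` nodes, standing in
#' for social networks whose true wiring is unavailable. Two models:
#' `"er"` links each pair independently with probability
#' `mean_degree / (n - 1)` (Erdos–Renyi, expected mean degree as given);
#' `"ring"` builds a ring lattice joining each node to its
#' `mean_degree / 2` nearest neighbours on each side and then rewires each
#' edge's far endpoint with probability `rewire_prob` (Watts–Strogatz
#' style). Output is deterministic for a fixed seed; connectedness is not
#' guaranteed (the distance measures treat disconnected pairs as maximally
#' distant).
#'
#' @param n number of nodes (at least 2).
#' @param mean_degree target mean degree, positive and below `n`; for the
#'   ring model it must be a positive even integer.
#' @param model `"er"` or `"ring"`.
#' @param seed integer random seed.
#' @param node_ids optional character ids (default `"1" .. "n"`).
#' @param rewire_prob ring-model rewiring probability (default 0.1; 0
#'   yields the exact lattice).
#' @return Two-column character matrix of edges (possibly zero rows).
#' @export
synth_edges <- function(n, mean_degree, model = c("er", "ring"), seed,
                        node_ids = as.character(seq_len(n)),
                        rewire_prob = 0.1) {
  model <- match.arg(model)
  if (length(n) != 1 || n < 2 || n != as.integer(n)) {
    stop_parameter("n must be an integer >= 2")
  }
  if (mean_degree <= 0 || mean_degree >= n) {
    stop_parameter("mean_degree must be in (0, n)")
  }
  if (length(node_ids) != n) stop_parameter("node_ids must have length n")
  if (model == "ring" &&
      (mean_degree != as.integer(mean_degree) || mean_degree %% 2 != 0)) {
    stop_parameter("ring model needs a positive even integer mean_degree")
  }
  if (rewire_prob < 0 || rewire_prob > 1) {
    stop_parameter("rewire_prob must lie in [0, 1]")
  }
  with_seed(seed, {
    if (model == "er") {
      pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      keep <- stats::runif(nrow(pairs)) < mean_degree / (n - 1)
      pairs <- pairs[keep, , drop = FALSE]
      i <- pairs[, 1]; j <- pairs[, 2]
    } else {
      half <- mean_degree / 2
      i <- integer(0); j <- integer(0)
      for (step in seq_len(half)) {
        from <- seq_len(n)
        to <- ((from - 1 + step) %% n) + 1
        i <- c(i, pmin(from, to)[from != to])
        j <- c(j, pmax(from, to)[from != to])
      }
      el <- unique(cbind(i, j))
      i <- el[, 1]; j <- el[, 2]
      if (rewire_prob > 0 && length(i) > 0) {
        adj <- matrix(FALSE, n, n)
        adj[cbind(i, j)] <- TRUE; adj[cbind(j, i)] <- TRUE
        for (e in seq_along(i)) {
          if (stats::runif(1) < rewire_prob) {
            u <- i[e]
            forbidden <- c(u, which(adj[u, ]))
            choices <- setdiff(seq_len(n), forbidden)
            if (length(choices) > 0) {
              w <- choices[[sample.int(length(choices), 1)]]
              adj[i[e], j[e]] <- adj[j[e], i[e]] <- FALSE
              adj[u, w] <- adj[w, u] <- TRUE
              i[e] <- min(u, w); j[e] <- max(u, w)
            }
          }
        }
      }
    }
    if (length(i) == 0) return(matrix(character(0), ncol = 2))
    cbind(node_ids[i], node_ids[j])
  })
}

#' Loss sweep over the (k, a) parameter grid
#'
#' Runs [greedy_k_cluster()] and computes the full [loss_report()] for
#' every combination of the cluster-size floor `k` and attribute weight
#' `a`. The default grids are k = 3, 6, ..., 30 and a = 0, 0.2, ..., 1.
#'
#' @param g a [social_graph()].
#' @param records node-record table.
#' @param schema an [attribute_schema()].
#' @param k_grid integer vector of k values (all at most `n_nodes(g)`).
#' @param a_grid numeric vector of weights in \[0, 1\].
#' @return An object of class `loss_grid`: list with `k`, `a`, `reports`
#'   (a `|k| x |a|` matrix-shaped list of [loss_report()]s) and
#'   `partitions` (same shape, the partitions themselves).
#' @export
sweep_losses <- function(g, records, schema,
                         k_grid = seq(3, 30, by = 3),
                         a_grid = seq(0, 1, by = 0.2)) {
  if (any(k_grid > n_nodes(g))) {
    stop_parameter("k grid value %d exceeds the number of nodes (%d)",
                   max(k_grid), n_nodes(g))
  }
  records <- validate_records(records, schema)
  ranges <- global_ranges(records, schema)
  reports <- vector("list", length(k_grid) * length(a_grid))
  partitions <- vector("list", length(k_grid) * length(a_grid))
  dim(reports) <- dim(partitions) <- c(length(k_grid), length(a_grid))
  dimnames(reports) <- dimnames(partitions) <- list(k_grid, a_grid)
  for (ki in seq_along(k_grid)) {
    for (ai in seq_along(a_grid)) {
      part <- greedy_k_cluster(g, records, schema, k_grid[ki], a_grid[ai])
      partitions[[ki, ai]] <- part
      reports[[ki, ai]] <- loss_report(g, part, records, schema,
                                       k = k_grid[ki], a = a_grid[ai],
                                       ranges = ranges)
    }
  }
  structure(list(k = k_grid, a = a_grid, reports = reports,
                 partitions = partitions), class = "loss_grid")
}

#' @export
as.data.frame.loss_grid <- function(x, ...) {
  do.call(rbind, lapply(x$reports, as.data.frame))
}

#' @export
print.loss_grid <- function(x, ...) {
  df <- as.data.frame(x)
  best <- df[which.min(df$total), ]
  cat(sprintf("<loss_grid> %d x %d cells (k in %s; a in %s); min total %.6f at k=%g a=%g\n",
              length(x$k), length(x$a),
              paste(range(x$k), collapse = ".."),
              paste(range(x$a), collapse = ".."),
              best$total, best$k, best$a))
  invisible(x)
}

#' Write a loss grid as a flat CSV
#' @param x a [sweep_losses()] result.
#' @param path output CSV path (columns `k`, `a`, `gloss`, `sloss`,
#'   `total`).
#' @return `path`, invisibly.
#' @export
write_loss_grid <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

partition_encoding <- function(partition, ids) {
  canon <- lapply(partition, function(s) sort(match(s, ids)))
  canon <- canon[order(vapply(canon, min, integer(1)))]
  paste(vapply(canon, paste, character(1), collapse = ","), collapse = "|")
}

#' Exhaustive minimum-loss partition (test oracle)
#'
#' Enumerates every partition of the node set into clusters of size at
#' least `k` and returns one minimizing the total loss
#' (generalization + structure). Ties are broken by the lexicographically
#' smallest canonical cluster encoding. Intended as an oracle for small
#' instances only: refuses `n > 10` (set-partition growth is super-
#' exponential).
#'
#' @param g a [social_graph()].
#' @param records node-record table.
#' @param schema an [attribute_schema()].
#' @param k minimum cluster size.
#' @return List with `partition`, `total`, `gloss`, `sloss`.
#' @export
brute_force_partition <- function(g, records, schema, k) {
  n <- n_nodes(g)
  if (n > 10) stop_parameter("exhaustive search is capped at n <= 10 (got n = %d)", n)
  if (k < 2 || k > n) stop_parameter("k must satisfy 2 <= k <= n")
  records <- validate_records(records, schema)
  records <- records[match(g$ids, records$id), , drop = FALSE]
  ranges <- global_ranges(records, schema)
  ids <- g$ids
  adj <- g$adj
  p_plus_q <- length(schema$numerical) + length(schema$categorical)
  num_vals <- lapply(stats::setNames(schema$numerical, schema$numerical),
                     function(x) records[[x]])
  gr_width <- vapply(schema$numerical,
                     function(x) interval_size(ranges[[x]]), numeric(1))
  # per categorical attribute: pairwise lca subtree heights between nodes;
  # a block's lca height is the max over its member pairs
  lca_h <- lapply(stats::setNames(names(schema$categorical),
                                  names(schema$categorical)), function(a) {
    h <- schema$categorical[[a]]
    v <- records[[a]]
    outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
      if (v[i] == v[j]) 0L else h$subtree_height[[hier_lca(h, c(v[i], v[j]))]]
    }))
  })
  cat_height <- vapply(schema$categorical, hier_height, integer(1))
  block_weight <- function(b) {    # |b| * (Attr + Cate) of one block
    acc <- 0
    for (x in schema$numerical) {
      if (gr_width[[x]] > 0) {
        acc <- acc + (max(num_vals[[x]][b]) - min(num_vals[[x]][b])) / gr_width[[x]]
      }
    }
    for (a in names(schema$categorical)) {
      acc <- acc + max(lca_h[[a]][b, b]) / cat_height[[a]]
    }
    length(b) * acc
  }
  sl_norm <- n * (n - 1) / 4
  best <- NULL
  consider <- function(blocks) {
    if (any(lengths(blocks) < k)) return()
    gl <- sum(vapply(blocks, block_weight, numeric(1))) / (n * p_plus_q)
    sl <- 0
    m <- length(blocks)
    for (i in seq_len(m)) {
      b <- blocks[[i]]
      if (length(b) >= 2) {
        e <- sum(adj[b, b]) / 2
        sl <- sl + 2 * e * (1 - e / choose(length(b), 2))
      }
      if (i < m) {
        for (j in seq(i + 1, m)) {
          e <- sum(adj[b, blocks[[j]]])
          sl <- sl + 2 * e * (1 - e / (length(b) * length(blocks[[j]])))
        }
      }
    }
    sl <- sl / sl_norm
    tot <- gl + sl
    if (!is.null(best) && tot > best$total + 1e-15) return()
    part <- lapply(blocks, function(b) ids[b])
    enc <- partition_encoding(part, ids)
    if (is.null(best) || tot < best$total - 1e-15 ||
        (abs(tot - best$total) <= 1e-15 && enc < best$encoding)) {
      best <<- list(partition = part, total = tot, gloss = gl, sloss = sl,
                    encoding = enc)
    }
  }
  recurse <- function(i, blocks) {
    if (i > n) {
      consider(blocks)
      return()
    }
    for (b in seq_along(blocks)) {
      blocks[[b]] <- c(blocks[[b]], i)
      recurse(i + 1, blocks)
      blocks[[b]] <- blocks[[b]][-length(blocks[[b]])]
    }
    if (n - i + 1 >= k) {          # a fresh block can still reach size k
      recurse(i + 1, c(blocks, list(i)))
    }
  }
  recurse(2L, list(1L))
  best$encoding <- NULL
  best
}
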