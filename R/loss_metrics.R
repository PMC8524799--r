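#' Number of edges inside a cluster
#' @param g a [social_graph()].
#' @param s character vector of node ids, a subset of the graph's nodes.
#' @return Integer count of unordered linked pairs within `s`.
#' @export
intra_edges <- function(g, s) {
  idx <- check_ids(g, s)
  sum(g$adj[idx, idx, drop = FALSE]) %/% 2L
}

#' Number of edges between two disjoint clusters
#' @param g a [social_graph()].
#' @param si,sj disjoint character vectors of node ids.
#' @return Integer count of edges with one endpoint in each cluster.
#' @export
inter_edges <- function(g, si, sj) {
  si <- as.character(si)
  sj <- as.character(sj)
  if (length(intersect(si, sj)) > 0) {
    stop_precondition("clusters overlap on: %s",
                      paste(intersect(si, sj), collapse = ", "))
  }
  i <- check_ids(g, si)
  j <- check_ids(g, sj)
  sum(g$adj[i, j, drop = FALSE])
}

#' Intra-cluster structure loss
#'
#' For a cluster with `e` internal edges out of `choose(|s|, 2)` possible,
#' the loss is `2 e (1 - e / choose(|s|, 2))`. It is 0 when the cluster is
#' edgeless or complete (in both cases the internal wiring is fully
#' determined by the published pair `(|s|, e)`), and largest when `e` is
#' half the possible pairs, i.e. when knowing the edge count says least
#' about which pairs are linked. Singleton clusters have loss 0.
#'
#' @param g a [social_graph()].
#' @param s character vector of node ids.
#' @return Non-negative real.
#' @export
intra_structure_loss <- function(g, s) {
  m <- length(s)
  if (m < 2) return(0)
  e <- intra_edges(g, s)
  pairs <- choose(m, 2)
  2 * e * (1 - e / pairs)
}

#' Inter-cluster structure loss
#'
#' For two disjoint clusters with `e` cross edges out of `|si| * |sj|`
#' possible, the loss is `2 e (1 - e / (|si| |sj|))`: 0 when no or all
#' cross pairs are linked, largest when half are.
#'
#' @param g a [social_graph()].
#' @param si,sj disjoint character vectors of node ids.
#' @return Non-negative real.
#' @export
inter_structure_loss <- function(g, si, sj) {
  e <- inter_edges(g, si, sj)
  2 * e * (1 - e / (length(si) * length(sj)))
}

#' Structure loss of a partition
#'
#' The total intra-cluster plus pairwise inter-cluster structure loss,
#' normalized by `n (n - 1) / 4` with `n` the node count of the graph.
#' Measures how much of the original wiring is hidden by publishing only
#' per-cluster and per-cluster-pair edge counts; lies in \[0, 1\].
#'
#' @param g a [social_graph()].
#' @param partition list of disjoint id vectors covering the graph's nodes.
#' @return A number in \[0, 1\].
#' @export
structure_loss <- function(g, partition) {
  partition <- validate_partition(partition, g$ids)
  n <- n_nodes(g)
  m <- length(partition)
  total <- sum(vapply(partition, function(s) intra_structure_loss(g, s), numeric(1)))
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in seq((i + 1), m)) {
        total <- total + inter_structure_loss(g, partition[[i]], partition[[j]])
      }
    }
  }
  total / (n * (n - 1) / 4)
}

#' Analytic maxima of the structure-loss components
#'
#' For a fixed partition, the largest value the intra-cluster term can take
#' over all graphs is `sum(|s_j| (|s_j| - 1) / 4)` (attained at half the
#' possible internal edges). For the inter-cluster term two values are
#' reported: `inter_stated`, the bound `sum_{i<j} |s_i||s_j| / 4` as
#' conventionally stated alongside the intra bound, and `inter_derived`,
#' the true maximum `sum_{i<j} |s_i||s_j| / 2` obtained by maximizing the
#' pairwise loss over the integer cross-edge count (the per-pair loss at
#' `e = |s_i||s_j|/2` equals `|s_i||s_j|/2`, not `/4`). Sanity assertions
#' in this package use `inter_derived`; `inter_stated` is reported for
#' reference.
#'
#' @param partition list of id vectors (only the sizes matter).
#' @return List with `max_intra`, `max_inter_stated`, `max_inter_derived`.
#' @export
structural_loss_bounds <- function(partition) {
  sizes <- lengths(partition)
  max_intra <- sum(sizes * (sizes - 1) / 4)
  cross <- 0
  m <- length(sizes)
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      cross <- cross + sizes[i] * sum(sizes[seq(i + 1, m)])
    }
  }
  list(max_intra = max_intra,
       max_inter_stated = cross / 4,
       max_inter_derived = cross / 2)
}

#' Combined information loss
#'
#' The total loss of an anonymized release is the unweighted sum of its
#' generalization loss and its structure loss. The attribute/structure
#' weight `a` steers the clustering itself, not this report.
#'
#' @param gloss generalization loss in \[0, 1\].
#' @param sloss structure loss in \[0, 1\].
#' @return `gloss + sloss`.
#' @export
total_loss <- function(gloss, sloss) {
  if (gloss < 0 || gloss > 1 || sloss < 0 || sloss > 1) {
    stop_precondition("gloss and sloss must both lie in [0, 1]")
  }
  gloss + sloss
}

#' Full loss report for a partition
#'
#' Computes the generalization loss, structure loss, total loss, and the
#' per-cluster / per-pair structure-loss breakdown for one partition.
#'
#' @param g a [social_graph()].
#' @param partition list of disjoint id vectors covering the graph.
#' @param records node-record table.
#' @param schema an [attribute_schema()].
#' @param k,a the parameters the partition was built with (recorded in the
#'   report; `NA` if not applicable).
#' @param ranges optional precomputed [global_ranges()].
#' @return An object of class `loss_report`: list with `gloss`, `sloss`,
#'   `total`, `k`, `a`, `cluster_sizes`, `per_cluster_intra` (numeric
#'   vector) and `per_pair_inter` (symmetric matrix).
#' @export
loss_report <- function(g, partition, records, schema, k = NA, a = NA,
                        ranges = NULL) {
  partition <- validate_partition(partition, g$ids)
  gloss <- generalization_loss(partition, records, schema, ranges)
  m <- length(partition)
  intra <- vapply(partition, function(s) intra_structure_loss(g, s), numeric(1))
  inter <- matrix(0, m, m)
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        inter[i, j] <- inter[j, i] <-
          inter_structure_loss(g, partition[[i]], partition[[j]])
      }
    }
  }
  n <- n_nodes(g)
  sloss <- (sum(intra) + sum(inter[upper.tri(inter)])) / (n * (n - 1) / 4)
  structure(list(
    gloss = gloss, sloss = sloss, total = total_loss(gloss, sloss),
    k = k, a = a, cluster_sizes = lengths(partition),
    per_cluster_intra = intra, per_pair_inter = inter
  ), class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("<loss_report> k=%s a=%s | gloss=%.6f sloss=%.6f total=%.6f | %d clusters (sizes %s)\n",
              format(x$k), format(x$a), x$gloss, x$sloss, x$total,
              length(x$cluster_sizes), paste(x$cluster_sizes, collapse = ",")))
  invisible(x)
}

#' @export
as.data.frame.loss_report <- function(x, ...) {
  data.frame(k = x$k, a = x$a, gloss = x$gloss, sloss = x$sloss,
             total = x$total)
}

#' Serialize a loss report to JSON
#' @param x a [loss_report()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
loss_report_json <- function(x, path = NULL) {
  payload <- list(k = x$k, a = x$a, gloss = x$gloss, sloss = x$sloss,
                  total = x$total, cluster_sizes = x$cluster_sizes,
                  per_cluster_intra = x$per_cluster_intra,
                  per_pair_inter = x$per_pair_inter)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
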