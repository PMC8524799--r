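#' Value-generalization hierarchy
#'
#' A rooted taxonomy over the values of one categorical attribute. Leaves
#' are the publishable raw values; internal nodes are coarser categories;
#' the root generalizes every value. Publishing an internal node instead of
#' a leaf loses information in proportion to the height of the subtree it
#' roots, relative to the height of the whole tree.
#'
#' @param tree a nested named list with a single top-level name (the root);
#'   each element is itself a named list of children, with leaves as empty
#'   lists. This is the in-memory form of the JSON hierarchy format
#'   `{"root": {"child": {...}, "leaf": {}}}`.
#' @return An object of class `hierarchy` with fields `root`, `labels`,
#'   `parent` (named character, `NA` for the root), `depth` (named integer,
#'   root = 0), `subtree_height` (named integer, 0 at leaves), `height`
#'   (of the whole tree) and `leaves`.
#' @examples
#' gender <- hierarchy(list(Person = list(M = list(), F = list())))
#' hier_height(gender)  # 1
#' hier_lca(gender, c("M", "F"))  # "Person"
#' @export
hierarchy <- function(tree) {
  if (!is.list(tree) || length(tree) != 1 || is.null(names(tree))) {
    stop_input("hierarchy tree must be a named list with a single root")
  }
  parent <- character(0)
  children <- list()
  walk <- function(node, label) {
    if (!is.list(node)) stop_input("hierarchy node '%s' must be a list", label)
    kids <- names(node)
    if (length(node) > 0 && (is.null(kids) || any(kids == ""))) {
      stop_input("children of hierarchy node '%s' must be named", label)
    }
    children[[label]] <<- kids %||% character(0)
    for (k in kids) {
      if (k %in% names(children) || k %in% names(parent) && !is.na(parent[[k]])) {
        stop_input("duplicate label '%s' in hierarchy", k)
      }
      parent[[k]] <<- label
      walk(node[[k]], k)
    }
  }
  root <- names(tree)
  walk(tree[[root]], root)
  labels <- c(root, names(parent))
  if (anyDuplicated(labels)) {
    stop_input("duplicate label in hierarchy: %s",
               paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  depth <- stats::setNames(integer(length(labels)), labels)
  for (lab in names(parent)) depth[[lab]] <- depth[[parent[[lab]]]] + 1L
  sub_h <- stats::setNames(integer(length(labels)), labels)
  # children were recorded pre-order, so reversing visits children first
  for (lab in rev(labels)) {
    kids <- children[[lab]] %||% character(0)
    sub_h[[lab]] <- if (length(kids) == 0) 0L else max(sub_h[kids]) + 1L
  }
  leaves <- labels[vapply(labels, function(l) length(children[[l]] %||% character(0)) == 0, logical(1))]
  h <- structure(list(
    root = root, labels = labels,
    parent = c(stats::setNames(NA_character_, root), parent),
    depth = depth, subtree_height = sub_h,
    height = sub_h[[root]], leaves = leaves
  ), class = "hierarchy")
  if (h$height < 1L) stop_input("hierarchy must have height >= 1 (root plus at least one leaf)")
  h
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.hierarchy <- function(x, ...) {
  cat(sprintf("<hierarchy> root '%s', %d labels, height %d\n",
              x$root, length(x$labels), x$height))
  invisible(x)
}

#' Height of a hierarchy
#' @param h a [hierarchy()].
#' @return Integer: the longest root-to-leaf edge count.
#' @export
hier_height <- function(h) h$height

#' Height of the subtree rooted at a node
#' @param h a [hierarchy()].
#' @param node a label of `h`.
#' @return Integer subtree height; 0 when `node` is a leaf.
#' @export
hier_subtree_height <- function(h, node) {
  if (!node %in% h$labels) stop_input("unknown hierarchy label: %s", node)
  h$subtree_height[[node]]
}

hier_path_to_root <- function(h, node) {
  path <- node
  while (!is.na(h$parent[[node]])) {
    node <- h$parent[[node]]
    path <- c(path, node)
  }
  path
}

#' Lowest common ancestor of a set of values
#'
#' The deepest hierarchy node that is an ancestor-or-self of every given
#' value; this is the most specific label a cluster containing those values
#' can publish.
#'
#' @param h a [hierarchy()].
#' @param values non-empty character vector of labels of `h`.
#' @return A single label of `h`.
#' @export
hier_lca <- function(h, values) {
  values <- unique(as.character(values))
  if (length(values) == 0) stop_precondition("values must be non-empty")
  unknown <- setdiff(values, h$labels)
  if (length(unknown) > 0) {
    stop_input("unknown hierarchy label: %s", paste(unknown, collapse = ", "))
  }
  anc <- Reduce(function(a, b) {
    keep <- a[a %in% b]   # both paths end at the root, in root-last order
    keep
  }, lapply(values, function(v) hier_path_to_root(h, v)))
  anc[[1]]  # deepest surviving common ancestor
}

#' Generalize a node by a number of hierarchy levels
#'
#' Climbs `levels` steps from `node` toward the root (stopping at the
#' root). Level 0 returns the node unchanged.
#'
#' @param h a [hierarchy()].
#' @param node a label of `h`.
#' @param levels non-negative integer number of steps.
#' @return A label of `h`.
#' @export
hier_ancestor <- function(h, node, levels) {
  if (!node %in% h$labels) stop_input("unknown hierarchy label: %s", node)
  if (levels < 0) stop_parameter("levels must be non-negative")
  for (i in seq_len(levels)) {
    p <- h$parent[[node]]
    if (is.na(p)) break
    node <- p
  }
  node
}

#' Flat two-level hierarchy over a set of raw values
#'
#' Convenience constructor for attributes like gender or smoking status:
#' a root with every observed value as a direct leaf (height 1).
#'
#' @param values character vector of raw values (duplicates ignored).
#' @param root label for the root node.
#' @return A [hierarchy()].
#' @export
flat_hierarchy <- function(values, root = "*") {
  values <- unique(as.character(values))
  kids <- stats::setNames(rep(list(list()), length(values)), values)
  hierarchy(stats::setNames(list(kids), root))
}

#' Prefix hierarchy for postal codes
#'
#' Builds the three-level taxonomy leaf (full code) -> leading-digit prefix
#' -> root, i.e. a tree of height 2, from the codes observed in the data.
#'
#' @param values character vector of zip/postal codes.
#' @param prefix_width number of leading characters forming the middle
#'   level (default 3).
#' @param root label for the root node.
#' @return A [hierarchy()].
#' @export
zip_prefix_hierarchy <- function(values, prefix_width = 3, root = "zip:*") {
  values <- unique(as.character(values))
  pref <- substr(values, 1, prefix_width)
  groups <- split(values, pref)
  mid <- lapply(groups, function(v) {
    stats::setNames(rep(list(list()), length(v)), v)
  })
  names(mid) <- paste0(names(groups), "*")
  hierarchy(stats::setNames(list(mid), root))
}

#' Convert a hierarchy back to its nested-list (JSON) form
#'
#' Inverse of [hierarchy()]: returns the nested named list whose JSON
#' rendering is the on-disk hierarchy format.
#'
#' @param h a [hierarchy()].
#' @return A nested named list with a single top-level name.
#' @export
hierarchy_to_list <- function(h) {
  kids_of <- split(names(h$parent)[!is.na(h$parent)],
                   h$parent[!is.na(h$parent)])
  build <- function(label) {
    kids <- kids_of[[label]] %||% character(0)
    kids <- kids[order(match(kids, h$labels))]  # original insertion order
    stats::setNames(lapply(kids, build), kids)
  }
  stats::setNames(list(build(h$root)), h$root)
}

#' Read hierarchies from a JSON file
#'
#' The file maps each categorical attribute name to a nested-object tree
#' `{"root": {"child": {...}, "leaf": {}}}` with leaves as empty objects.
#'
#' @param path path to the JSON file.
#' @return Named list of [hierarchy()] objects.
#' @export
read_hierarchies <- function(path) {
  if (!file.exists(path)) stop_input("hierarchy file not found: %s", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw) || is.null(names(raw))) {
    stop_input("hierarchy file must map attribute names to trees: %s", path)
  }
  lapply(raw, hierarchy)
}

#' Attribute schema
#'
#' Declares which columns of a node-attribute table are numerical and which
#' are categorical, binding each categorical attribute to its
#' value-generalization hierarchy. The sensitive attribute (e.g. diagnosis)
#' is deliberately left out of the schema: it is never used as a clustering
#' feature.
#'
#' @param numerical character vector of numerical attribute names (may be
#'   empty).
#' @param categorical named list of [hierarchy()] objects, one per
#'   categorical attribute (may be empty). At least one attribute in total
#'   is required.
#' @return An object of class `attribute_schema`.
#' @export
attribute_schema <- function(numerical = character(0), categorical = list()) {
  numerical <- as.character(numerical)
  if (length(categorical) > 0) {
    if (is.null(names(categorical)) || any(names(categorical) == "")) {
      stop_input("categorical hierarchies must be a named list")
    }
    ok <- vapply(categorical, inherits, logical(1), what = "hierarchy")
    if (!all(ok)) stop_input("every categorical attribute needs a hierarchy object")
  }
  all_names <- c(numerical, names(categorical))
  if (length(all_names) < 1) stop_input("schema needs at least one attribute")
  if (anyDuplicated(all_names)) {
    stop_input("attribute names must be unique across numerical and categorical sets")
  }
  structure(list(numerical = numerical, categorical = categorical),
            class = "attribute_schema")
}

#' @export
print.attribute_schema <- function(x, ...) {
  cat(sprintf("<attribute_schema> %d numerical (%s), %d categorical (%s)\n",
              length(x$numerical), paste(x$numerical, collapse = ", "),
              length(x$categorical), paste(names(x$categorical), collapse = ", ")))
  invisible(x)
}

schema_attrs <- function(schema) c(schema$numerical, names(schema$categorical))

#' Validate a node-record table against a schema
#'
#' Checks that the table has an `id` column with unique ids, that every
#' schema attribute is present, that numerical values are finite numbers,
#' and that every categorical value is a leaf of its hierarchy. Missing
#' values are rejected (no imputation).
#'
#' @param records data frame with an `id` column plus one column per schema
#'   attribute.
#' @param schema an [attribute_schema()].
#' @return `records`, invisibly, with `id` coerced to character.
#' @export
validate_records <- function(records, schema) {
  if (!is.data.frame(records)) stop_input("records must be a data frame")
  if (!"id" %in% names(records)) stop_input("records must have an 'id' column")
  records$id <- as.character(records$id)
  if (anyDuplicated(records$id)) {
    stop_input("duplicate record id: %s",
               paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  }
  missing_cols <- setdiff(schema_attrs(schema), names(records))
  if (length(missing_cols) > 0) {
    stop_input("records are missing schema column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  for (a in schema$numerical) {
    v <- records[[a]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      stop_input("numerical attribute '%s' must be finite and non-missing", a)
    }
  }
  for (a in names(schema$categorical)) {
    v <- as.character(records[[a]])
    if (anyNA(v)) stop_input("categorical attribute '%s' has missing values", a)
    h <- schema$categorical[[a]]
    bad <- setdiff(unique(v), h$leaves)
    if (length(bad) > 0) {
      stop_input("value(s) of '%s' not leaves of its hierarchy: %s",
                 a, paste(bad, collapse = ", "))
    }
    records[[a]] <- v
  }
  invisible(records)
}

#' Generalized record of a cluster
#'
#' The published summary of a cluster: each numerical attribute is replaced
#' by the `[min, max]` interval of the members' values, each categorical
#' attribute by the lowest common ancestor of the members' values in its
#' hierarchy.
#'
#' @param records data frame of the cluster members (rows of the full node
#'   table).
#' @param schema an [attribute_schema()].
#' @return An object of class `generalized_record`: a list with `numeric`
#'   (named list of `c(lo, hi)`) and `categorical` (named character of
#'   hierarchy labels).
#' @export
generalize_cluster <- function(records, schema) {
  if (NROW(records) == 0) stop_precondition("cluster must be non-empty")
  num <- lapply(stats::setNames(schema$numerical, schema$numerical), function(a) {
    v <- records[[a]]
    c(lo = min(v), hi = max(v))
  })
  cat_ <- vapply(stats::setNames(names(schema$categorical), names(schema$categorical)),
                 function(a) hier_lca(schema$categorical[[a]], records[[a]]),
                 character(1))
  structure(list(numeric = num, categorical = cat_),
            class = "generalized_record")
}

#' @export
format.generalized_record <- function(x, ...) {
  num <- vapply(names(x$numeric), function(a) {
    iv <- x$numeric[[a]]
    sprintf("%s=[%g..%g]", a, iv[["lo"]], iv[["hi"]])
  }, character(1))
  cat_ <- sprintf("%s=%s", names(x$categorical), x$categorical)
  paste(c(num, cat_), collapse = ", ")
}

#' @export
print.generalized_record <- function(x, ...) {
  cat("<generalized_record>", format(x), "\n")
  invisible(x)
}

#' Width of a generalization interval
#' @param interval numeric `c(lo, hi)` with `lo <= hi`.
#' @return `hi - lo`.
#' @export
interval_size <- function(interval) {
  if (length(interval) != 2 || interval[[2]] < interval[[1]]) {
    stop_input("interval must be c(lo, hi) with lo <= hi")
  }
  unname(interval[[2]] - interval[[1]])
}

#' Global numeric attribute ranges
#'
#' The `[min, max]` of each numerical attribute over the entire dataset,
#' computed once before clustering; the denominators of the numerical
#' generalization-loss terms.
#'
#' @param records the full node-record table.
#' @param schema an [attribute_schema()].
#' @return Named list of `c(lo, hi)` per numerical attribute.
#' @export
global_ranges <- function(records, schema) {
  lapply(stats::setNames(schema$numerical, schema$numerical), function(a) {
    v <- records[[a]]
    c(lo = min(v), hi = max(v))
  })
}

#' Numerical generalization-loss factor of a cluster
#'
#' Sum over numerical attributes of the cluster interval width divided by
#' the global attribute range. An attribute whose global range is zero
#' contributes 0: every cluster is already fully specific on it.
#'
#' @param cluster_records data frame of the cluster members.
#' @param schema an [attribute_schema()].
#' @param ranges global ranges from [global_ranges()].
#' @return Non-negative real (at most the number of numerical attributes).
#' @export
attr_loss_factor <- function(cluster_records, schema, ranges) {
  if (NROW(cluster_records) == 0) stop_precondition("cluster must be non-empty")
  total <- 0
  for (a in schema$numerical) {
    gr <- interval_size(ranges[[a]])
    if (gr > 0) {
      v <- cluster_records[[a]]
      total <- total + (max(v) - min(v)) / gr
    }
  }
  total
}

#' Categorical generalization-loss factor of a cluster
#'
#' Sum over categorical attributes of the height of the subtree rooted at
#' the cluster's lowest common ancestor, divided by the height of the whole
#' hierarchy. Each term is in \[0, 1\]: 0 when all members share one leaf
#' value, 1 when the cluster generalizes to the root.
#'
#' @param cluster_records data frame of the cluster members.
#' @param schema an [attribute_schema()].
#' @return Non-negative real (at most the number of categorical attributes).
#' @export
cate_loss_factor <- function(cluster_records, schema) {
  if (NROW(cluster_records) == 0) stop_precondition("cluster must be non-empty")
  total <- 0
  for (a in names(schema$categorical)) {
    h <- schema$categorical[[a]]
    anc <- hier_lca(h, cluster_records[[a]])
    total <- total + h$subtree_height[[anc]] / h$height
  }
  total
}

#' Generalization loss of a partition
#'
#' The normalized information loss incurred by publishing each cluster's
#' generalized record instead of its members' raw attributes:
#' the cluster-size-weighted mean of the per-cluster numerical and
#' categorical loss factors, divided by the number of attributes. 0 for a
#' partition of singletons; 1 when a single cluster spans every global
#' numeric range and generalizes every categorical attribute to its root.
#'
#' @param partition list of disjoint character id vectors covering all
#'   record ids.
#' @param records the full node-record table (with `id` column).
#' @param schema an [attribute_schema()].
#' @param ranges optional precomputed [global_ranges()].
#' @return A number in \[0, 1\].
#' @export
generalization_loss <- function(partition, records, schema, ranges = NULL) {
  records <- validate_records(records, schema)
  validate_partition(partition, records$id)
  ranges <- ranges %||% global_ranges(records, schema)
  n <- nrow(records)
  p_plus_q <- length(schema$numerical) + length(schema$categorical)
  num <- 0
  for (s in partition) {
    cl <- records[match(s, records$id), , drop = FALSE]
    num <- num + length(s) *
      (attr_loss_factor(cl, schema, ranges) + cate_loss_factor(cl, schema))
  }
  num / (n * p_plus_q)
}

#' Validate a partition of a node-id set
#'
#' Clusters must be non-empty, pairwise disjoint, and their union must be
#' exactly the given id set.
#'
#' @param partition list of character id vectors.
#' @param ids the full id set the partition must cover.
#' @return `partition` (ids as character), invisibly.
#' @export
validate_partition <- function(partition, ids) {
  if (!is.list(partition) || length(partition) < 1) {
    stop_validation("partition must be a non-empty list of clusters")
  }
  partition <- lapply(partition, as.character)
  sizes <- lengths(partition)
  if (any(sizes == 0)) stop_validation("partition contains an empty cluster")
  all_members <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop_validation("partition clusters overlap on: %s",
                    paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  }
  ids <- as.character(ids)
  if (!setequal(all_members, ids) || length(all_members) != length(ids)) {
    stop_validation("partition does not cover the node set exactly")
  }
  invisible(partition)
}
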