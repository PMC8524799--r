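#' Masked (anonymized) social graph
#'
#' The published form of an anonymized network: one supernode per cluster,
#' carrying the cluster's generalized record, its member count and its
#' internal edge count, and one superedge per cluster pair with at least
#' one cross edge, carrying the cross-edge count. Raw node ids never appear
#' in the masked graph; supernodes are named `SC1 .. SCm` in cluster order.
#'
#' @param g a [social_graph()].
#' @param partition list of disjoint id vectors covering the graph.
#' @param records node-record table.
#' @param schema an [attribute_schema()].
#' @param sensitive optional name of a column of `records` (outside the
#'   schema) whose values are carried through at cluster level only, as an
#'   unordered multiset per supernode (e.g. the diagnoses of a cluster).
#' @return An object of class `masked_graph`: list with `supernodes` (list
#'   of `name`, `size`, `intra_edges`, `gen` ([generalize_cluster()]
#'   record), optional `sensitive`), `superedges` (data frame `from`, `to`,
#'   `cross_count`), `n_nodes`, `n_edges`, and `schema_attrs` (which
#'   attributes are numeric vs categorical, needed to round-trip files).
#' @export
build_masked_graph <- function(g, partition, records, schema, sensitive = NULL) {
  partition <- tryCatch(validate_partition(partition, g$ids),
                        kanonet_validation_error = function(e) {
                          stop_validation("partition does not match the graph: %s",
                                          conditionMessage(e))
                        })
  records <- validate_records(records, schema)
  if (!setequal(records$id, g$ids)) {
    stop_validation("record ids do not cover the graph's node set")
  }
  if (!is.null(sensitive) && !sensitive %in% names(records)) {
    stop_input("sensitive column '%s' not found in records", sensitive)
  }
  m <- length(partition)
  supernodes <- lapply(seq_len(m), function(i) {
    s <- partition[[i]]
    cl <- records[match(s, records$id), , drop = FALSE]
    sn <- list(name = paste0("SC", i),
               size = length(s),
               intra_edges = intra_edges(g, s),
               gen = generalize_cluster(cl, schema))
    if (!is.null(sensitive)) sn$sensitive <- sort(as.character(cl[[sensitive]]))
    sn
  })
  from <- character(0); to <- character(0); cnt <- integer(0)
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        e <- inter_edges(g, partition[[i]], partition[[j]])
        if (e > 0) {
          from <- c(from, paste0("SC", i))
          to <- c(to, paste0("SC", j))
          cnt <- c(cnt, e)
        }
      }
    }
  }
  structure(list(
    supernodes = supernodes,
    superedges = data.frame(from = from, to = to, cross_count = cnt,
                            stringsAsFactors = FALSE),
    n_nodes = n_nodes(g), n_edges = n_edges(g),
    schema_attrs = list(numerical = schema$numerical,
                        categorical = names(schema$categorical))
  ), class = "masked_graph")
}

#' @export
print.masked_graph <- function(x, ...) {
  cat(sprintf("<masked_graph> %d supernodes over %d nodes, %d superedges (%d edges total)\n",
              length(x$supernodes), x$n_nodes, nrow(x$superedges), x$n_edges))
  invisible(x)
}

interval_string <- function(iv) sprintf("%g..%g", iv[["lo"]], iv[["hi"]])

parse_interval <- function(s) {
  parts <- strsplit(s, "..", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop_input("cannot parse interval string '%s'", s)
  c(lo = as.numeric(parts[1]), hi = as.numeric(parts[2]))
}

#' Write a masked graph to GraphML or JSON
#'
#' GraphML carries the supernodes as vertices (attributes: `size`,
#' `intra_edges`, one attribute per schema column — numeric intervals as
#' `"lo..hi"` strings, categorical generalizations as hierarchy labels —
#' and optionally `sensitive` as a `|`-joined multiset) and the superedges
#' with a `cross_count` attribute. The JSON format is a direct document
#' rendering of the same object. Both round-trip losslessly through
#' [read_masked_graph()].
#'
#' @param m a [build_masked_graph()] result.
#' @param path output file path.
#' @param format `"graphml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_masked_graph <- function(m, path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      n_nodes = m$n_nodes, n_edges = m$n_edges,
      schema_attrs = m$schema_attrs,
      supernodes = lapply(m$supernodes, function(sn) {
        out <- list(name = sn$name, size = sn$size,
                    intra_edges = sn$intra_edges,
                    numeric = lapply(sn$gen$numeric, function(iv)
                      list(lo = iv[["lo"]], hi = iv[["hi"]])),
                    categorical = as.list(sn$gen$categorical))
        if (!is.null(sn$sensitive)) out$sensitive <- sn$sensitive
        out
      }),
      superedges = m$superedges
    )
    ok <- tryCatch({
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop_input("cannot write masked graph to '%s'", path)
    return(invisible(path))
  }
  nm <- vapply(m$supernodes, `[[`, character(1), "name")
  ig <- igraph::make_empty_graph(n = length(nm), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = nm)
  ig <- igraph::set_vertex_attr(ig, "size", value =
    vapply(m$supernodes, `[[`, numeric(1), "size"))
  ig <- igraph::set_vertex_attr(ig, "intra_edges", value =
    vapply(m$supernodes, `[[`, numeric(1), "intra_edges"))
  for (a in m$schema_attrs$numerical) {
    ig <- igraph::set_vertex_attr(ig, a, value = vapply(
      m$supernodes, function(sn) interval_string(sn$gen$numeric[[a]]), character(1)))
  }
  for (a in m$schema_attrs$categorical) {
    ig <- igraph::set_vertex_attr(ig, a, value = vapply(
      m$supernodes, function(sn) sn$gen$categorical[[a]], character(1)))
  }
  has_sens <- !is.null(m$supernodes[[1]]$sensitive)
  if (has_sens) {
    ig <- igraph::set_vertex_attr(ig, "sensitive", value = vapply(
      m$supernodes, function(sn) paste(sn$sensitive, collapse = "|"), character(1)))
  }
  if (nrow(m$superedges) > 0) {
    ig <- igraph::add_edges(ig, rbind(m$superedges$from, m$superedges$to))
    ig <- igraph::set_edge_attr(ig, "cross_count", value = m$superedges$cross_count)
  }
  ig <- igraph::set_graph_attr(ig, "n_nodes", m$n_nodes)
  ig <- igraph::set_graph_attr(ig, "n_edges", m$n_edges)
  ig <- igraph::set_graph_attr(ig, "numerical_attrs",
                               paste(m$schema_attrs$numerical, collapse = ","))
  ig <- igraph::set_graph_attr(ig, "categorical_attrs",
                               paste(m$schema_attrs$categorical, collapse = ","))
  ok <- tryCatch({
    igraph::write_graph(ig, path, format = "graphml")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_input("cannot write masked graph to '%s'", path)
  invisible(path)
}

#' Read a masked graph written by [write_masked_graph()]
#'
#' @param path input file path.
#' @param format `"graphml"` or `"json"`.
#' @return A `masked_graph` object equal to the one written.
#' @export
read_masked_graph <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("masked-graph file not found: %s", path)
  if (format == "json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    supernodes <- lapply(doc$supernodes, function(sn) {
      gen <- structure(list(
        numeric = lapply(sn$numeric, function(iv)
          c(lo = as.numeric(iv$lo), hi = as.numeric(iv$hi))),
        categorical = vapply(sn$categorical, as.character, character(1))
      ), class = "generalized_record")
      out <- list(name = sn$name, size = as.integer(sn$size),
                  intra_edges = as.integer(sn$intra_edges), gen = gen)
      if (!is.null(sn$sensitive)) {
        out$sensitive <- vapply(sn$sensitive, as.character, character(1),
                                USE.NAMES = FALSE)
      }
      out
    })
    se <- doc$superedges
    superedges <- if (length(se) == 0) {
      data.frame(from = character(0), to = character(0),
                 cross_count = integer(0), stringsAsFactors = FALSE)
    } else {
      data.frame(from = vapply(se, `[[`, character(1), "from"),
                 to = vapply(se, `[[`, character(1), "to"),
                 cross_count = vapply(se, function(e) as.integer(e$cross_count),
                                      integer(1)),
                 stringsAsFactors = FALSE)
    }
    return(structure(list(
      supernodes = supernodes, superedges = superedges,
      n_nodes = as.integer(doc$n_nodes), n_edges = as.integer(doc$n_edges),
      schema_attrs = list(
        numerical = vapply(doc$schema_attrs$numerical, as.character,
                           character(1), USE.NAMES = FALSE),
        categorical = vapply(doc$schema_attrs$categorical, as.character,
                             character(1), USE.NAMES = FALSE))
    ), class = "masked_graph"))
  }
  ig <- igraph::read_graph(path, format = "graphml")
  num_attrs <- igraph::graph_attr(ig, "numerical_attrs")
  cat_attrs <- igraph::graph_attr(ig, "categorical_attrs")
  num_attrs <- if (nzchar(num_attrs)) strsplit(num_attrs, ",", fixed = TRUE)[[1]] else character(0)
  cat_attrs <- if (nzchar(cat_attrs)) strsplit(cat_attrs, ",", fixed = TRUE)[[1]] else character(0)
  va <- igraph::vertex_attr_names(ig)
  nm <- igraph::vertex_attr(ig, "name")
  supernodes <- lapply(seq_along(nm), function(i) {
    gen <- structure(list(
      numeric = lapply(stats::setNames(num_attrs, num_attrs), function(a)
        parse_interval(igraph::vertex_attr(ig, a)[i])),
      categorical = vapply(stats::setNames(cat_attrs, cat_attrs), function(a)
        igraph::vertex_attr(ig, a)[i], character(1))
    ), class = "generalized_record")
    out <- list(name = nm[i],
                size = as.integer(igraph::vertex_attr(ig, "size")[i]),
                intra_edges = as.integer(igraph::vertex_attr(ig, "intra_edges")[i]),
                gen = gen)
    if ("sensitive" %in% va) {
      out$sensitive <- strsplit(igraph::vertex_attr(ig, "sensitive")[i], "|",
                                fixed = TRUE)[[1]]
    }
    out
  })
  el <- igraph::as_edgelist(ig, names = TRUE)
  superedges <- if (nrow(el) == 0) {
    data.frame(from = character(0), to = character(0),
               cross_count = integer(0), stringsAsFactors = FALSE)
  } else {
    data.frame(from = el[, 1], to = el[, 2],
               cross_count = as.integer(igraph::edge_attr(ig, "cross_count")),
               stringsAsFactors = FALSE)
  }
  structure(list(
    supernodes = supernodes, superedges = superedges,
    n_nodes = as.integer(igraph::graph_attr(ig, "n_nodes")),
    n_edges = as.integer(igraph::graph_attr(ig, "n_edges")),
    schema_attrs = list(numerical = num_attrs, categorical = cat_attrs)
  ), class = "masked_graph")
}

#' Read and cross-validate the four input files
#'
#' Reads the node-attribute CSV (header `id,<attr>,...`), the edge list
#' (two columns, tab- or comma-separated, optional header), the schema JSON
#' (mapping each attribute column to `"numerical"` or `"categorical"`, the
#' latter optionally `{"type": "categorical", "hierarchy": "<name>"}`), and
#' the hierarchy JSON (see [read_hierarchies()]). Node order — the
#' clustering tie-break order — is the CSV row order. Each malformed-input
#' class (duplicate id, unparseable number, unknown category label, edge
#' referencing an absent id, schema/hierarchy mismatch) raises a distinct,
#' named input error.
#'
#' @param nodes_csv path to the node-attribute CSV.
#' @param edges_file path to the edge list.
#' @param schema_json path to the schema JSON.
#' @param hierarchy_json path to the hierarchy JSON.
#' @return List with `graph` ([social_graph()]), `records` (data frame) and
#'   `schema` ([attribute_schema()]); columns of `records` not in the
#'   schema (e.g. a sensitive diagnosis column) are carried through
#'   unvalidated.
#' @export
read_inputs <- function(nodes_csv, edges_file, schema_json, hierarchy_json) {
  for (f in c(nodes_csv, edges_file, schema_json, hierarchy_json)) {
    if (!file.exists(f)) stop_input("input file not found: %s", f)
  }
  records <- utils::read.csv(nodes_csv, colClasses = "character",
                             check.names = FALSE, strip.white = TRUE)
  if (!"id" %in% names(records)) {
    stop_input("node table %s must have an 'id' header column", nodes_csv)
  }
  hiers <- read_hierarchies(hierarchy_json)
  sdoc <- jsonlite::fromJSON(schema_json, simplifyVector = FALSE)
  if (!is.list(sdoc) || is.null(names(sdoc))) {
    stop_input("schema file must map column names to attribute kinds")
  }
  numerical <- character(0)
  categorical <- list()
  for (col in names(sdoc)) {
    if (!col %in% names(records)) {
      stop_input("schema column '%s' not found in node table", col)
    }
    entry <- sdoc[[col]]
    kind <- if (is.character(entry)) entry else entry$type
    if (identical(kind, "numerical")) {
      numerical <- c(numerical, col)
      parsed <- suppressWarnings(as.numeric(records[[col]]))
      bad <- which(is.na(parsed))
      if (length(bad) > 0) {
        stop_input("row %d, column '%s': cannot parse '%s' as a number",
                   bad[1], col, records[[col]][bad[1]])
      }
      records[[col]] <- parsed
    } else if (identical(kind, "categorical")) {
      hname <- if (is.character(entry)) col else (entry$hierarchy %||% col)
      if (!hname %in% names(hiers)) {
        stop_input("no hierarchy named '%s' for categorical column '%s'",
                   hname, col)
      }
      categorical[[col]] <- hiers[[hname]]
    } else {
      stop_input("schema column '%s': kind must be 'numerical' or 'categorical'",
                 col)
    }
  }
  schema <- attribute_schema(numerical, categorical)
  records <- validate_records(records, schema)
  edges <- read_edge_file(edges_file, records$id)
  graph <- social_graph_from_edges(edges, records$id)
  list(graph = graph, records = records, schema = schema)
}

#' Read a two-column edge list file
#'
#' Tab- or comma-separated, one edge per line, ids as strings. A first line
#' whose fields are not both known node ids is treated as a header and
#' skipped.
#'
#' @param path edge-list file.
#' @param node_ids known node ids (used for header detection only; unknown
#'   ids in data lines surface later as reference errors).
#' @return Two-column character matrix (possibly zero rows).
#' @export
read_edge_file <- function(path, node_ids) {
  if (!file.exists(path)) stop_input("edge file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(matrix(character(0), ncol = 2))
  sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    stop_input("edge file line %d does not have two %s-separated fields",
               bad[1], if (sep == "\t") "tab" else "comma")
  }
  mat <- do.call(rbind, lapply(parts, trimws))
  node_ids <- as.character(node_ids)
  if (!(mat[1, 1] %in% node_ids && mat[1, 2] %in% node_ids) &&
      nrow(mat) > 1) {
    mat <- mat[-1, , drop = FALSE]   # header line
  }
  mat
}

#' Write a node-record table in canonical form
#'
#' Canonical field order (`id` first, then schema attributes, then any
#' extra columns in their current order) so that accepted inputs
#' re-serialize byte-stably.
#'
#' @param records validated node-record table.
#' @param schema an [attribute_schema()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_node_table <- function(records, schema, path) {
  canon <- c("id", schema_attrs(schema))
  extra <- setdiff(names(records), canon)
  utils::write.csv(records[, c(canon, extra), drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an edge list file (tab-separated, canonical node order)
#' @param g a [social_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_file <- function(g, path) {
  el <- edge_list(g)
  utils::write.table(el, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
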