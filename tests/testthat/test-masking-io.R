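test_that("masked graph carries generalized supernodes, sizes and edge counts", {
  ids <- c("A", "B", "C", "D")
  g <- social_graph_from_edges(cbind(ids[-4], ids[-1]), ids)  # path
  recs <- data.frame(id = ids, x = c(1, 2, 3, 4),
                     city = c("A", "B", "C", "D"), stringsAsFactors = FALSE)
  m <- build_masked_graph(g, list(c("A", "B"), c("C", "D")), recs, toy_schema())
  expect_length(m$supernodes, 2)
  expect_equal(vapply(m$supernodes, `[[`, integer(1), "size"), c(2L, 2L))
  expect_equal(vapply(m$supernodes, `[[`, integer(1), "intra_edges"), c(1L, 1L))
  expect_equal(m$superedges$cross_count, 1L)
  expect_equal(m$supernodes[[1]]$gen$numeric$x, c(lo = 1, hi = 2))
  expect_equal(unname(m$supernodes[[2]]$gen$categorical["city"]), "west")
  # raw node ids never appear
  expect_false(any(ids %in% c(vapply(m$supernodes, `[[`, character(1), "name"),
                              m$superedges$from, m$superedges$to)))

  whole <- build_masked_graph(g, list(ids), recs, toy_schema())
  expect_length(whole$supernodes, 1)
  expect_equal(whole$supernodes[[1]]$intra_edges, 3L)
  expect_equal(nrow(whole$superedges), 0L)

  none <- social_graph_from_edges(NULL, ids)
  empty <- build_masked_graph(none, list(c("A", "B"), c("C", "D")), recs,
                              toy_schema())
  expect_equal(vapply(empty$supernodes, `[[`, integer(1), "intra_edges"),
               c(0L, 0L))
  expect_equal(nrow(empty$superedges), 0L)

  expect_error(build_masked_graph(g, list(c("A", "B")), recs, toy_schema()),
               class = "kanonet_validation_error")
})

test_that("edge conservation holds in the masked graph across a full sweep", {
  inst <- benchmark_instance(seed = 1)
  grid <- sweep_losses(inst$graph, inst$records, inst$schema,
                       k_grid = c(3, 9, 15, 24, 30),
                       a_grid = c(0, 0.4, 1))
  for (part in grid$partitions) {
    m <- build_masked_graph(inst$graph, part, inst$records, inst$schema,
                            sensitive = "Diagnosis")
    expect_equal(sum(vapply(m$supernodes, `[[`, integer(1), "size")),
                 n_nodes(inst$graph))
    expect_equal(sum(vapply(m$supernodes, `[[`, integer(1), "intra_edges")) +
                   sum(m$superedges$cross_count),
                 n_edges(inst$graph))
  }
})

test_that("masked graphs round-trip losslessly through GraphML and JSON", {
  inst <- benchmark_instance(seed = 4)
  part <- greedy_k_cluster(inst$graph, inst$records, inst$schema, 10, 0.5)
  m <- build_masked_graph(inst$graph, part, inst$records, inst$schema,
                          sensitive = "Diagnosis")
  for (fmt in c("graphml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_masked_graph(m, path, format = fmt)
    expect_equal(read_masked_graph(path, format = fmt), m)
  }
  # a masked graph with no superedges still round-trips
  ids <- c("A", "B", "C", "D")
  none <- social_graph_from_edges(NULL, ids)
  recs <- data.frame(id = ids, x = 1:4, city = c("A", "B", "C", "D"),
                     stringsAsFactors = FALSE)
  m0 <- build_masked_graph(none, list(c("A", "B"), c("C", "D")), recs,
                           toy_schema())
  for (fmt in c("graphml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_masked_graph(m0, path, format = fmt)
    rt <- read_masked_graph(path, format = fmt)
    expect_equal(nrow(rt$superedges), 0L)
    expect_equal(rt, m0)
  }
})

test_that("the packaged input files parse, cross-validate and re-serialize byte-stably", {
  nodes <- system.file("extdata", "patients60_nodes.csv", package = "kanonet")
  edges <- system.file("extdata", "patients60_synthetic_edges.tsv",
                       package = "kanonet")
  schema <- system.file("extdata", "patients60_schema.json", package = "kanonet")
  hier <- system.file("extdata", "patients60_hierarchies.json",
                      package = "kanonet")
  inp <- read_inputs(nodes, edges, schema, hier)
  expect_equal(nrow(inp$records), 60L)
  expect_equal(inp$schema$numerical, "Age")
  expect_setequal(names(inp$schema$categorical),
                  c("Gender", "Marriage", "Smoke", "Zip"))
  # the packaged CSV is exactly the embedded fixture (canonical column order)
  expect_equal(inp$records[, names(table3_records())], table3_records())
  # node order = CSV row order
  expect_identical(inp$graph$ids, inp$records$id)
  # canonical re-serialization is byte-identical
  out <- withr::local_tempfile(fileext = ".csv")
  write_node_table(inp$records, inp$schema, out)
  expect_identical(readLines(out), readLines(nodes))
})

test_that("each malformed-input class raises its own named error", {
  nodes <- system.file("extdata", "patients60_nodes.csv", package = "kanonet")
  edges <- system.file("extdata", "patients60_synthetic_edges.tsv",
                       package = "kanonet")
  schema <- system.file("extdata", "patients60_schema.json", package = "kanonet")
  hier <- system.file("extdata", "patients60_hierarchies.json",
                      package = "kanonet")
  tmp_write <- function(lines) {
    f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
    writeLines(lines, f)
    f
  }
  base <- readLines(nodes)

  # unparseable number names row and column
  bad_age <- base
  bad_age[2] <- sub(",56,", ",abc,", bad_age[2], fixed = TRUE)
  expect_error(read_inputs(tmp_write(bad_age), edges, schema, hier),
               "row 1, column 'Age'.*abc", class = "kanonet_input_error")

  # duplicate id
  dup <- c(base, base[2])
  expect_error(read_inputs(tmp_write(dup), edges, schema, hier),
               "duplicate", class = "kanonet_input_error")

  # unknown category label
  bad_cat <- base
  bad_cat[2] <- sub(",F,", ",Q,", bad_cat[2], fixed = TRUE)
  expect_error(read_inputs(tmp_write(bad_cat), edges, schema, hier),
               "Gender", class = "kanonet_input_error")

  # edge referencing an absent node id
  bad_edge <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t2", "1\tnope"), bad_edge)
  expect_error(read_inputs(nodes, bad_edge, schema, hier),
               "nope", class = "kanonet_input_error")

  # schema referencing a missing column
  bad_schema <- withr::local_tempfile(fileext = ".json")
  writeLines('{"Height": "numerical"}', bad_schema)
  expect_error(read_inputs(nodes, edges, bad_schema, hier),
               "Height", class = "kanonet_input_error")
})

test_that("edge files accept commas or tabs and an optional header", {
  ids <- c("n1", "n2", "n3")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("from,to", "n1,n2", "n2,n3"), f)
  expect_equal(nrow(read_edge_file(f, ids)), 2L)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("n1\tn2"), f2)
  expect_equal(read_edge_file(f2, ids), cbind("n1", "n2"), ignore_attr = TRUE)
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("n1\tn2\tn3", f3)
  expect_error(read_edge_file(f3, ids), class = "kanonet_input_error")
})
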