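test_that("the 60-patient fixture matches its printed source", {
  recs <- table3_records()
  expect_equal(nrow(recs), 60L)
  expect_equal(recs$id, as.character(1:60))
  r5 <- recs[5, ]
  expect_equal(unname(unlist(r5[c("Gender", "Age", "Zip", "Marriage",
                                  "Smoke", "Diagnosis")])),
               c("M", "56", "32211", "Marriage", "N", "AA"))
  expect_equal(range(recs$Age), c(19, 84))
  expect_equal(recs$Age[15], 19)
  expect_equal(recs$Age[c(9, 32)], c(84, 84))
  # the three records sharing the ambiguous zip agree on it
  expect_equal(unique(recs$Zip[c(1, 23, 46)]), "33613")
  # schema shape: 1 numerical + 4 categorical quasi-identifiers
  sch <- table3_schema()
  expect_equal(sch$numerical, "Age")
  expect_equal(names(sch$categorical), c("Gender", "Marriage", "Smoke", "Zip"))
  expect_equal(hier_height(sch$categorical$Zip), 2L)
  expect_silent(validate_records(recs, sch))
  expect_false("Diagnosis" %in% c(sch$numerical, names(sch$categorical)))
})

test_that("the linkage demonstration tables match their printed source", {
  lt <- link_attack_tables()
  expect_equal(nrow(lt$private), 7L)
  expect_equal(nrow(lt$public), 6L)
  expect_equal(unname(unlist(lt$private[5, c("Zip", "Age", "Disease")])),
               c("273207", "50", "cancer"))
  expect_equal(unname(unlist(lt$public[4, c("Name", "Gender", "Zip", "Age")])),
               c("Sam", "Female", "273207", "50"))
})

test_that("the raw linkage attack uniquely re-identifies 5 of 6 public records", {
  lt <- link_attack_tables()
  res <- linkage_attack(lt$private, lt$public, c("Zip", "Age"))
  expect_equal(res$match_sizes[["Sam"]], 1L)
  expect_equal(lt$private$Disease[res$matches[["Sam"]]], "cancer")
  expect_equal(res$match_sizes[["Mary"]], 0L)
  expect_equal(unname(res$summary),
               c(1L, 5L, 0L))
  expect_setequal(names(res$match_sizes)[res$match_sizes == 1],
                  c("Alice", "David", "Sam", "Joan", "Angle"))
  expect_error(linkage_attack(lt$private, lt$public, "Shoe size"),
               class = "kanonet_input_error")
})

test_that("generalized joins are monotone non-decreasing in match-set size", {
  lt <- link_attack_tables()
  sch <- attribute_schema(
    numerical = "Age",
    categorical = list(Zip = zip_prefix_hierarchy(c(lt$private$Zip,
                                                    lt$public$Zip))))
  raw <- linkage_attack(lt$private, lt$public, c("Zip", "Age"))
  # zero generalization reproduces the raw join
  zero <- generalized_linkage(lt$private, lt$public, c("Zip", "Age"), sch,
                              levels = list(Zip = 0, Age = 0))
  expect_equal(zero$match_sizes, raw$match_sizes)
  # full generalization matches everything to everything
  root <- generalized_linkage(lt$private, lt$public, c("Zip", "Age"), sch,
                              levels = list(Zip = 2, Age = 1000))
  expect_true(all(root$match_sizes == nrow(lt$private)))
  # monotonicity over the whole level lattice
  combos <- expand.grid(zip = 0:2, age = c(0, 5, 10, 1000))
  sizes <- lapply(seq_len(nrow(combos)), function(i) {
    generalized_linkage(lt$private, lt$public, c("Zip", "Age"), sch,
                        levels = list(Zip = combos$zip[i],
                                      Age = combos$age[i]))$match_sizes
  })
  for (i in seq_len(nrow(combos))) {
    for (j in seq_len(nrow(combos))) {
      if (combos$zip[i] <= combos$zip[j] && combos$age[i] <= combos$age[j] &&
          (combos$age[i] == 0) >= (combos$age[j] == 0)) {
        expect_true(all(sizes[[i]] <= sizes[[j]]))
      }
    }
  }
})

test_that("the printed loss grids are 10 x 6 with the quoted cells", {
  grids <- printed_loss_grids()
  expect_equal(dim(grids$generalization), c(10L, 6L))
  expect_equal(dim(grids$structure), c(10L, 6L))
  expect_equal(grids$generalization["21", "1"], 0.116333)
  expect_equal(grids$generalization["3", "1"], 0.118513)
  expect_equal(grids$structure["3", "0.4"], 0.150157)
  expect_equal(grids$structure["3", "1"], 0.184306)
  expect_true(all(grids$generalization > 0 & grids$generalization < 1))
  expect_true(all(grids$structure > 0 & grids$structure < 1))
})

test_that("synthetic edges are deterministic, with the documented shapes", {
  # exact ring lattice without rewiring
  ring <- synth_edges(4, 2, "ring", seed = 7, rewire_prob = 0)
  expect_equal(nrow(ring), 4L)
  g <- social_graph_from_edges(ring, as.character(1:4))
  expect_true(all(node_degrees(g) == 2))
  # determinism
  expect_identical(synth_edges(30, 4, "er", seed = 11),
                   synth_edges(30, 4, "er", seed = 11))
  expect_identical(synth_edges(30, 4, "ring", seed = 11),
                   synth_edges(30, 4, "ring", seed = 11))
  expect_false(identical(synth_edges(30, 4, "er", seed = 11),
                         synth_edges(30, 4, "er", seed = 12)))
  # Erdos-Renyi edge count within 4 sd of n * mean_degree / 2
  e <- nrow(synth_edges(60, 4, "er", seed = 1))
  p <- 4 / 59
  sd4 <- 4 * sqrt(choose(60, 2) * p * (1 - p))
  expect_lt(abs(e - 120), sd4)
  # parameter validation
  expect_error(synth_edges(1, 1, "er", seed = 1),
               class = "kanonet_parameter_error")
  expect_error(synth_edges(10, 12, "er", seed = 1),
               class = "kanonet_parameter_error")
  expect_error(synth_edges(10, 3, "ring", seed = 1),
               class = "kanonet_parameter_error")
})

test_that("sweeps cover the grid with in-range, k-anonymous losses", {
  inst <- benchmark_instance(seed = 1)
  grid <- sweep_losses(inst$graph, inst$records, inst$schema,
                       k_grid = c(3, 6), a_grid = c(0, 0.5, 1))
  expect_equal(dim(grid$reports), c(2L, 3L))
  df <- as.data.frame(grid)
  expect_equal(nrow(df), 6L)
  expect_true(all(df$gloss >= 0 & df$gloss <= 1))
  expect_true(all(df$sloss >= 0 & df$sloss <= 1))
  expect_equal(df$total, df$gloss + df$sloss)
  for (ki in 1:2) {
    for (ai in 1:3) {
      expect_true(assert_k_anonymous(grid$partitions[[ki, ai]],
                                     grid$k[ki]))
    }
  }
  out <- withr::local_tempfile(fileext = ".csv")
  write_loss_grid(grid, out)
  expect_equal(nrow(utils::read.csv(out)), 6L)
  expect_error(
    sweep_losses(inst$graph, inst$records, inst$schema, k_grid = c(3, 120)),
    class = "kanonet_parameter_error")
})

test_that("exhaustive search finds zero-loss pairings and the only legal cover", {
  sch <- toy_schema()
  ids <- as.character(1:4)
  none <- social_graph_from_edges(NULL, ids)
  recs <- data.frame(id = ids, x = c(1, 1, 9, 9),
                     city = c("A", "A", "D", "D"), stringsAsFactors = FALSE)
  best <- brute_force_partition(none, recs, sch, k = 2)
  expect_equal(best$total, 0)
  expect_setequal(lapply(best$partition, sort), list(c("1", "2"), c("3", "4")))
  whole <- brute_force_partition(none, recs, sch, k = 4)
  expect_equal(lapply(whole$partition, sort), list(ids))
  expect_error(brute_force_partition(random_graph(11), toy_records(as.character(1:11)),
                                     sch, k = 2),
               class = "kanonet_parameter_error")
})
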