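test_that("sampled indices cover tmin..tmax and always include tmax", {
  expect_equal(length(sampled_indices(0, 10000, 250, 250)), 41)
  expect_equal(sampled_indices(0, 10000, 250, 250)[c(1, 2, 41)],
               c(0L, 250L, 10000L))
  expect_equal(length(sampled_indices(0, 864, 4, 4)), 217)
  expect_equal(sampled_indices(0, 100, 40, 20), c(0L, 40L, 80L, 100L))
  expect_error(sampled_indices(0, 100, 30, 20), "multiple.*stride")
})

test_that("the time axis is anchored at 0 and spans the x extent", {
  cfg <- tree_config(".", xmin = -100, xmax = 100, ymin = -100, ymax = 100,
                     tmin = 0, tmax = 10000, file_step = 250)
  expect_equal(time_to_y(0, cfg), 0)
  expect_equal(time_to_y(10000, cfg), 200)
  expect_equal(time_to_y(5000, cfg), 100)
  ts <- time_scale(cfg)
  expect_equal(ts$time_step, 200 / 40)
  expect_equal(time_to_y(250, cfg), ts$time_step)
  # appended-tmax sampling keeps both anchors
  cfg2 <- tree_config(".", xmin = 0, xmax = 10, ymin = 0, ymax = 10,
                      tmin = 0, tmax = 100, file_step = 40)
  expect_equal(time_to_y(100, cfg2), 10)
})

test_that("clone_root finds the entry cell of a clone", {
  h <- cell_history(1:3, c(0, 0, 1), c(0, 1, 1), c(0, 5, 5), c(5, 0, 0))
  expect_equal(clone_root(h, 0), 1L)   # the founder
  expect_equal(clone_root(h, 1), 3L)   # the mutated daughter
  expect_error(clone_root(h, 7), "no cells of clone 7")
})

test_that("position lookup falls back to the nearest recorded ancestor", {
  fx <- make_fixture("one_division")
  # cell 1 present at snapshot 1
  expect_equal(position_of(fx$series, fx$history, 1, 1), c(0, 1))
  # daughter 2 not yet listed at snapshot 1 -> mother's position
  expect_equal(position_of(fx$series, fx$history, 2, 1), c(0, 1))
  # dead lineage: dying_branch cell 3 is absent from the final snapshot
  fd <- make_fixture("dying_branch")
  expect_null(position_of(fd$series, fd$history, 3, 3))
})

test_that("full trees of the hand fixtures match exact enumeration", {
  fx <- make_fixture("one_cell")
  bs <- build_full_tree(fx$history, fx$series, 0, fx$config)
  expect_equal(nrow(bs), 2)
  expect_true(all(bs$x1 == 2 & bs$x2 == 2 & bs$z1 == 3 & bs$z2 == 3))

  fx <- make_fixture("one_division")
  bs <- sort_branches(build_full_tree(fx$history, fx$series, 0, fx$config))
  # root segment + one segment per daughter, y spacing (xmax-xmin)/2 = 10
  expected <- sort_branches(data.frame(
    clone_id = 0L,
    x1 = c(0, 0, 0), y1 = c(0, 10, 10), z1 = c(0, 1, 1),
    x2 = c(0, -2, 2), y2 = c(10, 20, 20), z2 = c(1, 2, 2)))
  expect_equal(bs, expected)

  fd <- make_fixture("dying_branch")
  expect_equal(nrow(build_full_tree(fd$history, fd$series, 0, fd$config)), 4)
})

test_that("a mutated clone's first segment starts at the mother's position", {
  fx <- make_fixture("two_clones")
  b1 <- sort_branches(build_full_tree(fx$history, fx$series, 1, fx$config))
  ts <- 20 / 3
  expected <- sort_branches(data.frame(
    clone_id = 1L,
    x1 = c(0, 2), y1 = c(ts, 2 * ts), z1 = c(1, 2),
    x2 = c(2, 4), y2 = c(2 * ts, 3 * ts), z2 = c(2, 3)))
  expect_equal(b1, expected)
  # clone 0's tree never touches the mutated daughter's trace
  b0 <- build_full_tree(fx$history, fx$series, 0, fx$config)
  expect_equal(nrow(b0), 3)
  expect_true(all(b0$clone_id == 0))
})

test_that("surviving_set matches the brute-force reachability oracle", {
  h <- cell_history(1, 0, 0, 0, 0)
  s <- snapshot(5, 1, cbind(0, 0))
  expect_equal(surviving_set(h, s), 1L)
  expect_equal(surviving_set(h, snapshot(5, integer(0), cbind(numeric(0), numeric(0)))),
               integer(0))

  set.seed(11)
  for (rep in 1:30) {
    h <- random_history(n_events = sample(10:60, 1))
    alive <- h$cell_id[h$end_iter == 0]
    expect_equal(surviving_set(h, snapshot(99, alive,
                                           matrix(0, length(alive), 2))),
                 brute_force_surviving(h, alive))
    cl <- sample(unique(h$clone_id), 1)
    expect_equal(surviving_set(h, snapshot(99, alive,
                                           matrix(0, length(alive), 2)), cl),
                 brute_force_surviving(h, alive, cl))
  }
})

test_that("pruned trees of the fixtures match exact enumeration", {
  fd <- make_fixture("dying_branch")
  alive <- sort_branches(build_alive_tree(fd$history, fd$series, 0, fd$config))
  # the surviving path root -> cell 2 only: 3 segments
  ts <- 20 / 3
  expected <- sort_branches(data.frame(
    clone_id = 0L,
    x1 = c(0, 0, -2), y1 = c(0, ts, 2 * ts), z1 = c(0, 1, 2),
    x2 = c(0, -2, -3), y2 = c(ts, 2 * ts, 3 * ts), z2 = c(1, 2, 3)))
  expect_equal(alive, expected)

  # extinct clone -> empty pruned tree; surviving mutated clone keeps its path
  dx <- make_fixture("drug_extinction")
  expect_equal(nrow(build_alive_tree(dx$history, dx$series, 0, dx$config)), 0)
  expect_equal(nrow(build_alive_tree(dx$history, dx$series, 1, dx$config)), 2)
})

test_that("pruning is the identity when nothing dies", {
  fx <- make_fixture("one_division")
  expect_equal(sort_branches(build_alive_tree(fx$history, fx$series, 0, fx$config)),
               sort_branches(build_full_tree(fx$history, fx$series, 0, fx$config)))
})

test_that("forest = union of clone trees; alive subset of full; time monotone", {
  set.seed(23)
  for (rep in 1:10) {
    h <- random_history(n_events = sample(20:60, 1))
    tmax <- max(c(h$birth_iter, h$end_iter)) + 1
    series <- random_series(h, tmax)
    cfg <- random_tree_config(tmax)
    ncl <- max(h$clone_id)
    forest <- build_forest(h, series, ncl, "full", cfg)
    per_clone <- do.call(rbind, lapply(sort(unique(h$clone_id)), function(cl)
      as.data.frame(build_full_tree(h, series, cl, cfg))))
    expect_equal(sort_branches(forest), sort_branches(per_clone))

    aforest <- build_forest(h, series, ncl, "alive", cfg)
    expect_lte(nrow(aforest), nrow(forest))
    key <- function(df) do.call(paste, as.data.frame(df))
    expect_true(all(key(aforest) %in% key(forest)))

    expect_true(all(forest$y2 >= forest$y1))
    expect_true(all(forest$clone_id %in% 0:ncl))
  }
})

test_that("tree construction is deterministic", {
  set.seed(5)
  h <- random_history(40)
  tmax <- max(c(h$birth_iter, h$end_iter)) + 1
  series <- random_series(h, tmax)
  cfg <- random_tree_config(tmax)
  a <- build_forest(h, series, max(h$clone_id), "full", cfg)
  b <- build_forest(h, series, max(h$clone_id), "full", cfg)
  expect_identical(a, b)
})

test_that("coarser sampling straightens branches but keeps endpoints", {
  set.seed(9)
  h <- random_history(40, p_death = 0.1)
  tmax <- max(c(h$birth_iter, h$end_iter)) + 2
  series <- random_series(h, tmax)
  fine <- build_forest(h, series, max(h$clone_id), "full",
                       random_tree_config(tmax, file_step = 1))
  coarse <- build_forest(h, series, max(h$clone_id), "full",
                         random_tree_config(tmax, file_step = tmax))
  expect_lte(nrow(coarse), nrow(fine))
  expect_equal(unique(coarse$y1), 0)
  expect_equal(unique(coarse$y2), 40)
})
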