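# Small-scale simulator runs shared across several expectations.
small_params <- function(...) {
  defaults <- list(n_iters = 400, save_stride = 50, drug_start = 200,
                   division_age = 40, grid_n = 21, diffusion_coeff = 5)
  args <- list(...)
  defaults[names(args)] <- args
  do.call(sim_params, defaults)
}

test_that("no mutation means a single clone; histories are division-consistent", {
  out <- simulate_tumor(small_params(p_mut = 0, seed = 3))
  expect_equal(out$clone_count, 1L)
  expect_true(all(out$history$clone_id == 0))

  h <- out$history
  ended <- h$cell_id[h$end_iter > 0]
  for (id in ended) {
    kids <- children_of(h, id)
    expect_true(length(kids) %in% c(0L, 2L))
    if (length(kids)) {
      expect_equal(h$birth_iter[match(kids, h$cell_id)],
                   rep(h$end_iter[match(id, h$cell_id)], 2))
    }
  }
  expect_true(all(h$cell_id[h$end_iter == 0] %in%
                    out$series[[length(out$series)]]$ids))
})

test_that("with no death pressure the pruned forest equals the full forest", {
  out <- simulate_tumor(small_params(p_mut = 0.02, seed = 5,
                                     drug_start = 1000, n_iters = 400,
                                     random_death_prob = 0,
                                     motility_step = 0))
  dir <- withr::local_tempdir()
  write_dataset(out$history, out$series, NULL, dir)
  cfg <- sim_tree_config(out, dir)
  ncl <- max(out$history$clone_id)
  full <- build_forest(out$history, out$series, ncl, "full", cfg)
  alive <- build_forest(out$history, out$series, ncl, "alive", cfg)
  expect_equal(sort_branches(alive), sort_branches(full))
})

test_that("an immediate lethal drug extinguishes the sensitive tumor", {
  out <- simulate_tumor(small_params(p_mut = 0, seed = 8, drug_start = 100,
                                     death_threshold = 0,
                                     random_death_prob = 0))
  final <- out$series[[length(out$series)]]
  expect_equal(length(final$ids), 0)
  cfg <- sim_tree_config(out, ".", file_step = 50)
  aforest <- build_forest(out$history, out$series, 0, "alive", cfg)
  expect_equal(nrow(aforest), 0)
  # the full tree of the dead clone is still non-empty
  fforest <- build_forest(out$history, out$series, 0, "full", cfg)
  expect_gt(nrow(fforest), 0)
})

test_that("mutated clones are drug-resistant: only founder-clone cells die of drug", {
  out <- simulate_tumor(small_params(p_mut = 0.05, seed = 13,
                                     n_iters = 600, drug_start = 200,
                                     random_death_prob = 0,
                                     motility_step = 0))
  h <- out$history
  fate <- cell_fate(h)
  # with random death and motility off, every non-division end is a drug death
  drug_deaths <- h$cell_id[fate == "died"]
  expect_gt(length(drug_deaths), 0)
  expect_true(all(h$clone_id[match(drug_deaths, h$cell_id)] == 0))
})

test_that("a fixed seed reproduces the simulation exactly", {
  p <- small_params(p_mut = 0.02, seed = 21)
  a <- simulate_tumor(p)
  b <- simulate_tumor(p)
  expect_identical(as.data.frame(a$history), as.data.frame(b$history))
  expect_identical(a$drug$values, b$drug$values)
  expect_identical(lapply(a$series, `[[`, "xy"), lapply(b$series, `[[`, "xy"))
  expect_equal(a$clone_count, b$clone_count)
})

test_that("diffusion without sinks or sources conserves mass to 1e-9", {
  set.seed(2)
  f0 <- drug_field(matrix(stats::runif(21 * 21), 21, 21), c(-100, 100, -100, 100))
  p <- sim_params(grid_n = 21, decay_rate = 0, uptake_rate = 0,
                  diffusion_coeff = 5)
  f <- f0
  for (i in 1:50) f <- update_drug(f, NULL, NULL, p)$field
  expect_equal(sum(f$values), sum(f0$values), tolerance = 1e-9)
  # and the field stays non-negative and smooths out
  expect_gte(min(f$values), 0)
  expect_lt(diff(range(f$values)), diff(range(f0$values)))
})

test_that("uptake removes drug only at occupied nodes and doses the cells", {
  f <- drug_field(matrix(1, 21, 21), c(-100, 100, -100, 100))
  p <- sim_params(grid_n = 21, decay_rate = 0, uptake_rate = 0.1,
                  diffusion_coeff = 0)
  cells <- cbind(c(-100, 0), c(-100, 0))  # nodes (1,1) and (11,11)
  upd <- update_drug(f, cells, NULL, p)
  expect_equal(upd$dose, c(0.1, 0.1))
  expect_equal(upd$field$values[1, 1], 0.9)
  expect_equal(upd$field$values[11, 11], 0.9)
  expect_equal(upd$field$values[2, 2], 1)
  # two co-located cells share the node's supply
  upd2 <- update_drug(f, cbind(c(0, 0), c(0, 0)), NULL, p)
  expect_equal(sum(upd2$dose), 1 - (1 - 0.1)^2, tolerance = 1e-12)
})

test_that("an unstable diffusion setting is rejected by the CFL guard", {
  f <- drug_field(matrix(1, 21, 21), c(-100, 100, -100, 100))
  expect_error(sim_params(grid_n = 21, diffusion_coeff = 50), "0.25")
  p <- sim_params(grid_n = 21, diffusion_coeff = 5)
  p$diffusion_coeff <- 50  # bypass the constructor guard
  expect_error(update_drug(f, NULL, NULL, p), "CFL|0.25")
})

test_that("steady drug profile decays monotonically with distance from a vessel", {
  # run the model grid and an independently stepped fine grid (half the
  # spacing) to steady state around a single vessel at the origin
  steady_profile <- function(grid_n, n_steps) {
    p <- sim_params(grid_n = grid_n, diffusion_coeff = 1, decay_rate = 4e-4,
                    uptake_rate = 0)
    f <- drug_field(matrix(0, grid_n, grid_n), c(-100, 100, -100, 100))
    for (i in seq_len(n_steps)) f <- update_drug(f, NULL, cbind(0, 0), p)$field
    xs <- seq(-100, 100, length.out = grid_n)
    r <- sqrt(outer(xs^2, xs^2, "+"))
    prof <- tapply(as.vector(f$values), round(as.vector(r) / 5) * 5, mean)
    list(r = as.numeric(names(prof)), c = as.vector(prof))
  }
  coarse <- steady_profile(41, 8000)
  keep <- coarse$r > 0 & coarse$r <= 70
  expect_true(all(diff(coarse$c[keep]) < 0))

  fine <- steady_profile(81, 8000)
  at <- seq(15, 60, by = 5)
  cc <- coarse$c[match(at, coarse$r)]
  cf <- fine$c[match(at, fine$r)]
  # compare shapes after normalizing out the source-amplitude difference
  rel <- (cc / cc[1]) / (cf / cf[1])
  expect_lt(max(abs(rel - 1)), 0.10)
})

test_that("crowding relaxation separates overlaps and leaves loners alone", {
  set.seed(4)
  two <- matrix(c(0, 0, 0, 0), 2, 2)
  out <- resolve_crowding(two, radius = 1, n_steps = 10)
  expect_gte(sqrt(sum((out[1, ] - out[2, ])^2)), 1 - 1e-6)

  lone <- matrix(c(5, 7), 1, 2)
  expect_equal(resolve_crowding(lone, 1), lone)

  # dense ring: after relaxation no pair is closer than radius * (1 - tol)
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  ring <- cbind(cos(th), sin(th)) * 2
  relaxed <- resolve_crowding(ring, radius = 1, n_steps = 200)
  d <- as.matrix(dist(relaxed))
  diag(d) <- Inf
  expect_gte(min(d), 1 * (1 - 0.05))
})

test_that("simulated datasets satisfy the format invariants end-to-end", {
  out <- simulate_tumor(small_params(p_mut = 0.02, seed = 30))
  idx <- series_indices(out$series)
  expect_equal(idx, seq(0, 400, by = 50))
  h <- out$history
  for (k in as.character(c(0, 200, 400))) {
    s <- out$series[[k]]
    i <- match(s$ids, h$cell_id)
    expect_false(anyNA(i))
    expect_true(all(h$birth_iter[i] <= s$file_index))
    expect_true(all(h$end_iter[i] == 0 | h$end_iter[i] >= s$file_index))
  }
  expect_equal(out$clone_count, length(unique(h$clone_id)))
})
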