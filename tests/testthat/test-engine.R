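# Growth engine: bifurcation gate, tip advance, stepping, scenarios.

# fresh state holding one straight trunk entering from the bottom edge
trunk_state <- function(params, len = 10L, x0 = 32L) {
  st <- selfavoid:::new_state(params)
  selfavoid:::add_trunk(st, x0, 0L, 0L, 1L, len)
}

state_snapshot <- function(st) {
  n <- st$n
  list(n = n, x = st$x[seq_len(n)], y = st$y[seq_len(n)],
       kind = st$kind[seq_len(n)], parent = st$parent[seq_len(n)],
       gen = st$gen[seq_len(n)], tips = st$t_uid, step = st$step)
}

test_that("a tip does not branch while the sensed field is above threshold", {
  p <- small_params(branch_threshold = 0.001, noise_sd = 0)
  st <- trunk_state(p)
  before <- state_snapshot(st)
  st <- maybe_bifurcate(st, st$t_uid[1])
  expect_identical(state_snapshot(st), before)
})

test_that("a lone permissive tip bifurcates into two opposite daughters", {
  p <- small_params(branch_threshold = 1e6, noise_sd = 0)
  st <- trunk_state(p, len = 10L)
  set.seed(1)
  st <- maybe_bifurcate(st, st$t_uid[1])
  expect_equal(st$n, 12L)                       # +2 elements
  tips <- st$t_elem
  expect_length(tips, 2L)
  expect_true(all(st$kind[tips] == selfavoid:::KIND_TIP))
  # former tip is now a stalk (the branch point) and parents both daughters
  bp <- unique(st$parent[tips])
  expect_length(bp, 1L)
  expect_equal(st$kind[bp], selfavoid:::KIND_STALK)
  expect_true(all(st$gen[tips] == 1L))
  # daughters are diametrically opposite around the branch point
  expect_equal(st$x[tips[1]] - st$x[bp], -(st$x[tips[2]] - st$x[bp]))
  expect_equal(st$y[tips[1]] - st$y[bp], -(st$y[tips[2]] - st$y[bp]))
})

test_that("fresh daughters sense a field above threshold and do not re-branch", {
  p <- model_params(domain_width = 64, domain_height = 64, noise_sd = 0,
                    refractory_length = 0)
  st <- trunk_state(p, len = 10L)
  set.seed(1)
  st <- maybe_bifurcate(st, st$t_uid[1])
  trees <- selfavoid:::state_to_trees(st)
  for (tip in st$t_elem) {
    sensed <- brute_field(c(st$x[tip], st$y[tip]), trees, p,
                          exclude = c(st$x[tip], st$y[tip]))
    expect_gt(sensed, p$branch_threshold)
  }
  n_before <- st$n
  for (u in st$t_uid) st <- maybe_bifurcate(st, u)
  expect_equal(st$n, n_before)
})

test_that("tip advance follows the speed law and the field minimum", {
  # zero field: the move probability is 1, so the tip always moves
  p <- small_params(source_strength = 0, noise_sd = 0, refractory_length = 0)
  st <- trunk_state(p, len = 5L)
  set.seed(2)
  st <- advance_tip(st, st$t_uid[1])
  expect_equal(st$n, 6L)                        # stalk deposited, tip re-sited
  expect_equal(st$t_dist[1], 5 + sqrt((st$x[6] - st$x[5])^2 +
                                      (st$y[6] - st$y[5])^2))
  # a distant source directly left of an isolated tip pushes it right
  p2 <- small_params(noise_sd = 0, speed_half_saturation = 1e9,
                     tip_source_strength = 1)
  st2 <- selfavoid:::new_state(p2)
  st2 <- selfavoid:::add_trunk(st2, 5L, 30L, 1L, 0L, 1L)   # lone cell tip
  st2 <- selfavoid:::add_trunk(st2, 40L, 30L, -1L, 0L, 1L) # would-be sources
  set.seed(3)
  st2 <- advance_tip(st2, 2L)   # advance the SECOND tip (source on its left)
  moved <- st2$t_elem[2]
  expect_equal(st2$x[moved], 41L)               # moved away: due east
  expect_equal(st2$y[moved], 30L)
})

test_that("stepping preserves occupancy and connectivity invariants", {
  p <- small_params()
  set.seed(4)
  res <- run_scenario(scenario("single_bud", trunk_length = 8), p,
                      seed = 4, n_steps = 60)
  st <- res$state
  n <- st$n
  # every element on the grid exactly once
  occ_idx <- st$occ[st$occ > 0]
  expect_setequal(occ_idx, seq_len(n))
  expect_equal(length(occ_idx), n)
  # 8-connectivity to the root through parents
  for (tr in res$trees) {
    el <- tr$elements
    root <- which(is.na(el$parent))
    for (i in seq_len(nrow(el))) {
      path <- selfavoid:::path_to_root(tr, i)
      expect_equal(path[length(path)], root)
    }
  }
  # element count bookkeeping: trunk + one per move + two per bifurcation
  moves <- n - 8L - 2L * nrow(res$bifurcations)
  expect_gte(moves, 0)
})

test_that("a state with no tips is unchanged by a step except its counter", {
  p <- small_params()
  st <- selfavoid:::new_state(p)
  set.seed(1)
  st <- sim_step(st)
  expect_equal(st$step, 1L)
  expect_equal(st$n, 0L)
})

test_that("runs are bit-reproducible under a fixed seed", {
  p <- small_params()
  r1 <- run_scenario(scenario("single_bud", trunk_length = 8), p,
                     seed = 99, n_steps = 50)
  r2 <- run_scenario(scenario("single_bud", trunk_length = 8), p,
                     seed = 99, n_steps = 50)
  expect_identical(r1$trees[[1]]$elements, r2$trees[[1]]$elements)
  expect_identical(r1$tracks, r2$tracks)
  expect_identical(r1$bifurcations, r2$bifurcations)
  r3 <- run_scenario(scenario("single_bud", trunk_length = 8), p,
                     seed = 100, n_steps = 50)
  expect_false(identical(r1$trees[[1]]$elements, r3$trees[[1]]$elements))
})

test_that("scenario geometries build the expected trunks", {
  p <- small_params()
  st <- selfavoid:::init_scenario(scenario("head_on_pair", trunk_length = 6), p)
  expect_equal(st$n, 12L)
  expect_setequal(unique(st$tree[seq_len(st$n)]), c(1L, 2L))
  st3 <- selfavoid:::init_scenario(scenario("triple", trunk_length = 6), p)
  expect_setequal(unique(st3$tree[seq_len(st3$n)]), 1:3)
  expect_error(scenario("spiral"), "arg")
})

test_that("a single bud grows at least two branch generations", {
  res <- run_scenario(scenario("single_bud"), model_params(), seed = 5,
                      n_steps = 120)
  a <- angles_by_generation(res)
  expect_gte(max(a$generation), 2L)
})
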