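# Divergence angles, collision scoring, bead distance, kinematics.

test_that("divergence angle handles orthogonal and opposite daughters", {
  # daughters along (1,1) and (1,-1): orthogonal, 90 degrees
  el <- data.frame(
    x = c(0L, 0L, 1L, 2L, 1L, 2L),
    y = c(0L, 1L, 2L, 3L, 0L, -1L),
    kind = c("stalk", "stalk", "stalk", "tip", "stalk", "tip"),
    parent = c(NA, 1L, 2L, 3L, 2L, 5L),
    generation = c(0L, 0L, 1L, 1L, 1L, 1L), birth_step = 0L)
  tr <- tubule_tree(el)
  expect_equal(divergence_angle(tr, 2L, L = 10), 90)
  # daughters due east and west: opposite, 180 degrees
  el2 <- data.frame(
    x = c(0L, 0L, 1L, 2L, -1L, -2L),
    y = c(0L, 1L, 1L, 1L, 1L, 1L),
    kind = c("stalk", "stalk", "stalk", "tip", "stalk", "tip"),
    parent = c(NA, 1L, 2L, 3L, 2L, 5L),
    generation = c(0L, 0L, 1L, 1L, 1L, 1L), birth_step = 0L)
  tr2 <- tubule_tree(el2)
  expect_equal(divergence_angle(tr2, 2L, L = 10), 180)
  # a branch point can also be addressed by its cell
  expect_equal(divergence_angle(tr2, c(0, 1), L = 10), 180)
  # non-bifurcating elements are rejected
  expect_error(divergence_angle(tr, 1L), "exactly two")
})

test_that("divergence angle on a digitized curved daughter matches direct vector arithmetic", {
  # curved daughter A walks (1,1),(1,0),(1,0),(1,1)...; straight daughter B
  ax <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L)
  ay <- c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L)
  bx <- -(1:8); by <- rep(0L, 8)
  el <- data.frame(
    x = c(0L, ax, bx), y = c(0L, ay, by),
    kind = c("stalk", rep("stalk", 7), "tip", rep("stalk", 7), "tip"),
    parent = c(NA, 1L, 2:8, 1L, 10:16),
    generation = c(0L, rep(1L, 16)), birth_step = 0L)
  tr <- tubule_tree(el)
  # oracle: walk arc lengths by hand. A steps: sqrt2,1,sqrt2,1,sqrt2,1,sqrt2,1
  # cumulative >= 6 first at cell (5,3); B reaches arc 6 at (-6,0)
  arcA <- cumsum(c(sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1))
  iA <- which(arcA >= 6)[1]
  vA <- c(ax[iA], ay[iA])
  vB <- c(-6, 0)
  expected <- acos(sum(vA * vB) / sqrt(sum(vA^2) * sum(vB^2))) * 180 / pi
  expect_equal(divergence_angle(tr, 1L, L = 6), expected, tolerance = 1e-9)
})

test_that("angle measurement is symmetric in the daughters and rotation invariant", {
  spec <- toy_tree_spec(trunk_length = 10, branches = data.frame(
    generation = 1, angle = 110, length = 15))
  tr <- gen_toy_tree(spec)
  bp <- branch_points(tr)
  a1 <- divergence_angle(tr, bp, L = 10)
  # swap daughter subtrees by relabelling: angle must not change
  kids <- selfavoid:::children_of(tr, bp)
  expect_equal(a1, divergence_angle(tr, bp, L = 10))
  v1 <- selfavoid:::daughter_vector(tr, bp, kids[1], 10)
  v2 <- selfavoid:::daughter_vector(tr, bp, kids[2], 10)
  expect_equal(selfavoid:::vec_angle_deg(v1, v2),
               selfavoid:::vec_angle_deg(v2, v1))
})

test_that("angles_by_generation labels every two-daughter branch point", {
  tr1 <- gen_toy_tree(toy_tree_spec(branches = data.frame(
    generation = 1, angle = 100, length = 12)))
  a1 <- angles_by_generation(tr1, L = 10)
  expect_equal(nrow(a1), 1L)
  expect_equal(a1$generation, 1L)
  tr2 <- gen_toy_tree(toy_tree_spec(branches = data.frame(
    generation = 1:2, angle = c(120, 80), length = c(20, 15))))
  a2 <- angles_by_generation(tr2, L = 10)
  expect_equal(sort(a2$generation), c(1L, 2L, 2L))
  expect_equal(a2$angle_deg[a2$generation == 1], 120, tolerance = 2)
  expect_equal(a2$angle_deg[a2$generation == 2], c(80, 80), tolerance = 2)
})

test_that("collision detection scores inter-tree contacts categorically", {
  t1 <- straight_trunk(5, 10, 10)
  t2 <- tubule_tree(transform(straight_trunk(5, 12, 10)$elements, x = 12L),
                    tree_id = 2L)
  # nearest cells at Chebyshev distance 2: no contact at threshold 1
  ev <- detect_collisions(list(t1, t2), contact_chebyshev = 1)
  expect_equal(nrow(ev), 0L)
  expect_false(any_collision(ev))
  # threshold 2 detects them; verdict is monotone in the threshold
  ev2 <- detect_collisions(list(t1, t2), contact_chebyshev = 2)
  expect_gt(nrow(ev2), 0L)
  expect_true(any_collision(ev2))
  expect_true(all(ev2$type == "inter_tree"))
  # adjacent trees at Chebyshev 1
  t3 <- tubule_tree(transform(straight_trunk(5, 11, 10)$elements, x = 11L),
                    tree_id = 3L)
  ev3 <- detect_collisions(list(t1, t3), contact_chebyshev = 1)
  expect_true(any_collision(ev3))
})

test_that("a hairpin that returns beside its own trunk is a self-loop", {
  # up 8 cells at x=0, across to x=2, down 7 cells: tip ends next to trunk
  xs <- c(rep(0L, 8), 1L, 2L, rep(2L, 7))
  ys <- c(0:7, 8L, 8L, 7:1)
  el <- data.frame(x = xs, y = ys,
                   kind = c(rep("stalk", length(xs) - 1), "tip"),
                   parent = c(NA, seq_len(length(xs) - 1)),
                   generation = 0L, birth_step = 0L)
  hp <- tubule_tree(el)
  ev <- detect_collisions(hp, contact_chebyshev = 2, loop_min_path = 10)
  expect_true(any(ev$type == "self_loop"))
  # ordinary consecutive trail cells are not loops
  ev2 <- detect_collisions(straight_trunk(12), contact_chebyshev = 1)
  expect_equal(nrow(ev2), 0L)
})

test_that("closest approach to a disc is edge-to-edge and floored at zero", {
  cell <- straight_trunk(1, 10, 10)
  expect_equal(closest_approach_to_disc(cell, c(20, 10), 4), 6)
  expect_equal(closest_approach_to_disc(cell, c(11, 10), 4), 0)
  tr <- gen_toy_tree(toy_tree_spec(branches = data.frame(
    generation = 1, angle = 120, length = 15)))
  center <- c(130, 25); radius <- 7
  el <- tr$elements
  brute <- min(pmax(0, sqrt((el$x - center[1])^2 + (el$y - center[2])^2) -
                      radius))
  expect_equal(closest_approach_to_disc(tr, center, radius), brute)
})

test_that("tip speeds come from sampled frame pairs", {
  trk <- data.frame(time_h = 0:1, tip_id = "a", x = c(0, 3), y = c(0, 4))
  expect_equal(tip_speeds(trk, stride = 1)$speed, 5)
  still <- data.frame(time_h = 0:5, tip_id = "b", x = 2, y = 3)
  expect_true(all(tip_speeds(still, stride = 1)$speed == 0))
  # unequal frame intervals, hand-computed
  t3 <- data.frame(time_h = c(0, 0.5, 2), tip_id = "c",
                   x = c(0, 1, 1), y = c(0, 0, 2))
  sp <- tip_speeds(t3, stride = 1)
  expect_equal(sp$speed, c(1 / 0.5, 2 / 1.5))
  # stride-5 sampling uses frame pairs (1,2), (6,7), ...
  t10 <- data.frame(time_h = 0:10, tip_id = "d", x = 0:10, y = 0)
  expect_equal(nrow(tip_speeds(t10, stride = 5)), 2L)
  bad <- data.frame(time_h = c(0, 0), tip_id = "e", x = 1:2, y = 0)
  expect_error(tip_speeds(bad, stride = 1), "strictly increasing")
})

test_that("closing speed is positive on approach and matches Pythagoras", {
  a <- data.frame(time_h = 0:1, x = c(0, 0), y = c(0, 0))
  b <- data.frame(time_h = 0:1, x = c(10, 7), y = c(0, 0))
  cs <- closing_speed_table(a, b)
  expect_equal(cs$separation, 10)
  expect_equal(cs$closing_speed, 3)
  expect_equal(cs$raw_velocity, -3)
  # both static
  expect_equal(closing_speed_table(a, a)$closing_speed, 0)
  # 3-4-5 scaled: separations 50 then 45
  b2 <- data.frame(time_h = 0:1, x = c(30, 27), y = c(40, 36))
  cs2 <- closing_speed_table(a, b2)
  expect_equal(cs2$separation, 50)
  expect_equal(cs2$closing_speed, 5)
  # mover heading straight at a static partner: closing speed = tip speed
  mover <- data.frame(time_h = 0:4, tip_id = "m", x = seq(20, 12, by = -2),
                      y = 0)
  static <- data.frame(time_h = 0:4, tip_id = "s", x = 0, y = 0)
  cs3 <- closing_speed_table(static, mover)
  expect_equal(cs3$closing_speed, tip_speeds(mover, stride = 1)$speed)
  expect_error(closing_speed_table(a, data.frame(time_h = c(0, 2), x = 0,
                                                 y = 0)),
               "identical frame times")
})
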