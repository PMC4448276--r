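# Growth engine: threshold-gated bifurcation, field-guided tip advance,
# stalk deposition, preset multi-bud scenarios.

KIND_TIP <- 1L
KIND_STALK <- 2L

# neighbour offsets in fixed evaluation order (N, NE, E, SE, S, SW, W, NW);
# a fixed order keeps the RNG draw sequence reproducible
NBR_DX <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
NBR_DY <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
# unit-radius probe offsets for candidate evaluation: sampling the field at
# Euclidean radius 1 in each candidate direction keeps direction choice
# isotropic (the diagonal neighbour cells themselves sit at radius sqrt(2),
# which would otherwise bias every tip onto 45-degree lattice diagonals)
PROBE_DX <- NBR_DX / sqrt(NBR_DX^2 + NBR_DY^2)
PROBE_DY <- NBR_DY / sqrt(NBR_DX^2 + NBR_DY^2)

#' Simulation scenarios
#'
#' Named starting anatomies for the simulator. `single_bud` is one unbranched
#' trunk entering from the bottom edge; `head_on_pair` is two trunks entering
#' from the left and right edges at the same height, aimed directly at one
#' another; `offset_pair` shifts the right-hand trunk vertically by
#' `lateral_offset`; `triple` adds a third trunk entering from the bottom.
#'
#' @param name One of `"single_bud"`, `"head_on_pair"`, `"offset_pair"`,
#'   `"triple"`.
#' @param trunk_length Length in cells of each unbranched starting trunk.
#' @param lateral_offset Vertical offset in cells between the two trunks
#'   (`offset_pair` only).
#' @return An object of class `sa_scenario`.
#' @examples
#' scenario("head_on_pair")
#' @export
scenario <- function(name = c("single_bud", "head_on_pair", "offset_pair",
                              "triple"),
                     trunk_length = 15, lateral_offset = 30) {
  name <- match.arg(name)
  structure(list(name = name, trunk_length = as.integer(trunk_length),
                 lateral_offset = as.integer(lateral_offset)),
            class = "sa_scenario")
}

#' @export
print.sa_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (trunk length %d%s)\n", x$name, x$trunk_length,
              if (x$name == "offset_pair")
                sprintf(", lateral offset %d", x$lateral_offset) else ""))
  invisible(x)
}

# --- internal mutable-ish state -------------------------------------------

# The live state is an environment (reference semantics): tip moves mutate
# element vectors and the occupancy matrix in place, which keeps stepping
# O(1) in allocations instead of copying the whole state per move.
new_state <- function(params, seed = NA_integer_) {
  validate_params(params)
  cap <- 1024L
  e <- new.env(parent = emptyenv())
  e$step <- 0L; e$params <- params; e$seed <- as.integer(seed)
  e$n <- 0L; e$cap <- cap
  e$x <- integer(cap); e$y <- integer(cap); e$tree <- integer(cap)
  e$kind <- integer(cap); e$parent <- integer(cap); e$gen <- integer(cap)
  e$birth <- integer(cap)
  e$occ <- matrix(0L, params$domain_width, params$domain_height)
  e$t_uid <- integer(0); e$t_elem <- integer(0); e$t_dist <- numeric(0)
  e$n_stalled <- 0L
  e$next_uid <- 1L
  e$events <- list()
  e$contacts <- list()
  class(e) <- "sa_state"
  e
}

#' @export
print.sa_state <- function(x, ...) {
  cat(sprintf("Simulation state: step %d, %d elements, %d active tip(s), %d retired\n",
              x$step, x$n, length(x$t_uid), x$n_stalled))
  invisible(x)
}

grow_state <- function(state, need) {
  while (state$cap < need) {
    add <- state$cap
    for (f in c("x", "y", "tree", "kind", "parent", "gen", "birth"))
      state[[f]] <- c(state[[f]], integer(add))
    state$cap <- state$cap + add
  }
  state
}

add_element <- function(state, x, y, kind, parent, gen, birth) {
  state <- grow_state(state, state$n + 1L)
  i <- state$n + 1L
  state$n <- i
  state$x[i] <- x; state$y[i] <- y
  state$kind[i] <- kind; state$parent[i] <- parent
  state$gen[i] <- gen; state$birth[i] <- birth
  state$tree[i] <- if (parent == 0L) 0L else state$tree[parent]
  # live inter-tree contact monitor: a newly occupied cell touching (8-way)
  # a cell of another tree is a collision event
  nx <- x + NBR_DX; ny <- y + NBR_DY
  ok <- nx >= 0L & nx < state$params$domain_width &
        ny >= 0L & ny < state$params$domain_height
  nb <- state$occ[cbind(nx[ok] + 1L, ny[ok] + 1L)]
  nb <- nb[nb > 0L]
  other <- nb[state$tree[nb] != state$tree[i] & state$tree[nb] != 0L]
  if (length(other))
    state$contacts[[length(state$contacts) + 1L]] <-
      c(step = state$step, x = x, y = y,
        tree1 = state$tree[i], tree2 = state$tree[other[1]])
  state$occ[x + 1L, y + 1L] <- i
  state
}

# noisy summed field at a real point, excluding element index `excl` (0 = none)
state_field <- function(state, px, py, excl = 0L, noisy = TRUE) {
  n <- state$n
  if (n == 0L ||
      (state$params$source_strength == 0 &&
       state$params$tip_source_strength == 0)) {
    v <- 0
  } else {
    idx <- seq_len(n)
    if (excl > 0L) idx <- idx[idx != excl]
    w <- ifelse(state$kind[idx] == KIND_TIP,
                state$params$tip_source_strength,
                state$params$source_strength)
    v <- .field_sum(px, py, state$x[idx], state$y[idx],
                    w, state$params$decay_length)
  }
  if (noisy) v <- max(0, v + stats::rnorm(1, 0, state$params$noise_sd))
  v
}

# indices (into NBR_DX/NBR_DY) of the free in-domain neighbour cells
free_neighbours <- function(state, cx, cy) {
  nx <- cx + NBR_DX
  ny <- cy + NBR_DY
  ok <- nx >= 0L & nx < state$params$domain_width &
        ny >= 0L & ny < state$params$domain_height
  ok[ok] <- state$occ[cbind(nx[ok] + 1L, ny[ok] + 1L)] == 0L
  which(ok)
}

# one noisy field evaluation per candidate direction, at the unit-radius
# probe point; the tip's own cell is excluded. Batched over candidates for
# speed; the RNG draw sequence matches per-candidate evaluation.
candidate_fields <- function(state, cx, cy, dirs, excl) {
  k <- length(dirs)
  n <- state$n
  par <- state$params
  if (n == 0L || (par$source_strength == 0 && par$tip_source_strength == 0)) {
    return(pmax(0, stats::rnorm(k, 0, par$noise_sd)))
  }
  idx <- seq_len(n)
  if (excl > 0L) idx <- idx[idx != excl]
  w <- ifelse(state$kind[idx] == KIND_TIP,
              par$tip_source_strength, par$source_strength)
  px <- cx + PROBE_DX[dirs]
  py <- cy + PROBE_DY[dirs]
  dx <- outer(state$x[idx], px, "-")
  dy <- outer(state$y[idx], py, "-")
  v <- colSums(w * exp(-sqrt(dx * dx + dy * dy) / par$decay_length))
  pmax(0, v + stats::rnorm(k, 0, par$noise_sd))
}

tip_slot <- function(state, tip_uid) match(tip_uid, state$t_uid)

#' Threshold-gated bifurcation of one tip
#'
#' A tip bifurcates only when the concentration it senses (the summed field
#' of every occupied cell except its own, with noise) is below
#' `branch_threshold`, it has travelled at least `refractory_length` cells
#' since its last branch, and two admissible daughter cells exist. On
#' bifurcation the tip cell becomes a stalk (the branch point) and two new
#' tips of the next generation occupy a diametrically opposite pair of free
#' neighbour cells - the pair with the lowest total field, falling back to
#' the lowest-field mutually non-adjacent pair under crowding; the daughters
#' contribute to the field immediately. Inability to branch is a no-op, not
#' an error.
#'
#' @param state A simulation state (`sa_state`).
#' @param tip_uid Persistent tip identity (see `state$t_uid`).
#' @return The updated state.
#' @seealso [advance_tip()], [sim_step()], [run_scenario()]
#' @export
maybe_bifurcate <- function(state, tip_uid) {
  slot <- tip_slot(state, tip_uid)
  if (is.na(slot)) return(state)
  e <- state$t_elem[slot]
  cx <- state$x[e]; cy <- state$y[e]
  C <- state_field(state, cx, cy, excl = e, noisy = TRUE)
  if (C >= state$params$branch_threshold) return(state)
  if (state$t_dist[slot] < state$params$refractory_length) return(state)
  dirs <- free_neighbours(state, cx, cy)
  if (length(dirs) < 2L) return(state)
  f <- candidate_fields(state, cx, cy, dirs, excl = e)
  nbx <- cx + NBR_DX[dirs]
  nby <- cy + NBR_DY[dirs]
  # a bifurcating tip splits into two opposite directions: daughters occupy
  # the diametric pair of free cells with the lowest total field (lateral
  # tip-splitting). The pair choice is field-driven and identical for every
  # generation; the realized divergence angle is then narrowed from 180 by
  # the surrounding field as the daughters elongate. If no diametric pair
  # is free (crowding), fall back to the lowest-field non-adjacent pair.
  nc <- length(dirs)
  best <- NULL; best_sum <- Inf
  for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc) {
    if (NBR_DX[dirs[i]] != -NBR_DX[dirs[j]] ||
        NBR_DY[dirs[i]] != -NBR_DY[dirs[j]]) next
    if (f[i] + f[j] < best_sum) {
      best_sum <- f[i] + f[j]
      best <- c(i, j)
    }
  }
  if (is.null(best)) {
    for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc) {
      if (max(abs(nbx[i] - nbx[j]), abs(nby[i] - nby[j])) <= 1L) next
      if (f[i] + f[j] < best_sum) {
        best_sum <- f[i] + f[j]
        best <- c(i, j)
      }
    }
  }
  if (is.null(best)) return(state)
  d1 <- best[1]; d2 <- best[2]

  gen_new <- state$gen[e] + 1L
  state$kind[e] <- KIND_STALK
  for (k in c(d1, d2)) {
    state <- add_element(state, nbx[k], nby[k], KIND_TIP, e,
                         gen_new, state$step)
    state$t_uid <- c(state$t_uid, state$next_uid)
    state$t_elem <- c(state$t_elem, state$n)
    state$t_dist <- c(state$t_dist, 0)
    state$next_uid <- state$next_uid + 1L
  }
  keep <- -slot
  state$t_uid <- state$t_uid[keep]
  state$t_elem <- state$t_elem[keep]
  state$t_dist <- state$t_dist[keep]
  state$events[[length(state$events) + 1L]] <-
    c(step = state$step, x = cx, y = cy, parent_generation = state$gen[e],
      tree_id = state$tree[e])
  state
}

#' Field-guided advance of one tip
#'
#' With probability `1 / (1 + C / speed_half_saturation)` - where `C` is the
#' noisy field sensed at the tip, excluding its own cell - the tip moves to
#' the free 8-neighbour cell whose direction has the lowest evaluated field
#' (one noisy evaluation per candidate, sampled at a unit-radius probe point
#' so that direction choice is isotropic; exact ties broken uniformly at
#' random). The vacated cell is left behind as a stalk. High local
#' concentration slows a tip, even to a stop. A tip with no free neighbour
#' at all is permanently enclosed and retires from the active list (its cell
#' remains a tip).
#'
#' @inheritParams maybe_bifurcate
#' @return The updated state.
#' @export
advance_tip <- function(state, tip_uid) {
  slot <- tip_slot(state, tip_uid)
  if (is.na(slot)) return(state)
  e <- state$t_elem[slot]
  cx <- state$x[e]; cy <- state$y[e]
  dirs <- free_neighbours(state, cx, cy)
  if (length(dirs) == 0L) {
    # fully enclosed: occupancy never clears, so the tip is stalled for
    # good - retire it from the active list (its cell stays a tip)
    keep <- -slot
    state$t_uid <- state$t_uid[keep]
    state$t_elem <- state$t_elem[keep]
    state$t_dist <- state$t_dist[keep]
    state$n_stalled <- state$n_stalled + 1L
    return(state)
  }
  C <- state_field(state, cx, cy, excl = e, noisy = TRUE)
  p_move <- 1 / (1 + C / state$params$speed_half_saturation)
  if (stats::runif(1) >= p_move) return(state)
  f <- candidate_fields(state, cx, cy, dirs, excl = e)
  best <- which(f == min(f))
  pick <- if (length(best) == 1L) best else best[sample(length(best), 1L)]
  nx <- cx + NBR_DX[dirs[pick]]; ny <- cy + NBR_DY[dirs[pick]]
  step_len <- sqrt((nx - cx)^2 + (ny - cy)^2)
  state$kind[e] <- KIND_STALK
  state <- add_element(state, nx, ny, KIND_TIP, e, state$gen[e], state$step)
  state$t_elem[slot] <- state$n
  state$t_dist[slot] <- state$t_dist[slot] + step_len
  state
}

#' Advance the whole simulation by one step
#'
#' Iterates over the tips present at the start of the step in RNG-shuffled
#' order; each tip first tests the bifurcation gate ([maybe_bifurcate()]),
#' then - if it is still a tip - attempts a move ([advance_tip()]). Stalks
#' are left behind by advancing tips. Daughters created during a step first
#' act on the following step.
#'
#' @param state A simulation state (`sa_state`).
#' @return The updated state, with its step counter incremented.
#' @export
sim_step <- function(state) {
  uids <- state$t_uid
  if (length(uids) > 1L) uids <- uids[sample.int(length(uids))]
  for (u in uids) {
    state <- maybe_bifurcate(state, u)
    state <- advance_tip(state, u)
  }
  state$step <- state$step + 1L
  state
}

# --- scenario construction -------------------------------------------------

add_trunk <- function(state, x0, y0, dx, dy, len, birth = 0L) {
  tree_id <- max(0L, state$tree[seq_len(state$n)]) + 1L
  state <- add_element(state, x0, y0,
                       if (len == 1L) KIND_TIP else KIND_STALK, 0L, 0L, birth)
  state$tree[state$n] <- tree_id
  root <- state$n
  prev <- root
  for (k in seq_len(len - 1L)) {
    state <- add_element(state, x0 + k * dx, y0 + k * dy,
                         if (k == len - 1L) KIND_TIP else KIND_STALK,
                         prev, 0L, birth)
    prev <- state$n
  }
  state$t_uid <- c(state$t_uid, state$next_uid)
  state$t_elem <- c(state$t_elem, prev)
  # the starting stalk is a mature unbranched tubule: its tip is past any
  # refractory distance and may branch as soon as the field allows
  state$t_dist <- c(state$t_dist,
                    max(as.numeric(len), state$params$refractory_length))
  state$next_uid <- state$next_uid + 1L
  state
}

init_scenario <- function(scn, params, seed = NA_integer_) {
  stopifnot(inherits(scn, "sa_scenario"))
  state <- new_state(params, seed)
  w <- params$domain_width; h <- params$domain_height
  Tn <- scn$trunk_length
  midx <- as.integer(w %/% 2L); midy <- as.integer(h %/% 2L)
  if (scn$name == "single_bud") {
    state <- add_trunk(state, midx, 0L, 0L, 1L, Tn)
  } else if (scn$name == "head_on_pair") {
    state <- add_trunk(state, 0L, midy, 1L, 0L, Tn)
    state <- add_trunk(state, w - 1L, midy, -1L, 0L, Tn)
  } else if (scn$name == "offset_pair") {
    off <- scn$lateral_offset
    y2 <- min(h - 1L, midy + off)
    state <- add_trunk(state, 0L, midy, 1L, 0L, Tn)
    state <- add_trunk(state, w - 1L, y2, -1L, 0L, Tn)
  } else if (scn$name == "triple") {
    state <- add_trunk(state, 0L, midy, 1L, 0L, Tn)
    state <- add_trunk(state, w - 1L, midy, -1L, 0L, Tn)
    state <- add_trunk(state, midx, 0L, 0L, 1L, Tn)
  } else {
    stop("unknown scenario: ", scn$name, call. = FALSE)
  }
  state
}

# --- result extraction -----------------------------------------------------

state_to_trees <- function(state) {
  n <- state$n
  ids <- sort(unique(state$tree[seq_len(n)]))
  lapply(ids, function(tid) {
    idx <- which(state$tree[seq_len(n)] == tid)
    remap <- integer(n)
    remap[idx] <- seq_along(idx)
    par <- state$parent[idx]
    par2 <- ifelse(par == 0L, NA_integer_, remap[pmax(par, 1L)])
    tubule_tree(data.frame(
      x = state$x[idx], y = state$y[idx],
      kind = c("tip", "stalk")[state$kind[idx]],
      parent = par2, generation = state$gen[idx],
      birth_step = state$birth[idx]), tree_id = tid)
  })
}

record_tracks <- function(state) {
  if (length(state$t_uid) == 0L) return(NULL)
  data.frame(time_h = as.numeric(state$step), tip_id = state$t_uid,
             x = as.numeric(state$x[state$t_elem]),
             y = as.numeric(state$y[state$t_elem]))
}

#' Run a named scenario of the self-avoidance simulation
#'
#' Builds the starting trunks for the scenario, runs `n_steps` simulation
#' steps (stopping early if every tip is stalled), records tip positions
#' every `record_every` steps, and returns the final trees, the tip-track
#' table and the list of bifurcation events. Runs are bit-reproducible for a
#' given `(params, scenario, seed, n_steps)`.
#'
#' @param scn An [scenario()] object (or a scenario name).
#' @param params An [model_params()] object.
#' @param seed Integer RNG seed for the run.
#' @param n_steps Number of steps to simulate (>= 1).
#' @param record_every Recording stride for the tip-track table, in steps.
#' @param stop_on_contact If `TRUE`, stop as soon as a cell of one tree is
#'   deposited touching (8-way) a cell of another - useful when only the
#'   occurrence of an inter-tree collision matters.
#' @return An object of class `sa_result`: a list with components `trees`
#'   (list of [tubule_tree()]), `tracks` (data.frame `time_h, tip_id, x, y`),
#'   `bifurcations` (data.frame of branch events), `contacts` (data.frame of
#'   inter-tree contact events seen during growth), `state`, `params`,
#'   `scenario`, `seed`, `n_steps`.
#' @examples
#' \donttest{
#' res <- run_scenario(scenario("single_bud"), model_params(), seed = 1,
#'                     n_steps = 150)
#' res
#' angles_by_generation(res)
#' }
#' @export
run_scenario <- function(scn, params = model_params(), seed = 1L,
                         n_steps = 300L, record_every = 5L,
                         stop_on_contact = FALSE) {
  if (is.character(scn)) scn <- scenario(scn)
  stopifnot(inherits(scn, "sa_scenario"), n_steps >= 1L)
  validate_params(params)
  set.seed(seed)
  state <- init_scenario(scn, params, seed)
  tracks <- list(record_tracks(state))
  for (k in seq_len(n_steps)) {
    state <- sim_step(state)
    if (state$step %% record_every == 0L || k == n_steps)
      tracks[[length(tracks) + 1L]] <- record_tracks(state)
    if (length(state$t_uid) == 0L) break
    if (stop_on_contact && length(state$contacts)) break
  }
  tracks <- unique(do.call(rbind, tracks))
  rownames(tracks) <- NULL
  bif <- if (length(state$events))
    as.data.frame(do.call(rbind, state$events)) else
    data.frame(step = integer(0), x = integer(0), y = integer(0),
               parent_generation = integer(0), tree_id = integer(0))
  contacts <- if (length(state$contacts))
    as.data.frame(do.call(rbind, state$contacts)) else
    data.frame(step = integer(0), x = integer(0), y = integer(0),
               tree1 = integer(0), tree2 = integer(0))
  structure(list(trees = state_to_trees(state), tracks = tracks,
                 bifurcations = bif, contacts = contacts, state = state,
                 params = params, scenario = scn, seed = as.integer(seed),
                 n_steps = as.integer(n_steps)),
            class = "sa_result")
}

#' @export
print.sa_result <- function(x, ...) {
  cat(sprintf("Self-avoidance run: scenario '%s', seed %d, %d steps\n",
              x$scenario$name, x$seed, x$state$step))
  cat(sprintf("  %d tree(s), %d elements, %d bifurcation events, %d track rows\n",
              length(x$trees), x$state$n, nrow(x$bifurcations),
              nrow(x$tracks)))
  invisible(x)
}
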