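# Morphometrics: divergence angles by generation, collision scoring, bead
# closest-approach, tip-speed and closing-speed kinematics.

#' Divergence angle at a branch point
#'
#' The divergence angle is the angle between the directions along which the
#' two daughter branches lie after elongation, the operational equivalent of
#' drawing skeleton lines from the branch point and measuring with a
#' protractor. For each daughter, the direction is the unit vector from the
#' branch point to the skeleton point at arc length `L` along that daughter
#' (or to its end, if the daughter is shorter or bifurcates again first).
#'
#' @param tree A [tubule_tree()].
#' @param branch_point Either the element row index of the branch point, or
#'   an `(x, y)` cell.
#' @param L Arc-length lever arm in cells.
#' @return The angle in degrees, in `[0, 180]`.
#' @examples
#' tr <- gen_toy_tree(toy_tree_spec(branches = data.frame(
#'   generation = 1, angle = 90, length = 12)))
#' divergence_angle(tr, branch_points(tr), L = 10)
#' @export
divergence_angle <- function(tree, branch_point, L = 10) {
  stopifnot(inherits(tree, "tubule_tree"))
  el <- tree$elements
  if (length(branch_point) == 2L) {
    bp <- which(el$x == branch_point[1] & el$y == branch_point[2])
    if (length(bp) != 1L)
      stop("branch_point cell not found in tree", call. = FALSE)
  } else if (length(branch_point) == 1L) {
    bp <- as.integer(branch_point)
  } else {
    stop("branch_point must be an element index or an (x, y) cell",
         call. = FALSE)
  }
  kids <- children_of(tree, bp)
  if (length(kids) != 2L)
    stop("branch point must have exactly two daughter branches", call. = FALSE)
  v <- lapply(kids, function(k) daughter_vector(tree, bp, k, L))
  ang <- vec_angle_deg(v[[1]], v[[2]])
  ang
}

# unit-direction endpoint: walk along the daughter until arc length >= L,
# a further bifurcation, or the branch tip
daughter_vector <- function(tree, bp, child, L) {
  el <- tree$elements
  cur <- child
  arc <- sqrt((el$x[cur] - el$x[bp])^2 + (el$y[cur] - el$y[bp])^2)
  while (arc < L) {
    nxt <- children_of(tree, cur)
    if (length(nxt) != 1L) break
    arc <- arc + sqrt((el$x[nxt] - el$x[cur])^2 + (el$y[nxt] - el$y[cur])^2)
    cur <- nxt
  }
  c(el$x[cur] - el$x[bp], el$y[cur] - el$y[bp])
}

vec_angle_deg <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  cosang <- sum(a * b) / (na * nb)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' All divergence angles of a tree, labelled by branch generation
#'
#' Every branch point with exactly two daughters yields one angle record.
#' Generation 1 is the first bifurcation from the trunk; its angle is the
#' "first branch" divergence angle.
#'
#' @param x A [tubule_tree()], a list of them, or an `sa_result` from
#'   [run_scenario()].
#' @param L Arc-length lever arm in cells (defaults to the run's
#'   `arc_length_L` for `sa_result` input).
#' @return A data.frame with columns `tree_id`, `x`, `y`, `generation`,
#'   `angle_deg`.
#' @export
angles_by_generation <- function(x, L = NULL) {
  if (inherits(x, "sa_result")) {
    if (is.null(L)) L <- x$params$arc_length_L
    trees <- x$trees
  } else if (inherits(x, "tubule_tree")) {
    trees <- list(x)
  } else {
    trees <- x
  }
  if (is.null(L)) L <- 10
  out <- lapply(trees, function(tr) {
    bps <- branch_points(tr)
    bps <- bps[vapply(bps, function(b) length(children_of(tr, b)) == 2L, TRUE)]
    if (!length(bps))
      return(NULL)
    data.frame(
      tree_id = tr$tree_id,
      x = tr$elements$x[bps], y = tr$elements$y[bps],
      generation = vapply(bps, function(b)
        tr$elements$generation[children_of(tr, b)[1]], 0L),
      angle_deg = vapply(bps, function(b)
        divergence_angle(tr, b, L), 0))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(tree_id = integer(0), x = integer(0), y = integer(0),
                      generation = integer(0), angle_deg = numeric(0))
  rownames(out) <- NULL
  out
}

#' Collision scoring between and within tubule trees
#'
#' Mirrors categorical collision scoring of cultured trees: an approach so
#' close that no gap remains is a collision. On the lattice, two cells touch
#' when their Chebyshev distance is at most `contact_chebyshev`. Touching
#' cells of different trees are `inter_tree` events; touching cells of one
#' tree whose arc-length path through the tree exceeds `loop_min_path` are
#' `self_loop` events (closed loops of duct), while ordinary parent/daughter
#' adjacency is ignored.
#'
#' @param trees A `tubule_tree`, list of them, or `sa_result`.
#' @param contact_chebyshev Contact threshold in cells.
#' @param loop_min_path Minimum through-tree arc length (cells) for a
#'   same-tree contact to count as a loop.
#' @return A data.frame of events (`type`, `tree1`, `tree2`, `x1`, `y1`,
#'   `x2`, `y2`, `chebyshev`) with attribute `any_collision` (the categorical
#'   yes/no verdict); see [any_collision()].
#' @export
detect_collisions <- function(trees, contact_chebyshev = 1,
                              loop_min_path = 10) {
  if (inherits(trees, "sa_result")) trees <- trees$trees
  if (inherits(trees, "tubule_tree")) trees <- list(trees)
  cc <- as.integer(contact_chebyshev)
  cells <- do.call(rbind, lapply(seq_along(trees), function(i) {
    el <- trees[[i]]$elements
    data.frame(tree = trees[[i]]$tree_id, elem = seq_len(nrow(el)),
               tree_pos = i, x = el$x, y = el$y)
  }))
  ev <- list()
  if (!is.null(cells) && nrow(cells) > 1L) {
    ox <- min(cells$x); oy <- min(cells$y)
    W <- max(cells$x) - ox + 1L; H <- max(cells$y) - oy + 1L
    occ <- matrix(0L, W, H)
    occ[cbind(cells$x - ox + 1L, cells$y - oy + 1L)] <- seq_len(nrow(cells))
    offs <- expand.grid(dx = -cc:cc, dy = -cc:cc)
    offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
    for (i in seq_len(nrow(cells))) {
      nx <- cells$x[i] - ox + 1L + offs$dx
      ny <- cells$y[i] - oy + 1L + offs$dy
      ok <- nx >= 1L & nx <= W & ny >= 1L & ny <= H
      js <- occ[cbind(nx[ok], ny[ok])]
      js <- js[js > i]                        # each pair once
      for (j in js) {
        cheb <- max(abs(cells$x[i] - cells$x[j]), abs(cells$y[i] - cells$y[j]))
        if (cells$tree[i] != cells$tree[j]) {
          ev[[length(ev) + 1L]] <- data.frame(
            type = "inter_tree", tree1 = cells$tree[i], tree2 = cells$tree[j],
            x1 = cells$x[i], y1 = cells$y[i], x2 = cells$x[j], y2 = cells$y[j],
            chebyshev = cheb)
        } else {
          pd <- tree_path_distance(trees[[cells$tree_pos[i]]],
                                   cells$elem[i], cells$elem[j])
          if (pd > loop_min_path) {
            ev[[length(ev) + 1L]] <- data.frame(
              type = "self_loop", tree1 = cells$tree[i], tree2 = cells$tree[j],
              x1 = cells$x[i], y1 = cells$y[i], x2 = cells$x[j],
              y2 = cells$y[j], chebyshev = cheb)
          }
        }
      }
    }
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(type = character(0), tree1 = integer(0), tree2 = integer(0),
               x1 = integer(0), y1 = integer(0), x2 = integer(0),
               y2 = integer(0), chebyshev = integer(0))
  rownames(out) <- NULL
  attr(out, "any_collision") <- nrow(out) > 0L
  out
}

#' @rdname detect_collisions
#' @param events The data.frame returned by `detect_collisions()`.
#' @return `any_collision()` returns the categorical verdict: `TRUE` if any
#'   event was found.
#' @export
any_collision <- function(events) isTRUE(attr(events, "any_collision")) ||
  (is.data.frame(events) && nrow(events) > 0L)

#' Closest approach of a tree to a disc
#'
#' Edge-to-edge distance between a tree and a circular obstacle (the lattice
#' analogue of measuring the gap between a soaked bead and the nearest
#' branch): the minimum over tree cells of the Euclidean distance to the
#' disc centre minus the radius, floored at 0 for cells inside the disc.
#'
#' @param tree A [tubule_tree()].
#' @param center Numeric `(x, y)` disc centre.
#' @param radius Disc radius (> 0), same units as the coordinates.
#' @return The closest edge-to-edge distance (0 if the tree touches or
#'   enters the disc).
#' @export
closest_approach_to_disc <- function(tree, center, radius) {
  stopifnot(inherits(tree, "tubule_tree"), radius > 0)
  el <- tree$elements
  d <- sqrt((el$x - center[1])^2 + (el$y - center[2])^2) - radius
  max(0, min(d))
}

#' Tip speeds from a track table
#'
#' Frame-to-frame scalar speed of each tracked tip: for frame pairs
#' `(n, n+1)` sampled every `stride` frames, the Euclidean displacement
#' divided by elapsed time - the standard treatment of time-lapse tip
#' coordinates ("every 5 frames" sampling).
#'
#' @param track A data.frame with columns `time_h`, `tip_id`, `x`, `y`.
#' @param stride Sampling stride in frames.
#' @return A data.frame with columns `tip_id`, `time_h` (time at frame `n`)
#'   and `speed` (length units per hour).
#' @export
tip_speeds <- function(track, stride = 5) {
  check_track(track)
  out <- lapply(split(track, track$tip_id), function(tt) {
    tt <- tt[order(tt$time_h), ]
    if (any(diff(tt$time_h) <= 0))
      stop("track times must be strictly increasing per tip", call. = FALSE)
    nf <- nrow(tt)
    if (nf < 2L) return(NULL)
    i <- seq(1L, nf - 1L, by = stride)
    data.frame(
      tip_id = tt$tip_id[i], time_h = tt$time_h[i],
      speed = sqrt((tt$x[i + 1L] - tt$x[i])^2 + (tt$y[i + 1L] - tt$y[i])^2) /
        (tt$time_h[i + 1L] - tt$time_h[i]))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(tip_id = character(0), time_h = numeric(0),
                      speed = numeric(0))
  rownames(out) <- NULL
  out
}

#' Separation and closing speed of a pair of tracked tips
#'
#' For two tips recorded at the same frame times, computes their Euclidean
#' separation at every frame and the approach velocity between consecutive
#' frames: the raw velocity is `(d[n+1] - d[n]) / dt` (negative when the
#' tips approach); the closing speed is its negation, so that approaching
#' tips have positive closing speed. Both columns are returned.
#'
#' @param trackA,trackB Data.frames with columns `time_h`, `x`, `y` (a
#'   single tip each); frame times must match.
#' @return A data.frame with columns `time_h` (frame `n`), `separation` (at
#'   frame `n`), `raw_velocity` and `closing_speed`.
#' @export
closing_speed_table <- function(trackA, trackB) {
  a <- trackA[order(trackA$time_h), ]
  b <- trackB[order(trackB$time_h), ]
  if (nrow(a) != nrow(b) || any(a$time_h != b$time_h))
    stop("tracks must share identical frame times", call. = FALSE)
  if (any(diff(a$time_h) <= 0))
    stop("track times must be strictly increasing", call. = FALSE)
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  n <- length(d)
  if (n < 2L)
    return(data.frame(time_h = numeric(0), separation = numeric(0),
                      raw_velocity = numeric(0), closing_speed = numeric(0)))
  dt <- diff(a$time_h)
  raw <- diff(d) / dt
  data.frame(time_h = a$time_h[-n], separation = d[-n],
             raw_velocity = raw, closing_speed = -raw)
}

check_track <- function(track) {
  need <- c("time_h", "tip_id", "x", "y")
  miss <- setdiff(need, names(track))
  if (length(miss))
    stop("track table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(track$x)) || any(!is.finite(track$y)))
    stop("track coordinates must be finite", call. = FALSE)
  invisible(track)
}
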