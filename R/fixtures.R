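# Synthetic fixtures with known ground truth: tip-track pairs obeying a
# stop-distance closing-speed law, and toy trees with prescribed angles.

#' Closing-speed law for synthetic track pairs
#'
#' Generative law for pairs of approaching tips: at separation `d` the
#' deterministic closing speed is `max(0, c * ln(d / d0))` - log-linear in
#' separation, reaching a complete stop at the stop distance `d0` (default
#' 30 length units, the separation at which real approaching tips are
#' observed to stop). Gaussian frame noise is added on top of the floored
#' law, so recorded speeds may be slightly negative (tips jittering apart).
#' This is a test scaffold matching the *shape* of the observed log-linear
#' relation, not a biological claim.
#'
#' @param coefficient Speed per log-unit of separation (`c >= 0`).
#' @param stop_distance Separation at which deterministic approach stops
#'   (`d0 > 0`).
#' @param noise_sd Standard deviation of the per-frame speed noise.
#' @param initial_separation Starting separation (must exceed `d0`).
#' @param frame_interval Time between frames, hours.
#' @return An object of class `sa_track_law`.
#' @export
track_law <- function(coefficient = 5, stop_distance = 30, noise_sd = 1,
                      initial_separation = 120, frame_interval = 1) {
  law <- list(coefficient = coefficient, stop_distance = stop_distance,
              noise_sd = noise_sd, initial_separation = initial_separation,
              frame_interval = frame_interval)
  if (!all(vapply(law, function(v) is.numeric(v) && is.finite(v), TRUE)))
    stop("track law fields must be finite numbers", call. = FALSE)
  if (law$coefficient < 0 || law$stop_distance <= 0 || law$noise_sd < 0 ||
      law$frame_interval <= 0)
    stop("invalid track law: need c >= 0, d0 > 0, noise_sd >= 0, dt > 0",
         call. = FALSE)
  if (law$initial_separation <= law$stop_distance)
    stop("initial separation must exceed the stop distance", call. = FALSE)
  structure(law, class = "sa_track_law")
}

#' Generate synthetic pairs of approaching tip tracks
#'
#' Each pair consists of two tips approaching head-on along the x axis; per
#' frame the separation shrinks by the law speed (see [track_law()]) times
#' the frame interval, split equally between the two tips. The generating
#' parameters are stored in the `truth` attribute so analysis code can be
#' validated against known ground truth. Deterministic for a given seed.
#'
#' @param law An [track_law()] object.
#' @param n_pairs Number of tip pairs.
#' @param n_frames Number of recorded frames per tip (>= 3).
#' @param seed RNG seed.
#' @return A track data.frame (`time_h`, `tip_id`, `x`, `y`) with tip ids
#'   `p<k>a` / `p<k>b` and attribute `truth` (the law parameters).
#' @examples
#' trk <- gen_pair_tracks(track_law(noise_sd = 0), n_pairs = 1,
#'                        n_frames = 10, seed = 1)
#' pair <- split(trk, trk$tip_id)
#' closing_speed_table(pair[[1]], pair[[2]])
#' @export
gen_pair_tracks <- function(law = track_law(), n_pairs = 6, n_frames = 15,
                            seed = 1L) {
  stopifnot(inherits(law, "sa_track_law"))
  if (n_frames < 3L) stop("need n_frames >= 3", call. = FALSE)
  set.seed(seed)
  dt <- law$frame_interval
  rows <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    d <- law$initial_separation
    xa <- 0; xb <- d
    yk <- 50 * (k - 1)
    xs_a <- numeric(n_frames); xs_b <- numeric(n_frames)
    for (f in seq_len(n_frames)) {
      xs_a[f] <- xa; xs_b[f] <- xb
      v <- max(0, law$coefficient * log((xb - xa) / law$stop_distance)) +
        stats::rnorm(1, 0, law$noise_sd)
      xa <- xa + v * dt / 2
      xb <- xb - v * dt / 2
    }
    tt <- (seq_len(n_frames) - 1) * dt
    rows[[k]] <- data.frame(
      time_h = c(tt, tt),
      tip_id = rep(sprintf(c("p%02da", "p%02db"), k), each = n_frames),
      x = c(xs_a, xs_b), y = yk)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- unclass(law)
  out
}

#' Specification for a toy tree with prescribed branch angles
#'
#' Describes a symmetric binary toy tree: an upward trunk, then at each
#' branch generation a prescribed divergence angle and branch length.
#' Generation `g` settings apply to every branch point of that generation.
#'
#' @param trunk_length Trunk length in cells (>= 2).
#' @param branches A data.frame with columns `generation` (1, 2, ...),
#'   `angle` (degrees, in (0, 180)) and `length` (cells, >= 2). May have
#'   zero rows for a bare trunk.
#' @param origin Root cell `(x, y)`.
#' @return An object of class `sa_toy_spec`.
#' @export
toy_tree_spec <- function(trunk_length = 15,
                          branches = data.frame(generation = integer(0),
                                                angle = numeric(0),
                                                length = numeric(0)),
                          origin = c(100, 0)) {
  stopifnot(is.data.frame(branches))
  if (nrow(branches)) {
    if (!all(c("generation", "angle", "length") %in% names(branches)))
      stop("branches needs columns generation, angle, length", call. = FALSE)
    if (any(branches$angle <= 0 | branches$angle >= 180))
      stop("prescribed angles must lie in (0, 180)", call. = FALSE)
    if (any(branches$length < 2))
      stop("branch lengths must be >= 2 cells", call. = FALSE)
    if (!identical(sort(branches$generation), seq_len(nrow(branches)) * 1.0) &&
        !identical(as.integer(sort(branches$generation)),
                   seq_len(nrow(branches))))
      stop("branch generations must be 1, 2, ... with one row each",
           call. = FALSE)
  }
  structure(list(trunk_length = as.integer(trunk_length),
                 branches = branches[order(branches$generation), ,
                                     drop = FALSE],
                 origin = as.numeric(origin)),
            class = "sa_toy_spec")
}

# raster cells of a straight segment from real point p0 along unit vector u,
# until Euclidean length >= len; cells are 8-connected and deduplicated
raster_segment <- function(p0, u, len) {
  stepl <- 1 / max(abs(u))
  ts <- seq(stepl, len + stepl / 2, by = stepl)
  cells <- unique(cbind(round(p0[1] + ts * u[1]), round(p0[2] + ts * u[2])))
  cells
}

rot2 <- function(u, deg) {
  th <- deg * pi / 180
  c(cos(th) * u[1] - sin(th) * u[2], sin(th) * u[1] + cos(th) * u[2])
}

#' Generate a toy tubule tree with prescribed divergence angles
#'
#' Rasterises straight branches onto the lattice at the angles prescribed by
#' an [toy_tree_spec()]: the trunk grows upward, and each branch point
#' splits symmetrically about its parent direction by the prescribed
#' divergence angle. The intended angle of every branch point is stored in
#' the `truth_angles` attribute, so that angle measurements can be checked
#' against ground truth (recovery is exact up to rasterisation error).
#' Construction is deterministic; the `seed` argument is accepted for
#' interface symmetry with the other generators.
#'
#' @param spec An [toy_tree_spec()].
#' @param seed Unused (deterministic construction).
#' @return A [tubule_tree()] with attribute `truth_angles` (data.frame of
#'   `generation`, `angle`).
#' @examples
#' tr <- gen_toy_tree(toy_tree_spec(branches = data.frame(
#'   generation = 1:2, angle = c(150, 95), length = c(20, 20))))
#' angles_by_generation(tr, L = 10)
#' @export
gen_toy_tree <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sa_toy_spec"))
  el <- data.frame(x = integer(0), y = integer(0), kind = character(0),
                   parent = integer(0), generation = integer(0),
                   birth_step = integer(0))
  occ <- new.env(parent = emptyenv())
  key <- function(c2) paste(c2[1], c2[2])
  add_cell <- function(cell, kind, parent, gen) {
    k <- key(cell)
    if (!is.null(occ[[k]]))
      stop("invalid toy-tree spec: branches overlap at cell (",
           cell[1], ", ", cell[2], ")", call. = FALSE)
    el[nrow(el) + 1L, ] <<- list(as.integer(cell[1]), as.integer(cell[2]),
                                 kind, parent, as.integer(gen), 0L)
    occ[[k]] <- nrow(el)
    nrow(el)
  }
  add_branch <- function(p0, u, len, parent, gen, terminal) {
    cells <- raster_segment(p0, u, len)
    last <- parent
    for (i in seq_len(nrow(cells))) {
      kind <- if (terminal && i == nrow(cells)) "tip" else "stalk"
      last <- add_cell(cells[i, ], kind, last, gen)
    }
    last
  }

  root <- add_cell(round(spec$origin), "stalk", NA_integer_, 0L)
  up <- c(0, 1)
  trunk_end <- add_branch(round(spec$origin), up, spec$trunk_length - 1, root,
                          0L, terminal = nrow(spec$branches) == 0L)
  if (nrow(spec$branches) == 0L) {
    tr <- tubule_tree(el)
    attr(tr, "truth_angles") <- data.frame(generation = integer(0),
                                           angle = numeric(0))
    return(tr)
  }
  frontier <- list(list(elem = trunk_end, dir = up))
  truth <- list()
  for (g in seq_len(nrow(spec$branches))) {
    row <- spec$branches[g, ]
    terminal <- g == nrow(spec$branches)
    new_frontier <- list()
    for (node in frontier) {
      p0 <- c(el$x[node$elem], el$y[node$elem])
      for (sgn in c(-1, 1)) {
        u <- rot2(node$dir, sgn * row$angle / 2)
        endi <- add_branch(p0, u, row$length, node$elem, row$generation,
                           terminal)
        new_frontier[[length(new_frontier) + 1L]] <-
          list(elem = endi, dir = u)
      }
      truth[[length(truth) + 1L]] <-
        data.frame(generation = row$generation, angle = row$angle)
    }
    frontier <- new_frontier
  }
  tr <- tubule_tree(el)
  attr(tr, "truth_angles") <- do.call(rbind, truth)
  tr
}
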