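#' Contribution of a single occupied cell to the repulsive field
#'
#' Every occupied cell of a tubule tree is a point source of a diffusible
#' repulsive factor. Under the rapid-diffusion (steady-state) assumption with
#' first-order loss, the concentration contributed at distance `d` decays
#' exponentially: `s * exp(-d / lambda)` with `s = source_strength` and
#' `lambda = decay_length`.
#'
#' @param d Euclidean distance in cell units (non-negative; vectorised).
#' @param params An [model_params()] object.
#' @return Concentration contribution(s), same length as `d`.
#' @examples
#' point_source_contribution(0, model_params())   # = source_strength
#' point_source_contribution(4, model_params(decay_length = 4))  # = s * exp(-1)
#' @export
point_source_contribution <- function(d, params = model_params()) {
  validate_params(params)
  if (any(!is.finite(d)) || any(d < 0))
    stop("distance d must be finite and >= 0", call. = FALSE)
  params$source_strength * exp(-d / params$decay_length)
}

# Fast inner kernel: summed field at (px, py) from sources (sx, sy) with
# per-source strengths w.
.field_sum <- function(px, py, sx, sy, w, lambda) {
  if (length(sx) == 0L) return(0)
  sum(w * exp(-sqrt((sx - px)^2 + (sy - py)^2) / lambda))
}

# occupied cells of one tree or a list of trees with their source strengths
tree_sources <- function(trees, params) {
  if (inherits(trees, "tubule_tree")) trees <- list(trees)
  cells <- do.call(rbind, lapply(trees, function(tr)
    cbind(tr$elements$x, tr$elements$y,
          ifelse(tr$elements$kind == "tip",
                 params$tip_source_strength, params$source_strength))))
  if (is.null(cells)) matrix(numeric(0), ncol = 3) else cells
}

#' Total repulsive field at a point
#'
#' Sums the exponential contributions of every occupied cell of the given
#' trees at a (real-valued) query point - stalk cells at `source_strength`,
#' tip cells at `tip_source_strength` - optionally excluding one cell (a tip
#' evaluating the field it senses excludes its own cell) and optionally adding
#' one zero-mean Gaussian noise draw; the noisy total is clamped at 0. The
#' field is recomputed from current anatomy every time - the steady-state
#' kernel carries no history.
#'
#' @param point Numeric length-2 vector `(x, y)`; must lie inside the domain.
#' @param trees A `tubule_tree` or list of them.
#' @param params An [model_params()] object.
#' @param noise_on If `TRUE`, adds one `rnorm(1, 0, noise_sd)` draw from the
#'   current RNG stream and clamps at 0. Seed the session RNG (`set.seed`) for
#'   reproducibility.
#' @param exclude Optional integer cell `(x, y)` whose contribution is
#'   omitted.
#' @return A single non-negative concentration.
#' @examples
#' tr <- tubule_tree(data.frame(x = 10L, y = 10L, kind = "tip",
#'                              parent = NA, generation = 0L, birth_step = 0L))
#' field_at(c(10, 14), tr, model_params(decay_length = 4))  # = s * exp(-1)
#' @export
field_at <- function(point, trees, params = model_params(),
                     noise_on = FALSE, exclude = NULL) {
  validate_params(params)
  if (length(point) != 2L || any(!is.finite(point)))
    stop("point must be a finite (x, y) pair", call. = FALSE)
  if (point[1] < 0 || point[1] >= params$domain_width ||
      point[2] < 0 || point[2] >= params$domain_height)
    stop("point lies outside the domain", call. = FALSE)
  cells <- tree_sources(trees, params)
  if (!is.null(exclude) && nrow(cells)) {
    keep <- !(cells[, 1] == exclude[1] & cells[, 2] == exclude[2])
    cells <- cells[keep, , drop = FALSE]
  }
  v <- .field_sum(point[1], point[2], cells[, 1], cells[, 2],
                  cells[, 3], params$decay_length)
  if (noise_on) v <- max(0, v + stats::rnorm(1, 0, params$noise_sd))
  v
}

#' Repulsive field over the whole domain
#'
#' Evaluates the noise-free field at every cell of the domain; used for
#' snapshots and visualisation. Entry `[x + 1, y + 1]` of the returned matrix
#' is the field at cell `(x, y)`.
#'
#' @inheritParams field_at
#' @return A `domain_width` x `domain_height` numeric matrix.
#' @export
field_grid <- function(trees, params = model_params()) {
  validate_params(params)
  w <- params$domain_width
  h <- params$domain_height
  g <- matrix(0, nrow = w, ncol = h)
  cells <- tree_sources(trees, params)
  if (nrow(cells) == 0L) return(g)
  gx <- matrix(0:(w - 1L), nrow = w, ncol = h)
  gy <- matrix(0:(h - 1L), nrow = w, ncol = h, byrow = TRUE)
  lam <- params$decay_length
  for (i in seq_len(nrow(cells))) {
    g <- g + cells[i, 3] *
      exp(-sqrt((gx - cells[i, 1])^2 + (gy - cells[i, 2])^2) / lam)
  }
  g
}
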