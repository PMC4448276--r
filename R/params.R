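#' Model parameters for the self-avoidance simulation
#'
#' Bundles every tunable constant of the lattice model. Tubule trees occupy
#' integer cells of a 2D grid; every occupied cell is a point source of a
#' repulsive factor whose contribution at distance `d` (in cell units) is
#' `source_strength * exp(-d / decay_length)`. Tips sense the summed field
#' (plus Gaussian noise), branch when it falls below `branch_threshold`, and
#' advance toward the lowest local field with probability
#' `1 / (1 + C / speed_half_saturation)`.
#'
#' The defaults are the package's reference parameter set, calibrated once so
#' that a single bud reproduces the emergent angle narrowing (wide ~150 deg
#' first branch, ~95 deg later branches) and collision avoidance between
#' neighbouring trees; see the methods vignette for the calibration rationale.
#'
#' @param source_strength Concentration contributed by a stalk cell at
#'   distance 0 (arbitrary concentration units). Non-negative; 0 switches the
#'   repulsive signalling off (the in-silico analogue of blocking secretion).
#' @param tip_source_strength Concentration contributed by a tip cell at
#'   distance 0. Branch tips are the strongest secretion sites of the
#'   repellent in the developing kidney, and making tips stronger sources
#'   than the stalk trail is what lets the presence of nearby tips - rather
#'   than the tree's bulk - set the divergence angles. `NULL` scales with
#'   `source_strength` (default 20 x).
#' @param decay_length Length constant of the exponential decay, in cells.
#'   Must be positive.
#' @param noise_sd Standard deviation of the zero-mean Gaussian noise added to
#'   each field evaluation (concentration units). The noisy total is clamped
#'   at 0.
#' @param branch_threshold Tips bifurcate only when their sensed field is
#'   below this concentration.
#' @param speed_half_saturation Concentration at which the per-step move
#'   probability halves. Must be positive.
#' @param refractory_length Minimum arc length (cells) a tip must travel after
#'   a bifurcation before it may branch again.
#' @param contact_chebyshev Chebyshev distance (cells) at or below which two
#'   occupied cells count as touching, for collision scoring.
#' @param domain_width,domain_height Grid size in cells (at least 16).
#' @param arc_length_L Lever arm (cells) used when measuring divergence
#'   angles: the skeleton point this far along each daughter defines its
#'   direction.
#' @param cells_per_micron Optional scale factor converting cells to microns
#'   in morphometric output; `NA` (default) leaves results in cell units.
#'
#' @return An object of class `sa_params` (a named list).
#' @examples
#' p <- model_params()
#' p$decay_length
#' model_params(source_strength = 0)  # signalling-blocked variant
#' @export
model_params <- function(source_strength = 1,
                         tip_source_strength = NULL,
                         decay_length = 16,
                         noise_sd = 0.05,
                         branch_threshold = 20.5,
                         speed_half_saturation = 16.5,
                         refractory_length = 10,
                         contact_chebyshev = 1,
                         domain_width = 200,
                         domain_height = 200,
                         arc_length_L = 10,
                         cells_per_micron = NA_real_) {
  if (is.null(tip_source_strength))
    tip_source_strength <- 20 * source_strength
  p <- list(
    source_strength = as.numeric(source_strength),
    tip_source_strength = as.numeric(tip_source_strength),
    decay_length = as.numeric(decay_length),
    noise_sd = as.numeric(noise_sd),
    branch_threshold = as.numeric(branch_threshold),
    speed_half_saturation = as.numeric(speed_half_saturation),
    refractory_length = as.numeric(refractory_length),
    contact_chebyshev = as.numeric(contact_chebyshev),
    domain_width = as.integer(domain_width),
    domain_height = as.integer(domain_height),
    arc_length_L = as.numeric(arc_length_L),
    cells_per_micron = as.numeric(cells_per_micron)
  )
  class(p) <- "sa_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "sa_params"))
  if (!is.finite(p$decay_length) || p$decay_length <= 0)
    stop("decay_length must be > 0", call. = FALSE)
  if (!is.finite(p$source_strength) || p$source_strength < 0)
    stop("source_strength must be >= 0", call. = FALSE)
  if (!is.finite(p$tip_source_strength) || p$tip_source_strength < 0)
    stop("tip_source_strength must be >= 0", call. = FALSE)
  if (!is.finite(p$noise_sd) || p$noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.finite(p$branch_threshold) || p$branch_threshold < 0)
    stop("branch_threshold must be >= 0", call. = FALSE)
  if (!is.finite(p$speed_half_saturation) || p$speed_half_saturation <= 0)
    stop("speed_half_saturation must be > 0", call. = FALSE)
  if (!is.finite(p$refractory_length) || p$refractory_length < 0)
    stop("refractory_length must be >= 0", call. = FALSE)
  if (p$domain_width < 16L || p$domain_height < 16L)
    stop("domain dimensions must be at least 16 cells", call. = FALSE)
  invisible(p)
}

#' @export
print.sa_params <- function(x, ...) {
  cat("Self-avoidance model parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write model parameters as a flat key=value config file
#'
#' The config format is one `key = value` pair per line; blank lines and lines
#' starting with `#` are ignored. Every field of [model_params()] is
#' addressable by name; keys not belonging to `sa_params` are returned in the
#' `extra` attribute (this is how scenario/seed/steps settings ride along in
#' run configs).
#'
#' @param path File path.
#' @param params An `sa_params` object (for writing).
#' @param extra Named list of additional key=value pairs to write.
#' @return `read_config()` returns an `sa_params` object (with attribute
#'   `extra` holding unrecognised keys); `write_config()` returns `path`
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".cfg")
#' write_config(model_params(decay_length = 6), f)
#' read_config(f)$decay_length
#' @export
read_config <- function(path) {
  raw <- trimws(readLines(path, warn = FALSE))
  keep <- which(nzchar(raw) & !startsWith(raw, "#"))
  lines <- raw[keep]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) < 2L)
  if (length(bad))
    stop(sprintf("config parse error at line %d: expected key=value",
                 keep[bad[1]]), call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  known <- names(model_params())
  args <- list()
  extra <- list()
  for (i in seq_along(keys)) {
    v <- suppressWarnings(as.numeric(vals[i]))
    if (is.na(v) && !identical(tolower(vals[i]), "na")) v <- vals[i]
    if (keys[i] %in% known) args[[keys[i]]] <- v else extra[[keys[i]]] <- v
  }
  p <- do.call(model_params, args)
  attr(p, "extra") <- extra
  p
}

#' @rdname read_config
#' @export
write_config <- function(params, path, extra = list()) {
  validate_params(params)
  fmt <- function(v) {
    if (is.numeric(v)) format(v, digits = 15) else as.character(v)
  }
  lines <- c("# selfavoid run configuration",
             vapply(names(params), function(nm) {
               sprintf("%s = %s", nm, fmt(params[[nm]]))
             }, ""),
             if (length(extra)) vapply(names(extra), function(nm) {
               sprintf("%s = %s", nm, fmt(extra[[nm]]))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
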