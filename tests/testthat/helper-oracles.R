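# Independent numeric oracles used across the suite. These deliberately do
# not share code with the package: expected values are recomputed from first
# principles (series expansions, brute-force sums) and compared against the
# implementation.

# exp(x) by Taylor series (independent of base exp for small |x|)
exp_series <- function(x, terms = 60) {
  s <- 0
  term <- 1
  for (k in 0:terms) {
    s <- s + term
    term <- term * x / (k + 1)
  }
  s
}

# standard normal CDF via the error-function Taylor series
pnorm_series <- function(z) {
  x <- z / sqrt(2)
  # erf(x) = 2/sqrt(pi) * sum (-1)^k x^(2k+1) / (k! (2k+1))
  s <- 0
  term <- x
  for (k in 0:120) {
    s <- s + term / (2 * k + 1)
    term <- term * (-x * x) / (k + 1)
  }
  erf <- 2 / sqrt(pi) * s
  0.5 * (1 + erf)
}

# brute-force repulsive field: explicit loop over every occupied cell
brute_field <- function(point, trees, params, exclude = NULL) {
  if (inherits(trees, "tubule_tree")) trees <- list(trees)
  tot <- 0
  for (tr in trees) {
    el <- tr$elements
    for (i in seq_len(nrow(el))) {
      if (!is.null(exclude) && el$x[i] == exclude[1] && el$y[i] == exclude[2])
        next
      d <- sqrt((el$x[i] - point[1])^2 + (el$y[i] - point[2])^2)
      s <- if (el$kind[i] == "tip") params$tip_source_strength
           else params$source_strength
      tot <- tot + s * exp(-d / params$decay_length)
    }
  }
  tot
}

# a random scattering of single-cell trees (point sources) for field tests
random_source_trees <- function(n_sources, params, tip_fraction = 0.3) {
  lapply(seq_len(n_sources), function(i) {
    tubule_tree(data.frame(
      x = sample.int(params$domain_width, 1) - 1L,
      y = sample.int(params$domain_height, 1) - 1L,
      kind = if (stats::runif(1) < tip_fraction) "tip" else "stalk",
      parent = NA_integer_, generation = 0L, birth_step = 0L), tree_id = i)
  })
}

# straight-trunk tree along +y from (x0, y0), tip at the far end
straight_trunk <- function(len, x0 = 50L, y0 = 0L) {
  tubule_tree(data.frame(
    x = rep(as.integer(x0), len), y = as.integer(y0 + 0:(len - 1)),
    kind = c(rep("stalk", len - 1), "tip"),
    parent = c(NA_integer_, seq_len(len - 1)),
    generation = 0L, birth_step = 0L))
}

# stack the closing-speed tables of every pair in a generated track table
pairwise_closing <- function(trk) {
  do.call(rbind, lapply(split(trk, sub("[ab]$", "", trk$tip_id)),
    function(pp) {
      two <- split(pp, pp$tip_id)
      closing_speed_table(two[[1]], two[[2]])
    }))
}

# small parameter set for fast engine tests
small_params <- function(...) {
  model_params(domain_width = 64, domain_height = 64, ...)
}
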