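# File formats: tree JSON and SWC dialect, track CSV, PGM snapshots.

#' Write and read tubule trees as JSON
#'
#' The JSON form is the lossless interchange format: it carries every element
#' field including `generation` and `birth_step`, and roundtrips exactly.
#'
#' @param tree A [tubule_tree()].
#' @param path Output file path.
#' @return `write_tree_json()` returns `path` invisibly; `read_tree_json()`
#'   returns a [tubule_tree()].
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "tubule_tree"))
  jsonlite::write_json(
    list(format = "selfavoid-tree", version = 1L, tree_id = tree$tree_id,
         elements = tree$elements),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(obj$elements))
    stop("parse error in ", path, ": no 'elements' field", call. = FALSE)
  el <- as.data.frame(obj$elements)
  if (!"parent" %in% names(el)) el$parent <- NA_integer_
  el$parent[vapply(el$parent, is.null, TRUE)] <- NA
  el$parent <- suppressWarnings(as.integer(el$parent))
  tubule_tree(el, tree_id = if (!is.null(obj$tree_id)) obj$tree_id else 1L)
}

SWC_TYPE <- c(root = 1L, stalk = 3L, tip = 4L)

#' Write and read tubule trees in an SWC dialect
#'
#' SWC is the de facto plain-text format for tree skeletons (one element per
#' line: `id type x y z radius parent`). The dialect here fixes `z = 0` and
#' `radius = 1`, and maps element kinds to type codes 1 (root), 3 (stalk)
#' and 4 (tip). SWC does not carry branch generations or birth steps:
#' generations are recomputed from topology on read (counting bifurcations
#' from the root) and birth steps are set to 0.
#'
#' @inheritParams write_tree_json
#' @return `write_tree_swc()` returns `path` invisibly; `read_tree_swc()`
#'   returns a [tubule_tree()] with the same cells and parent relation.
#' @export
write_tree_swc <- function(tree, path) {
  stopifnot(inherits(tree, "tubule_tree"))
  el <- tree$elements
  type <- ifelse(is.na(el$parent), SWC_TYPE["root"],
                 SWC_TYPE[el$kind])
  parent <- ifelse(is.na(el$parent), -1L, el$parent)
  lines <- c(sprintf("# selfavoid tree %d (SWC dialect: z=0, radius=1)",
                     tree$tree_id),
             "# id type x y z radius parent",
             sprintf("%d %d %d %d 0 1 %d", seq_len(nrow(el)), type,
                     el$x, el$y, parent))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_tree_swc
#' @export
read_tree_swc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data_idx <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))
  rows <- lapply(data_idx, function(i) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(f) != 7L || any(is.na(f)))
      stop(sprintf("parse error in %s at line %d: expected 7 numeric fields",
                   path, i), call. = FALSE)
    f
  })
  m <- do.call(rbind, rows)
  if (is.null(m)) stop("parse error in ", path, ": no data lines",
                       call. = FALSE)
  ids <- as.integer(m[, 1])
  if (any(ids != seq_along(ids)))
    stop("parse error in ", path, ": ids must be contiguous from 1",
         call. = FALSE)
  parent <- as.integer(m[, 7])
  parent[parent == -1L] <- NA_integer_
  if (any(!is.na(parent) & parent >= ids))
    stop("parse error in ", path, ": parent must precede child",
         call. = FALSE)
  kind <- ifelse(as.integer(m[, 2]) == SWC_TYPE["tip"], "tip", "stalk")
  el <- data.frame(x = as.integer(m[, 3]), y = as.integer(m[, 4]),
                   kind = kind, parent = parent,
                   generation = 0L, birth_step = 0L)
  el$generation <- recompute_generations(el$parent)
  tubule_tree(el)
}

# generation = number of bifurcations on the path from the root
recompute_generations <- function(parent) {
  n <- length(parent)
  nkids <- tabulate(parent[!is.na(parent)], nbins = n)
  gen <- integer(n)
  for (i in seq_len(n)) {
    p <- parent[i]
    if (!is.na(p)) gen[i] <- gen[p] + as.integer(nkids[p] >= 2L)
  }
  gen
}

#' Write and read tip-track tables as CSV
#'
#' The track CSV is the package's surrogate for a time-lapse tip-coordinate
#' spreadsheet: header `time_h,tip_id,x,y`, one row per tip per recorded
#' frame, with the unit scale carried in a `# cells_per_micron=` comment
#' line. The reader sorts rows per tip by time and reports (via a message)
#' when the file needed reordering.
#'
#' @param track A data.frame with columns `time_h`, `tip_id`, `x`, `y`.
#' @param path File path.
#' @param cells_per_micron Optional scale recorded in the comment header.
#' @return `write_tracks_csv()` returns `path` invisibly;
#'   `read_tracks_csv()` returns the track data.frame with attribute
#'   `cells_per_micron`.
#' @export
write_tracks_csv <- function(track, path, cells_per_micron = NA_real_) {
  check_track(track)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cells_per_micron=%s", format(cells_per_micron)), con)
  utils::write.csv(track[, c("time_h", "tip_id", "x", "y")], con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  scale <- NA_real_
  cmt <- grep("^#", lines)
  for (i in cmt) {
    m <- regmatches(lines[i], regexec("cells_per_micron=([^ ]+)", lines[i]))[[1]]
    if (length(m) == 2L) scale <- suppressWarnings(as.numeric(m[2]))
  }
  body <- if (length(cmt)) lines[-cmt] else lines
  df <- tryCatch(utils::read.csv(text = paste(body, collapse = "\n")),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  miss <- setdiff(c("time_h", "tip_id", "x", "y"), names(df))
  if (length(miss))
    stop("parse error in ", path, ": missing columns ",
         paste(miss, collapse = ", "), call. = FALSE)
  ord <- order(df$tip_id, df$time_h)
  if (any(ord != seq_len(nrow(df)))) {
    message("read_tracks_csv: rows were not sorted by (tip, time); reordered")
    df <- df[ord, ]
    rownames(df) <- NULL
  }
  attr(df, "cells_per_micron") <- scale
  df
}

#' Write a field snapshot as a PGM image
#'
#' Writes a plain (P2) grayscale PGM of a field grid, scaled so the maximum
#' concentration maps to 255. Row 1 of the image is the top of the domain
#' (highest y).
#'
#' @param grid A matrix from [field_grid()] (entry `[x+1, y+1]` = cell
#'   `(x, y)`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_pgm <- function(grid, path) {
  w <- nrow(grid); h <- ncol(grid)
  mx <- max(grid)
  px <- if (mx > 0) round(grid / mx * 255) else grid * 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", w, h), "255"), con)
  for (r in h:1) writeLines(paste(px[, r], collapse = " "), con)
  invisible(path)
}
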