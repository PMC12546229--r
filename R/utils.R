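# Internal helpers shared across modules.

.datatable.aware <- TRUE

# Classed error so callers (and the CLI) can map failures to exit codes.
stop_treereg <- function(msg, class, call. = FALSE) {
  stop(structure(class = c(class, "treereg_error", "error", "condition"),
                 list(message = msg, call = if (call.) sys.call(-1) else NULL)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop_treereg("cannot normalize a zero vector", "treereg_degenerate_error")
  v / n
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Perpendicular distance of points (n x 3) to the 3D line (point, dir).
point_line_dist <- function(P, point, dir) {
  dir <- unit_vec(dir)
  W <- sweep(P, 2, point)
  t <- as.vector(W %*% dir)
  D <- W - outer(t, dir)
  sqrt(rowSums(D^2))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
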