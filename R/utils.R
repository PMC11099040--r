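# Internal helpers shared across modules. Angle convention: degrees in
# [0, 360), x rightward, y downward, so theta behaves like atan2(dy, dx)
# and the printed arccos branch formulas are reproduced exactly.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' @noRd
unit_vec <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  c(cos(th), sin(th))
}

# smallest absolute angular difference in degrees, result in [0, 180]
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# heading of the segment p1 -> p2 in [0, 360), y-down frame
seg_heading <- function(x1, y1, x2, y2) {
  (rad2deg(atan2(y2 - y1, x2 - x1))) %% 360
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(class, msg, ...) {
  stop(structure(class = c(class, "homingtraj_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Run expr with a locally seeded RNG stream, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# derive a reproducible child seed below 2^31 from a parent seed and an
# index. The mixing steps matter: arithmetic seed progressions fed straight
# to set.seed() produce streams with detectable cross-correlations.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  x <- (as.double(seed) * 2654435761 + as.double(i) * 40503 + 1013904223) %% 2^31
  x <- (x * 69069 + 362437) %% 2^31
  x <- (x * 1103515245 + 12345) %% 2^31
  as.integer(x %% 2147483647)
}
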