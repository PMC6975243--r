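# Internal helpers shared across modules.

fm_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "facetmorph_error"))
}

vnorm <- function(x) sqrt(sum(x^2))

normalize <- function(x) {
  n <- vnorm(x)
  if (n < 1e-300) fm_abort("cannot normalize a zero vector", "fm_undefined_angle")
  x / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Row-wise cross product for n x 3 matrices.
cross3_rows <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(code)
}

as_point3 <- function(p, arg = "point") {
  p <- as.numeric(p)
  if (length(p) != 3 || any(!is.finite(p))) {
    fm_abort(sprintf("'%s' must be a finite 3-vector", arg), "fm_validation_error")
  }
  p
}

as_points_matrix <- function(x, arg = "points") {
  if (is_facet_mesh(x)) return(x$vertices)
  x <- as.matrix(x)
  if (ncol(x) != 3) fm_abort(sprintf("'%s' must be an n x 3 matrix", arg), "fm_validation_error")
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) fm_abort(sprintf("'%s' contains non-finite coordinates", arg), "fm_validation_error")
  x
}
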