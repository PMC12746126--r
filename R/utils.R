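## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("tumorscape_config_error", "error")))
}

# coerce x/y inputs (matrix, data.frame with x/y, or 2-col anything) to an
# n x 2 numeric matrix
as_coords <- function(p) {
  if (is.data.frame(p)) {
    if (all(c("x", "y") %in% names(p))) p <- cbind(p$x, p$y)
    else p <- as.matrix(p[, 1:2])
  }
  if (is.null(dim(p))) {
    if (length(p) == 2L) p <- matrix(p, ncol = 2L)
    else stop("cannot interpret input as 2-D coordinates")
  }
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2L) stop("coordinates must have exactly two columns (x, y)")
  if (anyNA(p) || any(!is.finite(p))) stop("coordinates must be finite")
  p
}

# Euclidean distance from every row of `a` to every row of `b`; used only on
# small inputs, larger paths go through FNN
pairwise_dist <- function(a, b) {
  a <- as_coords(a); b <- as_coords(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
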