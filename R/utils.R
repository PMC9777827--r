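# internal helpers

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# promote (H,W) or (H,W,C) to rank-4 (H,W,C,N)
as_feature_array <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("input must be an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("input must have rank 2, 3 or 4")
  x
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2], da[4] == db[4])
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

is_binary <- function(m) {
  all(m %in% c(0, 1))
}

check_mask <- function(m, arg = "mask") {
  if (is.null(dim(m)) || length(dim(m)) != 2L)
    stop(sprintf("'%s' must be a 2-D matrix", arg))
  if (!is_binary(m)) stop(sprintf("'%s' must be binary (values 0/1)", arg))
  invisible(m)
}
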