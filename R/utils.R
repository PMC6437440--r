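# internal helpers: metric codes and local RNG scoping

.metric_code <- function(metric) {
  m <- tolower(metric[1])
  code <- c(l1 = 1L, manhattan = 1L, l2 = 2L, euclidean = 2L, angle = 3L)[m]
  if (is.na(code)) stop("unknown metric '", metric, "' (use L1, L2 or angle)")
  code
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.  seed = NULL leaves the RNG untouched.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.values <- function(x) {
  if (inherits(x, "cell_matrix")) x$values else as.matrix(x)
}

.assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(name, " must be a single positive number")
  invisible(x)
}

# non-Depends data.table usage (.N, := style) requires opting in
.datatable.aware <- TRUE
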