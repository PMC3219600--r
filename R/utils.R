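#' Derive a reproducible sub-stream seed from a master seed
#'
#' A single integer seed fans out to named sub-streams, one per simulation
#' stage, so that each stage is independently reproducible: regenerating the
#' arrays does not perturb the NIL panel, and vice versa.
#'
#' @param seed Master integer seed.
#' @param name Character name of the sub-stream (e.g. `"arrays"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' substream_seed(1, "arrays")
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes) * 7919) %% 999983L
  as.integer((abs(as.integer(seed)) %% 99991L) * 20011L + h) %% 2147483647L
}

# with_substream: evaluate expr under a named substream of `seed`,
# restoring the caller's RNG state afterwards. seed = NULL leaves RNG alone.
with_substream <- function(seed, name, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  force(expr)
}

# check a data frame has the required columns, with a readable error
check_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}
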