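#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

# stats::sd, masked at import time by IRanges
sd <- stats::sd

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so simulation calls do not perturb sessions.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
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

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

# round() half-up at `digits`, the convention used by the printed report
# tables (base round() is banker's rounding, which turns 0.305 into 0.30
# either way here, but half-up is what spreadsheets and the tables use).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of conserved regions, rounded as in report tables
#'
#' Formats a conserved/total count pair as the percentage printed in
#' order-conservation matrices (two decimals, half-up rounding).
#'
#' @param n_same_order Number of region pairs in the same rank position.
#' @param n_total Total number of matched region pairs.
#' @return A numeric percentage in `[0, 100]`; 0 when `n_total` is 0.
#' @examples
#' conservation_pct(286, 25919) # 1.10
#' @export
conservation_pct <- function(n_same_order, n_total) {
  if (n_total <= 0) return(0)
  round_half_up(100 * n_same_order / n_total, 2)
}

# Atomic write: materialize via `writer(path)` into a temp file in the
# destination directory, then rename. No partial output on failure.
write_atomic <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stop_("failed to move temp file onto %s", path)
  ok <- TRUE
  invisible(path)
}

write_tsv_atomic <- function(df, path) {
  write_atomic(path, function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  })
}

log_msg <- function(level, fmt, ...) {
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}
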