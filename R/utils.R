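# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic child seed for a named stream
#'
#' One master seed drives the whole simulator; each output type draws from its
#' own child stream so adding a new output never perturbs existing ones.
#'
#' @param master integer master seed.
#' @param stream character stream name.
#' @return An integer seed in `[0, .Machine$integer.max)`.
#' @keywords internal
child_seed <- function(master, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(master)) * 7919 + h * 104729) %% .Machine$integer.max)
}

# Evaluate `expr` under the child stream's RNG state, restoring the caller's
# RNG state afterwards.
with_stream <- function(master, stream, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(child_seed(master, stream))
  expr
}

# 0-based half-open interval data.frame -> IRanges (1-based closed).
intervals_to_iranges <- function(df) {
  if (is.null(df) || nrow(df) == 0) {
    return(IRanges::IRanges())
  }
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

# 1-based positions inside any 0-based half-open interval of `df` (same chrom).
pos_in_intervals <- function(pos, df) {
  if (is.null(df) || nrow(df) == 0 || length(pos) == 0) {
    return(rep(FALSE, length(pos)))
  }
  q <- IRanges::IRanges(start = pos, width = 1L)
  IRanges::overlapsAny(q, intervals_to_iranges(df))
}

# Sum of interval lengths after merging overlaps, per chromosome set given as a
# 0-based half-open data.frame with a `chrom` column.
merged_interval_length <- function(df) {
  if (is.null(df) || nrow(df) == 0) {
    return(0)
  }
  total <- 0
  for (ch in unique(df$chrom)) {
    ir <- IRanges::reduce(intervals_to_iranges(df[df$chrom == ch, , drop = FALSE]))
    total <- total + sum(IRanges::width(ir))
  }
  total
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
}
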