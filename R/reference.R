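#' Build a synthetic reference genome model
#'
#' Generates a toy stand-in for a reference assembly: chromosome sizes, a GC
#' fraction track over fixed-width windows, assembly-gap intervals and
#' simple/satellite repeat intervals. Gaps are treated as the unmappable part
#' of the genome; everything outside a gap is mappable.
#'
#' All intervals are 0-based half-open. The model is fully deterministic for a
#' fixed seed: each track draws from its own child RNG stream.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param gc_window width in bp of the fixed GC windows.
#' @param gc_mean,gc_sd mean and s.d. of the per-window GC fraction
#'   (clipped to `[0.2, 0.8]`).
#' @param repeat_density target fraction of the genome covered by
#'   simple/satellite repeats, in `[0, 1]`.
#' @param gap_density target fraction covered by assembly gaps, in `[0, 1]`.
#' @param repeat_mean_len,gap_mean_len mean interval lengths in bp.
#' @param seed integer master seed.
#' @return An object of class `reference_model`: a list with elements
#'   `chromosomes` (data.frame `name`, `length`), `gc` (data.frame `chrom`,
#'   `start`, `end`, `gc`), `gaps`, `repeats` (data.frames of intervals,
#'   repeats carry a `class` in `{"simple","satellite"}`), `gc_window`, and
#'   `genome_length`.
#' @examples
#' ref <- build_reference(c(chr1 = 1e6), repeat_density = 0.05, seed = 1)
#' @export
build_reference <- function(chromosomes = c(chr1 = 25e6, chr2 = 20e6, chr3 = 15e6),
                            gc_window = 20000,
                            gc_mean = 0.41, gc_sd = 0.06,
                            repeat_density = 0.02,
                            gap_density = 0.01,
                            repeat_mean_len = 600,
                            gap_mean_len = 50000,
                            seed = 1) {
  if (length(chromosomes) == 0 || any(chromosomes <= 0)) {
    stop("chromosome lengths must be positive")
  }
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes))) {
    stop("chromosomes must have unique names")
  }
  stopifnot_scalar_prob(repeat_density, "repeat_density")
  stopifnot_scalar_prob(gap_density, "gap_density")

  chroms <- data.frame(name = names(chromosomes),
                       length = as.numeric(chromosomes),
                       stringsAsFactors = FALSE)

  gc <- with_stream(seed, "reference/gc", {
    do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
      L <- chroms$length[i]
      starts <- seq(0, L - 1, by = gc_window)
      ends <- pmin(starts + gc_window, L)
      vals <- pmin(0.8, pmax(0.2, stats::rnorm(length(starts), gc_mean, gc_sd)))
      data.frame(chrom = chroms$name[i], start = starts, end = ends, gc = vals,
                 stringsAsFactors = FALSE)
    }))
  })

  gaps <- with_stream(seed, "reference/gaps",
                      sample_intervals(chroms, gap_density, gap_mean_len))
  repeats <- with_stream(seed, "reference/repeats", {
    r <- sample_intervals(chroms, repeat_density, repeat_mean_len)
    if (nrow(r) > 0) {
      r$class <- sample(c("simple", "satellite"), nrow(r), replace = TRUE,
                        prob = c(0.7, 0.3))
    } else {
      r$class <- character(0)
    }
    r
  })

  structure(list(chromosomes = chroms, gc = gc, gaps = gaps, repeats = repeats,
                 gc_window = gc_window, genome_length = sum(chroms$length)),
            class = "reference_model")
}

# Draw non-degenerate intervals totalling ~ density * genome length. Interval
# lengths are exponential around `mean_len`; overlapping draws are merged, so
# realised coverage falls slightly below the target at high density
# (1 - exp(-density) in the Poisson-coverage limit).
sample_intervals <- function(chroms, density, mean_len) {
  out <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                    stringsAsFactors = FALSE)
  if (density <= 0) {
    return(out)
  }
  pieces <- lapply(seq_len(nrow(chroms)), function(i) {
    L <- chroms$length[i]
    n <- max(0L, round(density * L / mean_len))
    if (n == 0L) {
      return(NULL)
    }
    len <- pmax(1, round(stats::rexp(n, 1 / mean_len)))
    start <- floor(stats::runif(n, 0, pmax(1, L - len)))
    ir <- IRanges::reduce(IRanges::IRanges(start = start + 1, end = pmin(start + len, L)))
    data.frame(chrom = chroms$name[i],
               start = IRanges::start(ir) - 1,
               end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (length(pieces) > 0) {
    out <- do.call(rbind, pieces)
  }
  rownames(out) <- NULL
  out
}

#' Mappable regions of a reference model
#'
#' The mappable genome is the complement of the assembly gaps.
#'
#' @param ref a `reference_model`.
#' @return Data.frame of 0-based half-open intervals (`chrom`, `start`, `end`).
#' @export
mappable_regions <- function(ref) {
  stopifnot(inherits(ref, "reference_model"))
  out <- lapply(seq_len(nrow(ref$chromosomes)), function(i) {
    ch <- ref$chromosomes$name[i]
    L <- ref$chromosomes$length[i]
    full <- IRanges::IRanges(1, L)
    g <- intervals_to_iranges(ref$gaps[ref$gaps$chrom == ch, , drop = FALSE])
    m <- IRanges::setdiff(full, g)
    if (length(m) == 0) {
      return(NULL)
    }
    data.frame(chrom = ch, start = IRanges::start(m) - 1, end = IRanges::end(m),
               stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  rownames(res) <- NULL
  res
}

# Draw n positions uniformly over the mappable genome; returns data.frame
# (chrom, pos) with 1-based positions.
sample_mappable_positions <- function(ref, n) {
  map <- mappable_regions(ref)
  w <- map$end - map$start
  idx <- sample.int(nrow(map), n, replace = TRUE, prob = w)
  pos <- map$start[idx] + 1L + floor(stats::runif(n) * w[idx])
  data.frame(chrom = map$chrom[idx], pos = as.integer(pos), stringsAsFactors = FALSE)
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("reference_model: %d chromosome(s), %.1f Mb total\n",
              nrow(x$chromosomes), x$genome_length / 1e6))
  cat(sprintf("  gaps: %d interval(s), %.2f%% of genome\n", nrow(x$gaps),
              100 * merged_interval_length(x$gaps) / x$genome_length))
  cat(sprintf("  repeats: %d interval(s), %.2f%% of genome\n", nrow(x$repeats),
              100 * merged_interval_length(x$repeats) / x$genome_length))
  invisible(x)
}
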