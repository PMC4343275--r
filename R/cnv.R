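#' Divide the genome into variable-width bins of equal mappable weight
#'
#' Bins are allocated to chromosomes proportionally to mappable weight and,
#' within a chromosome, boundaries are chosen so every bin receives an equal
#' share of (simulated) uniquely-mappable reads. With `n_sim_reads = NULL`
#' (default) the analytic limit of that scheme is used: bins of equal
#' mappable length. Supplying a finite `n_sim_reads` performs the literal
#' construction - uniform read starts are sampled over the mappable genome
#' and boundaries placed so bins hold equal read counts (+/-1).
#'
#' Bins never cross chromosome boundaries; they are 0-based half-open and may
#' contain embedded assembly gaps (which carry no mappable weight).
#'
#' @param ref a `reference_model`.
#' @param n_bins total number of bins (>= number of chromosomes).
#' @param n_sim_reads optional number of simulated reads.
#' @param seed seed for read simulation (ignored in the analytic limit).
#' @return Data.frame `chrom`, `start`, `end`, `gc` (GC fraction at the bin
#'   midpoint window), `mappable` (mappable bp in bin).
#' @export
make_variable_bins <- function(ref, n_bins, n_sim_reads = NULL, seed = 1) {
  stopifnot(inherits(ref, "reference_model"))
  if (n_bins < nrow(ref$chromosomes)) {
    stop("n_bins must be at least the number of chromosomes")
  }
  map <- mappable_regions(ref)
  w_chrom <- vapply(ref$chromosomes$name, function(ch) {
    sum(map$end[map$chrom == ch] - map$start[map$chrom == ch])
  }, numeric(1))
  if (any(w_chrom == 0)) {
    warning("chromosome(s) with zero mappable bases receive zero bins: ",
            paste(ref$chromosomes$name[w_chrom == 0], collapse = ", "))
  }

  if (is.null(n_sim_reads)) {
    alloc <- largest_remainder(n_bins, w_chrom / sum(w_chrom))
    pieces <- lapply(seq_along(w_chrom), function(i) {
      k <- alloc[i]
      if (k == 0) {
        return(NULL)
      }
      ch <- ref$chromosomes$name[i]
      m <- map[map$chrom == ch, , drop = FALSE]
      cuts <- seq(0, w_chrom[i], length.out = k + 1)
      bounds <- mappable_to_genomic(cuts, m)
      data.frame(chrom = ch, start = bounds[-length(bounds)], end = bounds[-1],
                 mappable = diff(cuts), stringsAsFactors = FALSE)
    })
  } else {
    reads <- with_stream(seed, "bins/reads",
                         sample_mappable_positions(ref, n_sim_reads))
    cnt <- vapply(ref$chromosomes$name, function(ch) sum(reads$chrom == ch),
                  numeric(1))
    alloc <- largest_remainder(n_bins, cnt / sum(cnt))
    pieces <- lapply(seq_along(cnt), function(i) {
      k <- alloc[i]
      if (k == 0) {
        return(NULL)
      }
      ch <- ref$chromosomes$name[i]
      pos <- sort(reads$pos[reads$chrom == ch])
      sizes <- largest_remainder(length(pos), rep(1 / k, k))
      idx <- cumsum(sizes)
      # boundary after the last read of each group (reads count by 0-based
      # start, bins are half-open)
      ends <- c(pos[idx[-k]], ref$chromosomes$length[i])
      starts <- c(0, ends[-k])
      data.frame(chrom = ch, start = starts, end = ends,
                 mappable = sizes, stringsAsFactors = FALSE)
    })
  }
  bins <- do.call(rbind, Filter(Negate(is.null), pieces))
  rownames(bins) <- NULL
  bins$gc <- gc_at(ref, bins$chrom, floor((bins$start + bins$end) / 2))
  bins[, c("chrom", "start", "end", "gc", "mappable")]
}

# Genomic coordinates of mappable-space offsets, given the chromosome's
# mappable intervals (0-based half-open, sorted).
mappable_to_genomic <- function(x, m) {
  w <- m$end - m$start
  cum <- c(0, cumsum(w))
  vapply(x, function(xi) {
    j <- findInterval(xi, cum, rightmost.closed = TRUE)
    j <- min(max(j, 1L), nrow(m))
    m$start[j] + (xi - cum[j])
  }, numeric(1))
}

# GC fraction of the fixed window containing each (chrom, pos).
gc_at <- function(ref, chrom, pos) {
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    g <- ref$gc[ref$gc$chrom == ch, , drop = FALSE]
    idx <- pmin(nrow(g), pmax(1L, floor(pos[sel] / ref$gc_window) + 1L))
    out[sel] <- g$gc[idx]
  }
  out
}

#' Count read start positions in bins
#'
#' Reads are assigned by their (0-based) start position; bins are half-open,
#' so a read at a bin's start coordinate belongs to that bin and a read at
#' its end coordinate to the next.
#'
#' @param reads data.frame with `chrom` and `start` (0-based read starts).
#' @param bins bin data.frame as from [make_variable_bins()].
#' @return Integer vector of counts, one per bin.
#' @export
count_in_bins <- function(reads, bins) {
  counts <- integer(nrow(bins))
  for (ch in unique(bins$chrom)) {
    b <- which(bins$chrom == ch)
    r <- reads$start[reads$chrom == ch]
    if (length(r) == 0) next
    idx <- findInterval(r, bins$start[b])
    ok <- idx >= 1 & r < bins$end[b][pmax(idx, 1)]
    tab <- tabulate(idx[ok], nbins = length(b))
    counts[b] <- counts[b] + tab
  }
  counts
}

#' GC-correct raw bin counts into copy ratios
#'
#' Fits a local linear (loess) regression of count on GC fraction and divides
#' each count by its fitted value; the resulting profile is normalized to
#' median 1.
#'
#' @param counts raw per-bin counts.
#' @param gc per-bin GC fractions (same length).
#' @param span loess span (default 0.3, degree 1).
#' @return Numeric vector of GC-corrected, median-normalized ratios.
#' @export
gc_normalize <- function(counts, gc, span = 0.3) {
  if (length(counts) != length(gc)) stop("counts and gc must align")
  if (all(counts == 0)) stop("all-zero counts cannot be normalized")
  fit <- stats::loess(counts ~ gc, span = span, degree = 1,
                      family = "symmetric")
  f <- pmax(stats::predict(fit, gc), .Machine$double.eps)
  ratio <- counts / f
  ratio / stats::median(ratio)
}

# Two-sample Kolmogorov-Smirnov statistic, computed directly from the pooled
# empirical distribution functions.
ks_statistic <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  ord <- order(pooled)
  z <- cumsum(ifelse(ord <= na, 1 / na, -1 / nb))
  # step heights only change at distinct pooled values
  dup <- c(diff(sort(pooled)) == 0, FALSE)
  max(abs(z[!dup]))
}

#' Segment a copy-ratio profile with recursive KS splitting
#'
#' Two-phase recursive KS segmentation. Split phase: each segment is split
#' at the point maximizing the size-normalized two-sample Kolmogorov-Smirnov
#' statistic `D * sqrt(m n / (m + n))` between the left and right bin ratios
#' (the raw statistic is trivially inflated for very small flanks), recursing
#' until segments fall below `2 * min_width` bins; ties between equally good
#' splits go to the leftmost. Prune phase: adjacent segments whose bin-ratio
#' samples the KS test cannot distinguish at level `alpha` are merged back,
#' most-similar pair first, until every remaining boundary is significant.
#' The pruning step is what allows short interior events (flanked on both
#' sides by long neutral runs, where a single left/right split is never
#' significant on its own) to survive as segments. Chromosomes are segmented
#' independently.
#'
#' @param ratios per-bin copy ratios.
#' @param chrom optional per-bin chromosome labels; `NULL` treats the profile
#'   as one chromosome.
#' @param alpha acceptance level for a split (default 0.01).
#' @param min_width minimum segment width in bins (default 3).
#' @return Data.frame of segments: `chrom`, `start_bin`, `end_bin` (1-based,
#'   inclusive, global bin indices), `n_bins`, `mean_ratio`.
#' @export
ks_segment <- function(ratios, chrom = NULL, alpha = 0.01, min_width = 3) {
  if (is.null(chrom)) chrom <- rep("genome", length(ratios))
  if (length(chrom) != length(ratios)) stop("chrom labels must align with ratios")
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    bounds <- ks_split_recursive(ratios[idx], alpha, min_width)
    for (b in bounds) {
      seg_idx <- idx[b[1]:b[2]]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start_bin = idx[b[1]], end_bin = idx[b[2]],
        n_bins = b[2] - b[1] + 1L,
        mean_ratio = mean(ratios[seg_idx]), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Returns a list of c(lo, hi) index pairs (local, 1-based) partitioning 1..n.
ks_split_recursive <- function(x, alpha, min_width) {
  ks_prune(x, ks_split_full(x, min_width), alpha)
}

# Split phase: recurse at the maximal normalized-KS split regardless of
# significance, down to min_width; returns boundary pairs.
ks_split_full <- function(x, min_width, offset = 0L) {
  n <- length(x)
  if (n < 2 * min_width || max(x) == min(x)) {
    return(list(c(offset + 1L, offset + n)))
  }
  ks_cand <- seq.int(min_width, n - min_width)
  d <- vapply(ks_cand, function(k) ks_statistic(x[1:k], x[(k + 1):n]), numeric(1))
  z <- d * sqrt(ks_cand * (n - ks_cand) / n)
  if (max(d) <= 0) {
    return(list(c(offset + 1L, offset + n)))
  }
  k_best <- ks_cand[which.max(z)]   # leftmost on ties
  c(ks_split_full(x[1:k_best], min_width, offset),
    ks_split_full(x[(k_best + 1):n], min_width, offset + k_best))
}

# Prune phase: iteratively merge the adjacent pair with the largest KS
# p-value until every remaining boundary is significant at `alpha`.
ks_prune <- function(x, segs, alpha) {
  pair_p <- function(a, b) {
    suppressWarnings(stats::ks.test(x[a[1]:a[2]], x[b[1]:b[2]])$p.value)
  }
  repeat {
    if (length(segs) < 2) {
      return(segs)
    }
    p <- vapply(seq_len(length(segs) - 1), function(i) {
      pair_p(segs[[i]], segs[[i + 1]])
    }, numeric(1))
    p[is.na(p)] <- 1
    i <- which.max(p)
    if (p[i] < alpha) {
      return(segs)
    }
    segs[[i]] <- c(segs[[i]][1], segs[[i + 1]][2])
    segs[[i + 1]] <- NULL
  }
}

#' Call gain/loss/neutral states on segments
#'
#' @param segments segment data.frame from [ks_segment()].
#' @param gain_thresh gain iff mean ratio >= this (default 1.4, inclusive).
#' @param loss_thresh loss iff mean ratio <= this (default 0.8, inclusive).
#' @return The segments with a `state` column in `{"loss","neutral","gain"}`.
#' @export
call_cna_states <- function(segments, gain_thresh = 1.4, loss_thresh = 0.8) {
  segments$state <- ifelse(segments$mean_ratio >= gain_thresh, "gain",
                           ifelse(segments$mean_ratio <= loss_thresh, "loss",
                                  "neutral"))
  segments
}

#' Expand state-labeled segments into a per-bin state vector
#'
#' @param segments output of [call_cna_states()].
#' @param n_bins total number of bins in the profile.
#' @return Character vector of states, one per bin.
#' @export
bin_states <- function(segments, n_bins = max(segments$end_bin)) {
  out <- rep("neutral", n_bins)
  for (i in seq_len(nrow(segments))) {
    out[segments$start_bin[i]:segments$end_bin[i]] <- segments$state[i]
  }
  out
}

#' Compare copy-number events across samples
#'
#' A CNA event is a maximal run of bins with the same non-neutral state.
#' Events from different samples describe the same alteration when their
#' states are equal and their bin ranges overlap; matched events are grouped
#' by single linkage and each group contributes one count to the sharing
#' (Venn) region of the samples it appears in.
#'
#' @param state_matrix character matrix of per-bin states (bins x samples, as
#'   from [bin_states()]), all over one common bin set.
#' @param bin_chrom per-bin chromosome labels (events never span chromosomes).
#' @return List with `events` (data.frame `sample`, `chrom`, `start_bin`,
#'   `end_bin`, `state`, `group`) and `venn` (named counts by sharing
#'   pattern, e.g. `"H+AA"`).
#' @export
compare_cna <- function(state_matrix, bin_chrom = rep("genome", nrow(state_matrix))) {
  if (is.null(colnames(state_matrix))) {
    stop("state_matrix must have sample names as columns")
  }
  if (length(bin_chrom) != nrow(state_matrix)) {
    stop("bin sets mismatch: bin_chrom must align with state_matrix rows")
  }
  events <- list()
  for (s in colnames(state_matrix)) {
    st <- state_matrix[, s]
    r <- rle(paste(bin_chrom, st, sep = "\r"))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- !grepl("\rneutral$", r$values)
    for (i in which(keep)) {
      events[[length(events) + 1]] <- data.frame(
        sample = s, chrom = bin_chrom[starts[i]],
        start_bin = starts[i], end_bin = ends[i],
        state = sub("^.*\r", "", r$values[i]), stringsAsFactors = FALSE)
    }
  }
  if (length(events) == 0) {
    return(list(events = data.frame(), venn = integer(0)))
  }
  ev <- do.call(rbind, events)
  # single-linkage grouping of same-state overlapping events
  n <- nrow(ev)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (ev$state[i] == ev$state[j] && ev$chrom[i] == ev$chrom[j] &&
          ev$start_bin[i] <= ev$end_bin[j] && ev$start_bin[j] <= ev$end_bin[i]) {
        parent[find(i)] <- find(j)
      }
    }
  }
  ev$group <- vapply(seq_len(n), find, integer(1))
  pats <- vapply(split(ev$sample, ev$group), function(ss) {
    paste(sort(unique(ss)), collapse = "+")
  }, character(1))
  venn <- table(pats)
  list(events = ev, venn = stats::setNames(as.integer(venn), names(venn)))
}
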