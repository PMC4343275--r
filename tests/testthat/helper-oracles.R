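# Independent brute-force oracles. These deliberately re-derive results from
# first principles (direct definitions, exhaustive search) so they share no
# code path with the implementations they check.

# Two-sample KS statistic straight from the definition: sup over observed
# thresholds of |F1 - F2|.
oracle_ks_stat <- function(a, b) {
  vals <- sort(unique(c(a, b)))
  max(vapply(vals, function(v) abs(mean(a <= v) - mean(b <= v)), numeric(1)))
}

# Split-then-prune KS segmentation, written independently: exhaustive split
# search with the size-normalized statistic, then iterative merging of the
# most similar adjacent pair while it is non-significant.
oracle_ks_segment <- function(x, alpha = 0.01, min_width = 3) {
  split_rec <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 2 * min_width || max(x[lo:hi]) == min(x[lo:hi])) {
      return(list(c(lo, hi)))
    }
    best_k <- NA
    best_z <- -Inf
    for (k in (lo + min_width - 1):(hi - min_width)) {
      m <- k - lo + 1
      d <- oracle_ks_stat(x[lo:k], x[(k + 1):hi])
      z <- d * sqrt(m * (n - m) / n)
      if (z > best_z) {
        best_z <- z
        best_k <- k
      }
    }
    if (best_z <= 0) {
      return(list(c(lo, hi)))
    }
    c(split_rec(lo, best_k), split_rec(best_k + 1, hi))
  }
  segs <- split_rec(1, length(x))
  repeat {
    if (length(segs) < 2) break
    p <- rep(NA_real_, length(segs) - 1)
    for (i in seq_len(length(segs) - 1)) {
      p[i] <- suppressWarnings(
        stats::ks.test(x[segs[[i]][1]:segs[[i]][2]],
                       x[segs[[i + 1]][1]:segs[[i + 1]][2]])$p.value)
    }
    p[is.na(p)] <- 1
    i <- which.max(p)
    if (p[i] < alpha) break
    segs[[i]] <- c(segs[[i]][1], segs[[i + 1]][2])
    segs[[i + 1]] <- NULL
  }
  do.call(rbind, segs)
}

# O(n^2) single-linkage clustering of split-read mappings by repeated passes
# over an explicit adjacency matrix.
oracle_cluster <- function(m, slop = 1) {
  n <- nrow(m)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- m$type[i] == m$type[j] &&
        m$chrom1[i] == m$chrom1[j] && m$chrom2[i] == m$chrom2[j] &&
        abs(m$pos1[i] - m$pos1[j]) <= 2 * slop &&
        abs(m$pos2[i] - m$pos2[j]) <= 2 * slop
    }
  }
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (f in frontier) {
        nb <- which(adj[f, ] & comp == 0L)
        comp[nb] <- cur
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
  }
  comp
}

# Representative of each cluster by direct all-by-all support counting.
oracle_representatives <- function(m, comp, slop = 1) {
  out <- NULL
  for (g in sort(unique(comp))) {
    idx <- which(comp == g)
    supp <- integer(length(idx))
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (abs(m$pos1[idx[a]] - m$pos1[idx[b]]) <= slop &&
            abs(m$pos2[idx[a]] - m$pos2[idx[b]]) <= slop) {
          supp[a] <- supp[a] + 1L
        }
      }
    }
    best <- idx[supp == max(supp)]
    best <- best[order(m$pos1[best], m$pos2[best])][1]
    out <- rbind(out, data.frame(type = m$type[best], chrom1 = m$chrom1[best],
                                 pos1 = m$pos1[best], chrom2 = m$chrom2[best],
                                 pos2 = m$pos2[best], support = max(supp),
                                 stringsAsFactors = FALSE))
  }
  out
}

# Canonical form of a clustering: sorted vector of sorted member-id sets.
canonical_partition <- function(ids, cluster) {
  sets <- lapply(split(ids, cluster), function(s) paste(sort(s), collapse = ","))
  sort(unlist(sets, use.names = FALSE))
}

# Random split-read mapping table for clustering oracles.
random_mappings <- function(n, pos_range = 300, seed = 1) {
  set.seed(seed)
  pos1 <- sample.int(pos_range, n, replace = TRUE) + 1000L
  data.frame(
    read_id = sprintf("r%04d", seq_len(n)),
    sample = sample(c("D", "H", "AA", "AB"), n, replace = TRUE),
    type = sample(c("DEL", "DUP"), n, replace = TRUE),
    chrom1 = "chr1", pos1 = pos1, strand1 = "+",
    chrom2 = "chr1", pos2 = pos1 + 500L + sample.int(pos_range, n, replace = TRUE),
    strand2 = "-",
    nb_end1 = pos1 - 80L - sample.int(20, n, replace = TRUE),
    nb_end2 = pos1 + 700L + sample.int(20, n, replace = TRUE),
    mq = sample(20:60, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

true_class_of <- function(pattern) {
  k <- nchar(gsub("[^+]", "", pattern)) + 1L
  c("late", "intermediate", "early")[pmin(k, 3L)]
}
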