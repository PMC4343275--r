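#' Strict duplicate removal of split-read mappings
#'
#' Within a sample, a mapping is dropped when an earlier-kept mapping has
#' both breakpoint ends within `slop` bp and identical non-breakpoint end
#' positions (multi-pass discordant deduplication).
#'
#' @param mappings split-read mapping data.frame (see [cluster_breakpoints()]
#'   for the expected columns).
#' @param slop positional tolerance in bp (default 3).
#' @return The deduplicated mappings.
#' @export
dedup_mappings <- function(mappings, slop = 3) {
  if (nrow(mappings) == 0) {
    return(mappings)
  }
  keep <- rep(TRUE, nrow(mappings))
  key <- paste(mappings$sample, mappings$type, mappings$chrom1, mappings$chrom2)
  for (g in split(seq_len(nrow(mappings)), key)) {
    if (length(g) < 2) next
    for (ii in seq_along(g)[-1]) {
      i <- g[ii]
      prev <- g[seq_len(ii - 1)]
      prev <- prev[keep[prev]]
      if (length(prev) == 0) next
      dup <- abs(mappings$pos1[prev] - mappings$pos1[i]) <= slop &
        abs(mappings$pos2[prev] - mappings$pos2[i]) <= slop &
        mappings$nb_end1[prev] == mappings$nb_end1[i] &
        mappings$nb_end2[prev] == mappings$nb_end2[i]
      if (any(dup)) keep[i] <- FALSE
    }
  }
  out <- mappings[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster split-read mappings into breakpoint candidates
#'
#' Each mapping's two breakpoint ends become +/- 1-bp intervals; mappings are
#' joined by single linkage whenever both end intervals overlap and the
#' predicted variant types match. Mappings from all samples are pooled before
#' clustering; per-sample read counts are tallied per cluster afterwards.
#' Clustering is invariant to input order.
#'
#' @param mappings data.frame with columns `read_id`, `sample`, `type`,
#'   `chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`, `strand2`, `nb_end1`,
#'   `nb_end2`, `mq`.
#' @param slop half-width of the breakpoint interval (default 1 bp; two ends
#'   overlap iff their positions differ by at most `2 * slop`).
#' @return The mappings with a `cluster` id column, ordered canonically.
#' @export
cluster_breakpoints <- function(mappings, slop = 1) {
  if (nrow(mappings) == 0) {
    mappings$cluster <- integer(0)
    return(mappings)
  }
  # canonical order makes the result independent of input order
  ord <- order(mappings$type, mappings$chrom1, mappings$chrom2,
               mappings$pos1, mappings$pos2, mappings$read_id)
  m <- mappings[ord, , drop = FALSE]
  n <- nrow(m)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key <- paste(m$type, m$chrom1, m$chrom2)
  tol <- 2 * slop
  for (g in split(seq_len(n), key)) {
    if (length(g) < 2) next
    g <- g[order(m$pos1[g], m$pos2[g])]
    for (a in seq_along(g)[-length(g)]) {
      i <- g[a]
      for (b in (a + 1):length(g)) {
        j <- g[b]
        if (m$pos1[j] - m$pos1[i] > tol) break
        if (abs(m$pos2[j] - m$pos2[i]) <= tol) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  m$cluster <- match(roots, unique(roots))
  rownames(m) <- NULL
  m
}

#' Representative breakpoint of each cluster
#'
#' Within each cluster an all-by-all comparison counts, for every member
#' breakpoint, how many members lie within +/- 1 bp of it at both ends; the
#' member with maximal support is reported as the cluster representative
#' (ties go to the smallest `(pos1, pos2)`).
#'
#' @param clustered output of [cluster_breakpoints()].
#' @param slop support tolerance in bp (default 1).
#' @return One row per cluster: `cluster`, `type`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2`, `support` (reads within +/- slop of the
#'   representative), `cluster_size`, `mean_mq`, `stagger_span`, and
#'   `n_<sample>` per-sample read counts over the whole cluster.
#' @export
representative_breakpoints <- function(clustered, slop = 1) {
  if (nrow(clustered) == 0) {
    return(data.frame())
  }
  samples <- sort(unique(clustered$sample))
  out <- lapply(split(seq_len(nrow(clustered)), clustered$cluster), function(idx) {
    cl <- clustered[idx, , drop = FALSE]
    supp <- vapply(seq_len(nrow(cl)), function(i) {
      sum(abs(cl$pos1 - cl$pos1[i]) <= slop & abs(cl$pos2 - cl$pos2[i]) <= slop)
    }, integer(1))
    best <- which(supp == max(supp))
    best <- best[order(cl$pos1[best], cl$pos2[best])][1]
    stag <- (max(cl$nb_end1) - min(cl$nb_end1)) +
      (max(cl$nb_end2) - min(cl$nb_end2))
    row <- data.frame(cluster = cl$cluster[1], type = cl$type[1],
                      chrom1 = cl$chrom1[best], pos1 = cl$pos1[best],
                      chrom2 = cl$chrom2[best], pos2 = cl$pos2[best],
                      support = max(supp), cluster_size = nrow(cl),
                      mean_mq = mean(cl$mq), stagger_span = stag,
                      stringsAsFactors = FALSE)
    for (s in samples) row[[paste0("n_", s)]] <- sum(cl$sample == s)
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply the five published breakpoint-call filters
#'
#' Fail flags are set per criterion: (1) fewer than 3 supporting reads;
#' (2) intrachromosomal size below 50 bp (interchromosomal calls are exempt);
#' (3) either breakpoint's +/- 1-bp interval overlapping a simple/satellite
#' repeat by more than 50% of the interval; (4) mean mapping quality not
#' greater than 30; (5) supporting reads' non-breakpoint ends staggered by a
#' total (positional span summed over both sides) of less than 3 bp.
#'
#' @param calls representative calls from [representative_breakpoints()].
#' @param repeats repeat annotation (`chrom`, `start`, `end`, `class`) with
#'   classes `simple`/`satellite`; `NULL` skips the repeat filter.
#' @param min_support,min_size,min_mq,min_stagger filter thresholds.
#' @return The calls with logical `fail_*` columns and a `pass` column.
#' @export
filter_sv_calls <- function(calls, repeats = NULL, min_support = 3,
                            min_size = 50, min_mq = 30, min_stagger = 3) {
  if (nrow(calls) == 0) {
    return(calls)
  }
  calls$fail_support <- calls$support < min_support
  intra <- calls$chrom1 == calls$chrom2
  calls$fail_size <- intra & abs(calls$pos2 - calls$pos1) < min_size
  calls$fail_mq <- calls$mean_mq <= min_mq
  calls$fail_stagger <- calls$stagger_span < min_stagger
  rep_frac <- function(chrom, pos) {
    if (is.null(repeats) || nrow(repeats) == 0) {
      return(numeric(length(pos)))
    }
    vapply(seq_along(pos), function(i) {
      r <- repeats[repeats$chrom == chrom[i], , drop = FALSE]
      if (nrow(r) == 0) {
        return(0)
      }
      lo <- pos[i] - 1
      hi <- pos[i] + 1
      ov <- pmax(0, pmin(hi, r$end) - pmax(lo - 1, r$start))
      max(ov) / 3
    }, numeric(1))
  }
  calls$fail_repeat <- rep_frac(calls$chrom1, calls$pos1) > 0.5 |
    rep_frac(calls$chrom2, calls$pos2) > 0.5
  calls$pass <- !(calls$fail_support | calls$fail_size | calls$fail_mq |
                    calls$fail_stagger | calls$fail_repeat)
  calls
}

#' Merge a split-read callset with a second callset
#'
#' Calls of the same variant type whose two ends both lie within +/- 10 bp of
#' one another are taken to describe the same somatic mutation: the merged
#' record keeps the split-read (SRM) coordinates and notes dual support.
#' Unmatched calls from either set pass through.
#'
#' @param srm,other breakpoint call data.frames (columns `type`, `chrom1`,
#'   `pos1`, `chrom2`, `pos2`, ...).
#' @param tol end tolerance in bp (default 10).
#' @return Unified call data.frame with `source` in
#'   `{"SRM","other","SRM+other"}`.
#' @export
merge_callsets <- function(srm, other, tol = 10) {
  srm$source <- rep("SRM", nrow(srm))
  other$source <- rep("other", nrow(other))
  if (nrow(srm) == 0) {
    return(other)
  }
  if (nrow(other) > 0) {
    matched_other <- logical(nrow(other))
    for (i in seq_len(nrow(srm))) {
      cand <- which(!matched_other &
                      other$type == srm$type[i] &
                      other$chrom1 == srm$chrom1[i] &
                      other$chrom2 == srm$chrom2[i] &
                      abs(other$pos1 - srm$pos1[i]) <= tol &
                      abs(other$pos2 - srm$pos2[i]) <= tol)
      if (length(cand) > 0) {
        matched_other[cand[1]] <- TRUE
        srm$source[i] <- "SRM+other"
      }
    }
    other <- other[!matched_other, , drop = FALSE]
  }
  common <- intersect(names(srm), names(other))
  res <- rbind(srm[, common, drop = FALSE], other[, common, drop = FALSE])
  rownames(res) <- NULL
  res
}

#' Genotype a breakpoint junction from read-to-contig alignments
#'
#' A read supports the junction iff its aligned span covers the junction
#' with at least `flank` aligned bases on each side. The call is germline if
#' one or more D reads support it; a tumor sample is genotyped positive with
#' at least two supporting reads. Germline calls are excluded from the
#' somatic set by the caller.
#'
#' @param alignments data.frame with `sample`, `start`, `end` (1-based
#'   inclusive aligned span on the breakpoint contig).
#' @param junction junction offset on the contig: the junction lies between
#'   contig bases `junction` and `junction + 1`.
#' @param contig_length length of the contig.
#' @param normal_label label of the normal sample.
#' @param tumor_labels tumor sample labels.
#' @param flank minimum aligned bases on each side (default 20).
#' @param min_tumor_reads supporting reads for a positive tumor genotype.
#' @return List `present` (named logical over tumors), `germline` (logical),
#'   `support` (named read counts).
#' @export
genotype_junction <- function(alignments, junction, contig_length,
                              normal_label = "D",
                              tumor_labels = c("H", "AA", "AB"),
                              flank = 20, min_tumor_reads = 2) {
  if (junction < 1 || junction >= contig_length) {
    stop("junction offset outside contig")
  }
  left <- junction - alignments$start + 1
  right <- alignments$end - junction
  supports <- left >= flank & right >= flank
  labs <- c(normal_label, tumor_labels)
  support <- vapply(labs, function(s) {
    sum(supports & alignments$sample == s)
  }, integer(1))
  germline <- support[normal_label] >= 1
  present <- support[tumor_labels] >= min_tumor_reads
  list(present = present, germline = unname(germline), support = support)
}
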