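#' Select high-confidence germline heterozygous SNPs
#'
#' A SNP is retained iff it is genotyped heterozygous in the normal diploid
#' (D) sample and its alternate-allele fraction in D lies in `[0.25, 0.75]`
#' (inclusive). Per-tumor minor allele frequencies (MAF = min(alt fraction,
#' 1 - alt fraction)) are attached for the requested tumor samples.
#'
#' @param snps data.frame with `chrom`, `pos`, `depth_D`, `alt_D` and, for
#'   each tumor, `depth_<label>`, `alt_<label>`. An optional logical
#'   `het_D` column gives the D genotype call; if absent, D heterozygosity is
#'   taken from the allele fraction criterion itself.
#' @param tumor_labels tumor sample labels.
#' @param bounds inclusive D alt-fraction bounds.
#' @return The retained rows with `af_D` and `maf_<label>` columns added.
#' @export
select_het_snps <- function(snps, tumor_labels = c("H", "AA", "AB"),
                            bounds = c(0.25, 0.75)) {
  if (!all(c("depth_D", "alt_D") %in% names(snps))) {
    stop("D counts are required")
  }
  depth <- snps$depth_D
  af <- ifelse(depth > 0, snps$alt_D / depth, NA_real_)
  keep <- !is.na(af) & af >= bounds[1] & af <= bounds[2]
  if (!is.null(snps$het_D)) keep <- keep & snps$het_D
  out <- snps[keep, , drop = FALSE]
  out$af_D <- af[keep]
  for (lab in tumor_labels) {
    d <- out[[paste0("depth_", lab)]]
    a <- out[[paste0("alt_", lab)]]
    frac <- ifelse(d > 0, a / d, NA_real_)
    out[[paste0("maf_", lab)]] <- pmin(frac, 1 - frac)
  }
  rownames(out) <- NULL
  out
}

# Cumulative non-gap ("analyzed") coordinate transform for one chromosome.
# Returns functions mapping genomic pos -> non-gap offset and back.
nongap_transform <- function(chrom_len, gaps) {
  if (is.null(gaps) || nrow(gaps) == 0) {
    return(list(fwd = identity, inv = identity, total = chrom_len))
  }
  g <- gaps[order(gaps$start), , drop = FALSE]
  ir <- IRanges::reduce(intervals_to_iranges(g))
  gs <- IRanges::start(ir) - 1
  ge <- IRanges::end(ir)
  # breakpoints of non-gap blocks
  block_start <- c(0, ge)
  block_end <- c(gs, chrom_len)
  keep <- block_end > block_start
  block_start <- block_start[keep]
  block_end <- block_end[keep]
  w <- block_end - block_start
  cum <- c(0, cumsum(w))
  fwd <- function(x) {
    j <- findInterval(x, block_start)
    j <- pmin(pmax(j, 1L), length(w))
    cum[j] + pmin(pmax(x - block_start[j], 0), w[j])
  }
  inv <- function(u) {
    j <- findInterval(u, cum, rightmost.closed = TRUE)
    j <- pmin(pmax(j, 1L), length(w))
    block_start[j] + (u - cum[j])
  }
  list(fwd = fwd, inv = inv, total = sum(w))
}

#' Detect loss-of-heterozygosity blocks by sliding-window mean MAF
#'
#' Mean MAF is measured in 1-Mb sliding windows of non-gap sequence advanced
#' by 500 kb (window extents are measured after excising assembly gaps). A
#' window is flagged iff the mean MAF of its SNPs is strictly below
#' `maf_thresh`; windows with no informative SNPs never open or extend a
#' block. Overlapping or adjacent flagged windows are merged into blocks. A
#' trailing sub-window chromosome remainder is evaluated as a final shorter
#' window.
#'
#' @param het het SNPs from [select_het_snps()], with `maf_<sample>` present.
#' @param sample tumor sample label.
#' @param chrom_lengths named chromosome lengths.
#' @param gaps assembly-gap intervals (`chrom`, `start`, `end`), or `NULL`.
#' @param window,step window and step size in non-gap bp.
#' @param maf_thresh flag threshold (strict) on window mean MAF.
#' @return Data.frame of blocks: `sample`, `chrom`, `start`, `end` (genomic,
#'   0-based half-open), `mean_maf`, `n_windows`.
#' @export
loh_blocks <- function(het, sample, chrom_lengths, gaps = NULL,
                       window = 1e6, step = 5e5, maf_thresh = 0.25) {
  maf_col <- paste0("maf_", sample)
  if (!maf_col %in% names(het)) stop("missing MAF column for sample ", sample)
  blocks <- list()
  for (ch in names(chrom_lengths)) {
    tr <- nongap_transform(chrom_lengths[[ch]],
                           if (is.null(gaps)) NULL else
                             gaps[gaps$chrom == ch, , drop = FALSE])
    snp <- het[het$chrom == ch & !is.na(het[[maf_col]]), , drop = FALSE]
    u <- tr$fwd(snp$pos - 1)
    starts <- seq(0, max(0, tr$total - 1), by = step)
    flagged <- logical(length(starts))
    for (i in seq_along(starts)) {
      lo <- starts[i]
      hi <- min(lo + window, tr$total)
      inw <- u >= lo & u < hi
      if (!any(inw)) next
      flagged[i] <- mean(snp[[maf_col]][inw]) < maf_thresh
    }
    if (!any(flagged)) next
    # merge overlapping/adjacent flagged windows (windows overlap when
    # step < window, so consecutive flagged windows always merge)
    r <- rle(flagged)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    for (j in which(r$values)) {
      lo <- starts[starts_i[j]]
      hi <- min(starts[ends_i[j]] + window, tr$total)
      inb <- u >= lo & u < hi
      nwin <- ends_i[j] - starts_i[j] + 1L
      blocks[[length(blocks) + 1]] <- data.frame(
        sample = sample, chrom = ch,
        start = tr$inv(lo), end = tr$inv(hi),
        mean_maf = mean(snp[[maf_col]][inb]),
        n_windows = nwin, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(sample = character(0), chrom = character(0), start = numeric(0),
               end = numeric(0), mean_maf = numeric(0), n_windows = integer(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Overlap between SNV positions and LOH blocks
#'
#' @param snvs data.frame with `chrom` and `pos` (1-based).
#' @param blocks LOH blocks (`chrom`, `start`, `end`, 0-based half-open).
#' @return List `overlap` (count of SNVs inside any block), `total`,
#'   `fraction`.
#' @export
snv_loh_overlap <- function(snvs, blocks) {
  total <- nrow(snvs)
  if (total == 0) {
    return(list(overlap = 0L, total = 0L, fraction = NA_real_))
  }
  hit <- logical(total)
  for (ch in unique(snvs$chrom)) {
    sel <- snvs$chrom == ch
    hit[sel] <- pos_in_intervals(snvs$pos[sel],
                                 blocks[blocks$chrom == ch, , drop = FALSE])
  }
  list(overlap = sum(hit), total = total, fraction = sum(hit) / total)
}

#' Fold enrichment of SNV-block overlap over chance
#'
#' The chance expectation for uniformly placed SNVs is the fraction of the
#' analyzed genome covered by blocks; the fold enrichment is the observed
#' overlap fraction divided by that expectation.
#'
#' @param overlap,total observed overlap count and total SNV count.
#' @param blocks LOH blocks (`chrom`, `start`, `end`).
#' @param analyzed_length total analyzed (non-gap) genome length in bp.
#' @return List `fold`, `observed_fraction`, `expected_fraction`.
#' @export
fold_enrichment <- function(overlap, total, blocks, analyzed_length) {
  block_len <- merged_interval_length(blocks)
  if (block_len <= 0) stop("zero total block length: fold enrichment undefined")
  if (analyzed_length < block_len) {
    stop("analyzed_length must be at least the total block length")
  }
  expected <- block_len / analyzed_length
  observed <- overlap / total
  list(fold = observed / expected, observed_fraction = observed,
       expected_fraction = expected)
}
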