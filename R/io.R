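# Readers/writers for the standard interchange formats. VCF positions are
# 1-based; BED/BEDPE intervals are 0-based half-open.

#' Write site observations as a multi-sample VCF
#'
#' Emits an uncompressed VCF 4.2 with per-sample `DP` (depth) and `AD`
#' (ref,alt read counts) FORMAT fields.
#'
#' @param obs observation data.frame (`chrom`, `pos`, `id`, `ref`, `alt`,
#'   plus `depth_<label>`/`alt_<label>` columns).
#' @param sample_labels sample column order.
#' @param path output file.
#' @param ref optional `reference_model` for contig header lines.
#' @export
write_sites_vcf <- function(obs, sample_labels, path, ref = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ploidyseq")
  if (!is.null(ref)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          ref$chromosomes$name, as.integer(ref$chromosomes$length)))
  }
  hdr <- c(hdr,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_labels), collapse = "\t"))
  o <- obs[order(obs$chrom, obs$pos), , drop = FALSE]
  fmt <- vapply(sample_labels, function(s) {
    d <- o[[paste0("depth_", s)]]
    a <- o[[paste0("alt_", s)]]
    sprintf("./.:%d:%d,%d", d, d - a, a)
  }, character(nrow(o)))
  if (nrow(o) == 1) fmt <- matrix(fmt, nrow = 1)
  lines <- paste(o$chrom, o$pos, o$id, o$ref, o$alt, ".", "PASS", ".",
                 "GT:DP:AD",
                 apply(fmt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a multi-sample VCF into the wide observation layout
#'
#' Parses per-sample `DP` and `AD` FORMAT fields (via \pkg{vcfR}) into
#' `depth_<label>`/`alt_<label>` columns.
#'
#' @param path VCF file (plain text or gzipped).
#' @return Observation data.frame.
#' @export
read_sites_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("vcfR is required to read VCF files")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), id = fix$ID,
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  for (s in colnames(dp)) {
    out[[paste0("depth_", s)]] <- as.integer(dp[, s])
    out[[paste0("alt_", s)]] <-
      as.integer(vapply(strsplit(ad[, s], ","), function(x) x[2], character(1)))
  }
  rownames(out) <- NULL
  out
}

#' Write intervals as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optional further columns appended as extra BED fields.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end", setdiff(names(df), c("chrom", "start", "end")))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' @param path BED file.
#' @param extra_names names for columns beyond the first three.
#' @return Data.frame with `chrom`, `start`, `end` and any extra columns.
#' @export
read_bed <- function(path, extra_names = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.null(extra_names) && ncol(df) > 3) {
    names(df)[3 + seq_along(extra_names)] <- extra_names
  }
  df
}

#' Write split-read mappings or breakpoint calls as BEDPE
#'
#' Standard ten columns (two 0-based half-open 1-bp intervals at the
#' breakpoint positions, name, score, strands) followed by the extra fields.
#'
#' @param df mapping/call data.frame with `chrom1`, `pos1`, `chrom2`, `pos2`
#'   and optionally `read_id`/`mq`/`strand1`/`strand2` plus extras.
#' @param path output file.
#' @param extra names of extra columns to append.
#' @export
write_bedpe <- function(df, path, extra = intersect(c("type", "sample", "support"),
                                                    names(df))) {
  name <- df$read_id %||% df$cluster %||% rep(".", nrow(df))
  out <- data.frame(chrom1 = df$chrom1, start1 = df$pos1 - 1, end1 = df$pos1,
                    chrom2 = df$chrom2, start2 = df$pos2 - 1, end2 = df$pos2,
                    name = name, score = df$mq %||% df$mean_mq %||% 0,
                    strand1 = df$strand1 %||% rep("+", nrow(df)),
                    strand2 = df$strand2 %||% rep("-", nrow(df)),
                    stringsAsFactors = FALSE)
  for (e in extra) out[[e]] <- df[[e]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE file written by [write_bedpe()]
#'
#' @param path BEDPE file.
#' @param extra names of the extra columns after the ten standard ones.
#' @return Data.frame with `chrom1`, `pos1`, `chrom2`, `pos2`, `read_id`,
#'   `mq`, `strand1`, `strand2` and the extras.
#' @export
read_bedpe <- function(path, extra = c("type", "sample")) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  out <- data.frame(chrom1 = df[[1]], pos1 = df[[3]],
                    chrom2 = df[[4]], pos2 = df[[6]],
                    read_id = as.character(df[[7]]), mq = df[[8]],
                    strand1 = df[[9]], strand2 = df[[10]],
                    stringsAsFactors = FALSE)
  for (i in seq_along(extra)) {
    if (ncol(df) >= 10 + i) out[[extra[i]]] <- df[[10 + i]]
  }
  out
}
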