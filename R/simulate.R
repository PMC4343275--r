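#' Define the flow-sorted subpopulation samples
#'
#' Builds the sample metadata (label, mean ploidy, cell fraction, clone
#' mixture, target coverage) for the four flow-sorted fractions. Defaults
#' follow the study design: D/H/AA/AB cell fractions 0.40/0.42/0.10/0.08 and
#' 53X mean coverage per sample.
#'
#' @param tree a `clone_tree` (supplies the clone mixtures).
#' @param ref optional `reference_model`; when given, each sample's mean
#'   ploidy (in N units) is computed from its clones' copy profiles.
#' @param coverage target mean sequencing depth per sample.
#' @param cell_fractions named fractions of total nuclei; must sum to 1.
#' @return A named list of `subpop_sample` objects.
#' @export
default_samples <- function(tree, ref = NULL, coverage = 53,
                            cell_fractions = c(D = 0.40, H = 0.42,
                                               AA = 0.10, AB = 0.08)) {
  if (abs(sum(cell_fractions) - 1) > 1e-8) {
    stop("cell fractions must sum to 1")
  }
  if (coverage <= 0) stop("coverage must be positive")
  labels <- names(tree$clone_mixtures)
  if (!all(labels %in% names(cell_fractions))) {
    stop("cell_fractions must cover all sample labels: ",
         paste(labels, collapse = ", "))
  }
  out <- lapply(labels, function(lab) {
    mix <- tree$clone_mixtures[[lab]]
    ploidy <- if (!is.null(ref)) {
      sum(vapply(names(mix), function(cl) {
        mix[[cl]] * clone_mean_copies(tree, cl, ref)
      }, numeric(1)))
    } else {
      NA_real_
    }
    structure(list(label = lab, ploidy = ploidy,
                   cell_fraction = unname(cell_fractions[lab]),
                   clone_mixture = mix, mean_coverage = coverage),
              class = "subpop_sample")
  })
  stats::setNames(out, labels)
}

#' @export
print.subpop_sample <- function(x, ...) {
  cat(sprintf("subpop_sample %s: ploidy %s N, cell fraction %.2f, %dX\n",
              x$label, ifelse(is.na(x$ploidy), "?", sprintf("%.2f", x$ploidy)),
              x$cell_fraction, round(x$mean_coverage)))
  invisible(x)
}

#' Simulate per-subpopulation sequencing observations
#'
#' Produces, from a clone tree and reference model, everything the analysis
#' pipeline consumes: per-site read counts for somatic SNVs/indels and
#' germline heterozygous SNPs, per-bin read counts, and split-read mappings
#' around each planted structural variant, all with ground truth attached.
#'
#' At each site a sample's alt fraction is the copy-weighted mutant fraction
#' over its clone mixture (equal to the mixture-weighted mean of per-clone
#' mutant/total ratios whenever total copies agree across clones). Depth is
#' Poisson with mean `coverage x local copy ratio`; alt reads are Binomial
#' with success probability `af (1 - e) + (1 - af) e / 3` for error rate `e`.
#'
#' @param tree a `clone_tree` carrying placed genomic events (build it with a
#'   `ref`).
#' @param samples list of `subpop_sample`s from [default_samples()].
#' @param ref the `reference_model` used to build the tree.
#' @param error_rate per-base sequencing error rate, in `[0, 0.01]`.
#' @param het_snp_rate germline heterozygous SNP density per mappable bp.
#' @param n_bins number of read-depth bins.
#' @param bin_base_count expected reads per bin in a copy-neutral diploid.
#' @param gc_bias strength of the planted quadratic GC bias on bin counts
#'   (0 disables it).
#' @param sv_read_factor split-read yield: expected supporting reads per SV
#'   per sample is `sv_read_factor x coverage x allele fraction`.
#' @param sv_mq mapping quality of planted split reads.
#' @param n_sv_germline germline SVs planted on the root (present in D).
#' @param sv_noise number of low-support noise mappings to sprinkle in.
#' @param seed integer master seed; each output draws from a child stream.
#' @return An object of class `ploidyseq_sim`: list with `sites` (somatic
#'   SNV/indel observations, wide columns `depth_<label>`, `alt_<label>`),
#'   `het` (germline het SNP observations), `bins`, `bin_counts` (matrix
#'   bins x samples), `splits` (split-read mappings), `sv_truth`, `samples`,
#'   `tree`, `ref`.
#' @export
simulate_observations <- function(tree, samples, ref,
                                  error_rate = 0.002,
                                  het_snp_rate = 5e-4,
                                  n_bins = 500,
                                  bin_base_count = 500,
                                  gc_bias = 0.3,
                                  sv_read_factor = 0.25,
                                  sv_mq = 60L,
                                  n_sv_germline = 5,
                                  sv_noise = 30,
                                  seed = 1) {
  if (error_rate < 0 || error_rate > 0.01) {
    stop("error_rate must lie in [0, 0.01]")
  }
  labels <- vapply(samples, `[[`, character(1), "label")
  if (any(!labels %in% names(tree$clone_mixtures))) {
    stop("samples must match the tree's clone mixtures")
  }

  muts <- tree$mutations
  point <- muts[muts$class %in% c("SNV", "indel"), , drop = FALSE]
  svs <- muts[muts$class == "SV", , drop = FALSE]

  bases <- c("A", "C", "G", "T")
  sites <- with_stream(seed, "sim/positions", {
    pos <- sample_mappable_positions(ref, nrow(point))
    refb <- sample(bases, nrow(point), replace = TRUE)
    altb <- vapply(refb, function(b) sample(setdiff(bases, b), 1), character(1))
    is_indel <- point$class == "indel"
    ins <- stats::runif(nrow(point)) < 0.5
    extra <- vapply(seq_len(nrow(point)), function(i) {
      paste(sample(bases, sample(1:3, 1), replace = TRUE), collapse = "")
    }, character(1))
    refv <- ifelse(is_indel & !ins, paste0(refb, extra), refb)
    altv <- ifelse(is_indel, ifelse(ins, paste0(refb, extra), refb), altb)
    data.frame(id = point$id, class = point$class, chrom = pos$chrom,
               pos = pos$pos, ref = refv, alt = altv, node = point$node,
               stringsAsFactors = FALSE)
  })

  het <- with_stream(seed, "sim/germline", {
    n_het <- round(het_snp_rate * sum(mappable_regions(ref)$end -
                                        mappable_regions(ref)$start))
    pos <- sample_mappable_positions(ref, n_het)
    refb <- sample(bases, n_het, replace = TRUE)
    altb <- vapply(refb, function(b) sample(setdiff(bases, b), 1), character(1))
    data.frame(id = sprintf("germ_%06d", seq_len(n_het)), class = "SNV",
               chrom = pos$chrom, pos = pos$pos, ref = refb, alt = altb,
               node = "germline", stringsAsFactors = FALSE)
  })

  all_sites <- rbind(sites, het)
  site_tab <- data.frame(chrom = all_sites$chrom, pos = all_sites$pos,
                         origin = all_sites$node, stringsAsFactors = FALSE)

  clones <- unique(unlist(lapply(tree$clone_mixtures[labels], names)))
  states <- lapply(clones, function(cl) copy_state(tree, cl, site_tab))
  names(states) <- clones
  mean_copies <- vapply(clones, function(cl) clone_mean_copies(tree, cl, ref),
                        numeric(1))

  truth_af <- matrix(0, nrow(all_sites), length(labels),
                     dimnames = list(all_sites$id, labels))
  copy_ratio <- matrix(0, nrow(all_sites), length(labels),
                       dimnames = list(all_sites$id, labels))
  for (lab in labels) {
    mix <- tree$clone_mixtures[[lab]]
    wm <- wt <- numeric(nrow(all_sites))
    denom <- 0
    for (cl in names(mix)) {
      wm <- wm + mix[[cl]] * states[[cl]]$m
      wt <- wt + mix[[cl]] * states[[cl]]$t
      denom <- denom + mix[[cl]] * mean_copies[[cl]]
    }
    truth_af[, lab] <- ifelse(wt > 0, wm / wt, 0)
    copy_ratio[, lab] <- wt / denom
  }

  obs <- with_stream(seed, "sim/readcounts", {
    out <- all_sites
    for (i in seq_along(labels)) {
      lab <- labels[i]
      cov <- samples[[lab]]$mean_coverage
      depth <- stats::rpois(nrow(out), cov * copy_ratio[, lab])
      af <- truth_af[, lab]
      p <- af * (1 - error_rate) + (1 - af) * error_rate / 3
      alt <- stats::rbinom(nrow(out), depth, p)
      out[[paste0("depth_", lab)]] <- depth
      out[[paste0("alt_", lab)]] <- alt
    }
    out
  })
  for (lab in labels) obs[[paste0("af_true_", lab)]] <- truth_af[, lab]
  # ground-truth sharing pattern: a sample truly carries a site iff its
  # planted allele fraction is positive (LOH/deletion events can remove a
  # mutation from a descendant lineage)
  tumor_labels <- setdiff(labels, "D")
  obs$pattern_true <- apply(truth_af[, tumor_labels, drop = FALSE] > 0, 1,
                            function(r) paste(tumor_labels[r], collapse = "+"))
  som_obs <- obs[obs$node != "germline", , drop = FALSE]
  het_obs <- obs[obs$node == "germline", , drop = FALSE]
  rownames(som_obs) <- rownames(het_obs) <- NULL

  bins <- make_variable_bins(ref, n_bins)
  bin_counts <- with_stream(seed, "sim/bins", {
    mids <- floor((bins$start + bins$end) / 2) + 1L
    bin_copies <- vapply(clones, function(cl) {
      clone_total_copies(tree, cl, bins$chrom, mids)
    }, numeric(nrow(bins)))
    bias <- 1 - gc_bias * 4 * (bins$gc - 0.45)^2
    bias <- pmax(bias, 0.05)
    m <- matrix(0L, nrow(bins), length(labels), dimnames = list(NULL, labels))
    for (lab in labels) {
      mix <- tree$clone_mixtures[[lab]]
      wt <- numeric(nrow(bins))
      denom <- 0
      for (cl in names(mix)) {
        wt <- wt + mix[[cl]] * bin_copies[, cl]
        denom <- denom + mix[[cl]] * mean_copies[[cl]]
      }
      lambda <- bin_base_count * (wt / denom) * bias
      m[, lab] <- stats::rpois(nrow(bins), lambda)
    }
    m
  })

  svres <- with_stream(seed, "sim/splitreads", {
    simulate_split_reads(tree, samples, ref, svs, labels,
                         sv_read_factor, sv_mq, n_sv_germline, sv_noise)
  })

  structure(list(sites = som_obs, het = het_obs, bins = bins,
                 bin_counts = bin_counts, splits = svres$splits,
                 sv_truth = svres$truth, samples = samples, tree = tree,
                 ref = ref,
                 params = list(error_rate = error_rate, seed = seed,
                               het_snp_rate = het_snp_rate, n_bins = n_bins,
                               gc_bias = gc_bias)),
            class = "ploidyseq_sim")
}

# Plant SV breakpoints and emit supporting split-read mappings per sample.
simulate_split_reads <- function(tree, samples, ref, svs, labels,
                                 sv_read_factor, sv_mq, n_sv_germline,
                                 sv_noise) {
  types <- c("DEL", "DUP", "INV", "TRA")
  n_som <- nrow(svs)
  n_all <- n_som + n_sv_germline
  truth <- NULL
  if (n_all > 0) {
    ty <- sample(types, n_all, replace = TRUE, prob = c(0.45, 0.25, 0.2, 0.1))
    p1 <- sample_mappable_positions(ref, n_all)
    size <- round(10^stats::runif(n_all, log10(5e3), log10(5e5)))
    chrom2 <- p1$chrom
    pos2 <- pmin(p1$pos + size,
                 ref$chromosomes$length[match(p1$chrom, ref$chromosomes$name)] - 1)
    tra <- ty == "TRA"
    if (any(tra)) {
      alt_pos <- sample_mappable_positions(ref, sum(tra))
      chrom2[tra] <- alt_pos$chrom
      pos2[tra] <- alt_pos$pos
    }
    truth <- data.frame(
      id = c(svs$id, if (n_sv_germline > 0) sprintf("svg_%03d", seq_len(n_sv_germline))),
      type = ty, chrom1 = p1$chrom, pos1 = p1$pos, chrom2 = chrom2, pos2 = pos2,
      node = c(svs$node, rep("normal", n_sv_germline)),
      germline = c(rep(FALSE, n_som), rep(TRUE, n_sv_germline)),
      stringsAsFactors = FALSE)
    # canonical end order for intrachromosomal records
    flip <- truth$chrom1 == truth$chrom2 & truth$pos2 < truth$pos1
    tmp <- truth$pos1[flip]
    truth$pos1[flip] <- truth$pos2[flip]
    truth$pos2[flip] <- tmp
  }

  rows <- list()
  if (n_all > 0) {
    site_tab <- data.frame(chrom = truth$chrom1, pos = truth$pos1,
                           origin = truth$node, stringsAsFactors = FALSE)
    for (lab in labels) {
      mix <- tree$clone_mixtures[[lab]]
      wm <- wt <- numeric(n_all)
      for (cl in names(mix)) {
        st <- copy_state(tree, cl, site_tab)
        wm <- wm + mix[[cl]] * st$m
        wt <- wt + mix[[cl]] * st$t
      }
      af <- ifelse(wt > 0, wm / wt, 0)
      cov <- samples[[lab]]$mean_coverage
      nsup <- stats::rpois(n_all, sv_read_factor * cov * af)
      for (i in which(nsup > 0)) {
        k <- nsup[i]
        j1 <- truth$pos1[i] + sample(c(-1L, 0L, 1L), k, replace = TRUE,
                                     prob = c(0.1, 0.8, 0.1))
        j2 <- truth$pos2[i] + sample(c(-1L, 0L, 1L), k, replace = TRUE,
                                     prob = c(0.1, 0.8, 0.1))
        off <- 80L + 7L * (seq_len(k) - 1L) + sample(0:2, k, replace = TRUE)
        rows[[length(rows) + 1]] <- data.frame(
          read_id = sprintf("%s_%s_r%02d", truth$id[i], lab, seq_len(k)),
          sample = lab, type = truth$type[i],
          chrom1 = truth$chrom1[i], pos1 = j1, strand1 = "+",
          chrom2 = truth$chrom2[i], pos2 = j2,
          strand2 = ifelse(truth$type[i] == "INV", "+", "-"),
          nb_end1 = truth$pos1[i] - off,
          nb_end2 = truth$pos2[i] + off,
          mq = sv_mq, stringsAsFactors = FALSE)
      }
    }
  }
  if (sv_noise > 0) {
    pn <- sample_mappable_positions(ref, sv_noise)
    sz <- round(stats::runif(sv_noise, 100, 5e4))
    rows[[length(rows) + 1]] <- data.frame(
      read_id = sprintf("noise_r%03d", seq_len(sv_noise)),
      sample = sample(labels, sv_noise, replace = TRUE),
      type = sample(c("DEL", "DUP", "INV"), sv_noise, replace = TRUE),
      chrom1 = pn$chrom, pos1 = pn$pos, strand1 = "+",
      chrom2 = pn$chrom, pos2 = pn$pos + sz,
      strand2 = "-",
      nb_end1 = pn$pos - 80L, nb_end2 = pn$pos + sz + 80L,
      mq = sample(5:60, sv_noise, replace = TRUE), stringsAsFactors = FALSE)
  }
  splits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), sample = character(0), type = character(0),
               chrom1 = character(0), pos1 = integer(0), strand1 = character(0),
               chrom2 = character(0), pos2 = integer(0), strand2 = character(0),
               nb_end1 = integer(0), nb_end2 = integer(0), mq = numeric(0),
               stringsAsFactors = FALSE)
  rownames(splits) <- NULL
  list(splits = splits, truth = truth)
}

#' @export
print.ploidyseq_sim <- function(x, ...) {
  cat(sprintf("ploidyseq_sim: %d somatic sites, %d germline het SNPs, %d bins, %d split reads\n",
              nrow(x$sites), nrow(x$het), nrow(x$bins), nrow(x$splits)))
  cat(sprintf("  samples: %s\n",
              paste(vapply(x$samples, `[[`, character(1), "label"), collapse = ", ")))
  invisible(x)
}
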