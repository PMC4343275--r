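#' Default pipeline configuration
#'
#' All analysis thresholds default to the published values: depth/alt-read
#' calling thresholds 20/5 with a 2,500-read cap; het-SNP D-fraction bounds
#' 0.25-0.75; LOH windows of 1 Mb stepped by 500 kb with mean-MAF threshold
#' 0.25; copy-ratio gain/loss thresholds 1.4/0.8; SV filters of >=3 reads,
#' >=50 bp, mapping quality >30, >=3 bp stagger, +/-10 bp callset merging;
#' junction genotyping with 20-base flanks, 1 normal read for a germline
#' flag and 2 tumor reads for presence. Simulation conditions default to the
#' study design (53X per subpopulation, 2,000 somatic SNVs, dual
#' endoreduplication).
#'
#' @param seed integer master seed.
#' @param ... named overrides of any top-level section (partial lists are
#'   merged over the defaults).
#' @return A validated configuration list of class `ploidyseq_config`.
#' @export
ploidyseq_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    genome = list(chromosomes = c(chr1 = 25e6, chr2 = 20e6, chr3 = 15e6),
                  gc_window = 20000, repeat_density = 0.02, gap_density = 0.01),
    lineage = list(mode = "dual_endoreduplication", n_snv = 2000,
                   n_indel = 400, n_sv = 60, loss_fraction = 0.30, f_aa = 0.40),
    samples = list(coverage = 53,
                   cell_fractions = c(D = 0.40, H = 0.42, AA = 0.10, AB = 0.08)),
    sim = list(error_rate = 0.002, het_snp_rate = 5e-4, n_bins = 500,
               bin_base_count = 500, gc_bias = 0.3, sv_read_factor = 0.25,
               n_sv_germline = 5, sv_noise = 30),
    thresholds = list(min_depth = 20, min_alt_reads = 5, depth_cap = 2500),
    cnv = list(alpha = 0.01, min_width = 3, span = 0.3,
               gain_thresh = 1.4, loss_thresh = 0.8),
    loh = list(het_bounds = c(0.25, 0.75), window = 1e6, step = 5e5,
               maf_thresh = 0.25),
    sv = list(min_support = 3, min_size = 50, min_mq = 30, min_stagger = 3,
              merge_tol = 10, junction_flank = 20, min_tumor_reads = 2),
    models = list(f_grid = seq(0, 1, by = 0.01), complexity_tol = 1e-3,
                  rescue_threshold = 0.5),
    mixing = list(coverages = c(30, 50, 100), mass_weighted = FALSE)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  validate_config(cfg)
  structure(cfg, class = "ploidyseq_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$thresholds$min_alt_reads <= cfg$thresholds$min_depth,
            cfg$loh$step <= cfg$loh$window,
            all(cfg$mixing$coverages > 0),
            cfg$samples$coverage > 0)
  stopifnot_scalar_prob(cfg$lineage$f_aa, "lineage$f_aa")
  stopifnot_scalar_prob(cfg$lineage$loss_fraction, "lineage$loss_fraction")
  invisible(cfg)
}

#' Read a YAML configuration file
#'
#' @param path YAML file whose top-level keys are config sections.
#' @return A `ploidyseq_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1
  y$seed <- NULL
  # YAML maps come back as lists; coerce the numeric vectors we expect
  if (!is.null(y$genome$chromosomes)) {
    y$genome$chromosomes <- unlist(y$genome$chromosomes)
  }
  if (!is.null(y$samples$cell_fractions)) {
    y$samples$cell_fractions <- unlist(y$samples$cell_fractions)
  }
  if (!is.null(y$mixing$coverages)) y$mixing$coverages <- unlist(y$mixing$coverages)
  do.call(ploidyseq_config, c(list(seed = seed), y))
}

subset_pm <- function(pm, keep) {
  out <- pm[keep, , drop = FALSE]
  structure(out, eligible = attr(pm, "eligible")[keep],
            variant_class = attr(pm, "variant_class")[keep],
            class = class(pm))
}

#' Run the full Ploidy-Seq analysis on a simulated tumor
#'
#' Orchestrates simulate -> genotype -> cnv/loh/sv -> phylo -> doubling-model
#' scoring -> bulk mixing into one reproducible run. Identical configuration
#' and seed give identical reports.
#'
#' @param config a [ploidyseq_config()].
#' @param outdir optional directory; when given, the standard output files
#'   (VCF, BED/BEDPE, SEG-like TSV, Newick trees, JSON summary, config echo)
#'   are written there.
#' @return An object of class `ploidyseq_report`.
#' @export
run_ploidyseq <- function(config = ploidyseq_config(), outdir = NULL) {
  seed <- config$seed
  thr <- ploidyseq_thresholds(config$thresholds$min_depth,
                              config$thresholds$min_alt_reads,
                              config$thresholds$depth_cap)

  ref <- do.call(build_reference, c(config$genome, list(seed = seed)))
  tree <- build_lineage(mode = config$lineage$mode,
                        n_snv = config$lineage$n_snv,
                        n_indel = config$lineage$n_indel,
                        n_sv = config$lineage$n_sv,
                        ref = ref,
                        loss_fraction = config$lineage$loss_fraction,
                        f_aa = config$lineage$f_aa,
                        seed = seed)
  samples <- default_samples(tree, ref, config$samples$coverage,
                             config$samples$cell_fractions)
  sim <- simulate_observations(tree, samples, ref,
                               error_rate = config$sim$error_rate,
                               het_snp_rate = config$sim$het_snp_rate,
                               n_bins = config$sim$n_bins,
                               bin_base_count = config$sim$bin_base_count,
                               gc_bias = config$sim$gc_bias,
                               sv_read_factor = config$sim$sv_read_factor,
                               n_sv_germline = config$sim$n_sv_germline,
                               sv_noise = config$sim$sv_noise,
                               seed = seed)
  labels <- names(tree$clone_mixtures)
  tumors <- setdiff(labels, "D")

  ## genotyping & chronology
  pm <- call_presence(sim$sites, labels, thr)
  som <- filter_somatic(pm, "D")
  chron <- classify_chronology(som)
  vclass <- attr(som, "variant_class")
  venn <- lapply(c(SNV = "SNV", indel = "indel"), function(cl) {
    sel <- vclass == cl
    if (sum(sel) == 0) {
      return(NULL)
    }
    venn_counts(subset_pm(som, sel))
  })
  ancestors <- list(n1 = infer_ancestor(som, tumors),
                    n2 = infer_ancestor(som, c("AA", "AB")))
  snv_sel <- vclass == "SNV"
  spec <- mutation_spectrum(sim$sites[match(rownames(som)[snv_sel], sim$sites$id), ],
                            subset_pm(som, snv_sel))
  afc <- af_by_chronology(chron, sim$sites, som)

  ## copy number
  ratios <- apply(sim$bin_counts, 2, gc_normalize, gc = sim$bins$gc,
                  span = config$cnv$span)
  seg <- lapply(labels, function(s) {
    call_cna_states(ks_segment(ratios[, s], sim$bins$chrom,
                               alpha = config$cnv$alpha,
                               min_width = config$cnv$min_width),
                    config$cnv$gain_thresh, config$cnv$loss_thresh)
  })
  names(seg) <- labels
  seg_ratio <- vapply(labels, function(s) {
    out <- numeric(nrow(sim$bins))
    for (i in seq_len(nrow(seg[[s]]))) {
      out[seg[[s]]$start_bin[i]:seg[[s]]$end_bin[i]] <- seg[[s]]$mean_ratio[i]
    }
    out
  }, numeric(nrow(sim$bins)))
  states <- vapply(tumors, function(s) bin_states(seg[[s]], nrow(sim$bins)),
                   character(nrow(sim$bins)))
  cna_cmp <- compare_cna(states, sim$bins$chrom)

  ## LOH
  het <- select_het_snps(sim$het, tumors, config$loh$het_bounds)
  chrom_lengths <- stats::setNames(ref$chromosomes$length, ref$chromosomes$name)
  blocks <- do.call(rbind, lapply(tumors, function(s) {
    loh_blocks(het, s, chrom_lengths, ref$gaps,
               window = config$loh$window, step = config$loh$step,
               maf_thresh = config$loh$maf_thresh)
  }))
  ab_blocks <- blocks[blocks$sample == "AB", , drop = FALSE]
  other_blocks <- blocks[blocks$sample %in% c("H", "AA"), , drop = FALSE]
  ab_specific <- ab_blocks[vapply(seq_len(nrow(ab_blocks)), function(i) {
    o <- other_blocks[other_blocks$chrom == ab_blocks$chrom[i], , drop = FALSE]
    !any(o$start < ab_blocks$end[i] & ab_blocks$start[i] < o$end)
  }, logical(1)), , drop = FALSE]

  aah_ids <- chron$id[chron$pattern == "H+AA"]
  aah_pos <- sim$sites[match(aah_ids, sim$sites$id), c("chrom", "pos")]
  analyzed <- ref$genome_length - merged_interval_length(ref$gaps)
  rescue <- loh_rescue_test(aah_pos, ab_specific, analyzed,
                            config$models$rescue_threshold)

  ## structural variants
  mp <- dedup_mappings(sim$splits)
  cl <- cluster_breakpoints(mp)
  reps <- representative_breakpoints(cl)
  calls <- filter_sv_calls(reps, ref$repeats,
                           min_support = config$sv$min_support,
                           min_size = config$sv$min_size,
                           min_mq = config$sv$min_mq,
                           min_stagger = config$sv$min_stagger)
  pass <- calls[calls$pass, , drop = FALSE]
  germ <- pass[[paste0("n_", "D")]] >= 1
  sv_pres <- vapply(tumors, function(s) pass[[paste0("n_", s)]] >= config$sv$min_tumor_reads,
                    logical(nrow(pass)))
  if (nrow(pass) == 1) sv_pres <- matrix(sv_pres, nrow = 1, dimnames = list(NULL, tumors))
  sv_somatic <- pass[!germ & rowSums(sv_pres) > 0, , drop = FALSE]
  sv_pres_som <- sv_pres[!germ & rowSums(sv_pres) > 0, , drop = FALSE]
  rownames(sv_pres_som) <- sprintf("sv_call_%03d", seq_len(nrow(sv_pres_som)))
  sv_venn <- if (nrow(sv_pres_som) > 0) venn_counts(
    structure(sv_pres_som, eligible = rep(TRUE, nrow(sv_pres_som)),
              variant_class = rep("SV", nrow(sv_pres_som)),
              class = c("presence_matrix", "matrix"))) else NULL

  ## lineage trees (one per mutation class)
  with_d <- function(m) {
    cbind(D = rep(FALSE, nrow(m)), m)
  }
  trees <- list()
  for (cl_name in c("SNV", "indel")) {
    sel <- vclass == cl_name
    if (sum(sel) >= 1) {
      d <- hamming_matrix(with_d(som[sel, , drop = FALSE]))
      trees[[cl_name]] <- reroot_at(neighbor_joining(d), "D")
    }
  }
  if (nrow(sv_pres_som) >= 1) {
    d <- hamming_matrix(with_d(sv_pres_som))
    trees[["SV"]] <- reroot_at(neighbor_joining(d), "D")
  }
  trees[["CNA"]] <- reroot_at(neighbor_joining(euclidean_matrix(seg_ratio)), "D")

  ## doubling-model comparison on observed class means, restricted to sites
  ## that are copy-neutral in both AA and AB (CNA and chromosome-loss regions
  ## distort the copy-configuration arithmetic the models predict)
  bin_of <- rep(NA_integer_, nrow(sim$sites))
  for (ch in unique(sim$bins$chrom)) {
    b <- which(sim$bins$chrom == ch)
    sel <- which(sim$sites$chrom == ch)
    idx <- findInterval(sim$sites$pos[sel] - 1, sim$bins$start[b])
    ok <- idx >= 1 & sim$sites$pos[sel] - 1 < sim$bins$end[b][pmax(idx, 1)]
    bin_of[sel[ok]] <- b[idx[ok]]
  }
  neutral <- !is.na(bin_of) &
    abs(seg_ratio[pmax(bin_of, 1), "AA"] - 1) <= 0.2 &
    abs(seg_ratio[pmax(bin_of, 1), "AB"] - 1) <= 0.2
  neutral_ids <- sim$sites$id[neutral]
  mean_af_in <- function(ids, s) {
    rows <- sim$sites[match(ids, sim$sites$id), ]
    d <- rows[[paste0("depth_", s)]]
    mean(ifelse(d > 0, rows[[paste0("alt_", s)]] / d, NA), na.rm = TRUE)
  }
  aaab_ids <- intersect(chron$id[chron$pattern == "AA+AB"], neutral_ids)
  observed_af <- data.frame(
    class = "AA-AB", subpop = c("AA", "AB"),
    af = pmin(0.5, c(mean_af_in(aaab_ids, "AA"), mean_af_in(aaab_ids, "AB"))),
    stringsAsFactors = FALSE)
  model_fit <- evaluate_models(observed_af,
                               f_grid = config$models$f_grid,
                               complexity_tol = config$models$complexity_tol)

  ## in-silico bulk mixing
  fr <- config$samples$cell_fractions[tumors]
  ploidies <- vapply(samples[tumors], `[[`, numeric(1), "ploidy")
  efficiency <- lapply(config$mixing$coverages, function(cov) {
    bulk <- mix_observations(sim$sites, fr / sum(fr), cov,
                             mass_weighted = config$mixing$mass_weighted,
                             ploidies = ploidies,
                             seed = child_seed(seed, paste0("mix", cov)))
    det <- detect_in_mixture(bulk, thr)
    detection_efficiency(det, rownames(som), chron)
  })
  names(efficiency) <- paste0(config$mixing$coverages, "X")

  report <- structure(list(
    config = config, ref = ref, tree = tree, samples = samples, sim = sim,
    presence = pm, somatic = som, chronology = chron, venn = venn,
    ancestors = ancestors, spectrum = spec, af_by_class = afc,
    bins = sim$bins, ratios = ratios, segments = seg, seg_ratio = seg_ratio,
    cna_compare = cna_cmp, het = het, loh_blocks = blocks,
    ab_specific_blocks = ab_specific, loh_rescue = rescue,
    sv_calls = calls, sv_somatic = sv_somatic, sv_presence = sv_pres_som,
    sv_venn = sv_venn, trees = trees, observed_af = observed_af,
    model_fit = model_fit, efficiency = efficiency
  ), class = "ploidyseq_report")

  if (!is.null(outdir)) {
    write_report(report, outdir)
  }
  report
}

#' @export
print.ploidyseq_report <- function(x, ...) {
  cat(sprintf("ploidyseq_report (%s mode, seed %d)\n",
              x$config$lineage$mode, x$config$seed))
  cat(sprintf("  somatic variants: %d (%d SNV, %d indel), SV calls: %d\n",
              nrow(x$somatic),
              sum(attr(x$somatic, "variant_class") == "SNV"),
              sum(attr(x$somatic, "variant_class") == "indel"),
              nrow(x$sv_somatic)))
  tab <- table(x$chronology$class)
  cat(sprintf("  chronology: %s\n",
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  LOH blocks: %d (%d AB-specific); rescue: %s\n",
              nrow(x$loh_blocks), nrow(x$ab_specific_blocks),
              x$loh_rescue$verdict))
  cat(sprintf("  preferred doubling model: %s\n", x$model_fit$preferred))
  eff <- vapply(x$efficiency, `[[`, numeric(1), "efficiency")
  cat(sprintf("  bulk detection efficiency: %s\n",
              paste(sprintf("%s %.0f%%", names(eff), 100 * eff), collapse = ", ")))
  invisible(x)
}

#' Write the standard output files of a pipeline run
#'
#' @param report a `ploidyseq_report`.
#' @param outdir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  labels <- names(report$tree$clone_mixtures)
  write_sites_vcf(report$sim$sites, labels,
                  file.path(outdir, "somatic_sites.vcf"), report$ref)
  write_sites_vcf(report$sim$het, labels,
                  file.path(outdir, "germline_het.vcf"), report$ref)
  utils::write.table(report$chronology, file.path(outdir, "chronology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(report$loh_blocks) > 0) {
    write_bed(report$loh_blocks[, c("chrom", "start", "end", "sample", "mean_maf")],
              file.path(outdir, "loh_blocks.bed"))
  }
  seg_rows <- do.call(rbind, lapply(names(report$segments), function(s) {
    sg <- report$segments[[s]]
    data.frame(sample = s, chrom = sg$chrom,
               start = report$bins$start[sg$start_bin],
               end = report$bins$end[sg$end_bin],
               n_bins = sg$n_bins, mean_ratio = sg$mean_ratio,
               state = sg$state, stringsAsFactors = FALSE)
  }))
  utils::write.table(seg_rows, file.path(outdir, "segments.seg"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(report$sv_somatic) > 0) {
    write_bedpe(report$sv_somatic, file.path(outdir, "sv_calls.bedpe"))
  }
  for (nm in names(report$trees)) {
    ape::write.tree(report$trees[[nm]],
                    file.path(outdir, sprintf("tree_%s.nwk", nm)))
  }
  summary <- list(
    seed = report$config$seed,
    mode = report$config$lineage$mode,
    venn = lapply(report$venn, function(v) if (!is.null(v)) as.list(v$regions)),
    sv_venn = if (!is.null(report$sv_venn)) as.list(report$sv_venn$regions),
    chronology_counts = as.list(table(report$chronology$class)),
    loh_rescue = report$loh_rescue[c("overlap", "total", "fraction", "fold", "verdict")],
    preferred_model = report$model_fit$preferred,
    model_residuals = stats::setNames(as.list(report$model_fit$models$rss),
                                      report$model_fit$models$model),
    efficiency = lapply(report$efficiency, function(e) {
      c(list(overall = e$efficiency), as.list(e$by_class))
    })
  )
  jsonlite::write_json(summary, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass_config(report$config), file.path(outdir, "config.yaml"))
  invisible(outdir)
}

unclass_config <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$genome$chromosomes <- as.list(cfg$genome$chromosomes)
  cfg$samples$cell_fractions <- as.list(cfg$samples$cell_fractions)
  cfg
}
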