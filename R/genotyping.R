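#' Detection thresholds for presence/absence genotyping
#'
#' Defaults follow the published calling rules: minimum coverage depth 20 and
#' minimum 5 variant reads in the calling sample, with loci above 2,500 reads
#' down-sampled (here: deterministically capped with proportional scaling of
#' the alt count). `min_base_quality` is informational - base qualities are
#' consumed upstream of this package.
#'
#' @param min_depth minimum capped depth required in every sample for a
#'   variant to be eligible.
#' @param min_alt_reads minimum alt reads for presence in a sample.
#' @param depth_cap maximum depth; deeper observations are capped.
#' @param min_base_quality informational note of the upstream base-quality
#'   floor.
#' @return A list of class `ploidyseq_thresholds`.
#' @export
ploidyseq_thresholds <- function(min_depth = 20, min_alt_reads = 5,
                                 depth_cap = 2500, min_base_quality = 20) {
  if (any(c(min_depth, min_alt_reads, depth_cap) <= 0)) {
    stop("thresholds must be positive")
  }
  if (min_alt_reads > min_depth) {
    stop("min_alt_reads must not exceed min_depth")
  }
  structure(list(min_depth = min_depth, min_alt_reads = min_alt_reads,
                 depth_cap = depth_cap, min_base_quality = min_base_quality),
            class = "ploidyseq_thresholds")
}

#' Call per-sample presence and eligibility of variants
#'
#' Depths above the cap are first down-sampled deterministically (alt reads
#' scaled proportionally, rounded down). A variant is eligible iff its capped
#' depth reaches `min_depth` in every sample (tumor and normal alike); it is
#' present in a sample iff its capped alt count reaches `min_alt_reads`.
#'
#' @param obs observation data.frame with `depth_<label>` and `alt_<label>`
#'   columns and an `id` column.
#' @param sample_labels character vector of sample labels to genotype.
#' @param thresholds a [ploidyseq_thresholds()] object.
#' @return A logical presence matrix (variants x samples, rownames = ids)
#'   of class `presence_matrix` with attributes `eligible` (logical) and
#'   `variant_class`.
#' @export
call_presence <- function(obs, sample_labels,
                          thresholds = ploidyseq_thresholds()) {
  missing_cols <- setdiff(c(paste0("depth_", sample_labels),
                            paste0("alt_", sample_labels)), names(obs))
  if (length(missing_cols) > 0) {
    stop("unknown sample label(s); missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(obs)
  pres <- matrix(FALSE, n, length(sample_labels),
                 dimnames = list(obs$id, sample_labels))
  eligible <- rep(TRUE, n)
  for (lab in sample_labels) {
    depth <- obs[[paste0("depth_", lab)]]
    alt <- obs[[paste0("alt_", lab)]]
    over <- depth > thresholds$depth_cap
    alt[over] <- floor(alt[over] * thresholds$depth_cap / depth[over])
    depth[over] <- thresholds$depth_cap
    if (any(alt > depth | alt < 0, na.rm = TRUE)) {
      stop("malformed observations: alt reads outside [0, depth]")
    }
    eligible <- eligible & depth >= thresholds$min_depth
    pres[, lab] <- alt >= thresholds$min_alt_reads
  }
  structure(pres, eligible = eligible,
            variant_class = obs$class %||% rep(NA_character_, n),
            class = c("presence_matrix", class(pres)))
}

#' Restrict a presence matrix to somatic variants
#'
#' Retains eligible variants that are present in at least one tumor sample
#' and absent from the matched normal; the normal column is dropped. By the
#' default (`"matched"`) rule, normal presence uses the same alt-read
#' threshold as the tumors; the stricter `"any_alt"` mode excludes a variant
#' if the normal shows a single alt read.
#'
#' @param pm a `presence_matrix` from [call_presence()].
#' @param normal_label label of the normal (diploid) sample.
#' @param obs the observation data.frame (required for `"any_alt"`).
#' @param exclusion `"matched"` or `"any_alt"`.
#' @return A `presence_matrix` over the tumor samples only.
#' @export
filter_somatic <- function(pm, normal_label = "D", obs = NULL,
                           exclusion = c("matched", "any_alt")) {
  exclusion <- match.arg(exclusion)
  if (!normal_label %in% colnames(pm)) {
    stop("normal label not in matrix: ", normal_label)
  }
  in_normal <- pm[, normal_label]
  if (exclusion == "any_alt") {
    if (is.null(obs)) stop("obs is required for any_alt exclusion")
    in_normal <- in_normal | obs[[paste0("alt_", normal_label)]] >= 1
  }
  tumor <- setdiff(colnames(pm), normal_label)
  keep <- attr(pm, "eligible") & !in_normal &
    rowSums(pm[, tumor, drop = FALSE]) > 0
  out <- pm[keep, tumor, drop = FALSE]
  structure(out, eligible = attr(pm, "eligible")[keep],
            variant_class = attr(pm, "variant_class")[keep],
            class = class(pm))
}

pattern_string <- function(pm) {
  labs <- colnames(pm)
  apply(pm, 1, function(r) paste(labs[r], collapse = "+"))
}

#' Classify mutational chronology from sharing patterns
#'
#' Early mutations are present in all tumor subpopulations, intermediate
#' mutations are shared by exactly two, late mutations are exclusive to one.
#'
#' @param pm a somatic `presence_matrix` over the tumor samples.
#' @return Data.frame `id`, `pattern` (e.g. `"H+AA"`), `class` in
#'   `{"early","intermediate","late"}`.
#' @export
classify_chronology <- function(pm) {
  k <- rowSums(pm)
  if (any(k == 0)) {
    stop("all-absent rows violate the somatic precondition")
  }
  cls <- c("late", "intermediate", "early")[pmin(k, 3)]
  data.frame(id = rownames(pm), pattern = pattern_string(pm), class = cls,
             stringsAsFactors = FALSE)
}

#' Venn region counts over three tumor samples
#'
#' @param pm a somatic `presence_matrix` with exactly three tumor columns.
#' @return List with `regions` (named counts of the 7 sharing regions),
#'   `total`, `per_sample` (variants present per sample) and `percent`
#'   (per-sample percentage of all somatic variants).
#' @export
venn_counts <- function(pm) {
  if (ncol(pm) != 3) {
    stop("venn_counts requires exactly 3 tumor samples")
  }
  pat <- pattern_string(pm)
  labs <- colnames(pm)
  region_names <- c(labs,
                    paste(labs[1], labs[2], sep = "+"),
                    paste(labs[1], labs[3], sep = "+"),
                    paste(labs[2], labs[3], sep = "+"),
                    paste(labs, collapse = "+"))
  regions <- vapply(region_names, function(r) sum(pat == r), integer(1))
  per_sample <- colSums(pm)
  list(regions = regions, total = nrow(pm), per_sample = per_sample,
       percent = 100 * per_sample / nrow(pm))
}

#' Infer an ancestral mutation set by intersection
#'
#' The ancestral genome of a set of subpopulations carries the mutations
#' present in all of them: `n1 = infer_ancestor(pm, c("H","AA","AB"))`,
#' `n2 = infer_ancestor(pm, c("AA","AB"))`.
#'
#' @param pm a somatic `presence_matrix`.
#' @param subset non-empty character vector of sample labels.
#' @return Character vector of variant ids present in every listed sample.
#' @export
infer_ancestor <- function(pm, subset) {
  if (length(subset) == 0) stop("subset must be non-empty")
  if (!all(subset %in% colnames(pm))) {
    stop("unknown sample label(s): ",
         paste(setdiff(subset, colnames(pm)), collapse = ", "))
  }
  rownames(pm)[rowSums(pm[, subset, drop = FALSE]) == length(subset)]
}

SPECTRUM_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

collapse_substitution <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, comp[ref], ref)
  a <- ifelse(flip, comp[alt], alt)
  paste0(r, ">", a)
}

#' Six-class substitution spectrum per sample
#'
#' Collapses substitutions onto the pyrimidine reference strand (so G>A is
#' counted as C>T) and reports, per sample, the fraction of SNVs in each of
#' the six classes, plus pairwise two-sample Kolmogorov-Smirnov comparisons
#' of the class distributions.
#'
#' @param snvs data.frame with `ref` and `alt` single-base columns.
#' @param pm presence matrix aligned to `snvs` rows (which sample carries
#'   which SNV); `NULL` treats all SNVs as one sample called `"all"`.
#' @return List with `spectrum` (samples x 6 matrix of fractions summing to 1
#'   per row) and `ks` (data.frame of pairwise KS statistics and p-values).
#' @export
mutation_spectrum <- function(snvs, pm = NULL) {
  if (any(nchar(snvs$ref) != 1 | nchar(snvs$alt) != 1)) {
    stop("mutation_spectrum accepts single-base SNVs only")
  }
  cls <- collapse_substitution(snvs$ref, snvs$alt)
  idx <- match(cls, SPECTRUM_CLASSES)
  if (anyNA(idx)) stop("non-substitution records in SNV input")
  groups <- if (is.null(pm)) {
    list(all = idx)
  } else {
    stats::setNames(lapply(colnames(pm), function(s) idx[pm[, s]]), colnames(pm))
  }
  spec <- t(vapply(groups, function(g) {
    tabulate(g, nbins = 6) / max(1, length(g))
  }, numeric(6)))
  colnames(spec) <- SPECTRUM_CLASSES
  ks <- NULL
  labs <- names(groups)
  if (length(labs) >= 2) {
    pairs <- utils::combn(labs, 2)
    ks <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- groups[[pairs[1, j]]]
      b <- groups[[pairs[2, j]]]
      kt <- suppressWarnings(stats::ks.test(a, b))
      data.frame(sample1 = pairs[1, j], sample2 = pairs[2, j],
                 statistic = unname(kt$statistic), p_value = kt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(spectrum = spec, ks = ks)
}

#' Mean allele fraction by chronology class
#'
#' Each variant's allele fraction is alt/depth averaged over the samples in
#' which it is present; class means are compared with Welch two-sample
#' t-tests (early vs intermediate, early vs late). Comparisons involving an
#' empty class are omitted.
#'
#' @param calls chronology calls from [classify_chronology()].
#' @param obs observation data.frame (must contain the called ids).
#' @param pm the somatic `presence_matrix` used for the calls.
#' @return List with `af` (per-variant AF and class), `means` (named class
#'   means) and `tests` (data.frame of Welch t-test results).
#' @export
af_by_chronology <- function(calls, obs, pm) {
  m <- match(calls$id, obs$id)
  if (anyNA(m)) stop("calls reference ids missing from obs")
  af <- vapply(seq_len(nrow(calls)), function(i) {
    row <- obs[m[i], ]
    labs <- colnames(pm)[pm[calls$id[i], ]]
    vals <- vapply(labs, function(s) {
      d <- row[[paste0("depth_", s)]]
      if (d > 0) row[[paste0("alt_", s)]] / d else NA_real_
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  df <- data.frame(id = calls$id, class = calls$class, af = af,
                   stringsAsFactors = FALSE)
  means <- tapply(df$af, factor(df$class, levels = c("early", "intermediate", "late")),
                  mean)
  tests <- NULL
  for (other in c("intermediate", "late")) {
    a <- df$af[df$class == "early"]
    b <- df$af[df$class == other]
    if (length(a) >= 2 && length(b) >= 2) {
      tt <- stats::t.test(a, b)
      tests <- rbind(tests, data.frame(
        comparison = paste0("early_vs_", other),
        estimate = unname(tt$estimate[1] - tt$estimate[2]),
        p_value = tt$p.value, stringsAsFactors = FALSE))
    }
  }
  list(af = df, means = means, tests = tests)
}
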