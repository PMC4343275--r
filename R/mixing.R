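#' Reconstruct bulk-tumor observations by in-silico mixing
#'
#' Combines per-subpopulation site observations into a simulated bulk sample:
#' at each site the bulk depth is Poisson with the target coverage, reads are
#' assigned to source subpopulations multinomially by mixing weight, and alt
#' reads are drawn binomially from each source's observed alt fraction. By
#' default weights follow cell numbers (as cytometric mixing does); with
#' `mass_weighted = TRUE` they are multiplied by sample ploidy to emulate
#' DNA-mass-proportional pooling.
#'
#' @param obs observation data.frame with `depth_<label>`/`alt_<label>`
#'   columns for every source sample (a common site table).
#' @param weights named non-negative mixing weights over the source samples
#'   (normalized internally).
#' @param coverage target mean bulk coverage.
#' @param mass_weighted multiply weights by `ploidies` before normalizing.
#' @param ploidies named ploidies (N units), required if `mass_weighted`.
#' @param seed integer seed.
#' @return The site table with `depth_bulk` and `alt_bulk` columns added
#'   (other columns, e.g. the normal sample's counts, are carried through).
#' @export
mix_observations <- function(obs, weights, coverage, mass_weighted = FALSE,
                             ploidies = NULL, seed = 1) {
  if (coverage <= 0) stop("coverage must be positive")
  if (any(weights < 0)) stop("weights must be >= 0")
  src <- names(weights)
  missing_cols <- setdiff(c(paste0("depth_", src), paste0("alt_", src)),
                          names(obs))
  if (length(missing_cols) > 0) {
    stop("missing source columns: ", paste(missing_cols, collapse = ", "))
  }
  if (mass_weighted) {
    if (is.null(ploidies)) stop("ploidies required for mass weighting")
    weights <- weights * ploidies[src]
  }
  w <- weights / sum(weights)
  af <- vapply(src, function(s) {
    d <- obs[[paste0("depth_", s)]]
    a <- obs[[paste0("alt_", s)]]
    out <- ifelse(d > 0, a / d, 0)
    if (any(d == 0)) {
      warning(sprintf("%d site(s) with zero depth in source %s treated as alt fraction 0",
                      sum(d == 0), s))
    }
    out
  }, numeric(nrow(obs)))
  n_sites <- nrow(obs)
  res <- with_stream(seed, "mixing", {
    depth <- stats::rpois(n_sites, coverage)
    alt <- integer(n_sites)
    for (i in seq_len(n_sites)) {
      if (depth[i] == 0) next
      n_src <- stats::rmultinom(1, depth[i], w)[, 1]
      alt[i] <- sum(stats::rbinom(length(src), n_src, af[i, ]))
    }
    list(depth = depth, alt = alt)
  })
  obs$depth_bulk <- res$depth
  obs$alt_bulk <- res$alt
  obs
}

#' Detect somatic variants in a simulated bulk sample
#'
#' Applies the same presence/eligibility thresholds and matched-normal
#' exclusion used for the subpopulations to the bulk observations.
#'
#' @param bulk output of [mix_observations()] (must retain the normal
#'   sample's `depth_`/`alt_` columns).
#' @param thresholds a [ploidyseq_thresholds()] object.
#' @param normal_label normal sample label.
#' @return Character vector of detected somatic variant ids.
#' @export
detect_in_mixture <- function(bulk, thresholds = ploidyseq_thresholds(),
                              normal_label = "D") {
  pm <- call_presence(bulk, c(normal_label, "bulk"), thresholds)
  som <- filter_somatic(pm, normal_label)
  rownames(som)[som[, "bulk"]]
}

#' Detection efficiency of bulk sequencing
#'
#' Fraction of the subpopulation-resolved somatic mutations recovered in the
#' bulk mixture, optionally stratified by chronology class.
#'
#' @param detected ids detected in the mixture.
#' @param union ids detected across the separately sequenced subpopulations.
#' @param chronology optional chronology calls (data.frame `id`, `class`).
#' @return List `efficiency` and (if chronology given) `by_class`.
#' @export
detection_efficiency <- function(detected, union, chronology = NULL) {
  if (length(union) == 0) stop("empty union of subpopulation detections")
  eff <- length(intersect(detected, union)) / length(union)
  by_class <- NULL
  if (!is.null(chronology)) {
    cl <- chronology[chronology$id %in% union, , drop = FALSE]
    by_class <- vapply(split(cl$id, cl$class), function(ids) {
      length(intersect(detected, ids)) / length(ids)
    }, numeric(1))
  }
  list(efficiency = eff, by_class = by_class)
}
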