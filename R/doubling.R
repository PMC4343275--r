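#' Expected allele fraction of a marker class under a genome-doubling model
#'
#' Closed-form predictions assuming one mutant copy per pre-doubling haploid
#' set (heterozygous origin) and no post-doubling copy drift:
#'
#' * Under `cell_fusion`, AA arises by fusion of a marker-heterozygous cell
#'   with a marker-free cell: AA-AB markers sit on one of four chromosome
#'   copies in AA (exactly 25%, independent of all parameters) and on two of
#'   four in AB (50%, endoreduplication).
#' * Under `dual_endoreduplication`, AA is a mixture of two independently
#'   doubled clones; a marker carried by the clone contributing fraction `f`
#'   of AA is seen at `f/2`.
#' * Under `linear_single_doubling`, a single doubling after divergence from
#'   H: the AA-H marker class is impossible (the single-cell bottleneck).
#'
#' @param model one of `"cell_fusion"`, `"dual_endoreduplication"`,
#'   `"linear_single_doubling"`.
#' @param marker_class one of `"AA-AB"`, `"AA-H"`, `"early"`,
#'   `"private-H"`, `"private-AA"`, `"private-AB"`.
#' @param subpop subpopulation the fraction is predicted for (`"H"`, `"AA"`,
#'   `"AB"`).
#' @param f mixture fraction of the marker-carrying clone within the
#'   subpopulation, where the subpopulation is a clone mixture (dual-model
#'   AA, and H); ignored where the model fixes the prediction.
#' @return Expected allele fraction in `[0, 1]`; classes impossible under
#'   the model return `NA` with attribute `impossible = TRUE`.
#' @examples
#' expected_af("cell_fusion", "AA-AB", "AA")            # 0.25
#' expected_af("dual_endoreduplication", "AA-AB", "AB") # 0.5
#' @export
expected_af <- function(model = c("cell_fusion", "dual_endoreduplication",
                                  "linear_single_doubling"),
                        marker_class, subpop, f = 1) {
  model <- match.arg(model)
  classes <- c("AA-AB", "AA-H", "early", "private-H", "private-AA", "private-AB")
  if (!marker_class %in% classes) {
    stop("unknown marker class: ", marker_class)
  }
  if (!subpop %in% c("H", "AA", "AB")) stop("unknown subpopulation: ", subpop)
  stopifnot_scalar_prob(f, "f")

  impossible <- function() structure(NA_real_, impossible = TRUE)
  pattern <- switch(marker_class,
                    "AA-AB" = c("AA", "AB"),
                    "AA-H" = c("AA", "H"),
                    "early" = c("H", "AA", "AB"),
                    "private-H" = "H",
                    "private-AA" = "AA",
                    "private-AB" = "AB")
  if (!subpop %in% pattern) {
    return(0)   # the class is defined by absence from this subpopulation
  }
  if (model == "linear_single_doubling" && marker_class == "AA-H") {
    return(impossible())
  }
  if (marker_class == "early") {
    return(if (subpop == "H") 0.5 else 0.5)
  }
  if (subpop == "H") {
    # H is (potentially) a clone mixture of diploid clones; carrier fraction f
    return(f * 0.5)
  }
  if (model == "cell_fusion") {
    # AA is one fused clone (4 copies); AB one doubled clone
    return(switch(marker_class,
                  "AA-AB" = if (subpop == "AA") 0.25 else 0.5,
                  "AA-H" = 0.25,                      # partner-derived, 1 of 4
                  "private-AA" = 0.25,                # post-fusion, 1 of 4
                  "private-AB" = 0.25))               # post-doubling, 1 of 4
  }
  if (model == "dual_endoreduplication") {
    return(switch(marker_class,
                  "AA-AB" = if (subpop == "AA") f * 0.5 else 0.5,
                  "AA-H" = f * 0.5,                   # pre-doubling, diluted by mixture
                  "private-AA" = f * 0.25,            # post-doubling, 1 of 4
                  "private-AB" = 0.25))
  }
  # linear single doubling
  switch(marker_class,
         "AA-AB" = 0.5,                               # pre-doubling shared lineage
         "private-AA" = 0.25,
         "private-AB" = 0.25)
}

#' Score genome-doubling models against observed allele frequencies
#'
#' For each model the summed squared discrepancy between observed class-mean
#' allele fractions and the model's predictions is minimized over a grid of
#' the clone-mixture fraction `f` (models whose predictions do not involve
#' `f` have no such freedom). Because the dual-endoreduplication model nests
#' the fusion predictions (f = 0.5 reproduces 0.25/0.50 exactly), the
#' preferred-model verdict applies a parsimony penalty: a model with a free
#' parameter must improve the residual by more than `complexity_tol` over a
#' parameter-free model to be preferred.
#'
#' @param observed data.frame with columns `class` (marker class), `subpop`,
#'   and `af` (observed mean allele fraction, in `[0, 0.5]`).
#' @param models models to score.
#' @param f_grid grid over the mixture fraction `f`.
#' @param complexity_tol residual improvement required per free parameter.
#' @return Object of class `doubling_fit` with per-model residuals, best `f`,
#'   and the preferred model.
#' @examples
#' obs <- data.frame(class = "AA-AB", subpop = c("AA", "AB"), af = c(0.13, 0.32))
#' evaluate_models(obs)
#' @export
evaluate_models <- function(observed,
                            models = c("cell_fusion", "dual_endoreduplication"),
                            f_grid = seq(0, 1, by = 0.01),
                            complexity_tol = 1e-3) {
  if (nrow(observed) == 0) stop("empty observation set")
  if (any(observed$af < 0 | observed$af > 0.5)) {
    stop("observed allele fractions must lie in [0, 0.5]")
  }
  fit_one <- function(model) {
    pred <- function(f) {
      vapply(seq_len(nrow(observed)), function(i) {
        e <- expected_af(model, observed$class[i], observed$subpop[i], f)
        if (is.na(e)) 0 else e   # impossible classes: the model predicts absence
      }, numeric(1))
    }
    rss <- vapply(f_grid, function(f) sum((observed$af - pred(f))^2), numeric(1))
    n_free <- as.integer(max(rss) - min(rss) > .Machine$double.eps^0.5)
    best <- which.min(rss)
    data.frame(model = model, rss = rss[best],
               best_f = if (n_free) f_grid[best] else NA_real_,
               n_free = n_free, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(models, fit_one))
  tab$score <- tab$rss + complexity_tol * tab$n_free
  preferred <- tab$model[which.min(tab$score)]
  structure(list(models = tab, preferred = preferred, observed = observed,
                 complexity_tol = complexity_tol),
            class = "doubling_fit")
}

#' @export
print.doubling_fit <- function(x, ...) {
  cat("Genome-doubling model comparison\n")
  for (i in seq_len(nrow(x$models))) {
    r <- x$models[i, ]
    cat(sprintf("  %-24s residual %.5f%s\n", r$model, r$rss,
                if (!is.na(r$best_f)) sprintf(" (best f = %.2f)", r$best_f) else ""))
  }
  cat(sprintf("Preferred model: %s\n", x$preferred))
  invisible(x)
}

#' @export
summary.doubling_fit <- function(object, ...) {
  cat(sprintf("Observed allele fractions (%d):\n", nrow(object$observed)))
  print(object$observed, row.names = FALSE)
  print(object)
  invisible(object)
}

#' Can late LOH explain the AA-H marker class?
#'
#' Tests the rescue hypothesis that mutations shared by AA and H but absent
#' from AB were lost from the AB lineage by LOH: counts how many such markers
#' fall inside AB-specific LOH blocks and compares the overlap to the chance
#' expectation.
#'
#' @param markers data.frame of AA-H marker positions (`chrom`, `pos`).
#' @param blocks AB-specific LOH blocks (`chrom`, `start`, `end`).
#' @param analyzed_length analyzed (non-gap) genome length in bp.
#' @param threshold minimum explained fraction for the "explained" verdict.
#' @return List `overlap`, `total`, `fraction`, `fold`, `verdict`.
#' @export
loh_rescue_test <- function(markers, blocks, analyzed_length, threshold = 0.5) {
  ov <- snv_loh_overlap(markers, blocks)
  fold <- if (is.null(blocks) || nrow(blocks) == 0 || ov$total == 0) {
    NA_real_
  } else {
    fold_enrichment(ov$overlap, ov$total, blocks, analyzed_length)$fold
  }
  frac <- if (is.na(ov$fraction)) 0 else ov$fraction
  list(overlap = ov$overlap, total = ov$total, fraction = ov$fraction,
       fold = fold,
       verdict = if (frac >= threshold) "LOH can explain the AA-H markers"
       else "LOH cannot explain the AA-H markers")
}
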