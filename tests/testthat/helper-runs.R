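# Pipeline runs are expensive enough to share across test files; each
# (mode, seed) pair is computed once per session.
.run_cache <- new.env(parent = emptyenv())

cached_report <- function(mode = "dual_endoreduplication", seed = 1) {
  key <- paste(mode, seed, sep = "/")
  if (is.null(.run_cache[[key]])) {
    cfg <- ploidyseq_config(seed = seed, lineage = list(mode = mode))
    .run_cache[[key]] <- suppressWarnings(run_ploidyseq(cfg))
  }
  .run_cache[[key]]
}

# Small reference for unit-scale simulations.
small_ref <- function(chroms = c(chr1 = 5e6), seed = 5, ...) {
  build_reference(chroms, gap_density = 0, repeat_density = 0, seed = seed, ...)
}

# Bare observation table builder for genotyping tests.
obs_row <- function(id = "v1", class = "SNV", ...) {
  vals <- list(...)
  df <- data.frame(id = id, class = class, stringsAsFactors = FALSE)
  for (nm in names(vals)) df[[nm]] <- vals[[nm]]
  df
}
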