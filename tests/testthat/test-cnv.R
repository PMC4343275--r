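test_that("variable bins honor mappable weight and chromosome bounds", {
  ref <- build_reference(c(chr1 = 1000), gc_window = 100, repeat_density = 0,
                         gap_density = 0, seed = 1)
  bins <- make_variable_bins(ref, 10)
  expect_equal(nrow(bins), 10)
  expect_equal(bins$end - bins$start, rep(100, 10))
  expect_equal(bins$start[1], 0)
  expect_equal(bins$end[10], 1000)

  # left half unmappable: all bins inside the right half
  ref2 <- ref
  ref2$gaps <- data.frame(chrom = "chr1", start = 0, end = 500,
                          stringsAsFactors = FALSE)
  bins2 <- make_variable_bins(ref2, 10)
  expect_true(all(bins2$start >= 500))
  expect_equal(sum(bins2$mappable), 500)

  # two chromosomes with 3:1 mappable weight: 6 and 2 bins
  ref3 <- build_reference(c(chr1 = 3000, chr2 = 1000), gc_window = 100,
                          repeat_density = 0, gap_density = 0, seed = 1)
  bins3 <- make_variable_bins(ref3, 8)
  expect_equal(as.integer(table(bins3$chrom)[c("chr1", "chr2")]), c(6L, 2L))
  expect_true(all(bins3$start[bins3$chrom == "chr2"] < 1000))

  # fully gapped chromosome: zero bins with a warning
  ref4 <- ref3
  ref4$gaps <- data.frame(chrom = "chr2", start = 0, end = 1000,
                          stringsAsFactors = FALSE)
  expect_warning(bins4 <- make_variable_bins(ref4, 8), "zero mappable")
  expect_false("chr2" %in% bins4$chrom)

  expect_error(make_variable_bins(ref3, 1), "at least")

  # finite-read construction gives equal read counts per bin (+/- 1; exact
  # when the simulated read start positions are distinct)
  ref5 <- build_reference(c(chr1 = 1e5), gc_window = 1000, repeat_density = 0,
                          gap_density = 0, seed = 1)
  bins5 <- make_variable_bins(ref5, 5, n_sim_reads = 1000, seed = 3)
  pos <- ploidyseq:::with_stream(3, "bins/reads",
                                 ploidyseq:::sample_mappable_positions(ref5, 1000))
  reads <- data.frame(chrom = pos$chrom, start = pos$pos - 1)
  counts <- count_in_bins(reads, bins5)
  expect_lte(max(counts) - min(counts), 1)
  expect_equal(sum(counts), 1000)
})

test_that("read counting respects the half-open bin convention", {
  bins <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 200),
                     gc = 0.4, mappable = 100, stringsAsFactors = FALSE)
  reads <- data.frame(chrom = "chr1", start = c(0, 99, 100, 199, 200),
                      stringsAsFactors = FALSE)
  counts <- count_in_bins(reads, bins)
  expect_equal(counts, c(2L, 2L))   # 0,99 in bin 1; 100,199 in bin 2; 200 outside

  # uniform reads over equal bins pass a chi-square goodness-of-fit check
  set.seed(10)
  bins10 <- data.frame(chrom = "chr1", start = seq(0, 900, 100),
                       end = seq(100, 1000, 100), gc = 0.4, mappable = 100)
  r <- data.frame(chrom = "chr1", start = sample.int(1000, 1e4, replace = TRUE) - 1)
  cnt <- count_in_bins(r, bins10)
  expect_equal(sum(cnt), 1e4)
  expect_gt(chisq.test(cnt)$p.value, 0.001)
})

test_that("GC normalization flattens planted bias and preserves flat profiles", {
  set.seed(11)
  gc <- runif(300, 0.3, 0.6)
  flat <- rpois(300, 200)
  r <- gc_normalize(flat, gc)
  expect_equal(median(r), 1)
  expect_lt(mean(abs(r - flat / median(flat))), 0.02)

  # planted unimodal bias: count ~ 1 - 4 (gc - 0.5)^2
  biased <- rpois(300, 400 * (1 - 4 * (gc - 0.5)^2))
  r2 <- gc_normalize(biased, gc)
  expect_lt(abs(cor(gc, r2)), 0.1)
  expect_lt(abs(cor(gc, biased)), 1)   # there was bias to remove
  expect_gt(abs(cor(gc, biased)), 0.3)

  expect_equal(gc_normalize(rep(7, 50), runif(50)), rep(1, 50))
  expect_error(gc_normalize(rep(0, 50), runif(50)), "all-zero")
})

test_that("KS segmentation finds clean steps and matches the brute-force oracle", {
  expect_equal(nrow(ks_segment(rep(1, 40))), 1)

  step <- c(rep(1, 50), rep(2, 50))
  seg <- ks_segment(step)
  expect_equal(seg$end_bin, c(50, 100))
  expect_equal(seg$mean_ratio, c(1, 2))

  # oracle equivalence on noiseless step profiles up to 30 bins
  profiles <- list()
  for (n in c(8, 12, 18, 24, 30)) {
    for (k in unique(c(3, floor(n / 2), n - 4))) {
      if (k >= 3 && n - k >= 3) {
        profiles[[length(profiles) + 1]] <- c(rep(1, k), rep(1.8, n - k))
      }
    }
  }
  # interior events flanked by neutral runs
  profiles[[length(profiles) + 1]] <- c(rep(1, 10), rep(0.5, 6), rep(1, 10))
  profiles[[length(profiles) + 1]] <- c(rep(1, 8), rep(2, 5), rep(1, 8), rep(0.4, 5))
  profiles[[length(profiles) + 1]] <- c(rep(0.5, 12), rep(1, 4), rep(1.6, 12))
  for (x in profiles) {
    got <- ks_segment(x)
    want <- oracle_ks_segment(x)
    expect_equal(cbind(got$start_bin, got$end_bin), unname(want),
                 info = paste(x, collapse = ","))
  }

  # chromosomes are segmented independently
  two <- ks_segment(c(rep(1, 30), rep(2, 30)),
                    chrom = rep(c("a", "b"), each = 30))
  expect_equal(nrow(two), 2)
  expect_equal(two$chrom, c("a", "b"))
})

test_that("segmentation is idempotent and scale invariant", {
  set.seed(12)
  x <- c(rnorm(40, 1, 0.05), rnorm(15, 1.8, 0.05), rnorm(35, 1, 0.05),
         rnorm(20, 0.5, 0.05))
  seg <- ks_segment(x)
  means <- numeric(length(x))
  for (i in seq_len(nrow(seg))) {
    means[seg$start_bin[i]:seg$end_bin[i]] <- seg$mean_ratio[i]
  }
  seg2 <- ks_segment(means)
  expect_equal(seg2$start_bin, seg$start_bin)
  expect_equal(seg2$end_bin, seg$end_bin)

  set.seed(13)
  gc <- runif(110, 0.3, 0.6)
  counts <- rpois(110, c(rep(300, 60), rep(600, 50)))
  r1 <- gc_normalize(counts, gc)
  r2 <- gc_normalize(counts * 17, gc)
  expect_equal(r1, r2, tolerance = 1e-8)
  s1 <- call_cna_states(ks_segment(r1))
  s2 <- call_cna_states(ks_segment(r2))
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("CNA states use the published inclusive ratio thresholds", {
  seg <- data.frame(chrom = "g", start_bin = c(1, 4, 7), end_bin = c(3, 6, 9),
                    n_bins = 3, mean_ratio = c(1.4, 0.8, 1.0))
  st <- call_cna_states(seg)
  expect_equal(st$state, c("gain", "loss", "neutral"))
  st2 <- call_cna_states(transform(seg, mean_ratio = c(1.39, 0.81, 2.5)))
  expect_equal(st2$state, c("neutral", "neutral", "gain"))
  expect_equal(bin_states(st, 9), rep(c("gain", "loss", "neutral"), each = 3))
})

test_that("cross-sample CNA comparison matches events by state and overlap", {
  st <- rep("neutral", 30)
  a <- b <- c <- st
  a[5:10] <- b[6:11] <- c[4:9] <- "gain"    # one shared gain, offset boundaries
  a[20:24] <- "loss"                        # private to one sample
  m <- cbind(H = a, AA = b, AB = c)
  cmp <- compare_cna(m)
  expect_equal(unname(cmp$venn["AA+AB+H"]), 1L)
  expect_equal(unname(cmp$venn["H"]), 1L)
  expect_equal(sum(cmp$venn), 2L)

  ident <- cbind(H = a, AA = a, AB = a)
  cmp2 <- compare_cna(ident)
  expect_true(all(names(cmp2$venn) == "AA+AB+H"))

  expect_error(compare_cna(m, bin_chrom = rep("g", 5)), "mismatch")
})

test_that("planted copy-number events are recovered with their sharing pattern", {
  rep1 <- cached_report()
  bins <- rep1$bins
  ev <- rep1$tree$events
  ev <- ev[ev$type == "cna", ]
  states <- sapply(c("H", "AA", "AB"),
                   function(s) bin_states(rep1$segments[[s]], nrow(bins)))
  pats <- branch_patterns(rep1$tree)
  good <- vapply(seq_len(nrow(ev)), function(i) {
    mid <- (ev$start[i] + ev$end[i]) / 2
    b <- which(bins$chrom == ev$chrom[i] & bins$start <= mid & bins$end > mid)
    expst <- if (ev$delta[i] > 0) "gain" else "loss"
    carriers <- strsplit(pats[[ev$node[i]]], "+", fixed = TRUE)[[1]]
    all(states[b, carriers] == expst) &&
      all(states[b, setdiff(c("H", "AA", "AB"), carriers)] == "neutral")
  }, logical(1))
  expect_gte(mean(good), 0.95)
})
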