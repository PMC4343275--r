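test_that("reference model builds consistent tracks and is deterministic", {
  ref <- build_reference(c(chr1 = 1e7), repeat_density = 0, gap_density = 0,
                         seed = 3)
  expect_equal(nrow(ref$gaps), 0)
  expect_equal(nrow(ref$repeats), 0)
  map <- mappable_regions(ref)
  expect_equal(map$start, 0)
  expect_equal(map$end, 1e7)
  # gc track tiles the chromosome exactly
  expect_equal(ref$gc$start[1], 0)
  expect_equal(max(ref$gc$end), 1e7)
  expect_true(all(ref$gc$gc >= 0.2 & ref$gc$gc <= 0.8))

  expect_identical(build_reference(seed = 7), build_reference(seed = 7))
  expect_false(identical(build_reference(seed = 7), build_reference(seed = 8)))

  expect_error(build_reference(c(a = 1e6, a = 1e6)), "unique")
  expect_error(build_reference(c(chr1 = -5)), "positive")
})

test_that("realized repeat density tracks the requested density", {
  frac <- vapply(1:20, function(sd) {
    ref <- build_reference(c(chr1 = 5e6), repeat_density = 0.1,
                           gap_density = 0, seed = sd)
    sum(ref$repeats$end - ref$repeats$start) / ref$genome_length
  }, numeric(1))
  expect_true(all(abs(frac - 0.1) < 0.02))
  # intervals lie inside the chromosome
  ref <- build_reference(c(chr1 = 5e6), repeat_density = 0.1, seed = 1)
  expect_true(all(ref$repeats$start >= 0 & ref$repeats$end <= 5e6))
})

test_that("lineage modes produce the expected marker-class structure", {
  # all rates zero: structure only
  t0 <- build_lineage("dual_endoreduplication", n_snv = 0, n_indel = 0, n_sv = 0)
  expect_equal(nrow(t0$mutations), 0)
  expect_equal(sum(is.na(t0$nodes$parent)), 1)

  # dual mode: AA&H-only and AA&AB-only marker classes both non-empty
  td <- build_lineage("dual_endoreduplication", n_snv = 900, n_indel = 0,
                      n_sv = 0, seed = 2)
  pat <- branch_patterns(td)[td$mutations$node]
  expect_gt(sum(pat == "H+AA"), 0)
  expect_gt(sum(pat == "AA+AB"), 0)
  expect_gt(sum(pat == "H"), 0)
  expect_gt(sum(pat == "AB"), 0)

  # linear single doubling: the single-cell bottleneck forbids AA&H-only
  tl <- build_lineage("linear", n_snv = 900, n_indel = 0, n_sv = 0, seed = 2)
  patl <- branch_patterns(tl)[tl$mutations$node]
  expect_equal(sum(patl == "H+AA"), 0)
  expect_equal(sum(patl == "H+AB"), 0)

  # fusion of clones with unequal doubling history is rejected
  expect_error(build_lineage("cell_fusion", fusion_parents = c("VIb", "P")),
               "incompatible")
})

test_that("every planted mutation is assigned to exactly one branch", {
  tree <- build_lineage("dual_endoreduplication", n_snv = 500, n_indel = 100,
                        n_sv = 30, seed = 4)
  expect_equal(nrow(tree$mutations), 630)
  expect_equal(anyDuplicated(tree$mutations$id), 0)
  expect_true(all(tree$mutations$node %in% tree$nodes$name))
  # mixtures normalized
  for (mix in tree$clone_mixtures) expect_equal(sum(mix), 1)
})

test_that("copy state follows the doubling, fusion, loss and LOH rules", {
  tree <- build_lineage("dual_endoreduplication", n_snv = 0, n_indel = 0, n_sv = 0)
  germ <- data.frame(chrom = "chr1", pos = 100L, origin = "germline",
                     stringsAsFactors = FALSE)
  expect_equal(copy_state(tree, "normal", germ), list(m = 1L, t = 2L))
  # endoreduplication doubles both mutant and total copies
  expect_equal(copy_state(tree, "VI", germ), list(m = 2L, t = 4L))

  mk <- data.frame(chrom = "chr1", pos = 100L, origin = "IIIv",
                   stringsAsFactors = FALSE)
  expect_equal(copy_state(tree, "VI", mk), list(m = 2L, t = 4L))    # pre-doubling marker
  expect_equal(copy_state(tree, "IV", mk), list(m = 0L, t = 4L))    # other clone
  expect_equal(copy_state(tree, "H_III", mk), list(m = 0L, t = 2L))

  # fusion sums the two parents' copies: one mutant copy of four
  tf <- build_lineage("cell_fusion", n_snv = 0, n_indel = 0, n_sv = 0)
  q <- data.frame(chrom = "chr1", pos = 100L, origin = "Q",
                  stringsAsFactors = FALSE)
  expect_equal(copy_state(tf, "AAf", q), list(m = 1L, t = 4L))
  expect_equal(copy_state(tf, "VIb", q), list(m = 2L, t = 4L))

  # LOH removes the mutant homolog of previously acquired mutations
  tl <- build_lineage("dual_endoreduplication", n_snv = 0, n_indel = 0,
                      n_sv = 0, cna_spec = NULL,
                      loh_spec = data.frame(node = "VI", chrom = "chr1",
                                            start = 0, end = 1e6))
  early <- data.frame(chrom = "chr1", pos = 5e5, origin = "n1",
                      stringsAsFactors = FALSE)
  expect_equal(copy_state(tl, "VI", early), list(m = 0L, t = 4L))
  expect_equal(copy_state(tl, "AA_V", early), list(m = 2L, t = 4L))

  # a copy loss removes the mutant homolog first
  tc <- build_lineage("dual_endoreduplication", n_snv = 0, n_indel = 0,
                      n_sv = 0, loh_spec = NULL,
                      cna_spec = data.frame(node = "H_II", chrom = "chr1",
                                            start = 0, end = 1e6, delta = -1))
  expect_equal(copy_state(tc, "H_II", early), list(m = 0L, t = 1L))
})

test_that("read counts follow the planted binomial/Poisson law", {
  ref <- small_ref(c(chr1 = 8e6))
  tree <- build_lineage("linear", n_snv = 200, n_indel = 0, n_sv = 0,
                        loss_fraction = 0, cna_spec = NULL, loh_spec = NULL,
                        seed = 9)
  samples <- default_samples(tree, ref, coverage = 53)
  sim <- simulate_observations(tree, samples, ref, error_rate = 0,
                               het_snp_rate = 2e-3, n_bins = 50,
                               sv_noise = 0, n_sv_germline = 0, seed = 11)
  het <- sim$het
  expect_gt(nrow(het), 10000)
  # diploid heterozygous sites: mean alt fraction 0.5 within 0.01
  af_d <- het$alt_D / pmax(het$depth_D, 1)
  expect_lt(abs(mean(af_d[het$depth_D > 0]) - 0.5), 0.01)
  # neutral-depth law: mean depth = coverage within 1
  expect_lt(abs(mean(het$depth_D) - 53), 1)

  # tetraploid clone with a marker on one of four copies: alt fraction 0.25
  tf <- build_lineage("cell_fusion", n_snv = 400, n_indel = 0, n_sv = 0,
                      loss_fraction = 0, cna_spec = NULL, loh_spec = NULL,
                      seed = 9)
  sf <- default_samples(tf, ref, coverage = 100)
  simf <- simulate_observations(tf, sf, ref, error_rate = 0,
                                het_snp_rate = 1e-5, n_bins = 50,
                                sv_noise = 0, n_sv_germline = 0, seed = 12)
  aaf <- simf$sites[simf$sites$node == "AAf", ]
  expect_true(all(aaf$af_true_AA == 0.25))
  obs_af <- sum(aaf$alt_AA) / sum(aaf$depth_AA)
  se <- sqrt(0.25 * 0.75 / sum(aaf$depth_AA))
  expect_lt(abs(obs_af - 0.25), 3 * se)
})

test_that("simulation is deterministic and conserves planted truth", {
  ref <- small_ref(c(chr1 = 3e6))
  tree <- build_lineage("dual_endoreduplication", n_snv = 150, n_indel = 30,
                        n_sv = 10, loss_fraction = 0, cna_spec = NULL,
                        loh_spec = NULL, seed = 5)
  samples <- default_samples(tree, ref)
  s1 <- simulate_observations(tree, samples, ref, het_snp_rate = 1e-4, seed = 21)
  s2 <- simulate_observations(tree, samples, ref, het_snp_rate = 1e-4, seed = 21)
  expect_identical(s1, s2)
  s3 <- simulate_observations(tree, samples, ref, het_snp_rate = 1e-4, seed = 22)
  expect_false(identical(s1$sites, s3$sites))

  # every planted mutation appears exactly once with its branch label
  point_ids <- tree$mutations$id[tree$mutations$class != "SV"]
  sv_ids <- tree$mutations$id[tree$mutations$class == "SV"]
  expect_setequal(s1$sites$id, point_ids)
  expect_equal(anyDuplicated(s1$sites$id), 0)
  expect_setequal(s1$sv_truth$id[!s1$sv_truth$germline], sv_ids)
  expect_equal(s1$sites$node,
               tree$mutations$node[match(s1$sites$id, tree$mutations$id)])
})
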