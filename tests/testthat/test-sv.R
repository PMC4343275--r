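mk_mapping <- function(pos1, pos2, type = "DEL", sample = "H",
                       nb1 = pos1 - 100, nb2 = pos2 + 100, mq = 60,
                       chrom1 = "chr1", chrom2 = chrom1,
                       id = sprintf("r%03d", seq_along(pos1))) {
  data.frame(read_id = id, sample = sample, type = type,
             chrom1 = chrom1, pos1 = pos1, strand1 = "+",
             chrom2 = chrom2, pos2 = pos2, strand2 = "-",
             nb_end1 = nb1, nb_end2 = nb2, mq = mq, stringsAsFactors = FALSE)
}

test_that("breakpoint clustering uses +/-1 bp interval overlap and types", {
  m <- mk_mapping(c(1000, 1000, 1000), c(5000, 5000, 5000))
  cl <- cluster_breakpoints(m)
  expect_equal(length(unique(cl$cluster)), 1)
  reps <- representative_breakpoints(cl)
  expect_equal(reps$support, 3L)

  # 2 bp apart: intervals touch, one cluster; 3 bp apart: two clusters
  m2 <- mk_mapping(c(1000, 1002), c(5000, 5000))
  expect_equal(length(unique(cluster_breakpoints(m2)$cluster)), 1)
  m3 <- mk_mapping(c(1000, 1003), c(5000, 5000))
  expect_equal(length(unique(cluster_breakpoints(m3)$cluster)), 2)

  # same coordinates, different predicted type: separate clusters
  m4 <- rbind(mk_mapping(1000, 5000, type = "DEL"),
              mk_mapping(1000, 5000, type = "DUP", id = "r900"))
  expect_equal(length(unique(cluster_breakpoints(m4)$cluster)), 2)

  # per-sample counts are tallied after pooled clustering
  m5 <- rbind(mk_mapping(c(1000, 1001), c(5000, 5000), sample = "AA"),
              mk_mapping(1000, 5001, sample = "D", id = "r800"))
  reps5 <- representative_breakpoints(cluster_breakpoints(m5))
  expect_equal(reps5$n_AA, 2L)
  expect_equal(reps5$n_D, 1L)
})

test_that("cluster representatives maximize all-by-all support with leftmost ties", {
  # 4 reads at X and 1 at X+1: representative X with support 5
  m <- mk_mapping(c(rep(1000, 4), 1001), rep(5000, 5))
  reps <- representative_breakpoints(cluster_breakpoints(m))
  expect_equal(reps$pos1, 1000)
  expect_equal(reps$support, 5L)
  expect_equal(reps$cluster_size, 5L)

  # single mapping is its own representative
  r1 <- representative_breakpoints(cluster_breakpoints(mk_mapping(1000, 5000)))
  expect_equal(r1$support, 1L)

  # exact 2 vs 2 tie at X and X+2: leftmost wins
  m2 <- mk_mapping(c(1000, 1000, 1002, 1002), rep(5000, 4))
  r2 <- representative_breakpoints(cluster_breakpoints(m2))
  expect_equal(r2$pos1, 1000)
})

test_that("clustering is input-order invariant and conserves reads", {
  set.seed(31)
  m <- random_mappings(120, seed = 31)
  cl1 <- cluster_breakpoints(m)
  cl2 <- cluster_breakpoints(m[sample.int(nrow(m)), ])
  expect_equal(canonical_partition(cl1$read_id, cl1$cluster),
               canonical_partition(cl2$read_id, cl2$cluster))
  reps <- representative_breakpoints(cl1)
  expect_equal(sum(reps$cluster_size), nrow(m))
  n_cols <- grep("^n_", names(reps), value = TRUE)
  expect_equal(sum(as.matrix(reps[, n_cols])), nrow(m))
})

test_that("clusters and representatives match the quadratic brute force", {
  for (sd in c(1, 2, 3)) {
    m <- random_mappings(150, seed = sd)
    cl <- cluster_breakpoints(m)
    comp <- oracle_cluster(m)
    expect_equal(canonical_partition(cl$read_id, cl$cluster),
                 canonical_partition(m$read_id, comp))
    reps <- representative_breakpoints(cl)
    want <- oracle_representatives(m, comp)
    got <- reps[order(reps$type, reps$pos1, reps$pos2),
                c("type", "chrom1", "pos1", "chrom2", "pos2", "support")]
    want <- want[order(want$type, want$pos1, want$pos2), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("the five published filters flag calls at their boundaries", {
  base <- mk_mapping(rep(1000, 3), rep(5000, 3),
                     nb1 = c(900, 905, 910), nb2 = c(5100, 5105, 5110))
  calls <- representative_breakpoints(cluster_breakpoints(base))
  f <- filter_sv_calls(calls)
  expect_true(f$pass)

  # support below 3
  two <- representative_breakpoints(cluster_breakpoints(base[1:2, ]))
  expect_true(filter_sv_calls(two)$fail_support)

  # size: 49 bp filtered, 50 bp passes; interchromosomal exempt
  short <- mk_mapping(rep(1000, 3), rep(1049, 3),
                      nb1 = c(900, 905, 910), nb2 = c(1149, 1154, 1159))
  expect_true(filter_sv_calls(representative_breakpoints(cluster_breakpoints(short)))$fail_size)
  ok50 <- mk_mapping(rep(1000, 3), rep(1050, 3),
                     nb1 = c(900, 905, 910), nb2 = c(1150, 1155, 1160))
  expect_false(filter_sv_calls(representative_breakpoints(cluster_breakpoints(ok50)))$fail_size)
  tra <- mk_mapping(rep(1000, 3), rep(1010, 3), chrom2 = "chr2", type = "TRA",
                    nb1 = c(900, 905, 910), nb2 = c(1110, 1115, 1120))
  expect_false(filter_sv_calls(representative_breakpoints(cluster_breakpoints(tra)))$fail_size)

  # mean mapping quality must exceed 30
  mq30 <- mk_mapping(rep(1000, 3), rep(5000, 3), mq = 30,
                     nb1 = c(900, 905, 910), nb2 = c(5100, 5105, 5110))
  expect_true(filter_sv_calls(representative_breakpoints(cluster_breakpoints(mq30)))$fail_mq)

  # identical non-breakpoint ends: unstaggered
  flat <- mk_mapping(rep(1000, 3), rep(5000, 3), nb1 = 900, nb2 = 5100)
  expect_true(filter_sv_calls(representative_breakpoints(cluster_breakpoints(flat)))$fail_stagger)

  # breakpoint inside a simple repeat: >50% of the 3-bp interval overlaps
  repeats <- data.frame(chrom = "chr1", start = 990, end = 1010,
                        class = "simple", stringsAsFactors = FALSE)
  fr <- filter_sv_calls(calls, repeats)
  expect_true(fr$fail_repeat)
  far <- data.frame(chrom = "chr1", start = 1500, end = 1600, class = "simple")
  expect_false(filter_sv_calls(calls, far)$fail_repeat)
})

test_that("callset merging keeps split-read coordinates within +/-10 bp", {
  srm <- data.frame(type = "DEL", chrom1 = "chr1", pos1 = 1000,
                    chrom2 = "chr1", pos2 = 5000, stringsAsFactors = FALSE)
  other <- data.frame(type = c("DEL", "DEL", "INV"), chrom1 = "chr1",
                      pos1 = c(1007, 2000, 1000), chrom2 = "chr1",
                      pos2 = c(4996, 6000, 5000), stringsAsFactors = FALSE)
  merged <- merge_callsets(srm, other)
  # offset (+7, -4): merged, SRM coordinates kept
  expect_equal(sum(merged$source == "SRM+other"), 1)
  expect_equal(merged$pos1[merged$source == "SRM+other"], 1000)
  # different type at identical ends: not merged
  expect_true("INV" %in% merged$type[merged$source == "other"])
  expect_equal(nrow(merged), 3)

  # 11 bp offset: not merged
  off11 <- data.frame(type = "DEL", chrom1 = "chr1", pos1 = 1011,
                      chrom2 = "chr1", pos2 = 5000, stringsAsFactors = FALSE)
  m2 <- merge_callsets(srm, off11)
  expect_equal(sort(m2$source), c("SRM", "other"))
})

test_that("junction genotyping applies the 20-base flank and read-count rules", {
  aln <- function(sample, start, end) {
    data.frame(sample = sample, start = start, end = end,
               stringsAsFactors = FALSE)
  }
  # one D read spanning 25/25: germline
  g <- genotype_junction(aln("D", 76, 125), junction = 100, contig_length = 200)
  expect_true(g$germline)

  # tumor: 1 spanning read absent, 2 present
  one <- genotype_junction(aln("H", c(76), c(125)), 100, 200)
  expect_false(one$present[["H"]])
  two <- genotype_junction(aln("H", c(76, 70), c(125, 130)), 100, 200)
  expect_true(two$present[["H"]])

  # 19 bases on one side does not count
  r19 <- genotype_junction(aln("H", c(82, 82), c(140, 140)), 100, 200)
  expect_false(r19$present[["H"]])
  r20 <- genotype_junction(aln("H", c(81, 81), c(140, 140)), 100, 200)
  expect_true(r20$present[["H"]])

  expect_error(genotype_junction(aln("H", 1, 50), 300, 200), "outside")
})

test_that("duplicate mappings are removed within samples only", {
  a <- mk_mapping(c(1000, 1002, 1000), c(5000, 5001, 5000),
                  nb1 = c(900, 900, 900), nb2 = c(5100, 5100, 5100))
  a$sample <- c("H", "H", "AA")
  dd <- dedup_mappings(a)
  # second H mapping is within 3 bp with identical non-breakpoint ends: dropped;
  # the AA mapping survives (different sample)
  expect_equal(nrow(dd), 2)
  expect_setequal(dd$sample, c("H", "AA"))

  b <- mk_mapping(c(1000, 1004), c(5000, 5000), nb1 = c(900, 900),
                  nb2 = c(5100, 5100))
  expect_equal(nrow(dedup_mappings(b)), 2)   # 4 bp apart: kept

  c2 <- mk_mapping(c(1000, 1001), c(5000, 5000), nb1 = c(900, 905),
                   nb2 = c(5100, 5100))
  expect_equal(nrow(dedup_mappings(c2)), 2)  # staggered ends: kept
})

test_that("planted structural variants with adequate support survive the filters", {
  rep1 <- cached_report()
  truth <- rep1$sim$sv_truth
  calls <- rep1$sv_calls
  pass <- calls[calls$pass, ]
  # pooled deduplicated read support per planted SV (read ids carry the SV id)
  dd <- dedup_mappings(rep1$sim$splits)
  sv_of_read <- sub("_(D|H|AA|AB)_r[0-9]+$", "", dd$read_id)
  support <- table(sv_of_read)
  truth$reads <- as.integer(support[truth$id])
  truth$reads[is.na(truth$reads)] <- 0L
  # repeat-overlapping breakpoints are legitimately filtered: exclude them
  in_repeat <- vapply(seq_len(nrow(truth)), function(i) {
    r <- rep1$ref$repeats
    any(r$chrom == truth$chrom1[i] & r$start < truth$pos1[i] + 1 &
          truth$pos1[i] - 2 < r$end) ||
      any(r$chrom == truth$chrom2[i] & r$start < truth$pos2[i] + 1 &
            truth$pos2[i] - 2 < r$end)
  }, logical(1))
  eligible <- truth$reads >= 3 & !in_repeat
  matched <- vapply(seq_len(nrow(truth)), function(i) {
    any(pass$type == truth$type[i] &
          pass$chrom1 == truth$chrom1[i] & pass$chrom2 == truth$chrom2[i] &
          abs(pass$pos1 - truth$pos1[i]) <= 10 &
          abs(pass$pos2 - truth$pos2[i]) <= 10)
  }, logical(1))
  expect_gt(sum(eligible), 20)
  expect_true(all(matched[eligible]))
  # nothing below the support threshold passes the filters
  expect_equal(sum(calls$support[calls$pass] < 3), 0)
  # per-sample genotyping marks germline SVs by any D read support
  germ <- pass[pass$n_D >= 1, ]
  expect_false(any(rownames(germ) %in% rownames(rep1$sv_presence)))
})
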