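simple_record <- function(qname = "r1", flag = 3L, chrom = "chrT",
                          pos = 1L, mapq = 60L, cigar = "4M",
                          seq = "ACGT", qual = rep(40L, 4L), nh = NA) {
  data.frame(qname = qname, flag = flag, chrom = chrom, pos = pos,
             mapq = mapq, cigar = cigar, rnext = "*", pnext = 0L,
             tlen = 0L, seq = seq, qual = I(list(qual)), nh = nh)
}

test_that("a single clean read is counted at every aligned position", {
  bam <- write_test_bam(simple_record(), c(chrT = 100L))
  pile <- accumulate_pileup(bam)
  expect_equal(pile$pos, 1:4)
  expect_equal(pile$coverage, rep(1L, 4))
  expect_equal(pile[pile$pos == 1, ]$A, 1L)
  expect_equal(pile[pile$pos == 2, ]$C, 1L)
  expect_equal(pile[pile$pos == 3, ]$G, 1L)
  expect_equal(pile[pile$pos == 4, ]$T, 1L)
  expect_equal(pile$mean_quality, rep(40, 4))
})

test_that("low base quality silences a position without touching others", {
  bam <- write_test_bam(simple_record(qual = c(40L, 10L, 40L, 40L)),
                        c(chrT = 100L))
  pile <- accumulate_pileup(bam)
  expect_false(2L %in% pile$pos)  # below min_base_quality 30
  expect_equal(pile$pos, c(1L, 3L, 4L))
})

test_that("read-level filters honor flags, MAPQ, NH and CIGAR ops", {
  recs <- rbind(
    simple_record("ok", 3L),
    simple_record("dup", bitwOr(3L, 1024L)),
    simple_record("sec", bitwOr(3L, 256L)),
    simple_record("multi", 3L, nh = 3L),
    simple_record("lowmapq", 3L, mapq = 30L),
    simple_record("discordant", 1L),
    # insertion consumes query only; deletion consumes reference only
    simple_record("indel", 3L, pos = 10L, cigar = "2M1I1M",
                  seq = "ACGT", qual = rep(40L, 4L)))
  bam <- write_test_bam(recs, c(chrT = 100L))

  pile <- accumulate_pileup(bam)
  expect_equal(pile[pile$pos == 1L, ]$coverage, 1L)  # only "ok"
  # indel read: positions 10,11 get A,C; the I is skipped; 12 gets T
  expect_equal(pile[pile$pos == 10L, ]$A, 1L)
  expect_equal(pile[pile$pos == 11L, ]$C, 1L)
  expect_equal(pile[pile$pos == 12L, ]$T, 1L)
  expect_false(13L %in% pile$pos)

  # relaxing each flag filter readmits the corresponding read
  loose <- filter_config(exclude_duplicates = FALSE,
                         exclude_multimappers = FALSE,
                         require_concordant_pairs = FALSE,
                         min_mapping_quality = 0L)
  pile_loose <- accumulate_pileup(bam, config = loose)
  expect_equal(pile_loose[pile_loose$pos == 1L, ]$coverage, 6L)
})

test_that("overlapping mates contribute once, higher quality wins", {
  recs <- rbind(
    simple_record("frag", bitwOr(3L, 64L), pos = 1L, seq = "ACGT",
                  qual = c(40L, 35L, 40L, 40L)),
    simple_record("frag", bitwOr(3L, 128L), pos = 2L, cigar = "4M",
                  seq = "GGGG", qual = c(39L, 40L, 40L, 40L)))
  bam <- write_test_bam(recs, c(chrT = 100L))
  pile <- accumulate_pileup(bam)
  # pos 2: first mate C@35 vs second mate G@39 -> G wins
  expect_equal(pile[pile$pos == 2L, ]$G, 1L)
  expect_equal(pile[pile$pos == 2L, ]$coverage, 1L)
  # pos 3: first mate G@40 vs second mate G@40 (tie -> first mate); one count
  expect_equal(pile[pile$pos == 3L, ]$G, 1L)
  expect_equal(pile[pile$pos == 3L, ]$coverage, 1L)
  # pos 1 and 5,6: single-mate coverage
  expect_equal(pile[pile$pos == 1L, ]$A, 1L)
  expect_equal(pile[pile$pos == 5L, ]$G, 1L)
})

test_that("pileup equals the brute-force per-read oracle under all flag filters", {
  genome <- tiny_genome(23)
  for (seed in c(101, 202, 303)) {
    recs <- random_records(n_reads = 50L, genome, seed = seed)
    bam <- write_test_bam(recs, setNames(nchar(genome), names(genome)))
    for (dup in c(TRUE, FALSE)) for (multi in c(TRUE, FALSE))
      for (proper in c(TRUE, FALSE)) {
        cfg <- filter_config(exclude_duplicates = dup,
                             exclude_multimappers = multi,
                             require_concordant_pairs = proper)
        got <- as.data.frame(accumulate_pileup(bam, config = cfg))
        want <- oracle_pileup(recs, exclude_dup = dup,
                              exclude_multi = multi,
                              require_proper = proper)
        rownames(want) <- NULL
        expect_equal(got, want, ignore_attr = TRUE,
                     label = sprintf("seed %d dup=%s multi=%s proper=%s",
                                     seed, dup, multi, proper))
      }
  }
})

test_that("coverage conservation and filter monotonicity hold", {
  genome <- tiny_genome(31)
  recs <- random_records(40L, genome, seed = 404)
  bam <- write_test_bam(recs, setNames(nchar(genome), names(genome)))
  base <- accumulate_pileup(bam, config = filter_config(
    min_base_quality = 20L, min_mapping_quality = 0L))
  expect_true(all(base$A + base$C + base$G + base$T == base$coverage))

  stricter <- accumulate_pileup(bam, config = filter_config(
    min_base_quality = 36L, min_mapping_quality = 60L))
  merged <- merge(as.data.frame(base), as.data.frame(stricter),
                  by = c("chrom", "pos"), suffixes = c("_loose", "_strict"))
  expect_true(all(stricter$pos %in% base$pos))
  expect_true(all(merged$coverage_strict <= merged$coverage_loose))

  # determinism: identical input -> identical table
  expect_identical(base, accumulate_pileup(bam, config = filter_config(
    min_base_quality = 20L, min_mapping_quality = 0L)))
})

test_that("variant calling thresholds, ordering and frequency are exact", {
  ref <- c(chrT = "AAAA")
  pile <- data.table::data.table(
    chrom = "chrT", pos = 1:4,
    A = c(8L, 5L, 4L, 0L), C = c(0L, 0L, 1L, 0L),
    G = c(2L, 0L, 3L, 4L), T = c(0L, 0L, 0L, 0L),
    coverage = c(10L, 5L, 8L, 4L), mean_quality = 40)
  calls <- call_sites(pile, ref)
  # pos 2 has no variant reads -> no call
  expect_equal(calls$position, c(1L, 3L, 4L))
  expect_equal(calls[calls$position == 1L, ]$substitutions, "AG")
  expect_equal(calls[calls$position == 1L, ]$frequency, 0.2)
  # descending support order, frequency of the principal substitution
  expect_equal(calls[calls$position == 3L, ]$substitutions, "AG,AC")
  expect_equal(calls[calls$position == 3L, ]$frequency, 3 / 8)
  expect_equal(calls[calls$position == 4L, ]$frequency, 1)

  # min_variant_reads raises the bar
  strict <- call_sites(pile, ref, filter_config(min_variant_reads = 3L))
  expect_equal(strict$position, c(3L, 4L))
  # min_coverage drops shallow positions
  deep <- call_sites(pile, ref, filter_config(min_coverage = 9L))
  expect_equal(deep$position, 1L)

  # ambiguous reference base is skipped
  refN <- c(chrT = "ANAA")
  expect_message(cn <- call_sites(pile[pos != 1], refN), "ambiguous")
  expect_false(2L %in% cn$position)
})

test_that("strand assignment flips substitutions and resolves A-to-I", {
  anno <- GenomicRanges::GRanges(
    c("chrT", "chrT", "chrT", "chrT"),
    IRanges::IRanges(c(1, 20, 40, 40), c(10, 30, 50, 50)),
    strand = c("+", "-", "+", "-"))
  anno$gene <- c("plusG", "minusG", "ampA", "ampB")

  calls <- data.table::data.table(
    chrom = "chrT", position = c(5L, 25L, 45L, 70L),
    strand = "*", ref = c("A", "T", "A", "A"),
    A = c(6L, 0L, 6L, 6L), C = c(0L, 4L, 0L, 0L),
    G = c(4L, 0L, 4L, 4L), T = c(0L, 6L, 0L, 0L),
    coverage = 10L, mean_quality = 40,
    substitutions = c("AG", "TC", "AG", "AG"),
    frequency = 0.4, is_a_to_i = FALSE)
  res <- assign_strand(calls, anno)

  expect_equal(res$strand, c("+", "-", "*", "*"))
  # minus-strand gene: observed T>C reported as A>G, ref complemented
  expect_equal(res[res$position == 25L, ]$substitutions, "AG")
  expect_equal(res[res$position == 25L, ]$ref, "A")
  expect_equal(res$is_a_to_i, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$gene, c("plusG", "minusG", NA, NA))
})
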