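test_that("divergence d spans the identity and saturation extremes", {
  s0 <- make_genome_pair(genome_pair_spec(n_genes = 5L,
                                          tx_length = c(150L, 200L),
                                          divergence = 0, seed = 2L))
  expect_identical(s0$seq_a, s0$seq_b)
  expect_identical(sum(lengths(s0$div_sites)), 0L)

  s1 <- make_genome_pair(genome_pair_spec(n_genes = 5L,
                                          tx_length = c(150L, 200L),
                                          divergence = 1, seed = 2L))
  expect_true(all(unlist(s1$seq_a) != unlist(s1$seq_b)))
})

test_that("divergent-site counts are binomial in the genome size", {
  d <- 0.01
  pair <- make_genome_pair(genome_pair_spec(n_genes = 400L,
                                            tx_length = c(150L, 150L),
                                            divergence = d, seed = 17L))
  n <- sum(pair$genes$contig_length)
  expect_gte(n, 1e5)
  k <- sum(lengths(pair$div_sites))
  expect_lt(abs(k - n * d), 3 * sqrt(n * d * (1 - d)))
  # the site map is exactly the set of differing positions: substitutions
  # never recreate the original base
  for (ctg in pair$genes$contig[1:20]) {
    expect_identical(which(pair$seq_a[[ctg]] != pair$seq_b[[ctg]]),
                     pair$div_sites[[ctg]])
  }
})

test_that("enumeration count follows the closed form across lengths", {
  pair <- make_genome_pair(genome_pair_spec(n_genes = 1L,
                                            tx_length = c(420L, 420L),
                                            divergence = 0, seed = 1L))
  tx <- sssort:::transcript_seq(pair, pair$genes$gene_id[1], "a")
  expect_identical(nrow(enumerate_reads(substr(tx, 1, 200))), 51L)
  expect_identical(nrow(enumerate_reads(substr(tx, 1, 149))), 0L)
  expect_identical(nrow(enumerate_reads(substr(tx, 1, 150))), 1L)
  set.seed(7)
  for (L in sample(140:420, 10)) {
    expect_identical(nrow(enumerate_reads(substr(tx, 1, L))),
                     max(0L, L - 150L + 1L))
  }
  # inner-distance reading widens the span
  expect_identical(nrow(enumerate_reads(substr(tx, 1, 200),
                                        insert_size = 50L,
                                        insert_mode = "inner")), 51L)
})

test_that("every enumerated mate relocates uniquely in its transcript", {
  pair <- make_genome_pair(genome_pair_spec(n_genes = 1L,
                                            tx_length = c(260L, 260L),
                                            divergence = 0, seed = 23L))
  tx <- sssort:::transcript_seq(pair, pair$genes$gene_id[1], "a")
  reads <- enumerate_reads(tx)
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  for (i in seq_len(nrow(reads))) {
    hits1 <- gregexpr(reads$mate1[i], tx, fixed = TRUE)[[1]]
    expect_identical(as.integer(hits1), reads$start[i] + 1L)
    hits2 <- gregexpr(rc(reads$mate2[i]), tx, fixed = TRUE)[[1]]
    expect_identical(as.integer(hits2), reads$start[i] + 101L)
  }
})

test_that("truth alignments carry exact divergence-derived mismatch counts", {
  spec <- genome_pair_spec(n_genes = 10L, tx_length = c(150L, 260L),
                           divergence = 0.03, seed = 29L)
  pair <- make_genome_pair(spec)
  sim <- emit_truth_alignments(pair, store_seq = TRUE)
  expect_true(all(sim$records_a$nm == 0L))
  # independent recount: compare each mate's sequence with the genome-B
  # substring it aligns to
  rb <- sim$records_b
  for (i in seq_len(min(nrow(rb), 200L))) {
    s <- strsplit(rb$seq[i], "")[[1]]
    if (rb$strand[i] == "-") {
      s <- rev(chartr("ACGT", "TGCA", s))
      s <- strsplit(paste(s, collapse = ""), "")[[1]]
    }
    gseq <- pair$seq_b[[rb$rname[i]]][rb$pos[i]:(rb$pos[i] + 49L)]
    expect_identical(rb$nm[i], sum(s != gseq))
  }
  # pair-level divergent coverage in the truth table matches the records
  nm_by_pair <- tapply(rb$nm, rb$qname, sum)
  tr <- sim$truth[match(names(nm_by_pair), sim$truth$qname), ]
  expect_equal(as.integer(nm_by_pair), tr$divergent_covered)
})

test_that("junction-spanning reads get split CIGARs consistent with the annotation", {
  spec <- genome_pair_spec(n_genes = 4L, tx_length = c(300L, 300L),
                           divergence = 0, n_introns = 1L,
                           intron_length = 90L, seed = 31L)
  pair <- make_genome_pair(spec)
  sim <- emit_truth_alignments(pair)
  cig <- sim$records_a$cigar
  expect_true(any(grepl("N", cig)))
  # query length is always the read length
  expect_true(all(GenomicAlignments::cigarWidthAlongQuerySpace(cig) == 50L))
  # junction gap equals the intron length
  gaps <- regmatches(cig, regexpr("(?<=M)[0-9]+(?=N)", cig, perl = TRUE))
  expect_true(all(as.integer(gaps) == 90L))
})

test_that("sequencing errors stress the filter without breaking soundness", {
  spec <- genome_pair_spec(n_genes = 20L, tx_length = c(150L, 220L),
                           divergence = 0.02, seed = 57L)
  pair <- make_genome_pair(spec)
  clean <- emit_truth_alignments(pair)
  set.seed(570)
  noisy <- emit_truth_alignments(pair, error_rate = 0.01, store_seq = TRUE)
  # recount: stored sequences versus the genome the record aligns to
  for (recs in list(a = noisy$records_a, b = noisy$records_b)) {
    gen <- if (identical(recs, noisy$records_a)) pair$seq_a else pair$seq_b
    idx <- sample(nrow(recs), 100L)
    for (i in idx) {
      s <- recs$seq[i]
      if (recs$strand[i] == "-") {
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      }
      g <- gen[[recs$rname[i]]][recs$pos[i]:(recs$pos[i] + 49L)]
      expect_identical(recs$nm[i], sum(strsplit(s, "")[[1L]] != g))
    }
  }
  fit_clean <- filter_sample(clean$records_a, clean$records_b)
  fit_noisy <- filter_sample(noisy$records_a, noisy$records_b)
  # errors can only remove reads from the error-free assigned set
  expect_lte(fit_noisy$stats$assigned_a + fit_noisy$stats$assigned_b,
             fit_clean$stats$assigned_a + fit_clean$stats$assigned_b)
  # the conservative guarantee holds regardless of errors
  verify_assigned_soundness(fit_noisy$assigned_a)
  verify_assigned_soundness(fit_noisy$assigned_b)
})

test_that("generation is deterministic in the seed, including written files", {
  spec <- genome_pair_spec(n_genes = 6L, tx_length = c(150L, 220L),
                           divergence = 0.02, seed = 101L)
  d1 <- tempfile(); d2 <- tempfile()
  write_genome_pair(make_genome_pair(spec), d1)
  write_genome_pair(make_genome_pair(spec), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  other <- make_genome_pair(genome_pair_spec(n_genes = 6L,
                                             tx_length = c(150L, 220L),
                                             divergence = 0.02, seed = 102L))
  expect_false(identical(other$seq_a, make_genome_pair(spec)$seq_a))
})

test_that("written simulator outputs are consumable by the ingestion layer", {
  spec <- genome_pair_spec(n_genes = 8L, tx_length = c(150L, 200L),
                           divergence = 0.05, seed = 41L)
  pair <- make_genome_pair(spec)
  sim <- emit_truth_alignments(pair, store_seq = TRUE)
  sam_a <- tempfile(fileext = ".sam")
  sam_b <- tempfile(fileext = ".sam")
  write_sam(sim$records_a, attr(sim$records_a, "header"), sam_a)
  write_sam(sim$records_b, attr(sim$records_b, "header"), sam_b)
  fit_files <- filter_sample(sam_a, sam_b)
  fit_mem <- filter_sample(sim$records_a, sim$records_b)
  expect_identical(fit_files$stats, fit_mem$stats)
  expect_identical(fit_files$decisions, fit_mem$decisions)
})

test_that("the scenario grid covers every verdict class", {
  grid <- make_scenario_grid()
  expected <- unlist(lapply(grid, function(b) b$truth$expected_verdict))
  expect_gte(length(expected), 800L)
  expect_setequal(unique(expected),
                  c("ASSIGNED_A", "ASSIGNED_B", "REJECTED_MULTIMAP",
                    "REJECTED_AMBIGUOUS", "REJECTED_STRUCTURE",
                    "REJECTED_MISMATCH"))
  # overhang boundary cases present with opposite outcomes
  def <- grid$default$truth
  expect_true(any(def$sa == "junction4" & def$nm_a == 0 & def$nm_b == 0 &
                    def$na == 1 & def$nb == 0 &
                    def$expected_verdict == "REJECTED_STRUCTURE"))
  expect_true(any(def$sa == "junction5" & def$nm_a == 0 & def$nm_b == 0 &
                    def$na == 1 & def$nb == 0 &
                    def$expected_verdict == "ASSIGNED_A"))
})
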