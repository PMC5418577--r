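test_that("gene models carry both length conventions", {
  models <- load_gene_models(write_toy_gtf())
  g <- models$genes
  expect_identical(g$max_transcript_length[g$gene_id == "gA"], 500L)
  expect_identical(g$union_exon_length[g$gene_id == "gA"], 700L)
  expect_identical(g$max_transcript_length[g$gene_id == "gU"], 300L)
  expect_identical(g$union_exon_length[g$gene_id == "gU"], 500L)
  expect_identical(g$union_exon_length[g$gene_id == "gB"], 600L)
})

test_that("union-exon lengths match a per-base mask oracle on random structures", {
  set.seed(21)
  for (rep in 1:10) {
    n_tx <- sample(1:4, 1)
    exons <- do.call(rbind, lapply(seq_len(n_tx), function(t) {
      k <- sample(1:4, 1)
      start <- sort(sample(1:900, k))
      end <- pmin(start + sample(10:120, k, replace = TRUE), 999L)
      data.frame(t = t, start = start, end = end)
    }))
    lines <- sprintf(
      'chrR\ttoy\texon\t%d\t%d\t.\t+\t.\tgene_id "gR"; transcript_id "gR.t%d";',
      exons$start, exons$end, exons$t)
    gtf <- tempfile(fileext = ".gtf")
    writeLines(lines, gtf)
    models <- load_gene_models(gtf)
    mask <- logical(1000)
    for (i in seq_len(nrow(exons))) {
      mask[exons$start[i]:exons$end[i]] <- TRUE
    }
    expect_identical(models$genes$union_exon_length, sum(mask))
    per_tx <- vapply(split(exons, exons$t), function(e) {
      m <- logical(1000)
      for (i in seq_len(nrow(e))) m[e$start[i]:e$end[i]] <- TRUE
      sum(m)
    }, integer(1))
    expect_identical(models$genes$max_transcript_length, max(per_tx))
  }
})

test_that("annotation defects are reported", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttoy\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "chr1\ttoy\texon\t1\t100\t.\t+\t.\tbroken"), gtf)
  expect_error(load_gene_models(gtf), "line 2")

  gtf2 <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttoy\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttoy\ttranscript\t1\t100\t.\t+\t.\tgene_id "g2"; transcript_id "t2";'),
    gtf2)
  expect_warning(load_gene_models(gtf2), "without exons.*t2")
})

test_that("fragments are counted once per unambiguous gene overlap", {
  models <- load_gene_models(write_toy_gtf())
  tab <- rbind(
    aln_pair("p1", pos = 50L),                      # inside gA only
    aln_pair("p2", pos = 150L),                     # overlaps gA t1+t2 (one gene)
    aln_pair("p3", pos = 2100L),                    # inside gB
    aln_pair("p4", pos = 3900L),                    # outside every gene
    # junction pair whose N-gap leaps over gB: gapped bases do not count
    rbind(aln_row("p5", 1L, pos = 1950L, cigar = "25M700N25M"),
          aln_row("p5", 2L, pos = 1900L, strand = "-")))
  tab$rname <- "chr1"
  # one mate in gA, the other in gB -> ambiguous, counted for neither
  amb <- rbind(aln_row("p6", 1L, pos = 201L, cigar = "50M"),
               aln_row("p6", 2L, pos = 2001L, strand = "-"))
  amb$rname <- "chr1"
  tab <- rbind(tab, amb)
  cnt <- count_fragments(tab, models)
  expect_identical(cnt$counts[["gA"]], 2L)   # p1, p2
  expect_identical(cnt$counts[["gB"]], 1L)   # p3
  expect_identical(cnt$n_ambiguous, 1L)      # p6
  expect_identical(cnt$n_no_feature, 2L)     # p4 and the gapped p5
  expect_identical(cnt$n_fragments,
                   cnt$n_counted + cnt$n_ambiguous + cnt$n_no_feature)
})

test_that("counting a reference missing from the annotation warns once", {
  models <- load_gene_models(write_toy_gtf())
  tab <- aln_pair("p1", pos = 10L)
  tab$rname <- "chrZ"
  expect_warning(cnt <- count_fragments(tab, models), "chrZ")
  expect_identical(cnt$n_no_feature, 1L)
})

test_that("simulated reads are counted back to their source genes exactly", {
  spec <- genome_pair_spec(n_genes = 15L, tx_length = c(200L, 320L),
                           divergence = 0.05, n_introns = 1L, seed = 13L)
  pair <- make_genome_pair(spec)
  dir <- tempfile(); paths <- write_genome_pair(pair, dir)
  models <- load_gene_models(paths[["annotation_a"]])
  sim <- emit_truth_alignments(pair)
  cnt <- count_fragments(sim$records_a, models)
  truth_counts <- table(sim$truth$gene_id)
  expect_identical(cnt$counts[names(truth_counts)],
                   stats::setNames(as.integer(truth_counts),
                                   names(truth_counts)))
  expect_identical(cnt$n_ambiguous, 0L)
  expect_identical(cnt$n_no_feature, 0L)
})

test_that("FPKM follows the assigned-fragment denominator convention", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttoy\texon\t1\t2000\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttoy\texon\t5001\t5400\t.\t+\t.\tgene_id "g2"; transcript_id "t2";'),
    gtf)
  models <- load_gene_models(gtf)
  tbl <- compute_fpkm(c(g1 = 10L, g2 = 0L), models, 1e6)
  expect_equal(tbl$fpkm[tbl$gene_id == "g1"], 5.0)
  expect_equal(tbl$fpkm[tbl$gene_id == "g2"], 0)
  # doubling the denominator halves every FPKM
  tbl2 <- compute_fpkm(c(g1 = 10L, g2 = 0L), models, 2e6)
  expect_equal(tbl2$fpkm, tbl$fpkm / 2)
  # duplicating fragments and denominator together leaves FPKM unchanged
  tbl3 <- compute_fpkm(c(g1 = 20L, g2 = 0L), models, 2e6)
  expect_equal(tbl3$fpkm, tbl$fpkm)
  expect_error(compute_fpkm(c(g1 = 10L, g2 = 0L), models, 0),
               "denominator is 0")
  expect_equal(compute_fpkm(c(g1 = 0L, g2 = 0L), models, 0)$fpkm, c(0, 0))
})

test_that("misassignment estimation applies the spurious-fraction rule", {
  ctl <- data.frame(gene_id = c("r1", "r2", "r3"),
                    total = c(500L, 400L, 0L),
                    crosscalled = c(100L, 0L, 0L))
  mixed <- c(m1 = 150, m2 = 80, m3 = 40)
  contam <- c(r1 = 100, r2 = 50, r3 = 10)
  map <- data.frame(primary_id = c("m1", "m2", "m3"),
                    contaminant_id = c("r1", "r2", "r3"))
  rep <- estimate_misassignment(ctl, mixed, contam, map, threshold = 0.10)
  expect_equal(rep$rate, c(0.2, 0, 0))
  expect_equal(rep$spurious_fraction[1], 0.2 * 100 / 150)
  expect_identical(rep$excluded, c(TRUE, FALSE, FALSE))
  # zero mixed count with nonzero estimated spurious reads -> excluded, Inf
  rep2 <- estimate_misassignment(ctl, c(m1 = 0, m2 = 80, m3 = 40),
                                 contam, map)
  expect_true(rep2$excluded[1])
  expect_identical(rep2$spurious_fraction[1], Inf)
  # rate 0 everywhere -> nothing excluded
  ctl0 <- transform(ctl, crosscalled = 0L)
  expect_false(any(estimate_misassignment(ctl0, mixed, contam, map)$excluded))
})

test_that("lowering the exclusion threshold never shrinks the excluded set", {
  set.seed(33)
  n <- 40L
  ctl <- data.frame(gene_id = sprintf("r%02d", 1:n),
                    total = sample(50:500, n),
                    crosscalled = sample(0:50, n, replace = TRUE))
  mixed <- stats::setNames(sample(10:300, n), sprintf("m%02d", 1:n))
  contam <- stats::setNames(sample(0:200, n), ctl$gene_id)
  map <- data.frame(primary_id = names(mixed), contaminant_id = ctl$gene_id)
  prev <- character(0)
  for (th in c(0.5, 0.2, 0.1, 0.05, 0)) {
    ex <- with(estimate_misassignment(ctl, mixed, contam, map, th),
               gene_id[excluded])
    expect_true(all(prev %in% ex))
    prev <- ex
  }
})

test_that("contamination mixing is linear in the contaminant cell fraction", {
  prim <- data.frame(id = c("t1", "t2"), per_cell_count = c(4, 0))
  cont <- data.frame(id = c("t2", "t3"), per_cell_count = c(2, 6))
  # no contaminant cells: output identical to primary
  m0 <- mix_contamination(prim, cont, c(95, 0))
  expect_equal(m0$mixed_count[m0$id == "t1"], 95 * 4)
  expect_equal(m0$mixed_count[m0$id %in% c("t2", "t3")], c(0, 0))
  # contaminant-only transcripts scale with q
  m5 <- mix_contamination(prim, cont, c(95, 5))
  m10 <- mix_contamination(prim, cont, c(90, 10))
  expect_equal(m10$mixed_count[m10$id == "t3"],
               2 * m5$mixed_count[m5$id == "t3"])
  expect_error(mix_contamination(prim, cont, c(0, 0)), "sum to zero")
})

test_that("stochastic mixing agrees with the deterministic expectation", {
  prim <- data.frame(id = sprintf("t%02d", 1:8),
                     per_cell_count = c(5, 2, 0, 8, 1, 0, 3, 4))
  cont <- data.frame(id = sprintf("t%02d", 1:8),
                     per_cell_count = c(0, 1, 6, 2, 0, 9, 1, 2))
  det <- mix_contamination(prim, cont, c(95, 5))
  draws <- sapply(1:200, function(s)
    mix_contamination(prim, cont, c(95, 5), mode = "stochastic",
                      seed = s)$mixed_count)
  mu <- rowMeans(draws)
  se <- apply(draws, 1, stats::sd) / sqrt(ncol(draws))
  expect_true(all(abs(mu - det$mixed_count) <= 3 * pmax(se, 1e-9) +
                    0.5))  # half-unit slack for deterministic rounding
})
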