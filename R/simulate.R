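BASES <- c("A", "C", "G", "T")

#' Specification of a homologous genome pair
#'
#' Describes a pair of synthetic genomes related by independent per-site
#' substitution at rate `divergence`: genome A is sampled uniformly at
#' random; genome B is a copy in which each site is substituted with
#' probability `divergence` (never back to the original base). Each gene
#' lives on its own contig with `flank` intergenic bases on each side and
#' carries one transcript, optionally split by introns. All randomness is
#' fixed by `seed`.
#'
#' @param n_genes number of genes (one transcript each).
#' @param tx_length integer vector of length 2, minimum and maximum spliced
#'   transcript length in nt (sampled uniformly per gene).
#' @param divergence per-site substitution probability d in \[0, 1\].
#' @param n_introns introns inserted per transcript (default 0).
#' @param intron_length intron length in nt.
#' @param flank intergenic flank per contig side in nt.
#' @param seed integer seed fixing all randomness.
#' @return an object of class `genome_pair_spec`.
#' @export
genome_pair_spec <- function(n_genes = 100L, tx_length = c(150L, 300L),
                             divergence = 0.01, n_introns = 0L,
                             intron_length = 90L, flank = 50L, seed = 1L) {
  stopifnot(n_genes >= 1L, length(tx_length) == 2L,
            tx_length[1] <= tx_length[2],
            divergence >= 0, divergence <= 1,
            n_introns >= 0L, intron_length >= 1L, flank >= 0L)
  s <- list(n_genes = as.integer(n_genes),
            tx_length = as.integer(tx_length),
            divergence = divergence,
            n_introns = as.integer(n_introns),
            intron_length = as.integer(intron_length),
            flank = as.integer(flank),
            seed = as.integer(seed))
  class(s) <- "genome_pair_spec"
  s
}

substitute_sites <- function(seq_chars, sites) {
  if (!length(sites)) return(seq_chars)
  idx <- match(seq_chars[sites], BASES)
  off <- sample.int(3L, length(sites), replace = TRUE)
  seq_chars[sites] <- BASES[((idx - 1L + off) %% 4L) + 1L]
  seq_chars
}

# uniform substitution sequencing errors (never the original base)
inject_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(ch)) < rate)
    if (length(hit)) ch <- substitute_sites(ch, hit)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# mismatches of forward-strand read sequences against a genome, over each
# read's genomic blocks
count_mm <- function(seqs, blocks, genome_chars) {
  vapply(seq_along(seqs), function(i) {
    gpos <- unlist(Map(seq.int, blocks[[i]]$g_start, blocks[[i]]$g_end))
    sum(strsplit(seqs[i], "", fixed = TRUE)[[1L]] != genome_chars[gpos])
  }, integer(1))
}

#' Generate a homologous genome pair at controlled divergence
#'
#' Realizes a [genome_pair_spec()]: genome A, genome B (per-site substituted
#' with probability `d`, substitutions never recreating the original base),
#' structurally identical annotations for both, and the map of every
#' divergent site. Per-gene overrides support planting control cases:
#' `gene_divergence` fixes the substitution rate of named genes (e.g. 0 for
#' an identical paralog), and `truncate_b` removes the 3' fraction of named
#' genes' loci from the genome-B assembly -- emulating the incompletely
#' assembled/annotated loci that cause reads of one species to align only to
#' the other genome.
#'
#' @param spec a [genome_pair_spec()].
#' @param gene_divergence optional named numeric vector of per-gene
#'   divergence overrides (names are gene ids `g0001`, ...).
#' @param truncate_b optional named numeric vector in (0, 1\]: fraction of
#'   the gene locus (measured from its 3' end) absent from the genome-B
#'   assembly.
#' @param conserved_tail optional named numeric vector in (0, 1\]: fraction
#'   of the gene locus (from its 3' end) kept free of substitutions, i.e. a
#'   perfectly conserved segment. Combining this with `truncate_b` at the
#'   same fraction reproduces the situation that causes cross-calls in real
#'   data: reads from a conserved region whose locus is missing from one
#'   assembly align cleanly, and exclusively, to the other genome.
#' @return an object of class `genome_pair`: gene table, per-contig A/B
#'   sequences, exon maps, divergent-site positions and retained genome-B
#'   contig lengths.
#' @export
make_genome_pair <- function(spec, gene_divergence = NULL, truncate_b = NULL,
                             conserved_tail = NULL) {
  stopifnot(inherits(spec, "genome_pair_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  wid <- max(4L, nchar(as.character(ng)))
  gene_id <- sprintf("g%0*d", wid, seq_len(ng))
  tx_id <- sprintf("t%0*d", wid, seq_len(ng))
  contig <- sprintf("chr_%s", gene_id)
  tx_len <- if (spec$tx_length[1] == spec$tx_length[2]) {
    rep(spec$tx_length[1], ng)
  } else {
    sample(seq(spec$tx_length[1], spec$tx_length[2]), ng, replace = TRUE)
  }

  # exon structure in transcript coordinates: n_introns+1 pieces of roughly
  # equal size; genomic blocks separated by intron_length
  exon_map <- lapply(seq_len(ng), function(g) {
    L <- tx_len[g]
    k <- spec$n_introns + 1L
    sizes <- rep(L %/% k, k)
    sizes[seq_len(L %% k)] <- sizes[seq_len(L %% k)] + 1L
    tx_end <- cumsum(sizes)
    tx_start <- tx_end - sizes + 1L
    gstart <- spec$flank + tx_start + (seq_len(k) - 1L) * spec$intron_length
    data.frame(tx_start = tx_start, tx_end = tx_end,
               g_start = gstart, g_end = gstart + sizes - 1L)
  })
  span <- vapply(exon_map, function(e) e$g_end[nrow(e)] - spec$flank,
                 integer(1))
  contig_len <- span + 2L * spec$flank

  d_gene <- rep(spec$divergence, ng)
  if (!is.null(gene_divergence)) {
    j <- match(names(gene_divergence), gene_id)
    if (anyNA(j)) stop("unknown gene id in gene_divergence")
    d_gene[j] <- gene_divergence
  }
  retained_b <- contig_len
  if (!is.null(truncate_b)) {
    j <- match(names(truncate_b), gene_id)
    if (anyNA(j)) stop("unknown gene id in truncate_b")
    stopifnot(truncate_b > 0, truncate_b <= 1)
    retained_b[j] <- spec$flank + floor(span[j] * (1 - truncate_b))
  }

  # one draw over the concatenated contigs, then split per contig
  total <- sum(contig_len)
  gof <- rep.int(seq_len(ng), contig_len)
  all_a <- sample(BASES, total, replace = TRUE)
  hit <- stats::runif(total) < d_gene[gof]
  if (!is.null(conserved_tail)) {
    j <- match(names(conserved_tail), gene_id)
    if (anyNA(j)) stop("unknown gene id in conserved_tail")
    stopifnot(conserved_tail > 0, conserved_tail <= 1)
    offset0 <- c(0L, cumsum(contig_len))
    for (k in seq_along(j)) {
      g <- j[k]
      from <- spec$flank + floor(span[g] * (1 - conserved_tail[k])) + 1L
      hit[(offset0[g] + from):offset0[g + 1L]] <- FALSE
    }
  }
  all_b <- substitute_sites(all_a, which(hit))
  offset <- c(0L, cumsum(contig_len))
  gfac <- factor(gof, levels = seq_len(ng))
  seq_a <- split(all_a, gfac)
  seq_b <- split(all_b, gfac)
  div_sites <- lapply(seq_len(ng), function(g) {
    which(hit[(offset[g] + 1L):offset[g + 1L]])
  })
  names(seq_a) <- names(seq_b) <- names(div_sites) <- contig

  pair <- list(spec = spec,
               genes = data.frame(gene_id = gene_id, tx_id = tx_id,
                                  contig = contig, tx_length = tx_len,
                                  span = span, contig_length = contig_len,
                                  retained_b = retained_b,
                                  divergence = d_gene,
                                  stringsAsFactors = FALSE),
               exon_map = stats::setNames(exon_map, gene_id),
               seq_a = seq_a, seq_b = seq_b, div_sites = div_sites)
  class(pair) <- "genome_pair"
  pair
}

#' @export
print.genome_pair <- function(x, ...) {
  cat("<genome_pair> ", nrow(x$genes), " genes, divergence d = ",
      x$spec$divergence, ", ", sum(lengths(x$div_sites)),
      " divergent sites over ", sum(x$genes$contig_length), " nt\n", sep = "")
  invisible(x)
}

# spliced transcript sequence from a genome ("a" or "b"); genome-B RNA uses
# the full (untruncated) substituted sequence -- truncation models the
# assembly, not the organism.
transcript_seq <- function(pair, gene, genome = c("a", "b")) {
  genome <- match.arg(genome)
  g <- match(gene, pair$genes$gene_id)
  e <- pair$exon_map[[gene]]
  s <- if (genome == "a") pair$seq_a[[g]] else pair$seq_b[[g]]
  paste(s[unlist(Map(seq.int, e$g_start, e$g_end))], collapse = "")
}

#' Write a genome pair to FASTA + GTF + site-map files
#'
#' Emits `genome_a.fa` / `genome_b.fa` (60-column wrapped), matching
#' Ensembl-dialect `annotation_a.gtf` / `annotation_b.gtf` (structurally
#' identical annotations), and `divergent_sites.tsv`. Genome B contigs are
#' truncated where the spec planted assembly truncations.
#'
#' @param pair a [make_genome_pair()] result.
#' @param dir output directory (created if needed).
#' @return (invisibly) named vector of the five file paths.
#' @export
write_genome_pair <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa_a <- file.path(dir, "genome_a.fa")
  fa_b <- file.path(dir, "genome_b.fa")
  to_dss <- function(seqs, lens) {
    Biostrings::DNAStringSet(vapply(seq_along(seqs), function(i) {
      paste(seqs[[i]][seq_len(lens[i])], collapse = "")
    }, character(1)))
  }
  da <- to_dss(pair$seq_a, pair$genes$contig_length)
  db <- to_dss(pair$seq_b, pair$genes$retained_b)
  names(da) <- names(db) <- pair$genes$contig
  Biostrings::writeXStringSet(da, fa_a, width = 60L)
  Biostrings::writeXStringSet(db, fa_b, width = 60L)

  gtf <- function(path) {
    rows <- lapply(seq_len(nrow(pair$genes)), function(g) {
      e <- pair$exon_map[[g]]
      gid <- pair$genes$gene_id[g]; tid <- pair$genes$tx_id[g]
      ctg <- pair$genes$contig[g]
      attr_g <- sprintf('gene_id "%s";', gid)
      attr_t <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
      c(sprintf("%s\tsssort\tgene\t%d\t%d\t.\t+\t.\t%s",
                ctg, e$g_start[1], e$g_end[nrow(e)], attr_g),
        sprintf("%s\tsssort\ttranscript\t%d\t%d\t.\t+\t.\t%s",
                ctg, e$g_start[1], e$g_end[nrow(e)], attr_t),
        sprintf("%s\tsssort\texon\t%d\t%d\t.\t+\t.\t%s",
                ctg, e$g_start, e$g_end, attr_t))
    })
    writeLines(unlist(rows), path)
  }
  gtf_a <- file.path(dir, "annotation_a.gtf")
  gtf_b <- file.path(dir, "annotation_b.gtf")
  gtf(gtf_a)
  gtf(gtf_b)

  sites <- file.path(dir, "divergent_sites.tsv")
  n <- lengths(pair$div_sites)
  utils::write.table(
    data.frame(contig = rep(pair$genes$contig, n),
               pos = unlist(pair$div_sites, use.names = FALSE)),
    sites, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genome_a = fa_a, genome_b = fa_b,
              annotation_a = gtf_a, annotation_b = gtf_b,
              divergent_sites = sites))
}

#' Enumerate all theoretical read pairs of a transcript
#'
#' Produces every possible error-free paired-end read obtainable from a
#' transcript: read length 50 nt and insert size (total fragment span, outer
#' distance) 150 nt by default, i.e. one fragment per start offset
#' `0 ... L - 150`, giving `L - 150 + 1` fragments for a transcript of
#' length `L >= 150` and none otherwise. Mate 1 is the forward sequence at
#' the fragment start; mate 2 is the reverse complement of the fragment's
#' last 50 nt (FR orientation). `insert_mode = "inner"` reinterprets
#' `insert_size` as the inner mate distance.
#'
#' @param tx_seq transcript sequence (single character string).
#' @param read_length read length in nt (default 50).
#' @param insert_size fragment span in nt (default 150).
#' @param insert_mode `"outer"` (span, default) or `"inner"` (gap between
#'   mates).
#' @return a `data.frame` with columns `start` (0-based fragment offset),
#'   `mate1`, `mate2`; attributes `read_length`, `insert_size`, `span`.
#' @export
enumerate_reads <- function(tx_seq, read_length = 50L, insert_size = 150L,
                            insert_mode = c("outer", "inner")) {
  insert_mode <- match.arg(insert_mode)
  span <- if (insert_mode == "outer") insert_size else
    2L * read_length + insert_size
  stopifnot(read_length >= 1L, span >= 2L * read_length)
  L <- nchar(tx_seq)
  if (L < span) {
    out <- data.frame(start = integer(0), mate1 = character(0),
                      mate2 = character(0), stringsAsFactors = FALSE)
  } else {
    start <- 0:(L - span)
    mate1 <- substring(tx_seq, start + 1L, start + read_length)
    m2f <- substring(tx_seq, start + span - read_length + 1L, start + span)
    mate2 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(m2f)))
    out <- data.frame(start = start, mate1 = mate1, mate2 = mate2,
                      stringsAsFactors = FALSE)
  }
  attr(out, "read_length") <- as.integer(read_length)
  attr(out, "insert_size") <- as.integer(insert_size)
  attr(out, "span") <- as.integer(span)
  out
}

# map a transcript-coordinate interval [s, e] (1-based) to genomic blocks
# through a gene's exon map; returns data.frame(g_start, g_end)
tx_to_genomic <- function(exon_map, s, e) {
  hit <- exon_map[exon_map$tx_end >= s & exon_map$tx_start <= e, , drop = FALSE]
  data.frame(g_start = hit$g_start + pmax(s - hit$tx_start, 0L),
             g_end = hit$g_end - pmax(hit$tx_end - e, 0L))
}

blocks_to_cigar <- function(blocks) {
  m <- blocks$g_end - blocks$g_start + 1L
  if (nrow(blocks) == 1L) return(paste0(m, "M"))
  gaps <- blocks$g_start[-1L] - blocks$g_end[-nrow(blocks)] - 1L
  paste0(paste0(m[-length(m)], "M", gaps, "N", collapse = ""),
         m[length(m)], "M")
}

#' Emit ground-truth alignments of theoretical reads against both genomes
#'
#' For every enumerated read pair of every (selected) gene, emits its
#' true-locus alignment record against genome A and against genome B:
#' positions and CIGARs follow the annotation (contiguous exon gives `50M`;
#' junction-spanning reads get `aMbNcM`), the mismatch count against the
#' origin genome is 0 and against the other genome equals the number of
#' divergent sites covered by that mate. Where a gene's genome-B locus is
#' truncated, reads extending past the retained assembly have no genome-B
#' alignment. This stands in for an aligner at desk scale, so the decision
#' procedure can be tested against known truth.
#'
#' @param pair a [make_genome_pair()] result.
#' @param read_length,insert_size,insert_mode as in [enumerate_reads()].
#' @param genes optional character vector of gene ids to simulate (default
#'   all).
#' @param origin `"a"` or `"b"`: the genome whose transcripts the reads
#'   derive from (use `"b"` for a single-species control of the contaminant
#'   species).
#' @param store_seq keep mate sequences in the tables (default `FALSE`;
#'   enable when writing SAM meant for re-alignment or sequence checks).
#' @param error_rate per-base substitution sequencing-error probability
#'   (default 0: theoretical reads are error-free). When positive, errors
#'   are injected into the mate sequences (uniformly over the three other
#'   bases, driven by the session RNG -- `set.seed()` first for
#'   reproducibility) and the per-mate mismatch counts against both genomes
#'   are recomputed from the erroneous sequences. Intended for stress
#'   tests; implies sequence materialization.
#' @return list with `records_a` and `records_b` (alignment tables as in
#'   [read_alignments()], headers attached) and `truth` (`data.frame` of
#'   `qname`, `gene_id`, `origin`, `covered_sites` -- distinct genomic sites
#'   covered by the pair -- and `divergent_covered`).
#' @export
emit_truth_alignments <- function(pair, read_length = 50L, insert_size = 150L,
                                  insert_mode = c("outer", "inner"),
                                  genes = NULL, origin = c("a", "b"),
                                  store_seq = FALSE, error_rate = 0) {
  insert_mode <- match.arg(insert_mode)
  origin <- match.arg(origin)
  if (is.null(genes)) genes <- pair$genes$gene_id
  gsel <- match(genes, pair$genes$gene_id)
  if (anyNA(gsel)) stop("unknown gene id")

  span <- if (insert_mode == "outer") insert_size else
    2L * read_length + insert_size
  acc <- list()
  stopifnot(error_rate >= 0, error_rate < 1)
  with_seq <- store_seq || error_rate > 0
  for (g in gsel) {
    gid <- pair$genes$gene_id[g]
    emap <- pair$exon_map[[gid]]
    if (with_seq) {
      tx <- transcript_seq(pair, gid, origin)
      reads <- enumerate_reads(tx, read_length, insert_size, insert_mode)
    } else {
      # geometry only; sequences are not materialized
      L <- pair$genes$tx_length[g]
      reads <- data.frame(start = if (L >= span) 0:(L - span) else integer(0))
    }
    if (!nrow(reads)) next
    qname <- sprintf("%s_f%06d", gid, reads$start + 1L)

    ind <- integer(pair$genes$contig_length[g])
    ind[pair$div_sites[[g]]] <- 1L
    cs0 <- c(0L, cumsum(ind))

    if (nrow(emap) == 1L && error_rate == 0) {
      # intronless fast path: one block per mate, contiguous CIGAR
      g0 <- emap$g_start[1L]
      s1 <- g0 + reads$start
      s2 <- s1 + span - read_length
      e1 <- s1 + read_length - 1L
      e2 <- s2 + read_length - 1L
      cig <- paste0(read_length, "M")
      cig1 <- rep(cig, nrow(reads)); cig2 <- cig1
      pos1 <- s1; pos2 <- s2
      nd1 <- cs0[e1 + 1L] - cs0[s1]
      nd2 <- cs0[e2 + 1L] - cs0[s2]
      end_max <- e2
    } else {
      # per-mate genomic blocks through the exon map (transcript
      # coordinates are shared by both genomes)
      b1 <- lapply(reads$start, function(s)
        tx_to_genomic(emap, s + 1L, s + read_length))
      b2 <- lapply(reads$start, function(s)
        tx_to_genomic(emap, s + span - read_length + 1L, s + span))
      cig1 <- vapply(b1, blocks_to_cigar, character(1))
      cig2 <- vapply(b2, blocks_to_cigar, character(1))
      pos1 <- vapply(b1, function(x) x$g_start[1L], integer(1))
      pos2 <- vapply(b2, function(x) x$g_start[1L], integer(1))
      nd <- function(blocks) {
        vapply(blocks, function(x)
          sum(cs0[x$g_end + 1L] - cs0[x$g_start]), integer(1))
      }
      nd1 <- nd(b1); nd2 <- nd(b2)
      end_max <- pmax(vapply(b1, function(x) x$g_end[nrow(x)], integer(1)),
                      vapply(b2, function(x) x$g_end[nrow(x)], integer(1)))
    }
    in_b <- end_max <= pair$genes$retained_b[g]

    if (error_rate > 0) {
      # inject seeded substitution errors on the forward strand, then
      # recount each mate's mismatches against both genomes from sequence
      m1f <- inject_errors(reads$mate1, error_rate)
      m2f <- inject_errors(as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads$mate2))), error_rate)
      nmA1 <- count_mm(m1f, b1, pair$seq_a[[g]])
      nmA2 <- count_mm(m2f, b2, pair$seq_a[[g]])
      nmB1 <- count_mm(m1f, b1, pair$seq_b[[g]])
      nmB2 <- count_mm(m2f, b2, pair$seq_b[[g]])
      reads$mate1 <- m1f
      reads$mate2 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(m2f)))
    } else {
      zero <- integer(length(qname))
      if (origin == "a") {
        nmA1 <- zero; nmA2 <- zero; nmB1 <- nd1; nmB2 <- nd2
      } else {
        nmA1 <- nd1; nmA2 <- nd2; nmB1 <- zero; nmB2 <- zero
      }
    }
    acc[[gid]] <- list(gid = gid, ctg = pair$genes$contig[g], qname = qname,
                       pos1 = pos1, pos2 = pos2, cig1 = cig1, cig2 = cig2,
                       nd1 = nd1, nd2 = nd2, in_b = in_b,
                       nmA1 = nmA1, nmA2 = nmA2, nmB1 = nmB1, nmB2 = nmB2,
                       m1 = if (store_seq) reads$mate1 else NULL,
                       m2 = if (store_seq) reads$mate2 else NULL)
  }

  if (!length(acc)) {
    empty_truth <- data.frame(qname = character(0), gene_id = character(0),
                              origin = character(0),
                              covered_sites = integer(0),
                              divergent_covered = integer(0),
                              aligned_b = logical(0), stringsAsFactors = FALSE)
    ra <- emit_empty_table(); rb <- emit_empty_table()
    attr(ra, "header") <- list(
      targets = stats::setNames(pair$genes$contig_length, pair$genes$contig),
      text = NULL)
    attr(rb, "header") <- list(
      targets = stats::setNames(pair$genes$retained_b, pair$genes$contig),
      text = NULL)
    return(list(records_a = ra, records_b = rb, truth = empty_truth))
  }

  cat_f <- function(f) unlist(lapply(acc, f), use.names = FALSE)
  qn <- cat_f(function(x) x$qname)
  ctg <- cat_f(function(x) rep(x$ctg, length(x$qname)))
  pos1 <- cat_f(function(x) x$pos1); pos2 <- cat_f(function(x) x$pos2)
  cig1 <- cat_f(function(x) x$cig1); cig2 <- cat_f(function(x) x$cig2)
  nd1 <- cat_f(function(x) x$nd1); nd2 <- cat_f(function(x) x$nd2)
  in_b <- cat_f(function(x) x$in_b)
  gid_all <- cat_f(function(x) rep(x$gid, length(x$qname)))
  m1 <- if (store_seq) cat_f(function(x) x$m1) else NULL
  m2 <- if (store_seq) cat_f(function(x) x$m2) else NULL

  mk <- function(nm1, nm2, keep) {
    n <- sum(keep)
    if (!n) return(emit_empty_table())
    data.frame(
      qname = rep(qn[keep], each = 2L),
      flag = rep(c(99L, 147L), n),
      mate = rep(c(1L, 2L), n),
      rname = rep(ctg[keep], each = 2L),
      pos = c(rbind(pos1[keep], pos2[keep])),
      strand = rep(c("+", "-"), n),
      cigar = c(rbind(cig1[keep], cig2[keep])),
      nm = c(rbind(nm1[keep], nm2[keep])),
      mapped = TRUE, paired = TRUE, primary = TRUE, hi = 1L,
      seq = if (store_seq) c(rbind(m1[keep], m2[keep])) else NA_character_,
      stringsAsFactors = FALSE)
  }
  ra <- mk(cat_f(function(x) x$nmA1), cat_f(function(x) x$nmA2),
           rep(TRUE, length(qn)))
  rb <- mk(cat_f(function(x) x$nmB1), cat_f(function(x) x$nmB2), in_b)
  truth <- data.frame(
    qname = qn, gene_id = gid_all, origin = toupper(origin),
    covered_sites = 2L * read_length,
    divergent_covered = nd1 + nd2,
    aligned_b = in_b,
    stringsAsFactors = FALSE)
  hdr_a <- list(targets = stats::setNames(pair$genes$contig_length,
                                          pair$genes$contig), text = NULL)
  hdr_b <- list(targets = stats::setNames(pair$genes$retained_b,
                                          pair$genes$contig), text = NULL)
  attr(ra, "header") <- hdr_a
  attr(rb, "header") <- hdr_b
  list(records_a = ra, records_b = rb, truth = truth)
}

emit_empty_table <- function() {
  data.frame(qname = character(0), flag = integer(0), mate = integer(0),
             rname = character(0), pos = integer(0), strand = character(0),
             cigar = character(0), nm = integer(0), mapped = logical(0),
             paired = logical(0), primary = logical(0), hi = integer(0),
             seq = character(0), stringsAsFactors = FALSE)
}

#' Write an alignment table as a SAM file
#'
#' Plain-text SAM emission for simulator outputs and fixtures: `@HD`/`@SQ`
#' header from the given reference dictionary, one line per record.
#'
#' @param records an alignment table.
#' @param header list with `targets` (named reference lengths) or a named
#'   integer vector.
#' @param file output path.
#' @return (invisibly) the path.
#' @export
write_sam <- function(records, header, file) {
  if (is.numeric(header)) header <- list(targets = header, text = NULL)
  lines <- c("@HD\tVN:1.6\tSO:queryname",
             paste0("@SQ\tSN:", names(header$targets),
                    "\tLN:", as.integer(header$targets)))
  if (nrow(records)) {
    r <- records
    seq_out <- if ("seq" %in% names(r))
      ifelse(is.na(r$seq) | r$seq == "", "*", r$seq) else "*"
    # mate bookkeeping assumes records of one pair are adjacent (mate 1, 2)
    is_pe <- r$paired
    rnext <- ifelse(is_pe, "=", "*")
    pnext <- ifelse(is_pe, ifelse(r$mate == 1L, c(r$pos[-1L], 0L),
                                  c(0L, r$pos[-nrow(r)])), 0L)
    lines <- c(lines, paste(r$qname, r$flag, r$rname, r$pos, 255L, r$cigar,
                            rnext, pnext, 0L, seq_out, "*",
                            paste0("NM:i:", r$nm), sep = "\t"))
  }
  writeLines(lines, file)
  invisible(file)
}

#' Deterministic scenario grid spanning the decision tree
#'
#' Builds fixture alignment-table pairs that cover the whole decision space:
#' exclusive mapping to either genome, multimapping on either or both sides,
#' mismatch ties and strict orderings 0-2, clipped versus full-length
#' alignments, splice junctions with overhangs 3-6, half-mapped mates, and
#' parameter variants (junction overhang threshold, relaxed final mismatch
#' cap, strict branch ordering). Every scenario carries the verdict expected
#' by construction in a sidecar truth table.
#'
#' @return list of blocks; each block is a list with `params`
#'   ([filter_params]), `records_a`, `records_b` (alignment tables sharing a
#'   toy reference), and `truth` (`data.frame` of `qname`,
#'   `expected_verdict`, scenario descriptors). Total scenarios across
#'   blocks: about a thousand.
#' @export
make_scenario_grid <- function() {
  structure_variants_a <- c("clean", "clipped", "junction3", "junction4",
                            "junction5", "junction6")
  structure_variants_b <- c("clean", "clipped")

  base <- expand.grid(na = 0:2, nb = 0:2, nm_a = 0:2, nm_b = 0:2,
                      sa = structure_variants_a, sb = structure_variants_b,
                      stringsAsFactors = FALSE)
  base <- base[!(base$na == 0L & base$nb == 0L), ]
  base$variant <- "default"

  extra <- rbind(
    data.frame(na = 1L, nb = 1L, nm_a = 0:2, nm_b = 0L,
               sa = "clean", sb = "clean", variant = "lenient_mm"),
    data.frame(na = 1L, nb = 1L, nm_a = 0L, nm_b = 0L,
               sa = structure_variants_a, sb = "clipped",
               variant = "overhang4"),
    expand.grid(na = 0:2, nb = 0:2, nm_a = 0L, nm_b = 0L,
                sa = "clean", sb = "clean", variant = "strict_order",
                stringsAsFactors = FALSE)
  )
  extra <- extra[!(extra$na == 0L & extra$nb == 0L), ]
  grid <- rbind(base, extra)

  params_of <- list(
    default = filter_params(),
    lenient_mm = filter_params(max_final_mismatches = 1L),
    overhang4 = filter_params(min_junction_overhang = 4L),
    strict_order = filter_params(strict_paper_order = TRUE))

  cigar_of <- function(variant) {
    switch(variant,
           clean = c("50M", "50M"),
           clipped = c("45M5S", "50M"),
           junction3 = c("3M100N47M", "50M"),
           junction4 = c("4M100N46M", "50M"),
           junction5 = c("5M100N45M", "50M"),
           junction6 = c("6M100N44M", "50M"))
  }
  str_ok_of <- function(variant, min_overhang) {
    switch(variant,
           clean = TRUE,
           clipped = FALSE,
           junction3 = 3L >= min_overhang,
           junction4 = 4L >= min_overhang,
           junction5 = 5L >= min_overhang,
           junction6 = 6L >= min_overhang)
  }

  # expected verdict, by construction (straight-line restatement of the
  # sorting rules over scenario descriptors)
  expected_of <- function(sc, p) {
    str_a <- str_ok_of(sc$sa, p$min_junction_overhang)
    str_b <- str_ok_of(sc$sb, p$min_junction_overhang)
    finalize <- function(side, n, nm, str) {
      if (!p$strict_paper_order && n > p$max_hits_per_genome)
        return("REJECTED_MULTIMAP")
      if (nm > p$max_final_mismatches) return("REJECTED_MISMATCH")
      if (!str) return("REJECTED_STRUCTURE")
      paste0("ASSIGNED_", side)
    }
    if (sc$na > 0L && sc$nb == 0L)
      return(finalize("A", sc$na, sc$nm_a, str_a))
    if (sc$nb > 0L && sc$na == 0L)
      return(finalize("B", sc$nb, sc$nm_b, str_b))
    if (sc$na > p$max_hits_per_genome || sc$nb > p$max_hits_per_genome)
      return("REJECTED_MULTIMAP")
    if (sc$nm_a < sc$nm_b) return(finalize("A", sc$na, sc$nm_a, str_a))
    if (sc$nm_b < sc$nm_a) return(finalize("B", sc$nb, sc$nm_b, str_b))
    if (str_a && !str_b) return(finalize("A", sc$na, sc$nm_a, str_a))
    if (str_b && !str_a) return(finalize("B", sc$nb, sc$nm_b, str_b))
    if (str_a && str_b) return("REJECTED_AMBIGUOUS")
    "REJECTED_STRUCTURE"
  }

  ref_len <- c(ref = 100000L)
  mk_side <- function(qname, n, nm, variant) {
    if (n == 0L) return(NULL)
    cig <- cigar_of(variant)
    do.call(rbind, lapply(seq_len(n), function(h) {
      data.frame(qname = qname,
                 flag = c(99L, 147L) + if (h > 1L) 256L else 0L,
                 mate = c(1L, 2L), rname = "ref",
                 pos = c(1000L, 1200L) + 500L * (h - 1L),
                 strand = c("+", "-"),
                 cigar = cig, nm = c(nm, 0L),
                 mapped = TRUE, paired = TRUE,
                 primary = h == 1L, hi = h, seq = NA_character_,
                 stringsAsFactors = FALSE)
    }))
  }

  blocks <- lapply(names(params_of), function(v) {
    sub <- grid[grid$variant == v, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    qn <- sprintf("sc%05d", seq_len(nrow(sub)))
    recs_a <- list(); recs_b <- list(); expd <- character(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      sc <- sub[i, ]
      recs_a[[i]] <- mk_side(qn[i], sc$na, sc$nm_a, sc$sa)
      recs_b[[i]] <- mk_side(qn[i], sc$nb, sc$nm_b, sc$sb)
      expd[i] <- expected_of(sc, params_of[[v]])
    }
    ra <- do.call(rbind, recs_a); rb <- do.call(rbind, recs_b)
    if (is.null(ra)) ra <- emit_empty_table()
    if (is.null(rb)) rb <- emit_empty_table()
    attr(ra, "header") <- list(targets = ref_len, text = NULL)
    attr(rb, "header") <- list(targets = ref_len, text = NULL)
    list(params = params_of[[v]], records_a = ra, records_b = rb,
         truth = cbind(data.frame(qname = qn,
                                  expected_verdict = expd,
                                  stringsAsFactors = FALSE),
                       sub[, c("na", "nb", "nm_a", "nm_b", "sa", "sb")],
                       row.names = NULL))
  })
  names(blocks) <- names(params_of)

  # half-mapped scenarios: one mate mapped to a genome counts as no
  # alignment to that genome
  hm_q <- sprintf("hm%05d", 1:3)
  one_mate <- function(qname, nm = 0L) {
    data.frame(qname = qname, flag = 99L + 8L, mate = 1L, rname = "ref",
               pos = 1000L, strand = "+", cigar = "50M", nm = nm,
               mapped = TRUE, paired = TRUE, primary = TRUE, hi = 1L,
               seq = NA_character_, stringsAsFactors = FALSE)
  }
  full_pair <- function(qname, nm = 0L) mk_side(qname, 1L, nm, "clean")
  hm_a <- rbind(full_pair(hm_q[1]),          # full pair vs A ...
                one_mate(hm_q[2]),           # half vs A, full vs B
                full_pair(hm_q[3]))          # full vs A, half vs B
  hm_b <- rbind(one_mate(hm_q[1]),           # ... half vs B -> exclusive A
                full_pair(hm_q[2]),
                one_mate(hm_q[3], nm = 0L))
  hm_a <- hm_a[order(hm_a$qname), ]; hm_b <- hm_b[order(hm_b$qname), ]
  attr(hm_a, "header") <- list(targets = ref_len, text = NULL)
  attr(hm_b, "header") <- list(targets = ref_len, text = NULL)
  blocks$half_mapped <- list(
    params = filter_params(), records_a = hm_a, records_b = hm_b,
    truth = data.frame(qname = hm_q,
                       expected_verdict = c("ASSIGNED_A", "ASSIGNED_B",
                                            "ASSIGNED_A"),
                       na = c(1L, 0L, 1L), nb = c(0L, 1L, 0L),
                       nm_a = 0L, nm_b = 0L, sa = "clean", sb = "clean",
                       stringsAsFactors = FALSE))
  blocks
}
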