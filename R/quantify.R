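#' Load gene models from a GTF annotation
#'
#' Parses an Ensembl-dialect GTF and computes, per gene, the two length
#' conventions used downstream: the *maximum transcript length* (largest sum
#' of exon widths over the gene's transcripts; the FPKM length term) and the
#' *union-exon length* (number of nucleotides in the union of all exons of
#' all transcripts, including UTRs; reported for transparency). Transcripts
#' without exons are skipped with a warning; a malformed attribute block is a
#' hard error naming the line.
#'
#' @param gtf path to a GTF file with `gene_id`/`transcript_id` attributes
#'   and `exon` features.
#' @return an object of class `gene_models`: list with `genes` (`data.frame`
#'   of `gene_id`, `max_transcript_length`, `union_exon_length`),
#'   `exons_by_gene` (reduced `GRangesList` keyed by gene) and
#'   `exons_by_tx`.
#' @export
load_gene_models <- function(gtf) {
  if (!file.exists(gtf)) stop("annotation not found: ", gtf)
  raw <- readLines(gtf)
  body <- which(!startsWith(raw, "#") & nzchar(raw))
  bad <- body[!grepl("gene_id", raw[body])]
  if (length(bad)) {
    stop("malformed attribute block (no gene_id) at line ", bad[1L],
         " of ", gtf)
  }
  gr <- rtracklayer::import(gtf, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("no exon features in ", gtf)
  if (anyNA(ex$transcript_id) || anyNA(ex$gene_id)) {
    stop("exon feature without gene_id/transcript_id in ", gtf)
  }

  tx_feats <- unique(gr$transcript_id[gr$type == "transcript"])
  tx_feats <- tx_feats[!is.na(tx_feats)]
  exonless <- setdiff(tx_feats, unique(ex$transcript_id))
  if (length(exonless)) {
    warning("skipping transcript(s) without exons: ",
            paste(exonless, collapse = ", "))
  }

  exons_by_tx <- GenomicRanges::reduce(
    S4Vectors::split(ex, ex$transcript_id))
  tx_len <- sum(IRanges::width(exons_by_tx))
  tx2gene <- ex$gene_id[match(names(exons_by_tx), ex$transcript_id)]
  max_len <- tapply(tx_len, tx2gene, max)

  exons_by_gene <- GenomicRanges::reduce(S4Vectors::split(ex, ex$gene_id))
  union_len <- sum(IRanges::width(exons_by_gene))

  gid <- names(exons_by_gene)
  models <- list(
    genes = data.frame(gene_id = gid,
                       max_transcript_length = as.integer(max_len[gid]),
                       union_exon_length = as.integer(union_len[gid]),
                       stringsAsFactors = FALSE),
    exons_by_gene = exons_by_gene,
    exons_by_tx = exons_by_tx)
  class(models) <- "gene_models"
  models
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x$genes), " genes, ",
      length(x$exons_by_tx), " transcripts\n", sep = "")
  invisible(x)
}

#' Count fragments per gene over exon unions
#'
#' Pair-level, unstranded fragment counting compatible with the
#' featureCounts defaults this workflow relies on: a fragment (read pair) is
#' counted once for a gene if any aligned base of either mate overlaps the
#' gene's exon union; fragments overlapping exons of more than one gene are
#' discarded as ambiguous; fragments overlapping no gene are left uncounted.
#' Aligned bases follow the CIGAR, so `N`-gapped junction reads only count
#' their exonic blocks.
#'
#' @param alignments alignment table of species-assigned records (e.g.
#'   `fit$assigned_a` from [filter_sample()], or a re-read output file).
#' @param models a [load_gene_models()] result.
#' @return an object of class `fragment_counts`: list with `counts` (named
#'   integer vector over all genes), `n_fragments`, `n_counted`,
#'   `n_ambiguous`, `n_no_feature` (the four obey
#'   `n_fragments = n_counted + n_ambiguous + n_no_feature`).
#' @export
count_fragments <- function(alignments, models) {
  stopifnot(inherits(models, "gene_models"))
  al <- as_alignment_table(alignments)
  al <- al[al$mapped, , drop = FALSE]
  genes <- models$genes$gene_id
  counts <- stats::setNames(integer(length(genes)), genes)
  n_frag <- length(unique(al$qname))
  if (!nrow(al)) {
    out <- list(counts = counts, n_fragments = 0L, n_counted = 0L,
                n_ambiguous = 0L, n_no_feature = 0L)
    class(out) <- "fragment_counts"
    return(out)
  }
  known <- unique(unlist(lapply(models$exons_by_gene, function(g)
    as.character(GenomicRanges::seqnames(g)))))
  unknown <- setdiff(unique(al$rname), known)
  if (length(unknown)) {
    warning("reference(s) absent from annotation, counted as no-overlap: ",
            paste(unknown, collapse = ", "))
  }

  kn <- al[al$rname %in% known, , drop = FALSE]
  blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    kn$cigar, pos = kn$pos, ops = c("M", "=", "X", "D"),
    reduce.ranges = TRUE)
  nb <- lengths(blocks)
  frag_gr <- GenomicRanges::GRanges(
    rep(kn$rname, nb), unlist(blocks, use.names = FALSE))
  frag_id <- rep(kn$qname, nb)

  exons <- unlist(models$exons_by_gene, use.names = FALSE)
  exon_gene <- rep(names(models$exons_by_gene),
                   lengths(models$exons_by_gene))
  hits <- GenomicRanges::findOverlaps(frag_gr, exons, ignore.strand = TRUE)
  if (length(hits)) {
    hit_pairs <- unique(data.frame(
      frag = frag_id[S4Vectors::queryHits(hits)],
      gene = exon_gene[S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE))
    genes_per_frag <- table(hit_pairs$frag)
    unambig <- names(genes_per_frag)[genes_per_frag == 1L]
    hit1 <- hit_pairs[hit_pairs$frag %in% unambig, , drop = FALSE]
    tab <- table(hit1$gene)
    counts[names(tab)] <- as.integer(tab)
    n_amb <- sum(genes_per_frag > 1L)
    n_counted <- length(unambig)
  } else {
    n_amb <- 0L; n_counted <- 0L
  }
  out <- list(counts = counts, n_fragments = n_frag, n_counted = n_counted,
              n_ambiguous = n_amb,
              n_no_feature = n_frag - n_counted - n_amb)
  class(out) <- "fragment_counts"
  out
}

#' @export
print.fragment_counts <- function(x, ...) {
  cat("<fragment_counts> ", x$n_fragments, " fragments: ", x$n_counted,
      " counted, ", x$n_ambiguous, " ambiguous, ", x$n_no_feature,
      " without feature\n", sep = "")
  invisible(x)
}

#' Compute species-aware FPKM
#'
#' Fragments per kilobase of message per million fragments, with the two
#' conventions of this workflow: the length term is the gene's *maximum
#' transcript length*, and the per-million denominator counts only the
#' fragments unambiguously assigned to this species in this sample (the
#' `assigned` tally of [filter_stats] -- not raw sequencing depth), so
#' `fpkm = count * 1e9 / (max_transcript_length * library_denominator)`.
#'
#' @param counts a [count_fragments()] result or named integer vector.
#' @param models a [load_gene_models()] result.
#' @param library_denominator total unambiguously assigned fragments for
#'   this species/sample.
#' @return a `data.frame` (`gene_id`, `count`, `fpkm`,
#'   `max_transcript_length`, `union_exon_length`) with the denominator
#'   attached as attribute `library_denominator`.
#' @export
compute_fpkm <- function(counts, models, library_denominator) {
  stopifnot(inherits(models, "gene_models"))
  if (inherits(counts, "fragment_counts")) counts <- counts$counts
  g <- models$genes
  cnt <- stats::setNames(integer(nrow(g)), g$gene_id)
  cnt[names(counts)] <- as.integer(counts)
  if (library_denominator == 0) {
    if (any(cnt > 0)) {
      stop("library denominator is 0 but fragment counts are nonzero")
    }
    fpkm <- numeric(nrow(g))
  } else {
    fpkm <- cnt * 1e9 / (g$max_transcript_length * library_denominator)
  }
  out <- data.frame(gene_id = g$gene_id, count = as.integer(cnt),
                    fpkm = fpkm,
                    max_transcript_length = g$max_transcript_length,
                    union_exon_length = g$union_exon_length,
                    stringsAsFactors = FALSE)
  attr(out, "library_denominator") <- library_denominator
  out
}

#' Estimate per-gene misassignment and exclude affected genes
#'
#' A single-species control sample run through the full sorting procedure
#' yields, per gene, how many of its fragments were incorrectly called as
#' the other species (`rate = crosscalled / total`). In a mixed sample, the
#' spurious contribution to a gene's own-species count is then estimated as
#' `rate * contaminant_count / mixed_count`, and genes whose estimated
#' spurious fraction exceeds `threshold` (default 10%) are excluded. A gene
#' with zero own-species count but nonzero estimated spurious fragments is
#' excluded with its spurious fraction flagged infinite. Cross-species gene
#' correspondence is the caller's responsibility via `gene_map`; it is never
#' inferred.
#'
#' @param control_stats `data.frame` with `gene_id` (contaminant-species
#'   ids), `total` and `crosscalled` fragment counts from the control.
#' @param mixed_counts named vector (or `data.frame` `gene_id`,`count`) of
#'   own-species counts per primary-species gene in the mixed sample.
#' @param contaminant_counts named vector (or `data.frame`) of
#'   contaminant-species counts in the mixed sample, keyed by
#'   contaminant-species gene id.
#' @param gene_map `data.frame` with columns `primary_id`,`contaminant_id`
#'   linking genes across species; `NULL` means identical ids.
#' @param threshold exclusion threshold on the spurious fraction
#'   (default 0.10).
#' @return an object of class `misassignment_report`: `data.frame` with
#'   `gene_id`, `contaminant_id`, `control_total`, `control_crosscalled`,
#'   `rate`, `mixed_count`, `contaminant_count`, `spurious_fraction`,
#'   `excluded`.
#' @export
estimate_misassignment <- function(control_stats, mixed_counts,
                                   contaminant_counts, gene_map = NULL,
                                   threshold = 0.10) {
  as_named <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$count, x$gene_id) else x
  }
  mixed <- as_named(mixed_counts)
  contam <- as_named(contaminant_counts)
  stopifnot(all(c("gene_id", "total", "crosscalled") %in%
                  names(control_stats)),
            threshold >= 0)
  if (is.null(gene_map)) {
    gene_map <- data.frame(primary_id = names(mixed),
                           contaminant_id = names(mixed),
                           stringsAsFactors = FALSE)
  }
  m <- gene_map
  ctl <- control_stats[match(m$contaminant_id, control_stats$gene_id), ]
  total <- ifelse(is.na(ctl$total), 0, ctl$total)
  crosscalled <- ifelse(is.na(ctl$crosscalled), 0, ctl$crosscalled)
  rate <- ifelse(total > 0, crosscalled / total, 0)
  mx <- mixed[m$primary_id]
  mx[is.na(mx)] <- 0
  cc <- contam[m$contaminant_id]
  cc[is.na(cc)] <- 0
  spurious_reads <- rate * cc
  spurious_fraction <- ifelse(mx > 0, spurious_reads / mx,
                              ifelse(spurious_reads > 0, Inf, 0))
  out <- data.frame(gene_id = m$primary_id,
                    contaminant_id = m$contaminant_id,
                    control_total = total,
                    control_crosscalled = crosscalled,
                    rate = rate,
                    mixed_count = as.numeric(mx),
                    contaminant_count = as.numeric(cc),
                    spurious_fraction = spurious_fraction,
                    excluded = spurious_fraction > threshold,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("misassignment_report", "data.frame")
  out
}

#' Mix primary and contaminant expression by cell numbers
#'
#' Emulates an imperfect physical cell-sorting step by mixing two
#' expression profiles at a given cell ratio (default 95:5): both inputs are
#' fragments-per-cell profiles, so the expected mixed count per transcript
#' is `p * primary_per_cell + q * contaminant_per_cell`. The deterministic
#' mode reports expected counts rounded half-to-even; the stochastic mode
#' draws a seeded multinomial over (transcript, origin) cells with the
#' expected totals as weights. Truth labels (per-origin counts) are kept in
#' either mode.
#'
#' @param primary,contaminant `data.frame`s with `id` and `per_cell_count`
#'   (mean fragments per cell for that transcript/gene).
#' @param cell_ratio numeric vector `c(p, q)` of cell numbers collected
#'   (default `c(95, 5)`).
#' @param mode `"deterministic"` (expected counts) or `"stochastic"`
#'   (multinomial draw).
#' @param seed integer seed used in stochastic mode.
#' @return a `data.frame` with `id`, `primary_count`, `contaminant_count`,
#'   `mixed_count` (= their sum).
#' @export
mix_contamination <- function(primary, contaminant, cell_ratio = c(95, 5),
                              mode = c("deterministic", "stochastic"),
                              seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(cell_ratio) == 2L, all(cell_ratio >= 0))
  p <- cell_ratio[1]; q <- cell_ratio[2]
  if (p + q == 0) stop("cell_ratio must not sum to zero")
  ids <- union(primary$id, contaminant$id)
  pc <- stats::setNames(numeric(length(ids)), ids)
  cc <- pc
  pc[primary$id] <- primary$per_cell_count
  cc[contaminant$id] <- contaminant$per_cell_count
  exp_p <- p * pc
  exp_c <- q * cc
  if (mode == "deterministic") {
    cnt_p <- round(exp_p)
    cnt_c <- round(exp_c)
  } else {
    set.seed(seed)
    w <- c(exp_p, exp_c)
    n <- round(sum(w))
    draw <- if (n > 0 && sum(w) > 0) {
      as.integer(stats::rmultinom(1L, n, w / sum(w)))
    } else integer(length(w))
    cnt_p <- draw[seq_along(ids)]
    cnt_c <- draw[seq_along(ids) + length(ids)]
  }
  data.frame(id = ids,
             primary_count = as.numeric(cnt_p),
             contaminant_count = as.numeric(cnt_c),
             mixed_count = as.numeric(cnt_p + cnt_c),
             stringsAsFactors = FALSE)
}
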