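#' Parameters of the species-sorting decision procedure
#'
#' The defaults encode the conservative strategy: an assigned read pair must
#' have a single, full-length, splice-consistent alignment to its genome with
#' zero mismatched bases.
#'
#' @param min_junction_overhang minimum aligned bases required on each side
#'   of every splice junction (default 5).
#' @param max_final_mismatches maximum pair mismatch sum tolerated at
#'   finalization (default 0, the conservative strategy).
#' @param allow_clipping whether soft/hard-clipped alignments are accepted as
#'   structurally valid (default `FALSE`).
#' @param max_hits_per_genome maximum reported alignment pairs per genome
#'   before a read is discarded as multimapping (default 1). The count uses
#'   the alignments as reported by the upstream aligner, which is expected to
#'   emit only top-scoring hits; the engine does not rescore.
#' @param compare_mismatches_by how mate mismatch counts are aggregated for
#'   the cross-genome comparison; only `"pair_sum"` (sum over mates) is
#'   supported.
#' @param strict_paper_order if `TRUE`, the multimap discard applies only
#'   when alignments to both genomes exist, so a read multimapping to one
#'   genome and absent from the other stays provisionally assigned. The
#'   default `FALSE` additionally rejects such reads at finalization, which
#'   guarantees every assigned pair has a single alignment.
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(min_junction_overhang = 5L,
                          max_final_mismatches = 0L,
                          allow_clipping = FALSE,
                          max_hits_per_genome = 1L,
                          compare_mismatches_by = "pair_sum",
                          strict_paper_order = FALSE) {
  stopifnot(min_junction_overhang >= 0L, max_final_mismatches >= 0L,
            max_hits_per_genome >= 1L)
  compare_mismatches_by <- match.arg(compare_mismatches_by, "pair_sum")
  p <- list(min_junction_overhang = as.integer(min_junction_overhang),
            max_final_mismatches = as.integer(max_final_mismatches),
            allow_clipping = isTRUE(allow_clipping),
            max_hits_per_genome = as.integer(max_hits_per_genome),
            compare_mismatches_by = compare_mismatches_by,
            strict_paper_order = isTRUE(strict_paper_order))
  class(p) <- "filter_params"
  p
}

#' @export
print.filter_params <- function(x, ...) {
  cat("<filter_params> overhang>=", x$min_junction_overhang,
      ", final mismatches<=", x$max_final_mismatches,
      ", clipping ", if (x$allow_clipping) "allowed" else "forbidden",
      ", hits/genome<=", x$max_hits_per_genome,
      if (x$strict_paper_order) ", strict branch order" else "", "\n", sep = "")
  invisible(x)
}

#' Mismatch sum of a read-pair alignment
#'
#' The pair-level mismatch count compared between genomes: the sum of both
#' mates' edit-distance (`NM`) counts, or the single mate's count for
#' single-end reads. Missing mismatch counts are a hard error.
#'
#' @param pair one pair alignment from a [read_pair_groups()] group (a list
#'   with `first` and optional `second` record).
#' @return non-negative integer.
#' @export
pair_mismatches <- function(pair) {
  n1 <- pair$first$nm
  n2 <- if (is.null(pair$second)) 0L else pair$second$nm
  if (is.null(n1) || is.na(n1) || (!is.null(pair$second) && is.na(n2))) {
    stop("missing mismatch count for read '", pair$first$qname, "'")
  }
  as.integer(n1 + n2)
}

verdict_levels <- c("ASSIGNED_A", "ASSIGNED_B", "REJECTED_MULTIMAP",
                    "REJECTED_AMBIGUOUS", "REJECTED_STRUCTURE",
                    "REJECTED_MISMATCH")

# The decision tree, vectorized over read pairs. Inputs are per-read
# summaries: number of reported pairs per genome (na, nb) and the candidate
# pair's mismatch sum and structural validity per genome (NA where absent).
#
#  (1) alignments to one genome only          -> provisional for that genome
#  (2) both genomes, either side multimapping -> REJECTED_MULTIMAP
#  (3) fewer mismatches on one side           -> provisional for that side
#  (4) mismatch tie: structure discriminates  -> provisional / AMBIGUOUS /
#                                                STRUCTURE
#  (5) finalization of any provisional call: single alignment (unless
#      strict_paper_order), mismatch sum <= max_final_mismatches, structural
#      criteria -- otherwise the corresponding typed rejection.
decide_verdicts <- function(na, nb, nm_a, nm_b, str_a, str_b, params) {
  n <- length(na)
  verdict <- rep(NA_character_, n)
  prov <- rep(NA_character_, n)

  if (any(na == 0L & nb == 0L)) {
    stop("read pair with no alignment to either genome reached the decision ",
         "procedure; unmapped pairs must be excluded upstream")
  }
  prov[na > 0L & nb == 0L] <- "A"
  prov[nb > 0L & na == 0L] <- "B"

  both <- na > 0L & nb > 0L
  mm <- both & (na > params$max_hits_per_genome |
                  nb > params$max_hits_per_genome)
  verdict[mm] <- "REJECTED_MULTIMAP"

  cmp <- both & !mm
  prov[cmp & nm_a < nm_b] <- "A"
  prov[cmp & nm_b < nm_a] <- "B"
  tie <- cmp & nm_a == nm_b
  prov[tie & str_a & !str_b] <- "A"
  prov[tie & str_b & !str_a] <- "B"
  verdict[tie & str_a & str_b] <- "REJECTED_AMBIGUOUS"
  verdict[tie & !str_a & !str_b] <- "REJECTED_STRUCTURE"

  isA <- !is.na(prov) & prov == "A"
  isB <- !is.na(prov) & prov == "B"
  pn <- ifelse(isA, na, nb)
  pnm <- ifelse(isA, nm_a, nm_b)
  pstr <- ifelse(isA, str_a, str_b)
  provd <- isA | isB
  f_mm <- provd & !params$strict_paper_order & pn > params$max_hits_per_genome
  verdict[f_mm] <- "REJECTED_MULTIMAP"
  f_nm <- provd & !f_mm & pnm > params$max_final_mismatches
  verdict[f_nm] <- "REJECTED_MISMATCH"
  f_st <- provd & !f_mm & !f_nm & !pstr
  verdict[f_st] <- "REJECTED_STRUCTURE"
  ok <- provd & !f_mm & !f_nm & !f_st
  verdict[ok & isA] <- "ASSIGNED_A"
  verdict[ok & isB] <- "ASSIGNED_B"
  stopifnot(!anyNA(verdict))
  verdict
}

# Candidate pair per genome: fewest mismatches, ties broken by structural
# validity, then primary flag, then input order. With the default
# max_hits_per_genome = 1 the candidate question only arises for exclusive
# one-genome multimaps, which are rejected at finalization anyway unless
# strict_paper_order is set.
candidate_index <- function(nm, str_ok, primary) {
  order(nm, !str_ok, !primary)[1L]
}

#' Decide the species of origin of one read pair
#'
#' Applies the full decision tree to one [read_pair_groups()] group:
#' exclusive mapping, multimap discard, mismatch comparison, structural
#' tie-break, then conservative finalization (single alignment, at most
#' `max_final_mismatches` mismatches, structural criteria). Every path ends
#' in a verdict; there is no randomness.
#'
#' @param group a `pair_alignment_group`.
#' @param params a [filter_params()] object.
#' @return an `assignment_decision`: list with `read_name`, `verdict` (one of
#'   `ASSIGNED_A`, `ASSIGNED_B`, `REJECTED_MULTIMAP`, `REJECTED_AMBIGUOUS`,
#'   `REJECTED_STRUCTURE`, `REJECTED_MISMATCH`) and `chosen_alignment` (the
#'   winning pair, present iff assigned).
#' @export
assign_species <- function(group, params = filter_params()) {
  summar <- function(alns) {
    if (!length(alns)) {
      return(list(n = 0L, nm = NA_integer_, str = NA, cand = NA_integer_))
    }
    nm <- vapply(alns, pair_mismatches, integer(1))
    str_ok <- vapply(alns, function(p) {
      check_structure(p$first$cigar,
                      if (is.null(p$second)) NULL else p$second$cigar,
                      min_overhang = params$min_junction_overhang,
                      allow_clipping = params$allow_clipping)
    }, logical(1))
    prim <- vapply(alns, function(p) isTRUE(p$primary), logical(1))
    i <- candidate_index(nm, str_ok, prim)
    list(n = length(alns), nm = nm[i], str = str_ok[i], cand = i)
  }
  sa <- summar(group$aln_a)
  sb <- summar(group$aln_b)
  verdict <- decide_verdicts(sa$n, sb$n, sa$nm, sb$nm, sa$str, sb$str, params)
  chosen <- NULL
  if (verdict == "ASSIGNED_A") chosen <- group$aln_a[[sa$cand]]
  if (verdict == "ASSIGNED_B") chosen <- group$aln_b[[sb$cand]]
  d <- list(read_name = group$read_name, verdict = verdict,
            chosen_alignment = chosen)
  class(d) <- "assignment_decision"
  d
}

#' @export
print.assignment_decision <- function(x, ...) {
  cat("<assignment_decision> ", x$read_name, ": ", x$verdict, "\n", sep = "")
  invisible(x)
}

#' Per-sample sorting tallies
#'
#' Constructor and validator for the six-way verdict tally of one sample;
#' the categories partition the read pairs, so `total_pairs` always equals
#' their sum.
#'
#' @param assigned_a,assigned_b,rejected_multimap,rejected_ambiguous,rejected_structure,rejected_mismatch
#'   non-negative verdict counts.
#' @return an object of class `filter_stats`.
#' @export
filter_stats <- function(assigned_a = 0L, assigned_b = 0L,
                         rejected_multimap = 0L, rejected_ambiguous = 0L,
                         rejected_structure = 0L, rejected_mismatch = 0L) {
  s <- list(assigned_a = as.integer(assigned_a),
            assigned_b = as.integer(assigned_b),
            rejected_multimap = as.integer(rejected_multimap),
            rejected_ambiguous = as.integer(rejected_ambiguous),
            rejected_structure = as.integer(rejected_structure),
            rejected_mismatch = as.integer(rejected_mismatch))
  if (any(unlist(s) < 0L)) stop("filter_stats counts must be non-negative")
  s$total_pairs <- sum(unlist(s))
  class(s) <- "filter_stats"
  s
}

#' @export
print.filter_stats <- function(x, ...) {
  cat("<filter_stats> ", x$total_pairs, " read pairs: ",
      x$assigned_a, " -> A, ", x$assigned_b, " -> B, rejected ",
      x$rejected_multimap, " multimap / ", x$rejected_ambiguous,
      " ambiguous / ", x$rejected_structure, " structure / ",
      x$rejected_mismatch, " mismatch\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.filter_stats <- function(x, ...) {
  data.frame(total_pairs = x$total_pairs, assigned_a = x$assigned_a,
             assigned_b = x$assigned_b, rejected_multimap = x$rejected_multimap,
             rejected_ambiguous = x$rejected_ambiguous,
             rejected_structure = x$rejected_structure,
             rejected_mismatch = x$rejected_mismatch)
}

#' Sort one mixed-species sample
#'
#' Runs the decision procedure over every read pair of a sample given its
#' alignments against the two genomes, optionally writing the assigned pairs
#' to per-species SAM/BAM files. The engine evaluates all pairs vectorized;
#' verdicts are identical to applying [assign_species()] group by group.
#'
#' @param a,b paths to name-sorted SAM/BAM files, or alignment tables, for
#'   genomes A and B (the same read set mapped to each).
#' @param params a [filter_params()] object.
#' @param out_a,out_b optional output paths for the assigned pairs of each
#'   species (`.sam` or `.bam`).
#' @param labels character vector of two species labels used in messages.
#' @return an object of class `sss_filter`: list with `stats`
#'   ([filter_stats]), `decisions` (data.frame of `qname`, `verdict`),
#'   `assigned_a`/`assigned_b` (alignment-table rows of the chosen
#'   alignments), `n_unmapped` (read names mapped to neither genome), the
#'   `params` and `labels`.
#' @export
filter_sample <- function(a, b, params = filter_params(),
                          out_a = NULL, out_b = NULL,
                          labels = c("A", "B")) {
  ta <- as_alignment_table(a)
  tb <- as_alignment_table(b)
  validate_name_order(ta$qname, paste0("genome ", labels[1], " input"))
  validate_name_order(tb$qname, paste0("genome ", labels[2], " input"))

  summarize_side <- function(tab, nms) {
    p <- pair_table(tab)
    if (nrow(p)) {
      str1 <- cigar_structure_ok(tab$cigar[p$i1],
                                 params$min_junction_overhang,
                                 params$allow_clipping)
      has2 <- !is.na(p$i2)
      str2 <- rep(TRUE, nrow(p))
      str2[has2] <- cigar_structure_ok(tab$cigar[p$i2[has2]],
                                       params$min_junction_overhang,
                                       params$allow_clipping)
      p$str_ok <- str1 & str2
      if (anyNA(p$nm)) {
        stop("missing mismatch count for read '",
             p$qname[which(is.na(p$nm))[1L]], "'")
      }
    } else p$str_ok <- logical(0)
    f <- factor(p$qname, levels = nms)
    n <- as.integer(table(f))
    # candidate pair per read: fewest mismatches, then structure, then primary
    o <- order(f, p$nm, !p$str_ok, !p$primary)
    first <- o[!duplicated(as.integer(f)[o])]
    cand <- rep(NA_integer_, length(nms))
    cand[as.integer(f)[first]] <- first
    list(pairs = p, n = n,
         nm = ifelse(is.na(cand), NA_integer_, p$nm[cand]),
         str = ifelse(is.na(cand), NA, p$str_ok[cand]),
         cand = cand)
  }

  nms <- sort(unique(c(ta$qname, tb$qname)), method = "radix")
  sa <- summarize_side(ta, nms)
  sb <- summarize_side(tb, nms)

  unmapped <- sa$n == 0L & sb$n == 0L
  keep <- !unmapped
  verdict <- character(length(nms))
  if (any(keep)) {
    verdict[keep] <- decide_verdicts(sa$n[keep], sb$n[keep],
                                     sa$nm[keep], sb$nm[keep],
                                     sa$str[keep], sb$str[keep], params)
  }

  chosen_rows <- function(side, tab, want) {
    idx <- side$cand[want]
    rows <- c(rbind(side$pairs$i1[idx], side$pairs$i2[idx]))
    rows <- rows[!is.na(rows)]
    tab[rows, , drop = FALSE]
  }
  wa <- keep & verdict == "ASSIGNED_A"
  wb <- keep & verdict == "ASSIGNED_B"
  assigned_a <- chosen_rows(sa, ta, wa)
  assigned_b <- chosen_rows(sb, tb, wb)

  tallies <- table(factor(verdict[keep], levels = verdict_levels))
  stats <- filter_stats(tallies[["ASSIGNED_A"]], tallies[["ASSIGNED_B"]],
                        tallies[["REJECTED_MULTIMAP"]],
                        tallies[["REJECTED_AMBIGUOUS"]],
                        tallies[["REJECTED_STRUCTURE"]],
                        tallies[["REJECTED_MISMATCH"]])

  res <- list(stats = stats,
              decisions = data.frame(qname = nms[keep],
                                     verdict = verdict[keep],
                                     stringsAsFactors = FALSE),
              assigned_a = assigned_a, assigned_b = assigned_b,
              n_unmapped = sum(unmapped),
              params = params, labels = labels)
  class(res) <- "sss_filter"
  if (!is.null(out_a)) {
    write_species_bam(assigned_a, attr(ta, "header"), out_a,
                      pg_cl = paste("sssort filter", labels[1]))
  }
  if (!is.null(out_b)) {
    write_species_bam(assigned_b, attr(tb, "header"), out_b,
                      pg_cl = paste("sssort filter", labels[2]))
  }
  res
}

#' @export
print.sss_filter <- function(x, ...) {
  cat("Species-specific sorting of one sample (", x$labels[1], " vs ",
      x$labels[2], ")\n", sep = "")
  print(x$stats)
  if (x$n_unmapped) cat(x$n_unmapped, "read pair(s) mapped to neither genome\n")
  invisible(x)
}

#' Post-hoc soundness scan of assigned output
#'
#' Verifies, record by record, that written/assigned alignments honour the
#' conservative guarantee: mismatch sum 0 per pair (or at most the configured
#' maximum), no clipped bases, and every splice-junction overhang at least
#' the configured minimum. Use on a [filter_sample()] result's assigned
#' tables or on a re-read output file.
#'
#' @param records alignment table of assigned records.
#' @param params the [filter_params()] the sample was sorted with.
#' @return `TRUE` invisibly; a violation is a hard error.
#' @export
verify_assigned_soundness <- function(records, params = filter_params()) {
  if (!nrow(records)) return(invisible(TRUE))
  nm_by_pair <- tapply(records$nm, records$qname, sum)
  if (any(nm_by_pair > params$max_final_mismatches)) {
    stop("soundness violation: assigned pair with mismatch sum > ",
         params$max_final_mismatches)
  }
  ok <- cigar_structure_ok(records$cigar, params$min_junction_overhang,
                           params$allow_clipping)
  if (!all(ok)) stop("soundness violation: assigned alignment fails the ",
                     "structural criteria")
  invisible(TRUE)
}
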