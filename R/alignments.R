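#' Normalize a read name
#'
#' Strips trailing mate suffixes (`/1`, `/2`) and anything after the first
#' whitespace (Casava-style ` 1:N:0:...` comments), so that both mates and
#' both genomes' files key a read pair identically. Idempotent.
#'
#' @param raw character vector of raw read names.
#' @return character vector of normalized names.
#' @examples
#' normalize_read_name(c("frag7/1", "frag7", "frag7 2:N:0:ACGT"))
#' @export
normalize_read_name <- function(raw) {
  sub("/[12]$", "", sub("[ \t].*$", "", raw))
}

#' Read an alignment file into an alignment table
#'
#' Reads a SAM or BAM file (SAM is converted on the fly through htslib) into
#' a plain `data.frame` with one row per alignment record, the package's
#' working representation. Secondary and supplementary records are retained
#' (they are evidence of multimapping); unmapped records are retained too and
#' ignored at grouping time. Per-record mismatch counts come from the `NM`
#' tag; when `NM` is absent they are recomputed from the `MD` tag, and a
#' mapped record carrying neither is a hard error -- mismatch counts drive
#' species assignment and are never silently assumed to be zero.
#'
#' @param file path to a SAM or BAM file.
#' @return a `data.frame` with columns `qname` (normalized), `flag`, `mate`
#'   (1 or 2), `rname`, `pos`, `strand`, `cigar`, `nm`, `mapped`, `paired`,
#'   `primary`, `hi` (hit index, `NA` when the tag is absent) and `seq`;
#'   the source header is attached as `attr(x, "header")`.
#' @export
read_alignments <- function(file) {
  if (!file.exists(file)) stop("alignment file not found: ", file)
  bam <- file
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "cigar", "seq"),
    tag = c("NM", "MD", "HI"))
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  header <- Rsamtools::scanBamHeader(bam)[[1L]]

  flag <- res$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  paired <- bitwAnd(flag, 1L) != 0L
  mate <- ifelse(paired & bitwAnd(flag, 128L) != 0L, 2L, 1L)
  nm <- as.integer(res$tag$NM)
  if (is.null(res$tag$NM)) nm <- rep(NA_integer_, length(flag))
  md <- res$tag$MD
  if (is.null(md)) md <- rep(NA_character_, length(flag))
  need <- mapped & is.na(nm)
  if (any(need)) {
    if (anyNA(md[need])) {
      bad <- which(need & is.na(md))[1L]
      stop("mapped record without NM or MD tag (read '", res$qname[bad],
           "', record ", bad, ") in ", file)
    }
    nm[need] <- md_mismatch_count(md[need])
  }
  hi <- res$tag$HI
  if (is.null(hi)) hi <- rep(NA_integer_, length(flag))

  out <- data.frame(
    qname = normalize_read_name(res$qname),
    flag = flag,
    mate = mate,
    rname = as.character(res$rname),
    pos = res$pos,
    strand = as.character(res$strand),
    cigar = res$cigar,
    nm = nm,
    mapped = mapped,
    paired = paired,
    primary = bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L,
    hi = as.integer(hi),
    seq = as.character(res$seq),
    stringsAsFactors = FALSE)
  attr(out, "header") <- header
  out
}

# Accept either a path or an already-read alignment table.
as_alignment_table <- function(x) {
  if (is.character(x) && length(x) == 1L) return(read_alignments(x))
  stopifnot(is.data.frame(x))
  needed <- c("qname", "mate", "rname", "pos", "cigar", "nm", "mapped", "paired")
  miss <- setdiff(needed, names(x))
  if (length(miss)) stop("alignment table lacks column(s): ",
                         paste(miss, collapse = ", "))
  x
}

# Validate the streaming contract: records for one read name must be
# contiguous and names must appear in byte-wise (C-locale) sorted order after
# normalization. Hard error naming the offending record.
validate_name_order <- function(qname, label = "input") {
  if (!length(qname)) return(invisible(TRUE))
  r <- rle(qname)
  v <- r$values
  if (anyDuplicated(v)) {
    dup <- v[duplicated(v)][1L]
    idx <- which(qname == dup)
    stop("name-order violation in ", label, ": read '", dup,
         "' reappears at record ", idx[length(idx)],
         " after other read names; input must be name-sorted")
  }
  if (length(v) > 1L) {
    o <- order(v, method = "radix")
    if (!identical(o, seq_along(v))) {
      bad <- which(o != seq_along(v))[1L]
      at <- sum(r$lengths[seq_len(bad)]) + 1L
      stop("name-order violation in ", label, ": read '", v[bad + 1L],
           "' at record ", at, " is out of byte-wise sorted order")
    }
  }
  invisible(TRUE)
}

# Collapse the mapped records of one genome's table into reported alignment
# pairs: one row per (read pair, locus). Mates are matched by the HI (hit
# index) tag when present, otherwise i-th first mate with i-th second mate in
# file order. Pairs with an unmapped or absent partner (half-mapped) are
# dropped: the decision procedure compares pair-level mismatches and
# structure, so a half-mapped pair counts as "no alignment to this genome".
# Single-end records (paired flag unset) form degenerate one-mate pairs.
pair_table <- function(tab) {
  m <- tab[tab$mapped, , drop = FALSE]
  if (!nrow(m)) {
    return(data.frame(qname = character(0), i1 = integer(0), i2 = integer(0),
                      nm = integer(0), primary = logical(0),
                      stringsAsFactors = FALSE))
  }
  m$row <- which(tab$mapped)
  se <- m[!m$paired, , drop = FALSE]
  pe <- m[m$paired, , drop = FALSE]
  out <- list()
  if (nrow(se)) {
    out$se <- data.frame(qname = se$qname, i1 = se$row, i2 = NA_integer_,
                         nm = se$nm, primary = se$primary,
                         stringsAsFactors = FALSE)
  }
  if (nrow(pe)) {
    key_rank <- function(d) {
      hit <- d$hi
      miss <- is.na(hit)
      if (any(miss)) {
        hit[miss] <- stats::ave(seq_len(sum(miss)),
                                paste(d$qname[miss], d$mate[miss]),
                                FUN = seq_along)
      }
      paste0(d$qname, "\r", hit)
    }
    k <- key_rank(pe)
    m1 <- pe[pe$mate == 1L, , drop = FALSE]
    m2 <- pe[pe$mate == 2L, , drop = FALSE]
    j <- match(k[pe$mate == 1L], k[pe$mate == 2L])
    keep <- !is.na(j)
    if (any(keep)) {
      m1 <- m1[keep, , drop = FALSE]
      m2 <- m2[j[keep], , drop = FALSE]
      out$pe <- data.frame(qname = m1$qname, i1 = m1$row, i2 = m2$row,
                           nm = m1$nm + m2$nm,
                           primary = m1$primary & m2$primary,
                           stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, unname(out))
  if (is.null(res)) {
    res <- data.frame(qname = character(0), i1 = integer(0), i2 = integer(0),
                      nm = integer(0), primary = logical(0),
                      stringsAsFactors = FALSE)
  }
  res[order(match(res$qname, unique(tab$qname)), res$i1), , drop = FALSE]
}

#' Group two name-matched alignment streams by read pair
#'
#' Takes the alignments of the *same* read set against two different genomes
#' and regroups them into per-read-pair units: one group per distinct read
#' name appearing in either input, carrying that pair's reported alignments
#' against genome A and against genome B. Both inputs must be name-sorted
#' under byte-wise collation of normalized names (validated; violations are
#' hard errors naming the offending record). Unmapped records contribute
#' nothing; a pair with only one mate mapped to a genome contributes no
#' alignment to that genome.
#'
#' @param a,b paths to SAM/BAM files, or alignment tables from
#'   [read_alignments()], for genomes A and B.
#' @return a named list of `pair_alignment_group` objects in name order; each
#'   has `read_name`, `aln_a` and `aln_b` (lists of pair alignments, each a
#'   list with `first` and `second` record rows, `second = NULL` for
#'   single-end), and `n_records` bookkeeping.
#' @export
read_pair_groups <- function(a, b) {
  ta <- as_alignment_table(a)
  tb <- as_alignment_table(b)
  validate_name_order(ta$qname, "genome A input")
  validate_name_order(tb$qname, "genome B input")
  pa <- pair_table(ta)
  pb <- pair_table(tb)
  nms <- sort(unique(c(ta$qname, tb$qname)), method = "radix")
  make_pairs <- function(p, tab) {
    lapply(seq_len(nrow(p)), function(i) {
      list(first = as.list(tab[p$i1[i], , drop = FALSE]),
           second = if (is.na(p$i2[i])) NULL else
             as.list(tab[p$i2[i], , drop = FALSE]),
           nm = p$nm[i], primary = p$primary[i])
    })
  }
  ga <- split(seq_len(nrow(pa)), factor(pa$qname, levels = nms))
  gb <- split(seq_len(nrow(pb)), factor(pb$qname, levels = nms))
  groups <- lapply(nms, function(nm) {
    g <- list(read_name = nm,
              aln_a = make_pairs(pa[ga[[nm]], , drop = FALSE], ta),
              aln_b = make_pairs(pb[gb[[nm]], , drop = FALSE], tb))
    class(g) <- "pair_alignment_group"
    g
  })
  names(groups) <- nms
  groups
}

#' @export
print.pair_alignment_group <- function(x, ...) {
  cat("<pair_alignment_group> ", x$read_name, ": ",
      length(x$aln_a), " alignment pair(s) vs A, ",
      length(x$aln_b), " vs B\n", sep = "")
  invisible(x)
}

# Reconstruct SAM header text lines from an Rsamtools header (list with
# $targets and $text).
header_lines <- function(header) {
  txt <- header$text
  if (is.null(txt) || !length(txt)) {
    return(paste0("@SQ\tSN:", names(header$targets),
                  "\tLN:", as.integer(header$targets)))
  }
  vapply(seq_along(txt), function(i) {
    paste(c(names(txt)[i], txt[[i]]), collapse = "\t")
  }, character(1))
}

#' Write species-assigned read pairs to a SAM or BAM file
#'
#' Writes exactly the chosen alignment (both mates) of each assigned pair,
#' with the reference dictionary of the target genome preserved from its
#' input header plus an added `@PG` line recording the tool and parameters.
#' A `.bam` destination is produced by writing SAM and converting through
#' htslib.
#'
#' @param records alignment table rows of the chosen alignments (as stored in
#'   a [filter_sample()] result, e.g. `fit$assigned_a`).
#' @param header header of the corresponding genome's input
#'   (`attr(read_alignments(f), "header")`), or a named integer vector of
#'   reference lengths.
#' @param file output path ending in `.sam` or `.bam`.
#' @param pg_cl command-line string recorded in the `@PG` line.
#' @return (invisibly) the number of read pairs written.
#' @export
write_species_bam <- function(records, header, file, pg_cl = "sssort") {
  if (is.numeric(header)) header <- list(targets = header, text = NULL)
  targets <- header$targets
  if (nrow(records)) {
    bad <- setdiff(unique(records$rname), names(targets))
    if (length(bad)) {
      stop("alignment reference(s) absent from output header: ",
           paste(bad, collapse = ", "))
    }
  }
  lines <- header_lines(header)
  lines <- c(lines, paste0("@PG\tID:sssort\tPN:sssort\tVN:",
                           as.character(utils::packageVersion("sssort")),
                           "\tCL:", pg_cl))
  n_pairs <- 0L
  if (nrow(records)) {
    r <- records
    # pair mates for RNEXT/PNEXT/TLEN bookkeeping
    ord <- order(match(r$qname, unique(r$qname)), r$mate)
    r <- r[ord, , drop = FALSE]
    flag_out <- r$flag
    flag_out <- bitwAnd(flag_out, bitwNot(256L + 2048L))  # written pairs are primary
    by_q <- split(seq_len(nrow(r)), r$qname)
    rnext <- rep("*", nrow(r)); pnext <- rep(0L, nrow(r)); tlen <- rep(0L, nrow(r))
    for (ix in by_q) {
      if (length(ix) == 2L) {
        rnext[ix] <- ifelse(r$rname[rev(ix)] == r$rname[ix], "=", r$rname[rev(ix)])
        pnext[ix] <- r$pos[rev(ix)]
        span <- max(r$pos[ix] + GenomicAlignments::cigarWidthAlongReferenceSpace(r$cigar[ix])) -
          min(r$pos[ix])
        tlen[ix] <- ifelse(r$pos[ix] <= r$pos[rev(ix)], span, -span)
      }
      n_pairs <- n_pairs + 1L
    }
    seq_out <- if ("seq" %in% names(r)) ifelse(is.na(r$seq) | r$seq == "", "*", r$seq) else "*"
    body <- paste(r$qname, flag_out, r$rname, r$pos, 255L, r$cigar,
                  rnext, pnext, tlen, seq_out, "*",
                  paste0("NM:i:", r$nm), sep = "\t")
    lines <- c(lines, body)
  }
  if (grepl("\\.bam$", file, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".sam")
    writeLines(lines, tmp)
    Rsamtools::asBam(tmp, sub("\\.bam$", "", file, ignore.case = TRUE),
                     overwrite = TRUE, indexDestination = FALSE)
    unlink(tmp)
  } else {
    writeLines(lines, file)
  }
  invisible(n_pairs)
}
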