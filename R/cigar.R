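#' Structural validity of alignments
#'
#' An alignment is structurally valid when it spans the full length of the
#' read -- no soft- or hard-clipped bases -- and, wherever it crosses a splice
#' junction (an `N` CIGAR operation), at least `min_overhang` read bases are
#' aligned to the exonic sequence on *each* side of the junction. The overhang
#' on one side is the total number of reference-aligned query bases
#' (`M`, `=`, `X` operations) on that side of the `N`, summed across all
#' operations, not just the run adjacent to the junction.
#'
#' @param cigar character vector of CIGAR strings.
#' @param min_overhang minimum aligned bases required on each side of every
#'   splice junction (default 5).
#' @param allow_clipping if `TRUE`, soft/hard clips do not invalidate an
#'   alignment (the junction-overhang rule still applies). Default `FALSE`.
#' @return logical vector, one element per CIGAR.
#' @examples
#' cigar_structure_ok(c("50M", "45M5S", "4M100N46M", "5M100N45M"))
#' @export
cigar_structure_ok <- function(cigar, min_overhang = 5L, allow_clipping = FALSE) {
  stopifnot(min_overhang >= 0L)
  if (!length(cigar)) return(logical(0))
  # evaluate each distinct CIGAR once; real samples repeat a handful of forms
  ucig <- unique(cigar)
  ops <- GenomicAlignments::explodeCigarOps(ucig)
  lens <- GenomicAlignments::explodeCigarOpLengths(ucig)
  ok <- mapply(function(op, len) {
    if (!allow_clipping && any(op == "S" | op == "H")) return(FALSE)
    ns <- which(op == "N")
    if (!length(ns)) return(TRUE)
    aligned <- ifelse(op %in% c("M", "=", "X"), len, 0L)
    cum <- cumsum(aligned)
    total <- cum[length(cum)]
    left <- ifelse(ns > 1L, cum[pmax(ns - 1L, 1L)], 0L)
    right <- total - cum[ns]
    all(left >= min_overhang & right >= min_overhang)
  }, ops, lens, USE.NAMES = FALSE)
  ok[match(cigar, ucig)]
}

#' Check the structural criteria for a read-pair alignment
#'
#' Pure predicate over the CIGARs of one read pair's alignment to one genome:
#' `TRUE` iff *both* mates are structurally valid under
#' [cigar_structure_ok()]. For single-end reads pass only `cigar1`.
#'
#' @param cigar1,cigar2 CIGAR strings of the two mates (`cigar2 = NULL` for
#'   single-end).
#' @inheritParams cigar_structure_ok
#' @return single logical.
#' @export
check_structure <- function(cigar1, cigar2 = NULL, min_overhang = 5L,
                            allow_clipping = FALSE) {
  cig <- c(cigar1, cigar2)
  all(cigar_structure_ok(cig, min_overhang = min_overhang,
                         allow_clipping = allow_clipping))
}

# query length implied by a CIGAR (query-consuming ops M,I,S,=,X)
cigar_query_length <- function(cigar) {
  GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
}

# Mismatch count from an MD tag: letters outside ^-prefixed deletion runs are
# substitutions. Used only when a record carries MD but no NM.
md_mismatch_count <- function(md) {
  vapply(md, function(x) {
    toks <- regmatches(x, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", x))[[1L]]
    sum(!grepl("^[0-9^]", toks))
  }, integer(1), USE.NAMES = FALSE)
}
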