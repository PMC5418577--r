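`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracle for the sorting decision: a straight-line
# restatement of the rules with its own CIGAR parsing, kept deliberately
# separate from the package implementation. A "side" is a list of pair
# alignments, each list(cigars = character vector over mates, nm = total
# mismatches, primary = flag).

oracle_cigar_ok <- function(cigar, min_overhang, allow_clipping) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  if (!allow_clipping && any(op %in% c("S", "H"))) return(FALSE)
  for (i in which(op == "N")) {
    before <- seq_len(i - 1L)
    left <- sum(len[before][op[before] %in% c("M", "=", "X")])
    after <- setdiff(seq_along(op), seq_len(i))
    right <- sum(len[after][op[after] %in% c("M", "=", "X")])
    if (left < min_overhang || right < min_overhang) return(FALSE)
  }
  TRUE
}

oracle_side_ok <- function(aln, p) {
  all(vapply(aln$cigars, oracle_cigar_ok, logical(1),
             p$min_junction_overhang, p$allow_clipping))
}

oracle_verdict <- function(aln_a, aln_b, p) {
  na <- length(aln_a)
  nb <- length(aln_b)
  best <- function(side) {
    nm <- vapply(side, `[[`, numeric(1), "nm")
    ok <- vapply(side, oracle_side_ok, logical(1), p)
    i <- order(nm, !ok)[1L]
    list(nm = nm[i], ok = ok[i])
  }
  final <- function(tag, n, cand) {
    if (!p$strict_paper_order && n > p$max_hits_per_genome)
      return("REJECTED_MULTIMAP")
    if (cand$nm > p$max_final_mismatches) return("REJECTED_MISMATCH")
    if (!cand$ok) return("REJECTED_STRUCTURE")
    paste0("ASSIGNED_", tag)
  }
  if (na > 0L && nb == 0L) return(final("A", na, best(aln_a)))
  if (nb > 0L && na == 0L) return(final("B", nb, best(aln_b)))
  if (na > p$max_hits_per_genome || nb > p$max_hits_per_genome)
    return("REJECTED_MULTIMAP")
  ca <- best(aln_a); cb <- best(aln_b)
  if (ca$nm < cb$nm) return(final("A", na, ca))
  if (cb$nm < ca$nm) return(final("B", nb, cb))
  if (ca$ok && !cb$ok) return(final("A", na, ca))
  if (cb$ok && !ca$ok) return(final("B", nb, cb))
  if (ca$ok && cb$ok) return("REJECTED_AMBIGUOUS")
  "REJECTED_STRUCTURE"
}

# rebuild oracle-style sides from a scenario-grid alignment table using only
# base R (no package grouping code)
oracle_sides_from_table <- function(tab) {
  tab <- tab[tab$mapped, , drop = FALSE]
  out <- list()
  for (q in unique(tab$qname)) {
    t1 <- tab[tab$qname == q, , drop = FALSE]
    sides <- list()
    for (h in unique(t1$hi)) {
      th <- t1[t1$hi == h, , drop = FALSE]
      has1 <- any(th$mate == 1L)
      has2 <- any(th$mate == 2L)
      if (th$paired[1] && !(has1 && has2)) next  # half-mapped: no alignment
      sides[[length(sides) + 1L]] <-
        list(cigars = th$cigar[order(th$mate)], nm = sum(th$nm),
             primary = all(th$primary))
    }
    out[[q]] <- sides
  }
  out
}
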