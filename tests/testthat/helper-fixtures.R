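# Shared fixture builders; everything is generated in code at test time.

# one alignment-table row (defaults: mapped primary first mate, 50M, NM 0)
aln_row <- function(qname, mate = 1L, rname = "ref", pos = 1000L,
                    cigar = "50M", nm = 0L, hi = 1L, primary = TRUE,
                    mapped = TRUE, paired = TRUE, strand = "+",
                    seq = NA_character_) {
  flag <- 0L
  if (paired) flag <- flag + 1L + 2L + (if (mate == 1L) 64L else 128L) +
      (if (mate == 1L) 32L else 16L)
  if (!mapped) flag <- flag + 4L
  if (!primary) flag <- flag + 256L
  data.frame(qname = qname, flag = flag, mate = mate, rname = rname,
             pos = pos, strand = strand, cigar = cigar, nm = nm,
             mapped = mapped, paired = paired, primary = primary, hi = hi,
             seq = seq, stringsAsFactors = FALSE)
}

# a full proper pair (two rows)
aln_pair <- function(qname, nm1 = 0L, nm2 = 0L, cigar1 = "50M",
                     cigar2 = "50M", pos = 1000L, hi = 1L, primary = TRUE) {
  rbind(aln_row(qname, 1L, pos = pos, cigar = cigar1, nm = nm1, hi = hi,
                primary = primary),
        aln_row(qname, 2L, pos = pos + 200L, cigar = cigar2, nm = nm2,
                hi = hi, primary = primary, strand = "-"))
}

with_header <- function(tab, len = c(ref = 100000L)) {
  attr(tab, "header") <- list(targets = len, text = NULL)
  tab
}

empty_tab <- function() with_header(sssort:::emit_empty_table())

# toy annotation written as a GTF tempfile:
#   gA: transcripts with exon sums 300 and 500 (sharing 100 nt) -> max 500
#   gU: exons [1,300] and [201,500] on chr2 -> union 500
#   gB: single 600-nt exon, overlapping nothing
write_toy_gtf <- function(path = tempfile(fileext = ".gtf")) {
  at <- function(g, t) sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  lines <- c(
    sprintf("chr1\ttoy\texon\t1\t300\t.\t+\t.\t%s", at("gA", "gA.t1")),
    sprintf("chr1\ttoy\texon\t201\t500\t.\t+\t.\t%s", at("gA", "gA.t2")),
    sprintf("chr1\ttoy\texon\t601\t800\t.\t+\t.\t%s", at("gA", "gA.t2")),
    sprintf("chr2\ttoy\texon\t1\t300\t.\t+\t.\t%s", at("gU", "gU.t1")),
    sprintf("chr2\ttoy\texon\t201\t500\t.\t+\t.\t%s", at("gU", "gU.t2")),
    sprintf("chr1\ttoy\texon\t2001\t2600\t.\t+\t.\t%s", at("gB", "gB.t1")))
  writeLines(lines, path)
  path
}
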