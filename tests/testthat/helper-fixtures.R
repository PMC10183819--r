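# Small in-code fixtures shared across test files.

# A point signal: all counts at explicit (pos, count) pairs on one contig.
point_signal <- function(pos, count, contig = "chr1", strand = "+") {
  base_signal(contig = rep(contig, length(pos)),
              strand = rep(strand, length(pos)),
              pos = as.integer(pos), count = count)
}

# A one-row transcript table.
one_transcript <- function(tss, strand = "+", contig = "chr1",
                           len = 1000L, id = "t1") {
  start <- if (strand == "+") tss else tss - len + 1L
  data.frame(gene_id = id, transcript_id = id, contig = contig,
             start = start, end = start + len, strand = strand,
             tss = tss, stringsAsFactors = FALSE)
}

# Write a FASTA file from a named character vector, return its path.
write_fasta_tmp <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  close(con)
  path
}

# The 2-position PWM used in scoring examples:
# pos1 A = 0.7 (others 0.1), pos2 T = 0.7 (others 0.1).
toy_pwm <- function() {
  pwm("toy", rbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.1, 0.1, 0.7)))
}
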