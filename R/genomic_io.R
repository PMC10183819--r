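## Coordinate conventions used throughout the package:
##   - all intervals are 0-based, half-open [start, end) (BED convention);
##   - single-base signals are keyed by 0-based position;
##   - strand is "+" or "-" ("." only where a format allows strandless data).

#' Single-base stranded signal
#'
#' The common currency for CAGE/STAP-seq 5'-end counts, PRO-seq active-site
#' counts and MNase fragment-center coverage: a sparse table of positive
#' counts keyed by (contig, strand, 0-based position).
#'
#' @param contig character vector of contig ids.
#' @param strand character vector, each "+" or "-".
#' @param pos integer vector of 0-based positions.
#' @param count numeric vector of positive counts.
#' @return A data.frame of class \code{base_signal} with columns
#'   \code{contig}, \code{strand}, \code{pos}, \code{count}, one row per
#'   occupied base, sorted, duplicate keys summed.
#' @export
base_signal <- function(contig = character(), strand = character(),
                        pos = integer(), count = numeric()) {
  n <- length(pos)
  if (length(contig) == 1L) contig <- rep(contig, n)
  if (length(strand) == 1L) strand <- rep(strand, n)
  if (length(count) == 1L) count <- rep(count, n)
  stopifnot(length(contig) == n, length(strand) == n, length(count) == n)
  if (n == 0L) {
    out <- data.frame(contig = character(), strand = character(),
                      pos = integer(), count = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("base_signal", "data.frame")
    return(out)
  }
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(pos < 0)) stop("positions must be >= 0")
  if (any(count <= 0)) stop("all counts must be positive")
  o <- order(contig, strand, pos)
  contig <- contig[o]; strand <- strand[o]
  pos <- as.integer(pos[o]); count <- count[o]
  new_grp <- c(TRUE, contig[-1L] != contig[-n] |
                 strand[-1L] != strand[-n] | pos[-1L] != pos[-n])
  grp <- cumsum(new_grp)
  first <- which(new_grp)
  out <- data.frame(contig = contig[first], strand = strand[first],
                    pos = pos[first],
                    count = as.numeric(rowsum(count, grp)[, 1L]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("base_signal", "data.frame")
  out
}

#' Look up signal counts over a window
#'
#' @param signal a \code{\link{base_signal}}.
#' @param contig,strand single contig id and strand.
#' @param positions integer vector of 0-based positions.
#' @return Numeric vector of counts, 0 at unoccupied positions.
#' @export
signal_counts <- function(signal, contig, strand, positions) {
  sel <- signal$contig == contig & signal$strand == strand
  idx <- match(positions, signal$pos[sel])
  cnt <- signal$count[sel][idx]
  cnt[is.na(cnt)] <- 0
  cnt
}

#' Read a genome from FASTA
#'
#' Sequences are uppercased and validated against the A,C,G,T,N alphabet.
#'
#' @param path FASTA file.
#' @return Named character vector, one uppercase sequence per contig,
#'   insertion order preserved.
#' @export
read_genome <- function(path) {
  dna <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(dna))
  if (anyDuplicated(ids)) {
    stop("duplicate contig id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(dna))
  if (any(nchar(seqs) == 0L)) stop("empty sequence in FASTA")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("character outside {A,C,G,T,N} in contig: ",
         paste(ids[bad], collapse = ", "))
  }
  setNames(seqs, ids)
}

#' Write a genome to FASTA
#'
#' @param genome named character vector as returned by \code{\link{read_genome}}.
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Load transcript models
#'
#' Reads transcript models and derives the strand-aware TSS: the interval
#' start for "+" transcripts and end - 1 for "-" transcripts (0-based).
#'
#' @param path input file.
#' @param dialect "bed12" (0-based half-open, 12 columns) or "gtf"
#'   (GTF-lite: only \code{transcript} feature rows are used; 1-based
#'   inclusive coordinates converted to 0-based half-open).
#' @return data.frame with columns gene_id, transcript_id, contig, start,
#'   end, strand, tss.
#' @export
load_transcripts <- function(path, dialect = c("bed12", "gtf")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed12") {
    tab <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(tab) != 12L) {
      stop("BED12 requires 12 columns, got ", ncol(tab), " in ", path)
    }
    df <- data.frame(gene_id = as.character(tab[[4L]]),
                     transcript_id = as.character(tab[[4L]]),
                     contig = as.character(tab[[1L]]),
                     start = as.integer(tab[[2L]]),
                     end = as.integer(tab[[3L]]),
                     strand = as.character(tab[[6L]]),
                     stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "transcript"]
    df <- data.frame(gene_id = as.character(gr$gene_id),
                     transcript_id = as.character(gr$transcript_id),
                     contig = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     stringsAsFactors = FALSE)
  }
  if (any(!df$strand %in% c("+", "-"))) {
    stop("transcript strand must be '+' or '-'")
  }
  if (any(df$start >= df$end)) stop("transcript with start >= end")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df
}

#' Write transcript models as BED12
#'
#' Single-block BED12 (the package models transcripts as plain intervals).
#'
#' @param transcripts data.frame as from \code{\link{load_transcripts}}.
#' @param path output file.
#' @export
write_transcripts_bed12 <- function(transcripts, path) {
  tab <- data.frame(transcripts$contig, transcripts$start, transcripts$end,
                    transcripts$transcript_id, 0L, transcripts$strand,
                    transcripts$start, transcripts$end, "0,0,0", 1L,
                    paste0(transcripts$end - transcripts$start, ","),
                    "0,")
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map a PRO-seq alignment to the polymerase active site
#'
#' PRO-seq sequences the 3' end of nascent RNA, so the read's 5' alignment
#' coordinate marks the base the polymerase was transcribing, on the strand
#' opposite to the alignment strand. Reads are switched to the transcript
#' strand and shortened to that single base.
#'
#' @param reads data.frame with columns contig, start, end, strand.
#' @return data.frame with columns contig, strand (transcript strand) and
#'   pos (active-site base, 0-based).
#' @export
proseq_active_site <- function(reads) {
  if (any(!reads$strand %in% c("+", "-"))) {
    stop("unstranded read: strand must be '+' or '-'")
  }
  if (any(reads$start >= reads$end)) stop("read with start >= end")
  data.frame(contig = reads$contig,
             strand = ifelse(reads$strand == "+", "-", "+"),
             pos = ifelse(reads$strand == "+", reads$start,
                          reads$end - 1L),
             stringsAsFactors = FALSE)
}

#' Collapse reads to unique UMIs per genomic position
#'
#' Reads are keyed by (contig, transcript strand, active-site position);
#' the signal value at a key is the number of distinct UMIs observed there.
#' Reads whose UMI contains N are dropped; the drop count is attached as
#' attribute \code{n_dropped_umi}.
#'
#' @param reads data.frame with columns contig, start, end, strand, umi.
#' @return A \code{\link{base_signal}} of unique-molecule counts.
#' @export
umi_collapse <- function(reads) {
  if (nrow(reads) == 0L) {
    out <- base_signal()
    attr(out, "n_dropped_umi") <- 0L
    return(out)
  }
  if (any(!nchar(reads$umi) %in% 8:10)) {
    stop("UMI length must be 8-10 nt")
  }
  if (any(grepl("[^ACGTN]", reads$umi))) {
    stop("UMI contains character outside {A,C,G,T,N}")
  }
  drop <- grepl("N", reads$umi, fixed = TRUE)
  n_dropped <- sum(drop)
  reads <- reads[!drop, , drop = FALSE]
  if (nrow(reads) == 0L) {
    out <- base_signal()
    attr(out, "n_dropped_umi") <- n_dropped
    return(out)
  }
  site <- proseq_active_site(reads)
  key <- paste(site$contig, site$strand, site$pos, sep = "\r")
  uniq <- !duplicated(paste(key, reads$umi, sep = "\r"))
  tab <- table(key[uniq])
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- base_signal(contig = vapply(parts, `[`, "", 1L),
                     strand = vapply(parts, `[`, "", 2L),
                     pos = as.integer(vapply(parts, `[`, "", 3L)),
                     count = as.numeric(tab))
  attr(out, "n_dropped_umi") <- n_dropped
  out
}

#' Read an aligned-read table
#'
#' TSV with columns contig, start, end, strand, umi (header optional,
#' detected from the first line).
#'
#' @param path input TSV.
#' @return data.frame of reads.
#' @export
read_read_table <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("contig", first, fixed = TRUE)
  tab <- read.table(path, sep = "\t", header = header,
                    stringsAsFactors = FALSE)
  if (ncol(tab) != 5L) stop("read table requires 5 columns")
  names(tab) <- c("contig", "start", "end", "strand", "umi")
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab
}

#' Write a stranded signal as a bedGraph pair
#'
#' Writes \code{<prefix>.plus.bedGraph} and \code{<prefix>.minus.bedGraph},
#' one single-base interval per occupied position. With
#' \code{per_million = TRUE} values are scaled by 1e6 / total count.
#'
#' @param signal a \code{\link{base_signal}}.
#' @param prefix output path prefix.
#' @param per_million scale values to counts per million?
#' @return Character vector of the two file paths, invisibly.
#' @export
write_signal_bedgraph <- function(signal, prefix, per_million = FALSE) {
  value <- signal$count
  if (per_million) {
    total <- sum(signal$count)
    if (total > 0) value <- value * 1e6 / total
  }
  paths <- paste0(prefix, c(".plus.bedGraph", ".minus.bedGraph"))
  for (i in 1:2) {
    st <- c("+", "-")[i]
    sel <- signal$strand == st
    gr <- GenomicRanges::GRanges(
      seqnames = signal$contig[sel],
      ranges = IRanges::IRanges(start = signal$pos[sel] + 1L, width = 1L),
      score = value[sel])
    rtracklayer::export(gr, paths[i], format = "bedGraph")
  }
  invisible(paths)
}

#' Read a stranded signal from a bedGraph pair
#'
#' Inverse of \code{\link{write_signal_bedgraph}} (for unscaled output the
#' round trip is exact). Multi-base bedGraph intervals are expanded to
#' per-base entries.
#'
#' @param prefix path prefix of a \code{.plus.bedGraph}/\code{.minus.bedGraph}
#'   pair.
#' @return A \code{\link{base_signal}}.
#' @export
read_signal_bedgraph <- function(prefix) {
  pieces <- list()
  for (i in 1:2) {
    st <- c("+", "-")[i]
    path <- paste0(prefix, c(".plus.bedGraph", ".minus.bedGraph")[i])
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0L) next
    if (any(gr$score < 0)) stop("negative value in ", path)
    if (any(gr$score == 0)) gr <- gr[gr$score > 0]
    if (length(gr) == 0L) next
    w <- GenomicRanges::width(gr)
    pieces[[st]] <- data.frame(
      contig = rep(as.character(GenomicRanges::seqnames(gr)), w),
      strand = st,
      pos = unlist(lapply(seq_along(gr), function(j) {
        seq.int(GenomicRanges::start(gr)[j] - 1L,
                GenomicRanges::end(gr)[j] - 1L)
      })),
      count = rep(gr$score, w),
      stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0L) return(base_signal())
  df <- do.call(rbind, pieces)
  base_signal(df$contig, df$strand, df$pos, df$count)
}

#' Read MNase fragments from BED
#'
#' Strandless BED3+ intervals; only the first three columns are used.
#'
#' @param path BED file.
#' @return data.frame with columns contig, start, end.
#' @export
read_fragments_bed <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("fragment BED requires at least 3 columns")
  df <- data.frame(contig = as.character(tab[[1L]]),
                   start = as.integer(tab[[2L]]),
                   end = as.integer(tab[[3L]]),
                   stringsAsFactors = FALSE)
  if (any(df$end - df$start < 1L)) stop("fragment of length < 1")
  df
}

#' Write MNase fragments as BED3
#'
#' @param fragments data.frame with columns contig, start, end.
#' @param path output file.
#' @export
write_fragments_bed <- function(fragments, path) {
  write.table(fragments[, c("contig", "start", "end")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
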