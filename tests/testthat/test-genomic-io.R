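test_that("FASTA reading uppercases, keeps order, and validates", {
  path <- write_fasta_tmp(c(a = "acgt", b = "GGNNCC"))
  g <- read_genome(path)
  expect_identical(g, c(a = "ACGT", b = "GGNNCC"))

  dup <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), dup)
  expect_error(read_genome(dup), "duplicate contig")

  bad <- write_fasta_tmp(c(x = "ACGU"))
  expect_error(read_genome(bad), "outside")
})

test_that("genome FASTA round trip is the identity", {
  g <- c(chr1 = "ACGTACGTNNACGT", chr2 = "TTTTGGGG")
  path <- tempfile(fileext = ".fa")
  write_genome(g, path)
  expect_identical(read_genome(path), g)
})

test_that("BED12 transcripts derive the strand-aware TSS", {
  path <- tempfile(fileext = ".bed")
  rows <- c(paste(c("chr1", 100, 500, "t1", 0, "+", 100, 500, "0,0,0",
                    1, "400,", "0,"), collapse = "\t"),
            paste(c("chr1", 100, 500, "t2", 0, "-", 100, 500, "0,0,0",
                    1, "400,", "0,"), collapse = "\t"))
  writeLines(rows, path)
  tx <- load_transcripts(path, "bed12")
  expect_equal(tx$tss, c(100L, 499L))

  short <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t500\tt1\t0", short)
  expect_error(load_transcripts(short, "bed12"), "12 columns")

  unstranded <- tempfile(fileext = ".bed")
  writeLines(paste(c("chr1", 100, 500, "t1", 0, ".", 100, 500, "0,0,0",
                     1, "400,", "0,"), collapse = "\t"), unstranded)
  expect_error(load_transcripts(unstranded, "bed12"), "strand")
})

test_that("BED12 write/read round trips the transcript table", {
  tx <- rbind(one_transcript(1000L, "+", id = "t1"),
              one_transcript(5000L, "-", id = "t2"))
  path <- tempfile(fileext = ".bed")
  write_transcripts_bed12(tx, path)
  back <- load_transcripts(path, "bed12")
  expect_equal(back[, c("transcript_id", "contig", "start", "end",
                        "strand", "tss")],
               tx[, c("transcript_id", "contig", "start", "end",
                      "strand", "tss")])
})

test_that("PRO-seq reads map to the active site on the opposite strand", {
  reads <- data.frame(contig = "chr1", start = c(100L, 100L),
                      end = c(150L, 150L), strand = c("+", "-"))
  site <- proseq_active_site(reads)
  expect_equal(site$strand, c("-", "+"))
  expect_equal(site$pos, c(100L, 149L))

  expect_error(proseq_active_site(
    data.frame(contig = "chr1", start = 1L, end = 5L, strand = ".")),
    "unstranded")

  # the active site always lies inside the aligned interval
  set.seed(7)
  r <- data.frame(contig = "c", start = sample.int(1000, 50),
                  strand = sample(c("+", "-"), 50, TRUE))
  r$end <- r$start + sample.int(80, 50)
  s <- proseq_active_site(r)
  expect_true(all(s$pos >= r$start & s$pos < r$end))
})

test_that("umi_collapse counts distinct UMIs per active-site position", {
  reads <- data.frame(
    contig = "chr1",
    start = c(100L, 100L, 100L, 200L),
    end = c(150L, 150L, 150L, 260L),
    strand = c("+", "+", "+", "+"),
    umi = c("ACGTACGT", "ACGTACGT", "TTTTACGT", "ACGTACGT"),
    stringsAsFactors = FALSE)
  sig <- umi_collapse(reads)
  # three reads at one key with UMIs {X, X, Y} -> 2; same UMI at another
  # key counts once there too
  expect_equal(signal_counts(sig, "chr1", "-", 100L), 2)
  expect_equal(signal_counts(sig, "chr1", "-", 200L), 1)
  expect_equal(attr(sig, "n_dropped_umi"), 0L)

  empty <- umi_collapse(reads[0, ])
  expect_equal(nrow(empty), 0L)

  withN <- reads
  withN$umi[1] <- "ACGTACGN"
  sigN <- umi_collapse(withN)
  expect_equal(attr(sigN, "n_dropped_umi"), 1L)
  expect_equal(signal_counts(sigN, "chr1", "-", 100L), 2)

  expect_error(umi_collapse(transform(reads, umi = "ACG")), "8-10")
})

test_that("umi_collapse is invariant to read order and duplication", {
  set.seed(11)
  reads <- data.frame(
    contig = "chr1",
    start = sample(c(10L, 20L, 30L), 40, TRUE),
    strand = sample(c("+", "-"), 40, TRUE),
    umi = sample(c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG"), 40, TRUE),
    stringsAsFactors = FALSE)
  reads$end <- reads$start + 50L
  ref <- umi_collapse(reads)
  shuf <- umi_collapse(reads[sample.int(nrow(reads)), ])
  dupd <- umi_collapse(rbind(reads, reads))
  expect_equal(as.data.frame(shuf), as.data.frame(ref))
  expect_equal(as.data.frame(dupd), as.data.frame(ref))
  # collapsed counts never exceed raw read counts at a key
  raw <- table(paste(reads$contig,
                     ifelse(reads$strand == "+", "-", "+"),
                     ifelse(reads$strand == "+", reads$start,
                            reads$end - 1L)))
  key <- paste(ref$contig, ref$strand, ref$pos)
  expect_true(all(ref$count <= as.vector(raw[key])))
})

test_that("stranded bedGraph pairs round trip exactly", {
  set.seed(3)
  sig <- base_signal(contig = sample(c("c1", "c2"), 30, TRUE),
                     strand = sample(c("+", "-"), 30, TRUE),
                     pos = sample.int(500, 30),
                     count = sample.int(20, 30, TRUE))
  prefix <- tempfile()
  write_signal_bedgraph(sig, prefix)
  back <- read_signal_bedgraph(prefix)
  expect_equal(as.data.frame(back), as.data.frame(sig))
})

test_that("per-million scaling divides by total/1e6", {
  sig <- point_signal(c(10, 20), c(1.5e6, 0.5e6))
  prefix <- tempfile()
  write_signal_bedgraph(sig, prefix, per_million = TRUE)
  back <- read_signal_bedgraph(prefix)
  expect_equal(back$count, c(1.5e6, 0.5e6) * 0.5)
})

test_that("malformed and negative bedGraph input is rejected", {
  prefix <- tempfile()
  writeLines("c1\t10\t5\t3", paste0(prefix, ".plus.bedGraph"))
  writeLines(character(0), paste0(prefix, ".minus.bedGraph"))
  expect_error(read_signal_bedgraph(prefix))

  prefix2 <- tempfile()
  writeLines("c1\t5\t6\t-3", paste0(prefix2, ".plus.bedGraph"))
  writeLines(character(0), paste0(prefix2, ".minus.bedGraph"))
  expect_error(read_signal_bedgraph(prefix2), "negative")
})

test_that("fragment BED round trips and rejects empty fragments", {
  fr <- data.frame(contig = c("c1", "c1"), start = c(5L, 50L),
                   end = c(150L, 220L))
  path <- tempfile(fileext = ".bed")
  write_fragments_bed(fr, path)
  expect_equal(read_fragments_bed(path), fr)

  bad <- tempfile(fileext = ".bed")
  writeLines("c1\t10\t10", bad)
  expect_error(read_fragments_bed(bad), "length")
})
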