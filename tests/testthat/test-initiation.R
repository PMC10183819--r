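mk_profile <- function(counts, offsets = seq_along(counts) - 1L) {
  structure(list(offsets = as.integer(offsets), counts = counts),
            class = "initiation_profile")
}

test_that("profile extraction flips minus-strand promoters into sense", {
  sig_p <- point_signal(105, 3)
  prof_p <- extract_profile(sig_p, "chr1", "+", 100L, 10, 10)
  expect_equal(prof_p$counts[prof_p$offsets == 5], 3)

  sig_m <- point_signal(95, 3, strand = "-")
  prof_m <- extract_profile(sig_m, "chr1", "-", 100L, 10, 10)
  expect_equal(prof_m$counts[prof_m$offsets == 5], 3)

  empty <- extract_profile(sig_p, "chr1", "+", 5000L, 10, 10)
  expect_true(all(empty$counts == 0))
})

test_that("dominant TSS takes the argmax with upstream tie-breaking", {
  expect_equal(dominant_tss(mk_profile(c(0, 5, 2), -1:1)), 0L)
  expect_equal(dominant_tss(mk_profile(c(3, 3), 0:1)), 0L)
  expect_error(dominant_tss(mk_profile(c(0, 0))), "all-zero")
})

test_that("dominant fraction divides the dominant count by the total", {
  expect_equal(dominant_fraction(mk_profile(5)), 1.0)
  expect_equal(dominant_fraction(mk_profile(c(6, 3, 1))), 0.6)
  expect_equal(dominant_fraction(mk_profile(c(3, 3, 3, 1))), 0.3)
})

test_that("activated-TSS counting distinguishes strict and inclusive", {
  p <- mk_profile(c(10, 3, 2, 1))
  expect_equal(count_activated_tss(p, 0.2, "strict"), 2L)
  expect_equal(count_activated_tss(p, 0.2, "inclusive"), 3L)
  expect_equal(count_activated_tss(mk_profile(5), 0.2, "strict"), 1L)
  expect_equal(count_activated_tss(mk_profile(5), 0.2, "inclusive"), 1L)
  expect_error(count_activated_tss(p, 1.5), "rel")
})

test_that("initiation width spans covered positions at the count floor", {
  expect_equal(initiation_width(mk_profile(c(0, 4, 0, 1, 2, 0))), 4L)
  expect_equal(initiation_width(mk_profile(5)), 1L)
  expect_equal(initiation_width(mk_profile(c(1, 1, 5)), floor = 2), 1L)
  expect_error(initiation_width(mk_profile(c(1, 1)), floor = 2), "floor")
})

test_that("shape metrics are invariant to scaling all counts", {
  set.seed(51)
  for (i in 1:20) {
    counts <- sample(0:5, 6, TRUE)
    if (all(counts == 0)) counts[2] <- 1
    p1 <- mk_profile(counts)
    p7 <- mk_profile(counts * 7L)
    expect_equal(dominant_tss(p1), dominant_tss(p7))
    expect_equal(dominant_fraction(p1), dominant_fraction(p7))
    expect_equal(count_activated_tss(p1, 0.2, "strict"),
                 count_activated_tss(p7, 0.2, "strict"))
    expect_equal(count_activated_tss(p1, 0.2, "inclusive"),
                 count_activated_tss(p7, 0.2, "inclusive"))
  }
})

test_that("strict counts never exceed inclusive counts", {
  set.seed(52)
  for (i in 1:30) {
    counts <- sample(0:3, 5, TRUE)
    if (all(counts == 0)) counts[1] <- 1
    p <- mk_profile(counts)
    s <- count_activated_tss(p, 0.2, "strict")
    incl <- count_activated_tss(p, 0.2, "inclusive")
    expect_lte(s, incl)
    expect_gte(s, 1L)
    f <- dominant_fraction(p)
    expect_true(f > 0 && f <= 1)
    expect_equal(f == 1, sum(counts > 0) == 1)
  }
})

test_that("-1/+1 dinucleotides are read strand-aware", {
  g <- c(chr1 = "TTGCATT")
  # TSS on the A (index 4, 0-based): -1 base C, +1 base A -> "CA"
  pr <- data.frame(contig = "chr1", strand = "+", tss = 4L)
  tab <- dinucleotide_at_tss(g, pr)
  expect_equal(unname(tab["CA"]), 1L)
  expect_equal(sum(tab), 1L)

  g2 <- c(c2 = "AATGCC")
  prm <- data.frame(contig = "c2", strand = "-", tss = 3L)
  tab2 <- dinucleotide_at_tss(g2, prm)
  expect_equal(unname(tab2["GC"]), 1L)

  edge <- data.frame(contig = "chr1", strand = "+", tss = 0L)
  tabe <- dinucleotide_at_tss(g, edge)
  expect_equal(sum(tabe), 0L)
  expect_equal(attr(tabe, "n_skipped"), 1L)
})

test_that("metaprofiles average sum-normalized profiles", {
  sig <- base_signal(contig = c("c1", "c1"), strand = c("+", "+"),
                     pos = c(100L, 200L), count = c(4, 9))
  anchors <- data.frame(contig = "c1", strand = "+",
                        anchor = c(100L, 200L))
  mp <- anchored_metaprofile(sig, anchors, flank = 10)
  expect_equal(mp$mean[mp$offset == 0], 1.0)
  expect_equal(sum(mp$mean), 1.0)

  # one promoter at -10, one at +10 -> 0.5 at each
  sig2 <- base_signal(contig = c("c1", "c1"), strand = c("+", "+"),
                      pos = c(90L, 210L), count = c(4, 4))
  mp2 <- anchored_metaprofile(sig2, anchors, flank = 10)
  expect_equal(mp2$mean[mp2$offset == -10], 0.5)
  expect_equal(mp2$mean[mp2$offset == 10], 0.5)

  expect_error(anchored_metaprofile(sig, anchors[0, ], flank = 10),
               "eligible")
})

test_that("single-occurrence filtering excludes multi-motif promoters", {
  p <- consensus_pwm("m", "TATCGATA")
  one <- paste0(strrep("C", 40), "TATCGATA", strrep("C", 250))
  two <- paste0(strrep("C", 40), "TATCGATA", strrep("C", 30),
                "TATCGATA", strrep("C", 220))
  g <- c(c1 = one, c2 = two)
  pr <- data.frame(promoter_id = c("p1", "p2"),
                   contig = c("c1", "c2"), strand = "+",
                   tss = 130L, stringsAsFactors = FALSE)
  res <- motif_anchors(g, pr, p, threshold = 95, max_dist = 120)
  expect_equal(res$n_occurrences, c(1L, 2L))
  expect_equal(res$anchor[1], 40L)
  expect_true(is.na(res$anchor[2]))
  expect_equal(attr(res, "n_excluded"), 1L)
})

test_that("per-promoter metrics table matches the scalar functions", {
  cfg <- sim_config(n_per_class = 2, seed = 12)
  land <- simulate_promoter_landscape(cfg)
  cage <- simulate_cage(land$truth, cfg)
  m <- initiation_metrics(cage, land$truth)
  expect_equal(nrow(m), nrow(land$truth))
  i <- which(m$active)[1]
  prof <- extract_profile(cage, land$truth$contig[i],
                          land$truth$strand[i], land$truth$tss[i],
                          60, 120)
  expect_equal(m$dominant_offset[i], dominant_tss(prof))
  expect_equal(m$dominant_fraction[i], dominant_fraction(prof))
  expect_equal(m$width[i], initiation_width(prof))
})
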