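test_that("log-odds scoring matches hand arithmetic", {
  unif <- pwm("u", matrix(0.25, 3, 4))
  expect_equal(logodds_score("ACG", unif), 0)

  expect_equal(logodds_score("AT", toy_pwm()), 2 * log2(0.7 / 0.25),
               tolerance = 1e-12)
  expect_equal(2 * log2(0.7 / 0.25), 2.9709, tolerance = 1e-4)

  expect_equal(logodds_score("NN", toy_pwm()), 0)
  expect_error(logodds_score("A", toy_pwm()), "length")
})

test_that("percent scores hit 100 at consensus and 0 at anti-consensus", {
  p <- consensus_pwm("m", "TATAAA")
  seqc <- paste0("GGGGG", "TATAAA", "GGGGG")
  sc <- percent_score(seqc, anchor = 6, p, c(-3, 3))
  expect_equal(sc$percent, 100)
  expect_equal(sc$best_offset, 0L)

  # every position at its minimal base scores 0 (here: any non-consensus
  # base has equal minimal probability)
  anti <- paste0(strrep("C", 17))
  sc0 <- percent_score(anti, anchor = 6, p, c(-3, 3))
  expect_equal(sc0$percent, 0)
})

test_that("the midpoint sequence scores 50 on the toy PWM", {
  # brute force over all 16 dinucleotides confirms AC is the midpoint
  sc <- percent_score("AC", anchor = 1, toy_pwm(), c(0, 0))
  expect_equal(sc$percent, 50, tolerance = 1e-9)
})

test_that("percent_score agrees with a brute-force oracle", {
  set.seed(31)
  bases <- c("A", "C", "G", "T")
  for (trial in 1:10) {
    L <- sample(2:5, 1)
    mat <- matrix(rgamma(4 * L, 1), L, 4)
    mat <- mat / rowSums(mat)
    x <- pwm("r", mat)
    seqlen <- 20L
    s <- paste(sample(bases, seqlen, TRUE), collapse = "")
    anchor <- 10L
    win <- c(-4L, 4L)
    got <- percent_score(s, anchor, x, win)

    # oracle: independent raw scoring of every offset; bounds from
    # enumerating all 4^L sequences
    lo <- log2(mat / 0.25)
    raw <- sapply(win[1]:win[2], function(o) {
      w <- substr(s, anchor + o, anchor + o + L - 1L)
      b <- match(strsplit(w, "")[[1]], bases)
      sum(lo[cbind(1:L, b)])
    })
    all_seqs <- do.call(expand.grid, rep(list(1:4), L))
    all_scores <- apply(all_seqs, 1, function(b) sum(lo[cbind(1:L, b)]))
    oracle <- 100 * (max(raw) - min(all_scores)) /
      (max(all_scores) - min(all_scores))
    expect_equal(got$percent, oracle, tolerance = 1e-9)
  }
})

test_that("threshold flags use strictly-greater semantics", {
  percent <- rbind(p1 = c(TATA = 90, INR = 95, DPE = 98, TCT = 95,
                          Ohler1 = 95, Ohler6 = 97, Ohler7 = 95,
                          DRE = 98.5),
                   p2 = c(TATA = 90.1, INR = 10, DPE = 10, TCT = 10,
                          Ohler1 = 10, Ohler6 = 10, Ohler7 = 10,
                          DRE = 10))
  flags <- apply_thresholds(percent)
  expect_false(flags["p1", "TATA"])   # exactly 90 is not a match
  expect_false(flags["p1", "INR"])
  expect_true(flags["p1", "DRE"])     # 98.5 > 98
  expect_true(flags["p2", "TATA"])

  expect_error(apply_thresholds(percent[, 1:3]), "lacks")
})

test_that("exclusive class assignment follows the precedence order", {
  motifs <- c("TCT", "TATA", "DPE", "INR", "DRE", "Ohler1", "Ohler6")
  mk <- function(on) {
    m <- matrix(FALSE, 1, length(motifs), dimnames = list("p", motifs))
    m[, on] <- TRUE
    m
  }
  expect_equal(unname(assign_class(mk(c("TATA", "INR")))), "TATA")
  expect_equal(unname(assign_class(mk("Ohler6"))), "Ohler1/6")
  expect_equal(unname(assign_class(mk(character(0)))), "other")
  expect_equal(unname(assign_class(mk(c("TCT", "DRE")))), "TCT")
  expect_equal(unname(assign_class(mk(c("DPE", "INR")))), "DPE")
})

test_that("k-means overview recovers well-separated score blocks", {
  set.seed(41)
  block1 <- matrix(rnorm(40 * 3, 10, 1), 40)
  block2 <- matrix(rnorm(40 * 3, 90, 1), 40)
  scores <- rbind(block1, block2)
  rownames(scores) <- sprintf("p%02d", 1:80)
  km <- kmeans_overview(scores, k = 2, seed = 1)
  expect_equal(length(unique(km$assignments[1:40])), 1L)
  expect_equal(length(unique(km$assignments[41:80])), 1L)
  expect_false(km$assignments[1] == km$assignments[41])

  km1 <- kmeans_overview(scores, k = 1, seed = 1)
  expect_equal(as.vector(km1$centers), colMeans(scores))

  expect_error(kmeans_overview(scores, k = 81), "exceeds")
})

test_that("prototype selection applies activity and strict score rules", {
  motifs <- c("TATA", "INR", "DPE", "TCT", "DRE", "Ohler1", "Ohler6",
              "Ohler7")
  base <- setNames(rep(10, length(motifs)), motifs)
  tbl <- rbind(
    good = replace(base, "TATA", 96),
    dpe_high = replace(replace(base, "TATA", 96), "DPE", 92),
    inactive = replace(base, "TATA", 96))
  sel <- select_prototypes(tbl, active = c(TRUE, TRUE, FALSE))
  expect_true("good" %in% sel$TATA)
  expect_false("dpe_high" %in% sel$TATA)   # forbidden DPE < 90 violated
  expect_false("inactive" %in% sel$TATA)

  bad_rule <- list(X = list(required = c(NOPE = 50), forbidden = c()))
  expect_error(select_prototypes(tbl, active = rep(TRUE, 3),
                                 rules = bad_rule), "unknown motif")
})

test_that("class assignment recovers generator classes on synthetic promoters", {
  cfg <- sim_config(n_per_class = 10, seed = 3)
  land <- simulate_promoter_landscape(cfg)
  sc <- score_promoters(land$genome, land$truth)
  lab <- assign_class(apply_thresholds(sc$percent))
  expect_gte(mean(lab == land$truth$class), 0.95)
})

test_that("cage_tpm measures promoter-local activity per million tags", {
  sig <- base_signal(contig = c("c1", "c1"), strand = c("+", "+"),
                     pos = c(100L, 5000L), count = c(30, 70))
  pr <- data.frame(contig = "c1", strand = "+", tss = 100L)
  expect_equal(cage_tpm(sig, pr), 0.3 * 1e6)
})

test_that("PWM text files round trip", {
  pwms <- default_pwm_set()[1:3]
  path <- tempfile(fileext = ".txt")
  write_pwms(pwms, path)
  back <- read_pwms(path)
  expect_equal(names(back), names(pwms))
  for (m in names(pwms)) {
    expect_equal(back[[m]]$mat, pwms[[m]]$mat, tolerance = 1e-12)
  }
})
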