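## Spike-in normalization, exact down-regulation calls, Fisher motif
## enrichment, ChIP z-scores, and candidate-intermediary set intersection.

#' Spike-in size factors
#'
#' Per-sample normalization factors proportional to the spike-in read
#' tally, rescaled to geometric mean 1. Dividing a sample's counts by its
#' factor yields per-cell-comparable values, making global transcriptional
#' shifts measurable.
#'
#' @param spike_reads positive numeric vector of per-sample spike-in read
#'   tallies.
#' @return Named numeric vector of size factors (geometric mean 1).
#' @export
spike_size_factors <- function(spike_reads) {
  if (any(spike_reads <= 0)) stop("zero spike reads in a sample")
  factors <- spike_reads / exp(mean(log(spike_reads)))
  if (!is.null(names(spike_reads))) names(factors) <- names(spike_reads)
  factors
}

#' Naive library-size factors
#'
#' Total-count normalization (geometric mean 1); provided as the contrast
#' to \code{\link{spike_size_factors}} — under a global transcriptional
#' shift it erases the shift.
#'
#' @param counts gene x sample count matrix.
#' @return Named numeric vector of size factors.
#' @export
library_size_factors <- function(counts) {
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("sample with zero total counts")
  totals / exp(mean(log(totals)))
}

#' Exact conditional ratio test
#'
#' Conditional on the total n = c + t, the depleted-condition total t is
#' Binomial(n, pi0) under the null of no expression change, with pi0 the
#' depleted share of the size factors. The two-sided p-value sums the
#' probabilities of all outcomes no more probable than the observed one.
#'
#' @param c,t summed counts in the control and depleted conditions.
#' @param control_factor_sum,depleted_factor_sum sums of the size factors
#'   of the samples entering each total.
#' @return Two-sided p-value in (0, 1], or NA when c = t = 0 (not
#'   testable).
#' @export
exact_ratio_test <- function(c, t, control_factor_sum = 1,
                             depleted_factor_sum = 1) {
  n <- c + t
  if (n == 0) return(NA_real_)
  pi0 <- depleted_factor_sum / (control_factor_sum + depleted_factor_sum)
  dens <- dbinom(0:n, n, pi0)
  obs <- dens[t + 1L]
  min(1, sum(dens[dens <= obs]))
}

#' Benjamini-Hochberg q-values
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return Step-up adjusted q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call down-regulated genes
#'
#' Fold changes come from size-factor-normalized condition sums with a
#' pseudocount of 0.5; p-values from \code{\link{exact_ratio_test}} on
#' replicate-summed raw counts; q-values by Benjamini-Hochberg. A gene is
#' called down when its fold change is at least \code{fold} down and
#' q < \code{fdr}. Genes whose normalized total is below
#' \code{min_norm_total} are reported as not testable.
#'
#' @param counts gene x sample integer count matrix.
#' @param samples data.frame with columns sample, condition ("control" or
#'   "depleted") matching \code{colnames(counts)}.
#' @param factors per-sample size factors (e.g.
#'   \code{\link{spike_size_factors}}).
#' @param fold fold-change threshold (calls require
#'   log2FC <= -log2(fold)).
#' @param fdr FDR threshold.
#' @param min_norm_total coverage floor on the normalized total.
#' @return data.frame: gene, log2fc, p, q, testable, down.
#' @export
call_downregulated <- function(counts, samples, factors,
                               fold = 1.5, fdr = 0.05,
                               min_norm_total = 10) {
  stopifnot(ncol(counts) == nrow(samples),
            length(factors) == nrow(samples))
  ctl <- samples$condition == "control"
  dep <- samples$condition == "depleted"
  if (!any(ctl) || !any(dep)) stop("both conditions must be present")
  norm <- sweep(counts, 2, factors, "/")
  ctl_norm <- rowSums(norm[, ctl, drop = FALSE])
  dep_norm <- rowSums(norm[, dep, drop = FALSE])
  log2fc <- log2((dep_norm + 0.5) / (ctl_norm + 0.5))
  c_raw <- rowSums(counts[, ctl, drop = FALSE])
  t_raw <- rowSums(counts[, dep, drop = FALSE])
  testable <- (ctl_norm + dep_norm) >= min_norm_total
  p <- rep(NA_real_, nrow(counts))
  fc_sum <- sum(factors[ctl]); fd_sum <- sum(factors[dep])
  p[testable] <- vapply(which(testable), function(g) {
    exact_ratio_test(c_raw[g], t_raw[g], fc_sum, fd_sum)
  }, 0)
  q <- bh_fdr(p)
  down <- testable & !is.na(q) & log2fc <= -log2(fold) & q < fdr
  data.frame(gene = rownames(counts), log2fc = log2fc, p = p, q = q,
             testable = testable, down = down,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fisher motif enrichment in a down-regulated set
#'
#' For each motif, tests enrichment of motif-positive promoters among the
#' down-regulated set against the expressed background with Fisher's exact
#' test: the two-sided p-value sums the hypergeometric probabilities of
#' all tables with the observed margins that are no more probable than the
#' observed one. The odds ratio is ad/bc, with a Haldane correction of 0.5
#' per cell iff any cell is zero.
#'
#' @param down character vector of down-regulated gene/promoter ids (must
#'   be a subset of \code{expressed}).
#' @param expressed character vector of expressed background ids.
#' @param flags logical promoter x motif matrix (rownames = ids).
#' @return data.frame: motif, a, b, c, d, odds_ratio, log2_odds_ratio, p.
#' @export
fisher_motif_enrichment <- function(down, expressed, flags) {
  if (length(down) == 0L) stop("empty down-regulated set")
  if (length(expressed) == 0L) stop("empty expressed background")
  if (!all(down %in% expressed)) {
    stop("down set must be a subset of the expressed background")
  }
  expressed <- intersect(expressed, rownames(flags))
  down <- intersect(down, expressed)
  rest <- setdiff(expressed, down)
  fisher_p <- function(a, b, c_, d) {
    # two-sided: sum hypergeometric probabilities <= that of the observed
    # table, over all tables with the same margins
    m1 <- a + b; k <- a + c_
    a_range <- max(0L, k - (c_ + d)):min(m1, k)
    dens <- stats::dhyper(a_range, m1, c_ + d, k)
    min(1, sum(dens[dens <= dens[match(a, a_range)]]))
  }
  res <- lapply(colnames(flags), function(m) {
    pos <- rownames(flags)[flags[, m]]
    a <- sum(down %in% pos); b <- length(down) - a
    c_ <- sum(rest %in% pos); d <- length(rest) - c_
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    or_tab <- if (any(tab == 0)) tab + 0.5 else tab
    or <- (or_tab[1, 1] * or_tab[2, 2]) / (or_tab[1, 2] * or_tab[2, 1])
    p <- fisher_p(a, b, c_, d)
    data.frame(motif = m, a = a, b = b, c = c_, d = d, odds_ratio = or,
               log2_odds_ratio = log2(or), p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' ChIP signal z-scores across promoter classes
#'
#' Per promoter, ChIP coverage over a TSS-centered window is normalized by
#' the gene's transcription level (nascent counts over gene length); class
#' means of these values are converted, per factor, to z-scores across the
#' class means. Genes with zero nascent signal are excluded and tallied.
#'
#' @param chip promoter x factor matrix of ChIP coverage (1-kb TSS-centered
#'   window).
#' @param nascent per-promoter nascent (PRO-seq) counts.
#' @param lengths per-promoter gene lengths.
#' @param classes per-promoter class labels.
#' @return List with \code{z} (class x factor z-score matrix),
#'   \code{class_means} and \code{n_excluded}.
#' @export
chip_zscore <- function(chip, nascent, lengths, classes) {
  stopifnot(nrow(chip) == length(nascent),
            length(nascent) == length(lengths),
            length(lengths) == length(classes))
  keep <- nascent > 0
  n_excluded <- sum(!keep)
  chip <- chip[keep, , drop = FALSE]
  value <- chip / (nascent[keep] / lengths[keep])
  cls <- classes[keep]
  if (length(unique(cls)) < 2L) {
    stop("fewer than two classes with data")
  }
  class_means <- apply(value, 2, function(v) {
    tapply(v, cls, mean)
  })
  z <- apply(class_means, 2, function(mu) {
    s <- sd(mu)
    if (s == 0) rep(0, length(mu)) else (mu - mean(mu)) / s
  })
  rownames(z) <- rownames(class_means)
  list(z = z, class_means = class_means, n_excluded = n_excluded)
}

#' Candidate intermediary factors by set intersection
#'
#' Intersects each promoter type's bound-protein set with an interactor
#' set (e.g. an immunoprecipitation hit list).
#'
#' @param bound_sets named list of character vectors (proteins bound per
#'   promoter type).
#' @param interactors character vector of interactor identifiers.
#' @return Named list with \code{members} and \code{size} per promoter
#'   type.
#' @export
candidate_intermediaries <- function(bound_sets, interactors) {
  lapply(bound_sets, function(s) {
    m <- sort(intersect(s, interactors))
    list(members = m, size = length(m))
  })
}
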