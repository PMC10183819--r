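## Positional PWM scoring of core promoter sequence, percent-of-optimum
## normalization, thresholded motif flags, exclusive class assignment,
## k-means overview and prototype selection.

.BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param motif_id motif name.
#' @param mat L x 4 matrix of per-position base probabilities, columns in
#'   order A, C, G, T; each row must sum to 1.
#' @param background background base probabilities (default uniform).
#' @param pseudocount added to every cell before renormalization so all
#'   probabilities are positive.
#' @return Object of class \code{pwm}.
#' @export
pwm <- function(motif_id, mat, background = rep(0.25, 4),
                pseudocount = 0) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L || nrow(mat) < 2L) {
    stop("PWM must be an L x 4 matrix with L >= 2")
  }
  if (pseudocount > 0) mat <- mat + pseudocount
  mat <- mat / rowSums(mat)
  if (any(mat <= 0)) stop("PWM probabilities must be positive (use pseudocount)")
  if (any(abs(rowSums(mat) - 1) > 1e-9)) stop("PWM rows must sum to 1")
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-9) {
    stop("background must be positive and sum to 1")
  }
  colnames(mat) <- .BASES
  structure(list(motif_id = motif_id, mat = mat,
                 background = setNames(background, .BASES)),
            class = "pwm")
}

#' Build a PWM from a consensus string
#'
#' Each position puts \code{p_consensus} on the consensus base and the
#' remainder uniformly on the other three bases.
#'
#' @param motif_id motif name.
#' @param consensus string over A,C,G,T.
#' @param p_consensus probability of the consensus base.
#' @return A \code{\link{pwm}}.
#' @export
consensus_pwm <- function(motif_id, consensus, p_consensus = 0.85) {
  b <- strsplit(toupper(consensus), "")[[1]]
  if (any(!b %in% .BASES)) stop("consensus must be over A,C,G,T")
  mat <- matrix((1 - p_consensus) / 3, length(b), 4,
                dimnames = list(NULL, .BASES))
  mat[cbind(seq_along(b), match(b, .BASES))] <- p_consensus
  pwm(motif_id, mat)
}

#' Default motif consensus strings
#'
#' Consensus-like strings for the eight scored core promoter motifs,
#' approximating published Drosophila consensi. These drive both the
#' default PWM set and the motifs the simulator embeds.
#'
#' @return Named character vector.
#' @export
motif_consensus_set <- function() {
  c(TATA = "TATAAAA", INR = "TCAGTC", DPE = "GGTCGT",
    TCT = "TCTTTC", DRE = "TATCGATA", Ohler1 = "GGTCACACT",
    Ohler6 = "TTCGGTATTTT", Ohler7 = "CAGCTGTCCA")
}

#' Default PWM set
#'
#' @param p_consensus consensus-base probability per position.
#' @return Named list of \code{\link{pwm}} objects.
#' @export
default_pwm_set <- function(p_consensus = 0.85) {
  cons <- motif_consensus_set()
  setNames(lapply(names(cons), function(m)
    consensus_pwm(m, cons[[m]], p_consensus)), names(cons))
}

#' Default TSS-relative search windows
#'
#' Allowed motif-start offsets relative to the TSS (downstream positive),
#' bracketing the positions where each motif is expected.
#'
#' @return Named list of length-2 integer vectors \code{c(lo, hi)}.
#' @export
default_search_windows <- function() {
  list(TATA = c(-40L, -20L), INR = c(-5L, 5L), DPE = c(20L, 35L),
       TCT = c(-5L, 5L), DRE = c(-80L, -40L), Ohler1 = c(-60L, -30L),
       Ohler6 = c(-60L, 10L), Ohler7 = c(-60L, 10L))
}

#' Motif presence thresholds (percent of optimal score)
#'
#' @return Named numeric vector: TATA 90, INR 95, DPE 98, TCT 95,
#'   Ohler1 95, Ohler6 97, Ohler7 95, DRE 98.
#' @export
default_thresholds <- function() {
  c(TATA = 90, INR = 95, DPE = 98, TCT = 95,
    Ohler1 = 95, Ohler6 = 97, Ohler7 = 95, DRE = 98)
}

#' Read PWMs from whitespace-delimited text
#'
#' Format: a header line \code{>motif_id} per motif, an optional line
#' \code{background: pA pC pG pT}, then one row of four probabilities
#' (A C G T) per motif position.
#'
#' @param path input file.
#' @return Named list of \code{\link{pwm}} objects.
#' @export
read_pwms <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  out <- list()
  cur_id <- NULL; cur_rows <- list(); cur_bg <- rep(0.25, 4)
  flush <- function() {
    if (is.null(cur_id)) return()
    out[[cur_id]] <<- pwm(cur_id, do.call(rbind, cur_rows), cur_bg)
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      cur_id <- sub("^>\\s*", "", ln); cur_rows <- list()
      cur_bg <- rep(0.25, 4)
    } else if (startsWith(ln, "background:")) {
      cur_bg <- as.numeric(strsplit(sub("^background:\\s*", "", ln),
                                    "\\s+")[[1]])
    } else {
      if (is.null(cur_id)) stop("PWM row before any motif header")
      cur_rows[[length(cur_rows) + 1L]] <-
        as.numeric(strsplit(ln, "\\s+")[[1]])
    }
  }
  flush()
  out
}

#' Write PWMs to text
#'
#' @param pwms named list of \code{\link{pwm}} objects.
#' @param path output file.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$motif_id), con)
    writeLines(paste("background:", paste(p$background, collapse = " ")),
               con)
    writeLines(apply(p$mat, 1, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Log-odds score of a sequence window
#'
#' Sum over positions of log2(p / background); an N base contributes 0.
#'
#' @param seq_window character string of length equal to the PWM length.
#' @param x a \code{\link{pwm}}.
#' @return Score in bits.
#' @export
logodds_score <- function(seq_window, x) {
  b <- strsplit(toupper(seq_window), "")[[1]]
  L <- nrow(x$mat)
  if (length(b) != L) stop("sequence length must equal PWM length")
  lo <- log2(x$mat / matrix(x$background, L, 4, byrow = TRUE))
  idx <- match(b, .BASES)
  sum(ifelse(is.na(idx), 0, lo[cbind(seq_len(L), idx)]))
}

.logodds_matrix <- function(x) {
  log2(x$mat / matrix(x$background, nrow(x$mat), 4, byrow = TRUE))
}

#' Percent-of-optimum PWM score within a search window
#'
#' Scans sense-strand motif-start offsets \code{window[1]..window[2]}
#' relative to the anchor and min-max normalizes the best raw log-odds
#' score: percent = 100 (S* - S_min) / (S_max - S_min), with S_max/S_min
#' the per-position maxima/minima of the log-odds matrix.
#'
#' @param sequence promoter sequence (sense strand).
#' @param anchor 1-based index in \code{sequence} of the TSS (offset 0).
#' @param x a \code{\link{pwm}}.
#' @param window integer c(lo, hi) of allowed motif-start offsets.
#' @return List with \code{percent} in [0, 100], \code{best_offset}, and
#'   \code{offsets}/\code{percents} for all scanned offsets.
#' @export
percent_score <- function(sequence, anchor, x, window) {
  if (window[1] > window[2]) stop("empty search window")
  L <- nrow(x$mat)
  offsets <- seq.int(window[1], window[2])
  starts <- anchor + offsets
  if (any(starts < 1L) || any(starts + L - 1L > nchar(sequence))) {
    stop("search window extends beyond available sequence")
  }
  lo <- .logodds_matrix(x)
  smax <- sum(apply(lo, 1, max))
  smin <- sum(apply(lo, 1, min))
  raw <- vapply(starts, function(s) {
    logodds_score(substr(sequence, s, s + L - 1L), x)
  }, 0)
  pct <- 100 * (raw - smin) / (smax - smin)
  best <- which.max(pct)
  list(percent = pct[best], best_offset = offsets[best],
       offsets = offsets, percents = pct)
}

#' Score promoters against a PWM set
#'
#' Extracts each promoter's sense-strand sequence around its TSS (minus
#' strand reverse-complemented) and computes the percent-of-optimum score
#' and best offset for every motif within its search window.
#'
#' @param genome named character vector of contig sequences.
#' @param promoters data.frame with columns promoter_id, contig, strand,
#'   tss.
#' @param pwms named list of \code{\link{pwm}} objects.
#' @param windows named list of search windows (see
#'   \code{\link{default_search_windows}}).
#' @param flank bp of sequence extracted on each side of the TSS; must
#'   cover every window plus motif length.
#' @return List with \code{percent} and \code{offset} matrices
#'   (promoter x motif).
#' @export
score_promoters <- function(genome, promoters, pwms = default_pwm_set(),
                            windows = default_search_windows(),
                            flank = 100) {
  motifs <- names(pwms)
  missing_w <- setdiff(motifs, names(windows))
  if (length(missing_w)) {
    stop("no search window for motif: ", paste(missing_w, collapse = ", "))
  }
  np <- nrow(promoters)
  percent <- matrix(NA_real_, np, length(motifs),
                    dimnames = list(promoters$promoter_id, motifs))
  offset <- percent
  for (i in seq_len(np)) {
    p <- promoters[i, ]
    seqlen <- nchar(genome[[p$contig]])
    lo <- p$tss - flank; hi <- p$tss + flank
    if (lo < 0L || hi >= seqlen) stop("promoter window outside contig")
    region <- substr(genome[[p$contig]], lo + 1L, hi + 1L)
    if (p$strand == "-") region <- .revcomp(region)
    for (m in motifs) {
      sc <- percent_score(region, flank + 1L, pwms[[m]], windows[[m]])
      percent[i, m] <- sc$percent
      offset[i, m] <- sc$best_offset
    }
  }
  list(percent = percent, offset = offset)
}

#' Apply motif presence thresholds
#'
#' A motif is flagged present when its percent score strictly exceeds its
#' threshold.
#'
#' @param percent promoter x motif percent-score matrix.
#' @param thresholds named numeric vector of percent thresholds.
#' @return Logical promoter x motif matrix over the thresholded motifs.
#' @export
apply_thresholds <- function(percent, thresholds = default_thresholds()) {
  missing_m <- setdiff(names(thresholds), colnames(percent))
  if (length(missing_m)) {
    stop("score table lacks motif column: ",
         paste(missing_m, collapse = ", "))
  }
  flags <- percent[, names(thresholds), drop = FALSE] >
    matrix(thresholds, nrow(percent), length(thresholds), byrow = TRUE)
  flags
}

#' Exclusive promoter class assignment
#'
#' Precedence TCT > TATA > DPE > INR > DRE > Ohler1/6 (the last fires on
#' Ohler1 or Ohler6); promoters with no flag are "other". The more
#' position-specific element names the class; binary flags remain available
#' for overlapping-group analyses.
#'
#' @param flags logical promoter x motif matrix from
#'   \code{\link{apply_thresholds}}.
#' @return Character vector of class labels.
#' @export
assign_class <- function(flags) {
  need <- c("TCT", "TATA", "DPE", "INR", "DRE", "Ohler1", "Ohler6")
  missing_m <- setdiff(need, colnames(flags))
  if (length(missing_m)) {
    stop("flags lack motif: ", paste(missing_m, collapse = ", "))
  }
  label <- rep("other", nrow(flags))
  label[flags[, "Ohler1"] | flags[, "Ohler6"]] <- "Ohler1/6"
  label[flags[, "DRE"]] <- "DRE"
  label[flags[, "INR"]] <- "INR"
  label[flags[, "DPE"]] <- "DPE"
  label[flags[, "TATA"]] <- "TATA"
  label[flags[, "TCT"]] <- "TCT"
  setNames(label, rownames(flags))
}

#' k-means overview of promoter motif scores
#'
#' Lloyd's algorithm on the raw percent scores, best of \code{restarts}
#' random starts by total within-cluster sum of squares; deterministic
#' given \code{seed}.
#'
#' @param percent promoter x motif percent-score matrix.
#' @param k number of clusters (default 9).
#' @param seed RNG seed.
#' @param restarts random restarts.
#' @return List with \code{assignments} and \code{centers}.
#' @export
kmeans_overview <- function(percent, k = 9, seed = 1, restarts = 10) {
  if (k > nrow(percent)) stop("k exceeds the number of promoters")
  set.seed(seed)
  fit <- kmeans(percent, centers = k, nstart = restarts,
                algorithm = "Lloyd", iter.max = 100)
  list(assignments = setNames(fit$cluster, rownames(percent)),
       centers = fit$centers)
}

#' Prototype promoter selection rules
#'
#' Stringent motif-match and co-occurrence rules for picking prototypical
#' promoters of each class among promoters active in the assayed cells.
#' \code{required} entries are strict minima (percent > value),
#' \code{forbidden} entries strict maxima (percent < value).
#'
#' @return Named list of rules, each with \code{required} and
#'   \code{forbidden} named numeric vectors.
#' @export
default_prototype_rules <- function() {
  hk <- c(TCT = 90, DRE = 90, Ohler1 = 90, Ohler6 = 90, Ohler7 = 90)
  list(
    TATA = list(required = c(TATA = 95),
                forbidden = c(DPE = 90, hk)),
    DPE = list(required = c(DPE = 95),
               forbidden = c(TATA = 80, TCT = 90, DRE = 90,
                             Ohler1 = 90, Ohler6 = 90, Ohler7 = 90)),
    INR = list(required = c(INR = 95),
               forbidden = c(TATA = 80, DPE = 85, TCT = 90, DRE = 90,
                             Ohler1 = 90, Ohler6 = 90, Ohler7 = 90)),
    TCT = list(required = c(TCT = 95), forbidden = c()),
    `Ohler1/6` = list(required = c(Ohler1 = 95, Ohler6 = 95),
                      forbidden = c(TATA = 80, INR = 85, DPE = 85,
                                    DRE = 95)),
    DRE = list(required = c(DRE = 99.999),
               forbidden = c(Ohler1 = 85, Ohler6 = 85, TATA = 80,
                             INR = 85, DPE = 85)))
}

#' Select prototype promoters per class
#'
#' A promoter is selected for a class when it is active and every required
#' minimum is strictly exceeded and every forbidden maximum strictly
#' respected.
#'
#' @param percent promoter x motif percent-score matrix.
#' @param active logical vector (or promoter-id subset) of active
#'   promoters.
#' @param rules rules as from \code{\link{default_prototype_rules}}.
#' @return Named list of promoter-id vectors per class.
#' @export
select_prototypes <- function(percent, active,
                              rules = default_prototype_rules()) {
  if (!is.logical(active)) active <- rownames(percent) %in% active
  out <- list()
  for (cls in names(rules)) {
    r <- rules[[cls]]
    motifs <- c(names(r$required), names(r$forbidden))
    missing_m <- setdiff(motifs, colnames(percent))
    if (length(missing_m)) {
      stop("rule references unknown motif: ",
           paste(missing_m, collapse = ", "))
    }
    keep <- active
    for (m in names(r$required)) {
      keep <- keep & percent[, m] > r$required[[m]]
    }
    for (m in names(r$forbidden)) {
      keep <- keep & percent[, m] < r$forbidden[[m]]
    }
    out[[cls]] <- rownames(percent)[keep]
  }
  out
}

#' CAGE activity in tags per million
#'
#' Tags within +/- \code{halfwidth} bp of the (corrected) TSS per million
#' total mapped tags; the activity measure behind the >= 5 tpm filter.
#'
#' @param signal CAGE \code{\link{base_signal}}.
#' @param promoters data.frame with columns contig, strand, tss.
#' @param halfwidth window half-width in bp.
#' @return Numeric vector of tpm values.
#' @export
cage_tpm <- function(signal, promoters, halfwidth = 50) {
  total <- sum(signal$count)
  if (total == 0) return(rep(0, nrow(promoters)))
  vapply(seq_len(nrow(promoters)), function(i) {
    p <- promoters[i, ]
    sum(signal_counts(signal, p$contig, p$strand,
                      (p$tss - halfwidth):(p$tss + halfwidth)))
  }, 0) / total * 1e6
}
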