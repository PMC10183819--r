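## Promoter-shape statistics on 5'-end profiles: dominant TSS, dominant
## fraction, activated-TSS count, initiation width, -1/+1 dinucleotides,
## and anchored metaprofiles.

#' Extract a TSS-relative initiation profile
#'
#' Windows the signal around an anchor and flips minus-strand promoters
#' into sense orientation (downstream positive).
#'
#' @param signal a \code{\link{base_signal}} of 5'-end counts.
#' @param contig,strand,anchor promoter anchor (genomic, 0-based).
#' @param w_up,w_down window extent upstream/downstream of the anchor (bp).
#' @return List of class \code{initiation_profile} with \code{offsets}
#'   (-w_up..w_down) and \code{counts}.
#' @export
extract_profile <- function(signal, contig, strand, anchor,
                            w_up = 60, w_down = 60) {
  stopifnot(w_up >= 0, w_down >= 0)
  offsets <- seq.int(-w_up, w_down)
  pos <- if (strand == "+") anchor + offsets else anchor - offsets
  counts <- signal_counts(signal, contig, strand, pos)
  structure(list(offsets = offsets, counts = counts),
            class = "initiation_profile")
}

.check_active <- function(profile) {
  if (all(profile$counts <= 0)) stop("all-zero (inactive) profile")
}

#' Dominant TSS of a profile
#'
#' The offset with the highest count; ties break to the upstream-most
#' offset.
#'
#' @param profile an \code{\link{extract_profile}} result.
#' @return Offset of the dominant TSS.
#' @export
dominant_tss <- function(profile) {
  .check_active(profile)
  profile$offsets[which.max(profile$counts)]
}

#' Fraction of initiation at the dominant TSS
#'
#' Count at the dominant TSS divided by the total count.
#'
#' @param profile an \code{\link{extract_profile}} result.
#' @return Fraction in (0, 1].
#' @export
dominant_fraction <- function(profile) {
  .check_active(profile)
  max(profile$counts) / sum(profile$counts)
}

#' Number of activated TSS positions
#'
#' Each position's count is divided by the dominant count; in mode
#' "strict" positions with a ratio strictly above \code{rel} are counted
#' as activated, in mode "inclusive" positions at or above \code{rel}.
#'
#' @param profile an \code{\link{extract_profile}} result.
#' @param rel relative threshold in (0, 1].
#' @param mode "strict" (ratio > rel) or "inclusive" (ratio >= rel).
#' @return Integer count >= 1.
#' @export
count_activated_tss <- function(profile, rel = 0.2,
                                mode = c("strict", "inclusive")) {
  mode <- match.arg(mode)
  if (rel <= 0 || rel > 1) stop("rel must be in (0, 1]")
  .check_active(profile)
  ratio <- profile$counts / max(profile$counts)
  if (mode == "strict") sum(ratio > rel) else sum(ratio >= rel)
}

#' Width of the initiation region
#'
#' Span (in bp, inclusive) between the first and last offset with count at
#' or above \code{floor}.
#'
#' @param profile an \code{\link{extract_profile}} result.
#' @param floor minimum count for a position to count as covered.
#' @return Width in bp (>= 1).
#' @export
initiation_width <- function(profile, floor = 1) {
  covered <- which(profile$counts >= floor)
  if (length(covered) == 0L) stop("no position at or above the count floor")
  profile$offsets[max(covered)] - profile$offsets[min(covered)] + 1L
}

#' Shape metrics for a set of promoters
#'
#' Convenience wrapper computing all initiation-shape statistics per
#' promoter; inactive promoters get NA metrics.
#'
#' @param signal a \code{\link{base_signal}}.
#' @param promoters data.frame with columns promoter_id, contig, strand,
#'   tss.
#' @param w_up,w_down profile window (bp).
#' @param rel activated-TSS relative threshold.
#' @param floor width count floor.
#' @return data.frame of per-promoter metrics.
#' @export
initiation_metrics <- function(signal, promoters, w_up = 60, w_down = 120,
                               rel = 0.2, floor = 1) {
  res <- lapply(seq_len(nrow(promoters)), function(i) {
    p <- promoters[i, ]
    prof <- extract_profile(signal, p$contig, p$strand, p$tss, w_up, w_down)
    if (all(prof$counts <= 0)) {
      return(data.frame(promoter_id = p$promoter_id, active = FALSE,
                        total = 0, dominant_offset = NA_integer_,
                        dominant_fraction = NA_real_,
                        n_activated_strict = NA_integer_,
                        n_activated_inclusive = NA_integer_,
                        width = NA_integer_, stringsAsFactors = FALSE))
    }
    data.frame(promoter_id = p$promoter_id, active = TRUE,
               total = sum(prof$counts),
               dominant_offset = dominant_tss(prof),
               dominant_fraction = dominant_fraction(prof),
               n_activated_strict = count_activated_tss(prof, rel, "strict"),
               n_activated_inclusive =
                 count_activated_tss(prof, rel, "inclusive"),
               width = initiation_width(prof, floor),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' -1/+1 dinucleotide table at TSSs
#'
#' For each TSS the sense-strand 2-mer (base at -1, base at +1 = the TSS
#' base) is tallied; minus-strand promoters are reverse-complemented.
#' TSSs at a contig edge or touching an N are skipped and tallied in
#' attribute \code{n_skipped}.
#'
#' @param genome named character vector of contig sequences.
#' @param promoters data.frame with columns contig, strand, tss.
#' @return Named integer vector over the 16 dinucleotides, with attribute
#'   \code{n_skipped}.
#' @export
dinucleotide_at_tss <- function(genome, promoters) {
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  counts <- setNames(integer(16), dinucs)
  skipped <- 0L
  for (i in seq_len(nrow(promoters))) {
    p <- promoters[i, ]
    seqlen <- nchar(genome[[p$contig]])
    if (p$strand == "+") {
      lo <- p$tss - 1L; hi <- p$tss
    } else {
      lo <- p$tss; hi <- p$tss + 1L
    }
    if (lo < 0L || hi >= seqlen) { skipped <- skipped + 1L; next }
    dn <- substr(genome[[p$contig]], lo + 1L, hi + 1L)
    if (p$strand == "-") dn <- .revcomp(dn)
    if (grepl("N", dn, fixed = TRUE)) { skipped <- skipped + 1L; next }
    counts[dn] <- counts[dn] + 1L
  }
  attr(counts, "n_skipped") <- skipped
  counts
}

#' Motif anchors with a single-occurrence filter
#'
#' Locates the position of a motif relative to each promoter's dominant
#' TSS. A promoter is kept only if exactly one scanned offset within
#' +/- \code{max_dist} bp scores at or above \code{threshold}; promoters
#' with zero or multiple occurrences are excluded (NA anchor) and tallied.
#'
#' @param genome named character vector.
#' @param promoters data.frame with columns promoter_id, contig, strand,
#'   tss (dominant TSS).
#' @param x a \code{\link{pwm}}.
#' @param threshold percent-of-optimum threshold defining an occurrence.
#' @param max_dist maximum motif-start distance from the TSS (bp).
#' @return data.frame with promoter_id, anchor (genomic motif start, NA if
#'   excluded) and n_occurrences; attribute \code{n_excluded}.
#' @export
motif_anchors <- function(genome, promoters, x, threshold,
                          max_dist = 120) {
  L <- nrow(x$mat)
  out <- data.frame(promoter_id = promoters$promoter_id,
                    anchor = NA_integer_, n_occurrences = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(promoters))) {
    p <- promoters[i, ]
    flank <- max_dist + L
    region_lo <- p$tss - flank
    if (region_lo < 0L ||
        p$tss + flank >= nchar(genome[[p$contig]])) next
    region <- substr(genome[[p$contig]], region_lo + 1L,
                     p$tss + flank + 1L)
    if (p$strand == "-") region <- .revcomp(region)
    sc <- percent_score(region, flank + 1L, x, c(-max_dist, max_dist))
    hits <- sc$offsets[sc$percents >= threshold]
    out$n_occurrences[i] <- length(hits)
    if (length(hits) == 1L) {
      out$anchor[i] <- if (p$strand == "+") p$tss + hits else p$tss - hits
    }
  }
  attr(out, "n_excluded") <- sum(is.na(out$anchor))
  out
}

#' Anchored metaprofile of a signal
#'
#' Sum-normalizes each promoter's windowed sense-oriented profile to 1 and
#' averages across promoters; inactive promoters (no signal in the window)
#' are excluded and tallied.
#'
#' @param signal a \code{\link{base_signal}}.
#' @param anchors data.frame with columns contig, strand, anchor (genomic
#'   position; rows with NA anchor are skipped).
#' @param flank window half-width around the anchor (bp).
#' @return data.frame of class \code{meta_profile}: offset, mean relative
#'   signal, n promoters aggregated (attribute \code{n_excluded} counts
#'   skipped promoters).
#' @export
anchored_metaprofile <- function(signal, anchors, flank = 200) {
  anchors <- anchors[!is.na(anchors$anchor), , drop = FALSE]
  offsets <- seq.int(-flank, flank)
  acc <- numeric(length(offsets)); n <- 0L; excluded <- 0L
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    prof <- extract_profile(signal, a$contig, a$strand, a$anchor,
                            flank, flank)
    tot <- sum(prof$counts)
    if (tot <= 0) { excluded <- excluded + 1L; next }
    acc <- acc + prof$counts / tot
    n <- n + 1L
  }
  if (n == 0L) stop("no eligible promoters for metaprofile")
  out <- data.frame(offset = offsets, mean = acc / n, n = n)
  attr(out, "n_excluded") <- excluded
  class(out) <- c("meta_profile", "data.frame")
  out
}
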