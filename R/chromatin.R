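## +1 nucleosome calling from MNase fragment centers and CAGE x MNase
## cross-correlation around dominant TSSs.

#' Fragment centers as a coverage signal
#'
#' Filters fragments to an inclusive length range and reduces each to its
#' center, floor((start + end) / 2). Centers are strandless; they are
#' recorded on both strands so strand-aware windowing sees the same
#' coverage either way.
#'
#' @param fragments data.frame with columns contig, start, end.
#' @param len_range inclusive fragment length range (bp).
#' @return A \code{\link{base_signal}} of center coverage.
#' @export
fragment_centers <- function(fragments, len_range = c(100, 200)) {
  if (len_range[1] > len_range[2] || len_range[1] < 1) {
    stop("invalid length range")
  }
  len <- fragments$end - fragments$start
  keep <- len >= len_range[1] & len <= len_range[2]
  fragments <- fragments[keep, , drop = FALSE]
  if (nrow(fragments) == 0L) return(base_signal())
  center <- as.integer(floor((fragments$start + fragments$end) / 2))
  base_signal(contig = rep(fragments$contig, 2L),
              strand = rep(c("+", "-"), each = nrow(fragments)),
              pos = rep(center, 2L),
              count = rep(1, 2L * nrow(fragments)))
}

#' Call the +1 nucleosome center
#'
#' The +1 nucleosome center is the offset with the highest coverage of
#' in-filter MNase fragment centers within a downstream search window
#' relative to the dominant TSS (sense-oriented); ties break to the offset
#' closest to the TSS.
#'
#' @param centers fragment-center \code{\link{base_signal}} from
#'   \code{\link{fragment_centers}}.
#' @param contig,strand,tss promoter dominant TSS.
#' @param window search window of TSS-relative offsets, default +1..+200.
#' @return List with \code{offset} (TSS-relative), \code{center} (genomic)
#'   and \code{support}, or NULL when no center falls in the window.
#' @export
plus1_center <- function(centers, contig, strand, tss,
                         window = c(1, 200)) {
  if (window[1] > window[2]) stop("invalid search window")
  offsets <- seq.int(window[1], window[2])
  pos <- if (strand == "+") tss + offsets else tss - offsets
  cov <- signal_counts(centers, contig, strand, pos)
  if (all(cov == 0)) return(NULL)
  best <- which(cov == max(cov))
  off <- offsets[best]
  off <- off[which.min(abs(off))]       # tie: closest to the TSS
  list(offset = off,
       center = if (strand == "+") tss + off else tss - off,
       support = max(cov))
}

#' Call +1 nucleosomes for a promoter set
#'
#' @param fragments data.frame of MNase fragments.
#' @param promoters data.frame with columns promoter_id, contig, strand,
#'   tss (dominant TSS).
#' @param window search window (TSS-relative offsets).
#' @param len_range inclusive fragment length filter (bp).
#' @return data.frame: promoter_id, offset, center, support; no-calls have
#'   NA offset/center and support 0.
#' @export
call_plus1 <- function(fragments, promoters, window = c(1, 200),
                       len_range = c(100, 200)) {
  centers <- fragment_centers(fragments, len_range)
  res <- lapply(seq_len(nrow(promoters)), function(i) {
    p <- promoters[i, ]
    call <- plus1_center(centers, p$contig, p$strand, p$tss, window)
    if (is.null(call)) {
      data.frame(promoter_id = p$promoter_id, offset = NA_integer_,
                 center = NA_integer_, support = 0L,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(promoter_id = p$promoter_id, offset = call$offset,
                 center = call$center, support = call$support,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}

#' CAGE metaprofile anchored on +1 nucleosome centers
#'
#' Averages sum-normalized CAGE profiles aligned to the called +1
#' nucleosome centers.
#'
#' @param signal CAGE \code{\link{base_signal}}.
#' @param calls result of \code{\link{call_plus1}} joined with promoter
#'   contig/strand (columns contig, strand, center).
#' @param flank window half-width (bp).
#' @return A \code{meta_profile} (see \code{\link{anchored_metaprofile}}).
#' @export
nucleosome_anchored_cage <- function(signal, calls, flank = 200) {
  calls <- calls[!is.na(calls$center), , drop = FALSE]
  if (nrow(calls) == 0L) stop("no +1 nucleosome calls")
  anchors <- data.frame(contig = calls$contig, strand = calls$strand,
                        anchor = calls$center, stringsAsFactors = FALSE)
  anchored_metaprofile(signal, anchors, flank)
}

#' Cross-correlation between CAGE and MNase fragment centers
#'
#' For each promoter the CAGE vector over TSS-relative offsets
#' \code{window[1]..window[2]} is correlated (Pearson) with the fragment-
#' center vector shifted by each lag, the shifted vector being read from
#' the untruncated signal. Promoters whose CAGE vector has zero variance
#' or that are supported by fewer than \code{min_fragments} fragment
#' centers in the base window are excluded; lags at which the shifted
#' center vector is constant yield NA for that promoter and are dropped
#' from that lag's mean.
#'
#' @param cage CAGE \code{\link{base_signal}}.
#' @param centers fragment-center \code{\link{base_signal}}.
#' @param promoters data.frame with columns contig, strand, tss (dominant
#'   TSS).
#' @param lags integer vector of lags (bp, downstream positive).
#' @param window TSS-relative base window, default -50..+200.
#' @param min_fragments minimum fragment-center support per promoter.
#' @return data.frame of class \code{crosscorrelation_curve}: lag, mean_r,
#'   sd_r, n.
#' @export
cage_mnase_crosscorrelation <- function(cage, centers, promoters,
                                        lags = -50:200,
                                        window = c(-50, 200),
                                        min_fragments = 10) {
  offsets <- seq.int(window[1], window[2])
  span <- seq.int(window[1] + min(lags), window[2] + max(lags))
  rmat <- matrix(NA_real_, nrow(promoters), length(lags))
  retained <- logical(nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    p <- promoters[i, ]
    pos <- if (p$strand == "+") p$tss + offsets else p$tss - offsets
    spanpos <- if (p$strand == "+") p$tss + span else p$tss - span
    cvec <- signal_counts(cage, p$contig, p$strand, pos)
    mspan <- signal_counts(centers, p$contig, p$strand, spanpos)
    if (sd(cvec) == 0 ||
        sum(mspan[span >= window[1] & span <= window[2]]) <
          min_fragments) next
    retained[i] <- TRUE
    shifted <- vapply(lags, function(k) {
      mspan[match(offsets + k, span)]
    }, numeric(length(offsets)))
    usable <- apply(shifted, 2, sd) > 0
    if (any(usable)) {
      rmat[i, usable] <- as.vector(cor(cvec, shifted[, usable,
                                                     drop = FALSE]))
    }
  }
  if (!any(retained)) stop("no promoters retained for cross-correlation")
  rmat <- rmat[retained, , drop = FALSE]
  out <- data.frame(
    lag = lags,
    mean_r = colMeans(rmat, na.rm = TRUE),
    sd_r = apply(rmat, 2, sd, na.rm = TRUE),
    n = colSums(!is.na(rmat)))
  class(out) <- c("crosscorrelation_curve", "data.frame")
  out
}
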