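## Reassign annotated TSSs to CAGE-supported positions via a two-window,
## primary-then-fallback search, then keep the longest transcript per TSS.

.search_window_hit <- function(signal, contig, strand, tss, w, min_count) {
  positions <- (max(0L, tss - w)):(tss + w)
  cnt <- signal_counts(signal, contig, strand, positions)
  hit <- cnt >= min_count & cnt > 0
  if (!any(hit)) return(NULL)
  pos <- positions[hit]; cnt <- cnt[hit]
  best <- cnt == max(cnt)
  pos <- pos[best]
  if (length(pos) > 1L) {          # tie: closest to the annotated TSS
    d <- abs(pos - tss)
    pos <- pos[d == min(d)]
    if (length(pos) > 1L) {        # still tied: upstream-most
      pos <- if (strand == "+") min(pos) else max(pos)
    }
  }
  list(pos = pos, count = max(cnt))
}

#' Correct annotated TSSs with CAGE signal
#'
#' For each transcript, searches same-strand CAGE signal in the order
#' primary at +/- \code{w_small}, each fallback at +/- \code{w_small},
#' primary at +/- \code{w_large}, fallbacks at +/- \code{w_large}. The
#' corrected TSS is the maximum-count position of the first window with a
#' hit (any position with count >= \code{min_count}); ties break to the
#' position closest to the annotated TSS, then upstream-most. Transcripts
#' with no hit anywhere keep their annotated TSS.
#'
#' @param transcripts data.frame as from \code{\link{load_transcripts}}.
#' @param primary primary CAGE \code{\link{base_signal}} (e.g. the assayed
#'   cell line).
#' @param fallbacks ordered list of fallback \code{\link{base_signal}}s
#'   (e.g. embryo or developmental time-course CAGE), searched
#'   sequentially.
#' @param w_small,w_large small and large search half-windows (bp).
#' @param min_count minimum tag count for a position to count as a hit.
#' @return \code{transcripts} with added columns \code{original_tss},
#'   \code{tss} (corrected) and \code{pass} (e.g. "primary-250",
#'   "fallback-500", "uncorrected").
#' @export
correct_tss <- function(transcripts, primary, fallbacks = list(),
                        w_small = 250, w_large = 500, min_count = 1) {
  stopifnot(w_small > 0, w_small <= w_large)
  signals <- c(list(primary), fallbacks)
  labels <- c("primary", rep("fallback", length(fallbacks)))
  n <- nrow(transcripts)
  corrected <- integer(n); pass <- character(n)
  for (i in seq_len(n)) {
    tx <- transcripts[i, ]
    res <- NULL
    for (w in c(w_small, w_large)) {
      for (k in seq_along(signals)) {
        hit <- .search_window_hit(signals[[k]], tx$contig, tx$strand,
                                  tx$tss, w, min_count)
        if (!is.null(hit)) {
          res <- list(pos = hit$pos, pass = paste0(labels[k], "-", w))
          break
        }
      }
      if (!is.null(res)) break
    }
    if (is.null(res)) {
      corrected[i] <- tx$tss; pass[i] <- "uncorrected"
    } else {
      corrected[i] <- res$pos; pass[i] <- res$pass
    }
  }
  out <- transcripts
  out$original_tss <- transcripts$tss
  out$tss <- corrected
  out$pass <- pass
  out
}

#' Keep the longest transcript per unique TSS
#'
#' Transcripts are grouped by (contig, strand, corrected TSS); within a
#' group the transcript maximizing end - start is kept, ties breaking to
#' the lexicographically smallest transcript_id.
#'
#' @param transcripts data.frame with corrected \code{tss} (from
#'   \code{\link{correct_tss}}).
#' @return Deduplicated transcript data.frame.
#' @export
collapse_by_tss <- function(transcripts) {
  if (nrow(transcripts) == 0L) return(transcripts)
  key <- paste(transcripts$contig, transcripts$strand, transcripts$tss,
               sep = "\r")
  len <- transcripts$end - transcripts$start
  ord <- order(key, -len, transcripts$transcript_id)
  out <- transcripts[ord, , drop = FALSE]
  out <- out[!duplicated(key[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
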