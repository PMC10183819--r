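## Deterministic, seeded generator of promoter landscapes and CAGE / MNase /
## PRO-seq style data with full ground truth. Each promoter (and each sample)
## draws from its own counter-derived substream so outputs are stable under
## subsetting; draw order within a substream is documented per function.

.substream_seed <- function(seed, salt, counter) {
  ((as.numeric(seed) %% 65521) * 65521 +
     salt * 7919 + as.numeric(counter)) %% 2147483647
}

.with_substream <- function(seed, salt, counter, expr) {
  set.seed(.substream_seed(seed, salt, counter))
  expr
}

#' Promoter class specifications
#'
#' The six promoter archetypes the generator emulates. Developmental classes
#' (TATA, DPE, INR) initiate focused (1-3 bp); housekeeping classes (TCT,
#' DRE, Ohler1/6) initiate dispersed over 50-100 bp upstream of a well
#' positioned +1 nucleosome. Motif embed offsets are TSS-relative motif
#' starts (downstream positive): TATA -31, INR 0, DPE +28, TCT 0, DRE -60,
#' Ohler1 -45.
#'
#' @return Named list of class specs, each with fields \code{name},
#'   \code{motifs} (data.frame motif/offset), \code{mode} ("focused" or
#'   "dispersed") and \code{nuc_sd} (+1 nucleosome positioning sd, bp).
#' @export
promoter_classes <- function() {
  cls <- list(
    list(name = "TATA", mode = "focused", nuc_sd = 40,
         motifs = data.frame(motif = c("TATA", "INR"),
                             offset = c(-31L, 0L))),
    list(name = "DPE", mode = "focused", nuc_sd = 40,
         motifs = data.frame(motif = c("INR", "DPE"),
                             offset = c(0L, 28L))),
    list(name = "INR", mode = "focused", nuc_sd = 40,
         motifs = data.frame(motif = "INR", offset = 0L)),
    list(name = "TCT", mode = "dispersed", nuc_sd = 10,
         motifs = data.frame(motif = "TCT", offset = 0L)),
    list(name = "DRE", mode = "dispersed", nuc_sd = 10,
         motifs = data.frame(motif = "DRE", offset = -60L)),
    list(name = "Ohler1/6", mode = "dispersed", nuc_sd = 10,
         motifs = data.frame(motif = "Ohler1", offset = -45L)))
  setNames(cls, vapply(cls, `[[`, "", "name"))
}

#' Simulation configuration
#'
#' All tunable constants of the generator with their defaults. Defaults
#' describe the emulated study conditions: 121-bp cores, focused initiation
#' concentrated on 1-3 bp (80\% of tags at the dominant TSS, geometric decay
#' within +/-3 bp), dispersed initiation over \code{dispersed_width} bp
#' ending 30 bp upstream of the +1 nucleosome center at +125, MNase fragment
#' lengths ~ round(Normal(147, 10)), and a two-condition spike-in PRO-seq
#' design with negative-binomial gene counts.
#'
#' @param n_per_class promoters simulated per class.
#' @param classes class list as from \code{\link{promoter_classes}}.
#' @param spacing distance between consecutive promoter TSSs (bp).
#' @param core_halfwidth half-width of the promoter core (60 gives 121 bp).
#' @param transcript_length length of each simulated transcript (bp).
#' @param mean_tags mean CAGE tags per promoter (Poisson).
#' @param focused_halfwidth decay half-width of focused initiation (bp).
#' @param focused_dominant_mass fraction of focused tags at the dominant TSS.
#' @param dispersed_width width of the dispersed initiation window (bp).
#' @param dispersed_dominant_mass fraction of dispersed tags at the true
#'   dominant TSS (kept below the 0.2 activated-TSS ratio).
#' @param nuc_offset +1 nucleosome center offset downstream of the TSS (bp).
#' @param nuc_gap gap between the dispersed window end and the nucleosome
#'   center (bp).
#' @param fragments_per_promoter MNase fragments per promoter.
#' @param mnase_len_mean,mnase_len_sd fragment length distribution.
#' @param n_genes,baseline_meanlog,baseline_sdlog gene count and log-normal
#'   baseline expression law.
#' @param phi negative-binomial dispersion. The default 0 (Poisson limit)
#'   is the regime in which the exact conditional down-call test is
#'   calibrated; positive values add biological overdispersion, under
#'   which that test's error control is known to degrade (see the methods
#'   vignette).
#' @param fold_change per-gene depletion fold change f applied to affected
#'   genes (depleted mean = baseline * f * global_factor).
#' @param frac_affected fraction of genes affected by \code{fold_change}
#'   (drawn at random; ignored when \code{affected_idx} is given).
#' @param affected_idx optional explicit integer indices of affected genes
#'   (e.g. genes whose promoters carry a targeted motif class).
#' @param global_factor global transcriptional output factor G of the
#'   depleted condition.
#' @param replicates replicates per condition.
#' @param depth sequencing depth per sample.
#' @param kappa spike-in fraction of cellular material (spike reads are
#'   Binomial(depth, kappa / (kappa + O_s)) with O_s the sample's relative
#'   total output).
#' @param seed integer seed driving every substream.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_per_class = 100, classes = promoter_classes(),
                       spacing = 3000, core_halfwidth = 60,
                       transcript_length = 1000,
                       mean_tags = 200, focused_halfwidth = 3,
                       focused_dominant_mass = 0.8,
                       dispersed_width = 100,
                       dispersed_dominant_mass = 0.15,
                       nuc_offset = 125,
                       nuc_gap = 30,
                       fragments_per_promoter = 200,
                       mnase_len_mean = 147, mnase_len_sd = 10,
                       n_genes = 2000, baseline_meanlog = log(200),
                       baseline_sdlog = 1, phi = 0,
                       fold_change = 1, frac_affected = 0,
                       affected_idx = NULL,
                       global_factor = 1, replicates = 2,
                       depth = 2e6, kappa = 0.01, seed = 1) {
  stopifnot(n_per_class >= 0, spacing >= 2 * core_halfwidth + 1,
            dispersed_width >= 1, focused_halfwidth >= 1,
            phi >= 0, depth > 0, kappa > 0, kappa < 1,
            replicates >= 1, seed == as.integer(seed))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

.embed_motif <- function(core, consensus, offset, halfwidth) {
  idx <- halfwidth + 1L + offset  # 1-based index of motif start in core
  L <- nchar(consensus)
  if (idx < 1L || idx + L - 1L > nchar(core)) {
    stop("motif does not fit in core at offset ", offset)
  }
  substr(core, idx, idx + L - 1L) <- consensus
  core
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Simulate a promoter landscape
#'
#' Lays out \code{n_per_class} promoters per class on one contig, alternating
#' strands, with each 121-bp core carrying its class consensus motif(s) at
#' the programmed TSS-relative offsets over an i.i.d. uniform background.
#' Byte-identical output for identical (config, seed).
#'
#' Draw order: substream 0 draws the background contig; substream i draws
#' promoter i's core background.
#'
#' @param config a \code{\link{sim_config}}.
#' @return List with \code{genome} (named character), \code{transcripts}
#'   (data.frame as \code{\link{load_transcripts}}) and \code{truth}
#'   (data.frame: promoter_id, class, mode, contig, strand, tss,
#'   nuc_center).
#' @export
simulate_promoter_landscape <- function(config) {
  cls <- config$classes
  n_pc <- config$n_per_class
  n_total <- length(cls) * n_pc
  if (n_total == 0L) {
    return(list(genome = setNames(character(0), character(0)),
                transcripts = data.frame(), truth = data.frame()))
  }
  hw <- config$core_halfwidth
  contig <- "simchr"
  contig_len <- (n_total + 2L) * config$spacing
  bg <- .with_substream(config$seed, 11L, 0L,
    sample(c("A", "C", "G", "T"), contig_len, replace = TRUE))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  consensi <- motif_consensus_set()
  rows <- vector("list", n_total)
  i <- 0L
  for (cl in cls) {
    for (j in seq_len(n_pc)) {
      i <- i + 1L
      strand <- if (i %% 2L == 1L) "+" else "-"
      tss <- i * config$spacing
      core <- .with_substream(config$seed, 13L, i,
        paste(sample(c("A", "C", "G", "T"), 2L * hw + 1L, replace = TRUE),
              collapse = ""))
      for (m in seq_len(nrow(cl$motifs))) {
        core <- .embed_motif(core, consensi[[cl$motifs$motif[m]]],
                             cl$motifs$offset[m], hw)
      }
      core_chars <- strsplit(core, "")[[1]]
      if (strand == "-") core_chars <- rev(unname(comp[core_chars]))
      bg[(tss - hw + 1L):(tss + hw + 1L)] <- core_chars
      nuc <- if (strand == "+") tss + config$nuc_offset
             else tss - config$nuc_offset
      rows[[i]] <- data.frame(
        promoter_id = sprintf("p%04d", i), class = cl$name,
        mode = cl$mode, nuc_sd = cl$nuc_sd, contig = contig,
        strand = strand, tss = tss, nuc_center = nuc,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  tx <- data.frame(
    gene_id = sub("^p", "g", truth$promoter_id),
    transcript_id = sub("^p", "t", truth$promoter_id),
    contig = truth$contig,
    start = ifelse(truth$strand == "+", truth$tss,
                   truth$tss - config$transcript_length + 1L),
    end = ifelse(truth$strand == "+", truth$tss + config$transcript_length,
                 truth$tss + 1L),
    strand = truth$strand, tss = truth$tss, stringsAsFactors = FALSE)
  list(genome = setNames(paste(bg, collapse = ""), contig),
       transcripts = tx, truth = truth)
}

.focused_weights <- function(halfwidth, dominant_mass, decay = 0.5) {
  d <- -halfwidth:halfwidth
  w <- decay^abs(d)
  w[d == 0] <- 0
  w <- w / sum(w) * (1 - dominant_mass)
  w[d == 0] <- dominant_mass
  list(offsets = d, weights = w)
}

#' Simulate CAGE 5'-end tags
#'
#' Focused promoters put \code{focused_dominant_mass} of their tags on the
#' dominant TSS with geometric decay within +/- \code{focused_halfwidth} bp;
#' dispersed promoters spread tags with random per-position weights
#' (Gamma(1) renormalized) over a \code{dispersed_width}-bp window ending
#' \code{nuc_gap} bp upstream of the true +1 nucleosome center. Per-promoter
#' totals are Poisson(\code{mean_tags}). The dispersed regime still has a
#' true dominant TSS: the window position at (or nearest) the design TSS
#' carries \code{dispersed_dominant_mass} of the tags — dispersed promoters
#' retain a clear but minor dominant position ~125 bp upstream of the +1
#' nucleosome center, with the bulk of initiation spread over the window.
#'
#' Draw order per promoter substream: total, then (dispersed only) the
#' per-position weights, then the multinomial allocation.
#'
#' @param truth truth table from \code{\link{simulate_promoter_landscape}}.
#' @param config the generating \code{\link{sim_config}}.
#' @return A \code{\link{base_signal}} of tag counts.
#' @export
simulate_cage <- function(truth, config) {
  pieces <- list()
  for (i in seq_len(nrow(truth))) {
    p <- truth[i, ]
    res <- .with_substream(config$seed, 17L, i, {
      total <- rpois(1L, config$mean_tags)
      if (total == 0L) NULL else {
        if (p$mode == "focused") {
          fw <- .focused_weights(config$focused_halfwidth,
                                 config$focused_dominant_mass)
          offsets <- fw$offsets
          weights <- fw$weights
        } else {
          hi <- config$nuc_offset - config$nuc_gap
          offsets <- seq.int(hi - config$dispersed_width + 1L, hi)
          weights <- rgamma(length(offsets), shape = 1)
          i_dom <- which.min(abs(offsets))   # window position at/nearest TSS
          weights[i_dom] <- 0
          weights <- weights / sum(weights) *
            (1 - config$dispersed_dominant_mass)
          weights[i_dom] <- config$dispersed_dominant_mass
        }
        counts <- as.vector(rmultinom(1L, total, weights))
        keep <- counts > 0L
        list(offsets = offsets[keep], counts = counts[keep])
      }
    })
    if (is.null(res)) next
    pos <- if (p$strand == "+") p$tss + res$offsets else p$tss - res$offsets
    pieces[[i]] <- data.frame(contig = p$contig, strand = p$strand,
                              pos = pos, count = res$counts,
                              stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0L) return(base_signal())
  df <- do.call(rbind, pieces)
  base_signal(df$contig, df$strand, df$pos, df$count)
}

#' Simulate MNase fragments
#'
#' Fragment centers are round(Normal(true +1 center, class positioning sd));
#' lengths are round(Normal(147, 10)) redrawn while outside [80, 220], so a
#' fraction fails the downstream [100, 200] length filter.
#'
#' Draw order per promoter substream: all centers, then lengths (with
#' redraws in place).
#'
#' @param truth truth table from \code{\link{simulate_promoter_landscape}}.
#' @param config the generating \code{\link{sim_config}}.
#' @return data.frame of strandless fragments (contig, start, end).
#' @export
simulate_mnase <- function(truth, config) {
  n <- config$fragments_per_promoter
  pieces <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    p <- truth[i, ]
    pieces[[i]] <- .with_substream(config$seed, 19L, i, {
      centers <- round(rnorm(n, p$nuc_center, p$nuc_sd))
      lens <- round(rnorm(n, config$mnase_len_mean, config$mnase_len_sd))
      bad <- which(lens < 80 | lens > 220)
      while (length(bad) > 0L) {
        lens[bad] <- round(rnorm(length(bad), config$mnase_len_mean,
                                 config$mnase_len_sd))
        bad <- bad[lens[bad] < 80 | lens[bad] > 220]
      }
      start <- as.integer(centers - floor(lens / 2))
      data.frame(contig = p$contig, start = start,
                 end = as.integer(start + lens), stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, pieces)
}

#' Simulate a two-condition spike-in PRO-seq count matrix
#'
#' Baseline gene means are LogNormal(\code{baseline_meanlog},
#' \code{baseline_sdlog}); in the depleted condition affected genes change
#' by \code{fold_change} and all genes by \code{global_factor}. Reads per
#' sample split between spike-in and reference by Binomial(depth,
#' kappa / (kappa + O_s)) where O_s is the sample's relative total output;
#' reference reads are allocated to genes with negative-binomial noise of
#' dispersion \code{phi}.
#'
#' Draw order: substream 0 draws baselines and the affected-gene subset;
#' sample substream s draws spike reads then gene counts.
#'
#' @param config a \code{\link{sim_config}}.
#' @return List with \code{counts} (gene x sample integer matrix),
#'   \code{samples} (data.frame: sample, condition, replicate, spike_reads,
#'   reference_reads) and \code{truth} (list: \code{genes} data.frame with
#'   true per-gene fold change, \code{samples} data.frame with true total
#'   output factor O_s).
#' @export
simulate_depletion_counts <- function(config) {
  stopifnot(config$phi >= 0, config$depth > 0)
  ng <- config$n_genes
  base <- .with_substream(config$seed, 23L, 0L, {
    lambda <- exp(rnorm(ng, config$baseline_meanlog, config$baseline_sdlog))
    affected <- if (is.null(config$affected_idx)) {
      sample(ng, round(config$frac_affected * ng))
    } else config$affected_idx
    list(lambda = lambda, affected = affected)
  })
  f <- rep(1, ng)
  f[base$affected] <- config$fold_change
  gene_ids <- sprintf("g%05d", seq_len(ng))
  conditions <- rep(c("control", "depleted"), each = config$replicates)
  n_s <- length(conditions)
  counts <- matrix(0L, ng, n_s,
                   dimnames = list(gene_ids, sprintf("s%02d", seq_len(n_s))))
  spike_reads <- integer(n_s)
  O <- ifelse(conditions == "depleted",
              config$global_factor * sum(base$lambda * f) / sum(base$lambda),
              1)
  for (s in seq_len(n_s)) {
    fs <- if (conditions[s] == "depleted") f else rep(1, ng)
    counts_s <- .with_substream(config$seed, 29L, s, {
      sp <- rbinom(1L, config$depth, config$kappa / (config$kappa + O[s]))
      ref <- config$depth - sp
      mu <- ref * base$lambda * fs / sum(base$lambda * fs)
      x <- if (config$phi == 0) rpois(ng, mu)
           else rnbinom(ng, mu = mu, size = 1 / config$phi)
      list(spike = sp, x = x)
    })
    spike_reads[s] <- counts_s$spike
    counts[, s] <- counts_s$x
  }
  samples <- data.frame(
    sample = colnames(counts), condition = conditions,
    replicate = ave(seq_len(n_s), conditions, FUN = seq_along),
    spike_reads = spike_reads,
    reference_reads = colSums(counts), stringsAsFactors = FALSE)
  truth <- list(
    genes = data.frame(gene_id = gene_ids, baseline = base$lambda,
                       fold_change = f, stringsAsFactors = FALSE),
    samples = data.frame(sample = samples$sample, output_factor = O,
                         stringsAsFactors = FALSE))
  list(counts = counts, samples = samples, truth = truth)
}
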