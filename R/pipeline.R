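## Configuration and orchestration of the simulate -> analyze flow with a
## stable on-disk layout. Every analysis table carries the config hash in a
## header comment; identical (config, seed) give byte-identical outputs.

#' Pipeline configuration
#'
#' Bundles the generator configuration with every analysis constant at its
#' default: +/-250 / +/-500 bp TSS-correction windows, the motif percent
#' thresholds, the 20\% activated-TSS ratio, the [100, 200] bp fragment
#' length filter, the +1..+200 bp nucleosome search window, -50..+200 bp
#' cross-correlation lags, the 1.5-fold / 0.05 FDR down-call thresholds,
#' the 5 tpm activity floor, and k = 9 for the k-means overview.
#'
#' @param seed integer seed (propagated to the generator).
#' @param sim a \code{\link{sim_config}}.
#' @param target_classes promoter classes whose genes are depleted in the
#'   simulated scenario (their counts change by \code{sim$fold_change}).
#' @param w_small,w_large TSS-correction search half-windows (bp).
#' @param thresholds,windows motif thresholds and search windows.
#' @param rel_activated activated-TSS relative threshold.
#' @param len_range MNase fragment length filter (bp, inclusive).
#' @param nuc_window +1 nucleosome search window (TSS-relative offsets).
#' @param lags cross-correlation lags (bp).
#' @param fold,fdr down-call thresholds.
#' @param tpm_min CAGE activity floor (tags per million).
#' @param k clusters for the k-means overview.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1,
                            sim = sim_config(seed = seed,
                                             fold_change = 0.25),
                            target_classes = "TATA",
                            w_small = 250, w_large = 500,
                            thresholds = default_thresholds(),
                            windows = default_search_windows(),
                            rel_activated = 0.2,
                            len_range = c(100, 200),
                            nuc_window = c(1, 200),
                            lags = -50:200,
                            fold = 1.5, fdr = 0.05,
                            tpm_min = 5, k = 9) {
  stopifnot(w_small > 0, w_small <= w_large,
            rel_activated > 0, rel_activated <= 1,
            fold >= 1, fdr > 0, fdr < 1)
  unknown <- setdiff(target_classes, names(sim$classes))
  if (length(unknown)) {
    stop("unknown promoter class in scenario: ",
         paste(unknown, collapse = ", "))
  }
  cfg <- as.list(environment())
  cfg$unknown <- NULL
  class(cfg) <- "pipeline_config"
  cfg
}

.strip_classes <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.data.frame(x)) return(as.list(as.data.frame(x)))
  if (is.list(x)) return(lapply(unclass(x), .strip_classes))
  x
}

.config_json <- function(config) {
  jsonlite::toJSON(.strip_classes(config), auto_unbox = TRUE,
                   digits = NA, null = "null")
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(.config_json(config)), tmp)
  unname(md5sum(tmp))
}

.write_table_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_table_hashed <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Run the simulation flow
#'
#' Generates the promoter landscape, CAGE signal, MNase fragments and the
#' two-condition spike-in count matrix, and writes them in standard
#' formats (FASTA, BED12, bedGraph pair, BED, TSV) together with the full
#' ground truth, the config as JSON, and a checksum manifest. Genes of the
#' count matrix map one-to-one onto promoters (gene i is driven by
#' promoter i); genes of \code{target_classes} promoters receive the
#' configured depletion fold change.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param outdir output directory (created if missing).
#' @return \code{outdir}, invisibly.
#' @export
run_simulate <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$sim
  land <- simulate_promoter_landscape(sim)
  sim$n_genes <- nrow(land$truth)
  sim$affected_idx <- which(land$truth$class %in% config$target_classes)
  cage <- simulate_cage(land$truth, sim)
  frags <- simulate_mnase(land$truth, sim)
  depl <- simulate_depletion_counts(sim)
  # count-matrix gene i is driven by promoter i: share identifiers
  gene_ids <- land$transcripts$gene_id
  rownames(depl$counts) <- gene_ids
  depl$truth$genes$gene_id <- gene_ids

  write_genome(land$genome, file.path(outdir, "genome.fa"))
  write_transcripts_bed12(land$transcripts,
                          file.path(outdir, "transcripts.bed12"))
  write_signal_bedgraph(cage, file.path(outdir, "cage"))
  write_fragments_bed(frags, file.path(outdir, "fragments.bed"))
  counts_df <- data.frame(gene_id = rownames(depl$counts), depl$counts,
                          stringsAsFactors = FALSE)
  write.table(counts_df, file.path(outdir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(depl$samples, file.path(outdir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(land$truth, file.path(outdir, "truth_promoters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(depl$truth$genes, file.path(outdir, "truth_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(depl$truth$samples, file.path(outdir, "truth_samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(as.character(.config_json(config)),
             file.path(outdir, "config.json"))

  files <- c("genome.fa", "transcripts.bed12", "cage.plus.bedGraph",
             "cage.minus.bedGraph", "fragments.bed", "counts.tsv",
             "samples.tsv", "truth_promoters.tsv", "truth_genes.tsv",
             "truth_samples.tsv", "config.json")
  sums <- md5sum(file.path(outdir, files))
  write.table(data.frame(file = files, md5 = unname(sums)),
              file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Run the analysis flow
#'
#' Reads a \code{\link{run_simulate}} directory (or any directory with the
#' same layout), runs TSS correction, motif classification, initiation
#' metrics, +1 nucleosome calling, per-regime CAGE x MNase
#' cross-correlation, spike-in-normalized down-calls and motif enrichment,
#' and writes one TSV per result. Deterministic given inputs and config.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param indir input directory.
#' @param outdir report directory (created if missing).
#' @return Named list of result tables, invisibly.
#' @export
run_analyze <- function(config, indir, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)

  genome <- read_genome(file.path(indir, "genome.fa"))
  tx <- load_transcripts(file.path(indir, "transcripts.bed12"), "bed12")
  cage <- read_signal_bedgraph(file.path(indir, "cage"))
  frags <- read_fragments_bed(file.path(indir, "fragments.bed"))
  counts_df <- read.table(file.path(indir, "counts.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- counts_df$gene_id
  samples <- read.table(file.path(indir, "samples.tsv"), sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)

  corrected <- correct_tss(tx, cage, w_small = config$w_small,
                           w_large = config$w_large)
  corrected <- collapse_by_tss(corrected)
  promoters <- data.frame(promoter_id = sub("^t", "p",
                                            corrected$transcript_id),
                          contig = corrected$contig,
                          strand = corrected$strand,
                          tss = corrected$tss, stringsAsFactors = FALSE)

  scores <- score_promoters(genome, promoters)
  flags <- apply_thresholds(scores$percent, config$thresholds)
  labels <- assign_class(flags)
  tpm <- cage_tpm(cage, promoters)
  classification <- data.frame(promoter_id = promoters$promoter_id,
                               label = unname(labels), tpm = tpm,
                               scores$percent, check.names = FALSE,
                               stringsAsFactors = FALSE)

  metrics <- initiation_metrics(cage, promoters,
                                rel = config$rel_activated)

  nuc <- call_plus1(frags, promoters, window = config$nuc_window,
                    len_range = config$len_range)
  nuc$contig <- promoters$contig
  nuc$strand <- promoters$strand

  centers <- fragment_centers(frags, config$len_range)
  hk <- labels %in% c("TCT", "DRE", "Ohler1/6")
  dev <- labels %in% c("TATA", "DPE", "INR")
  xc <- list()
  if (any(hk)) {
    xc$housekeeping <- cage_mnase_crosscorrelation(
      cage, centers, promoters[hk, ], lags = config$lags)
  }
  if (any(dev)) {
    xc$developmental <- cage_mnase_crosscorrelation(
      cage, centers, promoters[dev, ], lags = config$lags)
  }
  xc_tab <- do.call(rbind, lapply(names(xc), function(g) {
    data.frame(group = g, xc[[g]], stringsAsFactors = FALSE)
  }))

  factors <- spike_size_factors(
    setNames(samples$spike_reads, samples$sample))
  de <- call_downregulated(counts, samples, factors,
                           fold = config$fold, fdr = config$fdr)

  gene_of <- setNames(sub("^p", "g", promoters$promoter_id),
                      promoters$promoter_id)
  gflags <- flags
  rownames(gflags) <- gene_of[rownames(flags)]
  expressed <- intersect(de$gene[de$testable], rownames(gflags))
  down <- intersect(de$gene[de$down], expressed)
  enrich <- if (length(down) > 0L) {
    fisher_motif_enrichment(down, expressed, gflags)
  } else {
    data.frame(motif = character(), a = integer(), b = integer(),
               c = integer(), d = integer(), odds_ratio = numeric(),
               log2_odds_ratio = numeric(), p = numeric())
  }

  tabs <- list(correction = corrected, classification = classification,
               initiation_metrics = metrics, nucleosome_calls = nuc,
               crosscorrelation = xc_tab, size_factors =
                 data.frame(sample = names(factors),
                            factor = unname(factors)),
               differential = de, enrichment = enrich)
  for (nm in names(tabs)) {
    .write_table_hashed(tabs[[nm]], file.path(outdir, paste0(nm, ".tsv")),
                        hash)
  }
  invisible(tabs)
}
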