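#' Default pipeline configuration
#'
#' All analysis defaults equal the assay's stated constants: the amplicon
#' adapter, Q35 mismatch rule, 15-nt seed with 2/4 mismatch budgets,
#' 20-read minimum, pseudocount 0.5, +/-0.3 log2 threshold with alpha 0.05,
#' 5-nt junction tolerance, 10 read pairs / 5 exons / 5 kb circRNA filters,
#' and eCLIP P < 0.01 with >= 2-fold enrichment. Simulation settings are
#' sized for a fast demonstration run.
#'
#' @param outdir Output directory for the run.
#' @param seed Global seed.
#' @return A nested configuration list.
#' @export
default_config <- function(outdir = tempfile("tilefate_run_"), seed = 1L) {
  list(
    seed = as.integer(seed), outdir = outdir,
    stages = c("simulate", "count", "localize", "stability", "circquant",
               "annotate"),
    simulate = list(n_tiles = 60L, tile_length = 110L, gc_range = c(0.3, 0.7),
                    depth = 150, replicates = 2L, error_rate = 0.005,
                    shift_levels = c(-1, 0, 1),
                    half_life_levels = c(1, 2, 4, 8),
                    timepoints = c(0, 2, 4, 8), noise_cv = 0.1,
                    n_circs = 8L, circ_abundance = c(nuclear = 40,
                                                     cytoplasmic = 160),
                    jitter_sd = 1),
    matcher = list(adapter = "TAGGAGGCCTCATCTGACTG", umi_length = 10L,
                   quality_min = 35L, seed_length = 15L, max_seed_mm = 2L,
                   max_total_mm = 4L, min_reads = 20L, count_mode = "umi"),
    localize = list(pseudocount = 0.5, threshold = 0.3, alpha = 0.05),
    stability = list(base = 2, t0_normalize = TRUE),
    circquant = list(tolerance = 5L, min_pairs = 10L, max_exons = 5L,
                     max_length = 5000L, pseudocount = 0.5),
    annotate = list(motifs = c(srsf1_like = "GGAGGA", igf2bp_like = "CACACA"),
                    eclip_p_max = 0.01, eclip_min_fold = 2)
  )
}

write_tsv <- function(x, path) {
  fwrite(as.data.table(x, keep.rownames = "id"), path, sep = "\t")
  path
}

#' Run the full pipeline on synthetic data
#'
#' Executes the requested stages in dependency order on generator output:
#' read simulation, tile counting, localization calls, half-life fits,
#' circRNA junction quantification, and motif annotation with stratified
#' comparisons. Every stage writes plain TSV outputs under `config$outdir`
#' and appends to `run.log`; reruns with an identical config reproduce the
#' outputs byte for byte.
#'
#' @param config A configuration list, see [default_config].
#' @return Invisibly, a named list of stage results.
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(is.list(config), !is.null(config$outdir), !is.null(config$seed))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "run.log")
  logf <- function(...) cat(..., "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("tilefate run, seed ", config$seed)
  logf("config: ", paste(deparse(config), collapse = " "))

  stages <- config$stages
  res <- list()
  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    logf("stage ", name, " ...")
    out <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logf("stage ", name, " done")
    out
  }

  cfg_s <- config$simulate
  cfg_m <- do.call(matcher_config, config$matcher)

  res$simulate <- run_stage("simulate", function() {
    lib <- generate_tile_library(cfg_s$n_tiles, cfg_s$tile_length,
                                 cfg_s$gc_range, seed = config$seed)
    shifts <- setNames(rep(cfg_s$shift_levels, length.out = nrow(lib)),
                       lib$tile_id)
    design <- data.table(expand.grid(
      fraction = c("nuclear", "cytoplasmic"),
      replicate = seq_len(cfg_s$replicates), stringsAsFactors = FALSE))
    design[, sample_id := paste0(substr(fraction, 1, 3), "_rep", replicate)]
    sim <- simulate_fragment_reads(lib, design, shifts, depth = cfg_s$depth,
                                   adapter = cfg_m$adapter,
                                   umi_length = cfg_m$umi_length,
                                   error_rate = cfg_s$error_rate,
                                   seed = config$seed + 1L)
    hl <- setNames(rep(cfg_s$half_life_levels, length.out = nrow(lib)),
                   lib$tile_id)
    decay <- simulate_decay_series(lib, hl, timepoints = cfg_s$timepoints,
                                   replicates = 2L, noise_cv = cfg_s$noise_cv,
                                   seed = config$seed + 2L)
    ann <- as_circ_annotation(data.table(
      circ_id = sprintf("circ_%02d", seq_len(cfg_s$n_circs)),
      chrom = "chr1",
      start = seq(10000L, by = 20000L, length.out = cfg_s$n_circs),
      end = seq(12000L, by = 20000L, length.out = cfg_s$n_circs),
      strand = rep(c("+", "-"), length.out = cfg_s$n_circs),
      exon_count = rep(c(2L, 3L, 4L, 6L), length.out = cfg_s$n_circs),
      mature_length = rep(c(800L, 1500L, 3000L, 6000L),
                          length.out = cfg_s$n_circs)))
    abund <- cbind(nuclear = rep(cfg_s$circ_abundance[["nuclear"]],
                                 cfg_s$n_circs),
                   cytoplasmic = rep(cfg_s$circ_abundance[["cytoplasmic"]],
                                     cfg_s$n_circs))
    rownames(abund) <- ann$circ_id
    junc <- simulate_chimeric_junctions(ann, abund, jitter_sd = cfg_s$jitter_sd,
                                        seed = config$seed + 3L)
    write_tile_library(lib, file.path(config$outdir, "library.tsv"))
    list(library = lib, shifts = shifts, design = design, reads = sim$reads,
         half_lives = hl, decay = decay, circ_annotation = ann,
         junctions = junc)
  })

  res$count <- run_stage("count", function() {
    s <- res$simulate
    cm <- build_count_matrix(s$reads, s$library, cfg_m)
    write_tsv(cm$counts, file.path(config$outdir, "counts.tsv"))
    fwrite(cm$stats, file.path(config$outdir, "match_stats.tsv"), sep = "\t")
    logf("match status totals: ",
         paste(capture.output(print(cm$stats)), collapse = "\n"))
    cm
  })

  res$localize <- run_stage("localize", function() {
    s <- res$simulate
    pairs <- data.table(
      numerator = paste0("nuc_rep", seq_len(cfg_s$replicates)),
      denominator = paste0("cyt_rep", seq_len(cfg_s$replicates)),
      replicate = seq_len(cfg_s$replicates))
    ratios <- compute_ratios(res$count$counts, pairs,
                             pseudocount = config$localize$pseudocount,
                             min_reads = cfg_m$min_reads)
    calls <- call_localized_tiles(ratios,
                                  threshold = config$localize$threshold,
                                  alpha = config$localize$alpha)
    fwrite(ratios, file.path(config$outdir, "ratios.tsv"), sep = "\t")
    fwrite(calls, file.path(config$outdir, "localization_calls.tsv"),
           sep = "\t")
    list(ratios = ratios, calls = calls)
  })

  res$stability <- run_stage("stability", function() {
    s <- res$simulate
    norm <- spike_normalize(s$decay$counts, s$decay$spike_ids)
    fits <- fit_decay_matrix(norm, s$decay$samples,
                             base = config$stability$base,
                             t0_normalize = config$stability$t0_normalize)
    fwrite(fits, file.path(config$outdir, "half_lives.tsv"), sep = "\t")
    fits
  })

  res$circquant <- run_stage("circquant", function() {
    s <- res$simulate
    cc <- assign_junctions(s$junctions, s$circ_annotation,
                           tolerance = config$circquant$tolerance)
    filtered <- filter_circs(cc, s$circ_annotation,
                             min_pairs = config$circquant$min_pairs,
                             max_exons = config$circquant$max_exons,
                             max_length = config$circquant$max_length)
    ratios <- if (nrow(filtered) > 0)
      circ_ratios(filtered, "nuclear", "cytoplasmic",
                  pseudocount = config$circquant$pseudocount)
    else data.table(circ_id = character(), log2_ratio = numeric())
    write_tsv(filtered, file.path(config$outdir, "circ_counts.tsv"))
    fwrite(ratios, file.path(config$outdir, "circ_ratios.tsv"), sep = "\t")
    list(counts = cc, filtered = filtered, ratios = ratios)
  })

  res$annotate <- run_stage("annotate", function() {
    s <- res$simulate
    motif_counts <- lapply(config$annotate$motifs, function(m) {
      setNames(vapply(s$library$sequence, scan_motif, integer(1),
                      motif = m, USE.NAMES = FALSE), s$library$tile_id)
    })
    ann_tab <- data.table(tile_id = s$library$tile_id,
                          gc = gc_content(s$library$sequence))
    for (m in names(motif_counts)) ann_tab[[paste0("n_", m)]] <-
      motif_counts[[m]][ann_tab$tile_id]
    strata <- if (!is.null(res$localize)) {
      lapply(motif_counts, function(cnt)
        stratify(res$localize$calls, cnt))
    } else NULL
    fwrite(ann_tab, file.path(config$outdir, "tile_annotations.tsv"),
           sep = "\t")
    list(annotations = ann_tab, strata = strata)
  })

  logf("run complete")
  invisible(res)
}
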