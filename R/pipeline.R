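#' Assemble a pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end demonstration pipeline in
#' one list. Defaults follow the mapping design the package implements:
#' 100-kb ancestry windows, a minimum diagnostic count of 10 in every line,
#' minimum coverage 2 for frequency-based scans, an IBD exclusion threshold
#' of 1 fixed difference per 1,000 sites, 501-SNP Dxy windows, 101-SNP HKA
#' windows, a +/-0.05 candidate band around the 75% combined score, and an
#' 11-My calibration age for the clock.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param chrom_length,causal_position,snp_density,recombination_rate,pool_size
#'   Simulation design (see [simulate_experiment()]).
#' @param window_width Ancestry window width in bases.
#' @param min_count Minimum diagnostic-SNP count per line.
#' @param min_coverage Minimum coverage for frequency-based scans.
#' @param ibd_threshold IBD exclusion threshold (fixed differences per site).
#' @param band Candidate band half-width around the 0.75 target.
#' @param dxy_half_width,hka_half_width Sliding-window half-widths (SNPs).
#' @param peak_multiplier Dxy peak threshold multiple of the median.
#' @param locus_config A [balanced_locus_config()] for the haplotype stages.
#' @param calibration_age Clock calibration age (millions of years).
#' @param n_boot Site bootstraps for dating.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            chrom_length = 1e6,
                            causal_position = NULL,
                            snp_density = 0.005,
                            recombination_rate = 0.1,
                            pool_size = 30,
                            window_width = 1e5,
                            min_count = 10,
                            min_coverage = 2,
                            ibd_threshold = 1e-3,
                            band = 0.05,
                            dxy_half_width = 250,
                            hka_half_width = 50,
                            peak_multiplier = 5,
                            locus_config = balanced_locus_config(),
                            calibration_age = 11,
                            n_boot = 200) {
  structure(as.list(environment()), class = "pipeline_config")
}

write_tsv_commented <- function(df, path, comments) {
  writeLines(paste0("# ", comments), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full simulate-map-scan-test pipeline
#'
#' Executes every stage of the analysis on freshly simulated data and writes
#' all products (sync counts, per-SNP and per-window TSVs, candidate and peak
#' BEDs, haplotype FASTA, newick tree, dating table, JSON manifest with
#' parameter echo and per-file checksums) into `out_dir`. Reruns with the
#' same configuration are byte-identical. A stage failure aborts with the
#' stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the key results (`candidates`, `peaks`,
#'   `hka`, `haplogroups`, `dating`, `manifest`) and the output paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  paths <- list()

  exp <- stage("simulate", simulate_experiment(
    chrom_length = config$chrom_length,
    causal_position = config$causal_position,
    snp_density = config$snp_density,
    recombination_rate = config$recombination_rate,
    pool_size = config$pool_size,
    seed = config$seed
  ))
  paths$sync <- file.path(out_dir, "counts.sync")
  stage("simulate", write_sync(exp$counts, paths$sync,
                               samples = c("dark", "light", "bc", "hom",
                                           "outgroup")))

  map <- stage("map-ancestry", {
    diagnostic <- call_diagnostic_snps(exp$counts, "dark", "light",
                                       min_count = config$min_count)
    anc_bc <- snp_ancestry(exp$counts, diagnostic, "bc")
    anc_hom <- snp_ancestry(exp$counts, diagnostic, "hom")
    win_bc <- window_average(anc_bc, width = config$window_width,
                             chrom_length = config$chrom_length)
    win_hom <- window_average(anc_hom, width = config$window_width,
                              chrom_length = config$chrom_length)
    fd <- window_fixed_diffs(exp$parents, width = config$window_width)
    excluded <- ibd_filter(fd$n_fixed, fd$n_sites, config$ibd_threshold)
    windows <- candidate_windows(win_bc, win_hom, excluded,
                                 band = config$band)
    list(diagnostic = diagnostic, anc_bc = anc_bc, anc_hom = anc_hom,
         windows = windows, intervals = candidate_intervals(windows))
  })
  paths$ancestry_snp <- file.path(out_dir, "ancestry_snp.tsv")
  write_tsv_commented(
    dplyr::rename(dplyr::inner_join(map$anc_bc, map$anc_hom,
                                    by = c("chrom", "pos"),
                                    suffix = c("_bc", "_hom")),
                  depth_bc = "depth_bc", depth_hom = "depth_hom"),
    paths$ancestry_snp,
    c(paste0("min_count=", config$min_count),
      paste0("seed=", config$seed))
  )
  paths$ancestry_windows <- file.path(out_dir, "ancestry_windows.tsv")
  write_tsv_commented(
    map$windows, paths$ancestry_windows,
    c(paste0("window_width=", config$window_width),
      paste0("ibd_threshold=", config$ibd_threshold),
      paste0("band=", config$band), paste0("seed=", config$seed))
  )
  paths$candidates <- file.path(out_dir, "candidates.bed")
  write_bed(map$intervals, paths$candidates)

  scan <- stage("scan-dxy", {
    freqs <- line_frequencies(exp$counts, c("dark", "light"),
                              min_coverage = config$min_coverage)
    sc <- sliding_dxy(freqs, "dark", "light",
                      half_width = config$dxy_half_width)
    list(scan = sc, peaks = peak_interval(sc, config$peak_multiplier))
  })
  paths$dxy <- file.path(out_dir, "dxy_scan.tsv")
  write_tsv_commented(
    scan$scan, paths$dxy,
    c(paste0("half_width=", config$dxy_half_width),
      paste0("min_coverage=", config$min_coverage))
  )
  paths$peaks <- file.path(out_dir, "dxy_peaks.bed")
  write_bed(scan$peaks, paths$peaks)

  hka <- stage("scan-hka", {
    freqs <- line_frequencies(exp$counts, c("dark", "light", "outgroup"),
                              min_coverage = config$min_coverage)
    cls <- classify_sites(freqs$p_dark, freqs$p_light, freqs$p_outgroup)
    window_hka(cls, freqs$pos, half_width = config$hka_half_width)
  })
  paths$hka <- file.path(out_dir, "hka_scan.tsv")
  write_tsv_commented(
    hka, paths$hka, paste0("half_width=", config$hka_half_width)
  )

  haplo <- stage("haplo-stats", {
    aln <- simulate_balanced_locus(config$locus_config,
                                   seed = config$seed + 1)
    assign <- assign_haplogroups(aln)
    tree <- nj_tree(pairwise_distances(aln, ids = ingroup_ids(aln)))
    fst <- per_snp_fst(aln, assign)
    counts <- site_counts(aln, assign)
    ils <- ils_scan(aln, assign)
    list(aln = aln, assign = assign, tree = tree, fst = fst,
         counts = counts, ils = ils)
  })
  paths$fasta <- file.path(out_dir, "balanced_locus.fasta")
  write_alignment(haplo$aln, paths$fasta)
  paths$tree <- file.path(out_dir, "haplotypes.nwk")
  ape::write.tree(haplo$tree, paths$tree)
  paths$fst <- file.path(out_dir, "fst_sites.tsv")
  write_tsv_commented(haplo$fst, paths$fst, "estimator=hudson_1-Hw/Hb")
  paths$ils <- file.path(out_dir, "ils_intervals.bed")
  write_bed(haplo$ils, paths$ils, chrom = "locus")

  dating <- stage("clock-date", {
    aln <- haplo$aln
    cal <- clock_calibration(ingroup_ids(aln), aln$outgroup,
                             age = config$calibration_age)
    date_split(aln, haplo$assign$bipartition$A, haplo$assign$bipartition$B,
               cal, n_boot = config$n_boot, seed = config$seed + 2)
  })
  paths$dating <- file.path(out_dir, "dating.tsv")
  write_tsv_commented(
    tidy(dating), paths$dating,
    c(paste0("calibration_age=", config$calibration_age),
      paste0("n_boot=", config$n_boot), paste0("seed=", config$seed + 2))
  )

  manifest <- list(
    seed = config$seed,
    config = unclass(config)[!vapply(unclass(config), is.list, logical(1))],
    files = as.list(unname(tools::md5sum(unlist(paths))))
  )
  names(manifest$files) <- basename(unlist(paths))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(
    candidates = map$intervals, windows = map$windows, peaks = scan$peaks,
    dxy = scan$scan, hka = hka, haplogroups = haplo$assign,
    site_counts = haplo$counts, ils = haplo$ils, dating = dating,
    manifest = manifest, paths = paths, out_dir = out_dir
  ))
}
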