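# High-level screening pipeline: self-scan of one image, comparison of an
# image pair, and batch screening of a directory (every image against itself
# and every unordered pair). These are the functions the command-line script
# in inst/cli wraps. Exit semantics are operational only: a scan that finds
# candidate shifts is a *successful* scan -- judging manipulation is a human
# decision, and no function here renders a verdict.

#' Screening configuration
#'
#' Bundles every tunable of the screening pipeline with its default. The
#' config is echoed verbatim into each report so every threshold actually
#' applied can be audited.
#'
#' @param algorithms statistics to run on a self-scan.
#' @param pair_algorithms statistics to run on image pairs. Default drops the
#'   nearest-neighbor algorithm, the most expensive and the most fragile
#'   under re-encoding; set it explicitly to include it.
#' @param trivial_radius exclusion radius (pixels, toroidal Chebyshev) around
#'   shift (0, 0); shifts this small reflect neighborhood autocorrelation,
#'   not manipulation.
#' @param thresholds named list of absolute score thresholds per algorithm;
#'   `NULL` entries fall back to grid quantiles (top 0.05% for the counting
#'   algorithms, bottom 0.1% for variance), since absolute counts are
#'   image-specific.
#' @param variance_cutpoint per-block variance cut (gray levels squared) for
#'   the variance localization matrix; `NULL` skips that localization.
#' @param mono_levels gray levels masked as monochrome before the counting
#'   algorithms; see [mask_monochrome()].
#' @param min_rect_area smallest reconstructed rectangle worth reporting.
#' @param localize compute localization matrices and region reconstruction.
#' @param verbose print the thresholds as they are applied.
#' @return A list of class `"scan_config"`.
#' @export
scan_config <- function(algorithms = c("pixelwise", "nearest_neighbor", "variance"),
                        pair_algorithms = c("pixelwise", "variance"),
                        trivial_radius = 5L,
                        thresholds = list(),
                        variance_cutpoint = NULL,
                        mono_levels = c(0L, 255L),
                        min_rect_area = 4L,
                        localize = TRUE,
                        verbose = FALSE) {
  known <- c("pixelwise", "nearest_neighbor", "variance")
  algorithms <- match.arg(algorithms, known, several.ok = TRUE)
  pair_algorithms <- match.arg(pair_algorithms, known, several.ok = TRUE)
  structure(list(algorithms = algorithms, pair_algorithms = pair_algorithms,
                 trivial_radius = as.integer(trivial_radius),
                 thresholds = thresholds,
                 variance_cutpoint = variance_cutpoint,
                 mono_levels = as.integer(mono_levels),
                 min_rect_area = as.integer(min_rect_area),
                 localize = isTRUE(localize), verbose = isTRUE(verbose)),
            class = "scan_config")
}

grid_fun <- function(alg) {
  switch(alg,
         pixelwise = pixelwise_shift_counts,
         nearest_neighbor = nn_shift_counts,
         variance = variance_shift_sums,
         stop(sprintf("unknown algorithm '%s'", alg)))
}

load_scan_input <- function(x, id = NULL) {
  if (is.character(x)) {
    list(img = read_image(x), id = if (is.null(id)) x else id)
  } else {
    list(img = check_image(x, arg = "image"),
         id = if (is.null(id)) "in-memory image" else id)
  }
}

# Core of a scan: run the configured algorithms on a prepared (masked) input
# pair, rank candidates, optionally localize. Returns a screening_report.
run_scan <- function(imgA, imgB, ids, algorithms, config, self_scan) {
  masked <- sentinel_count(imgA) > 0 || sentinel_count(imgB) > 0
  cands <- list()
  grids <- list()
  for (alg in algorithms) {
    if (alg == "variance" && masked) {
      if (config$verbose)
        message("variance algorithm skipped: monochrome areas are masked")
      next
    }
    g <- if (self_scan) grid_fun(alg)(imgA) else grid_fun(alg)(imgA, imgB)
    thr <- config$thresholds[[alg]]
    dirn <- if (alg == "variance") "low" else "high"
    cc <- find_candidate_shifts(g, threshold = thr, direction = dirn,
                                radius = config$trivial_radius,
                                collapse_mirror = self_scan)
    if (config$verbose)
      message(sprintf("%s: threshold %.6g (%s), radius %d -> %d candidate(s)",
                      alg, attr(cc, "threshold"), dirn,
                      config$trivial_radius, nrow(cc)))
    attr(cc, "images") <- ids
    cands[[alg]] <- cc
    grids[[alg]] <- g
  }
  loc <- list()
  if (config$localize && "nearest_neighbor" %in% algorithms) {
    lg <- if (self_scan) localization_nn(imgA) else localization_nn(imgA, imgB)
    peak <- which(lg == max(lg), arr.ind = TRUE)[1L, , drop = TRUE]
    loc$nearest_neighbor <- list(max_count = max(lg),
                                 peak_row = unname(peak[1L]),
                                 peak_col = unname(peak[2L]),
                                 total = sum(lg))
    attr(loc$nearest_neighbor, "grid") <- lg
  }
  if (config$localize && !masked && !is.null(config$variance_cutpoint) &&
      "variance" %in% algorithms) {
    lg <- if (self_scan) localization_variance(imgA, cutpoint = config$variance_cutpoint)
          else localization_variance(imgA, imgB, cutpoint = config$variance_cutpoint)
    loc$variance <- list(cutpoint = config$variance_cutpoint,
                         max_count = max(lg), total = sum(lg))
    attr(loc$variance, "grid") <- lg
  }
  rep <- screening_report(cands, lapply(loc, strip_grid),
                          metadata = list(images = ids,
                                          config = unclass(config)))
  attr(rep, "grids") <- grids
  attr(rep, "localization_grids") <- lapply(loc, attr, "grid")
  rep
}

strip_grid <- function(x) { attr(x, "grid") <- NULL; x }

# Artifact paths are recorded relative to the output directory so that two
# runs with identical inputs give byte-identical reports.
emit_artifacts <- function(report, out_dir, stem) {
  dir.create(file.path(out_dir, "heatmaps"), recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  grids <- attr(report, "grids")
  for (alg in names(grids)) {
    rel <- file.path("heatmaps", sprintf("%s_%s.png", stem, alg))
    write_heatmap(grids[[alg]], file.path(out_dir, rel),
                  invert = (alg == "variance"))
    paths <- c(paths, rel)
  }
  locs <- attr(report, "localization_grids")
  for (alg in names(locs)) {
    rel <- file.path("heatmaps", sprintf("%s_localization_%s.png", stem, alg))
    write_heatmap(locs[[alg]], file.path(out_dir, rel))
    paths <- c(paths, rel)
  }
  cand <- do.call(rbind, lapply(report$algorithms, function(a) a$candidates))
  csv <- sprintf("%s_candidates.csv", stem)
  write.csv(cand, file.path(out_dir, csv), row.names = FALSE)
  c(csv, paths)
}

#' Self-scan one image for copied regions
#'
#' Reads the image, masks monochrome areas, scores every cyclic shift with
#' the configured algorithms, ranks the conspicuous shifts, and localizes
#' matching regions. When the masking leaves sentinels in the image the
#' variance algorithm is skipped (it cannot handle monochrome areas).
#'
#' Mirror shift pairs are collapsed: on a self-scan, shift `(di, dj)` and
#' `(M - di, N - dj)` describe the same duplication seen from either end.
#'
#' @param image file path (PNG/JPEG) or gray-level matrix.
#' @param config a [scan_config()].
#' @param output_dir if non-`NULL`, write `report.json`, a candidate CSV and
#'   shift/localization heatmaps there.
#' @return A `screening_report`, invisibly when `output_dir` is given.
#' @export
scan_image <- function(image, config = scan_config(), output_dir = NULL) {
  inp <- load_scan_input(image)
  prepped <- mask_monochrome(inp$img, config$mono_levels)
  rep <- run_scan(prepped, prepped, inp$id, config$algorithms, config,
                  self_scan = TRUE)
  finish_report(rep, output_dir, "scan")
}

#' Compare two images for duplication
#'
#' Scores every cyclic shift of one image over the other; for unequal sizes
#' the comparison window is the smaller extent and the shift space the
#' larger, so a cropped detail is found at the shift equal to its crop
#' origin.
#'
#' @param image_a,image_b file paths or gray-level matrices.
#' @inheritParams scan_image
#' @return A `screening_report`.
#' @export
compare_images <- function(image_a, image_b, config = scan_config(),
                           output_dir = NULL) {
  a <- load_scan_input(image_a); b <- load_scan_input(image_b)
  pa <- mask_monochrome(a$img, config$mono_levels)
  pb <- mask_monochrome(b$img, config$mono_levels)
  rep <- run_scan(pa, pb, c(a$id, b$id), config$pair_algorithms, config,
                  self_scan = FALSE)
  finish_report(rep, output_dir, "compare")
}

finish_report <- function(rep, output_dir, stem) {
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    rep$artifacts <- emit_artifacts(rep, output_dir, stem)
    write_report(rep, file.path(output_dir, "report.json"))
    return(invisible(rep))
  }
  rep
}

#' Batch-screen a directory of images
#'
#' Runs a self-scan on every PNG/JPEG in the directory and a pair comparison
#' for every unordered pair, and consolidates everything into one report --
#' the screening mode for checking all figures of a manuscript at once.
#'
#' @param directory directory containing at least one readable PNG or JPEG.
#' @inheritParams scan_image
#' @return A list of class `"batch_report"` with elements `self_scans` and
#'   `pair_scans`.
#' @export
batch_screen <- function(directory, config = scan_config(), output_dir = NULL) {
  if (!dir.exists(directory))
    stop(sprintf("directory '%s' does not exist", directory))
  files <- sort(list.files(directory, pattern = "\\.(png|jpe?g)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0)
    stop(sprintf("no PNG or JPEG images found in '%s'", directory))
  selfs <- lapply(files, function(f) scan_image(f, config))
  names(selfs) <- basename(files)
  pairs <- list()
  if (length(files) > 1) {
    combos <- utils::combn(seq_along(files), 2L)
    for (k in seq_len(ncol(combos))) {
      i <- combos[1L, k]; j <- combos[2L, k]
      nm <- paste(basename(files[i]), basename(files[j]), sep = " vs ")
      pairs[[nm]] <- compare_images(files[i], files[j], config)
    }
  }
  out <- structure(list(directory = directory,
                        n_images = length(files),
                        config = unclass(config),
                        self_scans = lapply(selfs, strip_report_attrs),
                        pair_scans = lapply(pairs, strip_report_attrs)),
                   class = "batch_report")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(out, file.path(output_dir, "report.json"))
    return(invisible(out))
  }
  out
}

strip_report_attrs <- function(rep) {
  attr(rep, "grids") <- NULL
  attr(rep, "localization_grids") <- NULL
  rep
}

#' @export
print.batch_report <- function(x, ...) {
  cat(sprintf("batch report: %d image(s) in %s (%d self-scans, %d pair scans)\n",
              x$n_images, x$directory, length(x$self_scans), length(x$pair_scans)))
  invisible(x)
}
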