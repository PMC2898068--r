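# Per-exon mean coverage from a run-length encoded depth track. A depth
# track is a tibble of non-overlapping, sorted 1-based inclusive runs
# (chrom, start, end, depth); positions absent from the track have depth 0.

#' Read a bedGraph-like depth track
#'
#' Four tab-separated columns (chrom, start, end, depth) in the bedGraph
#' convention of 0-based half-open intervals, converted here to 1-based
#' inclusive runs. Runs must not overlap within a chromosome.
#'
#' @param path Path to the track file.
#' @return A depth-track tibble, sorted by (chrom, start).
#' @export
read_depth_track <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "depth"),
    col_types = "ciid", progress = FALSE
  )
  track <- tibble(
    chrom = raw$chrom,
    start = raw$start + 1L,
    end = raw$end,
    depth = raw$depth
  ) |>
    arrange(.data$chrom, .data$start)
  validate_depth_track(track)
}

#' Validate a depth track
#'
#' @param track A tibble with columns `chrom`, `start`, `end`, `depth`
#'   (1-based inclusive runs).
#' @return The sorted, validated track.
#' @export
validate_depth_track <- function(track) {
  track <- as_tibble(track) |> arrange(.data$chrom, .data$start)
  if (any(track$depth < 0)) abort("depth must be >= 0")
  if (any(track$end < track$start)) abort("run with end < start")
  overl <- track |>
    group_by(.data$chrom) |>
    summarise(bad = any(.data$start[-1] <= head(.data$end, -1)), .groups = "drop")
  if (any(overl$bad, na.rm = TRUE)) abort("overlapping runs within a chromosome")
  track
}

#' Mean per-base coverage of each exon
#'
#' Coverage of an exon is the average number of reads covering each base
#' within it: the depth summed over all `end - start + 1` bases (zero for
#' bases absent from the track) divided by the exon length.
#'
#' @param track A depth-track tibble.
#' @param exons An exon tibble.
#' @return `exons` with a `mean_coverage` column appended.
#' @export
exon_mean_coverage <- function(track, exons) {
  track <- validate_depth_track(track)
  if (nrow(exons) == 0) {
    return(mutate(exons, mean_coverage = double(0)))
  }
  cov <- rep(0, nrow(exons))
  if (nrow(track) > 0) {
    ex_gr <- GenomicRanges::GRanges(
      exons$chrom, IRanges::IRanges(exons$start, exons$end)
    )
    tr_gr <- GenomicRanges::GRanges(
      track$chrom, IRanges::IRanges(track$start, track$end)
    )
    hits <- GenomicRanges::findOverlaps(ex_gr, tr_gr)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov_width <- pmin(exons$end[qh], track$end[sh]) -
      pmax(exons$start[qh], track$start[sh]) + 1L
    base_sum <- tapply(ov_width * track$depth[sh], qh, sum)
    idx <- as.integer(names(base_sum))
    cov[idx] <- as.numeric(base_sum)
  }
  mutate(exons, mean_coverage = cov / (.data$end - .data$start + 1L))
}

#' Summarise coverage adequacy across exons
#'
#' Reports the fraction of exons whose mean coverage meets a threshold and
#' the median coverage of that adequately covered subset. With the default
#' `comparator = ">="` an exon at exactly the threshold counts as covered.
#' For an even-sized subset the default median convention is the lower
#' median; `median_type = "interpolate"` uses the usual mean-of-middle-two.
#'
#' @param covs Output of [exon_mean_coverage()] (needs `mean_coverage`).
#' @param threshold Coverage threshold in reads per base (default 5).
#' @param comparator `">="` or `">"`.
#' @param median_type `"lower"` or `"interpolate"`.
#' @return A one-row tibble: `threshold`, `n_exons`, `fraction_ge_threshold`,
#'   `median_of_covered` (`NA` when no exon meets the threshold).
#' @export
coverage_summary <- function(covs, threshold = 5,
                             comparator = c(">=", ">"),
                             median_type = c("lower", "interpolate")) {
  comparator <- match.arg(comparator)
  median_type <- match.arg(median_type)
  if (nrow(covs) == 0) abort("coverage_summary needs at least one exon")
  meets <- if (comparator == ">=") {
    covs$mean_coverage >= threshold
  } else {
    covs$mean_coverage > threshold
  }
  covered <- covs$mean_coverage[meets]
  med <- if (length(covered) == 0) {
    NA_real_
  } else if (median_type == "lower") {
    sort(covered)[ceiling(length(covered) / 2)]
  } else {
    median(covered)
  }
  tibble(
    threshold = threshold,
    n_exons = nrow(covs),
    fraction_ge_threshold = mean(meets),
    median_of_covered = med
  )
}
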