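# Quality-control screens applied to a call set before concordance analysis.
# Rules are applied in a fixed order and each removed call is attributed to
# the first rule it fails.

#' Quality-control filter parameters
#'
#' Defaults follow the screens used for pileup-derived SNV calls: a minimum
#' Phred-scaled SNP quality (30 for cDNA, 20 for gDNA), at least 3 reads
#' supporting the non-reference allele, a maximum site depth (1e7 gDNA, 1e6
#' cDNA), and — for cDNA only — removal of calls where more than 20% of the
#' alt-supporting reads come from the first or last base of their read
#' (splice-boundary misalignment artifacts).
#'
#' Threshold inclusivity is configurable: by default quality exactly at the
#' minimum passes (`>=`), alt support exactly 3 passes, and an end fraction
#' of exactly 0.20 passes (only "more than 20%" fails).
#'
#' @param source `"cDNA"` or `"gDNA"`; sets the defaults.
#' @param min_snp_quality Minimum Phred SNP quality.
#' @param min_alt_support Minimum reads supporting the non-reference allele.
#' @param max_alt_end_fraction Maximum tolerated end-of-read fraction.
#' @param max_site_depth Maximum site read depth.
#' @param apply_end_filter Whether the end-of-read rule is active.
#' @param quality_strict,alt_strict,end_inclusive Comparator knobs: strict
#'   quality uses `>` instead of `>=`; strict alt support likewise;
#'   `end_inclusive = FALSE` would fail a call at exactly the end-fraction
#'   threshold.
#' @return A `filter_params` list.
#' @export
filter_params <- function(source = c("cDNA", "gDNA"),
                          min_snp_quality = NULL,
                          min_alt_support = 3,
                          max_alt_end_fraction = 0.20,
                          max_site_depth = NULL,
                          apply_end_filter = NULL,
                          quality_strict = FALSE,
                          alt_strict = FALSE,
                          end_inclusive = TRUE) {
  source <- match.arg(source)
  is_cdna <- source == "cDNA"
  min_snp_quality <- min_snp_quality %||% if (is_cdna) 30 else 20
  max_site_depth <- max_site_depth %||% if (is_cdna) 1e6 else 1e7
  apply_end_filter <- apply_end_filter %||% is_cdna
  stopifnot(
    min_snp_quality >= 0, min_alt_support >= 0, max_site_depth >= 0,
    max_alt_end_fraction >= 0, max_alt_end_fraction <= 1
  )
  structure(
    list(
      source = source,
      min_snp_quality = min_snp_quality,
      min_alt_support = min_alt_support,
      max_alt_end_fraction = max_alt_end_fraction,
      max_site_depth = max_site_depth,
      apply_end_filter = apply_end_filter,
      quality_strict = quality_strict,
      alt_strict = alt_strict,
      end_inclusive = end_inclusive
    ),
    class = "filter_params"
  )
}

#' Apply quality-control filters to a call set
#'
#' A call passes iff it clears the SNP-quality, alt-support, maximum-depth
#' and (when active) end-of-read rules of `params`; the pass set is a pure
#' conjunction of per-call predicates, so filtering is idempotent and
#' order-independent. Each removed call is attributed to the first failing
#' rule, in the order quality, alt support, max depth, end fraction.
#'
#' @param calls A variant-call tibble from a single source.
#' @param params A [filter_params()] object.
#' @return The passing calls, with a `filter_report` attribute (see
#'   [filter_report()]).
#' @export
filter_calls <- function(calls, params = filter_params(unique(calls$source))) {
  calls <- validate_calls(calls)
  if (length(unique(calls$source)) > 1) {
    abort("filter_calls expects calls from a single source")
  }
  ge <- function(x, t, strict) if (strict) x > t else x >= t
  le <- function(x, t, inclusive) if (inclusive) x <= t else x < t

  ok_qual <- ge(calls$snp_quality, params$min_snp_quality, params$quality_strict)
  ok_alt <- ge(calls$alt_support, params$min_alt_support, params$alt_strict)
  ok_depth <- calls$read_depth <= params$max_site_depth
  ok_end <- if (params$apply_end_filter) {
    le(calls$alt_end_fraction, params$max_alt_end_fraction, params$end_inclusive)
  } else {
    rep(TRUE, nrow(calls))
  }

  first_fail <- dplyr::case_when(
    !ok_qual ~ "min_snp_quality",
    !ok_alt ~ "min_alt_support",
    !ok_depth ~ "max_site_depth",
    !ok_end ~ "max_alt_end_fraction",
    TRUE ~ NA_character_
  )
  pass <- is.na(first_fail)
  removed <- table(factor(
    first_fail[!pass],
    levels = c(
      "min_snp_quality", "min_alt_support",
      "max_site_depth", "max_alt_end_fraction"
    )
  ))
  report <- structure(
    list(
      input_count = nrow(calls),
      pass_count = sum(pass),
      removed_by_rule = tibble(
        rule = names(removed),
        removed = as.integer(removed)
      )
    ),
    class = "filter_report"
  )
  out <- calls[pass, , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the report attached by [filter_calls()]
#'
#' @param calls The tibble returned by [filter_calls()].
#' @return A `filter_report`: input count, pass count and per-rule removal
#'   counts (each removal attributed to the first failing rule).
#' @export
filter_report <- function(calls) {
  rep <- attr(calls, "filter_report")
  if (is.null(rep)) abort("no filter_report attribute; was filter_calls() run?")
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  cat(
    "QC filter report:", x$input_count, "calls in,",
    x$pass_count, "passed\n"
  )
  print(x$removed_by_rule)
  invisible(x)
}

#' @export
format.filter_params <- function(x, ...) {
  paste0(
    "filter_params(", x$source, "): qual>=", x$min_snp_quality,
    ", alt>=", x$min_alt_support, ", depth<=", x$max_site_depth,
    if (x$apply_end_filter) paste0(", end<=", x$max_alt_end_fraction) else ""
  )
}

#' @export
print.filter_params <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Restrict calls to annotated exons
#'
#' Keeps a call iff some exon on the same chromosome covers its position
#' (interval endpoints inclusive), and annotates every kept call with the
#' covering transcript and gene identifiers as list-columns
#' `transcript_ids` and `gene_ids`.
#'
#' @param calls A variant-call tibble.
#' @param exons An exon tibble (see [read_exon_annotation()]).
#' @return The kept calls with annotation list-columns.
#' @export
restrict_to_exons <- function(calls, exons) {
  calls <- validate_calls(calls)
  if (nrow(exons) == 0) {
    warn("empty exon annotation: all calls removed")
    return(calls[0, , drop = FALSE] |>
      mutate(transcript_ids = list(), gene_ids = list()))
  }
  call_gr <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(calls$pos, calls$pos)
  )
  exon_gr <- GenomicRanges::GRanges(
    exons$chrom, IRanges::IRanges(exons$start, exons$end)
  )
  hits <- GenomicRanges::findOverlaps(call_gr, exon_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  keep <- sort(unique(qh))
  tx <- split(exons$transcript_id[sh], qh)
  gn <- split(exons$gene_id[sh], qh)
  out <- calls[keep, , drop = FALSE]
  key <- as.character(keep)
  out$transcript_ids <- map(tx[key], unique)
  out$gene_ids <- map(gn[key], unique)
  out
}
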