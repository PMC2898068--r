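# Concordance metrics recomputed within strata: log-spaced expression bins,
# read-depth windows, paralog status, known-site membership and cumulative
# sequencing lanes. Every stratum result is a row of a `stratum_tbl`
# (a tibble of counts + metrics), so results pipe into dplyr and ggplot2.

.stratum_tbl <- function(stratum, tp, fp, fn, n = NA_integer_) {
  out <- concordance_metrics(tibble(stratum = stratum, tp = tp, fp = fp, fn = fn))
  out$n <- n
  class(out) <- c("stratum_tbl", class(out))
  out
}

#' Log-spaced expression bin edges
#'
#' Builds bin edges on the percent-of-max expression scale at
#' `min_pct * 10^(k / bins_per_decade)`, capped at `max_pct`. With the
#' defaults (2 bins per decade from 0.04% to 100%) the 4% "well-expressed"
#' threshold falls exactly on an edge.
#'
#' @param min_pct Lowest edge (> 0; log scale).
#' @param max_pct Highest edge (<= 100).
#' @param bins_per_decade Number of bins per factor of 10 (>= 1).
#' @param expressed_threshold The percent-of-max level above which a
#'   transcript counts as well expressed (default 4). Must coincide with an
#'   edge (within floating-point rounding).
#' @return A numeric vector of strictly increasing edges with attribute
#'   `expressed_threshold`, of class `expression_bins`.
#' @export
make_log_bins <- function(min_pct = 0.04, max_pct = 100, bins_per_decade = 2,
                          expressed_threshold = 4) {
  if (!(min_pct > 0 && min_pct < max_pct && max_pct <= 100)) {
    abort("need 0 < min_pct < max_pct <= 100")
  }
  if (bins_per_decade < 1) abort("bins_per_decade must be >= 1")
  k_max <- ceiling(bins_per_decade * log10(max_pct / min_pct))
  edges <- min_pct * 10^(seq(0, k_max) / bins_per_decade)
  edges <- unique(pmin(edges, max_pct))
  if (min(abs(edges - expressed_threshold)) > 1e-9 * expressed_threshold) {
    abort("expressed_threshold must coincide with a bin edge")
  }
  structure(edges,
    expressed_threshold = expressed_threshold,
    class = "expression_bins"
  )
}

# expression value for each call: MAX over covering transcripts (a variant is
# detectable if any covering transcript is expressed)
.call_expression <- function(tx_ids, expr) {
  lut <- setNames(expr$expression_pct, expr$transcript_id)
  if (any(lengths(tx_ids) == 0)) {
    abort("call without transcript annotation; run restrict_to_exons() first")
  }
  map_dbl(tx_ids, function(tx) {
    v <- lut[tx]
    if (all(is.na(v))) {
      abort(paste0(
        "transcript(s) missing from expression table: ",
        paste(tx, collapse = ", ")
      ))
    }
    max(v, na.rm = TRUE)
  })
}

.tx_col <- function(x, side = c("plain", "gdna", "cdna")) {
  side <- match.arg(side)
  nm <- switch(side,
    plain = "transcript_ids",
    gdna = "gdna_transcript_ids",
    cdna = "cdna_transcript_ids"
  )
  if (!nm %in% names(x)) {
    abort(paste0("missing annotation column ", nm, "; run restrict_to_exons() first"))
  }
  x[[nm]]
}

#' Concordance metrics within expression bins
#'
#' Each call is assigned one expression value — the maximum percent-of-max
#' expression over its covering transcripts — and the bin containing that
#' value; TP/FP/FN counts and sensitivity/specificity are then recomputed
#' per bin. TP pairs use the gDNA-side transcript annotation (both sides
#' share the position, hence the exons).
#'
#' @param classified An `snv_classification` built from exon-restricted
#'   (annotated) call sets.
#' @param expr Expression tibble ([read_expression_table()]).
#' @param bins An [make_log_bins()] object.
#' @return A `stratum_tbl` with one row per occupied bin, ordered by
#'   expression, with columns `expr_lo`, `expr_hi`, counts and metrics.
#' @export
stratify_by_expression <- function(classified, expr, bins = make_log_bins()) {
  edges <- as.numeric(bins)
  assign_bin <- function(e) {
    # values below the first edge fall in bin 0 (below min_pct); values at an
    # edge belong to the bin it closes: bins are (lo, hi]
    findInterval(e, edges, left.open = TRUE) + 1L
  }
  e_tp <- .call_expression(.tx_col(classified$tp, "gdna"), expr)
  e_fp <- .call_expression(.tx_col(classified$fp, "plain"), expr)
  e_fn <- .call_expression(.tx_col(classified$fn, "plain"), expr)
  all_bins <- tibble(
    bin = c(assign_bin(e_tp), assign_bin(e_fp), assign_bin(e_fn)),
    class = rep(c("tp", "fp", "fn"), c(length(e_tp), length(e_fp), length(e_fn)))
  )
  counts <- all_bins |>
    count(.data$bin, .data$class) |>
    tidyr::pivot_wider(
      names_from = "class", values_from = "n", values_fill = 0L
    ) |>
    arrange(.data$bin)
  for (cl in c("tp", "fp", "fn")) if (!cl %in% names(counts)) counts[[cl]] <- 0L
  lo <- c(0, edges)
  hi <- c(edges, Inf)
  .stratum_tbl(
    stratum = paste0("expr(", signif(lo[counts$bin], 3), ",", signif(hi[counts$bin], 3), "]"),
    tp = counts$tp, fp = counts$fp, fn = counts$fn,
    n = counts$tp + counts$fp + counts$fn
  ) |>
    mutate(
      expr_lo = lo[counts$bin],
      expr_hi = hi[counts$bin]
    )
}

#' Concordance metrics within a cDNA read-depth window
#'
#' Restricts cDNA-side calls (TP pairs by their cDNA read depth, FPs by
#' their read depth) to `[d_min, d_max]` (both ends inclusive) before
#' recomputing TP and FP. False negatives are recomputed against the *full*
#' gDNA set — gDNA depth is a different quantity — so sensitivity drops when
#' the window excludes true calls.
#'
#' @param classified A position-mode `snv_classification`.
#' @param d_min,d_max Window bounds in reads (`d_max` may be `Inf`).
#' @return A one-row `stratum_tbl`.
#' @export
filter_by_depth_window <- function(classified, d_min = 1, d_max = Inf) {
  if (d_min < 1 || d_max < d_min) abort("need d_min >= 1 and d_max >= d_min")
  tp_in <- classified$tp$cdna_read_depth >= d_min &
    classified$tp$cdna_read_depth <= d_max
  fp_in <- classified$fp$read_depth >= d_min &
    classified$fp$read_depth <= d_max
  tp <- sum(tp_in)
  fp <- sum(fp_in)
  fn <- classified$n_gdna - tp
  .stratum_tbl(
    stratum = paste0("depth[", d_min, ",", d_max, "]"),
    tp = tp, fp = fp, fn = fn, n = tp + fp
  )
}

#' Concordance metrics for genes with and without paralogs
#'
#' A call belongs to the with-paralog stratum iff *any* of its covering
#' genes is annotated as having a paralog ("any-rule": one paralogous
#' covering gene suffices, since one misalignment source suffices to taint
#' the site). The two strata are disjoint and exhaustive.
#'
#' @param classified An `snv_classification` from annotated call sets.
#' @param genes Gene annotation tibble ([read_gene_annotations()]).
#' @return A two-row `stratum_tbl` (`with_paralog`, `without_paralog`).
#' @export
partition_by_paralog <- function(classified, genes) {
  lut <- setNames(genes$has_paralog, genes$gene_id)
  tainted <- function(gene_ids) {
    all_ids <- unique(unlist(gene_ids))
    missing <- setdiff(all_ids, names(lut))
    if (length(missing) > 0) {
      abort(paste0(
        "gene(s) absent from annotation table: ",
        paste(missing, collapse = ", ")
      ))
    }
    map_lgl(gene_ids, function(g) any(lut[g]))
  }
  gene_col <- function(x, side) {
    nm <- if (side == "pair") "gdna_gene_ids" else "gene_ids"
    if (!nm %in% names(x)) {
      abort(paste0("missing annotation column ", nm, "; run restrict_to_exons() first"))
    }
    x[[nm]]
  }
  t_tp <- tainted(gene_col(classified$tp, "pair"))
  t_fp <- tainted(gene_col(classified$fp, "single"))
  t_fn <- tainted(gene_col(classified$fn, "single"))
  .stratum_tbl(
    stratum = c("with_paralog", "without_paralog"),
    tp = c(sum(t_tp), sum(!t_tp)),
    fp = c(sum(t_fp), sum(!t_fp)),
    fn = c(sum(t_fn), sum(!t_fn)),
    n = c(
      sum(t_tp) + sum(t_fp) + sum(t_fn),
      sum(!t_tp) + sum(!t_fp) + sum(!t_fn)
    )
  )
}

#' Known-site (dbSNP-like) membership rate per class
#'
#' For each class — TP, FP, FN and the whole gDNA set (TP plus FN) — the
#' fraction of its members whose (chrom, pos) appears in the known-site
#' list. Matching is by position only.
#'
#' @param classified An `snv_classification`.
#' @param sites Position-set tibble ([read_position_set()]).
#' @return A tibble with columns `class`, `n`, `n_known`, `rate`.
#' @export
known_site_rates <- function(classified, sites) {
  keys <- paste(sites$chrom, sites$pos)
  rate_of <- function(chrom, pos) {
    hit <- paste(chrom, pos) %in% keys
    tibble(n = length(hit), n_known = sum(hit), rate = if (length(hit) > 0) mean(hit) else 0)
  }
  bind_rows(
    mutate(rate_of(classified$tp$chrom, classified$tp$pos), class = "TP"),
    mutate(rate_of(classified$fp$chrom, classified$fp$pos), class = "FP"),
    mutate(rate_of(classified$fn$chrom, classified$fn$pos), class = "FN"),
    mutate(rate_of(
      c(classified$tp$chrom, classified$fn$chrom),
      c(classified$tp$pos, classified$fn$pos)
    ), class = "gDNA_all")
  ) |>
    select("class", "n", "n_known", "rate")
}

#' Concordance as a function of cumulative sequencing lanes
#'
#' Takes cumulative cDNA call-set snapshots (lane 1, lanes 1-2, ...) — all
#' filtered with one fixed QC configuration — classifies each against the
#' same gDNA set and reports per-snapshot counts and metrics. A decreasing
#' TP count between snapshots violates the cumulative-data assumption and
#' is reported with a warning, never silently fixed.
#'
#' @param lane_callsets Ordered list of cDNA call tibbles, one per
#'   cumulative lane count.
#' @param gdna The gDNA call tibble.
#' @param mode Matching mode passed to [classify_calls()].
#' @return A `stratum_tbl` with one row per snapshot and a `lanes` column.
#' @export
lane_accumulation_curve <- function(lane_callsets, gdna, mode = "position") {
  if (length(lane_callsets) == 0) abort("need at least one lane snapshot")
  rows <- imap(lane_callsets, function(cdna, i) {
    glance(classify_calls(gdna, cdna, mode = mode)) |>
      mutate(lanes = as.integer(i))
  }) |> list_rbind()
  if (is.unsorted(rows$tp)) {
    warn("true-positive count decreases between lane snapshots")
  }
  out <- rows |>
    mutate(stratum = paste0("lanes=", .data$lanes), n = .data$tp + .data$fp) |>
    select("stratum", "tp", "fp", "fn", "mode", "sensitivity", "specificity", "n", "lanes")
  class(out) <- c("stratum_tbl", class(out))
  out
}
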