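# Shared miniature annotation: a well-expressed gene, a barely expressed
# paralogous gene, and a second transcript overlapping the first gene so the
# max-over-transcripts rule is exercised.
strat_exons <- function() {
  tibble::tibble(
    chrom = "chr1",
    start = c(1L, 50L, 201L),
    end = c(100L, 100L, 300L),
    transcript_id = c("TX_HI", "TX_MID", "TX_LO"),
    gene_id = c("G_HI", "G_HI", "G_LO"),
    is_core = TRUE, is_canonical = TRUE
  )
}

strat_expr <- function() {
  tibble::tibble(
    transcript_id = c("TX_HI", "TX_MID", "TX_LO"),
    expression_pct = c(50, 2, 0.5)
  )
}

strat_genes <- function() {
  tibble::tibble(gene_id = c("G_HI", "G_LO"), has_paralog = c(FALSE, TRUE))
}

annotate <- function(calls) restrict_to_exons(calls, strat_exons())

strat_classified <- function() {
  gdna <- annotate(dplyr::bind_rows(
    new_call(10, source = "gDNA"), # TP in G_HI
    new_call(60, source = "gDNA"), # TP in G_HI (covered by TX_HI and TX_MID)
    new_call(210, source = "gDNA"), # TP in G_LO
    new_call(90, source = "gDNA") # FN in G_HI
  ))
  cdna <- annotate(dplyr::bind_rows(
    new_call(10, depth = 300),
    new_call(60, depth = 40),
    new_call(210, depth = 4, alt = 3),
    new_call(250, depth = 3000, alt = 100) # FP in G_LO
  ))
  classify_calls(gdna, cdna, "position")
}

test_that("log bin edges are geometric and anchor the expressed threshold", {
  bins <- make_log_bins()
  edges <- as.numeric(bins)
  expect_equal(edges[1], 0.04)
  expect_equal(edges[length(edges)], 100)
  ratios <- edges[-1] / edges[-length(edges)]
  expect_true(all(abs(ratios[-length(ratios)] - sqrt(10)) < 1e-9))
  expect_true(any(abs(edges - 4) < 1e-9)) # 4% lies exactly on an edge
  expect_equal(attr(bins, "expressed_threshold"), 4)
  expect_error(make_log_bins(min_pct = 0.05), "coincide")
  expect_error(make_log_bins(min_pct = 0), "min_pct")
  expect_error(make_log_bins(max_pct = 150), "max_pct")
})

test_that("expression strata use max-over-transcripts and (lo, hi] bins", {
  cls <- strat_classified()
  strata <- stratify_by_expression(cls, strat_expr())
  expect_s3_class(strata, "stratum_tbl")
  # calls in G_HI land in the bin containing 50 (max of 50 and 2),
  # calls in G_LO in the bin containing 0.5
  hi_bin <- strata[strata$expr_lo < 50 & strata$expr_hi >= 50, ]
  lo_bin <- strata[strata$expr_lo < 0.5 & strata$expr_hi >= 0.5, ]
  expect_equal(hi_bin$tp, 2L)
  expect_equal(hi_bin$fn, 1L)
  expect_equal(hi_bin$fp, 0L)
  expect_equal(lo_bin$tp, 1L)
  expect_equal(lo_bin$fp, 1L)
  # totals are conserved across bins
  expect_equal(sum(strata$tp), nrow(cls$tp))
  expect_equal(sum(strata$fp), nrow(cls$fp))
  expect_equal(sum(strata$fn), nrow(cls$fn))
  expect_equal(strata$n, strata$tp + strata$fp + strata$fn)
})

test_that("expression exactly at an edge closes its bin; below-minimum gets bin 0", {
  exons <- tibble::tibble(
    chrom = "chr1", start = c(1L, 201L), end = c(100L, 300L),
    transcript_id = c("TX_EDGE", "TX_TINY"), gene_id = c("G1", "G2"),
    is_core = TRUE, is_canonical = TRUE
  )
  expr <- tibble::tibble(
    transcript_id = c("TX_EDGE", "TX_TINY"),
    expression_pct = c(4, 0.01) # exactly the threshold edge; below min edge
  )
  gdna <- restrict_to_exons(
    dplyr::bind_rows(new_call(10, source = "gDNA"), new_call(210, source = "gDNA")),
    exons
  )
  cls <- classify_calls(gdna, gdna[0, ], "position")
  strata <- stratify_by_expression(cls, expr)
  at_edge <- strata[strata$fn > 0 & strata$expr_hi >= 4 & strata$expr_lo < 4, ]
  expect_equal(at_edge$expr_hi, 4) # value 4 belongs to the bin it closes
  expect_true(any(strata$expr_lo == 0)) # 0.01 falls below the lowest edge
})

test_that("expression stratification demands annotation and known transcripts", {
  cls0 <- classify_calls(
    new_call(10, source = "gDNA"), new_call(10)
  )
  expect_error(stratify_by_expression(cls0, strat_expr()), "transcript")
  cls <- strat_classified()
  expect_error(
    stratify_by_expression(cls, strat_expr()[1:2, ]),
    "missing from expression table"
  )
})

test_that("depth window restricts cDNA calls but keeps the full gDNA denominator", {
  cls <- strat_classified()
  # cDNA depths: TP 300, 40, 4; FP 3000
  w <- filter_by_depth_window(cls, 50, 1200)
  expect_equal(w$tp, 1L)
  expect_equal(w$fp, 0L)
  expect_equal(w$fn, cls$n_gdna - 1L)
  expect_equal(w$sensitivity, 1 / cls$n_gdna)
  expect_equal(w$specificity, 1)
  all_in <- filter_by_depth_window(cls, 1, Inf)
  expect_equal(all_in$tp, nrow(cls$tp))
  expect_equal(all_in$fp, nrow(cls$fp))
  expect_error(filter_by_depth_window(cls, 0), "d_min")
  expect_error(filter_by_depth_window(cls, 10, 5), "d_min")
})

test_that("paralog partition is disjoint, exhaustive and uses the any-rule", {
  cls <- strat_classified()
  part <- partition_by_paralog(cls, strat_genes())
  expect_equal(part$stratum, c("with_paralog", "without_paralog"))
  with_p <- part[1, ]
  without_p <- part[2, ]
  # G_LO (paralogous) holds one TP and one FP; G_HI the rest
  expect_equal(with_p$tp, 1L)
  expect_equal(with_p$fp, 1L)
  expect_equal(with_p$fn, 0L)
  expect_equal(without_p$tp, 2L)
  expect_equal(without_p$fn, 1L)
  expect_equal(with_p$tp + without_p$tp, nrow(cls$tp))
  expect_equal(with_p$fp + without_p$fp, nrow(cls$fp))
  expect_equal(with_p$fn + without_p$fn, nrow(cls$fn))
  expect_error(
    partition_by_paralog(cls, strat_genes()[1, ]),
    "absent from annotation"
  )
})

test_that("known-site rates are per-class position-membership fractions", {
  cls <- strat_classified()
  sites <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(10L, 90L, 250L, 60L) # TP, FN, FP, and a different chromosome
  )
  rates <- known_site_rates(cls, sites)
  get <- function(cl) rates[rates$class == cl, ]
  expect_equal(get("TP")$rate, 1 / 3) # pos 10 of {10, 60, 210}
  expect_equal(get("FP")$rate, 1) # pos 250 of {250}
  expect_equal(get("FN")$rate, 1) # pos 90 of {90}
  ga <- get("gDNA_all")
  expect_equal(ga$n, nrow(cls$tp) + nrow(cls$fn))
  expect_equal(ga$n_known, 2L)
  expect_equal(ga$rate, 2 / 4)
  # chr2:60 must not match chr1:60
  expect_equal(get("TP")$n_known, 1L)
})

test_that("lane curve classifies each cumulative snapshot against one gDNA set", {
  gdna <- dplyr::bind_rows(
    new_call(10, source = "gDNA"),
    new_call(20, source = "gDNA"),
    new_call(30, source = "gDNA")
  )
  snaps <- list(
    new_call(10),
    dplyr::bind_rows(new_call(10), new_call(20), new_call(99)),
    dplyr::bind_rows(new_call(10), new_call(20), new_call(30), new_call(99))
  )
  curve <- lane_accumulation_curve(snaps, gdna)
  expect_equal(curve$lanes, 1:3)
  expect_equal(curve$tp, c(1L, 2L, 3L))
  expect_equal(curve$fp, c(0L, 1L, 1L))
  expect_equal(curve$fn, c(2L, 1L, 0L))
  expect_equal(curve$sensitivity, c(1, 2, 3) / 3)
  expect_equal(curve$specificity, c(1, 2 / 3, 3 / 4))
  # a shrinking snapshot is reported, not silently fixed
  expect_warning(
    lane_accumulation_curve(list(snaps[[2]], snaps[[1]]), gdna),
    "decreases"
  )
  expect_error(lane_accumulation_curve(list(), gdna), "at least one")
})

test_that("stratum tables plot through autoplot and helpers", {
  cls <- strat_classified()
  strata <- stratify_by_expression(cls, strat_expr())
  expect_s3_class(ggplot2::autoplot(strata), "ggplot")
  part <- partition_by_paralog(cls, strat_genes())
  expect_s3_class(ggplot2::autoplot(part), "ggplot")
  curve <- lane_accumulation_curve(list(new_call(10)), new_call(10, source = "gDNA"))
  expect_s3_class(ggplot2::autoplot(curve), "ggplot")
  expect_s3_class(plot_lane_tp(curve), "ggplot")
  covs <- tibble::tibble(mean_coverage = c(0, 3, 10))
  expect_s3_class(plot_exon_coverage(covs), "ggplot")
})
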