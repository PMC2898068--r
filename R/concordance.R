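# Classification of a cDNA call set against a gDNA call set. The gDNA set is
# the reference: a cDNA call confirmed in gDNA is a true positive, a
# cDNA-only call a false positive, a gDNA-only call a false negative.

#' Classify cDNA calls against gDNA calls
#'
#' In `"position"` mode a pair matches iff it shares (chrom, pos). In
#' `"genotype"` mode an exact unordered-allele-pair match is also required;
#' a position-matched but genotype-mismatched pair then counts as one false
#' positive *and* one false negative (the genomic variant was missed and a
#' wrong variant was asserted), which keeps the confusion-matrix
#' conservation laws intact. This tallying is configurable via
#' `mismatch_policy`.
#'
#' @param gdna,cdna Variant-call tibbles, QC-filtered and exon-restricted,
#'   unique per (chrom, pos) within each set.
#' @param mode `"position"` or `"genotype"`.
#' @param mismatch_policy How a position-matched genotype mismatch is
#'   tallied in genotype mode: `"fp+fn"` (default), `"fp"` or `"neither"`.
#' @return An object of class `snv_classification` with components `tp`
#'   (tibble of matched pairs, gDNA columns prefixed `gdna_`, cDNA columns
#'   `cdna_`), `fp` (cDNA-only calls), `fn` (gDNA-only calls), `mode`, and
#'   the two input sizes.
#' @export
classify_calls <- function(gdna, cdna, mode = c("position", "genotype"),
                           mismatch_policy = c("fp+fn", "fp", "neither")) {
  mode <- match.arg(mode)
  mismatch_policy <- match.arg(mismatch_policy)
  gdna <- validate_calls(gdna)
  cdna <- validate_calls(cdna)
  for (nm in c("gdna", "cdna")) {
    x <- get(nm)
    if (anyDuplicated(x[, c("chrom", "pos")])) {
      abort(paste0("duplicate positions in ", nm, " set; dedup at read time"))
    }
  }
  key <- function(x) paste(x$chrom, x$pos)
  gk <- key(gdna)
  ck <- key(cdna)
  shared <- intersect(gk, ck)
  gi <- match(shared, gk)
  ci <- match(shared, ck)
  if (length(shared) > 0 &&
    any(gdna$ref_allele[gi] != cdna$ref_allele[ci])) {
    abort("reference allele disagreement at shared positions: inputs must share a reference build")
  }

  prefix <- function(x, p) {
    stats::setNames(x, ifelse(
      names(x) %in% c("chrom", "pos", "ref_allele"),
      names(x), paste0(p, names(x))
    ))
  }
  pairs <- bind_cols(
    prefix(gdna[gi, , drop = FALSE], "gdna_"),
    prefix(cdna[ci, setdiff(names(cdna), c("chrom", "pos", "ref_allele")),
      drop = FALSE
    ], "cdna_")
  )
  gt_match <- pairs$gdna_allele1 == pairs$cdna_allele1 &
    pairs$gdna_allele2 == pairs$cdna_allele2

  if (mode == "position") {
    tp <- pairs
    fp <- cdna[-ci, , drop = FALSE]
    fn <- gdna[-gi, , drop = FALSE]
    if (length(ci) == 0) fp <- cdna
    if (length(gi) == 0) fn <- gdna
  } else {
    tp <- pairs[gt_match, , drop = FALSE]
    mism <- pairs[!gt_match, , drop = FALSE]
    fp_extra <- if (mismatch_policy %in% c("fp+fn", "fp")) mism else mism[0, ]
    fn_extra <- if (mismatch_policy == "fp+fn") mism else mism[0, ]
    fp_only <- if (length(ci) == 0) cdna else cdna[-ci, , drop = FALSE]
    fn_only <- if (length(gi) == 0) gdna else gdna[-gi, , drop = FALSE]
    fp <- bind_rows(
      fp_only,
      .unprefix(fp_extra, "cdna_")
    )
    fn <- bind_rows(
      fn_only,
      .unprefix(fn_extra, "gdna_")
    )
  }
  structure(
    list(
      tp = as_tibble(tp), fp = as_tibble(fp), fn = as_tibble(fn),
      mode = mode, n_gdna = nrow(gdna), n_cdna = nrow(cdna)
    ),
    class = "snv_classification"
  )
}

.unprefix <- function(pairs, p) {
  keep <- c("chrom", "pos", "ref_allele", names(pairs)[startsWith(names(pairs), p)])
  out <- pairs[, intersect(keep, names(pairs)), drop = FALSE]
  names(out) <- sub(paste0("^", p), "", names(out))
  out
}

#' @export
print.snv_classification <- function(x, ...) {
  cat(
    "SNV classification (", x$mode, " mode): TP=", nrow(x$tp),
    " FP=", nrow(x$fp), " FN=", nrow(x$fn), "\n",
    sep = ""
  )
  invisible(x)
}

#' Confusion counts of a classification
#'
#' @param classified An `snv_classification`.
#' @return A one-row tibble with `tp`, `fp`, `fn` and `mode`.
#' @export
concordance_counts <- function(classified) {
  tibble(
    tp = nrow(classified$tp),
    fp = nrow(classified$fp),
    fn = nrow(classified$fn),
    mode = classified$mode
  )
}

#' Sensitivity and specificity from confusion counts
#'
#' Sensitivity is TP/(TP+FN), the fraction of genome-identified exonic SNVs
#' recovered by RNA-Seq; specificity is TP/(TP+FP), the fraction of RNA-Seq
#' calls confirmed in the genome (a precision, despite its name). An
#' undefined ratio (zero denominator) is reported as `NA`, never as 0.
#'
#' @param counts A tibble with columns `tp`, `fp`, `fn` (one or more rows),
#'   or an `snv_classification`.
#' @return The input tibble with `sensitivity` and `specificity` columns.
#' @export
concordance_metrics <- function(counts) {
  if (inherits(counts, "snv_classification")) {
    counts <- concordance_counts(counts)
  }
  counts |>
    mutate(
      sensitivity = ifelse(.data$tp + .data$fn > 0,
        .data$tp / (.data$tp + .data$fn), NA_real_
      ),
      specificity = ifelse(.data$tp + .data$fp > 0,
        .data$tp / (.data$tp + .data$fp), NA_real_
      )
    )
}

#' Zygosity agreement among position-matched pairs
#'
#' Assigns every position-matched pair to exactly one category:
#' heterozygous in gDNA but homozygous in cDNA (allelic imbalance or low
#' cDNA coverage), homozygous in gDNA but heterozygous in cDNA, matching
#' zygosity, or a complete allele mismatch (the pair shares no allele).
#'
#' @param classified A position-mode `snv_classification`.
#' @return A one-row tibble of the four category counts; they sum to TP.
#' @export
zygosity_breakdown <- function(classified) {
  if (classified$mode != "position") {
    abort("zygosity_breakdown needs a position-mode classification")
  }
  tp <- classified$tp
  g_zyg <- zygosity(tp$gdna_allele1, tp$gdna_allele2)
  c_zyg <- zygosity(tp$cdna_allele1, tp$cdna_allele2)
  shares <- tp$gdna_allele1 == tp$cdna_allele1 |
    tp$gdna_allele1 == tp$cdna_allele2 |
    tp$gdna_allele2 == tp$cdna_allele1 |
    tp$gdna_allele2 == tp$cdna_allele2
  cat4 <- dplyr::case_when(
    !shares ~ "full_allele_mismatch",
    g_zyg == "het" & c_zyg == "hom" ~ "het_gdna_hom_cdna",
    g_zyg == "hom" & c_zyg == "het" ~ "hom_gdna_het_cdna",
    TRUE ~ "zygosity_match"
  )
  tibble(
    het_gdna_hom_cdna = sum(cat4 == "het_gdna_hom_cdna"),
    hom_gdna_het_cdna = sum(cat4 == "hom_gdna_het_cdna"),
    zygosity_match = sum(cat4 == "zygosity_match"),
    full_allele_mismatch = sum(cat4 == "full_allele_mismatch")
  )
}

#' @describeIn classify_calls One row per union position with its class
#'   label and both genotypes (where present).
#' @param x An `snv_classification`.
#' @param ... Unused.
#' @method tidy snv_classification
#' @export
tidy.snv_classification <- function(x, ...) {
  gt <- function(a1, a2) ifelse(is.na(a1), NA_character_, paste0(a1, "/", a2))
  bind_rows(
    tibble(
      chrom = x$tp$chrom, pos = x$tp$pos, class = "TP",
      gdna_genotype = gt(x$tp$gdna_allele1, x$tp$gdna_allele2),
      cdna_genotype = gt(x$tp$cdna_allele1, x$tp$cdna_allele2)
    ),
    tibble(
      chrom = x$fp$chrom, pos = x$fp$pos, class = "FP",
      gdna_genotype = NA_character_,
      cdna_genotype = gt(x$fp$allele1, x$fp$allele2)
    ),
    tibble(
      chrom = x$fn$chrom, pos = x$fn$pos, class = "FN",
      gdna_genotype = gt(x$fn$allele1, x$fn$allele2),
      cdna_genotype = NA_character_
    )
  ) |>
    arrange(.data$chrom, .data$pos)
}

#' @describeIn classify_calls One-row summary: counts plus sensitivity and
#'   specificity.
#' @method glance snv_classification
#' @export
glance.snv_classification <- function(x, ...) {
  concordance_metrics(concordance_counts(x))
}
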