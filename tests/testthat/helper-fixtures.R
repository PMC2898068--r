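# Constructors and independent brute-force oracles used across the suite.
# Oracles are deliberately naive (nested loops, per-base expansion) and share
# no code with the implementation paths they check.

new_call <- function(pos, chrom = "chr1", ref = "A", a1 = "A", a2 = "G",
                     qual = 50, depth = 30, alt = 10, endf = 0,
                     source = "cDNA") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref_allele = ref,
    allele1 = pmin(a1, a2), allele2 = pmax(a1, a2),
    snp_quality = qual, read_depth = as.integer(depth),
    alt_support = as.integer(alt), alt_end_fraction = endf, source = source
  )
}

# random call set over distinct positions, with spread-out QC covariates
random_callset <- function(n, max_pos = 500, source = "cDNA",
                           chroms = c("chr1", "chr2")) {
  pos_pool <- expand.grid(chrom = chroms, pos = seq_len(max_pos),
                          stringsAsFactors = FALSE)
  pick <- pos_pool[sample.int(nrow(pos_pool), n), ]
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1))
  het <- runif(n) < 0.6
  depth <- 3L + rpois(n, 40)
  new_call(
    pos = pick$pos, chrom = pick$chrom, ref = ref,
    a1 = ifelse(het, ref, alt), a2 = alt,
    qual = round(runif(n, 0, 80)),
    depth = depth,
    alt = pmin(depth, 1L + rpois(n, 15)),
    endf = round(runif(n), 2),
    source = source
  )
}

random_exons <- function(n, max_pos = 500, chroms = c("chr1", "chr2")) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample(5:60, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = as.integer(start), end = as.integer(start + len),
    transcript_id = sprintf("TX%03d", seq_len(n)),
    gene_id = sprintf("G%03d", seq_len(n)),
    is_core = TRUE, is_canonical = TRUE
  )
}

# plain data-frame view for whole-table comparisons: drops the bookkeeping
# attributes (filter_report, n_indels_skipped) that ride along on results
plain <- function(x) {
  x <- as.data.frame(x)
  attr(x, "filter_report") <- NULL
  attr(x, "n_indels_skipped") <- NULL
  rownames(x) <- NULL
  x
}

# --- oracles ---------------------------------------------------------------

# per-call predicate re-check of the QC rules
oracle_filter_pass <- function(calls, params) {
  vapply(seq_len(nrow(calls)), function(i) {
    c0 <- calls[i, ]
    c0$snp_quality >= params$min_snp_quality &&
      c0$alt_support >= params$min_alt_support &&
      c0$read_depth <= params$max_site_depth &&
      (!params$apply_end_filter ||
        c0$alt_end_fraction <= params$max_alt_end_fraction)
  }, logical(1))
}

# quadratic all-pairs interval scan
oracle_in_exon <- function(calls, exons) {
  vapply(seq_len(nrow(calls)), function(i) {
    hit <- FALSE
    for (j in seq_len(nrow(exons))) {
      if (calls$chrom[i] == exons$chrom[j] &&
        calls$pos[i] >= exons$start[j] && calls$pos[i] <= exons$end[j]) {
        hit <- TRUE
      }
    }
    hit
  }, logical(1))
}

# nested-loop matcher returning tp/fp/fn counts
oracle_classify_counts <- function(gdna, cdna, mode = "position") {
  tp <- 0L
  matched_c <- rep(FALSE, nrow(cdna))
  matched_g <- rep(FALSE, nrow(gdna))
  for (i in seq_len(nrow(gdna))) {
    for (j in seq_len(nrow(cdna))) {
      same_pos <- gdna$chrom[i] == cdna$chrom[j] && gdna$pos[i] == cdna$pos[j]
      same_gt <- same_pos &&
        gdna$allele1[i] == cdna$allele1[j] && gdna$allele2[i] == cdna$allele2[j]
      if ((mode == "position" && same_pos) || (mode == "genotype" && same_gt)) {
        tp <- tp + 1L
        matched_c[j] <- TRUE
        matched_g[i] <- TRUE
      }
    }
  }
  list(tp = tp, fp = sum(!matched_c), fn = sum(!matched_g))
}

# per-base expansion of a run-length depth track
oracle_exon_mean <- function(track, exon) {
  total <- 0
  for (p in seq(exon$start, exon$end)) {
    for (j in seq_len(nrow(track))) {
      if (track$chrom[j] == exon$chrom &&
        p >= track$start[j] && p <= track$end[j]) {
        total <- total + track$depth[j]
      }
    }
  }
  total / (exon$end - exon$start + 1)
}

random_track <- function(n_runs = 10, chrom = "chr1", max_pos = 200) {
  start <- sort(sample.int(max_pos, n_runs))
  end <- pmin(start + sample(0:15, n_runs, replace = TRUE), max_pos + 20L)
  # drop runs that overlap their successor
  keep <- c(end[-n_runs] < start[-1], TRUE)
  tibble::tibble(
    chrom = chrom, start = as.integer(start[keep]),
    end = as.integer(end[keep]),
    depth = sample(0:50, sum(keep), replace = TRUE)
  )
}
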