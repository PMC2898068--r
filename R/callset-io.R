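# Readers and writers for the external tables. Internal coordinates are
# 1-based inclusive everywhere (pileup/VCF convention); BED and bedGraph are
# converted at the boundary.

#' Read a variant-call table
#'
#' Reads SNV calls from either the pileup-style TSV dialect (tab-separated
#' with header `chrom pos ref genotype_iupac snp_quality read_depth
#' alt_support alt_end_fraction`) or a standard VCF. Indel rows are skipped
#' and their count reported; duplicate positions are collapsed with
#' [dedup_calls()].
#'
#' For VCF input, `snp_quality` is taken from QUAL, `read_depth` from the
#' sample DP, `alt_support` from the alternate-allele AD field, and
#' `alt_end_fraction` from a custom `ENDFRAC` INFO key (0 with a warning if
#' absent). Genotypes come from GT plus REF/ALT; rows whose genotype calls
#' more than two distinct alleles are rejected.
#'
#' @param path Path to the file.
#' @param dialect `"pileup-tsv"` or `"vcf"`.
#' @param source Which call set this is: `"gDNA"` or `"cDNA"`.
#' @return A validated variant-call tibble (see [validate_calls()]); the
#'   number of skipped indel rows is attached as attribute `n_indels_skipped`
#'   and reported with a message.
#' @export
read_variant_table <- function(path, dialect = c("pileup-tsv", "vcf"),
                               source = c("gDNA", "cDNA")) {
  dialect <- match.arg(dialect)
  source <- match.arg(source)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  calls <- switch(dialect,
    "pileup-tsv" = .read_pileup_tsv(path, source),
    "vcf" = .read_vcf(path, source)
  )
  n_skipped <- attr(calls, "n_indels_skipped") %||% 0L
  if (n_skipped > 0) {
    inform(paste0("skipped ", n_skipped, " indel row(s) in ", basename(path)))
  }
  out <- calls |>
    validate_calls() |>
    dedup_calls()
  attr(out, "n_indels_skipped") <- n_skipped
  out
}

.read_pileup_tsv <- function(path, source) {
  want <- c(
    "chrom", "pos", "ref", "genotype_iupac", "snp_quality",
    "read_depth", "alt_support", "alt_end_fraction"
  )
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_double(),
      ref = readr::col_character(),
      genotype_iupac = readr::col_character(),
      snp_quality = readr::col_double(),
      read_depth = readr::col_double(),
      alt_support = readr::col_double(),
      alt_end_fraction = readr::col_double()
    ),
    progress = FALSE
  )
  missing <- setdiff(want, names(raw))
  if (length(missing) > 0) {
    abort(paste0("pileup-tsv lacks column(s): ", paste(missing, collapse = ", ")))
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0(
      "malformed pileup-tsv row at line ", probs$row[1] + 1L, " of ", path
    ))
  }
  # indel rows: ref or genotype longer than one base, or '*' placeholders
  is_indel <- nchar(raw$ref) != 1L | nchar(raw$genotype_iupac) != 1L |
    raw$ref == "*" | raw$genotype_iupac == "*"
  n_indel <- sum(is_indel)
  raw <- raw[!is_indel, , drop = FALSE]
  gt <- decode_iupac(raw$genotype_iupac)
  out <- tibble(
    chrom = raw$chrom,
    pos = as.integer(raw$pos),
    ref_allele = toupper(raw$ref),
    allele1 = gt$allele1,
    allele2 = gt$allele2,
    snp_quality = raw$snp_quality,
    read_depth = as.integer(raw$read_depth),
    alt_support = as.integer(raw$alt_support),
    alt_end_fraction = raw$alt_end_fraction,
    source = source
  )
  attr(out, "n_indels_skipped") <- as.integer(n_indel)
  out
}

.read_vcf <- function(path, source) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- tibble(
      chrom = character(), pos = integer(), ref_allele = character(),
      allele1 = character(), allele2 = character(), snp_quality = double(),
      read_depth = integer(), alt_support = integer(),
      alt_end_fraction = double(), source = character()
    )
    attr(out, "n_indels_skipped") <- 0L
    return(out)
  }
  if (ncol(vcf@gt) != 2L) abort("VCF must contain exactly one sample")
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")[, 1]
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(vcf, element = "DP")[, 1]))
  ad <- vcfR::extract.gt(vcf, element = "AD")[, 1]
  endfrac <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "ENDFRAC")))
  if (all(is.na(endfrac))) {
    warn("no ENDFRAC INFO key in VCF; alt_end_fraction set to 0")
    endfrac <- rep(0, nrow(fix))
  }
  endfrac[is.na(endfrac)] <- 0

  alts <- stringr::str_split(fix$ALT, stringr::fixed(","))
  is_indel <- nchar(fix$REF) != 1L |
    map_lgl(alts, function(a) any(nchar(a) != 1L | a == "*"))
  keep <- which(!is_indel)
  n_indel <- sum(is_indel)

  rows <- map(keep, function(i) {
    alleles <- c(fix$REF[i], alts[[i]])
    idx <- suppressWarnings(
      as.integer(stringr::str_split(gt_raw[i], "[/|]")[[1]])
    )
    if (length(idx) != 2L || anyNA(idx) || any(idx + 1L > length(alleles))) {
      abort(paste0("malformed GT at ", fix$CHROM[i], ":", fix$POS[i]))
    }
    called <- alleles[idx + 1L]
    if (length(unique(called)) > 2L) {
      warn(paste0(
        "rejecting multi-allelic genotype at ", fix$CHROM[i], ":", fix$POS[i]
      ))
      return(NULL)
    }
    ad_i <- suppressWarnings(as.integer(stringr::str_split(ad[i], ",")[[1]]))
    # alt support: AD count of the called non-reference allele
    alt_allele <- setdiff(called, fix$REF[i])
    alt_n <- if (length(alt_allele) == 0 || anyNA(ad_i)) {
      NA_integer_
    } else {
      sum(ad_i[match(alt_allele, alleles)], na.rm = TRUE)
    }
    tibble(
      chrom = fix$CHROM[i],
      pos = as.integer(fix$POS[i]),
      ref_allele = fix$REF[i],
      allele1 = called[1],
      allele2 = called[2],
      snp_quality = suppressWarnings(as.numeric(fix$QUAL[i])),
      read_depth = dp[i],
      alt_support = alt_n,
      alt_end_fraction = endfrac[i],
      source = source
    )
  })
  out <- list_rbind(purrr::compact(rows))
  attr(out, "n_indels_skipped") <- as.integer(n_indel)
  out
}

#' Write a variant-call table in the pileup-tsv dialect
#'
#' @param calls A variant-call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(calls, path) {
  calls <- validate_calls(calls)
  out <- tibble(
    chrom = calls$chrom,
    pos = calls$pos,
    ref = calls$ref_allele,
    genotype_iupac = encode_iupac(calls$allele1, calls$allele2),
    snp_quality = calls$snp_quality,
    read_depth = calls$read_depth,
    alt_support = calls$alt_support,
    alt_end_fraction = calls$alt_end_fraction
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an exon annotation in BED dialect
#'
#' BED (0-based half-open) with the name field encoding
#' `transcript_id|gene_id`; optional fifth and sixth columns carry 0/1
#' core-exon and canonical-transcript flags (default both TRUE). Coordinates
#' are converted to 1-based inclusive (`start = bedStart + 1`,
#' `end = bedEnd`). Exact duplicate records are dropped with a message.
#'
#' @param path Path to the BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `transcript_id`,
#'   `gene_id`, `is_core`, `is_canonical`.
#' @export
read_exon_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(
    path,
    col_names = FALSE, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    warn(paste0("empty exon annotation: ", path))
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      transcript_id = character(), gene_id = character(),
      is_core = logical(), is_canonical = logical()
    ))
  }
  if (ncol(raw) < 4) abort("exon BED needs at least 4 columns")
  name <- stringr::str_split_fixed(raw[[4]], stringr::fixed("|"), 2)
  if (any(name[, 2] == "")) {
    abort("exon BED name field must encode transcript_id|gene_id")
  }
  exons <- tibble(
    chrom = raw[[1]],
    start = as.integer(raw[[2]]) + 1L,
    end = as.integer(raw[[3]]),
    transcript_id = name[, 1],
    gene_id = name[, 2],
    is_core = if (ncol(raw) >= 5) raw[[5]] == "1" else TRUE,
    is_canonical = if (ncol(raw) >= 6) raw[[6]] == "1" else TRUE
  )
  if (any(exons$end < exons$start)) {
    abort("exon with end < start after BED conversion")
  }
  n0 <- nrow(exons)
  exons <- distinct(exons)
  if (nrow(exons) < n0) {
    inform(paste0("dropped ", n0 - nrow(exons), " duplicate exon record(s)"))
  }
  dup_key <- duplicated(exons[, c("chrom", "start", "end", "transcript_id")])
  if (any(dup_key)) {
    abort("exon records must be unique on (chrom, start, end, transcript_id)")
  }
  exons
}

#' Write an exon annotation in BED dialect
#'
#' Inverse of [read_exon_annotation()]; coordinates converted back to 0-based
#' half-open.
#'
#' @param exons Exon tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exon_annotation <- function(exons, path) {
  out <- tibble(
    chrom = exons$chrom,
    start = exons$start - 1L,
    end = exons$end,
    name = paste(exons$transcript_id, exons$gene_id, sep = "|"),
    is_core = as.integer(exons$is_core),
    is_canonical = as.integer(exons$is_canonical)
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a transcript-expression table
#'
#' TSV with header columns `transcript_id` and `expression_pct`, where
#' expression is the percent of the most highly expressed transcript in the
#' tissue (0-100).
#'
#' @param path Path to the TSV.
#' @return A tibble with one row per transcript.
#' @export
read_expression_table <- function(path) {
  raw <- .read_headered_tsv(path, c("transcript_id", "expression_pct"))
  expr <- tibble(
    transcript_id = raw$transcript_id,
    expression_pct = as.numeric(raw$expression_pct)
  )
  if (any(is.na(expr$expression_pct) |
    expr$expression_pct < 0 | expr$expression_pct > 100)) {
    abort("expression_pct must lie in [0, 100]")
  }
  if (anyDuplicated(expr$transcript_id)) {
    abort("duplicate transcript_id rows in expression table")
  }
  expr
}

#' Read a gene paralog-annotation table
#'
#' TSV with header columns `gene_id` and `has_paralog` (0/1 or TRUE/FALSE).
#'
#' @param path Path to the TSV.
#' @return A tibble with one row per gene.
#' @export
read_gene_annotations <- function(path) {
  raw <- .read_headered_tsv(path, c("gene_id", "has_paralog"))
  genes <- tibble(
    gene_id = raw$gene_id,
    has_paralog = raw$has_paralog %in% c("1", "TRUE", "true")
  )
  if (anyDuplicated(genes$gene_id)) {
    abort("duplicate gene_id rows in gene annotation table")
  }
  genes
}

#' Read a known-site position list
#'
#' TSV with header columns `chrom` and `pos` (1-based), e.g. a dbSNP-like
#' site list. Duplicate positions are collapsed.
#'
#' @param path Path to the TSV.
#' @return A tibble of unique (chrom, pos) keys.
#' @export
read_position_set <- function(path) {
  raw <- .read_headered_tsv(path, c("chrom", "pos"))
  distinct(tibble(chrom = raw$chrom, pos = as.integer(raw$pos)))
}

.read_headered_tsv <- function(path, want) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(want, names(raw))
  if (length(missing) > 0) {
    abort(paste0(path, " lacks column(s): ", paste(missing, collapse = ", ")))
  }
  raw
}

#' Convert a quality-score character code between encodings
#'
#' Sequencer base qualities are Phred scores stored as printable characters
#' with an offset; older Illumina pipelines used offset 64 while the Sanger
#' FASTQ standard uses 33. The underlying Phred value is preserved.
#'
#' @param encoded Integer character code(s).
#' @param offset_from Offset of the input encoding (default 64).
#' @param offset_to Offset of the output encoding (default 33).
#' @return Integer character code(s) in the target encoding.
#' @export
#' @examples
#' convert_quality_score(104) # Qphred 40: 104 -> 73
convert_quality_score <- function(encoded, offset_from = 64L, offset_to = 33L) {
  if (any(encoded < offset_from)) {
    abort("encoded quality below the source offset: corrupt encoding")
  }
  as.integer(encoded - offset_from + offset_to)
}
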