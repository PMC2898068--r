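# Genotypes are unordered allele pairs stored as two sorted columns
# (allele1 <= allele2); phase is never represented.

.IUPAC <- c(
  A = "A/A", C = "C/C", G = "G/G", T = "T/T",
  R = "A/G", Y = "C/T", S = "C/G", W = "A/T", K = "G/T", M = "A/C"
)

#' Decode an IUPAC genotype code into an unordered allele pair
#'
#' Single bases (`A`, `C`, `G`, `T`) decode to homozygous pairs; two-allele
#' ambiguity codes (`R`, `Y`, `S`, `W`, `K`, `M`) decode to heterozygous
#' pairs. Three- and four-allele codes (`B`, `D`, `H`, `V`, `N`) are not
#' valid diploid genotypes and raise an error.
#'
#' @param code Character vector of single-letter IUPAC codes.
#' @return A tibble with columns `allele1` and `allele2`, alleles sorted so
#'   the pair is a canonical unordered genotype.
#' @export
#' @examples
#' decode_iupac(c("R", "T"))
decode_iupac <- function(code) {
  code <- toupper(code)
  bad <- setdiff(unique(code), names(.IUPAC))
  if (length(bad) > 0) {
    abort(paste0(
      "unknown or non-diploid IUPAC genotype code(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  pair <- stringr::str_split_fixed(.IUPAC[code], "/", 2)
  tibble(allele1 = pair[, 1], allele2 = pair[, 2])
}

#' Encode an unordered allele pair as an IUPAC code
#'
#' Inverse of [decode_iupac()]; allele order does not matter.
#'
#' @param allele1,allele2 Character vectors of single bases (A/C/G/T).
#' @return Character vector of IUPAC codes.
#' @export
encode_iupac <- function(allele1, allele2) {
  key <- paste(pmin(allele1, allele2), pmax(allele1, allele2), sep = "/")
  lut <- setNames(names(.IUPAC), .IUPAC)
  out <- lut[key]
  if (anyNA(out)) {
    abort(paste0(
      "cannot encode allele pair(s): ",
      paste(unique(key[is.na(out)]), collapse = ", ")
    ))
  }
  unname(out)
}

#' Zygosity of an allele pair
#'
#' @param allele1,allele2 Character vectors of single bases.
#' @return `"hom"` where the two alleles are identical, else `"het"`.
#' @export
zygosity <- function(allele1, allele2) {
  ifelse(allele1 == allele2, "hom", "het")
}

.canonical_genotype <- function(calls) {
  mutate(calls,
    a1 = pmin(.data$allele1, .data$allele2),
    a2 = pmax(.data$allele1, .data$allele2),
    allele1 = .data$a1, allele2 = .data$a2,
    a1 = NULL, a2 = NULL
  )
}

.variant_cols <- c(
  "chrom", "pos", "ref_allele", "allele1", "allele2",
  "snp_quality", "read_depth", "alt_support", "alt_end_fraction", "source"
)

#' Validate a variant-call table
#'
#' Checks the invariants of the SNV call model: required columns present,
#' 1-based positions, non-negative Phred quality, `0 <= alt_support <=
#' read_depth`, `alt_end_fraction` in \[0, 1\], a single `source` (gDNA or
#' cDNA), and that every call carries at least one non-reference allele.
#' Genotypes are canonicalised to sorted unordered pairs.
#'
#' @param calls A data frame of variant calls.
#' @return The validated tibble (invisibly identical content, canonical
#'   genotype order).
#' @export
validate_calls <- function(calls) {
  calls <- as_tibble(calls)
  missing <- setdiff(.variant_cols, names(calls))
  if (length(missing) > 0) {
    abort(paste0("variant table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  calls <- .canonical_genotype(calls)
  with(calls, {
    if (any(pos < 1)) abort("positions must be 1-based (pos >= 1)")
    if (any(snp_quality < 0)) abort("snp_quality must be >= 0")
    if (any(alt_support < 0 | alt_support > read_depth)) {
      abort("alt_support must satisfy 0 <= alt_support <= read_depth")
    }
    if (any(alt_end_fraction < 0 | alt_end_fraction > 1)) {
      abort("alt_end_fraction must lie in [0, 1]")
    }
    if (!all(source %in% c("gDNA", "cDNA"))) abort("source must be gDNA or cDNA")
    if (any(allele1 == ref_allele & allele2 == ref_allele)) {
      abort("every call must carry at least one non-reference allele")
    }
  })
  calls
}

#' Collapse duplicate call positions within one call set
#'
#' At each (chrom, pos) the record with the highest `snp_quality` is kept;
#' ties break deterministically by (chrom, pos, genotype) lexicographic
#' order.
#'
#' @param calls A variant-call tibble.
#' @return A tibble with one row per (chrom, pos).
#' @export
dedup_calls <- function(calls) {
  calls |>
    arrange(
      .data$chrom, .data$pos, desc(.data$snp_quality),
      .data$allele1, .data$allele2
    ) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE)
}
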