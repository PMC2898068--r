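# Ground-truthed synthetic data for the whole pipeline. Reads are never
# materialised: per-site read depths and allele-support counts are sampled
# directly (Poisson depth proportional to expression and lane count, binomial
# allele sampling), which is what the downstream call tables consume.

#' Simulation parameters
#'
#' Defaults describe a desk-scale PBMC-like study: eight lanes of ~35 million
#' reads, ~24x mean genomic depth, an exonic variant rate of 0.0016 per base,
#' a silent/expressed lognormal expression mixture on the percent-of-max
#' scale, 73% of genes carrying a paralog, and cDNA depth calibrated so the
#' median expressed-exon coverage at the full lane count is 126x. False
#' positives arise from three processes: paralog misalignment (intensity
#' proportional to depth on paralog-flagged genes), end-of-read splice
#' artifacts (alt-supporting bases drawn from read ends), and base-call
#' errors (three same-base errors at one site).
#'
#' @param n_genes Number of genes (one transcript each).
#' @param exons_per_gene_mean Mean exons per gene (>= 1).
#' @param exon_length_mean Mean exon length in bases.
#' @param het_rate Variants per exon base.
#' @param hom_fraction Fraction of variants homozygous non-reference.
#' @param expression_silent_fraction Fraction of genes effectively silent.
#' @param expression_sdlog Lognormal sd (log scale) of the expressed body.
#' @param paralog_fraction Fraction of genes flagged as having a paralog.
#' @param lanes Sequencing lanes in the full study.
#' @param reads_per_lane Reads per lane (metadata; depths are sampled
#'   directly).
#' @param gdna_mean_depth Mean gDNA read depth per site.
#' @param per_base_error Per-base sequencing error probability.
#' @param paralog_fp_rate Mean misaligned-read intensity per unit of the
#'   source locus' depth: at a paralog-misalignment site, misaligned reads
#'   arrive at a per-site fraction (uniform on (0, 2 * `paralog_fp_rate`),
#'   mean `paralog_fp_rate`) of the depth of a randomly drawn source
#'   paralog, adding to the target exon's own depth. Silent targets of
#'   weakly expressed sources thus yield low-depth, nearly all-alternate
#'   calls; highly expressed pairs yield very deep ones.
#' @param paralog_artifact_sites_per_exon Expected planted misalignment sites
#'   per paralog-flagged exon (misalignment does not require the target to be
#'   expressed).
#' @param end_artifact_rate Probability that a read supporting an end-artifact
#'   site is a read-end base.
#' @param end_artifact_sites_per_exon Expected planted end-artifact sites per
#'   adequately covered exon.
#' @param allelic_imbalance Probability a heterozygous site expresses one
#'   allele almost exclusively (half toward each allele).
#' @param known_site_probs Known-site (dbSNP-like) membership probability per
#'   planted class: named vector with `variant` and `artifact`.
#' @param target_median_expressed_depth Median cDNA depth the expressed exons
#'   (>= `expressed_threshold` percent-of-max) should reach at the full lane
#'   count; fixes the depth-per-expression constant.
#' @param expressed_threshold Percent-of-max level defining "expressed".
#' @param read_length Read length in bases (sets the baseline end-of-read
#'   fraction 2/read_length).
#' @param seed Integer random seed; identical config + seed gives identical
#'   output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              exons_per_gene_mean = 4,
                              exon_length_mean = 160,
                              het_rate = 0.0016,
                              hom_fraction = 0.35,
                              expression_silent_fraction = 0.47,
                              expression_sdlog = 0.94,
                              paralog_fraction = 0.73,
                              lanes = 8,
                              reads_per_lane = 35e6,
                              gdna_mean_depth = 24,
                              per_base_error = 0.001,
                              paralog_fp_rate = 0.25,
                              paralog_artifact_sites_per_exon = 0.5,
                              end_artifact_rate = 0.8,
                              end_artifact_sites_per_exon = 0.05,
                              allelic_imbalance = 0.2,
                              known_site_probs = c(variant = 0.90, artifact = 0.23),
                              target_median_expressed_depth = 126,
                              expressed_threshold = 4,
                              read_length = 75,
                              seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(
    het_rate, hom_fraction, expression_silent_fraction, paralog_fraction,
    per_base_error, end_artifact_rate, allelic_imbalance, known_site_probs
  )
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (!all(c("variant", "artifact") %in% names(known_site_probs))) {
    abort("known_site_probs needs elements 'variant' and 'artifact'")
  }
  stopifnot(
    n_genes >= 1, exons_per_gene_mean >= 1, exon_length_mean >= 10,
    lanes >= 1, gdna_mean_depth >= 0, seed < 2^31
  )
  structure(cfg, class = "simulation_config")
}

#' Simulate the latent truth of a study
#'
#' Lays out genes as tiled exons on one synthetic chromosome, assigns each
#' gene an expression level (percent of the most expressed transcript,
#' rescaled so the maximum is exactly 100) and a paralog flag, plants true
#' variants (heterozygous or homozygous, with an optional allelic-imbalance
#' state governing cDNA allele sampling), plants paralog-misalignment and
#' end-of-read artifact sites, and draws known-site membership per planted
#' class.
#'
#' @param config A [simulation_config()].
#' @return A `truth_set` list: `exons`, `expression`, `genes`, `known_sites`,
#'   `variants` (with per-site cDNA allele probability), `artifacts`, and the
#'   calibrated per-lane depth constant `k_depth`.
#' @export
simulate_truth <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("GENE%05d", seq_len(n))
  transcript_id <- sprintf("TX%05d", seq_len(n))

  genes <- tibble(
    gene_id = gene_id,
    has_paralog = runif(n) < config$paralog_fraction
  )

  silent <- runif(n) < config$expression_silent_fraction
  raw <- rlnorm(n,
    meanlog = ifelse(silent, -6, 0),
    sdlog = ifelse(silent, 0.5, config$expression_sdlog)
  )
  expression <- tibble(
    transcript_id = transcript_id,
    expression_pct = 100 * raw / max(raw)
  )

  n_ex <- 1L + rpois(n, config$exons_per_gene_mean - 1)
  ex_gene <- rep(seq_len(n), n_ex)
  len <- pmax(30L, as.integer(round(
    stats::rgamma(length(ex_gene), shape = 4, scale = config$exon_length_mean / 4)
  )))
  # tile: 100 bp between exons, 1000 bp between genes
  gap <- ifelse(c(TRUE, diff(ex_gene) != 0), 1000L, 100L)
  start <- cumsum(gap) + c(0L, cumsum(head(len, -1)))
  exons <- tibble(
    chrom = "chrS",
    start = start,
    end = start + len - 1L,
    transcript_id = transcript_id[ex_gene],
    gene_id = gene_id[ex_gene],
    is_core = runif(length(ex_gene)) < 0.85,
    is_canonical = TRUE
  )

  # depth calibration: per-lane per-base rate k * expression_pct, with k set
  # so expressed exons reach the target median depth at the full lane count
  expr_by_gene <- setNames(expression$expression_pct, gene_id)
  expressed <- expression$expression_pct >= config$expressed_threshold
  med_expr <- if (any(expressed)) median(expression$expression_pct[expressed]) else 1
  k_depth <- config$target_median_expressed_depth / (config$lanes * med_expr)

  # true variants
  n_var <- rbinom(nrow(exons), exons$end - exons$start + 1L, config$het_rate)
  variants <- .plant_sites(exons, n_var) |>
    mutate(
      ref = .random_base(n()),
      alt = .random_base(n(), avoid = .data$ref),
      hom = runif(n()) < config$hom_fraction
    )
  imb <- runif(nrow(variants))
  half <- config$allelic_imbalance / 2
  variants <- variants |>
    mutate(
      cdna_alt_prob = dplyr::case_when(
        .data$hom ~ 1 - config$per_base_error,
        imb < half ~ 1 - config$per_base_error, # monoallelic, alt expressed
        imb < 2 * half ~ config$per_base_error, # monoallelic, ref expressed
        TRUE ~ 0.5
      ),
      in_known_set = runif(n()) < config$known_site_probs[["variant"]],
      class = "variant"
    )

  # paralog-misalignment artifact sites on paralog-flagged exons; each site
  # draws a misalignment source whose expression sets the misaligned-read
  # depth (reads land on the target whether or not the target is expressed)
  exon_depth <- k_depth * config$lanes * expr_by_gene[exons$gene_id]
  paralogous <- genes$has_paralog[match(exons$gene_id, genes$gene_id)]
  n_par <- rpois(nrow(exons), config$paralog_artifact_sites_per_exon * paralogous)
  par_sites <- .plant_sites(exons, n_par, avoid = variants) |>
    mutate(class = "paralog_artifact")
  par_sites$source_expr_pct <- sample(
    expression$expression_pct, nrow(par_sites), replace = TRUE
  )
  par_sites$misalign_fraction <- runif(nrow(par_sites), 0, 2 * config$paralog_fp_rate)

  # end-of-read splice artifacts near exon boundaries of covered exons
  covered <- exon_depth >= 5
  n_end <- rpois(nrow(exons), config$end_artifact_sites_per_exon * covered)
  end_sites <- .plant_sites(exons, n_end,
    avoid = bind_rows(variants[, c("chrom", "pos")], par_sites[, c("chrom", "pos")]),
    near_edge = TRUE
  ) |>
    mutate(class = "end_artifact")

  artifacts <- bind_rows(par_sites, end_sites) |>
    mutate(
      ref = .random_base(n()),
      alt = .random_base(n(), avoid = .data$ref),
      # end artifacts: the fraction of the exon's own reads whose terminal
      # bases land across the splice boundary at this site
      alt_read_fraction = ifelse(.data$class == "end_artifact",
        runif(n(), 0.1, 0.4), NA_real_
      ),
      in_known_set = runif(n()) < config$known_site_probs[["artifact"]]
    )

  known_sites <- bind_rows(
    variants[variants$in_known_set, c("chrom", "pos")],
    artifacts[artifacts$in_known_set, c("chrom", "pos")]
  ) |> distinct()

  structure(
    list(
      exons = exons, expression = expression, genes = genes,
      known_sites = known_sites, variants = variants, artifacts = artifacts,
      k_depth = k_depth, config = config
    ),
    class = "truth_set"
  )
}

#' @export
print.truth_set <- function(x, ...) {
  cat(
    "truth_set:", nrow(x$exons), "exons,", nrow(x$variants), "variants,",
    nrow(x$artifacts), "artifact sites\n"
  )
  invisible(x)
}

.random_base <- function(n, avoid = NULL) {
  bases <- c("A", "C", "G", "T")
  if (is.null(avoid)) {
    sample(bases, n, replace = TRUE)
  } else {
    # pick uniformly among the three bases differing from `avoid`
    off <- sample.int(3L, n, replace = TRUE)
    idx <- (match(avoid, bases) - 1L + off) %% 4L + 1L
    bases[idx]
  }
}

# sample `n_sites[i]` distinct positions within exon i, avoiding previously
# planted positions
.plant_sites <- function(exons, n_sites, avoid = NULL, near_edge = FALSE) {
  taken <- if (is.null(avoid) || nrow(avoid) == 0) character() else {
    paste(avoid$chrom, avoid$pos)
  }
  idx <- which(n_sites > 0)
  rows <- map(idx, function(i) {
    cand <- if (near_edge) {
      unique(c(
        seq(exons$start[i], min(exons$end[i], exons$start[i] + 3L)),
        seq(max(exons$start[i], exons$end[i] - 3L), exons$end[i])
      ))
    } else {
      seq(exons$start[i], exons$end[i])
    }
    cand <- cand[!(paste(exons$chrom[i], cand) %in% taken)]
    if (length(cand) == 0) return(NULL)
    pos <- sort(cand[sample.int(length(cand), min(n_sites[i], length(cand)))])
    tibble(
      chrom = exons$chrom[i], pos = as.integer(pos),
      gene_id = exons$gene_id[i], transcript_id = exons$transcript_id[i]
    )
  })
  out <- list_rbind(purrr::compact(rows))
  if (nrow(out) == 0) {
    return(tibble(
      chrom = character(), pos = integer(),
      gene_id = character(), transcript_id = character()
    ))
  }
  out
}

# deterministic monotone quality proxy: grows with alt support, discounted
# when the alt fraction is small (mimics consensus callers down-weighting a
# few mismatching reads under a deep reference pile)
.quality_proxy <- function(alt, depth, noise) {
  f <- ifelse(depth > 0, alt / depth, 0)
  pmax(0, round(15 * alt * pmin(1, 2.5 * f) + noise))
}

# genotype from counts: near-fixed alt fraction is called homozygous
.called_genotype <- function(ref, alt_base, alt, depth) {
  hom <- alt / depth >= 0.8
  tibble(
    allele1 = ifelse(hom, alt_base, pmin(ref, alt_base)),
    allele2 = ifelse(hom, alt_base, pmax(ref, alt_base))
  )
}

#' Simulate the gDNA call set
#'
#' Each true variant gets a Poisson read depth around the genomic mean;
#' heterozygotes draw alternate support as Binomial(depth, 1/2), homozygotes
#' as Binomial(depth, 1 - error). A variant is emitted iff at least 3 reads
#' support the alternate allele and the quality proxy clears the gDNA
#' threshold (20). Sporadic error-driven false positives appear where three
#' independent base errors hit one site with the same base (rate ~ error^3).
#'
#' @param truth A `truth_set`.
#' @param config The [simulation_config()] (defaults to the one in `truth`).
#' @param seed Seed for this call set (default derived from the config seed).
#' @return A variant-call tibble (`source = "gDNA"`).
#' @export
simulate_gdna_callset <- function(truth, config = truth$config,
                                  seed = config$seed + 1L) {
  set.seed(seed)
  v <- truth$variants
  depth <- rpois(nrow(v), config$gdna_mean_depth)
  p <- ifelse(v$hom, 1 - config$per_base_error, 0.5)
  alt <- rbinom(nrow(v), depth, p)
  qual <- .quality_proxy(alt, depth, runif(nrow(v), -2, 2))
  keep <- alt >= 3 & qual >= 20 & depth > 0
  gt <- .called_genotype(v$ref[keep], v$alt[keep], alt[keep], depth[keep])
  calls <- tibble(
    chrom = v$chrom[keep], pos = v$pos[keep], ref_allele = v$ref[keep],
    allele1 = gt$allele1, allele2 = gt$allele2,
    snp_quality = qual[keep],
    read_depth = depth[keep], alt_support = alt[keep],
    alt_end_fraction = .end_fraction(alt[keep], 2 / config$read_length),
    source = "gDNA"
  )
  fp <- .gdna_error_fps(truth, config)
  validate_calls(bind_rows(calls, fp)) |> dedup_calls()
}

.end_fraction <- function(alt, p_end) {
  ifelse(alt > 0, rbinom(length(alt), alt, p_end) / alt, 0)
}

.gdna_error_fps <- function(truth, config) {
  ex <- truth$exons
  d <- config$gdna_mean_depth
  # P(>= 3 same-base errors at a site), x3 possible alternate bases
  p_site <- 3 * (1 - pbinom(2, d, config$per_base_error / 3))
  n_fp <- rbinom(nrow(ex), ex$end - ex$start + 1L, p_site)
  sites <- .plant_sites(ex, n_fp, avoid = truth$variants)
  if (nrow(sites) == 0) {
    return(tibble(
      chrom = character(), pos = integer(), ref_allele = character(),
      allele1 = character(), allele2 = character(), snp_quality = double(),
      read_depth = integer(), alt_support = integer(),
      alt_end_fraction = double(), source = character()
    ))
  }
  depth <- pmax(3L, rpois(nrow(sites), d))
  alt <- pmin(depth, 3L + rpois(nrow(sites), 0.2))
  ref <- .random_base(nrow(sites))
  altb <- .random_base(nrow(sites), avoid = ref)
  qual <- .quality_proxy(alt, depth, runif(nrow(sites), -2, 2))
  keep <- qual >= 20
  tibble(
    chrom = sites$chrom[keep], pos = sites$pos[keep], ref_allele = ref[keep],
    allele1 = pmin(ref, altb)[keep], allele2 = pmax(ref, altb)[keep],
    snp_quality = qual[keep], read_depth = depth[keep],
    alt_support = alt[keep],
    alt_end_fraction = .end_fraction(alt[keep], 2 / config$read_length),
    source = "gDNA"
  )
}

#' Simulate the cDNA call set with cumulative lane snapshots
#'
#' Site depth per lane is Poisson with rate `k_depth * expression_pct` of the
#' covering gene; alternate support is binomial with the site's allele
#' probability (1/2 for balanced heterozygotes, near 0 or 1 for monoallelic
#' expression, the misalignment fraction for paralog artifacts, the error
#' rate for base-error sites). Lane snapshots share one realised read stream
#' — per-lane counts are drawn once and accumulated — so snapshot call sets
#' are nested. A site is emitted in a snapshot iff its cumulative alternate
#' support reaches 3 (the raw caller gate); quality, end-of-read and depth
#' screens are left to [filter_calls()].
#'
#' @param truth A `truth_set`.
#' @param config The [simulation_config()].
#' @param lanes Number of lanes to simulate (<= `config$lanes`).
#' @param seed Seed for this call set.
#' @return A list: `calls` (full `lanes`-lane raw call set), `snapshots`
#'   (list of raw call tibbles for cumulative lanes 1..`lanes`),
#'   `depth_track` (per-exon expected-depth runs), and `site_stats` (one row
#'   per planted site: class, allele probability, realised cumulative depth
#'   and support — the hooks for closed-form oracles).
#' @export
simulate_cdna_callset <- function(truth, config = truth$config,
                                  lanes = config$lanes,
                                  seed = config$seed + 2L) {
  if (lanes > config$lanes) abort("lanes exceeds the configured study size")
  set.seed(seed)
  expr <- setNames(truth$expression$expression_pct, truth$expression$transcript_id)

  sites <- bind_rows(
    truth$variants |>
      transmute(
        .data$chrom, .data$pos, .data$gene_id, .data$transcript_id,
        .data$ref, .data$alt, .data$class,
        p_alt = .data$cdna_alt_prob, source_expr_pct = NA_real_
      ),
    truth$artifacts |>
      transmute(
        .data$chrom, .data$pos, .data$gene_id, .data$transcript_id,
        .data$ref, .data$alt, .data$class,
        # end artifacts draw alt support from the exon's own reads; paralog
        # artifacts add misaligned reads on top (p_alt = 0 here)
        p_alt = ifelse(.data$class == "end_artifact",
          .data$alt_read_fraction, 0
        ),
        source_expr_pct = .data$source_expr_pct,
        misalign_fraction = .data$misalign_fraction
      ),
    .cdna_error_sites(truth, config, lanes)
  )
  n <- nrow(sites)
  lambda <- truth$k_depth * expr[sites$transcript_id]
  lambda_mis <- ifelse(sites$class == "paralog_artifact",
    sites$misalign_fraction * truth$k_depth * sites$source_expr_pct, 0
  )
  p_end <- ifelse(sites$class == "end_artifact",
    config$end_artifact_rate, 2 / config$read_length
  )

  # per-lane draws, accumulated: snapshots share one realised stream. The
  # exon's own reads carry the alternate allele with p_alt; misaligned reads
  # (paralog artifacts) all carry it and add to the site depth.
  d_own <- matrix(rpois(n * lanes, rep(lambda, lanes)), nrow = n)
  m_mis <- matrix(rpois(n * lanes, rep(lambda_mis, lanes)), nrow = n)
  d_lane <- d_own + m_mis
  a_lane <- matrix(
    rbinom(n * lanes, as.vector(d_own), rep(sites$p_alt, lanes)),
    nrow = n
  ) + m_mis
  e_lane <- matrix(
    rbinom(n * lanes, as.vector(a_lane), rep(p_end, lanes)),
    nrow = n
  )
  row_cumsum <- function(m) {
    if (ncol(m) > 1) for (l in 2:ncol(m)) m[, l] <- m[, l - 1L] + m[, l]
    m
  }
  D <- row_cumsum(d_lane)
  A <- row_cumsum(a_lane)
  E <- row_cumsum(e_lane)
  noise <- runif(n, -2, 2) # one draw per site, shared across snapshots

  snapshot <- function(l) {
    keep <- which(A[, l] >= 3 & D[, l] > 0)
    gt <- .called_genotype(
      sites$ref[keep], sites$alt[keep], A[keep, l], D[keep, l]
    )
    tibble(
      chrom = sites$chrom[keep], pos = sites$pos[keep],
      ref_allele = sites$ref[keep],
      allele1 = gt$allele1, allele2 = gt$allele2,
      snp_quality = .quality_proxy(A[keep, l], D[keep, l], noise[keep]),
      read_depth = as.integer(D[keep, l]),
      alt_support = as.integer(A[keep, l]),
      alt_end_fraction = ifelse(A[keep, l] > 0, E[keep, l] / A[keep, l], 0),
      source = "cDNA"
    )
  }
  snapshots <- map(seq_len(lanes), snapshot)

  track <- truth$exons |>
    transmute(
      .data$chrom, .data$start, .data$end,
      depth = round(truth$k_depth * lanes * expr[.data$transcript_id])
    ) |>
    filter(.data$depth > 0)

  site_stats <- sites |>
    mutate(
      depth_total = D[, lanes],
      alt_total = A[, lanes],
      emitted = A[, lanes] >= 3 & D[, lanes] > 0
    )

  list(
    calls = snapshots[[lanes]],
    snapshots = snapshots,
    depth_track = as_tibble(track),
    site_stats = site_stats
  )
}

# base-error sites: where >= 3 independent errors with the same base pile up;
# realised once at the full lane count, alt reads assigned to lanes in
# proportion to per-lane depth so snapshots stay nested
.cdna_error_sites <- function(truth, config, lanes) {
  ex <- truth$exons
  expr <- setNames(truth$expression$expression_pct, truth$expression$transcript_id)
  d_exp <- truth$k_depth * lanes * expr[ex$transcript_id]
  p_site <- 3 * (1 - pbinom(2, pmax(1, round(d_exp)), config$per_base_error / 3))
  n_fp <- rbinom(nrow(ex), ex$end - ex$start + 1L, p_site)
  avoid <- bind_rows(
    truth$variants[, c("chrom", "pos")],
    truth$artifacts[, c("chrom", "pos")]
  )
  sites <- .plant_sites(ex, n_fp, avoid = avoid)
  if (nrow(sites) == 0) {
    return(tibble(
      chrom = character(), pos = integer(), gene_id = character(),
      transcript_id = character(), ref = character(), alt = character(),
      class = character(), p_alt = double(), source_expr_pct = double()
    ))
  }
  ref <- .random_base(nrow(sites))
  sites |>
    mutate(
      ref = ref,
      alt = .random_base(nrow(sites), avoid = ref),
      class = "error",
      p_alt = config$per_base_error / 3,
      source_expr_pct = NA_real_
    )
}

#' Write a complete fixture bundle
#'
#' Simulates truth plus both call sets and writes every pipeline input in
#' its external format: exon BED, expression / paralog / known-site TSVs,
#' gDNA and cDNA pileup-tsv call tables, per-lane cDNA snapshots, a
#' bedGraph depth track and a `truth.json` enabling exact recovery checks.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed).
#' @return A manifest tibble (file, path) with the seed as an attribute,
#'   also written as `manifest.json`.
#' @export
generate_fixture_bundle <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_truth(config)
  gdna <- simulate_gdna_callset(truth, config)
  cdna <- simulate_cdna_callset(truth, config)

  p <- function(f) file.path(outdir, f)
  write_exon_annotation(truth$exons, p("exons.bed"))
  readr::write_tsv(truth$expression, p("expression.tsv"), progress = FALSE)
  readr::write_tsv(
    mutate(truth$genes, has_paralog = as.integer(.data$has_paralog)),
    p("paralogs.tsv"),
    progress = FALSE
  )
  readr::write_tsv(truth$known_sites, p("known_sites.tsv"), progress = FALSE)
  write_variant_table(gdna, p("gdna.pileup.tsv"))
  write_variant_table(cdna$calls, p("cdna.pileup.tsv"))
  lane_files <- map_chr(seq_along(cdna$snapshots), function(l) {
    f <- p(sprintf("cdna.lane%02d.pileup.tsv", l))
    write_variant_table(cdna$snapshots[[l]], f)
    f
  })
  readr::write_tsv(
    mutate(cdna$depth_track, start = .data$start - 1L),
    p("depth.bedgraph"),
    col_names = FALSE, progress = FALSE
  )
  jsonlite::write_json(
    list(
      seed = config$seed,
      n_variants = nrow(truth$variants),
      n_artifacts = nrow(truth$artifacts),
      variants = truth$variants,
      artifacts = truth$artifacts
    ),
    p("truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  files <- c(
    "exons.bed", "expression.tsv", "paralogs.tsv", "known_sites.tsv",
    "gdna.pileup.tsv", "cdna.pileup.tsv", basename(lane_files),
    "depth.bedgraph", "truth.json"
  )
  manifest <- tibble(file = files, path = file.path(outdir, files))
  jsonlite::write_json(
    list(seed = config$seed, files = files),
    p("manifest.json"),
    auto_unbox = TRUE
  )
  attr(manifest, "seed") <- config$seed
  manifest
}
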