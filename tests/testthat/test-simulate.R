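small_config <- function(...) {
  args <- utils::modifyList(list(n_genes = 60, seed = 404L), list(...))
  do.call(simulation_config, args)
}

test_that("configuration validates its probability and size arguments", {
  cfg <- small_config()
  expect_s3_class(cfg, "simulation_config")
  expect_error(simulation_config(het_rate = 1.5), "probabilities")
  expect_error(simulation_config(hom_fraction = -0.1), "probabilities")
  expect_error(
    simulation_config(known_site_probs = c(variant = 0.9)),
    "artifact"
  )
  expect_error(simulation_config(n_genes = 0))
})

test_that("the whole simulation is reproducible from config and seed", {
  cfg <- small_config()
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_equal(t1$variants, t2$variants)
  expect_equal(t1$exons, t2$exons)
  g1 <- simulate_gdna_callset(t1)
  g2 <- simulate_gdna_callset(t2)
  expect_equal(plain(g1), plain(g2))
  c1 <- simulate_cdna_callset(t1)
  c2 <- simulate_cdna_callset(t2)
  expect_equal(plain(c1$calls), plain(c2$calls))
  t3 <- simulate_truth(small_config(seed = 405L))
  expect_false(identical(t1$variants$pos, t3$variants$pos))
})

test_that("simulated truth obeys its own structural invariants", {
  cfg <- small_config()
  truth <- simulate_truth(cfg)
  ex <- truth$exons
  # exons are laid out without overlap
  expect_silent(validate_depth_track(
    tibble::tibble(chrom = ex$chrom, start = ex$start, end = ex$end, depth = 1)
  ))
  # expression is a percent-of-max scale topping out at exactly 100
  expect_equal(max(truth$expression$expression_pct), 100)
  expect_true(all(truth$expression$expression_pct >= 0))
  # every planted site lies inside an exon of its own transcript
  planted <- dplyr::bind_rows(
    truth$variants[, c("chrom", "pos", "transcript_id")],
    truth$artifacts[, c("chrom", "pos", "transcript_id")]
  )
  own <- dplyr::left_join(
    planted, ex, by = c("chrom", "transcript_id"),
    relationship = "many-to-many"
  ) |>
    dplyr::group_by(chrom, pos, transcript_id) |>
    dplyr::summarise(ok = any(pos >= start & pos <= end), .groups = "drop")
  expect_true(all(own$ok))
  # planted positions never collide
  expect_equal(anyDuplicated(planted[, c("chrom", "pos")]), 0L)
  # variant alleles are genuine substitutions
  expect_true(all(truth$variants$ref != truth$variants$alt))
  # depth calibration: median expressed exon reaches the target at full lanes
  expr <- truth$expression$expression_pct
  med <- median(expr[expr >= cfg$expressed_threshold])
  expect_equal(truth$k_depth * cfg$lanes * med, cfg$target_median_expressed_depth)
  # paralog artifacts carry a source expression and misalignment fraction
  par <- truth$artifacts[truth$artifacts$class == "paralog_artifact", ]
  expect_true(all(!is.na(par$source_expr_pct)))
  expect_true(all(par$misalign_fraction > 0 &
    par$misalign_fraction < 2 * cfg$paralog_fp_rate))
  # known sites are a subset of planted sites
  expect_true(all(
    paste(truth$known_sites$chrom, truth$known_sites$pos) %in%
      paste(planted$chrom, planted$pos)
  ))
})

test_that("gDNA calls respect the caller gate and sit at planted positions", {
  cfg <- small_config()
  truth <- simulate_truth(cfg)
  gdna <- simulate_gdna_callset(truth)
  expect_true(all(gdna$source == "gDNA"))
  expect_true(all(gdna$alt_support >= 3))
  expect_true(all(gdna$snp_quality >= 20))
  expect_true(all(gdna$alt_support <= gdna$read_depth))
  expect_equal(anyDuplicated(gdna[, c("chrom", "pos")]), 0L)
  expect_true(all(oracle_in_exon(gdna, truth$exons)))
  # essentially every call is a true variant (error FPs have rate ~ error^3)
  at_variant <- paste(gdna$chrom, gdna$pos) %in%
    paste(truth$variants$chrom, truth$variants$pos)
  expect_gte(mean(at_variant), 0.99)
  # homozygous variants at ~24x are almost never missed
  hom <- truth$variants[truth$variants$hom, ]
  hom_called <- paste(hom$chrom, hom$pos) %in% paste(gdna$chrom, gdna$pos)
  expect_gte(mean(hom_called), 0.95)
  # called genotypes at homozygous sites are homozygous alternate
  hom_calls <- gdna[paste(gdna$chrom, gdna$pos) %in% paste(hom$chrom, hom$pos), ]
  expect_gte(mean(hom_calls$allele1 == hom_calls$allele2), 0.95)
})

test_that("cumulative lane snapshots are nested with monotone depth", {
  truth <- simulate_truth(small_config())
  sim <- simulate_cdna_callset(truth)
  snaps <- sim$snapshots
  expect_length(snaps, truth$config$lanes)
  expect_equal(plain(sim$calls), plain(snaps[[length(snaps)]]))
  key <- function(x) paste(x$chrom, x$pos)
  for (l in seq_len(length(snaps) - 1)) {
    a <- snaps[[l]]
    b <- snaps[[l + 1]]
    expect_true(all(key(a) %in% key(b))) # a call never disappears
    shared <- match(key(a), key(b))
    expect_true(all(b$read_depth[shared] >= a$read_depth))
    expect_true(all(b$alt_support[shared] >= a$alt_support))
  }
})

test_that("site bookkeeping agrees with the emitted call set", {
  truth <- simulate_truth(small_config())
  sim <- simulate_cdna_callset(truth)
  st <- sim$site_stats
  expect_equal(st$emitted, st$alt_total >= 3 & st$depth_total > 0)
  expect_equal(sum(st$emitted), nrow(sim$calls))
  emitted_keys <- paste(st$chrom[st$emitted], st$pos[st$emitted])
  expect_setequal(emitted_keys, paste(sim$calls$chrom, sim$calls$pos))
  # the realised depth and support of each emitted site match its call row
  m <- match(paste(sim$calls$chrom, sim$calls$pos), paste(st$chrom, st$pos))
  expect_equal(sim$calls$read_depth, as.integer(st$depth_total[m]))
  expect_equal(sim$calls$alt_support, as.integer(st$alt_total[m]))
})

test_that("a silent transcriptome yields an empty cDNA call set", {
  truth <- simulate_truth(small_config())
  truth$expression$expression_pct <- 0
  truth$artifacts$source_expr_pct <- 0
  sim <- simulate_cdna_callset(truth)
  expect_equal(nrow(sim$calls), 0)
  expect_equal(nrow(sim$depth_track), 0)
})

test_that("the depth track matches expected per-exon coverage", {
  truth <- simulate_truth(small_config())
  sim <- simulate_cdna_callset(truth)
  track <- validate_depth_track(sim$depth_track)
  covs <- exon_mean_coverage(track, truth$exons)
  expr <- setNames(
    truth$expression$expression_pct, truth$expression$transcript_id
  )
  expected <- round(truth$k_depth * truth$config$lanes * expr[covs$transcript_id])
  expect_equal(covs$mean_coverage, unname(expected))
})

test_that("a fixture bundle round-trips through the readers", {
  outdir <- withr::local_tempdir()
  cfg <- small_config()
  manifest <- generate_fixture_bundle(cfg, outdir)
  expect_true(all(file.exists(manifest$path)))
  expect_equal(attr(manifest, "seed"), cfg$seed)

  truth <- simulate_truth(cfg)
  exons <- read_exon_annotation(file.path(outdir, "exons.bed"))
  expect_equal(nrow(exons), nrow(truth$exons))
  expect_setequal(exons$transcript_id, truth$exons$transcript_id)

  gdna_mem <- simulate_gdna_callset(truth)
  gdna_file <- read_variant_table(
    file.path(outdir, "gdna.pileup.tsv"), "pileup-tsv", "gDNA"
  )
  expect_equal(
    plain(dplyr::arrange(gdna_file, chrom, pos)),
    plain(dplyr::arrange(gdna_mem, chrom, pos))
  )

  track <- read_depth_track(file.path(outdir, "depth.bedgraph"))
  expect_true(all(track$depth > 0))

  expr <- read_expression_table(file.path(outdir, "expression.tsv"))
  expect_equal(max(expr$expression_pct), 100)
  genes <- read_gene_annotations(file.path(outdir, "paralogs.tsv"))
  expect_equal(nrow(genes), cfg$n_genes)
  sites <- read_position_set(file.path(outdir, "known_sites.tsv"))
  expect_equal(nrow(sites), nrow(truth$known_sites))
})
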