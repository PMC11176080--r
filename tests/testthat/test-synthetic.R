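test_that("config validation enforces parameter domains", {
  expect_error(synthetic_config(gc_content = 1.2), "probabilities")
  expect_error(synthetic_config(m2_offset = 0), "m2_offset")
  expect_error(synthetic_config(nrl = 140), "146")
  expect_error(synthetic_config(dyad_jitter_sd = -1), "jitter")
  expect_error(synthetic_config(enrichment_factor = 0.5), "enrichment")
  expect_error(synthetic_config(ps_exponent = 0.5), "ps_exponent")
  expect_error(synthetic_config(boundary_strength = -2), "positive")
  expect_error(synthetic_config(tad_boundaries = c(5, 2)), "sorted")
})

test_that("genome simulation is deterministic and respects capacity", {
  cfg <- synthetic_config(genome_length = 1e5, n_sites = 30, seed = 4)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  # zero sites: pure background, empty site table
  g0 <- simulate_genome(synthetic_config(genome_length = 5e4,
                                         n_sites = 0, seed = 4))
  expect_equal(nrow(g0$sites), 0L)
  expect_equal(nchar(g0$genome$chr1), 5e4)
  # too many sites for the genome
  expect_error(simulate_genome(synthetic_config(genome_length = 5e3,
                                                n_sites = 500, seed = 1)),
               "too short")
})

test_that("planted M2 motifs start 21 bp 3' of the M1 center in oriented coordinates", {
  cfg <- synthetic_config(genome_length = 3e5, n_sites = 40,
                          m2_fraction = 1, seed = 6)
  g <- simulate_genome(cfg)
  expect_true(all(g$sites$has_m2))
  sq <- site_sequences(g$genome, g$sites)
  scan <- m2_site_scan(sq)
  expect_true(all(scan$has_m2))
  expect_true(all(scan$m2_offset == 21L))
  # genomic bookkeeping agrees for both strands
  plus <- g$sites$strand == "+"
  expect_equal(g$sites$m2_start[plus] - g$sites$center[plus],
               rep(21L, sum(plus)))
  expect_equal(g$sites$center[!plus] - (g$sites$m2_start[!plus] + 9L - 1L),
               rep(21L, sum(!plus)))
})

test_that("planted sites rescan at their recorded coordinates and scores", {
  cfg <- synthetic_config(genome_length = 2e5, n_sites = 25, seed = 8)
  g <- simulate_genome(cfg)
  hits <- scan_pwm(g$genome, ctcfkit:::default_m1_pwm(),
                   score_threshold = 0.3)
  key <- paste(hits$chrom, hits$start, hits$strand)
  planted <- paste(g$sites$chrom, g$sites$start, g$sites$strand)
  expect_gt(mean(planted %in% key), 0.9)
  m <- match(planted, key)
  ok <- !is.na(m)
  expect_equal(hits$pwm_score[m[ok]], g$sites$m1_score[ok],
               tolerance = 1e-9)
})

test_that("noiseless nucleosome fragments sit exactly on the dyad lattice", {
  cfg <- synthetic_config(genome_length = 1e5, dyad_jitter_sd = 0,
                          background_rate = 0, n_cells = 3L,
                          n_arrays_per_boundary = 4L, seed = 10)
  fr <- simulate_nucleosome_fragments(1e5, c(30000, 60000), cfg)
  lattice <- attr(fr, "dyad_lattice")
  mids <- fr$start + (fr$end - fr$start) %/% 2L
  expect_true(all(mids %in% lattice))
  expect_equal(nrow(fr), 2 * 3 * 8)   # anchors x cells x (2 x arrays)
  expect_error(simulate_nucleosome_fragments(
    1e5, 1000, synthetic_config(dyad_jitter_sd = -1)), "jitter")
})

test_that("IP simulation books fragments exactly and nulls at factor 1", {
  cfg <- synthetic_config(genome_length = 2e5, n_sites = 40,
                          read_depth = 5e4, enrichment_factor = 1,
                          seed = 12)
  g <- simulate_genome(cfg)
  sim <- simulate_ip_fragments(g$sites, cfg)
  expect_equal(nrow(sim$ip), 5e4)       # exact depth conservation
  expect_equal(nrow(sim$input), 5e4)
  called <- call_bound(g$sites, sim$ip, sim$input)
  expect_lt(abs(mean(called$enrichment)), 0.1)
  # depth 0: empty tables flagged, not an error
  cfg0 <- synthetic_config(read_depth = 0, seed = 1)
  sim0 <- simulate_ip_fragments(g$sites, cfg0)
  expect_equal(nrow(sim0$ip), 0L)
  expect_match(attr(sim0$ip, "sample_label"), "depth 0")
  # same seed, same tables
  sim2 <- simulate_ip_fragments(g$sites, cfg)
  expect_identical(as.data.frame(sim$ip), as.data.frame(sim2$ip))
})

test_that("planted enrichment recovers the generative log2 level", {
  # small planted mass fraction: measured bound enrichment has the
  # closed form log2(F L / Z), Z = L + n_bound (F - 1) w, here within
  # 0.2 of log2(F) at depth 1e6
  cfg <- synthetic_config(genome_length = 1e6, n_sites = 50,
                          read_depth = 1e6, enrichment_factor = 8,
                          seed = 14)
  g <- simulate_genome(cfg)
  sim <- simulate_ip_fragments(g$sites, cfg)
  called <- call_bound(g$sites, sim$ip, sim$input)
  expect_lt(abs(mean(called$enrichment) - log2(8)), 0.2)
})

test_that("SMF molecule simulation hits its deterministic limits", {
  cfg <- synthetic_config(genome_length = 5e4, n_sites = 3, seed = 16,
                          p_meth_protected = 0, p_meth_accessible = 1,
                          occupancy = 1, n_molecules = 50L)
  g <- simulate_genome(cfg)
  site <- g$sites[1, ]
  sim <- simulate_smf_molecules(g$genome, site, cfg)
  m <- smf_matrix(sim$calls, g$genome[[site$chrom]],
                  amplicon = sim$amplicon)
  fp <- footprint_profile(m, min_coverage = 1L)
  inside <- abs(fp$position - site$center) <= cfg$footprint_halfwidth
  expect_true(all(fp$footprint[inside] == 1))
  expect_true(all(fp$footprint[!inside] == 0))
  # occupancy 0: flat accessible profile at 1 - p_meth_accessible
  cfg0 <- synthetic_config(genome_length = 5e4, n_sites = 3, seed = 16,
                           p_meth_protected = 0, p_meth_accessible = 1,
                           occupancy = 0, n_molecules = 50L)
  sim0 <- simulate_smf_molecules(g$genome, site, cfg0)
  fp0 <- footprint_profile(smf_matrix(sim0$calls,
                                      g$genome[[site$chrom]]),
                           min_coverage = 1L)
  expect_true(all(fp0$footprint == 0))
})

test_that("contact matrices are symmetric with planted depletion and exact noiseless form", {
  cfg <- synthetic_config(seed = 18, hic_n_bins = 100,
                          boundary_strength = 2, tad_boundaries = 49L)
  for (noiseless in c(TRUE, FALSE)) {
    cm <- simulate_contact_matrix(cfg, noiseless = noiseless)
    expect_equal(cm$counts, t(cm$counts))
  }
  cm <- simulate_contact_matrix(cfg, noiseless = TRUE)
  # crossing pairs are depleted exactly twofold relative to the decay
  dec <- attr(cm, "expected_decay")
  expect_equal(cm$counts[30, 40], dec[11])
  expect_equal(cm$counts[45, 55], dec[11] / 2)
  # no boundary: flat unit O/E pileup
  cfg1 <- synthetic_config(seed = 18, hic_n_bins = 100,
                           boundary_strength = 1, tad_boundaries = 49L)
  cm1 <- simulate_contact_matrix(cfg1, noiseless = TRUE)
  oe1 <- observed_over_expected(cm1, expected = attr(cm1, "expected_decay"))
  pu <- hic_pileup(oe1, data.frame(bin = 49L), pad = 100000L)
  expect_equal(insulation_strength(pu), 1)
})

test_that("binding-response labels are exact at zero noise and recorded", {
  cfg <- synthetic_config(genome_length = 1e5, n_sites = 30, seed = 20)
  g <- simulate_genome(cfg)
  r <- simulate_binding_response(g$sites, a = 0.5, b = 0.8, noise_sd = 0)
  z <- as.numeric(scale(g$sites$m1_score))
  expect_equal(r$delta, 0.5 * z + 0.8 * g$sites$has_m2)
  expect_equal(attr(r, "coefficients"), c(a = 0.5, b = 0.8))
  r2 <- simulate_binding_response(g$sites, a = 0.5, b = 0.8, noise_sd = 0)
  expect_identical(r$delta, r2$delta)
  expect_error(simulate_binding_response(g$sites[, 1:4]), "m1_score")
})

test_that("site tables and genomes round-trip through BED and FASTA", {
  cfg <- synthetic_config(genome_length = 5e4, n_sites = 10, seed = 22)
  g <- simulate_genome(cfg)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g$genome, fa)
  back <- read_genome_fasta(fa)
  expect_equal(back, g$genome)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(g$sites, bed)
  lines <- read.table(bed, sep = "\t")
  expect_equal(nrow(lines), 10L)
  expect_equal(lines$V2, g$sites$start)
  expect_equal(lines$V5, round(g$sites$m1_score * 100))
})
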