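test_that("reference generation is deterministic and honours GC content", {
  cfg <- sim_config(seed = 7, contig_length = 1000L, gc_fraction = 0.5)
  g1 <- generate_reference(cfg)
  g2 <- generate_reference(cfg)
  expect_identical(g1$contigs, g2$contigs)

  gc_only <- generate_reference(sim_config(seed = 3, contig_length = 500L,
                                           gc_fraction = 1))
  expect_true(grepl("^[GC]+$", gc_only$contigs[[1]]))

  big <- generate_reference(sim_config(seed = 11, contig_length = 2e5,
                                       gc_fraction = 0.5))
  n_gc <- sum(strsplit(big$contigs[[1]], "")[[1]] %in% c("G", "C"))
  p_hat <- n_gc / 2e5
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 2e5))
})

test_that("invalid configurations are rejected with all violations listed", {
  expect_error(sim_config(contig_length = 0), class = "ffpeqc_config_error")
  expect_error(sim_config(gc_fraction = 1.5), class = "ffpeqc_config_error")
  expect_error(sim_config(clip_length_mean = 120, read_length = 100),
               "clip_length_mean")
  err <- tryCatch(sim_config(gc_fraction = 2, miscall_rate = -1),
                  error = function(e) conditionMessage(e))
  expect_match(err, "gc_fraction")
  expect_match(err, "miscall_rate")
})

test_that("variant planting matches zero-rate, Poisson, and tumor-only expectations", {
  cfg0 <- sim_config(seed = 5, contig_length = 5000L, het_snp_rate = 0,
                     somatic_mutation_rate = 0)
  g <- generate_reference(cfg0)
  tr0 <- plant_variants(g, cfg0)
  expect_identical(nrow(tr0$germline), 0L)
  expect_identical(nrow(tr0$somatic), 0L)
  expect_identical(tr0$haplotypes$hap1, g$contigs)
  expect_identical(tr0$haplotypes$hap2, g$contigs)

  cfg <- sim_config(seed = 5, contig_length = 1e5, het_snp_rate = 0,
                    somatic_mutation_rate = 1e-3)
  gg <- generate_reference(cfg)
  tr <- plant_variants(gg, cfg)
  # ~100 expected somatic records, Poisson-consistent
  expect_gt(nrow(tr$somatic), 100 - 3 * sqrt(100))
  expect_lt(nrow(tr$somatic), 100 + 3 * sqrt(100))
  # somatic records never touch the germline haplotypes
  for (i in seq_len(nrow(tr$somatic))) {
    p <- tr$somatic$pos[i] + 1L
    expect_identical(substr(tr$haplotypes$hap1[[1]], p, p), tr$somatic$ref[i])
    expect_identical(substr(tr$haplotypes$hap2[[1]], p, p), tr$somatic$ref[i])
  }
  # every planted variant appears exactly once
  expect_false(any(duplicated(tr$somatic[c("contig", "pos")])))
})

test_that("fragment lengths have the configured median and degenerate limits", {
  cfg <- sim_config(seed = 9, sample_type = "ffpe", contig_length = 5e4,
                    mean_depth = 50, insert_median = 100,
                    het_snp_rate = 0, somatic_mutation_rate = 0)
  g <- generate_reference(cfg)
  tr <- plant_variants(g, cfg)
  fr <- simulate_fragments(g, tr, cfg)
  expect_gt(nrow(fr), 1e4)
  expect_lt(abs(median(fr$insert) - 100) / 100, 0.05)
  expect_true(all(fr$insert >= 50 & fr$insert <= 1000))
  expect_true(all(nchar(fr$seq) == fr$insert))

  cfg0 <- sim_config(seed = 9, contig_length = 2e4, mean_depth = 5,
                     insert_median = 150, insert_log_sigma = 0)
  g0 <- generate_reference(cfg0)
  fr0 <- simulate_fragments(g0, plant_variants(g0, cfg0), cfg0)
  expect_true(all(fr0$insert == 150L))
})

test_that("FFPE median insert falls below frozen under per-type defaults", {
  trio <- simulate_trio(seed = 4, contig_length = 3e4, mean_depth = 20)
  med <- vapply(trio$libraries, function(l)
    insert_size_distribution(l$reads)$median, numeric(1))
  expect_lt(med[["ffpe"]], med[["frozen"]])
  expect_lt(abs(med[["ffpe"]] - 100), 6)
  expect_gt(med[["frozen"]], 150)
})

test_that("deamination is FFPE-only, binomially consistent, and class-pure", {
  cfg <- sim_config(seed = 2, sample_type = "frozen", contig_length = 5000L,
                    mean_depth = 5)
  g <- generate_reference(cfg)
  tr <- plant_variants(g, cfg)
  fr <- simulate_fragments(g, tr, cfg)
  expect_error(inject_ffpe_deamination(fr, cfg), "FFPE")

  cfg0 <- quick_config(seed = 2, deamination_rate = 0)
  g0 <- generate_reference(cfg0)
  tr0 <- plant_variants(g0, cfg0)
  fr0 <- simulate_fragments(g0, tr0, cfg0)
  fr0d <- inject_ffpe_deamination(fr0, cfg0)
  expect_identical(fr0$seq, fr0d$seq)

  lib <- quick_library(seed = 2, mean_depth = 60, deamination_rate = 2e-3)
  ev <- lib$realized$deamination
  for (cls in c("ct", "ga")) {
    n <- ev[[paste0("n_", substr(cls, 1, 1))]]
    k <- ev[[paste0("n_", cls)]]
    expect_lt(abs(k - n * 2e-3), 3 * sqrt(n * 2e-3 * (1 - 2e-3)))
  }

  # class purity: with zero miscalls every non-reference base at a planted-free
  # homozygous position is C>T or G>A in reference orientation
  cfgp <- sim_config(seed = 6, sample_type = "ffpe", contig_length = 8000L,
                     mean_depth = 20, miscall_rate = 0, het_snp_rate = 0,
                     somatic_mutation_rate = 0, clip_probability = 0,
                     deamination_rate = 5e-3)
  gp <- generate_reference(cfgp)
  libp <- simulate_library(gp, plant_variants(gp, cfgp), cfgp)
  pu <- pileup(libp$reads, filter_thresholds(0, 0, 0))
  refc <- strsplit(gp$contigs[[1]], "")[[1]]
  ref_at <- refc[pu$pos + 1L]
  for (b in c("A", "C", "G", "T")) {
    nonref <- pu[[b]][ref_at != b]
    src <- ref_at[ref_at != b]
    bad <- sum(nonref[!(src == "C" & b == "T") & !(src == "G" & b == "A")])
    expect_identical(bad, 0L)
  }
})

test_that("sequencing yields template-faithful, overlap-consistent mates", {
  cfg <- sim_config(seed = 8, sample_type = "ffpe", contig_length = 5000L,
                    mean_depth = 10, miscall_rate = 0, deamination_rate = 1e-2,
                    clip_probability = 0, unmapped_fraction = 0,
                    discordant_fraction = 0, insert_median = 100,
                    insert_log_sigma = 0.55)
  g <- generate_reference(cfg)
  tr <- plant_variants(g, cfg)
  fr <- inject_ffpe_deamination(simulate_fragments(g, tr, cfg), cfg)
  reads <- sequence_fragments(fr, cfg)
  first <- reads[reads$first_in_pair, ]
  second <- reads[!reads$first_in_pair, ]
  second <- second[match(first$qname, second$qname), ]
  # an insert no longer than the read covers identical template positions:
  # both mates read the same bases, including any deamination flip
  short <- first$tlen <= cfg$read_length
  expect_gt(sum(short), 0)
  expect_identical(first$seq[short], second$seq[short])
  expect_identical(first$pos[short], second$pos[short])

  # with zero miscall and zero deamination reads match the haplotypes exactly
  cfg0 <- sim_config(seed = 8, sample_type = "blood", contig_length = 5000L,
                     mean_depth = 10, miscall_rate = 0, het_snp_rate = 0,
                     clip_probability = 0, unmapped_fraction = 0,
                     discordant_fraction = 0)
  g0 <- generate_reference(cfg0)
  r0 <- sequence_fragments(simulate_fragments(g0, plant_variants(g0, cfg0), cfg0), cfg0)
  ref <- g0$contigs[[1]]
  expect_identical(r0$seq,
                   substring(ref, r0$pos + 1L, r0$pos + nchar(r0$seq)))
})

test_that("realized miscall counts are binomially consistent with the rate", {
  lib <- quick_library(seed = 3, sample_type = "blood", mean_depth = 80,
                       miscall_rate = 6e-4)
  ev <- lib$realized$miscalls
  expect_gt(ev$n_bases, 1e5)
  expect_lt(abs(ev$n_miscalls - ev$n_bases * 6e-4),
            3 * sqrt(ev$n_bases * 6e-4))
})

test_that("soft-clip injection respects zero rate, the cap, and the mean", {
  lib0 <- quick_library(seed = 4, clip_probability = 0)
  expect_true(all(lib0$reads$left_clip == 0L & lib0$reads$right_clip == 0L))

  lib <- quick_library(seed = 4, mean_depth = 50, clip_probability = 0.6,
                       clip_length_mean = 50, insert_median = 300,
                       insert_log_sigma = 0.3)
  clips <- lib$reads$left_clip + lib$reads$right_clip
  mapped <- !lib$reads$unmapped
  expect_true(all(clips[mapped] <= 80L))
  expect_true(all(lib$reads$m_len[mapped] >= 20L))
  frac <- sum(clips[mapped]) / sum(nchar(lib$reads$seq[mapped]))
  expect_lt(abs(frac - 0.30), 0.02)
})

test_that("mapping fates appear at configured fractions and proper flags", {
  lib <- quick_library(seed = 5, mean_depth = 60, unmapped_fraction = 0.05,
                       discordant_fraction = 0.03)
  st <- mapping_stats(lib$reads)
  n <- sum(st$n)
  for (cat in c("unmapped", "discordant")) {
    p <- if (cat == "unmapped") 0.05 else 0.03
    obs <- st$n[st$mapping_category == cat]
    expect_lt(abs(obs - n * p), 3 * sqrt(n * p * (1 - p)))
  }
  unm <- lib$reads[lib$reads$unmapped, ]
  expect_true(all(is.na(unm$contig)))
  expect_true(all(unm$cigar == "*"))
  expect_true(all(unm$tlen == 0L))
})

test_that("identical configs give byte-identical library files", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  for (d in c(dir1, dir2)) {
    cfg <- sim_config(seed = 42, sample_type = "ffpe", contig_length = 5000L,
                      mean_depth = 10)
    g <- generate_reference(cfg)
    tr <- plant_variants(g, cfg)
    write_library(simulate_library(g, tr, cfg), g, tr, d)
  }
  for (f in c("ffpe.sam", "reference.fa", "targets.bed", "ffpe.truth.vcf",
              "ffpe.realized.json")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)),
                     label = f)
  }
})

test_that("written SAM round-trips through read_alignments losslessly", {
  cfg <- sim_config(seed = 10, sample_type = "ffpe", contig_length = 4000L,
                    mean_depth = 8)
  g <- generate_reference(cfg)
  tr <- plant_variants(g, cfg)
  lib <- simulate_library(g, tr, cfg)
  d <- withr::local_tempdir()
  paths <- write_library(lib, g, tr, d)
  back <- read_alignments(paths$sam)
  orig <- lib$reads
  ord <- order(orig$unmapped, orig$contig, orig$pos, orig$qname)
  orig <- orig[ord, ]
  back <- back[order(back$unmapped, back$contig, back$pos, back$qname), ]
  for (col in c("qname", "contig", "pos", "mapq", "cigar", "seq", "qual",
                "tlen", "paired", "proper_pair", "unmapped", "reverse",
                "first_in_pair", "left_clip", "m_len", "right_clip")) {
    expect_identical(back[[col]], orig[[col]], label = col)
  }
  # TLEN convention: +insert on the leftmost mate, -insert on the rightmost
  # (positions compared on clip-free pairs: a leading soft clip shifts POS)
  pr <- back[back$proper_pair & !back$unmapped, ]
  f <- pr[pr$first_in_pair, ]
  s <- pr[!pr$first_in_pair, ][match(pr$qname[pr$first_in_pair],
                                     pr$qname[!pr$first_in_pair]), ]
  expect_true(all(f$tlen > 0))
  expect_identical(f$tlen, -s$tlen)
  unclipped <- f$left_clip == 0L & s$left_clip == 0L
  expect_true(all(f$pos[unclipped] <= s$pos[unclipped]))
})
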