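uniform_column_reads <- function(counts, pos = 0L, qname_prefix = "r") {
  # counts: named vector e.g. c(C = 55, T = 5) -> single-column fixture
  rows <- list()
  i <- 0L
  for (b in names(counts)) {
    for (k in seq_len(counts[[b]])) {
      i <- i + 1L
      rows[[i]] <- test_read(qname = paste0(qname_prefix, i), pos = pos,
                             cigar = "1M", seq = b, qual = Q35)
    }
  }
  do.call(test_reads, rows)
}

test_that("homozygous-site selection applies the single-allele and depth rules", {
  th <- filter_thresholds(20, 20, 50)
  only_c <- pileup(uniform_column_reads(c(C = 60)), th)
  s1 <- find_homozygous_sites(only_c, th)
  expect_identical(nrow(s1), 1L)
  expect_identical(s1$allele, "C")

  two_alleles <- pileup(uniform_column_reads(c(C = 55, T = 5)), th)
  expect_identical(nrow(find_homozygous_sites(two_alleles, th)), 0L)

  shallow <- pileup(uniform_column_reads(c(C = 49)), th)
  expect_identical(nrow(find_homozygous_sites(shallow, th)), 0L)

  # threshold mismatch between pileup and call is an error
  expect_error(find_homozygous_sites(only_c, filter_thresholds(60, 30, 0)),
               "rebuild the pileup")
})

test_that("discrepancy counting reproduces the 98C+2T arithmetic example", {
  sth <- stringent_thresholds()
  sites <- find_homozygous_sites(
    pileup(uniform_column_reads(c(C = 60)), lenient_thresholds()),
    lenient_thresholds())
  counting <- pileup(uniform_column_reads(c(C = 98, T = 2)), sth)
  spec <- count_discrepant(counting, sites, sth)
  expect_identical(spec$discrepant[spec$class == "C>T"], 2L)
  expect_identical(unique(spec$denominator[spec$ref == "C"]), 100)
  expect_identical(spec$rate_per_mb[spec$class == "C>T"], 20000)
  # classes with no homozygous source site are undefined, not zero
  expect_true(all(spec$undefined[spec$ref != "C"]))
  expect_true(all(is.na(spec$rate_per_mb[spec$ref != "C"])))
  expect_error(count_discrepant(counting, sites[0, ], sth), "empty")
})

test_that("spectrum equals an independent recount on a 30-site fixture", {
  set.seed(41)
  alleles <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
  site_rows <- list()
  count_rows <- list()
  truth_counts <- matrix(0L, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                                   c("A", "C", "G", "T")))
  truth_denom <- setNames(integer(4), c("A", "C", "G", "T"))
  for (p in seq_along(alleles)) {
    x <- alleles[p]
    site_rows[[p]] <- test_read(qname = paste0("s", p), pos = p - 1L,
                                cigar = "1M", seq = x,
                                qual = strrep(Q35, 1))
    n_err <- sample(0:3, 1)
    bases <- c(rep(x, 60 - n_err),
               sample(setdiff(c("A", "C", "G", "T"), x), n_err, replace = TRUE))
    for (b in bases) {
      count_rows[[length(count_rows) + 1L]] <-
        test_read(qname = paste0("c", p, "_", length(count_rows)), pos = p - 1L,
                  cigar = "1M", seq = b, qual = Q35)
      if (b != x) truth_counts[x, b] <- truth_counts[x, b] + 1L
      truth_denom[x] <- truth_denom[x] + 1L
    }
  }
  lth <- filter_thresholds(20, 20, 1)
  sth <- stringent_thresholds()
  sites <- find_homozygous_sites(pileup(do.call(test_reads, site_rows), lth), lth)
  spec <- count_discrepant(pileup(do.call(test_reads, count_rows), sth),
                           sites, sth)
  for (i in seq_len(nrow(spec))) {
    expect_identical(spec$discrepant[i], truth_counts[spec$ref[i], spec$alt[i]])
    expect_identical(spec$denominator[i], as.numeric(truth_denom[spec$ref[i]]))
  }
})

test_that("identical noise-free samples give all-zero spectra", {
  cfg_args <- list(seed = 51, mean_depth = 60, miscall_rate = 0,
                   clip_probability = 0, deamination_rate = 0,
                   low_qual_fraction = 0)
  blood <- do.call(quick_library, c(list(sample_type = "blood"), cfg_args))
  frozen <- do.call(quick_library, c(list(sample_type = "frozen"), cfg_args))
  spec <- background_error_rate(frozen$reads, blood$reads)
  expect_true(all(spec$discrepant == 0L))
  expect_true(all(spec$rate_per_mb[!spec$undefined] == 0))
})

test_that("two-pass estimation recovers miscall and deamination rates", {
  trio <- simulate_trio(seed = 61, contig_length = 1e5, mean_depth = 60,
                        miscall_rate = 6e-4,
                        blood = list(clip_probability = 0),
                        frozen = list(clip_probability = 0),
                        ffpe = list(clip_probability = 0,
                                    deamination_rate = 1e-3))
  blood <- trio$libraries$blood$reads
  ffpe <- trio$libraries$ffpe$reads

  bg <- background_error_rate(ffpe, blood)
  # uniform miscalls: every class near 6e-4/3 per base = 200/Mb, and all
  # twelve statistically indistinguishable (3-sigma on each count)
  for (i in seq_len(nrow(bg))) {
    expected <- bg$denominator[i] * 2e-4
    expect_lt(abs(bg$discrepant[i] - expected), 3 * sqrt(expected) + 1)
  }

  ov <- overall_transition_rate(blood, ffpe)
  ind <- ffpe_induced_rate(ov, bg)
  for (cls in c("C>T", "G>A")) {
    i <- which(ind$class == cls)
    sd_rate <- 1e6 * sqrt(ov$denominator[i] * 1.2e-3) / ov$denominator[i]
    expect_lt(abs(ind$rate_per_mb[i] - 1000), 3 * sd_rate + 50)
  }
  others <- ind$rate_per_mb[!ind$class %in% c("C>T", "G>A")]
  sd_other <- 1e6 * sqrt(max(ov$denominator) * 2e-4) / max(ov$denominator)
  expect_true(all(others < 3 * sd_other + 50))
})

test_that("direction asymmetry: swapping site definition changes the estimate", {
  trio <- simulate_trio(seed = 62, contig_length = 5e4, mean_depth = 60,
                        blood = list(clip_probability = 0),
                        ffpe = list(clip_probability = 0,
                                    deamination_rate = 3e-3))
  blood <- trio$libraries$blood$reads
  ffpe <- trio$libraries$ffpe$reads
  # artifact-bearing sample counted: strong C>T signal
  toward_ffpe <- overall_transition_rate(blood, ffpe)
  # artifact-bearing sample defines sites; intact blood counted: background only
  toward_blood <- background_error_rate(ffpe, blood)
  ct_assay <- toward_ffpe$rate_per_mb[toward_ffpe$class == "C>T"]
  ct_control <- toward_blood$rate_per_mb[toward_blood$class == "C>T"]
  expect_gt(ct_assay, 5 * ct_control)
})

test_that("raising base-quality stringency never raises background rates", {
  trio <- simulate_trio(seed = 63, contig_length = 4e4, mean_depth = 60,
                        low_qual_fraction = 0.05,
                        blood = list(clip_probability = 0),
                        ffpe = list(clip_probability = 0))
  bg30 <- background_error_rate(trio$libraries$ffpe$reads,
                                trio$libraries$blood$reads,
                                stringent = filter_thresholds(60, 30, 0))
  bg37 <- background_error_rate(trio$libraries$ffpe$reads,
                                trio$libraries$blood$reads,
                                stringent = filter_thresholds(60, 37, 0))
  ok <- !bg30$undefined & !bg37$undefined
  expect_true(all(bg37$discrepant[ok] <= bg30$discrepant[ok]))
})

test_that("fragment-dedup pileups do not exceed both-mates induced estimates", {
  trio <- simulate_trio(seed = 64, contig_length = 5e4, mean_depth = 60,
                        blood = list(clip_probability = 0),
                        ffpe = list(clip_probability = 0, insert_median = 80,
                                    deamination_rate = 3e-3))
  blood <- trio$libraries$blood$reads
  ffpe <- trio$libraries$ffpe$reads
  set.seed(1)
  ind_mates <- ffpe_induced_rate(
    overall_transition_rate(blood, ffpe, mode = "mates"),
    background_error_rate(ffpe, blood, mode = "mates"))
  ind_frag <- ffpe_induced_rate(
    overall_transition_rate(blood, ffpe, mode = "fragment"),
    background_error_rate(ffpe, blood, mode = "fragment"))
  # template-level deamination is double-counted by overlapping mates, so the
  # per-Mb C>T/G>A rate in fragment mode must not exceed mates mode materially
  for (cls in c("C>T", "G>A")) {
    expect_lte(ind_frag$rate_per_mb[ind_frag$class == cls],
               ind_mates$rate_per_mb[ind_mates$class == cls] * 1.05)
  }
})

test_that("subtraction floors negatives, flags them, and propagates undefined", {
  mk_spec <- function(rates, denom = 1e6) {
    spec <- ffpeqc:::count_discrepant
    classes <- ffpeqc:::SUBSTITUTION_CLASSES
    out <- tibble::tibble(
      class = classes,
      ref = substr(classes, 1, 1), alt = substr(classes, 3, 3),
      discrepant = as.integer(rates), denominator = denom,
      undefined = is.na(rates),
      rate_per_mb = ifelse(is.na(rates), NA_real_, 1e6 * rates / denom))
    class(out) <- c("ffpeqc_spectrum", class(out))
    out
  }
  ov <- mk_spec(c(100, 200, 300, 400, 1200, 500, 600, 700, 800, 900, 1000, NA))
  bg <- mk_spec(c(200, 200, 200, 200, 200, 200, 200, 200, 200, 200, 200, 200))
  ind <- ffpe_induced_rate(ov, bg)
  expect_identical(ind$rate_per_mb[ind$class == "A>C"], 0)
  expect_true(ind$floored[ind$class == "A>C"])
  expect_identical(ind$rate_per_mb[ind$class == "C>G"], 1000)
  expect_true(ind$undefined[12])
  expect_true(is.na(ind$rate_per_mb[12]))
  # identical spectra subtract to all zeros
  zero <- ffpe_induced_rate(bg, bg)
  expect_true(all(zero$rate_per_mb[!zero$undefined] == 0))
})
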