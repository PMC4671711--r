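#' Generate a random reference genome
#'
#' Draws i.i.d. nucleotides with expected GC content `gc_fraction` for each
#' contig, and attaches target regions (either the configured intervals or
#' auto-tiled 400-bp windows separated by 400-bp gaps). Deterministic under
#' the config seed.
#'
#' @param config A [sim_config()].
#' @return A `sim_genome`: list with `contigs` (named character vector of
#'   sequences) and `targets` (tibble `contig`, `start`, `end`, 0-based
#'   half-open).
#' @examples
#' g <- generate_reference(sim_config(seed = 7, contig_length = 1000))
#' nchar(g$contigs)
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gc <- config$gc_fraction
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  contigs <- withr::with_seed(derive_seed(config$seed, 0L), {
    vapply(seq_len(config$n_contigs), function(i) {
      codes <- sample.int(4L, config$contig_length, replace = TRUE,
                          prob = p[BASES])
      codes_to_strings(codes, config$contig_length)
    }, character(1))
  })
  names(contigs) <- paste0("chr", seq_len(config$n_contigs))
  structure(list(contigs = contigs, targets = resolve_targets(config, names(contigs))),
            class = "sim_genome")
}

#' @noRd
resolve_targets <- function(config, contig_names) {
  if (is.data.frame(config$target_regions)) {
    return(as_tibble(config$target_regions))
  }
  # auto: 400-bp windows tiled with 400-bp gaps, skipping 200 bp at each edge;
  # contigs too short to tile get one central target
  purrr::map_dfr(contig_names, function(cn) {
    L <- config$contig_length
    if (L < 1200L) {
      pad <- as.integer(L %/% 10)
      return(tibble(contig = cn, start = pad, end = L - pad))
    }
    starts <- seq(200L, L - 600L, by = 800L)
    tibble(contig = cn, start = starts, end = starts + 400L)
  })
}

#' Plant germline and somatic variants
#'
#' Heterozygous germline SNVs are drawn at `het_snp_rate` per base and assigned
#' to one of the two haplotypes; somatic SNVs are drawn at
#' `somatic_mutation_rate` at positions free of germline variants and are
#' carried only by tumor-derived fragments. The germline haplotype pair is
#' shared by blood, frozen and FFPE libraries of a matched set.
#'
#' @param genome A `sim_genome` from [generate_reference()].
#' @param config A [sim_config()].
#' @return A `sim_truth`: list with `haplotypes` (list of two named character
#'   vectors), `germline` (tibble `contig`, `pos`, `ref`, `alt`, `hap`),
#'   `somatic` (tibble `contig`, `pos`, `ref`, `alt`, `vaf` with
#'   `vaf = somatic_vaf * tumor_purity`, the expected observed VAF).
#' @export
plant_variants <- function(genome, config) {
  stopifnot(inherits(genome, "sim_genome"), inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, 1L), {
    germline <- list()
    somatic <- list()
    hap1 <- genome$contigs
    hap2 <- genome$contigs
    for (cn in names(genome$contigs)) {
      L <- nchar(genome$contigs[[cn]])
      ref_codes <- base_codes(genome$contigs[[cn]])
      gpos <- which(runif(L) < config$het_snp_rate)
      if (length(gpos)) {
        ref <- BASES[ref_codes[gpos]]
        alt <- other_base(ref)
        hap <- sample(1:2, length(gpos), replace = TRUE)
        germline[[cn]] <- tibble(contig = cn, pos = gpos - 1L, ref = ref,
                                 alt = alt, hap = hap)
        on1 <- gpos[hap == 1L]
        if (length(on1)) for (i in seq_along(on1))
          substr(hap1[[cn]], on1[i], on1[i]) <- alt[hap == 1L][i]
        on2 <- gpos[hap == 2L]
        if (length(on2)) for (i in seq_along(on2))
          substr(hap2[[cn]], on2[i], on2[i]) <- alt[hap == 2L][i]
      }
      spos <- which(runif(L) < config$somatic_mutation_rate)
      spos <- setdiff(spos, gpos)
      if (length(spos)) {
        ref <- BASES[ref_codes[spos]]
        somatic[[cn]] <- tibble(contig = cn, pos = spos - 1L, ref = ref,
                                alt = other_base(ref),
                                vaf = config$somatic_vaf * config$tumor_purity)
      }
    }
    empty_g <- tibble(contig = character(), pos = integer(), ref = character(),
                      alt = character(), hap = integer())
    empty_s <- tibble(contig = character(), pos = integer(), ref = character(),
                      alt = character(), vaf = double())
    structure(list(
      haplotypes = list(hap1 = hap1, hap2 = hap2),
      germline = if (length(germline)) bind_rows(germline) else empty_g,
      somatic = if (length(somatic)) bind_rows(somatic) else empty_s
    ), class = "sim_truth")
  })
}

#' @noRd
other_base <- function(ref) {
  vapply(ref, function(b) sample(setdiff(BASES, b), 1L), character(1),
         USE.NAMES = FALSE)
}

#' Draw template fragments for a library
#'
#' Fragment lengths are log-normal with median `insert_median` and log-scale
#' shape `insert_log_sigma`, clamped to `[read_length/2, 10 * insert_median]`
#' (clamping keeps the sample median at `insert_median`). Start positions are
#' uniform over each contig; the fragment count is calibrated so the expected
#' sequenced-base depth matches `mean_depth`. Each fragment is copied from one
#' of the two germline haplotypes (fair coin); in tumor libraries
#' (`frozen`/`ffpe`), fragments covering a somatic site carry the alternate
#' allele with probability `somatic_vaf * tumor_purity`.
#'
#' @param genome A `sim_genome`.
#' @param truth A `sim_truth` from [plant_variants()].
#' @param config A [sim_config()].
#' @return A tibble of fragments (`frag_id`, `contig`, `start`, `insert`,
#'   `seq`), 0-based starts, reference-orientation sequences; attribute
#'   `sample_type`.
#' @export
simulate_fragments <- function(genome, truth, config) {
  stopifnot(inherits(genome, "sim_genome"), inherits(truth, "sim_truth"),
            inherits(config, "sim_config"))
  if (config$mean_depth <= 0) abort("`mean_depth` must be > 0")
  rl <- config$read_length
  lo <- max(1L, as.integer(floor(rl / 2)))
  hi <- as.integer(ceiling(10 * config$insert_median))
  is_tumor <- config$sample_type %in% c("frozen", "ffpe")

  withr::with_seed(lib_seed(config, 2L), {
    frags <- purrr::map_dfr(names(genome$contigs), function(cn) {
      L <- nchar(genome$contigs[[cn]])
      # calibrate fragment count from a pilot sample of the insert distribution
      pilot <- clamp_inserts(rlnorm(5000, log(config$insert_median),
                                    config$insert_log_sigma), lo, min(hi, L))
      bases_per_frag <- mean(2 * pmin(rl, pilot))
      n <- as.integer(ceiling(config$mean_depth * L / bases_per_frag))
      insert <- clamp_inserts(rlnorm(n, log(config$insert_median),
                                     config$insert_log_sigma), lo, min(hi, L))
      start <- as.integer(floor(runif(n, 0, L - insert + 1)))
      hap <- sample.int(2L, n, replace = TRUE)
      seq <- character(n)
      for (h in 1:2) {
        sel <- hap == h
        seq[sel] <- substring(truth$haplotypes[[h]][[cn]],
                              start[sel] + 1L, start[sel] + insert[sel])
      }
      tibble(contig = cn, start = start, insert = insert, seq = seq)
    })
    frags$frag_id <- seq_len(nrow(frags))

    if (is_tumor && nrow(truth$somatic)) {
      for (i in seq_len(nrow(truth$somatic))) {
        v <- truth$somatic[i, ]
        cov <- which(frags$contig == v$contig & frags$start <= v$pos &
                       frags$start + frags$insert > v$pos)
        if (!length(cov)) next
        carry <- cov[runif(length(cov)) < v$vaf]
        if (length(carry)) {
          off <- v$pos - frags$start[carry] + 1L
          substr(frags$seq[carry], off, off) <- v$alt
        }
      }
    }
    structure(frags[c("frag_id", "contig", "start", "insert", "seq")],
              sample_type = config$sample_type, class = c("tbl_df", "tbl", "data.frame"))
  })
}

#' @noRd
clamp_inserts <- function(x, lo, hi) as.integer(pmin(pmax(round(x), lo), hi))

# Library-stage seed stream: distinct per sample type so matched libraries
# draw independent miscall/fragment randomness.
#' @noRd
lib_seed <- function(config, stream) {
  derive_seed(config$seed,
              stream + 100L * match(config$sample_type, c("blood", "frozen", "ffpe")))
}

#' Inject formalin-fixation deamination into FFPE fragments
#'
#' Models formalin cytosine lesions read through by the polymerase: every
#' reference-orientation C on a fragment flips to T with probability
#' `deamination_rate`, and symmetrically every G flips to A (the same lesion on
#' the opposite template strand, seen as G>A in reference orientation). The
#' alteration is template-level: both mates of an overlapping pair read the
#' flipped base identically. Only the C>T / G>A classes are ever produced.
#'
#' @param fragments Fragment tibble from [simulate_fragments()]; must carry
#'   `sample_type == "ffpe"`.
#' @param config A [sim_config()].
#' @return The fragment tibble with altered sequences; attribute
#'   `deamination_events` records realized counts and denominators:
#'   `n_ct`, `n_ga`, `n_c`, `n_g`.
#' @export
inject_ffpe_deamination <- function(fragments, config) {
  stopifnot(inherits(config, "sim_config"))
  st <- attr(fragments, "sample_type")
  if (!identical(st, "ffpe")) {
    abort(sprintf(
      "inject_ffpe_deamination() applies to FFPE libraries only (got sample_type \"%s\")",
      st %||% "<missing>"))
  }
  d <- config$deamination_rate
  lens <- nchar(fragments$seq)
  codes <- base_codes(fragments$seq)
  n_c <- sum(codes == 2L)
  n_g <- sum(codes == 3L)
  if (d > 0 && nrow(fragments)) {
    withr::with_seed(lib_seed(config, 3L), {
      idx_c <- which(codes == 2L)
      flip_c <- idx_c[runif(length(idx_c)) < d]
      idx_g <- which(codes == 3L)
      flip_g <- idx_g[runif(length(idx_g)) < d]
      codes[flip_c] <- 4L # C>T
      codes[flip_g] <- 1L # G>A
      fragments$seq <- codes_to_strings(codes, lens)
      ev <- list(n_ct = length(flip_c), n_ga = length(flip_g), n_c = n_c, n_g = n_g)
    })
  } else {
    ev <- list(n_ct = 0L, n_ga = 0L, n_c = n_c, n_g = n_g)
  }
  attr(fragments, "deamination_events") <- ev
  fragments
}

#' Sequence fragments into paired-end reads
#'
#' Mate 1 reads `min(read_length, insert)` bases from the 5' end of the
#' template; mate 2 reads the same number from the 3' end (stored in reference
#' orientation with the reverse flag, per SAM convention). When the insert is
#' no longer than the read length the two mates cover identical template
#' positions, so every insert base is sequenced twice. Base qualities are drawn
#' from the two-point quality profile; miscalls are injected independently per
#' sequenced base at `miscall_rate`, uniformly over the three alternative
#' bases, and are independent between mates (unlike deamination).
#'
#' @param fragments Fragment tibble (possibly after
#'   [inject_ffpe_deamination()]).
#' @param config A [sim_config()].
#' @return A read tibble in the package's alignment layout (see
#'   [read_alignments()]); attribute `miscall_events` records realized counts.
#' @export
sequence_fragments <- function(fragments, config) {
  stopifnot(inherits(config, "sim_config"))
  rl <- config$read_length
  n <- nrow(fragments)
  m <- pmin(rl, fragments$insert)
  withr::with_seed(lib_seed(config, 4L), {
    seq1 <- substring(fragments$seq, 1L, m)
    seq2 <- substring(fragments$seq, fragments$insert - m + 1L, fragments$insert)
    qname <- sprintf("frag%08d", fragments$frag_id)
    reads <- tibble(
      qname = rep(qname, 2L),
      contig = rep(fragments$contig, 2L),
      pos = c(fragments$start, fragments$start + fragments$insert - m),
      mapq = config$mapq,
      seq = c(seq1, seq2),
      tlen = c(fragments$insert, -fragments$insert),
      paired = TRUE, proper_pair = TRUE, unmapped = FALSE,
      mate_unmapped = FALSE,
      reverse = rep(c(FALSE, TRUE), each = n),
      mate_reverse = rep(c(TRUE, FALSE), each = n),
      first_in_pair = rep(c(TRUE, FALSE), each = n),
      duplicate = FALSE
    )
    lens <- c(m, m)
    total <- sum(lens)
    codes <- base_codes(reads$seq)
    miss <- which(runif(total) < config$miscall_rate)
    if (length(miss)) {
      # uniform over the three alternatives: shift current code by 1..3 mod 4
      shift <- sample.int(3L, length(miss), replace = TRUE)
      codes[miss] <- ((codes[miss] - 1L + shift) %% 4L) + 1L
      reads$seq <- codes_to_strings(codes, lens)
    }
    q <- ifelse(runif(total) < config$low_qual_fraction,
                config$qual_low, config$qual_high)
    reads$qual <- phred_to_strings(q, lens)
    reads$cigar <- paste0(lens, "M")
    reads$left_clip <- 0L
    reads$m_len <- as.integer(lens)
    reads$right_clip <- 0L
    attr(reads, "miscall_events") <- list(n_miscalls = length(miss), n_bases = total)
    reads
  })
}

#' Inject soft-clipped read ends
#'
#' With probability `clip_probability` per mapped read, one end (5' or 3',
#' fair coin, in reference orientation) is replaced by random sequence —
#' modelling non-specific annealing between degraded fragments during library
#' construction. Clip lengths follow a geometric distribution truncated at
#' `read_length - 20`, with rate calibrated so the truncated mean equals
#' `clip_length_mean`; at least 20 aligned bases always remain. The SAM writer
#' emits the clipped segment as a CIGAR `S` operation and the aligned span
#' (and `POS`, for leading clips) shrinks accordingly.
#'
#' @param reads Read tibble from [sequence_fragments()].
#' @param config A [sim_config()].
#' @return The read tibble with clip annotations; attribute `clip_events`
#'   records realized clipped-base counts.
#' @export
inject_soft_clips <- function(reads, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$clip_length_mean >= config$read_length) {
    abort("`clip_length_mean` must be smaller than `read_length`",
          class = "ffpeqc_config_error")
  }
  withr::with_seed(lib_seed(config, 5L), {
    eligible <- which(!reads$unmapped & nchar(reads$seq) > 21L)
    hit <- eligible[runif(length(eligible)) < config$clip_probability]
    if (length(hit)) {
      cap_cfg <- config$read_length - 20L
      p <- trunc_geom_rate(config$clip_length_mean, cap_cfg)
      cap_i <- nchar(reads$seq[hit]) - 20L
      len <- pmin(rgeom(length(hit), p) + 1L, cap_cfg, cap_i)
      side_left <- runif(length(hit)) < 0.5
      rand <- codes_to_strings(sample.int(4L, sum(len), replace = TRUE), len)
      rdlen <- nchar(reads$seq[hit])
      cl_start <- ifelse(side_left, 1L, rdlen - len + 1L)
      cl_end <- ifelse(side_left, len, rdlen)
      s <- reads$seq[hit]
      substr(s, cl_start, cl_end) <- rand
      reads$seq[hit] <- s
      reads$left_clip[hit] <- ifelse(side_left, len, 0L)
      reads$right_clip[hit] <- ifelse(side_left, 0L, len)
      reads$m_len[hit] <- rdlen - len
      reads$pos[hit] <- reads$pos[hit] + ifelse(side_left, len, 0L)
      reads$cigar[hit] <- ifelse(
        side_left,
        paste0(len, "S", rdlen - len, "M"),
        paste0(rdlen - len, "M", len, "S"))
      attr(reads, "clip_events") <- list(
        n_clipped_reads = length(hit), n_clipped_bases = sum(len),
        n_reads = length(eligible), n_bases = sum(nchar(reads$seq[!reads$unmapped])))
    } else {
      attr(reads, "clip_events") <- list(
        n_clipped_reads = 0L, n_clipped_bases = 0L,
        n_reads = length(eligible),
        n_bases = sum(nchar(reads$seq[!reads$unmapped])))
    }
    reads
  })
}

# Rate of a geometric distribution on {1, 2, ...} such that E[min(X, cap)]
# equals `mean`; E[min(X, cap)] = (1 - (1-p)^cap) / p.
#' @noRd
trunc_geom_rate <- function(mean, cap) {
  if (mean >= cap - 0.5) return(1e-9)
  uniroot(function(p) (1 - (1 - p)^cap) / p - mean,
          interval = c(1e-9, 1), tol = 1e-10)$root
}

#' @noRd
assign_mapping_fates <- function(reads, config) {
  n_pairs <- nrow(reads) / 2L
  withr::with_seed(lib_seed(config, 6L), {
    u <- runif(n_pairs)
    unm <- u < config$unmapped_fraction
    disc <- !unm & u < config$unmapped_fraction + config$discordant_fraction
    unm2 <- rep(unm, 2L)
    disc2 <- rep(disc, 2L)
    reads$unmapped[unm2] <- TRUE
    reads$mate_unmapped[unm2] <- TRUE
    reads$proper_pair[unm2 | disc2] <- FALSE
    reads$contig[unm2] <- NA_character_
    reads$pos[unm2] <- NA_integer_
    reads$mapq[unm2] <- 0L
    reads$cigar[unm2] <- "*"
    reads$tlen[unm2] <- 0L
    reads$left_clip[unm2] <- 0L
    reads$m_len[unm2] <- 0L
    reads$right_clip[unm2] <- 0L
    # discordant pairs: same-strand mates, still mapped
    reads$reverse[disc2] <- FALSE
    reads$mate_reverse[disc2] <- FALSE
    # unmapped reads may carry a heavier low-quality tail
    if (any(unm2) && config$unmapped_low_qual_fraction != config$low_qual_fraction) {
      lens <- nchar(reads$seq[unm2])
      q <- ifelse(runif(sum(lens)) < config$unmapped_low_qual_fraction,
                  config$qual_low, config$qual_high)
      reads$qual[unm2] <- phred_to_strings(q, lens)
    }
    attr(reads, "fate_events") <- list(
      n_pairs = n_pairs, n_unmapped_pairs = sum(unm), n_discordant_pairs = sum(disc))
    reads
  })
}

#' Simulate a complete library
#'
#' Runs the full pipeline for one sample type: fragments (from the shared
#' haplotypes), FFPE deamination where applicable, paired-end sequencing with
#' miscalls, mapping-fate assignment (unmapped / discordant pairs), soft-clip
#' injection, and coordinate sorting. All randomness derives from the config
#' seed, so an identical config reproduces the library byte for byte.
#'
#' @param genome A `sim_genome`.
#' @param truth A `sim_truth`.
#' @param config A [sim_config()].
#' @return A `sim_library`: list with `reads` (alignment tibble, see
#'   [read_alignments()]), `realized` (realized artifact counts and
#'   denominators: deamination, miscalls, clips, mapping fates), `config`.
#' @examples
#' cfg <- sim_config(seed = 1, sample_type = "ffpe", contig_length = 5000,
#'                   mean_depth = 10)
#' g <- generate_reference(cfg)
#' tr <- plant_variants(g, cfg)
#' lib <- simulate_library(g, tr, cfg)
#' nrow(lib$reads)
#' @export
simulate_library <- function(genome, truth, config) {
  frags <- simulate_fragments(genome, truth, config)
  dea <- list(n_ct = 0L, n_ga = 0L, n_c = NA_integer_, n_g = NA_integer_)
  if (config$sample_type == "ffpe") {
    frags <- inject_ffpe_deamination(frags, config)
    dea <- attr(frags, "deamination_events")
  }
  reads <- sequence_fragments(frags, config)
  mis <- attr(reads, "miscall_events")
  reads <- assign_mapping_fates(reads, config)
  fates <- attr(reads, "fate_events")
  reads <- inject_soft_clips(reads, config)
  clips <- attr(reads, "clip_events")
  reads <- sort_reads(reads)
  attr(reads, "contigs") <- vapply(genome$contigs, nchar, integer(1))
  class(reads) <- c("ffpeqc_reads", class(reads))
  structure(list(
    reads = reads,
    realized = list(deamination = dea, miscalls = mis, clips = clips,
                    mapping_fates = fates),
    config = config
  ), class = "sim_library")
}

#' @noRd
sort_reads <- function(reads) {
  ord <- order(reads$unmapped, match(reads$contig, unique(reads$contig)),
               reads$pos, reads$qname)
  out <- reads[ord, ]
  for (a in c("miscall_events", "clip_events", "fate_events"))
    attr(out, a) <- attr(reads, a)
  out
}

#' Simulate a matched blood / frozen / FFPE trio
#'
#' Builds one reference and one germline/somatic truth set, then three
#' libraries sharing them. Per-type defaults follow [sim_config()]; `...`
#' overrides apply to all three types, and `blood`, `frozen`, `ffpe` take
#' per-type override lists.
#'
#' @param seed Integer seed for the shared reference and truth.
#' @param ... Arguments passed to every [sim_config()].
#' @param blood,frozen,ffpe Named lists of per-type [sim_config()] overrides.
#' @return List with `genome`, `truth`, and `libraries` (named list of
#'   `sim_library` objects).
#' @export
simulate_trio <- function(seed = 1L, ..., blood = list(), frozen = list(),
                          ffpe = list()) {
  shared <- list(...)
  mk <- function(type, extra) {
    do.call(sim_config, c(list(seed = seed, sample_type = type),
                          utils::modifyList(shared, extra)))
  }
  cfg_b <- mk("blood", blood)
  genome <- generate_reference(cfg_b)
  truth <- plant_variants(genome, cfg_b)
  libs <- list(
    blood = simulate_library(genome, truth, cfg_b),
    frozen = simulate_library(genome, truth, mk("frozen", frozen)),
    ffpe = simulate_library(genome, truth, mk("ffpe", ffpe))
  )
  list(genome = genome, truth = truth, libraries = libs)
}
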