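#' Validate a declarative run configuration
#'
#' Reads a YAML configuration for [run_compare()] and validates every field,
#' reporting all violations at once rather than the first. The paper-style
#' thresholds (lenient MQ/BQ >= 20 with depth >= 50, stringent MQ >= 60 /
#' BQ >= 30, LOD grid 6.3-250, 100-bp flanks) are defaults, overridable in
#' the file.
#'
#' @param path Path to a YAML file with keys `samples:` (`blood`, `frozen`,
#'   `ffpe` SAM paths), `reference:` (FASTA), `targets:` (BED), and optional
#'   `lenient:`/`stringent:` threshold blocks (`min_mapq`, `min_baseq`,
#'   `min_depth`), `lod_thresholds:`, `error_rate:`, `flank:`, `outdir:`.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  bad <- character(0)
  need_path <- function(value, label) {
    if (is.null(value)) {
      bad <<- c(bad, sprintf("`%s` is missing", label))
      return(NULL)
    }
    if (!is.character(value) || length(value) != 1L || !nzchar(value) ||
        !file.exists(value)) {
      bad <<- c(bad, sprintf("`%s` does not point to an existing file (got \"%s\")",
                             label, paste0(value, collapse = ",")))
      return(NULL)
    }
    value
  }
  samples <- raw$samples %||% list()
  for (s in c("blood", "frozen", "ffpe")) need_path(samples[[s]], paste0("samples.", s))
  need_path(raw$reference, "reference")
  need_path(raw$targets, "targets")

  thr <- function(block, defaults, label) {
    block <- utils::modifyList(defaults, block %||% list())
    ok <- vapply(block[c("min_mapq", "min_baseq", "min_depth")],
                 function(v) is.numeric(v) && length(v) == 1L && v >= 0, logical(1))
    if (!all(ok)) {
      bad <<- c(bad, sprintf("`%s` thresholds must be non-negative numbers", label))
      return(NULL)
    }
    filter_thresholds(block$min_mapq, block$min_baseq, block$min_depth)
  }
  lenient <- thr(raw$lenient, list(min_mapq = 20, min_baseq = 20, min_depth = 50), "lenient")
  stringent <- thr(raw$stringent, list(min_mapq = 60, min_baseq = 30, min_depth = 0), "stringent")
  if (!is.null(lenient) && !is.null(stringent)) {
    if (lenient$min_mapq > stringent$min_mapq || lenient$min_baseq > stringent$min_baseq) {
      bad <- c(bad, sprintf(
        "lenient thresholds (MQ %d/BQ %d) must not exceed stringent ones (MQ %d/BQ %d)",
        lenient$min_mapq, lenient$min_baseq, stringent$min_mapq, stringent$min_baseq))
    }
  }
  lod <- raw$lod_thresholds %||% c(6.3, 10, 20, 30, 50, 100, 150, 200, 250)
  if (!is.numeric(unlist(lod)) || any(unlist(lod) < 0)) {
    bad <- c(bad, "`lod_thresholds` must be non-negative numbers")
  }
  error_rate <- raw$error_rate %||% 1e-3
  if (!is_prob(error_rate)) bad <- c(bad, "`error_rate` must be a probability")
  flank <- raw$flank %||% 100L
  if (!is.numeric(flank) || flank < 0) bad <- c(bad, "`flank` must be >= 0")

  if (length(bad)) {
    abort(c(sprintf("invalid run configuration (%s):", path),
            stats::setNames(bad, rep("x", length(bad)))),
          class = "ffpeqc_config_error")
  }
  structure(list(
    samples = samples[c("blood", "frozen", "ffpe")],
    reference = raw$reference, targets = raw$targets,
    lenient = lenient, stringent = stringent,
    lod_thresholds = sort(as.numeric(unlist(lod))),
    error_rate = error_rate, flank = as.integer(flank),
    outdir = raw$outdir %||% "ffpeqc_report"
  ), class = "run_config")
}

#' Run the full FFPE-versus-frozen comparison
#'
#' Orchestrates the pipeline over a matched blood / frozen / FFPE set:
#' degradation metrics per sample (insert sizes, mate overlap, soft clips,
#' mapping status, target coverage, quality by mapping status), the two-pass
#' artifact-rate estimate (background from FFPE-defined sites counted in
#' blood; overall from blood-defined sites counted in frozen and in FFPE;
#' induced = overall minus background), and the somatic-call concordance
#' sweep with one-read rescue. Writes a JSON summary, TSV tables and a plain
#' text report under `config$outdir`; outputs carry no timestamps, so reruns
#' on identical inputs are byte-identical.
#'
#' @param config A `run_config` from [validate_config()], or a path to the
#'   YAML file.
#' @return The report bundle (named list of all stage results), invisibly.
#' @export
run_compare <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage \"%s\" failed: %s", name, conditionMessage(e)))
    })
  }
  targets <- stage("inputs", read_bed(config$targets))
  reads <- stage("inputs", lapply(config$samples, read_alignments))

  metrics <- stage("metrics", lapply(reads, function(r) {
    list(insert = insert_size_distribution(r),
         overlap = double_sequenced(r),
         softclip = soft_clip_metrics(r),
         mapping = mapping_stats(r),
         coverage = target_coverage(r, targets, flank = config$flank),
         quality = quality_by_mapping_status(r))
  }))

  rates <- stage("rates", {
    background <- background_error_rate(reads$ffpe, reads$blood,
                                        config$lenient, config$stringent)
    overall_ffpe <- overall_transition_rate(reads$blood, reads$ffpe,
                                            config$lenient, config$stringent)
    overall_frozen <- overall_transition_rate(reads$blood, reads$frozen,
                                              config$lenient, config$stringent)
    list(background = background,
         overall_ffpe = overall_ffpe,
         overall_frozen = overall_frozen,
         induced_ffpe = ffpe_induced_rate(overall_ffpe, background),
         induced_frozen = ffpe_induced_rate(overall_frozen, background))
  })

  concordance <- stage("concordance", {
    normal_pu <- pileup(reads$blood, config$stringent)
    frozen_pu <- pileup(reads$frozen, config$stringent)
    ffpe_pu <- pileup(reads$ffpe, config$stringent)
    calls_frozen <- call_somatic_minimal(frozen_pu, normal_pu,
                                         error_rate = config$error_rate,
                                         lod_threshold = min(config$lod_thresholds))
    calls_ffpe <- call_somatic_minimal(ffpe_pu, normal_pu,
                                       error_rate = config$error_rate,
                                       lod_threshold = min(config$lod_thresholds))
    list(calls_frozen = calls_frozen, calls_ffpe = calls_ffpe,
         strict = sweep_concordance(calls_ffpe, calls_frozen, config$lod_thresholds),
         rescue = rescue_by_read_support(calls_ffpe, calls_frozen, frozen_pu,
                                         config$lod_thresholds))
  })

  bundle <- list(config = config, metrics = metrics, rates = rates,
                 concordance = concordance)
  stage("write", write_report(bundle, config$outdir))
  invisible(bundle)
}

#' @noRd
write_report <- function(bundle, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  m <- bundle$metrics
  summary <- list(
    samples = lapply(m, function(x) list(
      median_insert = x$insert$median,
      n_pairs = x$insert$n_pairs,
      double_sequenced_fraction = x$overlap$double_fraction,
      soft_clip_fraction = x$softclip$clip_fraction,
      mapping = stats::setNames(as.list(x$mapping$fraction),
                                as.character(x$mapping$mapping_category)),
      covered_target_fraction = x$coverage$covered_target_fraction,
      on_target_mean_depth = x$coverage$on_target_mean_depth,
      flanking_mean_depth = x$coverage$flanking_mean_depth,
      off_target_base_fraction = x$coverage$off_target_base_fraction,
      frac_ge_q30 = stats::setNames(as.list(x$quality$summary$frac_ge_q30),
                                    x$quality$summary$status))),
    rates = lapply(bundle$rates, function(s)
      stats::setNames(as.list(s$rate_per_mb), s$class)),
    concordance = list(
      strict = as.list(stats::setNames(bundle$concordance$strict$overlap_fraction,
                                       bundle$concordance$strict$threshold)),
      rescue = as.list(stats::setNames(bundle$concordance$rescue$overlap_fraction,
                                       bundle$concordance$rescue$threshold))))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (s in names(m)) {
    readr::write_tsv(m[[s]]$insert$histogram,
                     file.path(outdir, paste0("insert_histogram_", s, ".tsv")))
  }
  for (rn in names(bundle$rates)) {
    readr::write_tsv(as_tibble(bundle$rates[[rn]]),
                     file.path(outdir, paste0("spectrum_", rn, ".tsv")))
  }
  readr::write_tsv(as_tibble(bundle$concordance$strict),
                   file.path(outdir, "concordance_strict.tsv"))
  readr::write_tsv(as_tibble(bundle$concordance$rescue),
                   file.path(outdir, "concordance_rescue.tsv"))
  writeLines(render_text_report(bundle), file.path(outdir, "report.txt"))
  invisible(outdir)
}

#' @noRd
render_text_report <- function(bundle) {
  m <- bundle$metrics
  fmt_pct <- function(x) sprintf("%.1f%%", 100 * x)
  lines <- c("FFPE versus frozen exome comparison", strrep("=", 36), "")
  lines <- c(lines, "1. Sequencing yield and mapping", strrep("-", 31))
  for (s in names(m)) {
    map <- m[[s]]$mapping
    lines <- c(lines, sprintf(
      "  %-6s properly paired %s, discordant %s, unmapped %s; target covered %s, on-target %.1fx, flanking %.1fx, off-target bases %s",
      s, fmt_pct(map$fraction[1]), fmt_pct(map$fraction[2]), fmt_pct(map$fraction[3]),
      fmt_pct(m[[s]]$coverage$covered_target_fraction),
      m[[s]]$coverage$on_target_mean_depth, m[[s]]$coverage$flanking_mean_depth,
      fmt_pct(m[[s]]$coverage$off_target_base_fraction)))
  }
  lines <- c(lines, "", "2. DNA degradation", strrep("-", 18))
  for (s in names(m)) {
    lines <- c(lines, sprintf(
      "  %-6s median insert %.0f bp (%d pairs); double-sequenced %s of bases; soft-clipped %s of mapped bases",
      s, m[[s]]$insert$median, m[[s]]$insert$n_pairs,
      fmt_pct(m[[s]]$overlap$double_fraction),
      fmt_pct(m[[s]]$softclip$clip_fraction)))
  }
  lines <- c(lines, "", "3. Base quality by mapping status", strrep("-", 33))
  for (s in names(m)) {
    q <- m[[s]]$quality$summary
    for (i in seq_len(nrow(q))) {
      lines <- c(lines, sprintf("  %-6s %-8s Q>=30: %s  Q<=20: %s",
                                s, q$status[i], fmt_pct(q$frac_ge_q30[i]),
                                fmt_pct(q$frac_le_q20[i])))
    }
  }
  lines <- c(lines, "", "4. Base-alteration rates (per Mb)", strrep("-", 33))
  for (rn in names(bundle$rates)) {
    sp <- bundle$rates[[rn]]
    lines <- c(lines, sprintf("  %-15s %s", rn,
                              paste(sprintf("%s %.0f", sp$class, sp$rate_per_mb),
                                    collapse = "  ")))
  }
  lines <- c(lines, "", "5. Somatic-call concordance", strrep("-", 27))
  for (mode in c("strict", "rescue")) {
    cv <- bundle$concordance[[mode]]
    lines <- c(lines, sprintf("  %-7s %s", mode,
                              paste(sprintf("LOD>=%g: %s", cv$threshold,
                                            ifelse(is.na(cv$overlap_fraction), "NA",
                                                   fmt_pct(cv$overlap_fraction))),
                                    collapse = "  ")))
  }
  lines
}
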