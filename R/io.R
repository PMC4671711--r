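#' Write a simulated library to disk
#'
#' Emits the full file bundle for one library: a coordinate-sorted headered
#' SAM, the reference FASTA, the target BED (0-based half-open), a truth VCF
#' 4.2 with the planted germline and somatic variants (VAF in INFO), and a
#' JSON sidecar with the realized artifact counts and denominators.
#'
#' @param lib A `sim_library` from [simulate_library()].
#' @param genome The `sim_genome` it was simulated from.
#' @param truth The `sim_truth` it was simulated from.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; defaults to the library's sample type.
#' @return Named list of written paths (`sam`, `fasta`, `bed`, `vcf`,
#'   `truth_json`), invisibly.
#' @export
write_library <- function(lib, genome, truth, dir, prefix = NULL) {
  stopifnot(inherits(lib, "sim_library"), inherits(genome, "sim_genome"))
  prefix <- prefix %||% lib$config$sample_type
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    sam = file.path(dir, paste0(prefix, ".sam")),
    fasta = file.path(dir, "reference.fa"),
    bed = file.path(dir, "targets.bed"),
    vcf = file.path(dir, paste0(prefix, ".truth.vcf")),
    truth_json = file.path(dir, paste0(prefix, ".realized.json")))
  contigs <- vapply(genome$contigs, nchar, integer(1))
  tryCatch({
    write_sam(lib$reads, paths$sam, contigs = contigs)
    write_fasta(genome, paths$fasta)
    write_bed(genome$targets, paths$bed)
    write_truth_vcf(truth, lib$config, paths$vcf, contigs = contigs)
    jsonlite::write_json(lib$realized, paths$truth_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }, error = function(e) {
    abort(sprintf("failed writing library files under %s: %s", dir, conditionMessage(e)))
  })
  invisible(paths)
}

#' Write a simulated reference as FASTA
#'
#' @param genome A `sim_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  dna <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(dna, path, width = 60L)
  invisible(path)
}

#' Read a FASTA reference into a `sim_genome`-like object
#'
#' @param path FASTA path.
#' @param targets Optional target tibble to attach.
#' @return A `sim_genome` (contigs + targets, the latter possibly empty).
#' @export
read_fasta <- function(path, targets = NULL) {
  dna <- Biostrings::readDNAStringSet(path)
  contigs <- stats::setNames(as.character(dna),
                             sub("\\s.*$", "", names(dna)))
  structure(list(contigs = contigs,
                 targets = targets %||% tibble(contig = character(),
                                               start = integer(),
                                               end = integer())),
            class = "sim_genome")
}

#' Read target regions from BED
#'
#' @param path BED path (3+ columns).
#' @return Tibble `contig`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  gr <- rtracklayer::import(path, format = "BED")
  tibble(contig = as.character(GenomeInfoDb_seqnames(gr)),
         start = BiocGenerics::start(gr) - 1L,
         end = BiocGenerics::end(gr))
}

# avoid a hard GenomeInfoDb import for one accessor
#' @noRd
GenomeInfoDb_seqnames <- function(gr) {
  as.character(methods::slot(gr, "seqnames"))
}

#' Write target regions as BED
#'
#' @param targets Tibble `contig`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(targets, path) {
  writeLines(sprintf("%s\t%d\t%d", targets$contig, targets$start, targets$end),
             path)
  invisible(path)
}

#' @noRd
write_truth_vcf <- function(truth, config, path, contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Expected observed variant allele fraction\">",
    "##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description=\"Planted somatic variant\">",
    "##INFO=<ID=GT,Number=1,Type=String,Description=\"Planted germline genotype\">",
    if (!is.null(contigs)) sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  g <- truth$germline
  s <- truth$somatic
  lines <- character(0)
  if (nrow(g)) {
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tVAF=0.5;GT=0/1",
                              g$contig, g$pos + 1L, g$ref, g$alt))
  }
  if (nrow(s) && config$sample_type != "blood") {
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tVAF=%.4f;SOMATIC",
                              s$contig, s$pos + 1L, s$ref, s$alt, s$vaf))
  }
  # positional sort across the two variant classes
  if (length(lines)) {
    pos <- as.integer(sub("^[^\t]+\t([0-9]+)\t.*$", "\\1", lines))
    chrom <- sub("\t.*$", "", lines)
    lines <- lines[order(chrom, pos)]
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
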