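#' Write a genome to FASTA
#'
#' @param genome named character vector or `DNAStringSet` (or
#'   `synthetic_locus`).
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  if (inherits(genome, "synthetic_locus")) genome <- genome$genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(as_genome(genome)),
                              path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return named character vector of contigs.
#' @export
read_genome_fasta <- function(path) {
  as_genome(Biostrings::readDNAStringSet(path))
}

## data.frame (chrom, start, end [, name, score, strand]; 0-based half-open)
## -> BED via rtracklayer
df_to_granges <- function(df, name = NULL, score = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand %||% "*"
  )
  if (!is.null(name)) gr$name <- name
  if (!is.null(score)) gr$score <- score
  gr
}

#' Write an interval table as BED
#'
#' Intervals are taken 0-based half-open (the package's internal convention)
#' and written as standard BED.
#'
#' @param df data.frame with `chrom`, `start`, `end`, optional `strand`.
#' @param path output path.
#' @param name optional per-interval name column (character vector).
#' @export
write_bed <- function(df, path, name = NULL) {
  gr <- df_to_granges(df, name = name %||% df$name %||% df$kind)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read a BED file as an interval data.frame
#'
#' @param path BED path.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), `name`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             strand = as.character(BiocGenerics::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write simulated reads as FASTQ
#'
#' Unwrapped four-line records with a per-read constant base quality equal
#' to the rounded mean Phred quality. Records are emitted directly (nanopore
#' reads run to tens of kilobases, beyond what fixed-width FASTQ writers
#' accept).
#'
#' @param reads data.frame with `read_id`, `sequence`, `mean_q`.
#' @param path output path.
#' @export
write_reads_fastq <- function(reads, path) {
  qchar <- vapply(pmax(0L, pmin(93L, as.integer(round(reads$mean_q)))),
                  function(q) rawToChar(as.raw(33L + q)), character(1))
  lines <- as.vector(rbind(paste0("@", reads$read_id),
                           reads$sequence,
                           "+",
                           strrep(qchar, nchar(reads$sequence))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ of simulated reads
#'
#' Counterpart of [write_reads_fastq()] (unwrapped records); base qualities
#' are collapsed back to the per-read mean Phred score.
#'
#' @param path FASTQ path.
#' @return data.frame `read_id`, `sequence`, `mean_q`.
#' @export
read_reads_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  ids <- sub("^@", "", lines[seq(1, length(lines), by = 4L)])
  seqs <- lines[seq(2, length(lines), by = 4L)]
  qual <- lines[seq(4, length(lines), by = 4L)]
  mean_q <- vapply(qual, function(q) {
    mean(as.integer(charToRaw(q))) - 33
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(read_id = ids, sequence = seqs, mean_q = mean_q,
             stringsAsFactors = FALSE)
}

#' Write truth alignments as PAF
#'
#' Minimal PAF: query name/length/start/end, strand, target name/length/
#' start/end, residue matches, block length, mapping quality, plus an
#' `rq:f:` tag carrying the mean read quality.
#'
#' @param alignments data.frame (`read_id`, `chrom`, `start`, `end`,
#'   `strand`, `mean_q`), 0-based half-open.
#' @param chrom_lengths named integer vector.
#' @param path output path.
#' @export
write_truth_paf <- function(alignments, chrom_lengths, path) {
  len <- alignments$end - alignments$start
  paf <- data.frame(
    qname = alignments$read_id, qlen = len, qstart = 0L, qend = len,
    strand = alignments$strand, tname = alignments$chrom,
    tlen = as.integer(chrom_lengths[alignments$chrom]),
    tstart = alignments$start, tend = alignments$end,
    matches = len, block = len, mapq = 60L,
    rq = sprintf("rq:f:%.2f", alignments$mean_q),
    stringsAsFactors = FALSE
  )
  write.table(paf, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read alignments from PAF
#'
#' Parses the 12 standard PAF columns and, when present, the `rq:f:` mean
#' read-quality tag (reads without the tag get `mean_q = NA`).
#'
#' @param path PAF path.
#' @return data.frame `read_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `mean_q`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(data.frame(read_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), mean_q = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 12L
  if (any(bad)) stop("malformed PAF line ", which(bad)[1])
  get <- function(i) vapply(parts, `[[`, character(1), i)
  mean_q <- vapply(parts, function(x) {
    tag <- grep("^rq:f:", x[-(1:12)], value = TRUE)
    if (length(tag)) as.numeric(sub("^rq:f:", "", tag[1])) else NA_real_
  }, numeric(1))
  data.frame(read_id = get(1), chrom = get(6),
             start = as.integer(get(8)), end = as.integer(get(9)),
             strand = get(5), mean_q = mean_q, stringsAsFactors = FALSE)
}

#' Write per-read methylation calls as TSV
#'
#' Columns: chromosome, position (1-based C of the CpG), read_id, call
#' (1 methylated / 0 unmethylated).
#'
#' @param calls data.frame from [simulate_protocol()] (`position` 0-based).
#' @param path output path.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- data.frame(chromosome = calls$chrom, position = calls$position + 1L,
                    read_id = calls$read_id, call = calls$call)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-read methylation call TSV
#'
#' @param path TSV written by [write_calls_tsv()].
#' @return data.frame `chrom`, `position` (0-based), `read_id`, `call`.
#' @export
read_calls_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  data.frame(chrom = tab$chromosome, position = as.integer(tab$position) - 1L,
             read_id = tab$read_id, call = as.integer(tab$call),
             stringsAsFactors = FALSE)
}

#' Write all ground-truth annotation of a synthetic locus
#'
#' Emits `genome.fasta`, `motif_instances.bed`, `domains.bed`,
#' `cg_sites.bed`, `regions.bed`, and `guides.tsv` under `outdir`.
#'
#' @param locus `synthetic_locus`.
#' @param outdir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_locus <- function(locus, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(outdir, "genome.fasta"),
    motifs = file.path(outdir, "motif_instances.bed"),
    domains = file.path(outdir, "domains.bed"),
    cg = file.path(outdir, "cg_sites.bed"),
    regions = file.path(outdir, "regions.bed"),
    guides = file.path(outdir, "guides.tsv")
  )
  write_genome_fasta(locus, paths["genome"])
  write_bed(locus$motif_instances, paths["motifs"])
  write_bed(locus$domains, paths["domains"], name = locus$domains$kind)
  cg <- data.frame(chrom = locus$cg_sites$chrom,
                   start = locus$cg_sites$position,
                   end = locus$cg_sites$position + 2L)
  write_bed(cg, paths["cg"],
            name = ifelse(is.na(locus$cg_sites$motif), "CG",
                          locus$cg_sites$motif))
  reg <- data.frame(chrom = locus$regions$chrom,
                    start = locus$regions$start - 1L,
                    end = locus$regions$end)
  write_bed(reg, paths["regions"], name = locus$regions$label)
  write_guides_tsv(locus$guides, paths["guides"])
  invisible(paths)
}

#' Write simulation outputs
#'
#' Emits `reads.fastq`, `truth.paf`, and `meth_calls.tsv` under `outdir`.
#'
#' @param sim `ceo_simulation` from [simulate_protocol()].
#' @param chrom_lengths named integer vector.
#' @param outdir output directory.
#' @return named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, chrom_lengths, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fastq = file.path(outdir, "reads.fastq"),
             paf = file.path(outdir, "truth.paf"),
             calls = file.path(outdir, "meth_calls.tsv"))
  write_reads_fastq(sim$reads, paths["fastq"])
  write_truth_paf(sim$alignments, chrom_lengths, paths["paf"])
  if (!is.null(sim$calls)) write_calls_tsv(sim$calls, paths["calls"])
  invisible(paths)
}
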