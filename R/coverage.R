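#' Filter alignments by mean read quality
#'
#' Keeps records with mean Phred quality at or above the threshold; the
#' standard nanopore pass filter drops reads with quality below 7.
#'
#' @param alignments data.frame with a `mean_q` column.
#' @param min_q threshold (default 7); records with `mean_q >= min_q` are
#'   kept.
#' @return the filtered data.frame.
#' @export
filter_reads <- function(alignments, min_q = 7) {
  if (min_q < 0) stop("min_q must be >= 0")
  out <- alignments[alignments$mean_q >= min_q, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-base depth of coverage
#'
#' Difference-array accumulation of alignment intervals into one integer
#' depth vector per chromosome.
#'
#' @param alignments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param chrom_lengths named integer vector of contig lengths.
#' @return named list of integer depth vectors (element `i` is coverage of
#'   0-based position `i - 1`).
#' @export
depth_profile <- function(alignments, chrom_lengths) {
  bad <- !(alignments$chrom %in% names(chrom_lengths))
  if (any(bad)) {
    stop("alignment on unknown chromosome: ", alignments$read_id[bad][1])
  }
  oob <- alignments$start < 0 |
    alignments$end > chrom_lengths[alignments$chrom] |
    alignments$start >= alignments$end
  if (any(oob)) {
    stop("out-of-bounds alignment: ",
         (alignments$read_id %||% rownames(alignments))[oob][1])
  }
  lapply(setNames(names(chrom_lengths), names(chrom_lengths)), function(ch) {
    n <- chrom_lengths[[ch]]
    d <- integer(n + 1L)
    a <- alignments[alignments$chrom == ch, , drop = FALSE]
    if (nrow(a)) {
      add <- tabulate(a$start + 1L, nbins = n + 1L)
      sub <- tabulate(a$end + 1L, nbins = n + 1L)
      d <- add - sub
    }
    cumsum(d)[seq_len(n)]
  })
}

#' Mean depth over a region
#'
#' @param profile list as from [depth_profile()].
#' @param region list/data.frame row with `chrom`, `start`, `end` (1-based
#'   inclusive, the reporting convention) — or a numeric `c(start, end)` with
#'   `chrom` given separately.
#' @param chrom chromosome when `region` is a bare numeric pair.
#' @return mean per-base coverage (numeric).
#' @export
region_mean_depth <- function(profile, region, chrom = NULL) {
  if (is.numeric(region)) {
    region <- list(chrom = chrom %||% names(profile)[1],
                   start = region[1], end = region[2])
  }
  s <- as.integer(region$start); e <- as.integer(region$end)
  if (e < s) stop("empty region")
  d <- profile[[region$chrom]]
  if (is.null(d) || e > length(d) || s < 1) stop("region outside chromosome")
  mean(d[s:e])
}

#' Enrichment fold of a region
#'
#' Region mean depth over genome-wide mean depth, rounded to two decimals as
#' reported.
#'
#' @param region_depth mean depth of the region.
#' @param genome_depth genome-wide mean depth (> 0).
#' @return numeric fold.
#' @export
enrichment_fold <- function(region_depth, genome_depth) {
  if (any(genome_depth <= 0)) stop("genome_depth must be > 0")
  round_half_up(region_depth / genome_depth, 2)
}

#' Genome-wide mean depth
#'
#' Total aligned bases divided by genome length.
#'
#' @param alignments data.frame with `start`, `end` (0-based half-open).
#' @param chrom_lengths named integer vector.
#' @return numeric mean depth.
#' @export
genome_mean_depth <- function(alignments, chrom_lengths) {
  sum(as.numeric(alignments$end - alignments$start)) /
    sum(as.numeric(chrom_lengths))
}

#' Count long reads overlapping a region
#'
#' Number of alignments that overlap the region by at least one base and
#' whose aligned span is `min_len` bp or more.
#'
#' @param alignments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param region `chrom`/`start`/`end` (1-based inclusive) list or row.
#' @param min_len minimum aligned length in bp (boundary inclusive).
#' @return integer count.
#' @export
long_read_tally <- function(alignments, region, min_len = 16000) {
  if (min_len < 0) stop("min_len must be >= 0")
  r0 <- as.integer(region$start) - 1L  # 0-based half-open
  r1 <- as.integer(region$end)
  hit <- alignments$chrom == region$chrom &
    alignments$start < r1 & alignments$end > r0 &
    (alignments$end - alignments$start) >= min_len
  sum(hit)
}

#' Per-region enrichment table
#'
#' The published-style summary: one row per region with mean depth and
#' enrichment fold against the genome-wide mean, both to two decimals.
#' Reads overlapping a region by at least `min_overlap` fraction of their
#' length are counted toward its depth profile (default any overlap).
#'
#' @param alignments data.frame (`read_id`, `chrom`, `start`, `end`,
#'   `strand`, `mean_q`), 0-based half-open.
#' @param regions data.frame (`label`, `chrom`, `start`, `end`), 1-based
#'   inclusive.
#' @param chrom_lengths named integer vector.
#' @param min_q quality filter applied first (`NULL` to skip).
#' @param genome_depth genome-wide mean depth to normalize against; computed
#'   from the (filtered) alignments when `NULL`.
#' @param stat `"mean"` (default, reproduces the published arithmetic) or
#'   `"median"` per-base depth.
#' @return data.frame `label`, `chrom`, `start`, `end`, `n_reads`,
#'   `average_depth`, `enrichment_fold`.
#' @export
region_depth_table <- function(alignments, regions, chrom_lengths,
                               min_q = 7, genome_depth = NULL,
                               stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!is.null(min_q)) alignments <- filter_reads(alignments, min_q)
  prof <- depth_profile(alignments, chrom_lengths)
  gd <- genome_depth %||% genome_mean_depth(alignments, chrom_lengths)
  res <- regions
  res$n_reads <- vapply(seq_len(nrow(regions)), function(i) {
    long_read_tally(alignments, regions[i, ], min_len = 0)
  }, integer(1))
  res$average_depth <- vapply(seq_len(nrow(regions)), function(i) {
    reg <- regions[i, ]
    d <- prof[[reg$chrom]][reg$start:reg$end]
    if (stat == "mean") mean(d) else stats::median(d)
  }, numeric(1))
  res$enrichment_fold <- enrichment_fold(res$average_depth, gd)
  res$average_depth <- round_half_up(res$average_depth, 2)
  attr(res, "genome_depth") <- gd
  res
}
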