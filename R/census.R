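#' Count motif occurrences in a sequence
#'
#' Exhaustive exact-match scan (forward strand) for each motif; overlapping
#' occurrences of the same motif are counted. An optional Hamming tolerance
#' admits degenerate copies (off by default so counts carry the literal-motif
#' semantics of the published census).
#'
#' @param sequence character sequence or `DNAString` (or a
#'   `synthetic_locus`, scanned over its whole chromosome).
#' @param motifs data.frame with `name` and `sequence` columns (e.g.
#'   [fibh_motifs()]), or a named character vector.
#' @param max_mismatch Hamming tolerance per occurrence (default 0).
#' @param chrom chromosome name used in the instance table.
#' @return list with `counts` (data.frame `name`, `sequence`, `count`) and
#'   `instances` (data.frame `name`, `chrom`, `start`, `end` 0-based
#'   half-open, `strand`, sorted by position).
#' @export
count_motifs <- function(sequence, motifs, max_mismatch = 0,
                         chrom = "chr1") {
  if (inherits(sequence, "synthetic_locus")) {
    chrom <- names(sequence$genome)[1]
    sequence <- sequence$genome[[1]]
  }
  sequence <- as.character(sequence)
  if (is.character(motifs) && is.null(dim(motifs))) {
    motifs <- data.frame(name = names(motifs) %||% motifs, sequence = motifs,
                         stringsAsFactors = FALSE)
  }
  check_dna(motifs$sequence, "motif sequence")
  subj <- Biostrings::DNAString(sequence)
  inst <- lapply(seq_len(nrow(motifs)), function(i) {
    hits <- Biostrings::matchPattern(motifs$sequence[i], subj,
                                     max.mismatch = max_mismatch)
    s <- BiocGenerics::start(hits) - 1L
    data.frame(name = rep(motifs$name[i], length(s)),
               chrom = rep(chrom, length(s)), start = s,
               end = s + nchar(motifs$sequence[i]),
               strand = rep("+", length(s)), stringsAsFactors = FALSE)
  })
  instances <- do.call(rbind, inst)
  instances <- instances[order(instances$start, instances$name), ]
  rownames(instances) <- NULL
  counts <- data.frame(name = motifs$name, sequence = motifs$sequence,
                       count = vapply(inst, nrow, integer(1)),
                       stringsAsFactors = FALSE)
  list(counts = counts, instances = instances)
}

#' Find CpG dinucleotide positions
#'
#' 0-based start position of every `CG` in the sequence; `CGCG` yields
#' positions 0 and 2.
#'
#' @param sequence character sequence or `DNAString`.
#' @return integer vector of 0-based positions.
#' @export
find_cg_sites <- function(sequence) {
  sequence <- check_dna(as.character(sequence), "sequence")
  match_iupac(sequence, "CG")
}

#' Segment a locus into repetitive and amorphous domains
#'
#' Density-window segmentation: per-base motif coverage is averaged over a
#' centered sliding window; bases at or above the density threshold seed
#' repetitive segments, sub-threshold gaps shorter than `merge_gap` are
#' absorbed, and each repetitive segment is then snapped to the motif
#' instances it contains. The remaining gaps between repetitive segments are
#' amorphous; sequence before the first and after the last repetitive
#' segment is labeled N-/C-terminal. The output tiles `[0, locus_len)`
#' exactly.
#'
#' @param motif_instances data.frame with `start`, `end` (0-based half-open,
#'   locus frame).
#' @param locus_len locus length in bp.
#' @param window sliding-window width, bp (default 200).
#' @param density_threshold minimum motif-coverage fraction calling a window
#'   repetitive (default 0.5).
#' @param merge_gap sub-threshold gaps shorter than this are merged into the
#'   flanking repetitive segment (default 50 bp).
#' @return data.frame `kind` (`R`, `A`, `N-terminal`, `C-terminal`),
#'   `start`, `end` (0-based half-open), `motif_density` (fraction of bases
#'   covered by motif instances).
#' @export
segment_domains <- function(motif_instances, locus_len, window = 200,
                            density_threshold = 0.5, merge_gap = 50) {
  locus_len <- as.integer(locus_len)
  mi <- motif_instances[order(motif_instances$start), , drop = FALSE]
  if (nrow(mi) && (min(mi$start) < 0 || max(mi$end) > locus_len)) {
    stop("motif instance outside locus")
  }
  cov_of <- function(s, e) {  # total covered bases in [s, e)
    if (!nrow(mi)) return(0L)
    sum(pmax(0L, pmin(mi$end, e) - pmax(mi$start, s)))
  }
  if (!nrow(mi)) {
    return(data.frame(kind = "N-terminal", start = 0L, end = locus_len,
                      motif_density = 0, stringsAsFactors = FALSE))
  }
  ## per-base coverage via difference array, then centered rolling mean
  d <- integer(locus_len + 1L)
  d[mi$start + 1L] <- d[mi$start + 1L] + 1L
  d[mi$end + 1L] <- d[mi$end + 1L] - 1L
  cov <- pmin(1L, cumsum(d)[seq_len(locus_len)])
  half <- floor(window / 2)
  cs <- c(0, cumsum(cov))
  pos <- seq_len(locus_len)
  lo <- pmax(0L, pos - 1L - half)
  hi <- pmin(locus_len, pos + half)
  dens <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  rep_base <- dens >= density_threshold
  if (!any(rep_base)) {
    return(data.frame(kind = "N-terminal", start = 0L, end = locus_len,
                      motif_density = cov_of(0L, locus_len) / locus_len,
                      stringsAsFactors = FALSE))
  }
  ## runs of repetitive bases; absorb short sub-threshold gaps
  rl <- rle(rep_base)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths  # 0-based
  seg <- data.frame(rep = rl$values, start = starts, end = ends)
  rs <- seg[seg$rep, , drop = FALSE]
  merged <- list(c(rs$start[1], rs$end[1]))
  for (i in seq_len(nrow(rs))[-1]) {
    last <- merged[[length(merged)]]
    if (rs$start[i] - last[2] < merge_gap) {
      merged[[length(merged)]][2] <- rs$end[i]
    } else {
      merged[[length(merged) + 1L]] <- c(rs$start[i], rs$end[i])
    }
  }
  ## snap each repetitive segment to the motif instances it intersects;
  ## the centered window depresses density right at domain edges, so runs
  ## are expanded by half a window before intersecting
  snap <- lapply(merged, function(se) {
    olap <- mi$start < se[2] + half & mi$end > se[1] - half
    if (!any(olap)) return(NULL)
    c(min(mi$start[olap]), max(mi$end[olap]))
  })
  snap <- do.call(rbind, snap[!vapply(snap, is.null, logical(1))])
  ## snapping can make neighbors touch; merge any overlap
  keep <- list(snap[1, ])
  for (i in seq_len(nrow(snap))[-1]) {
    last <- keep[[length(keep)]]
    if (snap[i, 1] <= last[2]) keep[[length(keep)]][2] <- snap[i, 2]
    else keep[[length(keep) + 1L]] <- snap[i, ]
  }
  snap <- do.call(rbind, keep)
  out <- list()
  if (snap[1, 1] > 0) {
    out[[1]] <- data.frame(kind = "N-terminal", start = 0L, end = snap[1, 1])
  }
  for (i in seq_len(nrow(snap))) {
    out[[length(out) + 1L]] <- data.frame(kind = "R", start = snap[i, 1],
                                          end = snap[i, 2])
    if (i < nrow(snap)) {
      out[[length(out) + 1L]] <- data.frame(kind = "A", start = snap[i, 2],
                                            end = snap[i + 1, 1])
    }
  }
  if (snap[nrow(snap), 2] < locus_len) {
    out[[length(out) + 1L]] <- data.frame(kind = "C-terminal",
                                          start = snap[nrow(snap), 2],
                                          end = locus_len)
  }
  res <- do.call(rbind, out)
  res$motif_density <- vapply(seq_len(nrow(res)), function(i) {
    cov_of(res$start[i], res$end[i]) / (res$end[i] - res$start[i])
  }, numeric(1))
  rownames(res) <- NULL
  res
}
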