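#' GC content of a protospacer
#'
#' Percent G+C of a spacer sequence, rounded to the nearest integer. The PAM
#' is never part of the spacer and must not be included by the caller.
#'
#' @param protospacer character vector of A/C/G/T sequences.
#' @return integer vector of percents in `[0, 100]`.
#' @examples
#' gc_percent("TGTTACCGGGGTCTAGTGAC")  # 55
#' @export
gc_percent <- function(protospacer) {
  protospacer <- check_dna(protospacer, "protospacer")
  n <- nchar(protospacer)
  gc <- nchar(gsub("[AT]", "", protospacer))
  as.integer(round_half_up(100 * gc / n))
}

#' AT content of a protospacer
#'
#' Complement of [gc_percent()] on the same rounding convention is not exact
#' for odd compositions, so this is computed directly from the A+T count.
#'
#' @inheritParams gc_percent
#' @return numeric vector of percents (unrounded).
#' @export
at_percent <- function(protospacer) {
  protospacer <- check_dna(protospacer, "protospacer")
  100 * nchar(gsub("[GC]", "", protospacer)) / nchar(protospacer)
}

## One candidate row in the printed-table convention: the genomic location
## spans PAM + protospacer, 1-based inclusive, with descending start/end on
## the reverse strand (start = PAM-proximal terminus on the guide's strand).
guide_row <- function(name, chrom, strand, pam, protospacer, start, end) {
  data.frame(
    name = name, chrom = chrom, strand = strand, pam = pam,
    protospacer = protospacer, start = start, end = end,
    gc_percent = gc_percent(protospacer),
    size = nchar(protospacer),
    stringsAsFactors = FALSE
  )
}

#' Scan a genome for Cas12a guide candidates
#'
#' Finds every occurrence of the PAM (default TTTV, the canonical Cas12a
#' T-rich PAM) on both strands and reports the `spacer_len` bases immediately
#' 3' of the PAM as a candidate protospacer. Candidates whose spacer would run
#' past the contig end are skipped.
#'
#' Reported coordinates follow the printed-table convention: 1-based
#' inclusive, spanning PAM plus protospacer, with `start` the PAM-side
#' terminus — so reverse-strand guides have `start > end`.
#'
#' @param genome `DNAStringSet` or named character vector of contigs.
#' @param pam_pattern IUPAC PAM pattern 5' of the spacer (default `"TTTV"`).
#' @param spacer_len protospacer length in bp (default 21; Cas12a guides are
#'   typically 20-23 nt).
#' @return data.frame of guide candidates with columns `name`, `chrom`,
#'   `strand`, `pam`, `protospacer`, `start`, `end`, `gc_percent`, `size`.
#' @export
scan_pams <- function(genome, pam_pattern = "TTTV", spacer_len = 21) {
  genome <- as_genome(genome)
  if (spacer_len < 1) stop("spacer_len must be >= 1")
  plen <- nchar(pam_pattern)
  out <- list()
  skipped <- 0L
  for (chrom in names(genome)) {
    seq_f <- genome[[chrom]]
    n <- nchar(seq_f)
    ## forward strand: PAM at [p, p+plen), spacer 3' of it
    p <- match_iupac(seq_f, pam_pattern)
    fit <- p + plen + spacer_len <= n
    skipped <- skipped + sum(!fit)
    p <- p[fit]
    if (length(p)) {
      out[[length(out) + 1L]] <- guide_row(
        name = sprintf("%s_%d_fwd", chrom, p + 1L),
        chrom = chrom, strand = "+",
        pam = substring(seq_f, p + 1L, p + plen),
        protospacer = substring(seq_f, p + plen + 1L, p + plen + spacer_len),
        start = p + 1L, end = p + plen + spacer_len
      )
    }
    ## reverse strand: scan the reverse complement, map back to forward coords
    seq_r <- revcomp(seq_f)
    q <- match_iupac(seq_r, pam_pattern)
    fit <- q + plen + spacer_len <= n
    skipped <- skipped + sum(!fit)
    q <- q[fit]
    if (length(q)) {
      out[[length(out) + 1L]] <- guide_row(
        name = sprintf("%s_%d_rev", chrom, n - q),
        chrom = chrom, strand = "-",
        pam = substring(seq_r, q + 1L, q + plen),
        protospacer = substring(seq_r, q + plen + 1L, q + plen + spacer_len),
        start = n - q, end = n - q - plen - spacer_len + 1L
      )
    }
  }
  if (skipped > 0L) {
    message(skipped, " PAM occurrence(s) skipped: spacer extends past contig end")
  }
  if (!length(out)) {
    return(guide_row(character(), character(), character(), character(),
                     character(), integer(), integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## All PAM-anchored spacer sites in a genome, with Hamming distance to
## `protospacer` counted within the spacer only. Internal engine shared by
## count_offtargets(). Returns chrom/strand/start(printed)/mm.
pam_anchored_sites <- function(genome, protospacer, pam_pattern) {
  genome <- as_genome(genome)
  L <- nchar(protospacer)
  plen <- nchar(pam_pattern)
  gchars <- strsplit(protospacer, "")[[1]]
  res <- list()
  for (chrom in names(genome)) {
    for (strand in c("+", "-")) {
      seq_s <- if (strand == "+") genome[[chrom]] else revcomp(genome[[chrom]])
      n <- nchar(seq_s)
      p <- match_iupac(seq_s, pam_pattern)
      p <- p[p + plen + L <= n]
      if (!length(p)) next
      spacers <- substring(seq_s, p + plen + 1L, p + plen + L)
      mat <- matrix(unlist(strsplit(spacers, ""), use.names = FALSE),
                    nrow = L)
      mm <- colSums(mat != gchars)
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, strand = strand,
        start = if (strand == "+") p + 1L else n - p,
        mm = mm, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res)) {
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), mm = integer()))
  }
  do.call(rbind, res)
}

#' Mismatch-bounded off-target census for a guide
#'
#' Counts genomic sites that carry an exact PAM match followed by a spacer
#' within `max_mm` Hamming mismatches of the guide's protospacer, on both
#' strands. Mismatches are counted only within the protospacer; the PAM must
#' match the (IUPAC) pattern exactly unless `degenerate_pam = TRUE`, which
#' drops the PAM requirement altogether. The guide's own locus, when its
#' coordinates are supplied, is excluded — so a genome-unique guide reports
#' MM0 = 0, matching the off-target convention of CRISPR design tools.
#'
#' @param guide a one-row data.frame or list with `protospacer`, and
#'   optionally `chrom`, `strand`, `start` (printed convention) identifying
#'   the on-target locus to exclude; a bare character protospacer is also
#'   accepted (nothing excluded).
#' @param genome `DNAStringSet` or named character vector.
#' @param pam_pattern IUPAC PAM (default `"TTTV"`).
#' @param max_mm maximum mismatch count tallied (default 3).
#' @param degenerate_pam if `TRUE`, any 4-mer is accepted as PAM.
#' @return named integer vector `c(mm0 = ..., mm1 = ..., ..., mm<max_mm>)`.
#' @export
count_offtargets <- function(guide, genome, pam_pattern = "TTTV", max_mm = 3,
                             degenerate_pam = FALSE) {
  if (is.character(guide)) guide <- list(protospacer = guide)
  spacer <- check_dna(guide$protospacer, "protospacer")
  if (degenerate_pam) pam_pattern <- strrep("N", nchar(pam_pattern))
  sites <- pam_anchored_sites(genome, spacer, pam_pattern)
  if (!is.null(guide$chrom) && !is.null(guide$start)) {
    own <- sites$chrom == guide$chrom & sites$start == guide$start &
      sites$strand == (guide$strand %||% "+")
    sites <- sites[!own, , drop = FALSE]
  }
  counts <- vapply(0:max_mm, function(m) sum(sites$mm == m), integer(1))
  setNames(counts, paste0("mm", 0:max_mm))
}

#' Derive enrichment regions from two guide pairs
#'
#' A pair of guides upstream and a pair downstream of a target locus define
#' three adjacent regions: the excised target between the inner guides, and
#' the upstream/downstream intervals between the members of each pair (cuts
#' at the outer guides release those flanks too, so they are co-enriched).
#' The boundary contributed by each guide site is its 5'-most genomic
#' coordinate, i.e. `min(start, end)` of the printed PAM-inclusive site; this
#' convention reproduces the published region table from the published guide
#' table.
#'
#' @param up_pair,down_pair two-row data.frames of guide records (as from
#'   [scan_pams()] or [fibh_guides()]) with `chrom`, `start`, `end`.
#' @param target_label label for the target row (default `"target"`).
#' @return data.frame with columns `label`, `chrom`, `start`, `end`
#'   (1-based inclusive, ascending by position as printed).
#' @export
define_enrichment_regions <- function(up_pair, down_pair,
                                      target_label = "target") {
  stopifnot(nrow(up_pair) == 2L, nrow(down_pair) == 2L)
  chroms <- unique(c(up_pair$chrom, down_pair$chrom))
  if (length(chroms) != 1L) stop("guides lie on different chromosomes")
  b_up <- sort(pmin(up_pair$start, up_pair$end))
  b_dn <- sort(pmin(down_pair$start, down_pair$end))
  lo_up <- range(c(up_pair$start, up_pair$end))
  lo_dn <- range(c(down_pair$start, down_pair$end))
  if (lo_up[1] <= lo_dn[2] && lo_dn[1] <= lo_up[2]) {
    stop("up and down guide pairs overlap; cannot derive regions")
  }
  up_high <- min(b_up) > max(b_dn)
  inner_up <- if (up_high) b_up[1] else b_up[2]
  inner_dn <- if (up_high) b_dn[2] else b_dn[1]
  target <- sort(c(inner_up, inner_dn))
  regions <- data.frame(
    label = c("downstream", target_label, "upstream"),
    chrom = chroms,
    start = c(b_dn[1], target[1], b_up[1]),
    end = c(b_dn[2], target[2], b_up[2]),
    stringsAsFactors = FALSE
  )
  regions <- regions[order(regions$start), ]
  rownames(regions) <- NULL
  regions
}

#' The published FibH guide set
#'
#' The four crRNA target sites flanking the silkworm fibroin heavy-chain gene
#' (*FibH*, KWMTBOMO15365) on chromosome 25: two upstream of the gene
#' (reverse strand, descending printed coordinates) and two downstream
#' (forward strand). Genomic locations span PAM plus protospacer. Efficiency
#' scores are stored external predictions, never computed here; mm0-mm3 are
#' the published genome-wide off-target counts.
#'
#' @return data.frame of four guide records.
#' @export
fibh_guides <- function() {
  g <- rbind(
    guide_row("FibH-up 1", "Bomo_Chr25", "-", "TTTA",
              "TGTTACCGGGGTCTAGTGAC", 10372894L, 10372871L),
    guide_row("FibH-up 2", "Bomo_Chr25", "-", "TTTA",
              "AGCTTGTTGTACAAAACTGC", 10372500L, 10372477L),
    guide_row("FibH-down 1", "Bomo_Chr25", "+", "TTTA",
              "TATGAACCTATTGTAATTTAG", 10354516L, 10354540L),
    guide_row("FibH-down 2", "Bomo_Chr25", "+", "TTTG",
              "TACCCTCATACCTCAAAGAAC", 10353778L, 10353802L)
  )
  g$efficiency_score <- c(60L, 52L, 59L, 42L)
  g$mm0 <- c(0L, 0L, 0L, 0L)
  g$mm1 <- c(0L, 0L, 0L, 0L)
  g$mm2 <- c(0L, 0L, 0L, 0L)
  g$mm3 <- c(0L, 1L, 0L, 0L)
  g$cut_efficiency <- c(1.00, 1.00, 1.00, 0.98)
  g
}

#' Write a guide table in the published layout
#'
#' Columns: name, target_sequence (PAM in lowercase, then protospacer),
#' genomic_location, gc_percent, efficiency, mm0-mm3, size.
#'
#' @param guides guide data.frame (with optional `efficiency_score`,
#'   `mm0`..`mm3` columns).
#' @param path output TSV path.
#' @return the formatted data.frame, invisibly.
#' @export
write_guides_tsv <- function(guides, path) {
  tab <- data.frame(
    name = guides$name,
    target_sequence = paste0(tolower(guides$pam), guides$protospacer),
    genomic_location = sprintf("%s: %s-%s", guides$chrom,
                               format(guides$start, big.mark = ",", trim = TRUE),
                               format(guides$end, big.mark = ",", trim = TRUE)),
    gc_percent = guides$gc_percent,
    efficiency = guides$efficiency_score %||% NA_integer_,
    stringsAsFactors = FALSE
  )
  for (col in c("mm0", "mm1", "mm2", "mm3")) tab[[col]] <- guides[[col]] %||% NA_integer_
  tab$size <- guides$size
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
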