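# Independent brute-force oracles, base R only, deliberately naive.

IUPAC <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
           W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
           V = "ACG", N = "ACGT")

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

## 0-based starts of IUPAC pattern matches, by per-position set membership
oracle_iupac_match <- function(seq, pattern) {
  ch <- strsplit(seq, "")[[1]]
  pat <- strsplit(toupper(pattern), "")[[1]]
  allowed <- lapply(pat, function(p) strsplit(IUPAC[[p]], "")[[1]])
  n <- length(ch); k <- length(pat)
  if (n < k) return(integer(0))
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    ok <- ok & ch[seq_len(n - k + 1L) + j - 1L] %in% allowed[[j]]
  }
  which(ok) - 1L
}

## Candidate table in the printed convention, matching scan_pams()'s contract
oracle_scan <- function(genome_seq, pam = "TTTV", spacer_len = 21) {
  plen <- nchar(pam)
  n <- nchar(genome_seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome_seq else oracle_revcomp(genome_seq)
    for (p in oracle_iupac_match(s, pam)) {
      if (p + plen + spacer_len > n) next
      proto <- substring(s, p + plen + 1L, p + plen + spacer_len)
      loc <- if (strand == "+") c(p + 1L, p + plen + spacer_len) else
        c(n - p, n - p - plen - spacer_len + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        strand = strand, start = loc[1], end = loc[2], protospacer = proto,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## Exhaustive PAM-anchored Hamming census; excludes one site by
## (strand, printed start) when own != NULL
oracle_offtargets <- function(spacer, genome_seq, pam = "TTTV", max_mm = 3,
                              own = NULL) {
  L <- nchar(spacer)
  sp <- strsplit(spacer, "")[[1]]
  plen <- nchar(pam)
  n <- nchar(genome_seq)
  counts <- integer(max_mm + 1L)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome_seq else oracle_revcomp(genome_seq)
    ch <- strsplit(s, "")[[1]]
    for (p in oracle_iupac_match(s, pam)) {
      if (p + plen + L > n) next
      printed_start <- if (strand == "+") p + 1L else n - p
      if (!is.null(own) && strand == own$strand &&
          printed_start == own$start) next
      mm <- sum(ch[p + plen + seq_len(L)] != sp)
      if (mm <= max_mm) counts[mm + 1L] <- counts[mm + 1L] + 1L
    }
  }
  setNames(counts, paste0("mm", 0:max_mm))
}

## Naive per-base depth by looping reads over positions
oracle_depth <- function(alignments, chrom_len) {
  d <- integer(chrom_len)
  for (i in seq_len(nrow(alignments))) {
    idx <- (alignments$start[i] + 1L):alignments$end[i]
    d[idx] <- d[idx] + 1L
  }
  d
}

## All occurrences (0-based, overlapping allowed) of motif in seq
oracle_motif_positions <- function(seq, motif) {
  n <- nchar(seq); k <- nchar(motif)
  pos <- integer(0)
  for (i in seq_len(max(0L, n - k + 1L))) {
    if (substring(seq, i, i + k - 1L) == motif) pos <- c(pos, i - 1L)
  }
  pos
}

random_seq <- function(n, gc = 0.4) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}
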