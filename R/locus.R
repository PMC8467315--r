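#' The FibH repeat-motif catalogue
#'
#' The ten 11-mer repeat motifs of the fibroin heavy-chain gene core, with
#' their published copy numbers and total per-motif methylation frequencies
#' (sum of CpG-site methylation frequency over the motif's instances). Each
#' motif carries exactly one CG dinucleotide. `meth_prob`, the default
#' per-instance methylation probability used by the simulator, is the total
#' frequency divided by the copy number.
#'
#' @return data.frame with columns `name`, `sequence`, `copies`,
#'   `total_meth_freq`, `meth_prob`, `cg_offset` (0-based offset of the CG
#'   within the motif).
#' @export
fibh_motifs <- function() {
  m <- data.frame(
    name = paste0("motif-", 1:10),
    sequence = c("TGCTCCGTATC", "AGCACCGGCAC", "AGCTCCGCTTC", "ATATCCGCCAT",
                 "TACTCCGTATC", "TGAACCGGCAC", "AGCTCCGGCAC", "TGCTCCGTACC",
                 "AGAACCGGCAC", "AGTTCCGCTTC"),
    copies = c(145L, 92L, 65L, 11L, 10L, 9L, 8L, 8L, 3L, 3L),
    total_meth_freq = c(2.121, 1.782, 3.251, 0.267, 0.222, 0.123, 0.123,
                        0.166, 0.092, 0.438),
    stringsAsFactors = FALSE
  )
  m$meth_prob <- m$total_meth_freq / m$copies
  m$cg_offset <- vapply(m$sequence,
                        function(s) as.integer(regexpr("CG", s)) - 1L,
                        integer(1), USE.NAMES = FALSE)
  m
}

#' Blueprint for a FibH-like repetitive locus
#'
#' Describes a two-exon gene whose large second exon carries a GC-rich
#' repetitive core: `n_repetitive_domains` motif-dense domains separated by
#' `n_repetitive_domains - 1` amorphous (motif-free) spacers, flanked by
#' unique sequence, embedded centrally in a larger single-chromosome
#' background. Defaults emulate the silkworm FibH architecture: a 57-bp first
#' exon, a 971-bp intron, a 16,845-bp gene, twelve repetitive domains with
#' eleven amorphous regions, the ten-motif catalogue of [fibh_motifs()], and
#' a repetitive-core GC content of 0.59.
#'
#' @param n_repetitive_domains number of repetitive domains (default 12).
#' @param motif_mix data.frame as from [fibh_motifs()].
#' @param exon1_len,intron_len lengths of the short first exon and the intron
#'   preceding the repetitive exon (bp).
#' @param gene_len_target total gene length (bp); unique N-/C-terminal
#'   stretches of exon 2 are sized to reach it.
#' @param amorphous_len length of each amorphous spacer (bp). Must exceed the
#'   domain-segmentation window for the planted layout to be recoverable.
#' @param linker_range min/max length of the short random linkers between
#'   motif copies within a domain (bp).
#' @param core_gc target GC fraction of the repetitive core; non-motif filler
#'   GC is solved from the motif composition to hit it in expectation.
#' @param background_len,background_gc single-chromosome background size and
#'   GC (silkworm genome-wide GC is about 0.38).
#' @param bg_meth_prob methylation probability of CG sites outside motif
#'   instances.
#' @param guide_margin_down,guide_margin_up distance from the gene to the
#'   inner target boundary on each side (bp); defaults place the inner guide
#'   boundaries 17,962 bp apart around a 16,845-bp gene, as published.
#' @param guide_gap_down,guide_gap_up distance between the two boundary
#'   coordinates of each guide pair (bp); defaults 738 and 394, the published
#'   downstream/upstream region lengths.
#' @param chrom name of the synthetic chromosome.
#' @return object of class `locus_spec` (a named list).
#' @export
locus_spec <- function(n_repetitive_domains = 12,
                       motif_mix = fibh_motifs(),
                       exon1_len = 57,
                       intron_len = 971,
                       gene_len_target = 16845,
                       amorphous_len = 250,
                       linker_range = c(2, 8),
                       core_gc = 0.59,
                       background_len = 500000,
                       background_gc = 0.38,
                       bg_meth_prob = 0.01,
                       guide_margin_down = 600,
                       guide_margin_up = 516,
                       guide_gap_down = 738,
                       guide_gap_up = 394,
                       chrom = "chrSim") {
  stopifnot(n_repetitive_domains >= 1, nrow(motif_mix) >= 1,
            all(motif_mix$copies >= 0), all(motif_mix$meth_prob >= 0),
            all(motif_mix$meth_prob <= 1), amorphous_len >= 0,
            core_gc > 0, core_gc < 1)
  check_dna(motif_mix$sequence, "motif sequence")
  spec <- list(
    n_repetitive_domains = as.integer(n_repetitive_domains),
    n_amorphous = as.integer(n_repetitive_domains) - 1L,
    motif_mix = motif_mix,
    exon1_len = exon1_len, intron_len = intron_len,
    gene_len_target = gene_len_target,
    amorphous_len = amorphous_len, linker_range = linker_range,
    core_gc = core_gc,
    background_len = background_len, background_gc = background_gc,
    bg_meth_prob = bg_meth_prob,
    guide_margin_down = guide_margin_down, guide_margin_up = guide_margin_up,
    guide_gap_down = guide_gap_down, guide_gap_up = guide_gap_up,
    chrom = chrom
  )
  class(spec) <- "locus_spec"
  spec
}

random_dna <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

## Filler that never starts with G: most motifs end in C, and a G-leading
## linker/spacer would mint a junction CpG inside the preceding motif
## instance span, polluting the per-motif methylation bookkeeping.
random_filler <- function(n, gc) {
  s <- random_dna(n, gc)
  while (n > 0 && substring(s, 1, 1) == "G") s <- random_dna(n, gc)
  s
}

## Replace accidental (unplanted) motif occurrences by mutating one base that
## lies outside every protected interval. `protected` is a 2-column matrix of
## 0-based half-open intervals (planted instances, guide sites).
scrub_motifs <- function(seq, motifs, protected) {
  prot_mask <- function(pos) {
    if (nrow(protected) == 0L) return(rep(FALSE, length(pos)))
    hit <- rep(FALSE, length(pos))
    for (k in seq_len(nrow(protected))) {
      hit <- hit | (pos >= protected[k, 1] & pos < protected[k, 2])
    }
    hit
  }
  for (iter in 1:20) {
    extra <- NULL
    for (mseq in motifs) {
      pos <- match_iupac(seq, mseq)  # 0-based starts
      if (!length(pos)) next
      planted <- prot_mask(pos)
      extra <- c(extra, pos[!planted])
      pos <- pos[!planted]
      for (p in pos) {
        cand <- p:(p + nchar(mseq) - 1L)
        cand <- cand[!prot_mask(cand)]
        fixed <- FALSE
        for (ci in cand) {
          j <- ci - p + 1L  # 1-based offset within the occurrence window
          old <- substring(seq, ci + 1L, ci + 1L)
          prevc <- if (ci >= 1L) substring(seq, ci, ci) else ""
          nextc <- substring(seq, ci + 2L, ci + 2L)
          for (b in c("A", "T", "C", "G")) {
            ## the replacement must change the base, must not mint a CpG
            ## with a neighbor, and must not convert this window into a
            ## different catalogued motif (some motifs differ by one base)
            if (b == old) next
            if (b == "G" && prevc == "C") next
            if (b == "C" && nextc == "G") next
            w <- substring(seq, p + 1L, p + nchar(mseq))
            substring(w, j, j) <- b
            if (w %in% motifs) next
            substring(seq, ci + 1L, ci + 1L) <- b
            fixed <- TRUE
            break
          }
          if (fixed) break
        }
      }
    }
    if (is.null(extra) || !length(extra)) break
  }
  seq
}

#' Build a synthetic FibH-like locus with ground truth
#'
#' Realizes a [locus_spec()]: assembles the repetitive core (motif copies
#' distributed evenly over the domains, joined by short GC-matched linkers,
#' domains separated by motif-free amorphous spacers), pads it with unique
#' exonic/intronic sequence to the target gene length, embeds the gene at the
#' center of a random background chromosome, and plants the four published
#' Cas12a guide sites (two reverse-strand upstream of the gene, two
#' forward-strand downstream) so that each pair brackets its enrichment
#' region. Accidental motif occurrences created by random sequence are
#' removed by point mutation, so the emitted annotation is exact ground
#' truth.
#'
#' @param spec a [locus_spec()].
#' @param seed integer seed; the build is fully reproducible given
#'   `(spec, seed)`.
#' @return object of class `synthetic_locus`: a list with `genome` (named
#'   character), `guides` (guide table with planted coordinates and
#'   `cut_efficiency`), `motif_instances` (`name`, `chrom`, `start`, `end`,
#'   0-based half-open, `strand`), `domains` (planted `kind` R/A segments
#'   plus N-/C-terminal flanks, genome-frame 0-based half-open
#'   `start`/`end`), `cg_sites` (all genomic CG
#'   positions with per-site `meth_prob` and covering `motif`), `regions`
#'   (downstream/target/upstream, 1-based inclusive), `gene` (`start`, `end`,
#'   0-based half-open), `core` (likewise), `spec`, `seed`.
#' @export
build_synthetic_locus <- function(spec = locus_spec(), seed = 1) {
  stopifnot(inherits(spec, "locus_spec"))
  with_seed(seed, build_locus_impl(spec, seed))
}

build_locus_impl <- function(spec, seed) {
  mm <- spec$motif_mix
  nd <- spec$n_repetitive_domains
  mlen <- nchar(mm$sequence)

  ## solve the filler (linker + amorphous) GC so the expected core GC hits
  ## spec$core_gc given the motif composition
  n_copies <- sum(mm$copies)
  motif_bases <- sum(mm$copies * mlen)
  motif_gc_bases <- sum(mm$copies * vapply(
    mm$sequence, function(s) nchar(gsub("[AT]", "", s)), numeric(1)))
  mean_linker <- mean(spec$linker_range)
  linker_bases <- (n_copies - nd) * mean_linker  # one fewer linker than copies per domain
  amorph_bases <- spec$n_amorphous * spec$amorphous_len
  filler <- linker_bases + amorph_bases
  filler_gc <- (spec$core_gc * (motif_bases + filler) - motif_gc_bases) / filler
  if (filler_gc < 0 || filler_gc > 1) {
    stop("core_gc unreachable with this motif mix; got filler GC ", filler_gc)
  }

  ## assign motif copies to domains: each motif spread as evenly as possible,
  ## staggered so low-copy motifs do not pile into the first domains
  assign <- unlist(lapply(seq_len(nrow(mm)), function(i) {
    if (mm$copies[i] == 0L) return(integer())
    ((seq_len(mm$copies[i]) - 1L + i) %% nd) + 1L
  }))
  motif_of <- rep(seq_len(nrow(mm)), mm$copies)

  ## build each domain: shuffled motif copies joined by short linkers
  domains <- vector("list", nd)
  inst <- list()
  for (d in seq_len(nd)) {
    ids <- motif_of[assign == d]
    ids <- ids[sample.int(length(ids))]
    if (!length(ids)) stop("domain ", d, " received no motif copies")
    parts <- character(2L * length(ids) - 1L)
    offs <- integer(length(ids))
    cur <- 0L
    for (j in seq_along(ids)) {
      if (j > 1L) {
        ln <- sample(spec$linker_range[1]:spec$linker_range[2], 1)
        parts[2L * j - 2L] <- random_filler(ln, filler_gc)
        cur <- cur + ln
      }
      parts[2L * j - 1L] <- mm$sequence[ids[j]]
      offs[j] <- cur
      cur <- cur + mlen[ids[j]]
    }
    domains[[d]] <- paste(parts, collapse = "")
    inst[[d]] <- data.frame(motif = ids, offset = offs, domain = d)
  }

  ## core = D1 A1 D2 ... D12; record domain segment offsets
  dom_len <- nchar(unlist(domains))
  seg_kind <- rep(c("R", "A"), length.out = 2L * nd - 1L)
  seg_len <- ifelse(seg_kind == "R", dom_len[cumsum(seg_kind == "R")],
                    spec$amorphous_len)
  seg_start <- cumsum(c(0L, seg_len[-length(seg_len)]))
  core_parts <- character(length(seg_kind))
  core_parts[seg_kind == "R"] <- unlist(domains)
  core_parts[seg_kind == "A"] <- vapply(
    seq_len(spec$n_amorphous), function(i) random_filler(spec$amorphous_len, filler_gc),
    character(1))
  core <- paste(core_parts, collapse = "")
  core_len <- nchar(core)

  ## gene = exon1 | intron | N-terminal unique | core | C-terminal unique
  head_len <- spec$exon1_len + spec$intron_len
  pad <- spec$gene_len_target - head_len - core_len
  if (pad < 2) {
    stop("gene_len_target too small for core (", core_len,
         " bp) plus exon1/intron")
  }
  nterm <- floor(pad / 2)
  cterm <- pad - nterm
  unique_gc <- 0.45  # non-repetitive coding/intron sequence, moderate GC
  gene <- paste0(random_dna(head_len, unique_gc), random_dna(nterm, unique_gc),
                 core, random_filler(cterm, unique_gc))
  gene_len <- nchar(gene)
  core_off <- head_len + nterm  # gene-relative core start

  ## embed at the center of the background chromosome
  G <- spec$background_len
  gene_start <- floor((G - gene_len) / 2)
  bg <- random_dna(G, spec$background_gc)
  genome_seq <- paste0(substring(bg, 1, gene_start), gene,
                       substring(bg, gene_start + gene_len + 1, G))

  ## plant the four guide sites around the published target-region geometry
  target_start0 <- gene_start - spec$guide_margin_down       # 0-based
  target_end0 <- gene_start + gene_len + spec$guide_margin_up
  pg <- fibh_guides()
  site_seq <- ifelse(pg$strand == "+", paste0(pg$pam, pg$protospacer),
                     revcomp(paste0(pg$pam, pg$protospacer)))
  site_len <- nchar(site_seq)
  ## 0-based site starts: boundary coordinate = min printed coordinate
  site_start0 <- c(
    target_end0 + spec$guide_gap_up,   # FibH-up 1 (outer, reverse)
    target_end0,                       # FibH-up 2 (inner, reverse)
    target_start0,                     # FibH-down 1 (inner, forward)
    target_start0 - spec$guide_gap_down # FibH-down 2 (outer, forward)
  )
  for (i in 1:4) {
    substring(genome_seq, site_start0[i] + 1L,
              site_start0[i] + site_len[i]) <- site_seq[i]
  }
  guides <- pg
  guides$chrom <- spec$chrom
  guides$start <- ifelse(pg$strand == "+", site_start0 + 1L,
                         site_start0 + site_len)
  guides$end <- ifelse(pg$strand == "+", site_start0 + site_len,
                       site_start0 + 1L)

  ## motif instance coordinates (0-based half-open, genome frame)
  instances <- do.call(rbind, inst)
  rep_starts <- seg_start[seg_kind == "R"]
  inst_start <- gene_start + core_off + rep_starts[instances$domain] +
    instances$offset
  motif_instances <- data.frame(
    name = mm$name[instances$motif],
    chrom = spec$chrom,
    start = inst_start,
    end = inst_start + mlen[instances$motif],
    strand = "+",
    stringsAsFactors = FALSE
  )
  motif_instances <- motif_instances[order(motif_instances$start), ]
  rownames(motif_instances) <- NULL

  ## remove accidental motif copies from random sequence (point mutations
  ## outside planted instances and guide sites)
  protected <- rbind(
    cbind(motif_instances$start, motif_instances$end),
    cbind(site_start0, site_start0 + site_len)
  )
  genome_seq <- scrub_motifs(genome_seq, unique(mm$sequence), protected)

  ## planted domain layout (genome frame) + terminal flanks of the gene
  seg <- data.frame(
    kind = seg_kind,
    start = gene_start + core_off + seg_start,
    end = gene_start + core_off + seg_start + seg_len,
    stringsAsFactors = FALSE
  )
  domains_df <- rbind(
    data.frame(kind = "N-terminal", start = gene_start,
               end = seg$start[1], stringsAsFactors = FALSE),
    seg,
    data.frame(kind = "C-terminal", start = seg$end[nrow(seg)],
               end = gene_start + gene_len, stringsAsFactors = FALSE)
  )
  domains_df <- cbind(chrom = spec$chrom, domains_df)
  rownames(domains_df) <- NULL

  ## all genomic CG sites with their methylation probability
  cg_pos <- match_iupac(genome_seq, "CG")
  cg_motif <- rep(NA_character_, length(cg_pos))
  cg_prob <- rep(spec$bg_meth_prob, length(cg_pos))
  mi_cg <- motif_instances$start +
    mm$cg_offset[match(motif_instances$name, mm$name)]
  hit <- match(mi_cg, cg_pos)
  if (anyNA(hit)) stop("internal: planted motif CG missing from genome scan")
  cg_motif[hit] <- motif_instances$name
  cg_prob[hit] <- mm$meth_prob[match(motif_instances$name, mm$name)]
  cg_sites <- data.frame(
    chrom = spec$chrom, position = cg_pos, motif = cg_motif,
    meth_prob = cg_prob, stringsAsFactors = FALSE
  )

  regions <- define_enrichment_regions(guides[1:2, ], guides[3:4, ],
                                       target_label = "gene-target")

  structure(list(
    genome = setNames(genome_seq, spec$chrom),
    guides = guides,
    motif_instances = motif_instances,
    domains = domains_df,
    cg_sites = cg_sites,
    regions = regions,
    gene = c(start = gene_start, end = gene_start + gene_len),
    core = c(start = gene_start + core_off,
             end = gene_start + core_off + core_len),
    spec = spec,
    seed = seed
  ), class = "synthetic_locus")
}

#' GC fraction of a sequence interval
#'
#' @param genome named character vector (or `synthetic_locus`).
#' @param start,end 0-based half-open interval; defaults to the whole contig.
#' @param chrom contig name (first contig by default).
#' @return GC fraction in `[0, 1]`.
#' @export
gc_fraction <- function(genome, start = NULL, end = NULL, chrom = NULL) {
  if (inherits(genome, "synthetic_locus")) genome <- genome$genome
  genome <- as_genome(genome)
  chrom <- chrom %||% names(genome)[1]
  s <- genome[[chrom]]
  start <- start %||% 0L
  end <- end %||% nchar(s)
  sub <- substring(s, start + 1L, end)
  nchar(gsub("[AT]", "", sub)) / nchar(sub)
}

#' @export
print.synthetic_locus <- function(x, ...) {
  cat("Synthetic repetitive locus on", names(x$genome), "(",
      nchar(x$genome[[1]]), "bp background )\n")
  cat("  gene:", x$gene["start"], "-", x$gene["end"],
      sprintf("(%d bp)", x$gene["end"] - x$gene["start"]), "\n")
  nR <- sum(x$domains$kind == "R")
  cat("  repetitive core:", x$core["start"], "-", x$core["end"], "with", nR,
      "repetitive domains /", sum(x$domains$kind == "A"),
      "amorphous regions\n")
  cat("  motif instances:", nrow(x$motif_instances), " CG sites:",
      nrow(x$cg_sites), "\n")
  cat("  guides:", paste(x$guides$name, collapse = ", "), "\n")
  invisible(x)
}
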