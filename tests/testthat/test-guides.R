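test_that("gc_percent matches published guide metrics and degenerate cases", {
  expect_equal(gc_percent("TGTTACCGGGGTCTAGTGAC"), 55L)
  expect_equal(gc_percent("TATGAACCTATTGTAATTTAG"), 24L)
  expect_equal(gc_percent(c("AAAA", "GCGC")), c(0L, 100L))
  expect_error(gc_percent("ACGN"), "non-ACGT")
  expect_error(gc_percent(""), "non-empty")
})

test_that("gc and at percentages are complementary", {
  set.seed(3)
  for (i in 1:20) {
    s <- random_seq(sample(5:40, 1), gc = runif(1, 0.2, 0.8))
    gc_exact <- 100 * nchar(gsub("[AT]", "", s)) / nchar(s)
    expect_equal(gc_exact + at_percent(s), 100)
  }
})

test_that("scan_pams finds the single constructed site on each strand", {
  g <- "AAATTTACCCCCCCCCCCCCCCCCCCCCAAA"
  cand <- scan_pams(c(chrX = g), "TTTV", spacer_len = 20)
  fwd <- cand[cand$strand == "+", ]
  expect_true(sum(fwd$protospacer == strrep("C", 20)) == 1L)
  expect_equal(fwd$pam[fwd$protospacer == strrep("C", 20)], "TTTA")
  rc <- scan_pams(c(chrX = oracle_revcomp(g)), "TTTV", spacer_len = 20)
  rev_hits <- rc[rc$strand == "-" & rc$protospacer == strrep("C", 20), ]
  expect_equal(nrow(rev_hits), 1L)
})

test_that("scan_pams printed coordinates span PAM plus protospacer", {
  set.seed(7)
  g <- c(chr1 = random_seq(3000))
  cand <- scan_pams(g, "TTTV", spacer_len = 21)
  expect_true(all(abs(cand$end - cand$start) + 1L == cand$size + 4L))
  expect_true(all(cand$start[cand$strand == "-"] >
                    cand$end[cand$strand == "-"]))
  ## every reported protospacer is the genomic sequence 3' of its PAM
  for (i in sample(nrow(cand), 10)) {
    row <- cand[i, ]
    lo <- min(row$start, row$end); hi <- max(row$start, row$end)
    site <- substring(g[[1]], lo, hi)
    if (row$strand == "-") site <- oracle_revcomp(site)
    expect_equal(site, paste0(row$pam, row$protospacer))
  }
})

test_that("scan_pams agrees with a brute-force scan of both strands", {
  set.seed(19)
  g <- random_seq(10000)
  cand <- scan_pams(c(chr1 = g), "TTTV", spacer_len = 21)
  oracle <- oracle_scan(g, "TTTV", 21)
  key <- function(d) sort(paste(d$strand, d$start, d$end, d$protospacer))
  expect_equal(key(cand), key(oracle))
})

test_that("off-target census counts planted mismatch copies", {
  set.seed(5)
  bg <- random_seq(6000, gc = 0.5)
  proto <- "GACTGACTGACTGACTGACAC"
  site <- paste0("TTTA", proto)
  ## genome with the guide site planted once
  g1 <- paste0(substring(bg, 1, 2000), site, substring(bg, 2001, 6000))
  own <- list(protospacer = proto, chrom = "chr1", strand = "+",
              start = 2001L)
  cen <- count_offtargets(own, c(chr1 = g1))
  expect_equal(unname(cen), unname(oracle_offtargets(proto, g1, own = list(
    strand = "+", start = 2001L))))
  expect_equal(cen[["mm0"]], 0L)
  ## plant a copy with exactly 3 protospacer mismatches -> census 0 0 0 1
  mut <- proto
  substring(mut, 3, 3) <- "T"; substring(mut, 10, 10) <- "T"
  substring(mut, 17, 17) <- "A"
  g2 <- paste0(g1, "TTTG", mut, substring(bg, 1, 100))
  cen2 <- count_offtargets(own, c(chr1 = g2))
  expect_equal(unname(cen2), c(0L, 0L, 0L, 1L))
})

test_that("off-target census equals the brute-force oracle on random guides", {
  set.seed(23)
  g <- random_seq(20000)
  cand <- scan_pams(c(chr1 = g), "TTTV", spacer_len = 21)
  pick <- cand[sample(nrow(cand), 8), ]
  for (i in seq_len(nrow(pick))) {
    guide <- pick[i, ]
    cen <- count_offtargets(guide, c(chr1 = g))
    oracle <- oracle_offtargets(guide$protospacer, g,
                                own = list(strand = guide$strand,
                                           start = guide$start))
    expect_equal(unname(cen), unname(oracle))
  }
})

test_that("degenerate-PAM flag widens the census monotonically", {
  set.seed(31)
  g <- random_seq(20000)
  cand <- scan_pams(c(chr1 = g), "TTTV", spacer_len = 21)
  guide <- cand[1, ]
  strict <- count_offtargets(guide, c(chr1 = g))
  loose <- count_offtargets(guide, c(chr1 = g), degenerate_pam = TRUE)
  expect_true(all(loose >= strict))
})

test_that("published guide pairs reproduce the published regions", {
  g <- fibh_guides()
  reg <- define_enrichment_regions(g[1:2, ], g[3:4, ],
                                   target_label = "KWMTBOMO15365")
  expect_equal(reg$start, c(10353778L, 10354516L, 10372477L))
  expect_equal(reg$end, c(10354516L, 10372477L, 10372871L))
  expect_equal(reg$label, c("downstream", "KWMTBOMO15365", "upstream"))
})

test_that("region derivation tiles the locus between the outer guides", {
  toy_guide <- function(chrom, start, end) {
    data.frame(chrom = chrom, start = start, end = end)
  }
  up <- rbind(toy_guide("c", 1020, 1000), toy_guide("c", 1520, 1500))
  dn <- rbind(toy_guide("c", 5000, 5020), toy_guide("c", 5400, 5420))
  reg <- define_enrichment_regions(up, dn)
  expect_equal(reg$label, c("upstream", "target", "downstream"))
  expect_equal(reg$start, c(1000, 1500, 5000))
  expect_equal(reg$end, c(1500, 5000, 5400))
  ## randomized placements: three regions always tile without gaps
  set.seed(13)
  for (i in 1:25) {
    b <- sort(sample.int(100000, 4))
    up <- rbind(toy_guide("c", b[3] + 20, b[3]), toy_guide("c", b[4] + 20, b[4]))
    dn <- rbind(toy_guide("c", b[1], b[1] + 20), toy_guide("c", b[2], b[2] + 20))
    reg <- define_enrichment_regions(up, dn)
    reg <- reg[order(reg$start), ]
    expect_equal(reg$start[-1], reg$end[-3])
    expect_equal(reg$start[1], b[1])
    expect_equal(reg$end[3], b[4])
  }
})

test_that("region derivation rejects invalid guide geometry", {
  g <- fibh_guides()
  g2 <- g; g2$chrom[1] <- "other"
  expect_error(define_enrichment_regions(g2[1:2, ], g2[3:4, ]),
               "different chromosomes")
  expect_error(define_enrichment_regions(g[1:2, ], g[1:2, ]), "overlap")
})
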