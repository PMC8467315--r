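test_that("locus realizes its blueprint: domains, motif copies, CG truth", {
  loc <- small_locus()
  spec <- loc$spec
  core_dom <- loc$domains[loc$domains$kind %in% c("R", "A"), ]
  expect_equal(nrow(core_dom), 2L * spec$n_repetitive_domains - 1L)  # 23
  expect_equal(rle(core_dom$kind)$values, core_dom$kind)  # strict alternation
  expect_equal(sum(core_dom$kind == "R"), 12L)
  expect_equal(sum(core_dom$kind == "A"), 11L)
  ## census of the emitted sequence returns the spec copy numbers
  cm <- count_motifs(loc, spec$motif_mix)
  expect_equal(cm$counts$count, spec$motif_mix$copies)
  ## and the annotated instances are exactly what the census finds
  expect_equal(loc$motif_instances$start, cm$instances$start)
  ## every motif instance contains exactly one CG, at the annotated position
  mm <- spec$motif_mix
  inst_cg <- loc$motif_instances$start +
    mm$cg_offset[match(loc$motif_instances$name, mm$name)]
  expect_true(all(inst_cg %in% loc$cg_sites$position))
  ## annotation indexes the FASTA correctly
  g <- loc$genome[[1]]
  picks <- loc$motif_instances[seq(1, nrow(loc$motif_instances), by = 40), ]
  expect_equal(substring(g, picks$start + 1, picks$end),
               mm$sequence[match(picks$name, mm$name)])
  cg_picks <- loc$cg_sites$position[seq(1, nrow(loc$cg_sites), by = 500)]
  expect_true(all(substring(g, cg_picks + 1, cg_picks + 2) == "CG"))
})

test_that("locus gene length and core GC meet the blueprint", {
  loc <- default_locus()
  expect_equal(unname(loc$gene["end"] - loc$gene["start"]),
               loc$spec$gene_len_target)
  gc <- gc_fraction(loc, loc$core["start"], loc$core["end"])
  expect_gt(gc, 0.56)
  expect_lt(gc, 0.62)
  ## planted guide sites carry valid PAM + protospacer at their coordinates
  g <- loc$genome[[1]]
  for (i in 1:4) {
    row <- loc$guides[i, ]
    lo <- min(row$start, row$end); hi <- max(row$start, row$end)
    site <- substring(g, lo, hi)
    if (row$strand == "-") site <- oracle_revcomp(site)
    expect_equal(site, paste0(row$pam, row$protospacer))
  }
})

test_that("locus build is deterministic given (spec, seed)", {
  spec <- locus_spec(background_len = 40000)
  a <- build_synthetic_locus(spec, seed = 5)
  b <- build_synthetic_locus(spec, seed = 5)
  expect_identical(a, b)
  c <- build_synthetic_locus(spec, seed = 6)
  expect_false(identical(a$genome, c$genome))
})

test_that("locus rejects an over-stuffed blueprint", {
  mm <- fibh_motifs()
  mm$copies <- mm$copies * 10L
  expect_error(build_synthetic_locus(locus_spec(motif_mix = mm), seed = 1),
               "gene_len_target too small")
})

test_that("with full dephosphorylation every read starts or ends at a cut", {
  loc <- small_locus()
  p <- protocol_params(dephos_efficiency = 1, background_end_rate = 0,
                       n_molecules = 60)
  p$seed <- NULL
  loc2 <- loc
  loc2$guides$cut_efficiency <- 1
  sim <- simulate_protocol(loc2, p, seed = 3)
  cuts <- ceoseq:::guide_cut_coords(loc2$guides, p$cut_offsets)
  cutcoords <- c(cuts$c1, cuts$c2)
  expect_gt(nrow(sim$reads), 0)
  expect_true(all(sim$reads$start %in% cutcoords |
                    sim$reads$end %in% cutcoords))
})

test_that("no cuts and no background ends yields an empty read set", {
  loc <- small_locus()
  loc$guides$cut_efficiency <- 0
  p <- protocol_params(dephos_efficiency = 1, background_end_rate = 0,
                       n_molecules = 10)
  expect_warning(sim <- simulate_protocol(loc, p, seed = 3), "no ligatable")
  expect_equal(nrow(sim$reads), 0L)
})

test_that("simulation is seed-deterministic and reads map 1:1 to truth", {
  loc <- small_locus()
  p <- protocol_params(n_molecules = 40)
  a <- simulate_protocol(loc, p, seed = 9)
  b <- simulate_protocol(loc, p, seed = 9)
  expect_identical(a, b)
  expect_false(identical(
    a$reads, simulate_protocol(loc, p, seed = 10)$reads))
  ## read ids unique; alignments mirror reads; sequence length == interval
  expect_equal(anyDuplicated(a$reads$read_id), 0L)
  expect_equal(a$alignments$read_id, a$reads$read_id)
  expect_equal(nchar(a$reads$sequence), a$reads$end - a$reads$start)
  ## truth sequence round-trips through the genome (reverse reads revcomp'd)
  i <- which(a$reads$strand == "+")[1]
  j <- which(a$reads$strand == "-")[1]
  g <- loc$genome[[1]]
  expect_equal(a$reads$sequence[i],
               substring(g, a$reads$start[i] + 1, a$reads$end[i]))
  expect_equal(a$reads$sequence[j],
               oracle_revcomp(substring(g, a$reads$start[j] + 1,
                                        a$reads$end[j])))
})

test_that("methylation calls honor per-site probabilities at the extremes", {
  loc <- small_locus()
  loc$cg_sites$meth_prob[!is.na(loc$cg_sites$motif) &
                           loc$cg_sites$motif == "motif-1"] <- 1
  loc$cg_sites$meth_prob[is.na(loc$cg_sites$motif)] <- 0
  p <- protocol_params(meth_caller_error = 0, n_molecules = 120)
  sim <- simulate_protocol(loc, p, seed = 21)
  m1_pos <- loc$cg_sites$position[!is.na(loc$cg_sites$motif) &
                                    loc$cg_sites$motif == "motif-1"]
  bg_pos <- loc$cg_sites$position[is.na(loc$cg_sites$motif)]
  calls_m1 <- sim$calls$call[sim$calls$position %in% m1_pos]
  calls_bg <- sim$calls$call[sim$calls$position %in% bg_pos]
  expect_gt(length(calls_m1), 50)
  expect_true(all(calls_m1 == 1L))
  expect_true(all(calls_bg == 0L))
  ## every call lies inside its read's truth interval
  idx <- match(sim$calls$read_id, sim$alignments$read_id)
  expect_true(all(sim$calls$position >= sim$alignments$start[idx] &
                    sim$calls$position + 2 <= sim$alignments$end[idx]))
})

test_that("empirical enrichment fold is monotone in cut efficiency and dephosphorylation", {
  loc <- default_locus()
  cl <- setNames(nchar(loc$genome), names(loc$genome))
  tg <- loc$regions[grepl("target", loc$regions$label), ]
  ## short-fragment regime keeps background coverage visible, so the fold
  ## responds to both knobs instead of saturating
  fold_at <- function(cut_scale, dephos, seeds) {
    loc2 <- loc
    loc2$guides$cut_efficiency <- loc$guides$cut_efficiency * cut_scale
    p <- protocol_params(n_molecules = 120, dephos_efficiency = dephos,
                         fragment_len_range = c(5000, 20000))
    mean(vapply(seeds, function(s) {
      sim <- simulate_protocol(loc2, p, seed = s)
      prof <- depth_profile(sim$alignments, cl)
      region_mean_depth(prof, tg) / genome_mean_depth(sim$alignments, cl)
    }, numeric(1)))
  }
  f_cut <- vapply(c(0.1, 0.5, 1), fold_at, numeric(1), dephos = 0.9,
                  seeds = 1:4)
  expect_true(all(diff(f_cut) > 0))
  f_dep <- vapply(c(0.3, 0.7, 0.95), function(d) fold_at(1, d, seeds = 5:8),
                  numeric(1))
  expect_true(all(diff(f_dep) > 0))
})

test_that("per-site methylation recovery at deep coverage matches assigned probabilities", {
  ## spanning-read regime, no caller error: empirical per-site frequency
  ## within the binomial 99% CI of the assigned probability
  loc <- default_locus()
  p <- protocol_params(n_molecules = 250, reads_per_ligatable_end = 0.3,
                       read_len_meanlog = 9.9, read_len_sdlog = 0.3,
                       meth_caller_error = 0)
  sim <- simulate_protocol(loc, p, seed = 77)
  sites <- site_frequencies(sim$calls)
  key <- match(paste(loc$cg_sites$chrom, loc$cg_sites$position),
               paste(sites$chrom, sites$position))
  motif1 <- !is.na(loc$cg_sites$motif) & loc$cg_sites$motif == "motif-1" &
    !is.na(key)
  got <- sites[key[motif1], ]
  expect_gt(min(got$called_sites), 50)
  p0 <- fibh_motifs()$meth_prob[1]
  ci <- 2.576 * sqrt(p0 * (1 - p0) / got$called_sites)
  expect_true(mean(abs(got$frequency - p0) <= ci) > 0.95)
  ## pooled across motif-1 instances the estimate is tight
  pooled <- sum(got$called_sites_methylated) / sum(got$called_sites)
  expect_lt(abs(pooled - p0),
            2.576 * sqrt(p0 * (1 - p0) / sum(got$called_sites)))
})
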