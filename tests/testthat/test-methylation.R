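mk_calls <- function(position, call, read = NULL, chrom = "c1") {
  data.frame(chrom = chrom, position = position,
             read_id = read %||% sprintf("r%03d", seq_along(position)),
             call = call, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("site frequencies follow called_methylated / called", {
  calls <- mk_calls(rep(100L, 10), c(rep(1L, 5), rep(0L, 5)))
  s <- site_frequencies(calls)
  expect_equal(s$called_sites, 10L)
  expect_equal(s$called_sites_methylated, 5L)
  expect_equal(s$frequency, 0.5)
  all0 <- site_frequencies(mk_calls(rep(7L, 8), rep(0L, 8)))
  expect_equal(all0$frequency, 0)
  all1 <- site_frequencies(mk_calls(rep(7L, 8), rep(1L, 8)))
  expect_equal(all1$frequency, 1)
})

test_that("duplicate read/site calls are rejected", {
  calls <- mk_calls(c(5L, 5L), c(1L, 0L), read = c("r1", "r1"))
  expect_error(site_frequencies(calls), "duplicate")
})

test_that("per-motif frequency is a sum over instance site frequencies", {
  inst <- data.frame(name = "motif-X", chrom = "c1",
                     start = c(100L, 200L, 300L), end = c(111L, 211L, 311L))
  sites <- data.frame(chrom = "c1", position = c(105L, 205L, 305L),
                      called_sites = 10L, called_sites_methylated = c(1L, 2L, 3L),
                      frequency = c(0.1, 0.2, 0.3))
  out <- motif_frequencies(sites, inst)
  expect_equal(out$repetition, 3L)
  expect_equal(out$methylation_frequency, 0.6)
  ## an uncalled instance contributes zero
  out2 <- motif_frequencies(sites[1:2, ], inst)
  expect_equal(out2$methylation_frequency, 0.3)
  expect_equal(out2$repetition, 3L)
  ## call-order invariance
  out3 <- motif_frequencies(sites[c(3, 1, 2), ], inst)
  expect_equal(out3$methylation_frequency, 0.6)
})

test_that("per-motif sums equal hand-summed site frequencies on a 20-call fixture", {
  ## two motifs, three instances, 20 per-read calls laid out by hand
  inst <- data.frame(name = c("mA", "mA", "mB"), chrom = "c1",
                     start = c(0L, 20L, 40L), end = c(11L, 31L, 51L))
  calls <- rbind(
    mk_calls(rep(5L, 8), c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),
             read = sprintf("a%d", 1:8)),        # site 5: 2/8
    mk_calls(rep(25L, 7), c(1L, 0L, 0L, 0L, 0L, 0L, 0L),
             read = sprintf("b%d", 1:7)),        # site 25: 1/7
    mk_calls(rep(45L, 5), c(1L, 1L, 1L, 0L, 0L),
             read = sprintf("c%d", 1:5))         # site 45: 3/5
  )
  expect_equal(nrow(calls), 20L)
  sites <- site_frequencies(calls)
  out <- motif_frequencies(sites, inst)
  expect_equal(out$methylation_frequency[out$motif_name == "mA"],
               2 / 8 + 1 / 7)
  expect_equal(out$methylation_frequency[out$motif_name == "mB"], 3 / 5)
  expect_equal(out$repetition, c(2L, 1L))
})

test_that("overlapping instances are an error, sites outside instances are ignored", {
  inst <- data.frame(name = c("m", "m"), chrom = "c1",
                     start = c(0L, 5L), end = c(11L, 16L))
  sites <- data.frame(chrom = "c1", position = 3L, called_sites = 1L,
                      called_sites_methylated = 1L, frequency = 1)
  expect_error(motif_frequencies(sites, inst), "overlap")
  inst_ok <- data.frame(name = "m", chrom = "c1", start = 100L, end = 111L)
  out <- motif_frequencies(sites, inst_ok)
  expect_equal(out$methylation_frequency, 0)
})

test_that("motif frequency sum never exceeds total site frequency mass", {
  loc <- small_locus()
  p <- protocol_params(n_molecules = 60, meth_caller_error = 0)
  sim <- simulate_protocol(loc, p, seed = 31)
  sites <- site_frequencies(sim$calls)
  out <- motif_frequencies(sites, loc$motif_instances,
                           motifs = loc$spec$motif_mix)
  expect_lte(sum(out$methylation_frequency), sum(sites$frequency))
  expect_true(all(out$methylation_frequency <= out$repetition))
  expect_equal(out$repetition, loc$spec$motif_mix$copies)
})

test_that("methylated-site counting applies the frequency threshold", {
  sites <- data.frame(chrom = "c1", position = 1:3, called_sites = 10L,
                      called_sites_methylated = c(0L, 1L, 5L),
                      frequency = c(0, 0.1, 0.5))
  expect_equal(count_methylated_sites(sites), 2L)
  expect_equal(count_methylated_sites(sites[sites$frequency == 0, ]), 0L)
  expect_equal(count_methylated_sites(sites, min_frequency = 0.3), 1L)
  expect_error(count_methylated_sites(sites, min_frequency = 2), "min_frequency")
})

test_that("nanopolish-style frequency tables are accepted directly", {
  tab <- data.frame(chromosome = "c1", start = c(10L, 20L), end = c(11L, 21L),
                    num_motifs = 1L, called_sites = c(20L, 10L),
                    called_sites_methylated = c(5L, 0L),
                    methylated_frequency = c(0.25, 0))
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sites <- read_nanopolish_frequency(path)
  expect_equal(sites$frequency, c(0.25, 0))
  expect_equal(count_methylated_sites(sites), 1L)
  expect_error(read_nanopolish_frequency({
    p2 <- tempfile(); writeLines("a\tb", p2); p2
  }), "methylation-frequency")
})
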