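#' Assemble and validate a pipeline configuration
#'
#' One structured configuration drives the whole pipeline. Unknown keys in
#' any section are rejected.
#'
#' @param seed integer seed for every stochastic stage.
#' @param outdir output directory; `NULL` keeps everything in memory.
#' @param locus named list of [locus_spec()] overrides.
#' @param protocol named list of [protocol_params()] overrides.
#' @param min_q read-quality filter threshold (default 7).
#' @param min_len long-read tally threshold, bp (default 16000).
#' @param window,density_threshold,merge_gap domain-segmentation parameters
#'   (see [segment_domains()]).
#' @param min_frequency optional methylated-site threshold (see
#'   [count_methylated_sites()]).
#' @return validated list of class `ceo_config`.
#' @export
ceo_config <- function(seed = 1, outdir = NULL, locus = list(),
                       protocol = list(), min_q = 7, min_len = 16000,
                       window = 200, density_threshold = 0.5,
                       merge_gap = 50, min_frequency = NULL) {
  check_keys <- function(given, allowed, where) {
    extra <- setdiff(names(given), allowed)
    if (length(extra)) {
      stop("unknown ", where, " key(s): ", paste(extra, collapse = ", "))
    }
  }
  check_keys(locus, names(formals(locus_spec)), "locus")
  check_keys(protocol, names(formals(protocol_params)), "protocol")
  cfg <- list(seed = as.integer(seed), outdir = outdir, locus = locus,
              protocol = protocol, min_q = min_q, min_len = min_len,
              window = window, density_threshold = density_threshold,
              merge_gap = merge_gap, min_frequency = min_frequency)
  class(cfg) <- "ceo_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [ceo_config()] arguments.
#' @return validated `ceo_config`.
#' @export
read_ceo_config <- function(path) {
  do.call(ceo_config, yaml::read_yaml(path))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes simulate, design-verify, quantify, census, and methylation in
#' order over a synthetic locus, and returns a consolidated report with the
#' guide-, enrichment-, and motif-table outputs. With `outdir` set, every
#' intermediate file is written together with a manifest (parameters, seed,
#' md5 checksums).
#'
#' @param config a [ceo_config()].
#' @return list of class `ceo_report`: `locus`, `sim` (alignments/calls
#'   kept, sequences dropped), `guides` (verified guide table),
#'   `regions` (enrichment table), `census` (motif counts), `domains`
#'   (segmentation), `methylation` (per-motif table), `site_frequencies`,
#'   `n_methylated_sites`, `read_accounting`, `config`.
#' @export
run_all <- function(config = ceo_config()) {
  stopifnot(inherits(config, "ceo_config"))
  spec <- run_stage("configure", do.call(locus_spec, config$locus))
  params <- run_stage("configure", do.call(protocol_params, config$protocol))

  locus <- run_stage("simulate",
                     build_synthetic_locus(spec, seed = config$seed))
  sim <- run_stage("simulate",
                   simulate_protocol(locus, params, seed = config$seed + 1L))
  chrom_lengths <- setNames(nchar(locus$genome), names(locus$genome))

  ## design-verify: recompute GC and the off-target census for each planted
  ## guide on the synthetic genome
  guides <- run_stage("design", {
    g <- locus$guides
    g$gc_percent <- gc_percent(g$protospacer)
    cen <- t(vapply(seq_len(nrow(g)), function(i) {
      count_offtargets(g[i, ], locus$genome)
    }, integer(4)))
    g[, c("mm0", "mm1", "mm2", "mm3")] <- cen
    g
  })

  quant <- run_stage("quantify", {
    kept <- filter_reads(sim$alignments, config$min_q)
    tab <- region_depth_table(kept, locus$regions, chrom_lengths,
                              min_q = NULL)
    target <- locus$regions[grepl("target", locus$regions$label), ]
    list(table = tab,
         genome_depth = attr(tab, "genome_depth"),
         genome_depth_unfiltered = genome_mean_depth(sim$alignments,
                                                     chrom_lengths),
         long_reads = long_read_tally(kept, target, config$min_len),
         accounting = c(reads_total = nrow(sim$alignments),
                        reads_pass_q = nrow(kept)))
  })

  census <- run_stage("census", {
    cm <- count_motifs(locus$genome[[1]], spec$motif_mix,
                       chrom = names(locus$genome))
    gene0 <- locus$gene["start"]
    gi <- cm$instances[cm$instances$start >= gene0 &
                         cm$instances$end <= locus$gene["end"], ]
    gi$start <- gi$start - gene0
    gi$end <- gi$end - gene0
    dom <- segment_domains(gi, locus$gene["end"] - gene0,
                           window = config$window,
                           density_threshold = config$density_threshold,
                           merge_gap = config$merge_gap)
    dom$start <- dom$start + gene0
    dom$end <- dom$end + gene0
    list(counts = cm$counts, instances = cm$instances, domains = dom)
  })

  meth <- run_stage("methylation", {
    if (is.null(sim$calls)) return(NULL)
    sites <- site_frequencies(sim$calls)
    list(sites = sites,
         motifs = motif_frequencies(sites, census$instances,
                                    motifs = spec$motif_mix),
         n_methylated = count_methylated_sites(sites, config$min_frequency))
  })

  report <- structure(list(
    locus = locus, sim = sim[c("alignments", "calls", "seed")],
    guides = guides,
    regions = quant$table, genome_depth = quant$genome_depth,
    genome_depth_unfiltered = quant$genome_depth_unfiltered,
    long_reads = quant$long_reads,
    read_accounting = quant$accounting,
    census = census$counts, domains = census$domains,
    methylation = meth$motifs, site_frequencies = meth$sites,
    n_methylated_sites = meth$n_methylated,
    config = config
  ), class = "ceo_report")

  if (!is.null(config$outdir)) write_report(report, sim, config$outdir)
  report
}

write_report <- function(report, sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  locus <- report$locus
  chrom_lengths <- setNames(nchar(locus$genome), names(locus$genome))
  p1 <- write_locus(locus, file.path(outdir, "locus"))
  p2 <- write_simulation(sim, chrom_lengths, file.path(outdir, "sim"))
  tsv <- function(df, name) {
    path <- file.path(outdir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  p3 <- c(
    tsv(report$regions, "enrichment.tsv"),
    tsv(report$census, "motif_counts.tsv"),
    tsv(report$domains, "domains.tsv"),
    guides = { write_guides_tsv(report$guides,
                                file.path(outdir, "guides.tsv"))
      file.path(outdir, "guides.tsv") }
  )
  if (!is.null(report$methylation)) {
    p3 <- c(p3, tsv(report$methylation, "motif_methylation.tsv"),
            tsv(report$site_frequencies, "site_frequencies.tsv"))
  }
  files <- c(p1, p2, p3)
  files <- files[file.exists(files)]
  manifest <- list(
    seed = report$config$seed,
    locus = report$config$locus,
    protocol = report$config$protocol,
    thresholds = report$config[c("min_q", "min_len", "window",
                                 "density_threshold", "merge_gap")],
    read_accounting = as.list(report$read_accounting),
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.ceo_report <- function(x, ...) {
  cat("CEO pipeline report (seed", x$config$seed, ")\n\n")
  cat("Reads:", x$read_accounting["reads_total"], "total,",
      x$read_accounting["reads_pass_q"], "pass Q filter;",
      x$long_reads, "long reads over the target\n")
  cat("Genome mean depth:", round(x$genome_depth, 2), "\n\n")
  cat("Enrichment:\n")
  print(x$regions, row.names = FALSE)
  cat("\nMotif census (top rows):\n")
  print(head(x$census, 5), row.names = FALSE)
  nR <- sum(x$domains$kind == "R")
  cat("\nDomains:", nR, "repetitive /", sum(x$domains$kind == "A"),
      "amorphous\n")
  if (!is.null(x$n_methylated_sites)) {
    cat("Methylated CG sites:", x$n_methylated_sites, "of",
        nrow(x$site_frequencies), "called\n")
  }
  invisible(x)
}
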