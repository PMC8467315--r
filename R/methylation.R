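#' Aggregate per-read CpG calls into per-site frequencies
#'
#' For every (chrom, position): `called_sites` is the number of reads with a
#' call there, `called_sites_methylated` the number called methylated, and
#' `frequency = called_sites_methylated / called_sites` — the standard
#' nanopore methylation-frequency definition. Sites with no calls do not
#' appear.
#'
#' @param calls data.frame with `chrom`, `position` (0-based CG start),
#'   `read_id`, `call` (1 methylated / 0 unmethylated; logical or
#'   `"methylated"`/`"unmethylated"` also accepted).
#' @return data.frame `chrom`, `position`, `called_sites`,
#'   `called_sites_methylated`, `frequency`, sorted by position.
#' @export
site_frequencies <- function(calls) {
  stopifnot(all(c("chrom", "position", "read_id", "call") %in% names(calls)))
  st <- calls$call
  if (is.character(st)) st <- as.integer(st == "methylated" | st == "1")
  st <- as.integer(st)
  if (any(is.na(st) | !(st %in% c(0L, 1L)))) stop("invalid call state")
  key <- paste(calls$chrom, calls$position, calls$read_id)
  if (anyDuplicated(key)) {
    stop("duplicate call for read/site pair: ", key[duplicated(key)][1])
  }
  grp <- paste(calls$chrom, calls$position)
  n <- tapply(st, grp, length)
  m <- tapply(st, grp, sum)
  first <- !duplicated(grp)
  res <- data.frame(chrom = calls$chrom[first],
                    position = calls$position[first],
                    stringsAsFactors = FALSE)
  idx <- match(paste(res$chrom, res$position), names(n))
  res$called_sites <- as.integer(n[idx])
  res$called_sites_methylated <- as.integer(m[idx])
  res$frequency <- res$called_sites_methylated / res$called_sites
  res <- res[order(res$chrom, res$position), ]
  rownames(res) <- NULL
  res
}

#' Per-motif summed methylation frequency
#'
#' Assigns each called CG site to the motif instance containing it (a site
#' belongs to an instance when its start lies within the instance span;
#' overlapping instances are an error) and reports, per motif, the SUM of
#' its instances' site frequencies — the published per-motif statistic,
#' which can exceed 1 and is bounded by the instance count. Instances whose
#' CG was never called contribute 0.
#'
#' @param sites data.frame from [site_frequencies()].
#' @param instances motif-instance data.frame (`name`, `chrom`, `start`,
#'   `end` 0-based half-open).
#' @param motifs optional motif catalogue (adds the `sequence` column and
#'   fixes motif order).
#' @param per_copy also report `mean_per_copy = methylation_frequency /
#'   repetition`.
#' @return data.frame `motif_name`, `sequence` (if available),
#'   `repetition`, `methylation_frequency` (and `mean_per_copy`).
#' @export
motif_frequencies <- function(sites, instances, motifs = NULL,
                              per_copy = FALSE) {
  inst <- instances[order(instances$chrom, instances$start), , drop = FALSE]
  if (nrow(inst) > 1) {
    prev_end <- c(-Inf, ifelse(inst$chrom[-1] == inst$chrom[-nrow(inst)],
                               inst$end[-nrow(inst)], -Inf))
    if (any(inst$start < prev_end)) stop("overlapping motif instances")
  }
  ## assign each site to the covering instance (start within span)
  idx <- rep(NA_integer_, nrow(sites))
  for (ch in unique(inst$chrom)) {
    ii <- which(inst$chrom == ch)
    ss <- which(sites$chrom == ch)
    if (!length(ss)) next
    j <- findInterval(sites$position[ss], inst$start[ii])
    inside <- j >= 1 & sites$position[ss] < inst$end[ii][pmax(j, 1)]
    idx[ss[inside]] <- ii[j[inside]]
  }
  names_all <- motifs$name %||% unique(instances$name)
  rep_count <- vapply(names_all, function(nm) sum(inst$name == nm), integer(1))
  freq_sum <- vapply(names_all, function(nm) {
    sum(sites$frequency[!is.na(idx) & inst$name[idx] == nm])
  }, numeric(1))
  res <- data.frame(motif_name = names_all, stringsAsFactors = FALSE)
  if (!is.null(motifs)) {
    res$sequence <- motifs$sequence[match(names_all, motifs$name)]
  }
  res$repetition <- rep_count
  res$methylation_frequency <- freq_sum
  if (per_copy) res$mean_per_copy <- freq_sum / pmax(rep_count, 1L)
  rownames(res) <- NULL
  res
}

#' Count methylated CG sites
#'
#' Number of sites whose methylation frequency is positive (default: at
#' least one methylated call) or at least `min_frequency` when given.
#'
#' @param sites data.frame from [site_frequencies()].
#' @param min_frequency optional inclusive threshold in `[0, 1]`.
#' @return integer count.
#' @export
count_methylated_sites <- function(sites, min_frequency = NULL) {
  if (is.null(min_frequency)) return(sum(sites$frequency > 0))
  if (min_frequency < 0 || min_frequency > 1) {
    stop("min_frequency must lie in [0, 1]")
  }
  sum(sites$frequency >= min_frequency)
}

#' Read a nanopolish-style methylation frequency table
#'
#' Accepts the `calculate_methylation_frequency` output layout (chromosome,
#' start, end, num_motifs, called_sites, called_sites_methylated,
#' methylated_frequency) directly as per-site records; positions are
#' converted to the package's 0-based convention.
#'
#' @param path TSV path.
#' @return data.frame in the [site_frequencies()] layout.
#' @export
read_nanopolish_frequency <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chromosome", "start", "called_sites", "called_sites_methylated")
  if (!all(need %in% names(tab))) {
    stop("not a methylation-frequency table: missing ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  data.frame(chrom = tab$chromosome,
             position = as.integer(tab$start),
             called_sites = as.integer(tab$called_sites),
             called_sites_methylated = as.integer(tab$called_sites_methylated),
             frequency = tab$called_sites_methylated / tab$called_sites,
             stringsAsFactors = FALSE)
}
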