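#' Parameters of the in-silico enrichment protocol
#'
#' Tunables of the four-step negative-selection protocol: dephosphorylation
#' of all pre-existing DNA ends, Cas12a cleavage at the guide sites, adapter
#' ligation to ligatable ends only, and sequencing of adapter-bearing ends.
#'
#' @param n_molecules genome copies put into the reaction.
#' @param dephos_efficiency probability that a pre-existing 5' end is
#'   dephosphorylated (and so cannot take an adapter).
#' @param background_end_rate probability that a dephosphorylated end is
#'   nonetheless ligatable (residual nicking / incomplete blocking); together
#'   with `dephos_efficiency` this sets the genome-wide background, for which
#'   the protocol itself fixes no mechanism.
#' @param cut_offsets staggered cut positions, nt 3' of the PAM on the
#'   non-target and target strands (default `c(18, 23)`, the canonical
#'   Cas12a cut leaving a 5-nt 5' overhang that is filled in before
#'   ligation).
#' @param fragment_len_range pre-existing fragment lengths (bp), uniform
#'   (default 23-200 kb, high-molecular-weight genomic DNA).
#' @param reads_per_ligatable_end probability a ligatable end yields a read.
#' @param read_len_meanlog,read_len_sdlog,read_len_min log-normal read-length
#'   model (bp), truncated below at `read_len_min` and above at the fragment
#'   end.
#' @param q_weights,q_means,q_sds two-component Gaussian mixture for per-read
#'   mean Phred quality (a good-read mode and a low-quality mode, so the
#'   Q >= 7 filter is exercisable); floored at `q_min`.
#' @param q_min minimum reported mean quality.
#' @param meth_caller_error probability a CpG methylation call is flipped.
#' @param seed optional default seed.
#' @return object of class `protocol_params`.
#' @export
protocol_params <- function(n_molecules = 300,
                            dephos_efficiency = 0.99,
                            background_end_rate = 0.05,
                            cut_offsets = c(18, 23),
                            fragment_len_range = c(23000, 200000),
                            reads_per_ligatable_end = 0.15,
                            read_len_meanlog = 8.5,
                            read_len_sdlog = 0.55,
                            read_len_min = 200,
                            q_weights = c(0.9, 0.1),
                            q_means = c(12, 5),
                            q_sds = c(2, 1.5),
                            q_min = 1,
                            meth_caller_error = 0.02,
                            seed = NULL) {
  p <- list(n_molecules = n_molecules,
            dephos_efficiency = dephos_efficiency,
            background_end_rate = background_end_rate,
            cut_offsets = sort(cut_offsets),
            fragment_len_range = fragment_len_range,
            reads_per_ligatable_end = reads_per_ligatable_end,
            read_len_meanlog = read_len_meanlog,
            read_len_sdlog = read_len_sdlog,
            read_len_min = read_len_min,
            q_weights = q_weights / sum(q_weights),
            q_means = q_means, q_sds = q_sds, q_min = q_min,
            meth_caller_error = meth_caller_error,
            seed = seed)
  probs <- c(p$dephos_efficiency, p$background_end_rate,
             p$reads_per_ligatable_end, p$meth_caller_error)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(p$fragment_len_range <= 0) ||
      p$fragment_len_range[1] > p$fragment_len_range[2]) {
    stop("fragment_len_range must be positive and ordered")
  }
  class(p) <- "protocol_params"
  p
}

## Blunt-equivalent cut boundaries for each guide site after overhang
## fill-in: the left fragment retains [.., c2) and the right [c1, ..),
## c2 - c1 = overhang. 0-based, genome frame.
guide_cut_coords <- function(guides, offsets) {
  pam_len <- nchar(guides$pam)
  fwd <- guides$strand == "+"
  pam0 <- ifelse(fwd, guides$start - 1L, NA_integer_)
  top0 <- ifelse(fwd, NA_integer_, guides$start)  # exclusive top end
  c1 <- ifelse(fwd, pam0 + pam_len + offsets[1],
               top0 - pam_len - offsets[2])
  c2 <- ifelse(fwd, pam0 + pam_len + offsets[2],
               top0 - pam_len - offsets[1])
  data.frame(name = guides$name, chrom = guides$chrom,
             c1 = as.integer(c1), c2 = as.integer(c2),
             cut_efficiency = guides$cut_efficiency %||% 1,
             stringsAsFactors = FALSE)
}

#' Simulate the enrichment + nanopore protocol
#'
#' Draws `n_molecules` copies of the genome, fragments each into
#' high-molecular-weight pieces, dephosphorylates pre-existing ends, cuts
#' each guide site per its cleavage efficiency, and sequences reads inward
#' from every adapter-ligatable end. Reads are error-free copies of the
#' reference (coordinates, not basecall realism, are the quantity of
#' interest); per-read CpG states are drawn from the per-site methylation
#' probabilities and flipped with the caller error rate.
#'
#' @param locus a `synthetic_locus` (or a named-character genome, in which
#'   case `guides` and optionally `cg_sites` must be given).
#' @param params [protocol_params()].
#' @param seed integer seed; identical `(locus, params, seed)` give identical
#'   output.
#' @param guides guide table overriding `locus$guides`.
#' @param cg_sites data.frame (`chrom`, `position` 0-based, `meth_prob`)
#'   overriding `locus$cg_sites`; `NULL` disables methylation calls.
#' @return list of class `ceo_simulation`: `reads` (read_id, sequence,
#'   mean_q, chrom, start, end, strand; coordinates 0-based half-open truth
#'   intervals), `alignments` (the same without sequence), `calls` (chrom,
#'   position, read_id, call 1/0), `params`, `seed`.
#' @export
simulate_protocol <- function(locus, params = protocol_params(), seed = NULL,
                              guides = NULL, cg_sites = NULL) {
  if (inherits(locus, "synthetic_locus")) {
    genome <- locus$genome
    guides <- guides %||% locus$guides
    cg_sites <- cg_sites %||% locus$cg_sites
  } else {
    genome <- as_genome(locus)
    if (is.null(guides)) stop("guides must be supplied for a raw genome")
  }
  seed <- seed %||% params$seed
  with_seed(seed, simulate_impl(genome, guides, cg_sites, params, seed))
}

simulate_impl <- function(genome, guides, cg_sites, params, seed) {
  p_lig <- (1 - params$dephos_efficiency) +
    params$dephos_efficiency * params$background_end_rate
  r <- params$reads_per_ligatable_end
  cuts_all <- guide_cut_coords(guides, params$cut_offsets)

  starts <- ends <- integer(0)
  dirs <- character(0)
  chroms <- character(0)

  for (chrom in names(genome)) {
    G <- nchar(genome[[chrom]])
    cuts <- cuts_all[cuts_all$chrom == chrom, , drop = FALSE]
    cuts <- cuts[order(cuts$c1), , drop = FALSE]
    for (mol in seq_len(params$n_molecules)) {
      ## fragmentation: iid uniform lengths until the chromosome is used up
      bp <- integer(0)
      pos <- 0
      repeat {
        pos <- pos + runif(1, params$fragment_len_range[1],
                           params$fragment_len_range[2])
        if (pos >= G) break
        bp <- c(bp, as.integer(pos))
      }
      fs <- c(0L, bp)
      fe <- c(bp, G)
      for (k in seq_along(fs)) {
        a <- fs[k]; b <- fe[k]
        in_frag <- cuts$c1 > a & cuts$c2 < b
        hit <- in_frag & (runif(nrow(cuts)) < cuts$cut_efficiency)
        ps <- c(a, cuts$c1[hit])      # piece starts
        pe <- c(cuts$c2[hit], b)      # piece ends
        npc <- length(ps)
        ## left end of piece 1 and right end of piece npc are pre-existing
        lig_left <- c(runif(1) < p_lig, rep(TRUE, npc - 1L))
        lig_right <- c(rep(TRUE, npc - 1L), runif(1) < p_lig)
        seed_left <- lig_left & (runif(npc) < r)
        seed_right <- lig_right & (runif(npc) < r)
        if (any(seed_left)) {
          n <- sum(seed_left)
          len <- pmin(read_lengths(n, params), pe[seed_left] - ps[seed_left])
          starts <- c(starts, ps[seed_left])
          ends <- c(ends, as.integer(ps[seed_left] + len))
          dirs <- c(dirs, rep("+", n))
          chroms <- c(chroms, rep(chrom, n))
        }
        if (any(seed_right)) {
          n <- sum(seed_right)
          len <- pmin(read_lengths(n, params), pe[seed_right] - ps[seed_right])
          starts <- c(starts, as.integer(pe[seed_right] - len))
          ends <- c(ends, pe[seed_right])
          dirs <- c(dirs, rep("-", n))
          chroms <- c(chroms, rep(chrom, n))
        }
      }
    }
  }

  n_reads <- length(starts)
  if (n_reads == 0L) {
    warning("no ligatable ends produced any reads")
  }
  ord <- order(chroms, starts, ends)
  starts <- starts[ord]; ends <- ends[ord]
  dirs <- dirs[ord]; chroms <- chroms[ord]
  ids <- sprintf("read_%06d", seq_len(n_reads))

  comp <- sample.int(2L, n_reads, replace = TRUE, prob = params$q_weights)
  mean_q <- pmax(params$q_min,
                 rnorm(n_reads, params$q_means[comp], params$q_sds[comp]))

  seqs <- substring(genome[chroms], starts + 1L, ends)
  if (any(dirs == "-") && n_reads > 0L) {
    seqs[dirs == "-"] <- revcomp(seqs[dirs == "-"])
  }
  reads <- data.frame(read_id = ids, sequence = seqs,
                      mean_q = round(mean_q, 2), chrom = chroms,
                      start = starts, end = ends, strand = dirs,
                      stringsAsFactors = FALSE)

  calls <- NULL
  if (!is.null(cg_sites) && n_reads > 0L) {
    calls <- draw_meth_calls(reads, cg_sites, params)
  }

  structure(list(reads = reads,
                 alignments = reads[, c("read_id", "chrom", "start", "end",
                                        "strand", "mean_q")],
                 calls = calls, params = params, seed = seed),
            class = "ceo_simulation")
}

read_lengths <- function(n, params) {
  pmax(params$read_len_min,
       as.integer(rlnorm(n, params$read_len_meanlog, params$read_len_sdlog)))
}

## Per-read Bernoulli methylation states at every CG covered by each read,
## flipped with the caller error rate. A CG is covered when the whole
## dinucleotide lies inside the truth interval.
draw_meth_calls <- function(reads, cg_sites, params) {
  out <- list()
  for (chrom in unique(reads$chrom)) {
    cg <- cg_sites[cg_sites$chrom == chrom, , drop = FALSE]
    cg <- cg[order(cg$position), , drop = FALSE]
    if (!nrow(cg)) next
    rd <- reads[reads$chrom == chrom, , drop = FALSE]
    lo <- findInterval(rd$start - 0.5, cg$position) + 1L
    hi <- findInterval(rd$end - 1.5, cg$position)
    nn <- pmax(0L, hi - lo + 1L)
    keep <- nn > 0L
    if (!any(keep)) next
    idx <- sequence(nn[keep], from = lo[keep])
    rid <- rep(rd$read_id[keep], nn[keep])
    prob <- cg$meth_prob[idx]
    state <- rbinom(length(idx), 1L, prob)
    flip <- rbinom(length(idx), 1L, params$meth_caller_error)
    out[[chrom]] <- data.frame(chrom = chrom, position = cg$position[idx],
                               read_id = rid,
                               call = as.integer(xor(state, flip)),
                               stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Closed-form expected enrichment fold under the protocol model
#'
#' Deterministic expectation of (mean target depth) / (mean genome depth)
#' under the sampling model of [simulate_protocol()]. Expected depth at a
#' position is assembled from two source classes: a continuum of
#' pre-existing fragment ends (density one breakpoint per mean fragment
#' length, ligatable with the residual-end probability) and the discrete cut
#' ends at each guide site (weight equal to its cleavage efficiency). A read
#' from a source at distance `u` covers the position with probability
#' S_L(u) * S_F(u) * prod(1 - e_j): the read-length survival, the
#' probability no pre-existing breakpoint intervenes (forward-recurrence
#' survival of the uniform fragment law for interior cut ends; the plain
#' fragment survival for reads launched at a breakpoint), and a factor
#' (1 - e_j) for every intervening guide cut. Genome-edge effects beyond the
#' breakpoint treatment are ignored.
#'
#' @param locus a `synthetic_locus`.
#' @param params [protocol_params()].
#' @param region 1-based inclusive `c(start, end)` target interval; defaults
#'   to the locus target region.
#' @param grid_step evaluation grid spacing, bp.
#' @return list with `fold`, `target_depth`, `genome_depth` (all per
#'   expectation, depths in units of absolute coverage).
#' @export
expected_enrichment_fold <- function(locus, params = protocol_params(),
                                     region = NULL, grid_step = 100) {
  stopifnot(inherits(locus, "synthetic_locus"))
  G <- nchar(locus$genome[[1]])
  if (is.null(region)) {
    tr <- locus$regions[locus$regions$label != "downstream" &
                          locus$regions$label != "upstream", ]
    region <- c(tr$start, tr$end)
  }
  cuts <- guide_cut_coords(locus$guides, params$cut_offsets)
  cpos <- (cuts$c1 + cuts$c2) / 2
  ceff <- cuts$cut_efficiency
  o <- order(cpos); cpos <- cpos[o]; ceff <- ceff[o]

  p_lig <- (1 - params$dephos_efficiency) +
    params$dephos_efficiency * params$background_end_rate
  r <- params$reads_per_ligatable_end
  n <- params$n_molecules
  fl <- params$fragment_len_range
  mu_f <- mean(fl)

  S_L <- function(u) {
    ifelse(u <= params$read_len_min, 1,
           1 - plnorm(u, params$read_len_meanlog, params$read_len_sdlog))
  }
  ## fragment survival seen from a breakpoint (plain uniform survival)
  S_Fb <- function(u) pmin(1, pmax(0, (fl[2] - u) / (fl[2] - fl[1])))
  ## breakpoint-free span from an interior point (forward recurrence)
  S_Fc <- function(u) {
    ifelse(u <= fl[1], (mu_f - u) / mu_f,
           ifelse(u >= fl[2], 0, (fl[2] - u)^2 / (2 * (fl[2] - fl[1])) / mu_f))
  }

  ## cumulative integrals of the coverage kernels, tabulated once
  ugrid <- seq(0, fl[2], by = 25)
  tab_cum <- function(g) {
    v <- g(ugrid)
    c(0, cumsum((v[-1] + v[-length(v)]) / 2 * diff(ugrid)))
  }
  cum_bg <- tab_cum(function(u) S_L(u) * S_Fb(u))
  look <- function(cum, u) {
    u <- pmin(pmax(u, 0), max(ugrid))
    i <- findInterval(u, ugrid)
    frac <- (u - ugrid[i]) / 25
    cum[i] + frac * (cum[pmin(i + 1, length(cum))] - cum[i])
  }

  ## product of (1 - e_j) over cut sites strictly between y and x
  block <- function(from, to) {
    lo <- pmin(from, to); hi <- pmax(from, to)
    f <- rep(1, length(lo))
    for (j in seq_along(cpos)) {
      between <- cpos[j] > lo & cpos[j] < hi
      f[between] <- f[between] * (1 - ceff[j])
    }
    f
  }

  ## expected depth at x per (n * r): background integral split at cut sites
  ## + discrete cut-end sources
  depth_at <- function(x) {
    bounds <- sort(unique(c(0, cpos, G)))
    bg <- 0
    for (j in seq_len(length(bounds) - 1)) {
      y1 <- bounds[j]; y2 <- bounds[j + 1]
      mid <- (y1 + y2) / 2
      bfac <- block(mid, x)
      d1 <- pmin(abs(x - y1), abs(x - y2))
      d2 <- pmax(abs(x - y1), abs(x - y2))
      if (x > y1 && x < y2) {  # x inside: both directions, distances 0..
        seg <- look(cum_bg, x - y1) + look(cum_bg, y2 - x)
      } else {
        seg <- look(cum_bg, d2) - look(cum_bg, d1)
      }
      bg <- bg + p_lig / mu_f * seg * bfac
    }
    cut <- sum(ceff * S_L(abs(x - cpos)) * S_Fc(abs(x - cpos)) *
                 block(cpos, x))
    ## molecule ends are pre-existing ends too (one inward-facing per side)
    edge <- p_lig * (S_L(x) * S_Fb(x) * block(0, x) +
                       S_L(G - x) * S_Fb(G - x) * block(G, x))
    bg + cut + edge
  }

  xt <- seq(region[1] - 1, region[2] - 1, by = grid_step)
  xg <- seq(0, G - 1, by = grid_step * 5)
  dt <- mean(vapply(xt, depth_at, numeric(1)))
  dg <- mean(vapply(xg, depth_at, numeric(1)))
  list(fold = dt / dg,
       target_depth = n * r * dt,
       genome_depth = n * r * dg)
}
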