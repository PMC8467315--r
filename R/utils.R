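#' @importFrom stats rbinom runif rnorm rlnorm plnorm setNames aggregate
#' @importFrom utils write.table read.delim head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce a genome to a named character vector
#'
#' Accepts a `Biostrings::DNAStringSet`, a named character vector, or a single
#' unnamed sequence (named `"chr1"`). Sequences are upper-cased and checked to
#' be pure A/C/G/T.
#'
#' @param x genome input.
#' @return named character vector of contig sequences.
#' @keywords internal
as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  if (!is.character(x)) {
    stop("genome must be a DNAStringSet or a character vector of sequences")
  }
  if (is.null(names(x))) {
    if (length(x) == 1L) names(x) <- "chr1" else
      stop("multi-contig character genomes must be named")
  }
  x <- toupper(x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("non-ACGT character in contig(s): ", paste(names(x)[bad], collapse = ", "))
  }
  x
}

check_dna <- function(s, what = "sequence") {
  if (!is.character(s) || any(is.na(s)) || any(nchar(s) == 0L)) {
    stop(what, " must be non-empty character")
  }
  if (any(grepl("[^ACGTacgt]", s))) stop("non-ACGT character in ", what)
  invisible(toupper(s))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

## Round half away from zero, matching how the source tables print numbers
## (base round() ties to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. seed = NULL runs on the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## IUPAC pattern -> per-position list of allowed bases
iupac_expand <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(pattern), "")[[1]]
  if (!all(chars %in% names(map))) {
    stop("invalid IUPAC character in pattern: ", pattern)
  }
  lapply(chars, function(ch) strsplit(map[[ch]], "")[[1]])
}

## Positions (0-based) where `pattern` (IUPAC) matches `seq` exactly.
match_iupac <- function(seq, pattern) {
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(pattern), Biostrings::DNAString(seq),
    fixed = "subject"
  )
  BiocGenerics::start(hits) - 1L
}
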