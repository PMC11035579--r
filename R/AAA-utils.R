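# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
CYS_CODONS <- c("TGT", "TGC")

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state so that seeded package
#' operations never perturb the caller's random number stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Translate DNA strings, vectorised
#'
#' Trailing bases that do not complete a codon are dropped. Stops are "*",
#' ambiguous codons "X". Returns "" for sequences shorter than one codon.
#' Uses a plain codon lookup (the standard genetic code) to stay cheap on
#' the many short per-contig calls the annotator makes.
#' @noRd
translateNt <- local({
  codeTable <- NULL
  function(x) {
    if (is.null(codeTable)) codeTable <<- Biostrings::GENETIC_CODE
    x <- as.character(x)
    n <- nchar(x) %/% 3L * 3L
    if (length(x) > 100L) {
      # batch path: one C-level call for the simulator's large draws
      out <- character(length(x))
      nz <- which(n >= 3L)
      if (length(nz)) {
        dna <- Biostrings::DNAStringSet(substr(x[nz], 1L, n[nz]))
        out[nz] <- as.character(suppressWarnings(
          Biostrings::translate(dna, no.init.codon = TRUE)))
      }
      return(out)
    }
    vapply(seq_along(x), function(i) {
      k <- n[[i]] %/% 3L
      if (k == 0L) return("")
      starts <- seq.int(1L, by = 3L, length.out = k)
      aa <- codeTable[substring(x[[i]], starts, starts + 2L)]
      aa[is.na(aa)] <- "X"
      paste0(aa, collapse = "")
    }, character(1L))
  }
})

#' Stop-free translation check from position 1 through `end`,
#' with the final straddling codon completed from the bases that follow.
#' @noRd
stopFreeThrough <- function(seq, end) {
  stopifnot(length(seq) == length(end))
  padEnd <- pmin(nchar(seq), 3L * ceiling(end / 3L))
  aa <- translateNt(substr(seq, 1L, padEnd))
  !grepl("*", aa, fixed = TRUE)
}

#' Truncated geometric sampler on 0..max with P(k) proportional to (1-p)^k
#' @noRd
rtruncgeom <- function(n, p, max) {
  if (max == 0L) return(integer(n))
  k <- 0:max
  sample(k, n, replace = TRUE, prob = p * (1 - p)^k)
}

#' Random DNA strings of the given lengths (uniform ACGT)
#' @noRd
randomDna <- function(lengths) {
  n <- length(lengths)
  if (n == 0L) return(character())
  maxLen <- max(lengths)
  if (maxLen == 0L) return(character(n))
  m <- matrix(sample(DNA_BASES, n * maxLen, replace = TRUE), nrow = n)
  full <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  substr(full, 1L, lengths)
}

#' Deterministic distinct 16-mer barcodes (base-4 encoding of an index)
#' @noRd
sequentialBarcodes <- function(n) {
  if (n > 4^16) stop("cannot generate more than 4^16 distinct barcodes")
  idx <- as.numeric(seq_len(n) - 1L)
  digits <- matrix(0L, nrow = n, ncol = 16L)
  for (j in 16:1) {
    digits[, j] <- idx %% 4
    idx <- idx %/% 4
  }
  m <- matrix(DNA_BASES[digits + 1L], nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Segment key "<segment_id>*<allele>"
#' @noRd
segmentKey <- function(segment_id, allele) paste0(segment_id, "*", allele)

#' Fraction identity of a pairwise alignment
#' @noRd
alnIdentity <- function(aln) {
  Biostrings::nmatch(aln) / (Biostrings::nmatch(aln) + Biostrings::nmismatch(aln))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
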