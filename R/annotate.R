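# Contig annotation: segment assignment by local alignment (with a
# shared-k-mer prescreen to keep the candidate set small), CDR3
# extraction between the mapped V-cysteine and J-[FW]GXG anchors, and
# productivity calling. D segments are not assigned.

SW_MATCH <- 2
SW_MISMATCH <- -2
SW_GAP_OPEN <- 4
SW_GAP_EXT <- 1
SW_SCORE_FLOOR <- 40
MIN_CONTIG_LENGTH <- 100L
KMER_K <- 12L

swSubstMat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = SW_MATCH,
                                           mismatch = SW_MISMATCH,
                                           baseOnly = FALSE)
}

#' Shared k-mer counts between every segment and every contig
#' @return matrix segments x contigs
#' @noRd
kmerScreen <- function(segSeqs, contigSet, k = KMER_K) {
  kmers <- lapply(segSeqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  segIdx <- rep.int(seq_along(kmers), lengths(kmers))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(unlist(kmers)))
  counts <- Biostrings::vcountPDict(pd, contigSet)
  m <- rowsum(counts, group = segIdx)
  full <- matrix(0L, nrow = length(segSeqs), ncol = length(contigSet),
                 dimnames = list(names(segSeqs), NULL))
  full[as.integer(rownames(m)), ] <- m
  full
}

#' Pattern-position -> subject-position map of a pairwise alignment
#' @noRd
alnMap <- function(aln, patternLength) {
  p <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::subject(aln)), "")[[1L]]
  map <- rep(NA_integer_, patternLength)
  pPos <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  sPos <- Biostrings::start(Biostrings::subject(aln)) - 1L
  for (i in seq_along(p)) {
    if (p[i] != "-") pPos <- pPos + 1L
    if (s[i] != "-") sPos <- sPos + 1L
    if (p[i] != "-" && s[i] != "-") map[pPos] <- sPos
  }
  map
}

#' Align the best candidate segment(s) against one contig
#'
#' Candidates are first ranked by score-only alignment (cheap); only the
#' winner (and any exact score ties, for the identity tie-break) gets a
#' full traceback alignment.
#' @noRd
bestSegmentHit <- function(contig, candKeys, segSeqs, substMat = swSubstMat()) {
  swAlign <- function(patterns, scoreOnly = FALSE) {
    Biostrings::pairwiseAlignment(
      patterns, contig, type = "local", substitutionMatrix = substMat,
      gapOpening = SW_GAP_OPEN, gapExtension = SW_GAP_EXT,
      scoreOnly = scoreOnly)
  }
  scores <- if (length(candKeys) == 1L) NULL else swAlign(segSeqs[candKeys], TRUE)
  tied <- if (is.null(scores)) candKeys else candKeys[scores == max(scores)]
  tied <- sort(tied)
  alns <- lapply(tied, function(k) swAlign(segSeqs[[k]]))
  ident <- vapply(alns, alnIdentity, numeric(1L))
  best <- order(-ident, tied)[[1L]]
  tie <- length(tied) > 1L && sum(ident == ident[best]) > 1L
  list(key = tied[best], score = Biostrings::score(alns[[best]]),
       identity = ident[best], aln = alns[[best]], tie = tie)
}

#' Annotate one contig against the reference; returns a one-row list
#' @noRd
annotateOne <- function(contig, vCand, jCandByChain, segSeqs, segInfo,
                        scoreFloor = SW_SCORE_FLOOR, substMat = swSubstMat()) {
  res <- list(chain = NA_character_, v_call = NA_character_,
              j_call = NA_character_, v_identity = NA_real_,
              j_identity = NA_real_, cdr3_nt = NA_character_,
              cdr3_aa = NA_character_, frame_offset = NA_integer_,
              has_stop = NA, full_length = FALSE, productive = FALSE,
              segment_tie = FALSE, reason = "ok")
  L <- nchar(contig)
  if (L < MIN_CONTIG_LENGTH) { res$reason <- "too_short"; return(res) }
  if (!length(vCand)) { res$reason <- "no_v_call"; return(res) }
  vHit <- bestSegmentHit(contig, vCand, segSeqs, substMat)
  if (vHit$score < scoreFloor) { res$reason <- "low_v_score"; return(res) }
  vKey <- vHit$key
  chain <- segInfo[vKey, "chain"]
  res$chain <- chain
  res$v_call <- vKey
  res$v_identity <- vHit$identity
  res$segment_tie <- vHit$tie
  vLen <- nchar(segSeqs[[vKey]])
  vMap <- alnMap(vHit$aln, vLen)
  vPatStart <- Biostrings::start(Biostrings::pattern(vHit$aln))
  vOrigin <- Biostrings::start(Biostrings::subject(vHit$aln)) - (vPatStart - 1L)
  res$frame_offset <- ((vOrigin - 1L) %% 3L + 3L) %% 3L

  jCand <- jCandByChain[[chain]]
  if (!length(jCand)) { res$reason <- "no_j_call"; return(res) }
  jHit <- bestSegmentHit(contig, jCand, segSeqs, substMat)
  if (jHit$score < scoreFloor) { res$reason <- "low_j_score"; return(res) }
  jKey <- jHit$key
  res$j_call <- jKey
  res$j_identity <- jHit$identity
  res$segment_tie <- res$segment_tie || jHit$tie
  jLen <- nchar(segSeqs[[jKey]])
  jMap <- alnMap(jHit$aln, jLen)
  res$full_length <- Biostrings::end(Biostrings::pattern(jHit$aln)) == jLen

  # stop scan from the V origin (in V frame) through the end of the
  # aligned J region, straddling codon completed from what follows
  jEndContig <- Biostrings::end(Biostrings::subject(jHit$aln))
  scanStart <- max(1L, vOrigin)
  stopFree <- stopFreeThrough(substr(contig, scanStart, L),
                              jEndContig - scanStart + 1L)
  res$has_stop <- !stopFree

  cys <- segInfo[vKey, "cys_anchor"]
  jAnchor <- segInfo[jKey, "jmotif_anchor"]
  if (is.na(cys) || is.na(jAnchor)) { res$reason <- "anchor_missing"; return(res) }
  cysPos <- vMap[cys + seq_len(3L)]
  jFPos <- jMap[jAnchor + seq_len(3L)]
  contiguous <- function(x) !anyNA(x) && all(diff(x) == 1L)
  if (!contiguous(cysPos) || !contiguous(jFPos)) {
    res$reason <- "anchor_unmapped"; return(res)
  }
  cdr3 <- substr(contig, cysPos[1L], jFPos[3L])
  res$cdr3_nt <- cdr3
  inframe <- nchar(cdr3) %% 3L == 0L && nchar(cdr3) > 0L
  if (inframe) res$cdr3_aa <- translateNt(cdr3)

  if (!inframe) {
    res$reason <- "out_of_frame"
  } else if (!stopFree) {
    res$reason <- "stop_codon"
  } else if (!grepl("^C.*[FW]$", res$cdr3_aa)) {
    res$reason <- "anchor_noncanonical"
  } else {
    res$productive <- TRUE
  }
  res
}

normalizeContigInput <- function(contigs) {
  if (methods::is(contigs, "SimulatedRepertoire")) contigs <- simContigs(contigs)
  if (methods::is(contigs, "DNAStringSet")) {
    ids <- names(contigs) %||% paste0("contig_", seq_along(contigs))
    contigs <- data.frame(contig_id = ids,
                          barcode = sub("_contig_.*$", "", ids),
                          contig_nt = as.character(contigs),
                          stringsAsFactors = FALSE)
  }
  if (is.character(contigs)) {
    contigs <- data.frame(contig_id = sprintf("contig_%d", seq_along(contigs)),
                          barcode = rep(NA_character_, length(contigs)),
                          contig_nt = contigs, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(contigs), "contig_nt" %in% names(contigs))
  if (is.null(contigs$contig_id)) {
    contigs$contig_id <- paste0("contig_", seq_len(nrow(contigs)))
  }
  if (is.null(contigs$barcode)) contigs$barcode <- NA_character_
  contigs
}

#' Annotate contigs against a segment reference
#'
#' For each contig: local alignment against candidate V segments (both
#' chains; candidates prescreened by shared 12-mers, ties kept), chain
#' inferred from the best V, local alignment against that chain's J
#' segments, CDR3 extracted between the mapped conserved-Cys codon and
#' the \[FW\] codon of the J motif (both inclusive), and productivity
#' called: CDR3 present, junction in frame, no stop codon from the V
#' origin through the end of the J region, canonical C...F/W anchors.
#' Assignment ties are broken by higher identity then lexicographically
#' smaller key, and flagged in `segment_tie`.
#'
#' @param contigs a data.frame with `contig_nt` (plus optional
#'   `contig_id`, `barcode`, `umi_count`), a named
#'   [Biostrings::DNAStringSet], a character vector, or a
#'   [SimulatedRepertoire-class].
#' @param refset an anchored [TCRReferenceSet-class].
#' @param scoreFloor minimum Smith-Waterman score for a segment call.
#' @return data.frame, one row per contig: `barcode`, `contig_id`,
#'   `chain`, `v_call`, `j_call`, `v_identity`, `j_identity`, `cdr3_nt`,
#'   `cdr3_aa`, `frame_offset`, `has_stop`, `full_length`, `productive`,
#'   `segment_tie`, `reason`, `contig_length`.
#' @export
annotateContigs <- function(contigs, refset, scoreFloor = SW_SCORE_FLOOR) {
  contigs <- normalizeContigInput(contigs)
  n <- nrow(contigs)
  base <- data.frame(barcode = contigs$barcode, contig_id = contigs$contig_id,
                     contig_length = nchar(contigs$contig_nt),
                     stringsAsFactors = FALSE)
  if (n == 0L) {
    return(data.frame(barcode = character(), contig_id = character(),
                      contig_length = integer(), chain = character(),
                      v_call = character(), j_call = character(),
                      v_identity = numeric(), j_identity = numeric(),
                      cdr3_nt = character(), cdr3_aa = character(),
                      frame_offset = integer(), has_stop = logical(),
                      full_length = logical(), productive = logical(),
                      segment_tie = logical(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  seg <- refSegments(refset)
  segSeqs <- as.character(refSequences(refset))
  substMat <- swSubstMat()
  vKeys <- rownames(seg)[seg$segment_class == "V"]
  jKeys <- rownames(seg)[seg$segment_class == "J"]
  contigSet <- Biostrings::DNAStringSet(contigs$contig_nt)

  vScores <- kmerScreen(segSeqs[vKeys], contigSet)
  jScores <- kmerScreen(segSeqs[jKeys], contigSet)
  jByChain <- split(jKeys, seg[jKeys, "chain"])

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    vs <- vScores[, i]
    vCand <- vKeys[vs >= max(max(vs) - 2L, 3L)]
    js <- jScores[, i]
    jCandByChain <- lapply(jByChain, function(k) {
      s <- js[k]
      k[s >= max(max(s) - 2L, 3L)]
    })
    rows[[i]] <- annotateOne(contigs$contig_nt[[i]], vCand, jCandByChain,
                             segSeqs, seg, scoreFloor, substMat)
  }
  ann <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  cbind(base, ann)
}

#' Assign V and J segments to contigs
#'
#' Thin wrapper over [annotateContigs()] exposing the segment-assignment
#' columns only.
#' @inheritParams annotateContigs
#' @return data.frame: `contig_id`, `chain`, `v_call`, `j_call`,
#'   `v_identity`, `j_identity`, `segment_tie`, `reason`.
#' @export
assignSegments <- function(contigs, refset, scoreFloor = SW_SCORE_FLOOR) {
  ann <- annotateContigs(contigs, refset, scoreFloor)
  ann[, c("contig_id", "chain", "v_call", "j_call", "v_identity",
          "j_identity", "segment_tie", "reason")]
}

#' Extract CDR3 sequences from contigs
#'
#' @inheritParams annotateContigs
#' @return data.frame: `contig_id`, `cdr3_nt`, `cdr3_aa`, `reason`.
#' @export
extractCDR3 <- function(contigs, refset, scoreFloor = SW_SCORE_FLOOR) {
  ann <- annotateContigs(contigs, refset, scoreFloor)
  ann[, c("contig_id", "cdr3_nt", "cdr3_aa", "reason")]
}

#' Call productivity for contigs
#'
#' @inheritParams annotateContigs
#' @return data.frame: `contig_id`, `productive`, `reason`.
#' @export
callProductivity <- function(contigs, refset, scoreFloor = SW_SCORE_FLOOR) {
  ann <- annotateContigs(contigs, refset, scoreFloor)
  ann[, c("contig_id", "productive", "reason")]
}

#' Per-barcode annotation flags
#'
#' Aggregates a contig annotation table into Table-2-style per-cell
#' flags: presence of a TRA/TRB contig, a CDR3-annotated contig, a
#' productive contig per chain, and a productive V-J spanning pair
#' (at least one productive TRA and one productive TRB).
#'
#' @param annotations output of [annotateContigs()].
#' @return data.frame, one row per barcode.
#' @export
barcodeSummary <- function(annotations) {
  bc <- unique(annotations$barcode)
  f <- function(cond) {
    as.logical(tapply(cond, factor(annotations$barcode, levels = bc),
                      any, default = FALSE))
  }
  isTra <- annotations$chain %in% "TRA"
  isTrb <- annotations$chain %in% "TRB"
  hasCdr3 <- !is.na(annotations$cdr3_nt)
  prod <- annotations$productive %in% TRUE
  out <- data.frame(
    barcode = bc,
    has_tra = f(isTra), has_trb = f(isTrb),
    cdr3_tra = f(isTra & hasCdr3), cdr3_trb = f(isTrb & hasCdr3),
    productive_tra = f(isTra & prod), productive_trb = f(isTrb & prod),
    stringsAsFactors = FALSE)
  out$productive_pair <- out$productive_tra & out$productive_trb
  rownames(out) <- NULL
  out
}
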