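# Synthetic default reference. All sequences are generated in code; the
# defective segments reproduce, at the sequence-geometry level, the three
# canonical canine pseudogene-rescue situations: a V with an in-frame stop
# late in FR3 correctable by a single germline SNV (TRBV19-like), a V with
# an early in-frame stop plus a frameshift correctable by a multi-variant
# germline consensus (TRAV9-2-like), and a J with a stop in its second
# codon that junctional trimming can remove (TRBJ1-3-like).

NONSTOP_CODONS <- local({
  all <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  setdiff(all, STOP_CODONS)
})

randCodons <- function(n, exclude = character()) {
  pool <- setdiff(NONSTOP_CODONS, exclude)
  paste0(sample(pool, n, replace = TRUE), collapse = "")
}

# Functional V body: nCodon codons, Cys anchor 4 codons from the 3' end,
# no other TGT/TGC codon-aligned within the final 15 codons.
makeFunctionalV <- function(nCodon = 100L) {
  head <- randCodons(nCodon - 15L)
  guard <- randCodons(11L, exclude = CYS_CODONS)
  paste0(head, guard, "TGT", "GCC", "AGC", "AGT")
}

makeFunctionalJ <- function(stopCodon2 = FALSE) {
  lead <- if (stopCodon2) paste0(randCodons(1L), "TAG", randCodons(3L))
          else randCodons(5L)
  tail <- randCodons(11L, exclude = c(grep("^GG", NONSTOP_CODONS, value = TRUE),
                                      grep("^TT[TC]$|^TGG$", NONSTOP_CODONS, value = TRUE)))
  paste0(lead, "TTT", "GGA", randCodons(1L, exclude = grep("^GG", NONSTOP_CODONS, value = TRUE)),
         "GGC", tail)
}

makeCRegion <- function(n = 150L) {
  paste0(sample(c("A", "C", "G"), n, replace = TRUE), collapse = "")
}

#' Apply germline edits to a segment sequence
#'
#' Edits are expressed on reference coordinates (0-based): `SNV` replaces
#' the base at `position`; `insertion` inserts `obs_allele` before
#' `position`; `deletion` removes `nchar(ref_allele)` bases starting at
#' `position`. Edits are applied from the 3' end so positions stay valid.
#'
#' @param seq character DNA sequence.
#' @param edits data.frame with columns `kind`, `position`, `ref_allele`,
#'   `obs_allele`.
#' @return edited sequence.
#' @export
applyEdits <- function(seq, edits) {
  if (is.null(edits) || nrow(edits) == 0L) return(seq)
  edits <- edits[order(edits$position, decreasing = TRUE), , drop = FALSE]
  for (i in seq_len(nrow(edits))) {
    p <- edits$position[i]
    kind <- edits$kind[i]
    if (kind == "SNV") {
      stopifnot(substr(seq, p + 1L, p + 1L) == edits$ref_allele[i])
      substr(seq, p + 1L, p + 1L) <- edits$obs_allele[i]
    } else if (kind == "insertion") {
      seq <- paste0(substr(seq, 1L, p), edits$obs_allele[i],
                    substr(seq, p + 1L, nchar(seq)))
    } else if (kind == "deletion") {
      n <- nchar(edits$ref_allele[i])
      stopifnot(substr(seq, p + 1L, p + n) == edits$ref_allele[i])
      seq <- paste0(substr(seq, 1L, p), substr(seq, p + n + 1L, nchar(seq)))
    } else stop("unknown edit kind: ", kind)
  }
  seq
}

#' Default synthetic TRA/TRB segment reference
#'
#' Builds a deterministic, fully synthetic annotated reference: 8
#' functional V and 6 functional J segments per chain, one D and one C
#' segment for TRB (one C for TRA), plus three defective segments whose
#' geometries mirror the canine pseudogenes that turn out to be usable in
#' productive rearrangements:
#' \describe{
#'   \item{TRBV19*01 (pseudogene)}{in-frame TAG two codons 5' of the
#'     conserved Cys; a single germline T->C SNV converts it to CAG (Q).}
#'   \item{TRAV9-2*01 (pseudogene)}{in-frame TGA at codon 45 and a 1-nt
#'     frameshift at codon 57; the donor consensus differs by 8 SNVs plus
#'     a single C insertion that restore an open reading frame.}
#'   \item{TRBJ1-3*01 (pseudogene)}{TAG in codon 2, removable by
#'     junctional trimming while the \[FW\]GXG anchor survives.}
#' }
#' The corrective edit sets are available from [syntheticRescueEdits()].
#'
#' @param seed integer; the reference is a fixed artefact, so the default
#'   should normally be left alone.
#' @return An anchored [TCRReferenceSet-class].
#' @export
syntheticReference <- function(seed = 101L) {
  withSeed(seed, {
    rows <- list(); seqs <- character()
    addSeg <- function(id, chain, cls, fun, seq, frame = 0L) {
      rows[[length(rows) + 1L]] <<- data.frame(
        segment_id = id, allele = "01", chain = chain, segment_class = cls,
        functional_class = fun, frame = frame,
        cys_anchor = NA_integer_, jmotif_anchor = NA_integer_,
        stringsAsFactors = FALSE)
      seqs[[length(seqs) + 1L]] <<- seq
    }

    for (i in 1:8) addSeg(paste0("TRAV", i), "TRA", "V", "functional", makeFunctionalV())
    for (i in 1:6) addSeg(paste0("TRAJ", i), "TRA", "J", "functional", makeFunctionalJ())
    addSeg("TRAC", "TRA", "C", "functional", makeCRegion())

    for (i in 1:8) addSeg(paste0("TRBV", i), "TRB", "V", "functional", makeFunctionalV())
    addSeg("TRBD1", "TRB", "D", "functional", "GGGACAGGGGGC")
    for (id in c("TRBJ1-1", "TRBJ1-2", "TRBJ2-1", "TRBJ2-2", "TRBJ2-3", "TRBJ2-4")) {
      addSeg(id, "TRB", "J", "functional", makeFunctionalJ())
    }
    addSeg("TRBC1", "TRB", "C", "functional", makeCRegion())

    # TRBV19-like: 108 codons; codon 104 (1-based) is TAG; Cys at codon 106.
    trbv19 <- paste0(randCodons(108L - 15L),
                     randCodons(9L, exclude = CYS_CODONS),   # codons 94..102
                     randCodons(1L, exclude = CYS_CODONS),   # codon 103
                     "TAG",                                  # codon 104 (nt 309)
                     randCodons(1L, exclude = CYS_CODONS),   # codon 105
                     "TGT", "GCC", "AGC")                    # codons 106..108
    addSeg("TRBV19", "TRB", "V", "pseudogene", trbv19)

    # TRAV9-2-like: build the functional donor consensus first, then derive
    # the defective reference by reverting 8 SNVs and deleting one C.
    repeat {
      fun92 <- makeFunctionalV()
      # codon 45 (nt 133-135, 1-based) must be TCA in the donor consensus;
      # codon 57 (0-based nt 168-170) must end in C with a non-C neighbour
      # so the planted insertion is already left-normalised.
      substr(fun92, 133L, 135L) <- "TCA"
      substr(fun92, 169L, 171L) <- "AAC"
      if (substr(fun92, 172L, 172L) == "C") substr(fun92, 172L, 172L) <- "G"
      snvPos <- c(58L, 73L, 88L, 103L, 118L, 148L, 160L)  # 0-based, interior
      edits <- data.frame(kind = "SNV", position = 133L,
                          ref_allele = "G", obs_allele = "C",
                          stringsAsFactors = FALSE)  # TGA -> TCA at codon 45
      for (p in snvPos) {
        obs <- substr(fun92, p + 1L, p + 1L)
        refBase <- sample(setdiff(DNA_BASES, obs), 1L)
        edits <- rbind(edits, data.frame(kind = "SNV", position = p,
                                         ref_allele = refBase, obs_allele = obs,
                                         stringsAsFactors = FALSE))
      }
      edits <- rbind(edits, data.frame(kind = "insertion", position = 170L,
                                       ref_allele = "", obs_allele = "C",
                                       stringsAsFactors = FALSE))
      # reference = donor consensus with the corrective edits reverted
      ref92 <- fun92
      substr(ref92, 134L, 134L) <- "G"                       # restore TGA stop
      for (k in seq_len(nrow(edits))) {
        if (edits$kind[k] == "SNV" && edits$position[k] != 133L) {
          substr(ref92, edits$position[k] + 1L, edits$position[k] + 1L) <-
            edits$ref_allele[k]
        }
      }
      ref92 <- paste0(substr(ref92, 1L, 170L), substr(ref92, 172L, nchar(ref92)))
      # reference must show downstream stops in the shifted frame, no stop
      # before codon 45, and the defective stop intact
      aaRef <- translateNt(ref92)
      okStops <- grepl("\\*", substr(aaRef, 58L, nchar(aaRef))) &&
        !grepl("\\*", substr(aaRef, 1L, 44L)) &&
        substr(aaRef, 45L, 45L) == "*"
      aaFun <- translateNt(fun92)
      if (okStops && !grepl("\\*", aaFun)) break
    }
    addSeg("TRAV9-2", "TRA", "V", "pseudogene", ref92)

    trbj13 <- makeFunctionalJ(stopCodon2 = TRUE)
    addSeg("TRBJ1-3", "TRB", "J", "pseudogene", trbj13)

    defects <- data.frame(
      segment_id = c("TRBV19", "TRAV9-2", "TRAV9-2", "TRBJ1-3"),
      allele = "01",
      kind = c("in_frame_stop", "in_frame_stop", "frameshift", "in_frame_stop"),
      region = c("FR3", "FR2", "FR2", "J-REGION"),
      nt_position = c(309L, 132L, 170L, 3L),
      note = c("TAG at codon 104; corrected to CAG (Q) by germline T>C in some donors",
               "TGA at codon 45; corrected to TCA (S) by germline G>C",
               "single-base C deletion relative to donor consensus shifts frame",
               "TAG at codon 2; removable by junctional trimming"),
      stringsAsFactors = FALSE)

    ref <- newReferenceSet(do.call(rbind, rows),
                           Biostrings::DNAStringSet(seqs), defects)
    ref <- annotateAnchors(ref)
    attr(ref, "rescueEdits") <- list(
      "TRBV19*01" = data.frame(kind = "SNV", position = 309L,
                               ref_allele = "T", obs_allele = "C",
                               stringsAsFactors = FALSE),
      "TRAV9-2*01" = edits[order(edits$position), , drop = FALSE])
    ref
  })
}

#' Corrective germline edit sets bundled with the synthetic reference
#'
#' @param refset a reference built by [syntheticReference()].
#' @return named list of edit data.frames (see [applyEdits()]), keyed by
#'   segment key, each transforming the defective reference sequence into
#'   the functional donor consensus.
#' @export
syntheticRescueEdits <- function(refset = syntheticReference()) {
  edits <- attr(refset, "rescueEdits")
  if (is.null(edits)) stop("reference carries no bundled rescue edits")
  edits
}
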