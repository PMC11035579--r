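# Pseudogene / ORF rescue analysis: align clonotype consensus sequences
# to defective reference segments, enumerate sequence differences,
# separate donor-shared (germline) from junctional corrections, and
# propose re-annotations.

RESCUE_JUNCTION_WINDOW <- 12L
RESCUE_MIN_IDENTITY <- 0.6
DONOR_SHARED_FRACTION <- 0.9

diffKey <- function(d) paste(d$kind, d$segment_position, d$ref_allele,
                             d$obs_allele, sep = "|")

emptyDiffs <- function() {
  data.frame(kind = character(), segment_position = integer(),
             ref_allele = character(), obs_allele = character(),
             in_junction_window = logical(), stringsAsFactors = FALSE)
}

#' Left-normalise an indel on the reference axis (VCF-style)
#' @noRd
normalizeIndel <- function(refSeq, pos, alleleSeq) {
  len <- nchar(alleleSeq)
  while (pos > 0L &&
         substr(refSeq, pos, pos) == substr(alleleSeq, len, len)) {
    alleleSeq <- paste0(substr(refSeq, pos, pos),
                        substr(alleleSeq, 1L, len - 1L))
    pos <- pos - 1L
  }
  list(position = pos, allele = alleleSeq)
}

inJunctionWindow <- function(start, len, segLength, segmentClass,
                             window = RESCUE_JUNCTION_WINDOW) {
  end <- start + max(len, 1L) - 1L
  if (segmentClass == "J") start < window
  else end >= segLength - window
}

#' Align a clonotype consensus to a reference segment and enumerate diffs
#'
#' Global alignment of the full segment within the consensus
#' ("global-local"). Differences are emitted as SNVs, insertions and
#' deletions on 0-based segment coordinates; indels are left-normalised
#' so the same underlying variant yields the same record across
#' clonotypes. Positions falling in the junction window (V 3'-terminal /
#' J 5'-terminal `junctionWindow` nt) are flagged.
#'
#' @param consensus consensus/contig nucleotide sequence (character).
#' @param segmentSeq reference segment sequence (character).
#' @param segmentClass `"V"` or `"J"` (decides which end is junctional).
#' @param junctionWindow window width in nt.
#' @param minIdentity alignments below this identity return `NULL`
#'   (segment not covered).
#' @return data.frame of diffs (`kind`, `segment_position`, `ref_allele`,
#'   `obs_allele`, `in_junction_window`), or `NULL` when not covered.
#' @export
alignConsensusToSegment <- function(consensus, segmentSeq,
                                    segmentClass = c("V", "J"),
                                    junctionWindow = RESCUE_JUNCTION_WINDOW,
                                    minIdentity = RESCUE_MIN_IDENTITY) {
  segmentClass <- match.arg(segmentClass)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(segmentSeq), Biostrings::DNAString(consensus),
    type = "global-local", substitutionMatrix = swSubstMat(),
    gapOpening = SW_GAP_OPEN, gapExtension = SW_GAP_EXT)
  if (alnIdentity(aln) < minIdentity) return(NULL)

  p <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::subject(aln)), "")[[1L]]
  L <- nchar(segmentSeq)
  diffs <- list()
  pPos <- 0L  # reference bases consumed
  i <- 1L
  while (i <= length(p)) {
    if (p[i] != "-" && s[i] != "-") {
      pPos <- pPos + 1L
      if (p[i] != s[i]) {
        diffs[[length(diffs) + 1L]] <- data.frame(
          kind = "SNV", segment_position = pPos - 1L,
          ref_allele = p[i], obs_allele = s[i], stringsAsFactors = FALSE)
      }
      i <- i + 1L
    } else if (p[i] == "-") {
      j <- i
      while (j <= length(p) && p[j] == "-") j <- j + 1L
      obs <- paste0(s[i:(j - 1L)], collapse = "")
      nrm <- normalizeIndel(segmentSeq, pPos, obs)
      diffs[[length(diffs) + 1L]] <- data.frame(
        kind = "insertion", segment_position = nrm$position,
        ref_allele = "", obs_allele = nrm$allele, stringsAsFactors = FALSE)
      i <- j
    } else {
      j <- i
      while (j <= length(p) && s[j] == "-") j <- j + 1L
      refRun <- paste0(p[i:(j - 1L)], collapse = "")
      start <- pPos  # 0-based start of the deleted run
      nrm <- normalizeIndel(segmentSeq, start, refRun)
      diffs[[length(diffs) + 1L]] <- data.frame(
        kind = "deletion", segment_position = nrm$position,
        ref_allele = nrm$allele, obs_allele = "", stringsAsFactors = FALSE)
      pPos <- pPos + (j - i)
      i <- j
    }
  }
  if (!length(diffs)) return(emptyDiffs())
  out <- do.call(rbind, diffs)
  out$in_junction_window <- mapply(function(pos, ra, oa) {
    inJunctionWindow(pos, max(nchar(ra), nchar(oa)), L, segmentClass,
                     junctionWindow)
  }, out$segment_position, out$ref_allele, out$obs_allele)
  rownames(out) <- NULL
  out
}

#' Infer donor-shared (germline) variants for one segment
#'
#' A difference is donor-shared when it is present in at least
#' `sharedFraction` of the donor's clonotypes using the segment and lies
#' outside the junction window. At least two clonotypes are required;
#' fewer yield an empty set with a reason attribute.
#'
#' @param consensusList character vector of clonotype consensus
#'   sequences from one donor, all using the segment.
#' @param segmentSeq reference segment sequence.
#' @param segmentClass `"V"` or `"J"`.
#' @param sharedFraction sharing threshold (default 0.9).
#' @param junctionWindow junction window width in nt.
#' @return data.frame of shared diffs with an `n_support` column;
#'   attribute `reason` set when inference was not possible.
#' @export
inferDonorReference <- function(consensusList, segmentSeq,
                                segmentClass = c("V", "J"),
                                sharedFraction = DONOR_SHARED_FRACTION,
                                junctionWindow = RESCUE_JUNCTION_WINDOW) {
  segmentClass <- match.arg(segmentClass)
  perClone <- lapply(consensusList, alignConsensusToSegment,
                     segmentSeq = segmentSeq, segmentClass = segmentClass,
                     junctionWindow = junctionWindow)
  covered <- !vapply(perClone, is.null, logical(1L))
  perClone <- perClone[covered]
  out <- cbind(emptyDiffs(), data.frame(n_support = integer()))
  if (length(perClone) < 2L) {
    attr(out, "reason") <- "fewer than 2 covering clonotypes"
    return(out)
  }
  all <- do.call(rbind, perClone)
  all <- all[!all$in_junction_window, , drop = FALSE]
  if (!nrow(all)) return(out)
  keys <- diffKey(all)
  counts <- table(keys)
  shared <- names(counts)[as.integer(counts) >= sharedFraction * length(perClone)]
  if (!length(shared)) return(out)
  first <- match(shared, keys)
  out <- all[first, , drop = FALSE]
  out$n_support <- as.integer(counts[shared])
  out <- out[order(out$segment_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract one consensus per productive clonotype using a segment
#'
#' Convenience for feeding [assessDefects()] from a simulated
#' repertoire: productive contigs calling the segment are grouped per
#' donor, one representative contig per distinct junction (clonotype).
#'
#' @param sim a [SimulatedRepertoire-class].
#' @param segment segment key.
#' @return named list: donor id -> character vector of consensus
#'   sequences.
#' @export
segmentConsensus <- function(sim, segment) {
  contigs <- simContigs(sim)
  use <- contigs$truth_productive %in% TRUE &
    (contigs$v_key %in% segment | contigs$j_key %in% segment)
  u <- contigs[use, , drop = FALSE]
  if (!nrow(u)) return(list())
  lapply(split(u, u$donor_id), function(g) {
    g$contig_nt[!duplicated(g$truth_cdr3_nt)]
  })
}

#' Assess whether recorded defects are corrected, and by what mechanism
#'
#' For every in-frame-stop or frameshift defect of `segment`, clonotype
#' consensus sequences are aligned to the reference segment and the
#' defect locus inspected: a stop codon counts as corrected in a
#' clonotype when the codon is altered to a non-stop or removed entirely
#' (junctional trimming); a frameshift counts as corrected when the
#' non-junctional part of the observed segment translates without stop
#' codons (the frame having been restored by an indel). The mechanism is
#' `germline_shared` when the correcting differences are donor-shared
#' germline variants, `junctional` when they sit in the junction window
#' and vary across clonotypes, otherwise `unresolved`.
#'
#' @param refset the universal reference.
#' @param segment segment key.
#' @param consensusByDonor named list donor -> character vector of
#'   clonotype consensus sequences (see [segmentConsensus()]).
#' @param junctionWindow junction window width in nt.
#' @param sharedFraction donor-sharing threshold.
#' @return data.frame, one row per defect: `segment`, `kind`,
#'   `nt_position`, `status` (corrected / retained / not_covered),
#'   `mechanism` (germline_shared / junctional / unresolved),
#'   `n_clonotypes_examined`, `n_donors_with_usage`,
#'   `frac_corrected`; attribute `evidence`: named list of donor-shared
#'   diff tables per donor.
#' @export
assessDefects <- function(refset, segment, consensusByDonor,
                          junctionWindow = RESCUE_JUNCTION_WINDOW,
                          sharedFraction = DONOR_SHARED_FRACTION) {
  seg <- refSegments(refset)
  if (!segment %in% rownames(seg)) stop("unknown segment: ", segment)
  segRow <- seg[segment, ]
  segSeq <- as.character(refSequences(refset)[[segment]])
  L <- nchar(segSeq)
  def <- refDefects(refset)
  def <- def[segmentKey(def$segment_id, def$allele) == segment &
               def$kind %in% c("in_frame_stop", "frameshift"), , drop = FALSE]
  if (!nrow(def)) stop("segment ", segment, " has no assessable defect")
  cls <- segRow$segment_class

  consensusByDonor <- Filter(length, consensusByDonor)
  donorDiffs <- lapply(consensusByDonor, function(cons) {
    lapply(cons, alignConsensusToSegment, segmentSeq = segSeq,
           segmentClass = cls, junctionWindow = junctionWindow)
  })
  donorShared <- lapply(consensusByDonor, inferDonorReference,
                        segmentSeq = segSeq, segmentClass = cls,
                        sharedFraction = sharedFraction,
                        junctionWindow = junctionWindow)

  assessOne <- function(kind, p) {
    perCloneCorr <- list()   # corrected flag per covering clonotype
    perCloneEvid <- list()   # correcting-diff signature per clonotype
    for (d in names(donorDiffs)) {
      for (diffs in donorDiffs[[d]]) {
        if (is.null(diffs)) next
        if (kind == "in_frame_stop") {
          codonPos <- p + 0:2
          del <- diffs[diffs$kind == "deletion", , drop = FALSE]
          delCover <- logical(3L)
          if (nrow(del)) {
            for (r in seq_len(nrow(del))) {
              run <- del$segment_position[r] + seq_len(nchar(del$ref_allele[r])) - 1L
              delCover <- delCover | codonPos %in% run
            }
          }
          snv <- diffs[diffs$kind == "SNV" & diffs$segment_position %in% codonPos, ,
                       drop = FALSE]
          if (all(delCover)) {
            corrected <- TRUE
          } else if (any(delCover)) {
            corrected <- TRUE  # codon disrupted by partial junctional removal
          } else {
            codon <- strsplit(substr(segSeq, p + 1L, p + 3L), "")[[1L]]
            if (nrow(snv)) {
              codon[match(snv$segment_position, codonPos)] <- snv$obs_allele
            }
            corrected <- !(paste0(codon, collapse = "") %in% STOP_CODONS)
          }
          correcting <- rbind(snv, del[vapply(seq_len(nrow(del)), function(r) {
            run <- del$segment_position[r] + seq_len(nchar(del$ref_allele[r])) - 1L
            any(codonPos %in% run)
          }, logical(1L)), , drop = FALSE])
        } else {  # frameshift
          nonJ <- diffs[!diffs$in_junction_window, , drop = FALSE]
          indels <- nonJ[nonJ$kind %in% c("insertion", "deletion"), , drop = FALSE]
          # rebuild the observed (non-junction) segment sequence and check
          # for an open reading frame
          obs <- segSeq
          if (nrow(nonJ)) obs <- applyEdits(obs, data.frame(
            kind = nonJ$kind, position = nonJ$segment_position,
            ref_allele = nonJ$ref_allele, obs_allele = nonJ$obs_allele,
            stringsAsFactors = FALSE))
          body <- if (cls == "J") substr(obs, junctionWindow + 1L, nchar(obs))
                  else substr(obs, 1L, nchar(obs) - junctionWindow)
          corrected <- !grepl("*", translateNt(body), fixed = TRUE)
          correcting <- indels
        }
        perCloneCorr[[length(perCloneCorr) + 1L]] <- corrected
        perCloneEvid[[length(perCloneEvid) + 1L]] <-
          list(donor = d, diffs = correcting)
      }
    }
    nExamined <- length(perCloneCorr)
    if (nExamined == 0L) {
      return(data.frame(segment = segment, kind = kind, nt_position = p,
                        status = "not_covered", mechanism = "unresolved",
                        n_clonotypes_examined = 0L,
                        n_donors_with_usage = 0L, frac_corrected = NA_real_,
                        stringsAsFactors = FALSE))
    }
    frac <- mean(unlist(perCloneCorr))
    status <- if (frac > 0.5) "corrected" else "retained"

    mechanism <- "unresolved"
    if (status == "corrected") {
      evidCorr <- perCloneEvid[unlist(perCloneCorr)]
      allDiffs <- do.call(rbind, lapply(evidCorr, `[[`, "diffs"))
      if (!is.null(allDiffs) && nrow(allDiffs)) {
        if (all(allDiffs$in_junction_window)) {
          sigs <- vapply(evidCorr, function(e) {
            paste(diffKey(e$diffs), collapse = ",")
          }, character(1L))
          if (length(unique(sigs)) > 1L || length(sigs) == 1L) {
            mechanism <- "junctional"
          }
        } else {
          germOk <- vapply(evidCorr, function(e) {
            d <- e$diffs[!e$diffs$in_junction_window, , drop = FALSE]
            nrow(d) > 0L &&
              all(diffKey(d) %in% diffKey(donorShared[[e$donor]]))
          }, logical(1L))
          if (all(germOk)) mechanism <- "germline_shared"
        }
      }
    }
    data.frame(segment = segment, kind = kind, nt_position = p,
               status = status, mechanism = mechanism,
               n_clonotypes_examined = nExamined,
               n_donors_with_usage = length(consensusByDonor),
               frac_corrected = frac, stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(seq_len(nrow(def)), function(i) {
    assessOne(def$kind[i], def$nt_position[i])
  }))
  rownames(out) <- NULL
  attr(out, "evidence") <- donorShared
  out
}

#' Propose re-annotations from defect assessments and usage
#'
#' Policy: recommend `reannotate_functional` when every assessable
#' defect of a segment is corrected in at least `minDonors` donors and
#' the segment is used in at least `minCells` productive cells or
#' `minClonotypes` unique clonotypes; recommend `donor_specific_note`
#' when corrected in exactly one donor (further dogs would be required);
#' otherwise `no_change`.
#'
#' @param assessments [assessDefects()] output (possibly several
#'   segments row-bound).
#' @param usage [segmentUsage()] output (its `per_segment` table), or
#'   the list returned by `segmentUsage()` itself.
#' @param minDonors,minCells,minClonotypes policy thresholds.
#' @return data.frame per segment: `segment`, `all_corrected`,
#'   `n_donors`, `n_cells`, `n_clonotypes`, `recommendation`.
#' @export
proposeReannotation <- function(assessments, usage, minDonors = 2L,
                                minCells = 100L, minClonotypes = 50L) {
  perSeg <- if (is.list(usage) && !is.data.frame(usage)) usage$per_segment else usage
  out <- do.call(rbind, lapply(split(assessments, assessments$segment),
                               function(a) {
    segId <- a$segment[[1L]]
    allCorr <- all(a$status == "corrected")
    nDonors <- max(a$n_donors_with_usage)
    row <- perSeg[perSeg$segment == segId, , drop = FALSE]
    nCells <- if (nrow(row)) row$n_barcodes[[1L]] else 0L
    nClon <- if (nrow(row)) row$n_clonotypes[[1L]] else 0L
    rec <- if (allCorr && nDonors >= minDonors &&
               (nCells >= minCells || nClon >= minClonotypes)) {
      "reannotate_functional"
    } else if (allCorr && nDonors == 1L) {
      "donor_specific_note"
    } else {
      "no_change"
    }
    data.frame(segment = segId, all_corrected = allCorr, n_donors = nDonors,
               n_cells = nCells, n_clonotypes = nClon, recommendation = rec,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
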