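#' @import methods
NULL

FUNCTIONAL_CLASSES <- c("functional", "ORF", "pseudogene")
SEGMENT_CLASSES <- c("V", "D", "J", "C")
CHAINS <- c("TRA", "TRB")
DEFECT_KINDS <- c("in_frame_stop", "frameshift", "noncanonical_RSS",
                  "nonconserved_motif")
PAIRING_CATEGORIES <- c("single_pair", "tra_only", "trb_only",
                        "extra_tra", "extra_trb", "extra_both")

emptyDefects <- function() {
  data.frame(segment_id = character(), allele = character(),
             kind = character(), region = character(),
             nt_position = integer(), note = character(),
             stringsAsFactors = FALSE)
}

#' TCRReferenceSet: annotated TRA/TRB gene segment reference
#'
#' Container for V, D, J and C gene segments of the dog T-cell receptor
#' alpha and beta loci, with IMGT-style functional classes (functional,
#' ORF, pseudogene), recorded sequence defects, and CDR3 anchor
#' coordinates (the conserved V cysteine codon and the first codon of the
#' J-region \[FW\]-G-X-G motif). All sequences are stored 5'->3' in
#' transcript orientation; coordinates are 0-based.
#'
#' @slot segments data.frame with one row per segment allele: columns
#'   `segment_id`, `allele`, `chain`, `segment_class`, `functional_class`,
#'   `frame` (declared J reading-frame offset, 0 for V/D/C),
#'   `cys_anchor`, `jmotif_anchor` (0-based nt offsets, NA if absent).
#'   Row names are `<segment_id>*<allele>` keys.
#' @slot sequences [Biostrings::DNAStringSet] named by the same keys.
#' @slot defects data.frame of recorded defects (`segment_id`, `allele`,
#'   `kind`, `region`, `nt_position`, `note`).
#'
#' @seealso [readSegmentFasta()], [annotateAnchors()], [syntheticReference()]
#' @export
setClass("TCRReferenceSet",
  representation(segments = "data.frame",
                 sequences = "DNAStringSet",
                 defects = "data.frame"))

setValidity("TCRReferenceSet", function(object) {
  seg <- object@segments
  msgs <- character()
  need <- c("segment_id", "allele", "chain", "segment_class",
            "functional_class", "frame", "cys_anchor", "jmotif_anchor")
  if (!all(need %in% names(seg))) {
    return(paste("segments must have columns:", paste(need, collapse = ", ")))
  }
  keys <- segmentKey(seg$segment_id, seg$allele)
  if (anyDuplicated(keys)) {
    msgs <- c(msgs, paste("duplicate segment keys:",
                          paste(unique(keys[duplicated(keys)]), collapse = ", ")))
  }
  if (!identical(rownames(seg), keys) || !identical(names(object@sequences), keys)) {
    msgs <- c(msgs, "segment keys, row names and sequence names must agree")
  }
  if (!all(seg$chain %in% CHAINS)) msgs <- c(msgs, "chain must be TRA or TRB")
  if (!all(seg$segment_class %in% SEGMENT_CLASSES)) {
    msgs <- c(msgs, "segment_class must be one of V, D, J, C")
  }
  if (!all(seg$functional_class %in% FUNCTIONAL_CLASSES)) {
    msgs <- c(msgs, "functional_class must be functional, ORF or pseudogene")
  }
  w <- Biostrings::width(object@sequences)
  if (any(w == 0L)) msgs <- c(msgs, "empty segment sequence")
  letters <- unique(unlist(strsplit(as.character(object@sequences), "")))
  if (!all(letters %in% c(DNA_BASES, "N"))) {
    msgs <- c(msgs, "sequences must be restricted to ACGTN")
  }
  ca <- seg$cys_anchor
  if (any(!is.na(ca) & (ca %% 3L != 0L | ca + 3L > w))) {
    msgs <- c(msgs, "cys_anchor must be codon-aligned and within the sequence")
  }
  ok <- !is.na(ca)
  if (any(ok)) {
    cod <- substr(as.character(object@sequences[ok]), ca[ok] + 1L, ca[ok] + 3L)
    if (!all(cod %in% CYS_CODONS)) {
      msgs <- c(msgs, "cys_anchor must point at a TGT/TGC codon")
    }
  }
  ja <- seg$jmotif_anchor
  if (any(!is.na(ja) & ((ja - seg$frame) %% 3L != 0L | ja + 3L > w))) {
    msgs <- c(msgs, "jmotif_anchor must be codon-aligned to the declared J frame")
  }
  def <- object@defects
  if (nrow(def)) {
    dk <- segmentKey(def$segment_id, def$allele)
    known <- dk %in% keys
    if (!all(known)) {
      msgs <- c(msgs, paste("defect refers to unknown segment:",
                            paste(unique(dk[!known]), collapse = ", ")))
    }
    if (!all(def$kind %in% DEFECT_KINDS)) {
      msgs <- c(msgs, "unknown defect kind")
    }
    wd <- w[match(dk, keys)]
    if (any(known & (def$nt_position < 0L | def$nt_position >= wd))) {
      msgs <- c(msgs, "defect nt_position outside segment bounds")
    }
    ifs <- known & def$kind == "in_frame_stop"
    if (any(ifs & def$nt_position %% 3L != 0L)) {
      msgs <- c(msgs, "in_frame_stop positions must be codon-aligned")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' TemplateConstruct: in-silico 10x V(D)JC cDNA template
#'
#' The ordered 5'->3' concatenation used for enrichment primer design:
#' Illumina R1 adapter, 16 x N cell barcode, 10 x N UMI, 13-nt template
#' switch oligo, then the V, (D,) J and C gene segments.
#'
#' @slot chain "TRA" or "TRB".
#' @slot parts named character vector of the components, in order.
#' @slot offsets data.frame (`part`, `start`, `end`) of 0-based half-open
#'   component coordinates on the full sequence.
#' @seealso [buildTemplate()]
#' @export
setClass("TemplateConstruct",
  representation(chain = "character", parts = "character",
                 offsets = "data.frame"))

setValidity("TemplateConstruct", function(object) {
  p <- object@parts
  msgs <- character()
  if (nchar(p[["barcode"]]) != 16L) msgs <- c(msgs, "barcode placeholder must be 16 nt")
  if (nchar(p[["umi"]]) != 10L) msgs <- c(msgs, "UMI placeholder must be 10 nt")
  if (nchar(p[["tso"]]) != 13L) msgs <- c(msgs, "TSO must be 13 nt")
  if (!object@chain %in% CHAINS) msgs <- c(msgs, "chain must be TRA or TRB")
  if (sum(nchar(p)) != max(object@offsets$end)) {
    msgs <- c(msgs, "offsets must tile the full sequence")
  }
  if (length(msgs)) msgs else TRUE
})

#' SimulatedRepertoire: synthetic single-cell TRA/TRB repertoire with truth
#'
#' Output of [simulateRepertoire()]. Carries per-contig ground truth
#' (segment choices, trims, nontemplated insertions, CDR3 and
#' productivity) so that annotation and clonotype recovery can be tested
#' against a known answer.
#'
#' @slot contigs data.frame, one row per contig (see [simContigs()]).
#' @slot cells data.frame, one row per cell: `barcode`, `donor_id`,
#'   `clone_id`, `pairing_category`, `n_tra`, `n_trb`,
#'   `truth_clonotype` (key over productive truth CDR3s, NA if none).
#' @slot config the [simulationConfig()] list used.
#' @slot truth list: `clonotypes` (truth clonotype table),
#'   `variants` (planted donor germline edits), `rescue`
#'   (planted defect-rescue mechanism labels).
#' @export
setClass("SimulatedRepertoire",
  representation(contigs = "data.frame", cells = "data.frame",
                 config = "list", truth = "list"))

setValidity("SimulatedRepertoire", function(object) {
  msgs <- character()
  if (anyDuplicated(object@cells$barcode)) msgs <- c(msgs, "barcodes must be unique")
  if (!all(object@contigs$barcode %in% object@cells$barcode)) {
    msgs <- c(msgs, "every contig must belong to an emitted cell")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn TCRReferenceSet-class segment metadata table
#' @param x,object a `TCRReferenceSet`
#' @export
refSegments <- function(x) x@segments

#' @describeIn TCRReferenceSet-class segment sequences as a DNAStringSet
#' @export
refSequences <- function(x) x@sequences

#' @describeIn TCRReferenceSet-class recorded defect table
#' @export
refDefects <- function(x) x@defects

#' @describeIn SimulatedRepertoire-class per-contig table with truth fields
#' @param x,object a `SimulatedRepertoire`
#' @export
simContigs <- function(x) x@contigs

#' @describeIn SimulatedRepertoire-class per-cell table
#' @export
simCells <- function(x) x@cells

#' @describeIn SimulatedRepertoire-class truth tables (clonotypes, planted
#'   variants, rescue mechanism labels)
#' @export
simTruth <- function(x) x@truth

#' @describeIn SimulatedRepertoire-class the simulation configuration used
#' @export
simConfig <- function(x) x@config

#' @describeIn TemplateConstruct-class the full concatenated sequence
#' @param x,object a `TemplateConstruct`
#' @export
fullSequence <- function(x) paste0(x@parts, collapse = "")

setMethod("show", "TCRReferenceSet", function(object) {
  seg <- object@segments
  cat("TCRReferenceSet with", nrow(seg), "segments\n")
  print(table(chain = seg$chain, class = seg$segment_class))
  cat("functional classes:",
      paste(sprintf("%s=%d", names(table(seg$functional_class)),
                    table(seg$functional_class)), collapse = ", "), "\n")
  if (nrow(object@defects)) {
    cat("recorded defects:", nrow(object@defects), "\n")
  }
})

setMethod("show", "TemplateConstruct", function(object) {
  cat("TemplateConstruct (", object@chain, "), ",
      sum(nchar(object@parts)), " nt\n", sep = "")
  print(object@offsets)
})

setMethod("show", "SimulatedRepertoire", function(object) {
  cat("SimulatedRepertoire:", nrow(object@cells), "cells,",
      nrow(object@contigs), "contigs\n")
  cat("profile:", object@config$clonality_profile,
      "| seed:", object@config$seed, "\n")
  if (nrow(object@cells)) {
    print(round(table(object@cells$pairing_category) / nrow(object@cells), 3))
  }
})
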