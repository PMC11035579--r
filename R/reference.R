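# Segment reference model: FASTA IO, anchor discovery, template geometry.
#
# FASTA header dialect (pipe-delimited, IMGT-flavoured):
#   >SEGMENT_ID*ALLELE|CHAIN|CLASS|FUNCTIONAL_CLASS[|FRAME]
# e.g. ">TRBV20*01|TRB|V|functional" or ">TRBJ1-3*01|TRB|J|pseudogene|0".
# FRAME is the declared J reading-frame offset (0..2) and defaults to 0.

#' Assemble a TCRReferenceSet from parsed components
#' @noRd
newReferenceSet <- function(segments, sequences, defects = emptyDefects()) {
  keys <- segmentKey(segments$segment_id, segments$allele)
  rownames(segments) <- keys
  names(sequences) <- keys
  methods::new("TCRReferenceSet", segments = segments,
               sequences = sequences, defects = defects)
}

#' Read an annotated segment reference from FASTA
#'
#' Parses a pipe-delimited, IMGT-flavoured FASTA of TRA/TRB V, D, J and C
#' gene segments (see the header dialect in the package vignette) and an
#' optional defect side table, and returns a validated
#' [TCRReferenceSet-class]. Sequences are uppercased on input.
#'
#' @param path FASTA file path.
#' @param defects optional defect table: a TSV path or data.frame with
#'   columns `segment_id`, `allele`, `kind`, `region`, `nt_position`
#'   (0-based), `note`.
#' @return A [TCRReferenceSet-class] (anchors unset; see
#'   [annotateAnchors()]).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">TRBV20*01|TRB|V|functional", "ATGACCTGTGCCAGC"), fa)
#' ref <- readSegmentFasta(fa)
#' segmentCensus(ref)
#' @export
readSegmentFasta <- function(path, defects = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  fields <- strsplit(headers, "|", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L | nf > 5L)) {
    stop("malformed FASTA header (expected 4-5 pipe-delimited fields): ",
         headers[which(nf < 4L | nf > 5L)[1L]])
  }
  idAllele <- vapply(fields, `[`, character(1L), 1L)
  hasAllele <- grepl("*", idAllele, fixed = TRUE)
  segment_id <- ifelse(hasAllele, sub("\\*.*$", "", idAllele), idAllele)
  allele <- ifelse(hasAllele, sub("^.*\\*", "", idAllele), "01")
  chain <- vapply(fields, `[`, character(1L), 2L)
  segment_class <- vapply(fields, `[`, character(1L), 3L)
  functional_class <- vapply(fields, `[`, character(1L), 4L)
  frame <- vapply(fields, function(f) {
    if (length(f) >= 5L) as.integer(f[5L]) else 0L
  }, integer(1L))

  keys <- segmentKey(segment_id, allele)
  if (anyDuplicated(keys)) {
    stop("duplicate segment record: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  bad <- !functional_class %in% FUNCTIONAL_CLASSES
  if (any(bad)) {
    stop("unknown functional_class token: ",
         paste(unique(functional_class[bad]), collapse = ", "))
  }
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("empty sequence for: ", keys[which(Biostrings::width(seqs) == 0L)[1L]])
  }
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))

  segments <- data.frame(
    segment_id = segment_id, allele = allele, chain = chain,
    segment_class = segment_class, functional_class = functional_class,
    frame = frame, cys_anchor = NA_integer_, jmotif_anchor = NA_integer_,
    stringsAsFactors = FALSE)

  def <- emptyDefects()
  if (!is.null(defects)) {
    def <- if (is.character(defects)) {
      utils::read.delim(defects, stringsAsFactors = FALSE,
                        colClasses = "character")
    } else {
      as.data.frame(defects, stringsAsFactors = FALSE)
    }
    def$allele <- as.character(def$allele)
    def$nt_position <- as.integer(def$nt_position)
  }
  newReferenceSet(segments, seqs, def)
}

#' Write a segment reference back to FASTA (and optional defect TSV)
#'
#' Inverse of [readSegmentFasta()]; a read/write/read round trip yields an
#' identical reference (anchors are rediscovered by [annotateAnchors()],
#' not serialised).
#'
#' @param refset a [TCRReferenceSet-class].
#' @param path output FASTA path.
#' @param defectsPath optional output TSV path for the defect table.
#' @return `path`, invisibly.
#' @export
writeSegmentFasta <- function(refset, path, defectsPath = NULL) {
  seg <- refSegments(refset)
  headers <- paste(segmentKey(seg$segment_id, seg$allele), seg$chain,
                   seg$segment_class, seg$functional_class, seg$frame,
                   sep = "|")
  lines <- character(2L * nrow(seg))
  lines[c(TRUE, FALSE)] <- paste0(">", headers)
  lines[c(FALSE, TRUE)] <- as.character(refSequences(refset))
  writeLines(lines, path)
  if (!is.null(defectsPath)) {
    utils::write.table(refDefects(refset), defectsPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Census of segments per chain, class and functional class
#'
#' @param refset a [TCRReferenceSet-class].
#' @return data.frame with columns `chain`, `segment_class`,
#'   `functional_class`, `n`.
#' @export
segmentCensus <- function(refset) {
  seg <- refSegments(refset)
  out <- as.data.frame(table(chain = seg$chain, segment_class = seg$segment_class,
                             functional_class = seg$functional_class),
                       stringsAsFactors = FALSE)
  names(out)[4L] <- "n"
  out <- out[out$n > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$chain, out$segment_class, out$functional_class), , drop = FALSE]
}

#' Locate CDR3 anchors on V and J segments
#'
#' Each V segment gains `cys_anchor`: the 0-based offset of the
#' codon-aligned TGT/TGC closest to the 3' end within the final 15 codons
#' (the conserved CDR3-opening cysteine). Each J segment gains
#' `jmotif_anchor`: the first codon of the last \[FW\]-G-X-G motif in the
#' J translation at its declared frame (the CDR3-closing
#' phenylalanine/tryptophan). Segments lacking the motif are flagged with
#' a `nonconserved_motif` defect rather than rejected.
#'
#' @param refset a [TCRReferenceSet-class].
#' @return The reference with anchors filled in.
#' @export
annotateAnchors <- function(refset) {
  seg <- refSegments(refset)
  seqs <- as.character(refSequences(refset))
  def <- refDefects(refset)

  for (i in which(seg$segment_class == "V")) {
    s <- seqs[[i]]
    L <- nchar(s)
    nCodon <- L %/% 3L
    from <- max(0L, (nCodon - 15L)) * 3L
    starts <- seq.int(from, L - 3L, by = 3L)
    codons <- substr(rep(s, length(starts)), starts + 1L, starts + 3L)
    hit <- which(codons %in% CYS_CODONS)
    if (length(hit)) {
      seg$cys_anchor[i] <- starts[hit[length(hit)]]
    } else if (!anyFlagged(def, seg[i, ], "nonconserved_motif")) {
      def <- rbind(def, data.frame(
        segment_id = seg$segment_id[i], allele = seg$allele[i],
        kind = "nonconserved_motif", region = "V-REGION",
        nt_position = max(0L, L - 3L),
        note = "no codon-aligned Cys in final 15 codons",
        stringsAsFactors = FALSE))
    }
  }

  for (i in which(seg$segment_class == "J")) {
    s <- seqs[[i]]
    fr <- seg$frame[i]
    aa <- translateNt(substr(s, fr + 1L, nchar(s)))
    m <- gregexpr("[FW]G.G", aa)[[1L]]
    if (m[1L] != -1L) {
      last <- m[length(m)]
      seg$jmotif_anchor[i] <- fr + (last - 1L) * 3L
    } else if (!anyFlagged(def, seg[i, ], "nonconserved_motif")) {
      def <- rbind(def, data.frame(
        segment_id = seg$segment_id[i], allele = seg$allele[i],
        kind = "nonconserved_motif", region = "J-REGION",
        nt_position = 0L, note = "no [FW]GXG motif in declared frame",
        stringsAsFactors = FALSE))
    }
  }
  newReferenceSet(seg, refSequences(refset), def)
}

anyFlagged <- function(def, segRow, kind) {
  nrow(def) > 0L && any(def$segment_id == segRow$segment_id &
                        def$allele == segRow$allele & def$kind == kind)
}

#' Adapter configuration for the 10x-style template construct
#'
#' @param r1Adapter Illumina read-1 sequencing adapter.
#' @param tso 13-nt template switch oligo.
#' @return named list used by [buildTemplate()].
#' @export
templateAdapters <- function(r1Adapter = "CTACACGACGCTCTTCCGATCT",
                             tso = "TTTCTTATATGGG") {
  stopifnot(nchar(tso) == 13L)
  list(r1_adapter = toupper(r1Adapter), tso = toupper(tso))
}

#' Build the in-silico V(D)JC cDNA template
#'
#' Concatenates, 5' to 3': R1 adapter, 16 x N cell barcode placeholder,
#' 10 x N UMI placeholder, 13-nt TSO, then the V, (D,) J and C segments.
#' Component offsets are recorded so a downstream primer-design step can
#' target the C region.
#'
#' @param refset a [TCRReferenceSet-class].
#' @param vKey,jKey,cKey segment keys (`"TRBV1*01"` style); all must share
#'   a chain.
#' @param dKey optional D segment key; only valid for TRB.
#' @param adapters see [templateAdapters()].
#' @return a [TemplateConstruct-class].
#' @export
buildTemplate <- function(refset, vKey, jKey, cKey, dKey = NULL,
                          adapters = templateAdapters()) {
  seg <- refSegments(refset)
  keys <- c(v = vKey, j = jKey, c = cKey)
  if (!is.null(dKey)) keys <- c(keys, d = dKey)
  missing <- setdiff(keys, rownames(seg))
  if (length(missing)) stop("unknown segment key: ", paste(missing, collapse = ", "))
  if (!cKey %in% rownames(seg)[seg$segment_class == "C"]) {
    stop("cKey must name a C segment")
  }
  chains <- seg[keys, "chain"]
  if (length(unique(chains)) != 1L) {
    stop("chain mismatch among segments: ", paste(unique(chains), collapse = ", "))
  }
  chain <- chains[[1L]]
  if (!is.null(dKey) && chain != "TRB") stop("D segment supplied for a non-TRB template")

  seqs <- as.character(refSequences(refset))
  parts <- c(r1_adapter = adapters$r1_adapter,
             barcode = strrep("N", 16L),
             umi = strrep("N", 10L),
             tso = adapters$tso,
             v = seqs[[vKey]])
  if (!is.null(dKey)) parts <- c(parts, d = seqs[[dKey]])
  parts <- c(parts, j = seqs[[jKey]], c = seqs[[cKey]])

  ends <- cumsum(nchar(parts))
  offsets <- data.frame(part = names(parts),
                        start = c(0L, utils::head(ends, -1L)),
                        end = unname(ends), stringsAsFactors = FALSE)
  methods::new("TemplateConstruct", chain = chain, parts = parts,
               offsets = offsets)
}
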