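# Segment reference model: FASTA parsing, anchors, census, template.

test_that("segment FASTA parsing handles the documented dialect and errors", {
  fa <- writeTestFasta(list(
    list("TRBV20*01|TRB|V|functional", "atgacctgtgccagc"),
    list("TRBJ1-3*01|TRB|J|pseudogene", "ACATAGTTTGGACAAGGCACC")))
  def <- data.frame(segment_id = "TRBJ1-3", allele = "01",
                    kind = "in_frame_stop", region = "J-REGION",
                    nt_position = 3L, note = "stop in codon 2")
  ref <- readSegmentFasta(fa, defects = def)
  seg <- refSegments(ref)
  expect_equal(nrow(seg), 2L)
  # lowercase input is uppercased, content unchanged
  expect_equal(as.character(refSequences(ref)[["TRBV20*01"]]),
               "ATGACCTGTGCCAGC")
  census <- segmentCensus(ref)
  expect_equal(census$n[census$segment_class == "V"], 1L)
  expect_equal(census$n[census$segment_class == "J"], 1L)
  expect_equal(nrow(refDefects(ref)), 1L)

  # duplicate keys are a hard error naming the duplicate
  dup <- writeTestFasta(list(
    list("TRBV20*01|TRB|V|functional", "ACGT"),
    list("TRBV20*01|TRB|V|functional", "ACGG")))
  expect_error(readSegmentFasta(dup), "TRBV20\\*01")
  # unknown functional class token
  badClass <- writeTestFasta(list(list("TRBV1*01|TRB|V|mystery", "ACGT")))
  expect_error(readSegmentFasta(badClass), "mystery")
  # empty sequence
  emptySeq <- writeTestFasta(list(list("TRBV1*01|TRB|V|functional", "")))
  expect_error(readSegmentFasta(emptySeq), "empty sequence")
})

test_that("census conserves segment counts per chain", {
  ref <- sharedRef()
  seg <- refSegments(ref)
  census <- segmentCensus(ref)
  for (ch in c("TRA", "TRB")) {
    expect_equal(sum(census$n[census$chain == ch]), sum(seg$chain == ch))
  }
})

test_that("anchor discovery finds Cys and [FW]GXG motifs and flags absences", {
  v <- paste0(strrep("GCT", 40L), "TGT", "GCC", "AGC")  # ...C A S
  jGood <- paste0("GCAAAC", "TTTGGACAAGGC", strrep("ACC", 4L))
  jBad <- strrep("GCAAAC", 6L)  # no [FW]GXG anywhere
  fa <- writeTestFasta(list(
    list("TRAV1*01|TRA|V|functional", v),
    list("TRAJ1*01|TRA|J|functional", jGood),
    list("TRAJ2*01|TRA|J|ORF", jBad)))
  ref <- annotateAnchors(readSegmentFasta(fa))
  seg <- refSegments(ref)
  expect_equal(seg["TRAV1*01", "cys_anchor"], 120L)
  expect_equal(substr(v, 121L, 123L), "TGT")
  expect_equal(seg["TRAJ1*01", "jmotif_anchor"], 6L)
  # anchor round-trip: the anchored codons translate to C and [FW]G.G
  expect_true(is.na(seg["TRAJ2*01", "jmotif_anchor"]))
  def <- refDefects(ref)
  expect_true(any(def$segment_id == "TRAJ2" & def$kind == "nonconserved_motif"))
})

test_that("anchor round-trip holds across the whole default reference", {
  ref <- sharedRef()
  seg <- refSegments(ref)
  seqs <- as.character(refSequences(ref))
  vs <- which(!is.na(seg$cys_anchor))
  for (i in vs) {
    codon <- substr(seqs[[i]], seg$cys_anchor[i] + 1L, seg$cys_anchor[i] + 3L)
    expect_true(codon %in% c("TGT", "TGC"))
  }
  js <- which(!is.na(seg$jmotif_anchor))
  for (i in js) {
    a <- seg$jmotif_anchor[i]
    aa4 <- Biostrings::GENETIC_CODE[substring(seqs[[i]],
                                              a + c(1L, 4L, 7L, 10L),
                                              a + c(3L, 6L, 9L, 12L))]
    expect_match(paste0(aa4, collapse = ""), "^[FW]G.G$")
  }
})

test_that("write -> read round trip reproduces the reference", {
  ref <- sharedRef()
  fa <- tempfile(fileext = ".fasta")
  defTsv <- tempfile(fileext = ".tsv")
  writeSegmentFasta(ref, fa, defectsPath = defTsv)
  back <- annotateAnchors(readSegmentFasta(fa, defects = defTsv))
  expect_equal(refSegments(back), refSegments(ref))
  expect_equal(as.character(refSequences(back)),
               as.character(refSequences(ref)))
  expect_equal(refDefects(back)[order(refDefects(back)$segment_id,
                                      refDefects(back)$kind), ],
               refDefects(ref)[order(refDefects(ref)$segment_id,
                                     refDefects(ref)$kind), ],
               ignore_attr = TRUE)
})

test_that("template construct has the 10x geometry and component sum", {
  ref <- sharedRef()
  tpl <- buildTemplate(ref, "TRBV1*01", "TRBJ1-1*01", "TRBC1*01",
                       dKey = "TRBD1*01")
  parts <- tpl@parts
  expect_equal(nchar(parts[["barcode"]]), 16L)
  expect_equal(nchar(parts[["umi"]]), 10L)
  expect_equal(nchar(parts[["tso"]]), 13L)
  w <- Biostrings::width(refSequences(ref))
  names(w) <- names(refSequences(ref))
  expect_equal(nchar(fullSequence(tpl)),
               nchar(parts[["r1_adapter"]]) + 16L + 10L + 13L +
                 w[["TRBV1*01"]] + w[["TRBD1*01"]] + w[["TRBJ1-1*01"]] +
                 w[["TRBC1*01"]])
  # offsets tile the sequence
  off <- tpl@offsets
  expect_equal(off$start, c(0L, utils::head(off$end, -1L)))

  # chain mismatch and missing C are errors
  expect_error(buildTemplate(ref, "TRAV1*01", "TRBJ1-1*01", "TRBC1*01"),
               "chain mismatch")
  expect_error(buildTemplate(ref, "TRBV1*01", "TRBJ1-1*01", "TRBV2*01"),
               "C segment")
  # D for a TRA template is rejected
  expect_error(buildTemplate(ref, "TRAV1*01", "TRAJ1*01", "TRAC*01",
                             dKey = "TRBD1*01"),
               "chain mismatch")
})
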