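# Pseudogene rescue: diff enumeration, donor-reference inference,
# defect assessment mechanisms, re-annotation policy.

test_that("diff enumeration: identity, planted SNV, planted indel profile", {
  ref <- sharedRef()
  segSeq <- as.character(refSequences(ref)[["TRBV19*01"]])
  flank <- strrep("GCA", 30L)
  expect_equal(nrow(alignConsensusToSegment(paste0(segSeq, flank), segSeq, "V")),
               0L)
  # single planted T->C at the recorded stop position
  edited <- applyEdits(segSeq, data.frame(kind = "SNV", position = 309L,
                                          ref_allele = "T", obs_allele = "C"))
  d <- alignConsensusToSegment(paste0(edited, flank), segSeq, "V")
  expect_equal(nrow(d), 1L)
  expect_equal(d$kind, "SNV")
  expect_equal(d$segment_position, 309L)
  expect_equal(d$obs_allele, "C")
  expect_false(d$in_junction_window)

  # the bundled multi-variant profile: exactly 9 diffs, 8 SNVs + 1 insertion
  ref92 <- as.character(refSequences(ref)[["TRAV9-2*01"]])
  edits <- syntheticRescueEdits(ref)[["TRAV9-2*01"]]
  donor <- applyEdits(ref92, edits)
  d9 <- alignConsensusToSegment(paste0(donor, flank), ref92, "V")
  d9 <- d9[!d9$in_junction_window, , drop = FALSE]
  expect_equal(nrow(d9), 9L)
  expect_equal(sum(d9$kind == "SNV"), 8L)
  expect_equal(sum(d9$kind == "insertion"), 1L)
  expect_setequal(d9$segment_position, edits$position)

  # unrelated sequence: segment not covered
  expect_null(alignConsensusToSegment(strrep("CAGT", 100L), segSeq, "V"))
})

test_that("indels are left-normalised to a canonical position", {
  refSeq <- paste0("GGAT", "CCCC", "GGAT")  # C-run: insertions shift left
  withIns <- paste0("GGAT", "CCCCC", "GGAT")
  d <- alignConsensusToSegment(paste0(withIns, strrep("AGT", 40L)),
                               paste0(refSeq, strrep("AGT", 40L)), "V")
  ins <- d[d$kind == "insertion", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$segment_position, 4L)  # leftmost equivalent placement
})

test_that("donor-shared inference applies the 90% threshold and window rule", {
  ref <- sharedRef()
  segSeq <- as.character(refSequences(ref)[["TRBV19*01"]])
  flank <- strrep("GCA", 30L)
  shared <- applyEdits(segSeq, data.frame(kind = "SNV", position = 100L,
                                          ref_allele = substr(segSeq, 101L, 101L),
                                          obs_allele = setdiff(c("A", "C", "G", "T"),
                                                               substr(segSeq, 101L, 101L))[1L]))
  private <- applyEdits(shared, data.frame(kind = "SNV", position = 50L,
                                           ref_allele = substr(shared, 51L, 51L),
                                           obs_allele = setdiff(c("A", "C", "G", "T"),
                                                                substr(shared, 51L, 51L))[1L]))
  cons <- c(rep(paste0(shared, flank), 19L), paste0(private, flank))
  ds <- inferDonorReference(cons, segSeq, "V")
  expect_equal(ds$segment_position, 100L)   # 20/20 shared
  expect_false(50L %in% ds$segment_position) # 1/20 is not donor-shared
  # a diff inside the junction window is excluded even when universal
  L <- nchar(segSeq)
  jw <- applyEdits(segSeq, data.frame(kind = "SNV", position = L - 2L,
                                      ref_allele = substr(segSeq, L - 1L, L - 1L),
                                      obs_allele = setdiff(c("A", "C", "G", "T"),
                                                           substr(segSeq, L - 1L, L - 1L))[1L]))
  ds2 <- inferDonorReference(rep(paste0(jw, flank), 10L), segSeq, "V")
  expect_equal(nrow(ds2), 0L)
  # fewer than two clonotypes: empty set with a reason
  one <- inferDonorReference(paste0(shared, flank), segSeq, "V")
  expect_equal(nrow(one), 0L)
  expect_match(attr(one, "reason"), "fewer than 2")
})

test_that("the three rescue mechanisms are classified from simulation", {
  ref <- sharedRef()
  # (a) germline SNV in one carrier donor only
  planA <- plantDefectRescue(ref, "germline_snv", "TRBV19*01",
                             donors = "donor1")
  simA <- simulateRepertoire(ref, simulationConfig(
    seed = 81, n_cells = 400, n_donors = 4, rescue = list(planA)))
  consA <- segmentConsensus(simA, "TRBV19*01")
  expect_equal(names(consA), "donor1")  # productive usage only in the carrier
  assA <- assessDefects(ref, "TRBV19*01", consA)
  expect_equal(assA$status, "corrected")
  expect_equal(assA$mechanism, "germline_shared")

  # (b) multi-variant germline consensus across donors
  planB <- plantDefectRescue(ref, "germline_consensus", "TRAV9-2*01",
                             donors = paste0("donor", 1:3))
  simB <- simulateRepertoire(ref, simulationConfig(
    seed = 82, n_cells = 400, n_donors = 3, rescue = list(planB)))
  assB <- assessDefects(ref, "TRAV9-2*01", segmentConsensus(simB, "TRAV9-2*01"))
  expect_equal(nrow(assB), 2L)  # the stop and the frameshift
  expect_true(all(assB$status == "corrected"))
  expect_true(all(assB$mechanism == "germline_shared"))
  ev <- attr(assB, "evidence")[["donor1"]]
  expect_equal(nrow(ev), 9L)

  # (c) junctional correction of the J-region stop, all donors
  planC <- plantDefectRescue(ref, "junctional", "TRBJ1-3*01")
  simC <- simulateRepertoire(ref, simulationConfig(
    seed = 83, n_cells = 500, n_donors = 3, rescue = list(planC)))
  consC <- segmentConsensus(simC, "TRBJ1-3*01")
  expect_equal(length(consC), 3L)  # productive usage in every donor
  assC <- assessDefects(ref, "TRBJ1-3*01", consC)
  expect_equal(assC$status, "corrected")
  expect_equal(assC$mechanism, "junctional")

  # no rescue planted: donor sequences are identical to the reference and
  # the defective segment is never used productively
  simNone <- simulateRepertoire(ref, simulationConfig(seed = 84, n_cells = 100))
  expect_equal(nrow(simTruth(simNone)$variants), 0L)
  expect_equal(length(segmentConsensus(simNone, "TRBV19*01")), 0L)
})

test_that("junctional rescue is refused for a defect outside the window", {
  ref <- sharedRef()
  expect_error(plantDefectRescue(ref, "junctional", "TRBV19*01"),
               "junction window")
  expect_error(plantDefectRescue(ref, "germline_snv", "TRBV1*01",
                                 donors = "donor1"),
               "no in_frame_stop")
})

test_that("assessments are invariant to clonotype input order", {
  ref <- sharedRef()
  planC <- plantDefectRescue(ref, "junctional", "TRBJ1-3*01")
  sim <- simulateRepertoire(ref, simulationConfig(
    seed = 85, n_cells = 300, n_donors = 2, rescue = list(planC)))
  cons <- segmentConsensus(sim, "TRBJ1-3*01")
  shuffled <- lapply(cons, rev)
  a1 <- assessDefects(ref, "TRBJ1-3*01", cons)
  a2 <- assessDefects(ref, "TRBJ1-3*01", shuffled)
  expect_equal(a1[, c("status", "mechanism", "n_clonotypes_examined")],
               a2[, c("status", "mechanism", "n_clonotypes_examined")])
})

test_that("re-annotation policy distinguishes broad, donor-specific and unused", {
  usage <- data.frame(segment = c("TRBJ1-3*01", "TRBV19*01", "TRAV9-2*01"),
                      chain = c("TRB", "TRB", "TRA"), class = c("J", "V", "V"),
                      n_barcodes = c(500L, 40L, 10L),
                      n_clonotypes = c(300L, 30L, 8L),
                      stringsAsFactors = FALSE)
  mk <- function(segment, status, nDonors) {
    data.frame(segment = segment, kind = "in_frame_stop", nt_position = 0L,
               status = status, mechanism = "junctional",
               n_clonotypes_examined = 10L, n_donors_with_usage = nDonors,
               frac_corrected = 1, stringsAsFactors = FALSE)
  }
  ass <- rbind(mk("TRBJ1-3*01", "corrected", 5L),
               mk("TRBV19*01", "corrected", 1L),
               mk("TRAV9-2*01", "retained", 3L))
  rec <- proposeReannotation(ass, usage)
  expect_equal(rec$recommendation[rec$segment == "TRBJ1-3*01"],
               "reannotate_functional")
  expect_equal(rec$recommendation[rec$segment == "TRBV19*01"],
               "donor_specific_note")
  expect_equal(rec$recommendation[rec$segment == "TRAV9-2*01"], "no_change")
})
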