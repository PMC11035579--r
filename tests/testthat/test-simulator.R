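# Repertoire generator: identity cases, determinism, truth bookkeeping,
# clonality profiles, pairing noise, export round trips.

test_that("zero trimming and zero insertion reproduce exact reference concatenation", {
  ref <- sharedRef()
  cfg <- simulationConfig(seed = 5, n_cells = 10,
                          trim_model = list(p = 0.5, max = 0L),
                          d_trim_model = list(p = 0.5, max = 0L),
                          insertion_model = list(p = 0.5, max = 0L))
  seqs <- as.character(refSequences(ref))
  for (chain in c("TRA", "TRB")) {
    rr <- simulateRearrangement(ref, cfg, chain, n = 6L,
                                requireProductive = FALSE)
    expected <- if (chain == "TRA") {
      paste0(seqs[rr$v_key], seqs[rr$j_key], seqs[rr$c_key])
    } else {
      paste0(seqs[rr$v_key], seqs[rr$d_key], seqs[rr$j_key], seqs[rr$c_key])
    }
    expect_equal(rr$contig_nt, unname(expected))
  }
})

test_that("rearrangement draws are deterministic under a fixed seed", {
  ref <- sharedRef()
  cfg <- simulationConfig(seed = 99, n_cells = 10)
  a <- simulateRearrangement(ref, cfg, "TRB", n = 20L)
  b <- simulateRearrangement(ref, cfg, "TRB", n = 20L)
  expect_identical(a, b)
})

test_that("truth productivity agrees with a translate-and-scan oracle", {
  # oracle: re-derive frame and stop status from the assembled string,
  # independently of the generator's arithmetic
  ref <- sharedRef()
  seg <- refSegments(ref)
  seqs <- as.character(refSequences(ref))
  cfg <- simulationConfig(seed = 31, n_cells = 10)
  code <- Biostrings::GENETIC_CODE
  translate <- function(s) {
    k <- nchar(s) %/% 3L
    starts <- seq.int(1L, by = 3L, length.out = k)
    paste0(code[substring(s, starts, starts + 2L)], collapse = "")
  }
  for (chain in c("TRA", "TRB")) {
    rr <- simulateRearrangement(ref, cfg, chain, n = 500L,
                                requireProductive = FALSE)
    for (i in seq_len(nrow(rr))) {
      r <- rr[i, ]
      vLen <- nchar(seqs[[r$v_key]]) - r$v_trim
      jSeq <- substr(seqs[[r$j_key]], r$j_trim + 1L, nchar(seqs[[r$j_key]]))
      jStart <- vLen + nchar(r$ins1) +
        (if (chain == "TRB") nchar(seqs[[r$d_key]]) - r$d5_trim - r$d3_trim else 0L) +
        nchar(r$ins2)
      jEnd <- jStart + nchar(jSeq)
      jAnchorPos <- jStart + seg[r$j_key, "jmotif_anchor"] - r$j_trim
      cys <- seg[r$v_key, "cys_anchor"]
      scan <- substr(r$contig_nt, 1L, 3L * ceiling(jEnd / 3))
      aa <- translate(scan)
      oracle <- (jAnchorPos %% 3L == 0L) &&          # junction in frame
        !grepl("*", aa, fixed = TRUE) &&             # no stop through J
        substr(aa, cys / 3L + 1L, cys / 3L + 1L) == "C" &&
        (vLen >= cys + 3L) && (seg[r$j_key, "jmotif_anchor"] >= r$j_trim)
      expect_equal(r$truth_productive, oracle)
      # junction in frame is necessary for productivity
      if (r$truth_productive) {
        expect_equal(nchar(r$truth_cdr3_nt) %% 3L, 0L)
        expect_equal(r$truth_cdr3_aa, translate(r$truth_cdr3_nt))
      }
    }
  }
})

test_that("contigs reassemble exactly from their truth components", {
  ref <- sharedRef()
  cfg <- simulationConfig(seed = 8, n_cells = 60)
  sim <- simulateRepertoire(ref, cfg)
  ct <- simContigs(sim)
  seqs <- as.character(refSequences(ref))
  vPart <- substr(seqs[ct$v_key], 1L, nchar(seqs[ct$v_key]) - ct$v_trim)
  jPart <- substr(seqs[ct$j_key], ct$j_trim + 1L, nchar(seqs[ct$j_key]))
  dPart <- ifelse(is.na(ct$d_key), "",
                  substr(seqs[ifelse(is.na(ct$d_key), ct$v_key, ct$d_key)],
                         ct$d5_trim + 1L,
                         nchar(seqs[ifelse(is.na(ct$d_key), ct$v_key, ct$d_key)]) - ct$d3_trim))
  rebuilt <- paste0(vPart, ct$ins1, dPart, ct$ins2, jPart, seqs[ct$c_key])
  expect_equal(ct$contig_nt, unname(rebuilt))
})

test_that("repertoire conservation and degenerate sizes", {
  ref <- sharedRef()
  sim <- simulateRepertoire(ref, simulationConfig(seed = 2, n_cells = 1))
  expect_equal(nrow(simCells(sim)), 1L)
  expect_equal(length(unique(simCells(sim)$clone_id)), 1L)
  expect_error(simulationConfig(seed = 1, n_cells = 0), "n_cells")

  sim2 <- simulateRepertoire(ref, simulationConfig(seed = 3, n_cells = 150))
  expect_equal(nrow(simCells(sim2)), 150L)
  expect_false(anyDuplicated(simCells(sim2)$barcode) > 0L)
  # cells of one clone share identical productive CDR3 sets pre-noise
  pre <- simulateRepertoire(ref, simulationConfig(seed = 3, n_cells = 80),
                            pairing = FALSE)
  cells <- simCells(pre)
  perClone <- split(cells$truth_clonotype, cells$clone_id)
  expect_true(all(vapply(perClone, function(x) length(unique(x)) == 1L,
                         logical(1L))))
})

test_that("monoclonal dominant-clone fraction is recovered", {
  ref <- sharedRef()
  cfg <- simulationConfig(seed = 17, n_cells = 8000,
                          clonality_profile = "monoclonal")
  sim <- simulateRepertoire(ref, cfg)
  cells <- simCells(sim)
  top <- max(table(cells$clone_id)) / nrow(cells)
  sigma <- sqrt(0.88 * 0.12 / 8000)
  expect_lt(abs(top - 0.88), 3 * sigma)
})

test_that("polyclonal repertoires are near maximally diverse", {
  ref <- sharedRef()
  cfg <- simulationConfig(seed = 23, n_cells = 5000)
  sim <- simulateRepertoire(ref, cfg)
  counts <- table(simCells(sim)$clone_id)
  div <- inverseSimpson(as.numeric(counts) / sum(counts))
  expect_gte(div, 0.5 * length(counts))
})

test_that("pairing model: degenerate preset and validation", {
  ref <- sharedRef()
  pp <- c(single_pair = 1, tra_only = 0, trb_only = 0,
          extra_tra = 0, extra_trb = 0, extra_both = 0)
  sim <- simulateRepertoire(ref, simulationConfig(seed = 4, n_cells = 100,
                                                  pairing_model = pp))
  cells <- simCells(sim)
  expect_true(all(cells$n_tra == 1L & cells$n_trb == 1L))
  bad <- pp; bad[["single_pair"]] <- 0.9
  expect_error(simulationConfig(seed = 1, pairing_model = bad), "sum to 1")
  expect_error(simulationConfig(seed = 1, pairing_model = pp[-1]),
               "categories")
})

test_that("applyPairingModel drops and duplicates chains per category", {
  ref <- sharedRef()
  pre <- simulateRepertoire(ref, simulationConfig(seed = 12, n_cells = 300),
                            pairing = FALSE)
  noisy <- applyPairingModel(pre, ref)
  cells <- simCells(noisy)
  expect_setequal(unique(cells$pairing_category),
                  intersect(names(pairingPreset("v2")),
                            unique(cells$pairing_category)))
  # chain counts match the assigned category
  chk <- data.frame(cat = cells$pairing_category, a = cells$n_tra,
                    b = cells$n_trb)
  expect_true(all(chk$a[chk$cat == "single_pair"] == 1L &
                  chk$b[chk$cat == "single_pair"] == 1L))
  expect_true(all(chk$a[chk$cat == "tra_only"] == 1L &
                  chk$b[chk$cat == "tra_only"] == 0L))
  expect_true(all(chk$a[chk$cat == "extra_tra"] == 2L &
                  chk$b[chk$cat == "extra_tra"] == 1L))
  expect_true(all(chk$a[chk$cat == "extra_both"] == 2L &
                  chk$b[chk$cat == "extra_both"] == 2L))
  # applying to an already-noisy repertoire is rejected
  expect_error(applyPairingModel(noisy, ref), "exactly 1 TRA")
})

test_that("export round-trips and is byte-identical under the same seed", {
  ref <- sharedRef()
  cfg <- simulationConfig(seed = 77, n_cells = 40)
  sim <- simulateRepertoire(ref, cfg)
  d1 <- file.path(tempfile(), "a")
  files <- exportSimulation(sim, d1)
  airr <- readAirr(files[["airr"]])
  ct <- simContigs(sim)
  expect_equal(nrow(airr), nrow(ct))
  expect_equal(airr$junction, ct$truth_cdr3_nt)
  expect_equal(airr$productive, ct$truth_productive)
  fa <- Biostrings::readDNAStringSet(files[["fasta"]])
  expect_equal(length(fa), nrow(ct))
  expect_equal(unname(as.character(fa)), ct$contig_nt)

  sim2 <- simulateRepertoire(ref, cfg)
  d2 <- file.path(tempfile(), "b")
  files2 <- exportSimulation(sim2, d2)
  for (f in names(files)) {
    expect_identical(readLines(files[[f]]), readLines(files2[[f]]))
  }
})
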