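# Clonotype construction, pairing taxonomy, diversity and summaries.

test_that("clonotypes group cells by exact productive CDR3 nt multisets", {
  ann <- rbind(
    annRow("bc1", "TRA", "TGTGCAGCATTT"), annRow("bc1", "TRB", "TGTGCCAAATTT"),
    annRow("bc2", "TRA", "TGTGCAGCATTT"), annRow("bc2", "TRB", "TGTGCCAAATTT"),
    annRow("bc3", "TRA", "TGTGCGGCATTT"), annRow("bc3", "TRB", "TGTGCCAAATTT"),
    annRow("bc4", "TRA", NA_character_, productive = FALSE))
  cl <- buildClonotypes(ann)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$n_cells, c(2L, 1L))
  expect_equal(sum(cl$proportion), 1)
  expect_equal(attr(cl, "n_excluded"), 1L)
  # same aa, one silent nt difference -> distinct clonotypes (bc3)
  expect_equal(attr(cl, "cells")$clonotype_id[
    attr(cl, "cells")$barcode == "bc3"], "clonotype2")
  # clonotype recovery equals the simulator truth partition
  ref <- sharedRef()
  sim <- simulateRepertoire(ref, simulationConfig(seed = 61, n_cells = 150))
  simAnn <- annotateContigs(sim, ref)
  simCl <- buildClonotypes(simAnn)
  cellMap <- attr(simCl, "cells")
  truth <- simCells(sim)
  m <- merge(cellMap, truth[, c("barcode", "truth_clonotype")], by = "barcode")
  # recovered partition == truth partition (same label blocks)
  expect_equal(length(unique(m$clonotype_id)),
               length(unique(m$truth_clonotype)))
  expect_true(all(tapply(m$truth_clonotype, m$clonotype_id,
                         function(x) length(unique(x))) == 1L))
})

test_that("pairing categories follow the chain-count taxonomy", {
  expect_equal(classifyPairing(1L, 1L), "single_pair")
  expect_equal(classifyPairing(1L, 0L), "tra_only")
  expect_equal(classifyPairing(0L, 1L), "trb_only")
  expect_equal(classifyPairing(2L, 1L), "extra_tra")
  expect_equal(classifyPairing(1L, 2L), "extra_trb")
  expect_equal(classifyPairing(2L, 2L), "extra_both")
  expect_equal(classifyPairing(3L, 1L), "gt2_chains")
  expect_error(classifyPairing(0L, 0L), "impossible")

  allPairs <- data.frame(n_tra = rep(1L, 5L), n_trb = rep(1L, 5L),
                         n_cells = 1:5)
  ps <- pairingSummary(allPairs)
  expect_equal(unname(ps[["single_pair"]]), 1)
  expect_equal(sum(ps), 1, tolerance = 1e-12)
  expect_error(pairingSummary(allPairs[0L, ]), "no clonotypes")
})

test_that("inverse Simpson matches the closed form and its bounds", {
  expect_equal(inverseSimpson(1), 1)
  n <- 137L
  expect_equal(inverseSimpson(rep(1 / n, n)), n)
  expect_equal(inverseSimpson(c(0.5, 0.25, 0.25)), 1 / 0.375)
  expect_error(inverseSimpson(numeric()), "empty")
  expect_error(inverseSimpson(c(0.5, 0.4)), "sum to 1")
  # independent cross-check against vegan on random count vectors
  skip_if_not_installed("vegan")
  set.seed(9)
  for (i in 1:5) {
    counts <- rpois(50, 4) + 1L
    p <- counts / sum(counts)
    expect_equal(inverseSimpson(p),
                 unname(vegan::diversity(counts, index = "invsimpson")))
  }
})

test_that("concentrating cell mass never increases inverse Simpson", {
  set.seed(11)
  for (i in 1:20) {
    counts <- sort(rpois(30, 5) + 1L, decreasing = TRUE)
    before <- inverseSimpson(counts / sum(counts))
    donor <- length(counts)
    moved <- counts
    moved[1L] <- moved[1L] + moved[donor]
    moved <- moved[-donor]
    after <- inverseSimpson(moved / sum(moved))
    expect_lte(after, before + 1e-12)
  }
})

test_that("rank-bin proportions: extremes and normalisation", {
  mono <- clonotypeBinProportions(c(1000L))
  expect_equal(unname(mono[["1"]]), 1)
  set.seed(3)
  counts <- rpois(2500, 1) + 1L
  bins <- clonotypeBinProportions(counts)
  expect_equal(sum(bins), 1, tolerance = 1e-12)
  expect_true(all(names(bins) == c("1", "2-5", "6-10", "11-100",
                                   "101-1000", ">1000")))
})

test_that("downsampling a single-clonotype sample always returns diversity 1", {
  ds <- downsampleDiversity(rep("c1", 500L), nTarget = 500L, nPerm = 20L,
                            seed = 5)
  expect_equal(ds$inverse_simpson, 1)
  expect_equal(unname(ds$bin_fractions[["1"]]), 1)
  expect_error(downsampleDiversity(rep("c1", 5L), nPerm = 0L), "nPerm")
})

test_that("per-subset diversity conserves cells and finds planted structure", {
  cellClon <- data.frame(barcode = paste0("bc", 1:40),
                         clonotype_id = c(rep("dom", 18L), paste0("s", 1:22)),
                         stringsAsFactors = FALSE)
  types <- data.frame(barcode = paste0("bc", 1:40),
                      cell_type = c(rep("CD8", 20L), rep("CD4", 20L)),
                      stringsAsFactors = FALSE)
  sd <- subsetDiversity(cellClon, types)
  expect_equal(sum(sd$n_cells), 40L)
  cd8 <- sd[sd$cell_type == "CD8", ]
  expect_equal(cd8$top_clonotype_proportion, 18 / 20)
  cd4 <- sd[sd$cell_type == "CD4", ]
  expect_equal(cd4$inverse_simpson, 20)
  # one label -> equals the whole-sample result
  one <- subsetDiversity(cellClon,
                         data.frame(barcode = cellClon$barcode,
                                    cell_type = "all"))
  expect_equal(one$inverse_simpson,
               inverseSimpson(table(cellClon$clonotype_id) / 40))
  expect_error(subsetDiversity(cellClon,
                               data.frame(barcode = "zz", cell_type = "x")),
               "no labeled")
})

test_that("segment usage census observes all weighted functional segments", {
  ref <- sharedRef()
  seg <- refSegments(ref)
  # zero weight on one functional V -> never used, census marks it
  w <- stats::setNames(rep(1, nrow(seg)), rownames(seg))
  w[seg$functional_class != "functional"] <- 0
  w[["TRAV5*01"]] <- 0
  cfg <- simulationConfig(seed = 71, n_cells = 600, usage_weights = w)
  sim <- simulateRepertoire(ref, cfg)
  ann <- annotateContigs(sim, ref)
  su <- segmentUsage(ann, ref)
  expect_false("TRAV5*01" %in% su$per_segment$segment)
  cov <- su$coverage
  travCov <- cov[cov$chain == "TRA" & cov$segment_class == "V" &
                   cov$functional_class == "functional", ]
  expect_equal(travCov$observed, travCov$known - 1L)
  # all other functional classes fully observed at this depth
  trbCov <- cov[cov$chain == "TRB" & cov$segment_class == "J" &
                  cov$functional_class == "functional", ]
  expect_equal(trbCov$observed, trbCov$known)
  # usage matrix total equals the number of called chain observations
  expect_equal(sum(su$usage$n_barcodes),
               sum(!is.na(ann$v_call) & !is.na(ann$j_call)))
})

test_that("reference combination lengths equal brute-force sums", {
  ref <- sharedRef()
  ld <- lengthDistributions(annotateContigs(character(), ref)[0, ], ref)
  combos <- ld$reference_combinations
  seg <- refSegments(ref)
  w <- Biostrings::width(refSequences(ref))
  names(w) <- rownames(seg)
  dLen <- w[["TRBD1*01"]]
  for (i in sample(nrow(combos), 20L)) {
    r <- combos[i, ]
    expected <- w[[r$v_call]] + w[[r$j_call]] +
      if (r$chain == "TRB") dLen else 0L
    expect_equal(r$reference_length, expected)
  }
  nV <- table(seg$chain[seg$segment_class == "V"])
  nJ <- table(seg$chain[seg$segment_class == "J"])
  expect_equal(nrow(combos), sum(nV * nJ))
})

test_that("summary metrics match hand computation on a 5-cell fixture", {
  ann <- rbind(
    annRow("c1", "TRA", "TGTGCAGCATTT"), annRow("c1", "TRB", "TGTGCCAAATTT"),
    annRow("c2", "TRA", "TGTGCAGCATTT"), annRow("c2", "TRB", "TGTGCCAAATTT"),
    annRow("c3", "TRB", "TGTCCCAAATTT"),
    annRow("c4", "TRA", NA_character_, productive = FALSE),
    annRow("c5", "TRA", "TGTAAAGCATTT"))
  cl <- buildClonotypes(ann)
  met <- summaryMetrics(ann, cl)
  expect_equal(met$estimated_cells, 5L)
  expect_equal(met$cells_with_tra_contig, 4 / 5)
  expect_equal(met$cells_with_productive_trb, 3 / 5)
  expect_equal(met$cells_with_productive_pair, 2 / 5)
  expect_equal(met$unique_clonotypes, 3L)
  # frequencies: clonotype of c1+c2 (2 cells), c3 (1), c5 (1)
  expect_equal(met$paired_clonotype_diversity,
               inverseSimpson(c(2, 1, 1) / 4))
})
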