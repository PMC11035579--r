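# Clonotype construction, pairing taxonomy and repertoire statistics.

#' Build clonotypes from annotated contigs
#'
#' A clonotype is the exact sorted multiset of productive (chain, CDR3
#' nucleotide) sequences carried by a cell — one or more TRA and/or one
#' or more TRB chains expressed in one or more cells. Cells with no
#' productive chain are excluded (and counted in the `n_excluded`
#' attribute).
#'
#' @param annotations contig annotation table ([annotateContigs()] output
#'   or any data.frame with `barcode`, `chain`, `cdr3_nt`, `cdr3_aa`,
#'   `productive`).
#' @return data.frame ranked by descending cell count (ties by key):
#'   `clonotype_id`, `key`, `cdr3s_nt`, `cdr3s_aa`, `n_tra`, `n_trb`,
#'   `n_cells`, `proportion`. Attributes: `cells` (data.frame barcode ->
#'   clonotype_id), `n_excluded`.
#' @export
buildClonotypes <- function(annotations) {
  prod <- annotations[annotations$productive %in% TRUE &
                        !is.na(annotations$cdr3_nt), , drop = FALSE]
  allBc <- unique(annotations$barcode)
  if (nrow(prod) == 0L) {
    out <- data.frame(clonotype_id = character(), key = character(),
                      cdr3s_nt = character(), cdr3s_aa = character(),
                      n_tra = integer(), n_trb = integer(),
                      n_cells = integer(), proportion = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "cells") <- data.frame(barcode = character(),
                                     clonotype_id = character(),
                                     stringsAsFactors = FALSE)
    attr(out, "n_excluded") <- length(allBc)
    return(out)
  }
  lab <- paste0(prod$chain, ":", prod$cdr3_nt)
  aa <- paste0(prod$chain, ":", ifelse(is.na(prod$cdr3_aa), "", prod$cdr3_aa))
  byCell <- split(seq_len(nrow(prod)), prod$barcode)
  keys <- vapply(byCell, function(ix) paste(sort(lab[ix]), collapse = ";"),
                 character(1L))
  aaKeys <- vapply(byCell, function(ix) {
    paste(aa[ix][order(lab[ix])], collapse = ";")
  }, character(1L))
  nTra <- vapply(byCell, function(ix) sum(prod$chain[ix] == "TRA"), integer(1L))
  nTrb <- vapply(byCell, function(ix) sum(prod$chain[ix] == "TRB"), integer(1L))

  tab <- table(keys)
  ord <- order(-as.integer(tab), names(tab))
  key <- names(tab)[ord]
  first <- match(key, keys)
  out <- data.frame(
    clonotype_id = paste0("clonotype", seq_along(key)),
    key = key,
    cdr3s_nt = key,
    cdr3s_aa = aaKeys[first],
    n_tra = nTra[first], n_trb = nTrb[first],
    n_cells = as.integer(tab)[ord],
    stringsAsFactors = FALSE)
  out$proportion <- out$n_cells / sum(out$n_cells)
  rownames(out) <- NULL
  cellMap <- data.frame(barcode = names(keys),
                        clonotype_id = out$clonotype_id[match(keys, out$key)],
                        stringsAsFactors = FALSE)
  attr(out, "cells") <- cellMap
  attr(out, "n_excluded") <- length(setdiff(allBc, names(keys)))
  out
}

#' Classify the TRA/TRB pairing of clonotypes
#'
#' Category from the chain counts (a = TRA, b = TRB): (1,1) single_pair,
#' (1,0) tra_only, (0,1) trb_only, (2,1) extra_tra, (1,2) extra_trb,
#' (2,2) extra_both, anything with more than 2 of either chain
#' gt2_chains.
#'
#' @param nTra,nTrb integer vectors of per-clonotype chain counts, or a
#'   clonotype table from [buildClonotypes()] as the first argument.
#' @return character vector of categories.
#' @export
classifyPairing <- function(nTra, nTrb = NULL) {
  if (is.data.frame(nTra)) {
    nTrb <- nTra$n_trb
    nTra <- nTra$n_tra
  }
  stopifnot(length(nTra) == length(nTrb))
  out <- character(length(nTra))
  for (i in seq_along(nTra)) {
    a <- nTra[i]; b <- nTrb[i]
    out[i] <- if (a == 0L && b == 0L) {
      stop("clonotype with zero chains should be impossible by construction")
    } else if (a > 2L || b > 2L) "gt2_chains"
    else if (a == 1L && b == 1L) "single_pair"
    else if (a == 1L && b == 0L) "tra_only"
    else if (a == 0L && b == 1L) "trb_only"
    else if (a == 2L && b == 1L) "extra_tra"
    else if (a == 1L && b == 2L) "extra_trb"
    else if (a == 2L && b == 2L) "extra_both"
    else if (a == 2L && b == 0L) "extra_tra"   # duplicated single chain
    else "extra_trb"                           # (0,2)
  }
  out
}

#' Pairing-category fractions over clonotypes
#'
#' @param clonotypes a [buildClonotypes()] table (or any data.frame with
#'   `n_tra`, `n_trb`; rows may be weighted by `n_cells` via `weighted`).
#' @param weighted if TRUE, fractions are over cells rather than
#'   clonotypes.
#' @return named numeric vector over the pairing categories plus
#'   `gt2_chains`, summing to 1.
#' @export
pairingSummary <- function(clonotypes, weighted = FALSE) {
  if (nrow(clonotypes) == 0L) stop("no clonotypes to summarise")
  cat <- classifyPairing(clonotypes)
  w <- if (weighted) clonotypes$n_cells else rep(1L, nrow(clonotypes))
  lev <- c(PAIRING_CATEGORIES, "gt2_chains")
  out <- vapply(lev, function(l) sum(w[cat == l]), numeric(1L)) / sum(w)
  out
}

#' Inverse Simpson diversity index
#'
#' `1 / sum(p_i^2)` over clonotype frequencies: 1 for a minimally diverse
#' (monoclonal) sample; equal to the number of clonotypes when all are
#' equally frequent.
#'
#' @param proportions non-negative frequencies summing to 1 (within
#'   1e-9).
#' @return the index, a number in `[1, length(proportions)]`.
#' @export
inverseSimpson <- function(proportions) {
  if (length(proportions) == 0L) stop("empty proportion vector")
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1 (got ", format(sum(proportions)), ")")
  }
  1 / sum(proportions^2)
}

#' Diversity of a clonotype table
#'
#' @param clonotypes [buildClonotypes()] output.
#' @param pairedOnly restrict the frequency vector to clonotypes with at
#'   least one TRA and one TRB chain ("paired clonotype diversity").
#' @return list: `inverse_simpson`, `n_cells`, `n_clonotypes`.
#' @export
clonotypeDiversity <- function(clonotypes, pairedOnly = FALSE) {
  cl <- clonotypes
  if (pairedOnly) cl <- cl[cl$n_tra >= 1L & cl$n_trb >= 1L, , drop = FALSE]
  if (nrow(cl) == 0L) stop("no clonotypes in the frequency vector")
  p <- cl$n_cells / sum(cl$n_cells)
  list(inverse_simpson = inverseSimpson(p),
       n_cells = sum(cl$n_cells), n_clonotypes = nrow(cl))
}

CLONOTYPE_BINS <- list("1" = c(1L, 1L), "2-5" = c(2L, 5L),
                       "6-10" = c(6L, 10L), "11-100" = c(11L, 100L),
                       "101-1000" = c(101L, 1000L), ">1000" = c(1001L, .Machine$integer.max))

#' Cell fractions by clonotype rank bin
#'
#' Clonotypes are ranked in descending order of cell count (ties broken
#' by clonotype key) and cells are binned by the rank of their clonotype:
#' 1, 2-5, 6-10, 11-100, 101-1000, >1000.
#'
#' @param cellCounts per-clonotype cell counts, ranked (a
#'   [buildClonotypes()] table is accepted and re-ranked defensively).
#' @return named numeric vector of cell fractions per bin, summing to 1.
#' @export
clonotypeBinProportions <- function(cellCounts) {
  if (is.data.frame(cellCounts)) {
    ord <- order(-cellCounts$n_cells, cellCounts$key)
    cellCounts <- cellCounts$n_cells[ord]
  } else {
    cellCounts <- sort(cellCounts, decreasing = TRUE)
  }
  if (!length(cellCounts)) stop("no clonotypes")
  rank <- seq_along(cellCounts)
  total <- sum(cellCounts)
  vapply(CLONOTYPE_BINS, function(b) {
    sum(cellCounts[rank >= b[1L] & rank <= b[2L]]) / total
  }, numeric(1L))
}

#' Permutation downsampling of clonotype labels
#'
#' Draws `nTarget` cells with replacement from the cell-level clonotype
#' labels and recomputes clonotype cell proportions per permutation.
#' Per-clonotype proportions are averaged across the permutations and
#' then ranked and binned (so a clonotype keeps its identity across
#' permutations, as when average cell proportions are computed across
#' downsampling permutations and then plotted by rank bin); the Inverse
#' Simpson index is averaged over the per-permutation values. Defaults
#' follow the study design: 100 permutations at 1,850 cells (the
#' smallest clonotyped sample).
#'
#' @param labels character vector: one clonotype label per cell.
#' @param nTarget cells per permutation.
#' @param nPerm number of permutations.
#' @param seed RNG seed.
#' @return list: `bin_fractions` (from the averaged per-clonotype
#'   proportions), `inverse_simpson` (mean over permutations),
#'   `proportions` (averaged per-clonotype proportions),
#'   `per_permutation_diversity` (numeric vector).
#' @export
downsampleDiversity <- function(labels, nTarget = 1850L, nPerm = 100L,
                                seed = 1L) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) stop("no clonotype labels")
  if (nTarget < 1L) stop("nTarget must be at least 1")
  if (nPerm < 1L) stop("nPerm must be at least 1")
  lev <- sort(unique(labels))
  f <- factor(labels, levels = lev)
  withSeed(seed, {
    meanProp <- numeric(length(lev))
    div <- numeric(nPerm)
    for (i in seq_len(nPerm)) {
      draw <- sample.int(length(labels), nTarget, replace = TRUE)
      counts <- tabulate(f[draw], nbins = length(lev))
      meanProp <- meanProp + counts / nTarget
      div[i] <- inverseSimpson(counts[counts > 0L] / nTarget)
    }
    meanProp <- meanProp / nPerm
    ord <- order(-meanProp, lev)
    rank <- seq_along(lev)
    props <- meanProp[ord]
    bins <- vapply(CLONOTYPE_BINS, function(b) {
      sum(props[rank >= b[1L] & rank <= b[2L]])
    }, numeric(1L))
    list(bin_fractions = bins,
         inverse_simpson = mean(div),
         proportions = stats::setNames(meanProp, lev),
         per_permutation_diversity = div)
  })
}

#' Per-cell-type diversity
#'
#' Splits clonotyped cells by a cell-type label (e.g. CD4/CD8 from
#' expression-based typing) and reports diversity and top-clonotype
#' proportion per subset. Unlabeled cells are excluded and counted.
#'
#' @param cellClonotypes data.frame `barcode`, `clonotype_id` (the
#'   `cells` attribute of [buildClonotypes()]).
#' @param cellTypes data.frame `barcode`, `cell_type`.
#' @return data.frame per cell type: `cell_type`, `n_cells`,
#'   `n_clonotypes`, `inverse_simpson`, `top_clonotype_proportion`;
#'   attribute `n_unlabeled`.
#' @export
subsetDiversity <- function(cellClonotypes, cellTypes) {
  m <- merge(cellClonotypes, cellTypes, by = "barcode")
  if (nrow(m) == 0L) stop("no labeled clonotyped cells")
  out <- do.call(rbind, lapply(split(m, m$cell_type), function(g) {
    counts <- as.integer(table(g$clonotype_id))
    p <- counts / sum(counts)
    data.frame(cell_type = g$cell_type[[1L]], n_cells = nrow(g),
               n_clonotypes = length(counts),
               inverse_simpson = inverseSimpson(p),
               top_clonotype_proportion = max(p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "n_unlabeled") <- nrow(cellClonotypes) - nrow(m)
  out
}

#' V x J usage counts and functional-coverage census
#'
#' Counts cell barcodes per V x J combination and chain (a cell may count
#' toward several segments when it carries multiple chains), and reports
#' the observed/known coverage per chain, segment class and functional
#' class. When `clonotypes`/`sample` information is available, also
#' reports unique clonotypes per segment (per sample when a `sample`
#' column exists).
#'
#' @param annotations [annotateContigs()] output; an optional `sample`
#'   column stratifies the per-segment clonotype counts.
#' @param refset the reference the calls were made against.
#' @return list: `usage` (chain, v_call, j_call, n_barcodes), `coverage`
#'   (chain, segment_class, functional_class, known, observed,
#'   coverage), `per_segment` (segment, chain, class, n_barcodes,
#'   n_clonotypes).
#' @export
segmentUsage <- function(annotations, refset) {
  seg <- refSegments(refset)
  ann <- annotations[!is.na(annotations$v_call) & !is.na(annotations$j_call), ,
                     drop = FALSE]
  unknown <- setdiff(c(ann$v_call, ann$j_call), rownames(seg))
  if (length(unknown)) {
    warning("segment call absent from reference: ",
            paste(unknown, collapse = ", "))
  }
  usage <- as.data.frame(table(chain = ann$chain, v_call = ann$v_call,
                               j_call = ann$j_call), stringsAsFactors = FALSE)
  names(usage)[4L] <- "n_barcodes"
  usage <- usage[usage$n_barcodes > 0L, , drop = FALSE]
  rownames(usage) <- NULL

  observed <- unique(c(ann$v_call, ann$j_call))
  cov <- do.call(rbind, lapply(split(seq_len(nrow(seg)),
                                     paste(seg$chain, seg$segment_class,
                                           seg$functional_class)), function(ix) {
    data.frame(chain = seg$chain[ix[1L]],
               segment_class = seg$segment_class[ix[1L]],
               functional_class = seg$functional_class[ix[1L]],
               known = length(ix),
               observed = sum(rownames(seg)[ix] %in% observed),
               stringsAsFactors = FALSE)
  }))
  cov <- cov[cov$segment_class %in% c("V", "J"), , drop = FALSE]
  cov$coverage <- cov$observed / cov$known
  rownames(cov) <- NULL

  longSeg <- rbind(
    data.frame(segment = ann$v_call, chain = ann$chain, class = "V",
               barcode = ann$barcode,
               cdr3 = ifelse(is.na(ann$cdr3_nt), "", ann$cdr3_nt),
               stringsAsFactors = FALSE),
    data.frame(segment = ann$j_call, chain = ann$chain, class = "J",
               barcode = ann$barcode,
               cdr3 = ifelse(is.na(ann$cdr3_nt), "", ann$cdr3_nt),
               stringsAsFactors = FALSE))
  perSeg <- do.call(rbind, lapply(split(longSeg, longSeg$segment), function(g) {
    data.frame(segment = g$segment[[1L]], chain = g$chain[[1L]],
               class = g$class[[1L]],
               n_barcodes = length(unique(g$barcode)),
               n_clonotypes = length(unique(g$cdr3[g$cdr3 != ""])),
               stringsAsFactors = FALSE)
  }))
  rownames(perSeg) <- NULL
  list(usage = usage, coverage = cov, per_segment = perSeg)
}

#' Contig, CDR3 and reference-combination length summaries
#'
#' @param annotations [annotateContigs()] output.
#' @param refset reference for the V-J (TRB: V-D-J) combination lengths,
#'   computed by summing segment lengths over all per-chain combinations.
#' @return list of data.frames: `contig` (per-chain median and range of
#'   contig lengths), `cdr3` (per-chain nt and aa medians/ranges),
#'   `reference_combinations`.
#' @export
lengthDistributions <- function(annotations, refset) {
  summarise <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(median = NA_real_, min = NA_real_, max = NA_real_))
    c(median = stats::median(x), min = min(x), max = max(x))
  }
  chains <- c("TRA", "TRB")
  contig <- do.call(rbind, lapply(chains, function(ch) {
    s <- summarise(annotations$contig_length[annotations$chain %in% ch])
    data.frame(chain = ch, t(s), stringsAsFactors = FALSE)
  }))
  cdr3 <- do.call(rbind, lapply(chains, function(ch) {
    sel <- annotations$chain %in% ch
    nt <- summarise(nchar(annotations$cdr3_nt[sel]))
    aa <- summarise(nchar(annotations$cdr3_aa[sel]))
    data.frame(chain = ch, nt_median = nt[["median"]], nt_min = nt[["min"]],
               nt_max = nt[["max"]], aa_median = aa[["median"]],
               aa_min = aa[["min"]], aa_max = aa[["max"]],
               stringsAsFactors = FALSE)
  }))
  seg <- refSegments(refset)
  w <- Biostrings::width(refSequences(refset))
  combos <- do.call(rbind, lapply(chains, function(ch) {
    vIdx <- which(seg$chain == ch & seg$segment_class == "V")
    jIdx <- which(seg$chain == ch & seg$segment_class == "J")
    dIdx <- which(seg$chain == ch & seg$segment_class == "D")
    dLen <- if (length(dIdx)) w[dIdx[[1L]]] else 0L
    grid <- expand.grid(v = vIdx, j = jIdx)
    data.frame(chain = ch, v_call = rownames(seg)[grid$v],
               j_call = rownames(seg)[grid$j],
               reference_length = w[grid$v] + dLen + w[grid$j],
               stringsAsFactors = FALSE)
  }))
  rownames(combos) <- NULL
  list(contig = contig, cdr3 = cdr3, reference_combinations = combos)
}

#' Table-2-style sample summary metrics
#'
#' @param annotations [annotateContigs()] output.
#' @param clonotypes [buildClonotypes()] output for the same sample.
#' @param umiCounts optional named (by contig_id) or parallel vector of
#'   per-contig UMI counts for the median-UMIs metric.
#' @return named list of summary metrics; percentages are fractions of
#'   estimated cells.
#' @export
summaryMetrics <- function(annotations, clonotypes, umiCounts = NULL) {
  bs <- barcodeSummary(annotations)
  n <- nrow(bs)
  div <- clonotypeDiversity(clonotypes)
  out <- list(
    estimated_cells = n,
    cells_with_tra_contig = mean(bs$has_tra),
    cells_with_trb_contig = mean(bs$has_trb),
    cells_with_cdr3_tra = mean(bs$cdr3_tra),
    cells_with_cdr3_trb = mean(bs$cdr3_trb),
    cells_with_productive_tra = mean(bs$productive_tra),
    cells_with_productive_trb = mean(bs$productive_trb),
    cells_with_productive_pair = mean(bs$productive_pair),
    unique_clonotypes = nrow(clonotypes),
    paired_clonotype_diversity = div$inverse_simpson)
  if (!is.null(umiCounts)) {
    perCell <- tapply(umiCounts, annotations$barcode, sum)
    out$median_umis_per_cell <- stats::median(perCell)
  }
  out
}
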