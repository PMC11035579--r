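# Synthetic single-cell V(D)J repertoire generator.
#
# A repertoire is drawn clone-first: a clonality profile fixes clone mass,
# every clone receives one TRA and one TRB rearrangement (junctional
# trimming + nontemplated insertion against a donor-specific germline),
# cells are sampled from clones, and a chain-pairing noise model then
# drops or duplicates chains per cell. All per-contig ground truth
# (segments, trims, insertions, CDR3, productivity) is kept for oracle
# testing of the downstream annotator and clonotype analytics.

#' Chain-pairing category presets
#'
#' Category probabilities over \{single_pair, tra_only, trb_only,
#' extra_tra, extra_trb, extra_both\} matching the per-clonotype pairing
#' statistics observed with 10x 5' v1 and v2 kits in canine scTCRseq.
#'
#' @param kit `"v2"` (default) or `"v1"`.
#' @return named numeric vector summing to 1.
#' @export
pairingPreset <- function(kit = c("v2", "v1")) {
  kit <- match.arg(kit)
  if (kit == "v2") {
    c(single_pair = 0.698, tra_only = 0.025, trb_only = 0.157,
      extra_tra = 0.066, extra_trb = 0.033, extra_both = 0.021)
  } else {
    c(single_pair = 0.309, tra_only = 0.202, trb_only = 0.409,
      extra_tra = 0.023, extra_trb = 0.054, extra_both = 0.003)
  }
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the repertoire generator. The
#' defaults are the package's declared study conditions: truncated
#' geometric trimming (p = 0.25, max 8 nt per end) and nontemplated
#' insertion (p = 0.25, max 12 nt, uniform ACGT), the v2 pairing preset,
#' a monoclonal dominant-clone fraction of 0.88 and oligoclonal expanded
#' fractions (0.10, 0.05, 0.03).
#'
#' @param seed integer RNG seed; `(config, seed)` fully determines output.
#' @param n_cells number of cells to emit.
#' @param clonality_profile `"polyclonal"`, `"oligoclonal"` or
#'   `"monoclonal"`.
#' @param dominant_fraction monoclonal top-clone cell fraction, in (0,1].
#' @param expanded_fractions oligoclonal expanded-clone fractions; must
#'   sum to at most 1.
#' @param n_background_clones background clone count; default: `n_cells`
#'   (polyclonal, oligoclonal) or 400 (monoclonal).
#' @param usage_weights named numeric vector of per-segment sampling
#'   weights (keys like `"TRBV1*01"`); defaults to uniform over
#'   functional segments, 0 elsewhere.
#' @param trim_model,d_trim_model list `p`, `max`: truncated geometric
#'   trimming per V/J end (and per D end for TRB).
#' @param insertion_model list `p`, `max`: truncated geometric insertion
#'   length, uniform ACGT composition.
#' @param pairing_model category probabilities; see [pairingPreset()].
#' @param germline_model list `snv_rate` (per-base donor V SNV rate) and
#'   `variants` (explicit edits: data.frame with `donor_id`, `segment`,
#'   `kind`, `position`, `ref_allele`, `obs_allele`).
#' @param umi_model list `tra_lambda`, `trb_lambda` for shifted-Poisson
#'   per-chain UMI counts (bookkeeping only).
#' @param n_donors,donor_ids donors; cells are split evenly.
#' @param rescue list of plans from [plantDefectRescue()].
#' @param error_rate optional per-base substitution rate applied to the
#'   emitted contig sequence (truth fields are left at the error-free
#'   values); default 0.
#' @param productive_only if TRUE (default) clone rearrangements are
#'   redrawn until productive, mirroring a repertoire of reported
#'   clonotypes; set FALSE to emit unselected rearrangements.
#' @param max_retries rejection-sampling bound per rearrangement.
#' @return a validated config list (class `tcr_sim_config`).
#' @export
simulationConfig <- function(seed = 1L,
                             n_cells = 1000L,
                             clonality_profile = c("polyclonal", "oligoclonal",
                                                   "monoclonal"),
                             dominant_fraction = 0.88,
                             expanded_fractions = c(0.10, 0.05, 0.03),
                             n_background_clones = NULL,
                             usage_weights = NULL,
                             trim_model = list(p = 0.25, max = 8L),
                             d_trim_model = list(p = 0.25, max = 4L),
                             insertion_model = list(p = 0.25, max = 12L),
                             pairing_model = pairingPreset("v2"),
                             germline_model = list(snv_rate = 0, variants = NULL),
                             umi_model = list(tra_lambda = 6.6, trb_lambda = 12.5),
                             n_donors = 1L,
                             donor_ids = NULL,
                             rescue = list(),
                             error_rate = 0,
                             productive_only = TRUE,
                             max_retries = 200L) {
  clonality_profile <- match.arg(clonality_profile)
  if (n_cells < 1L) stop("n_cells must be at least 1")
  checkPairingProbs(pairing_model)
  if (dominant_fraction <= 0 || dominant_fraction > 1) {
    stop("dominant_fraction must be in (0, 1]")
  }
  if (any(expanded_fractions <= 0) || sum(expanded_fractions) > 1) {
    stop("expanded_fractions must be in (0,1] and sum to at most 1")
  }
  if (is.null(donor_ids)) donor_ids <- paste0("donor", seq_len(n_donors))
  if (length(donor_ids) != n_donors) stop("donor_ids must have length n_donors")
  structure(list(
    seed = as.integer(seed), n_cells = as.integer(n_cells),
    clonality_profile = clonality_profile,
    dominant_fraction = dominant_fraction,
    expanded_fractions = expanded_fractions,
    n_background_clones = n_background_clones,
    usage_weights = usage_weights,
    trim_model = trim_model, d_trim_model = d_trim_model,
    insertion_model = insertion_model, pairing_model = pairing_model,
    germline_model = germline_model, umi_model = umi_model,
    n_donors = as.integer(n_donors), donor_ids = donor_ids,
    rescue = rescue, error_rate = error_rate,
    productive_only = productive_only, max_retries = as.integer(max_retries)
  ), class = "tcr_sim_config")
}

checkPairingProbs <- function(probs) {
  if (!setequal(names(probs), PAIRING_CATEGORIES)) {
    stop("pairing probabilities must name exactly the categories: ",
         paste(PAIRING_CATEGORIES, collapse = ", "))
  }
  if (any(probs < 0)) stop("pairing probabilities must be >= 0")
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("pairing probabilities must sum to 1 (got ", format(sum(probs)), ")")
  }
  invisible(TRUE)
}

#' Plan a germline or junctional rescue of a defective segment
#'
#' Three mechanisms can be planted: `"germline_snv"` (a corrective SNV in
#' selected donors only), `"germline_consensus"` (a multi-variant donor
#' consensus, e.g. SNVs plus a frame-restoring insertion, in the listed
#' donors), and `"junctional"` (no germline change; the defect must sit
#' inside the junction window so that per-clonotype trimming can remove
#' it). Plans are handed to [simulationConfig()] via `rescue = list(...)`;
#' the planned segment automatically enters the usage weights.
#'
#' @param refset the universal reference.
#' @param mechanism one of `"germline_snv"`, `"germline_consensus"`,
#'   `"junctional"`.
#' @param segment segment key, e.g. `"TRBV19*01"`.
#' @param donors carrier donor ids (germline mechanisms only).
#' @param edits corrective edits ([applyEdits()] format); defaults to the
#'   bundled [syntheticRescueEdits()] entry when available.
#' @param junction_window junction window width in nt (V 3' / J 5').
#' @return a rescue plan (class `tcr_rescue_plan`).
#' @export
plantDefectRescue <- function(refset,
                              mechanism = c("germline_snv", "germline_consensus",
                                            "junctional"),
                              segment, donors = NULL, edits = NULL,
                              junction_window = 12L) {
  mechanism <- match.arg(mechanism)
  seg <- refSegments(refset)
  if (!segment %in% rownames(seg)) stop("unknown segment: ", segment)
  row <- seg[segment, ]
  def <- refDefects(refset)
  def <- def[segmentKey(def$segment_id, def$allele) == segment &
               def$kind %in% c("in_frame_stop", "frameshift"), , drop = FALSE]
  if (nrow(def) == 0L) {
    stop("segment ", segment, " carries no in_frame_stop/frameshift defect")
  }
  L <- Biostrings::width(refSequences(refset)[segment])
  if (mechanism == "junctional") {
    inWindow <- if (row$segment_class == "J") {
      def$nt_position + 3L <= junction_window
    } else {
      def$nt_position >= L - junction_window
    }
    if (!all(inWindow)) {
      stop("junctional rescue requested for a defect outside the ",
           junction_window, "-nt junction window of ", segment)
    }
  } else {
    if (is.null(edits)) {
      bundled <- attr(refset, "rescueEdits")
      edits <- bundled[[segment]]
      if (is.null(edits)) stop("no corrective edits supplied for ", segment)
    }
    if (is.null(donors)) stop("germline rescue requires carrier donors")
  }
  structure(list(mechanism = mechanism, segment = segment,
                 donors = donors, edits = edits,
                 junction_window = junction_window),
            class = "tcr_rescue_plan")
}

#' Effective per-segment sampling weights
#' @noRd
effectiveWeights <- function(refset, cfg) {
  seg <- refSegments(refset)
  w <- ifelse(seg$functional_class == "functional", 1, 0)
  names(w) <- rownames(seg)
  for (plan in cfg$rescue) w[plan$segment] <- 1
  if (!is.null(cfg$usage_weights)) {
    unknown <- setdiff(names(cfg$usage_weights), names(w))
    if (length(unknown)) stop("usage weight for unknown segment: ",
                              paste(unknown, collapse = ", "))
    w[names(cfg$usage_weights)] <- cfg$usage_weights
  }
  w
}

#' Donor-specific references (planted rescues + random germline SNVs).
#' Consumes the ambient RNG stream only when snv_rate > 0.
#' @noRd
donorReferences <- function(refset, cfg) {
  variants <- list()
  refs <- list()
  seqsU <- as.character(refSequences(refset))
  segU <- refSegments(refset)
  emptyVar <- data.frame(donor_id = character(), segment = character(),
                         kind = character(), position = integer(),
                         ref_allele = character(), obs_allele = character(),
                         mechanism = character(), stringsAsFactors = FALSE)
  for (d in cfg$donor_ids) {
    seqs <- seqsU
    ed <- emptyVar
    ex <- cfg$germline_model$variants
    if (!is.null(ex)) {
      ex <- ex[ex$donor_id == d, , drop = FALSE]
      if (nrow(ex)) {
        ex$mechanism <- ex$mechanism %||% "explicit"
        ed <- rbind(ed, ex[names(emptyVar)])
      }
    }
    for (plan in cfg$rescue) {
      if (plan$mechanism == "junctional" || !d %in% (plan$donors %||% character())) next
      pe <- plan$edits
      pe$donor_id <- d
      pe$segment <- plan$segment
      pe$mechanism <- plan$mechanism
      ed <- rbind(ed, pe[names(emptyVar)])
    }
    rate <- cfg$germline_model$snv_rate %||% 0
    if (rate > 0) {
      vKeys <- rownames(segU)[segU$segment_class == "V"]
      for (k in vKeys) {
        L <- nchar(seqs[[k]])
        nmut <- stats::rbinom(1L, L, rate)
        if (nmut > 0L) {
          for (p in sample.int(L, nmut) - 1L) {
            refb <- substr(seqs[[k]], p + 1L, p + 1L)
            ed <- rbind(ed, data.frame(
              donor_id = d, segment = k, kind = "SNV", position = p,
              ref_allele = refb,
              obs_allele = sample(setdiff(DNA_BASES, refb), 1L),
              mechanism = "random", stringsAsFactors = FALSE))
          }
        }
      }
    }
    if (nrow(ed)) {
      for (k in unique(ed$segment)) {
        seqs[[k]] <- applyEdits(seqs[[k]], ed[ed$segment == k, , drop = FALSE])
      }
      variants[[d]] <- ed
    }
    segD <- segU
    segD$cys_anchor <- NA_integer_
    segD$jmotif_anchor <- NA_integer_
    refs[[d]] <- annotateAnchors(newReferenceSet(segD,
                                                 Biostrings::DNAStringSet(seqs),
                                                 refDefects(refset)))
  }
  list(refs = refs,
       variants = if (length(variants)) do.call(rbind, c(variants, list(make.row.names = FALSE)))
                  else emptyVar)
}

#' Vectorised rearrangement draw against one donor reference.
#' Uses the ambient RNG stream. Returns a data.frame, one row per contig.
#' @noRd
drawRearrangements <- function(donorRef, cfg, chain, n,
                               requireProductive = cfg$productive_only) {
  if (n == 0L) return(NULL)
  seg <- refSegments(donorRef)
  seqs <- as.character(refSequences(donorRef))
  w <- effectiveWeights(donorRef, cfg)
  pick <- function(cls) {
    k <- rownames(seg)[seg$chain == chain & seg$segment_class == cls]
    k <- k[w[k] > 0]
    if (!length(k)) stop("no usable ", cls, " segment for ", chain)
    k
  }
  vKeys <- pick("V"); jKeys <- pick("J")
  cKeys <- rownames(seg)[seg$chain == chain & seg$segment_class == "C"]
  if (!length(cKeys)) stop("no C segment for ", chain)
  cKey <- cKeys[[1L]]
  dKeys <- if (chain == "TRB") pick("D") else character()

  tm <- cfg$trim_model; im <- cfg$insertion_model; dm <- cfg$d_trim_model
  cysOf <- stats::setNames(seg$cys_anchor, rownames(seg))
  jAnchorOf <- stats::setNames(seg$jmotif_anchor, rownames(seg))
  batches <- list()
  got <- 0L
  tries <- 0L
  repeat {
    todo <- n - got
    if (todo <= 0L) break
    tries <- tries + 1L
    if (tries > cfg$max_retries) {
      stop("failed to draw a productive ", chain,
           " rearrangement within max_retries")
    }
    m <- todo
    vk <- sample(vKeys, m, replace = TRUE, prob = w[vKeys])
    jk <- sample(jKeys, m, replace = TRUE, prob = w[jKeys])
    vTrim <- rtruncgeom(m, tm$p, tm$max)
    jTrim <- rtruncgeom(m, tm$p, tm$max)
    Lv <- unname(nchar(seqs[vk])); Lj <- unname(nchar(seqs[jk]))
    ins1 <- randomDna(rtruncgeom(m, im$p, im$max))
    if (chain == "TRB") {
      dk <- sample(dKeys, m, replace = TRUE, prob = w[dKeys])
      d5 <- rtruncgeom(m, dm$p, dm$max)
      d3 <- rtruncgeom(m, dm$p, dm$max)
      Ld <- unname(nchar(seqs[dk]))
      ins2 <- randomDna(rtruncgeom(m, im$p, im$max))
      dPart <- unname(substr(seqs[dk], d5 + 1L, Ld - d3))
      dOk <- d5 + d3 < Ld
    } else {
      dk <- NA_character_; d5 <- 0L; d3 <- 0L
      ins2 <- ""; dPart <- ""; dOk <- rep(TRUE, m)
    }
    geomOk <- dOk & vTrim < Lv & jTrim < Lj
    vPart <- unname(substr(seqs[vk], 1L, Lv - vTrim))
    jPart <- unname(substr(seqs[jk], jTrim + 1L, Lj))
    contig <- paste0(vPart, ins1, dPart, ins2, jPart, seqs[[cKey]])

    cys <- unname(cysOf[vk])
    jAnchor <- unname(jAnchorOf[jk])
    anchorRel <- jAnchor - jTrim
    anchorOk <- !is.na(cys) & !is.na(jAnchor) &
      (Lv - vTrim >= cys + 3L) & anchorRel >= 0L
    midLen <- nchar(ins1) + nchar(dPart) + nchar(ins2)
    jpos <- nchar(vPart) + midLen + anchorRel
    jEnd <- nchar(vPart) + midLen + (Lj - jTrim)
    inframe <- jpos %% 3L == 0L
    stopFree <- stopFreeThrough(contig, jEnd)
    productive <- geomOk & anchorOk & inframe & stopFree

    cdr3 <- ifelse(anchorOk & geomOk,
                   substr(contig, cys + 1L, jpos + 3L), NA_character_)
    cdr3aa <- rep(NA_character_, m)
    doAa <- !is.na(cdr3) & inframe
    cdr3aa[doAa] <- translateNt(cdr3[doAa])

    batch <- data.frame(
      chain = chain, v_key = vk, d_key = dk, j_key = jk, c_key = cKey,
      v_trim = vTrim, j_trim = jTrim, d5_trim = d5, d3_trim = d3,
      ins1 = ins1, ins2 = ins2, contig_nt = contig,
      truth_cdr3_nt = cdr3, truth_cdr3_aa = cdr3aa,
      truth_productive = productive, stringsAsFactors = FALSE)

    keep <- if (requireProductive) productive else geomOk
    kept <- batch[keep, , drop = FALSE]
    batches[[length(batches) + 1L]] <- kept
    got <- got + nrow(kept)
  }
  out <- do.call(rbind, batches)
  rownames(out) <- NULL
  out[seq_len(n), , drop = FALSE]
}

#' Draw V(D)J rearrangements with ground truth
#'
#' Low-level access to the generator: draws `n` rearranged contigs of one
#' chain under the config's trim/insertion models, with per-contig truth
#' (CDR3, productivity) computed by definitional bookkeeping, not by the
#' annotator.
#'
#' @param refset reference (anchored).
#' @param cfg a [simulationConfig()].
#' @param chain `"TRA"` or `"TRB"`.
#' @param n number of rearrangements.
#' @param requireProductive redraw until productive? Defaults to the
#'   config's `productive_only`.
#' @return data.frame, one row per contig.
#' @export
simulateRearrangement <- function(refset, cfg, chain = c("TRA", "TRB"), n = 1L,
                                  requireProductive = cfg$productive_only) {
  chain <- match.arg(chain)
  withSeed(cfg$seed, drawRearrangements(refset, cfg, chain, n, requireProductive))
}

#' Clone mass vector for one donor under the configured profile
#' @noRd
cloneMasses <- function(cfg, nCells) {
  prof <- cfg$clonality_profile
  if (prof == "polyclonal") {
    nbg <- cfg$n_background_clones %||% nCells
    rep(1 / nbg, nbg)
  } else if (prof == "oligoclonal") {
    e <- cfg$expanded_fractions
    nbg <- cfg$n_background_clones %||% nCells
    c(e, rep((1 - sum(e)) / nbg, nbg))
  } else {
    f <- cfg$dominant_fraction
    nbg <- max(1L, cfg$n_background_clones %||% 400L)
    c(f, rep((1 - f) / nbg, nbg))
  }
}

#' Pairing noise: assign a category per cell, drop/duplicate chains.
#' Ambient RNG. `contigs$cell` indexes rows of `cells`.
#' @noRd
pairingStep <- function(cells, contigs, cfg, refs, probs = cfg$pairing_model) {
  cat_draw <- sample(names(probs), nrow(cells), replace = TRUE, prob = probs)
  cells$pairing_category <- cat_draw
  keep <- rep(TRUE, nrow(contigs))
  keep[contigs$chain == "TRB" & contigs$cell %in% which(cat_draw == "tra_only")] <- FALSE
  keep[contigs$chain == "TRA" & contigs$cell %in% which(cat_draw == "trb_only")] <- FALSE
  contigs <- contigs[keep, , drop = FALSE]

  for (ch in c("TRA", "TRB")) {
    extraCat <- if (ch == "TRA") c("extra_tra", "extra_both") else c("extra_trb", "extra_both")
    need <- which(cat_draw %in% extraCat)
    if (!length(need)) next
    donorsOf <- cells$donor_id[need]
    for (d in unique(donorsOf)) {
      sel <- need[donorsOf == d]
      extra <- drawRearrangements(refs[[d]], cfg, ch, length(sel))
      extra$clone_id <- cells$clone_id[sel]
      extra$cell <- sel
      extra$donor_id <- d
      extra$extra_chain <- TRUE
      contigs <- rbind(contigs, extra)
    }
  }
  list(cells = cells, contigs = contigs)
}

#' Barcodes, contig ids, UMIs, sequencing errors, truth summaries.
#' Ambient RNG (UMIs, errors).
#' @noRd
finalizeRepertoire <- function(cells, contigs, cfg) {
  contigs <- contigs[order(contigs$cell, contigs$chain, contigs$extra_chain), ,
                     drop = FALSE]
  rownames(contigs) <- NULL
  if (is.null(cells$barcode)) cells$barcode <- sequentialBarcodes(nrow(cells))
  contigs$barcode <- cells$barcode[contigs$cell]
  contigs$contig_id <- paste0(contigs$barcode, "_contig_",
                              stats::ave(seq_len(nrow(contigs)), contigs$cell,
                                         FUN = seq_along))
  lam <- ifelse(contigs$chain == "TRA", cfg$umi_model$tra_lambda,
                cfg$umi_model$trb_lambda)
  contigs$umi_count <- 1L + stats::rpois(nrow(contigs), lam)
  contigs$contig_length <- nchar(contigs$contig_nt)

  if (cfg$error_rate > 0) {
    nerr <- stats::rbinom(nrow(contigs), contigs$contig_length, cfg$error_rate)
    for (i in which(nerr > 0L)) {
      s <- contigs$contig_nt[i]
      for (p in sample.int(contigs$contig_length[i], nerr[i])) {
        substr(s, p, p) <- sample(setdiff(DNA_BASES, substr(s, p, p)), 1L)
      }
      contigs$contig_nt[i] <- s
    }
  }

  cells$n_tra <- tabulate(contigs$cell[contigs$chain == "TRA"], nrow(cells))
  cells$n_trb <- tabulate(contigs$cell[contigs$chain == "TRB"], nrow(cells))
  cells$truth_clonotype <- clonotypeKeys(contigs, nrow(cells))
  list(cells = cells, contigs = contigs)
}

truthClonotypeTable <- function(cells) {
  tt <- table(cells$truth_clonotype[!is.na(cells$truth_clonotype)])
  out <- data.frame(clonotype = names(tt), n_cells = as.integer(tt),
                    stringsAsFactors = FALSE)
  if (nrow(out)) out$proportion <- out$n_cells / sum(out$n_cells)
  out <- out[order(-out$n_cells, out$clonotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}

CELL_COLS <- c("barcode", "donor_id", "clone_id", "pairing_category",
               "n_tra", "n_trb", "truth_clonotype")
CONTIG_COLS <- c("barcode", "contig_id", "donor_id", "clone_id", "chain",
                 "v_key", "d_key", "j_key", "c_key", "v_trim", "j_trim",
                 "d5_trim", "d3_trim", "ins1", "ins2", "contig_nt",
                 "contig_length", "umi_count", "extra_chain",
                 "truth_cdr3_nt", "truth_cdr3_aa", "truth_productive")

assembleRepertoire <- function(cells, contigs, cfg, variants, cellIndex = TRUE) {
  rescue <- if (length(cfg$rescue)) {
    data.frame(segment = vapply(cfg$rescue, `[[`, character(1L), "segment"),
               mechanism = vapply(cfg$rescue, `[[`, character(1L), "mechanism"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(segment = character(), mechanism = character(),
               stringsAsFactors = FALSE)
  }
  methods::new("SimulatedRepertoire",
               contigs = contigs[, CONTIG_COLS],
               cells = cells[, CELL_COLS],
               config = unclass(cfg),
               truth = list(clonotypes = truthClonotypeTable(cells),
                            variants = variants,
                            rescue = rescue))
}

#' Simulate a single-cell TRA/TRB repertoire with known truth
#'
#' Draws clone masses under the configured clonality profile, gives every
#' clone a productive TRA and TRB rearrangement (by default), samples
#' cells from clones, applies the chain-pairing noise model, and assigns
#' barcodes and per-chain UMI counts. `(refset, cfg)` is fully
#' deterministic.
#'
#' @param refset an anchored [TCRReferenceSet-class]; see
#'   [syntheticReference()].
#' @param cfg a [simulationConfig()].
#' @param pairing apply the pairing noise model (default TRUE); when
#'   FALSE every cell keeps exactly one TRA and one TRB.
#' @return a [SimulatedRepertoire-class].
#' @export
simulateRepertoire <- function(refset, cfg, pairing = TRUE) {
  stopifnot(inherits(cfg, "tcr_sim_config"))
  if (cfg$n_cells < 1L) stop("n_cells must be at least 1")
  withSeed(cfg$seed, {
    dr <- donorReferences(refset, cfg)
    nd <- cfg$n_donors
    perDonor <- diff(round(seq(0, cfg$n_cells, length.out = nd + 1L)))

    cells <- NULL; contigs <- NULL
    for (di in seq_len(nd)) {
      d <- cfg$donor_ids[[di]]
      nc <- perDonor[[di]]
      if (nc == 0L) next
      ref <- dr$refs[[d]]
      masses <- cloneMasses(cfg, nc)
      cloneOf <- sample.int(length(masses), nc, replace = TRUE, prob = masses)
      used <- sort(unique(cloneOf))
      cloneIds <- paste0(d, "_c", used)
      tra <- drawRearrangements(ref, cfg, "TRA", length(used))
      trb <- drawRearrangements(ref, cfg, "TRB", length(used))
      tra$clone_id <- cloneIds; trb$clone_id <- cloneIds
      idx <- match(cloneOf, used)
      offset <- NROW(cells)
      cellDf <- data.frame(donor_id = d, clone_id = cloneIds[idx],
                           stringsAsFactors = FALSE)
      cellContigs <- rbind(tra[idx, , drop = FALSE], trb[idx, , drop = FALSE])
      cellContigs$cell <- rep(seq_len(nc) + offset, 2L)
      cellContigs$donor_id <- d
      cellContigs$extra_chain <- FALSE
      cells <- rbind(cells, cellDf)
      contigs <- rbind(contigs, cellContigs)
    }
    rownames(cells) <- NULL

    if (pairing) {
      st <- pairingStep(cells, contigs, cfg, dr$refs)
      cells <- st$cells; contigs <- st$contigs
    } else {
      cells$pairing_category <- "single_pair"
    }
    fin <- finalizeRepertoire(cells, contigs, cfg)
    assembleRepertoire(fin$cells, fin$contigs, cfg, dr$variants)
  })
}

#' Truth clonotype key per cell: sorted multiset of productive (chain, cdr3)
#' @noRd
clonotypeKeys <- function(contigs, nCells) {
  prod <- contigs[contigs$truth_productive & !is.na(contigs$truth_cdr3_nt), ,
                  drop = FALSE]
  keys <- rep(NA_character_, nCells)
  if (nrow(prod)) {
    lab <- paste0(prod$chain, ":", prod$truth_cdr3_nt)
    byCell <- split(lab, prod$cell)
    keys[as.integer(names(byCell))] <-
      vapply(byCell, function(x) paste(sort(x), collapse = ";"), character(1L))
  }
  keys
}

#' Apply the chain-pairing noise model to a pristine repertoire
#'
#' Takes a repertoire in the generator's pre-noise state (every cell with
#' exactly one TRA and one TRB contig, e.g. `simulateRepertoire(...,
#' pairing = FALSE)`), assigns a pairing category per cell i.i.d. from
#' `probs`, and drops or duplicates chains accordingly; "extra" chains
#' receive an independently re-drawn junction. Existing junction
#' sequences are untouched; contig identifiers and UMI counts are
#' reassigned during finalisation.
#'
#' @param sim a [SimulatedRepertoire-class] with 1 TRA + 1 TRB per cell.
#' @param refset the reference the repertoire was drawn against.
#' @param probs pairing category probabilities (must sum to 1).
#' @param seed RNG seed for the category draw and extra-chain junctions;
#'   defaults to the simulation seed + 1.
#' @return a modified [SimulatedRepertoire-class].
#' @export
applyPairingModel <- function(sim, refset, probs = simConfig(sim)$pairing_model,
                              seed = simConfig(sim)$seed + 1L) {
  checkPairingProbs(probs)
  cells <- simCells(sim)
  if (!all(cells$n_tra == 1L & cells$n_trb == 1L)) {
    stop("applyPairingModel expects exactly 1 TRA and 1 TRB per cell")
  }
  cfg <- do.call(simulationConfig, simConfig(sim))
  contigs <- simContigs(sim)
  contigs$cell <- match(contigs$barcode, cells$barcode)
  # back to the pre-finalisation column set so fresh extra chains rbind
  # cleanly; identifiers, UMI counts and lengths are reassigned afterwards
  contigs <- contigs[, setdiff(names(contigs),
                               c("barcode", "contig_id", "umi_count",
                                 "contig_length"))]
  refs <- withSeed(cfg$seed, donorReferences(refset, cfg))$refs
  withSeed(seed, {
    st <- pairingStep(cells, contigs, cfg, refs, probs = probs)
    fin <- finalizeRepertoire(st$cells, st$contigs, cfg)
    assembleRepertoire(fin$cells, fin$contigs, cfg, simTruth(sim)$variants)
  })
}

#' Export a simulated repertoire to disk
#'
#' Writes `contigs.fasta` (per-contig sequences), `airr.tsv` (AIRR
#' Rearrangement records derived from truth fields), `truth_cells.csv`,
#' `truth_contigs.csv` and `config.yaml`. Re-export under the same
#' (config, seed) is byte-identical.
#'
#' @param sim a [SimulatedRepertoire-class].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
exportSimulation <- function(sim, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir)
  }
  contigs <- simContigs(sim)
  fa <- file.path(dir, "contigs.fasta")
  lines <- character(2L * nrow(contigs))
  lines[c(TRUE, FALSE)] <- paste0(">", contigs$contig_id)
  lines[c(FALSE, TRUE)] <- contigs$contig_nt
  writeLines(lines, fa)

  airr <- data.frame(cell_id = contigs$barcode,
                     locus = contigs$chain,
                     v_call = contigs$v_key,
                     j_call = contigs$j_key,
                     junction = contigs$truth_cdr3_nt,
                     junction_aa = contigs$truth_cdr3_aa,
                     productive = contigs$truth_productive,
                     consensus_count = contigs$umi_count,
                     stringsAsFactors = FALSE)
  airrPath <- file.path(dir, "airr.tsv")
  writeAirr(airr, airrPath)

  cellsPath <- file.path(dir, "truth_cells.csv")
  utils::write.csv(simCells(sim), cellsPath, row.names = FALSE, quote = FALSE)
  contigsPath <- file.path(dir, "truth_contigs.csv")
  utils::write.csv(contigs, contigsPath, row.names = FALSE, quote = FALSE)
  cfgPath <- file.path(dir, "config.yaml")
  cfgOut <- simConfig(sim)
  cfgOut$rescue <- lapply(cfgOut$rescue, unclass)
  yaml::write_yaml(cfgOut, cfgPath)
  invisible(c(fasta = fa, airr = airrPath, cells = cellsPath,
              contigs = contigsPath, config = cfgPath))
}
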