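# Expanded vs non-expanded T-cell phenotype testing: activation,
# exhaustion, effector-memory and naive marker panels compared between
# cells of expanded clonotypes (> 1% of all cells) and the rest, with a
# two-sided Wilcoxon rank-sum test and Bonferroni correction over the
# markers tested.

#' Marker panels mapped to dog orthologs
#'
#' The default differential-expression run tests the 16
#' activation + exhaustion markers.
#'
#' @return named list of character vectors: `activation`, `exhaustion`,
#'   `effector_memory`, `naive`.
#' @export
markerPanels <- function() {
  list(
    activation = c("CD38", "GZMA", "GZMK", "MKI67"),
    exhaustion = c("CTLA4", "HAVCR2", "NFATC1", "NR4A1", "NR4A2", "NR4A3",
                   "PDCD1", "PRDM1", "TCF7", "TIGIT", "TOX", "TOX2"),
    effector_memory = c("CCL5", "ZEB2", "GZMK"),
    naive = c("LEF1", "TCF7", "CCR7"))
}

#' Label cells as expanded by clonotype frequency
#'
#' A cell is expanded iff its clonotype represents strictly more than
#' `threshold` of all cells (clonotype proportions computed over all
#' cells); a clonotype at exactly the threshold is not expanded.
#'
#' @param cellClonotypes data.frame `barcode`, `clonotype_id` (the
#'   `cells` attribute of [buildClonotypes()]), or a character vector of
#'   per-cell clonotype labels.
#' @param clonotypes [buildClonotypes()] table supplying `proportion`
#'   per clonotype; ignored when `proportions` is given.
#' @param threshold expansion threshold on the clonotype proportion,
#'   in (0, 1); default 0.01.
#' @param proportions optional named numeric vector of clonotype
#'   proportions (overrides `clonotypes`).
#' @return logical vector (named by barcode when available).
#' @export
labelExpanded <- function(cellClonotypes, clonotypes = NULL, threshold = 0.01,
                          proportions = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (is.data.frame(cellClonotypes)) {
    labels <- cellClonotypes$clonotype_id
    names(labels) <- cellClonotypes$barcode
  } else {
    labels <- cellClonotypes
  }
  if (is.null(proportions)) {
    if (is.null(clonotypes)) {
      tab <- table(labels)
      proportions <- as.numeric(tab) / length(labels)
      names(proportions) <- names(tab)
    } else {
      proportions <- stats::setNames(clonotypes$proportion,
                                     clonotypes$clonotype_id)
    }
  }
  out <- unname(proportions[labels] > threshold)
  out[is.na(out)] <- FALSE
  names(out) <- names(labels)
  out
}

#' Test marker genes between expanded and non-expanded cells
#'
#' Two-sided Wilcoxon rank-sum test per marker on normalized expression
#' values; Bonferroni correction over the number of markers actually
#' tested in the run (16 for the default activation + exhaustion
#' panels). Direction is `up_in_expanded` / `down_in_expanded` when the
#' adjusted p-value is below `alpha`, else `ns`.
#'
#' @param expression numeric genes x cells matrix of log-normalized
#'   values (rows named by gene).
#' @param expanded logical vector over cells (columns).
#' @param panels which panels of [markerPanels()] to test; default
#'   activation + exhaustion.
#' @param markers explicit marker vector (overrides `panels`).
#' @param alpha significance level on the adjusted p-value.
#' @return data.frame: `gene`, `panel`, `statistic`, `p_value`,
#'   `p_adjusted`, `direction`, `missing`.
#' @export
testMarkers <- function(expression, expanded,
                        panels = c("activation", "exhaustion"),
                        markers = NULL, alpha = 0.05) {
  stopifnot(ncol(expression) == length(expanded))
  if (!any(expanded) || all(expanded)) {
    stop("both expanded and non-expanded groups must be non-empty")
  }
  panelMap <- markerPanels()
  if (is.null(markers)) {
    sel <- panelMap[panels]
    markers <- unique(unlist(sel))
    panelOf <- vapply(markers, function(g) {
      paste(names(sel)[vapply(sel, function(p) g %in% p, logical(1L))],
            collapse = "/")
    }, character(1L))
  } else {
    panelOf <- vapply(markers, function(g) {
      hit <- names(panelMap)[vapply(panelMap, function(p) g %in% p, logical(1L))]
      if (length(hit)) paste(hit, collapse = "/") else "custom"
    }, character(1L))
  }
  present <- markers %in% rownames(expression)
  nTested <- sum(present)
  rows <- lapply(seq_along(markers), function(i) {
    g <- markers[[i]]
    if (!present[[i]]) {
      return(data.frame(gene = g, panel = panelOf[[i]],
                        statistic = NA_real_, p_value = NA_real_,
                        p_adjusted = NA_real_, direction = NA_character_,
                        missing = TRUE, stringsAsFactors = FALSE))
    }
    x <- expression[g, expanded]
    y <- expression[g, !expanded]
    wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
    padj <- min(1, wt$p.value * nTested)
    dir <- if (padj < alpha) {
      if (mean(x) > mean(y)) "up_in_expanded" else "down_in_expanded"
    } else "ns"
    data.frame(gene = g, panel = panelOf[[i]],
               statistic = unname(wt$statistic), p_value = wt$p.value,
               p_adjusted = padj, direction = dir, missing = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_markers_tested") <- nTested
  out
}

#' Simulate a marker expression matrix for expanded/non-expanded cells
#'
#' Synthetic log-normalized expression: every marker is Gaussian around
#' a baseline, with optional location shifts planted in the expanded
#' group. Used to calibrate and power-test [testMarkers()].
#'
#' @param nExpanded,nOther group sizes.
#' @param shifts named numeric vector of log-scale shifts added to the
#'   expanded group (e.g. `c(GZMA = 1)`).
#' @param markers genes to emit; default activation + exhaustion panels.
#' @param baseline,sd Gaussian baseline and standard deviation.
#' @param seed RNG seed.
#' @return list: `expression` (genes x cells matrix), `expanded`
#'   (logical vector).
#' @export
simulateMarkerExpression <- function(nExpanded, nOther, shifts = NULL,
                                     markers = NULL, baseline = 1, sd = 0.5,
                                     seed = 1L) {
  if (is.null(markers)) {
    markers <- unique(unlist(markerPanels()[c("activation", "exhaustion")]))
  }
  withSeed(seed, {
    n <- nExpanded + nOther
    expanded <- rep(c(TRUE, FALSE), c(nExpanded, nOther))
    m <- matrix(stats::rnorm(length(markers) * n, mean = baseline, sd = sd),
                nrow = length(markers), dimnames = list(markers, NULL))
    if (!is.null(shifts)) {
      for (g in names(shifts)) {
        if (g %in% markers) m[g, expanded] <- m[g, expanded] + shifts[[g]]
      }
    }
    m <- pmax(m, 0)
    colnames(m) <- sequentialBarcodes(n)
    list(expression = m, expanded = expanded)
  })
}
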