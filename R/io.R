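# Format readers and writers: AIRR Rearrangement TSV and the
# cellranger-style filtered_contig_annotations.csv / clonotypes.csv
# dialects. All tables are written with explicit headers, UTF-8 and LF
# line endings.

AIRR_COLUMNS <- c("cell_id", "locus", "v_call", "j_call", "junction",
                  "junction_aa", "productive", "consensus_count")

#' Write AIRR Rearrangement records
#'
#' @param records data.frame carrying the AIRR columns (`cell_id`,
#'   `locus`, `v_call`, `j_call`, `junction`, `junction_aa`,
#'   `productive`, `consensus_count`); a contig annotation table from
#'   [annotateContigs()] is mapped automatically.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeAirr <- function(records, path) {
  if (!all(AIRR_COLUMNS %in% names(records)) && "contig_id" %in% names(records)) {
    records <- data.frame(
      cell_id = records$barcode, locus = records$chain,
      v_call = records$v_call, j_call = records$j_call,
      junction = records$cdr3_nt, junction_aa = records$cdr3_aa,
      productive = records$productive,
      consensus_count = records$umi_count %||% NA_integer_,
      stringsAsFactors = FALSE)
  }
  missing <- setdiff(AIRR_COLUMNS, names(records))
  if (length(missing)) stop("missing AIRR column: ", paste(missing, collapse = ", "))
  out <- records[, AIRR_COLUMNS, drop = FALSE]
  out$productive <- ifelse(is.na(out$productive), "",
                           ifelse(out$productive, "T", "F"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read AIRR Rearrangement records
#'
#' @param path AIRR TSV path.
#' @return data.frame with `productive` parsed to logical; empty fields
#'   become NA.
#' @export
readAirr <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "")
  missing <- setdiff(AIRR_COLUMNS, names(df))
  if (length(missing)) {
    stop("missing mandatory AIRR column: ", paste(missing, collapse = ", "))
  }
  df$productive <- df$productive == "T"
  df$consensus_count <- as.integer(df$consensus_count)
  df
}

CELLRANGER_CONTIG_COLUMNS <- c("barcode", "contig_id", "chain", "v_gene",
                               "j_gene", "cdr3", "cdr3_nt", "productive",
                               "full_length", "length")

#' Write a cellranger-style filtered_contig_annotations.csv
#'
#' @param annotations [annotateContigs()] output, or any data.frame with
#'   the dialect's columns already in place.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeContigCsv <- function(annotations, path) {
  if (!all(CELLRANGER_CONTIG_COLUMNS %in% names(annotations))) {
    consumed <- c("barcode", "contig_id", "chain", "v_call", "j_call",
                  "cdr3_aa", "cdr3_nt", "productive", "full_length",
                  "contig_length", "contig_nt")
    extras <- annotations[, setdiff(names(annotations), consumed),
                          drop = FALSE]
    annotations <- cbind(data.frame(
      barcode = annotations$barcode, contig_id = annotations$contig_id,
      chain = annotations$chain, v_gene = annotations$v_call,
      j_gene = annotations$j_call, cdr3 = annotations$cdr3_aa,
      cdr3_nt = annotations$cdr3_nt,
      productive = annotations$productive,
      full_length = annotations$full_length,
      length = annotations$contig_length, stringsAsFactors = FALSE),
      extras)
  }
  extras <- setdiff(names(annotations), CELLRANGER_CONTIG_COLUMNS)
  out <- annotations[, c(CELLRANGER_CONTIG_COLUMNS, extras), drop = FALSE]
  for (col in c("productive", "full_length")) {
    if (is.logical(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "None",
                           ifelse(out[[col]], "True", "False"))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a cellranger-style filtered_contig_annotations.csv
#'
#' Unknown extra columns are preserved.
#'
#' @param path CSV path.
#' @return data.frame; `productive` and `full_length` parsed to logical,
#'   plus internal aliases `v_call`, `j_call`, `cdr3_nt`, `cdr3_aa`,
#'   `contig_length`.
#' @export
readContigCsv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = ""),
    error = function(e) stop("malformed CSV in ", path, ": ", conditionMessage(e)))
  missing <- setdiff(CELLRANGER_CONTIG_COLUMNS, names(df))
  if (length(missing)) {
    stop("missing contig annotation column: ", paste(missing, collapse = ", "))
  }
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  bad <- which(nf != nf[[1L]])
  if (length(bad)) stop("malformed CSV row at line ", bad[[1L]], " of ", path)
  for (col in c("productive", "full_length")) {
    df[[col]] <- df[[col]] == "True"
  }
  df$length <- as.integer(df$length)
  df$v_call <- df$v_gene
  df$j_call <- df$j_gene
  df$cdr3_nt <- df$cdr3_nt
  df$cdr3_aa <- df$cdr3
  df$contig_length <- df$length
  df
}

#' Serialise per-chain CDR3 sets to the cellranger `cdr3s_aa` dialect
#' ("TRA:CA..;TRB:CAS..") and back
#'
#' @param x for `formatCdr3sField`: a clonotype `key` string
#'   ("TRA:...;TRB:..."); for `parseCdr3sField`: the serialized field.
#' @return `parseCdr3sField`: data.frame `chain`, `cdr3` (one row per
#'   chain entry).
#' @export
parseCdr3sField <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(parts)]
  data.frame(chain = sub(":.*$", "", parts),
             cdr3 = sub("^[^:]*:", "", parts), stringsAsFactors = FALSE)
}

#' Write a cellranger-style clonotypes.csv
#'
#' @param clonotypes [buildClonotypes()] output.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeClonotypesCsv <- function(clonotypes, path) {
  out <- data.frame(clonotype_id = clonotypes$clonotype_id,
                    frequency = clonotypes$n_cells,
                    proportion = signif(clonotypes$proportion, 6L),
                    cdr3s_aa = clonotypes$cdr3s_aa,
                    cdr3s_nt = clonotypes$cdr3s_nt,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cellranger-style clonotypes.csv
#'
#' @param path CSV path.
#' @return data.frame with `n_cells` (= frequency), `proportion` and
#'   per-chain counts `n_tra`, `n_trb` recovered from `cdr3s_nt`.
#' @export
readClonotypesCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("clonotype_id", "frequency", "proportion", "cdr3s_aa", "cdr3s_nt")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing clonotype column: ", paste(missing, collapse = ", "))
  }
  df$n_cells <- as.integer(df$frequency)
  counts <- lapply(df$cdr3s_nt, parseCdr3sField)
  df$n_tra <- vapply(counts, function(p) sum(p$chain == "TRA"), integer(1L))
  df$n_trb <- vapply(counts, function(p) sum(p$chain == "TRB"), integer(1L))
  df$key <- df$cdr3s_nt
  df
}
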