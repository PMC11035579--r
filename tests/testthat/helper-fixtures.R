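# Shared fixtures, built in code at test time.

# memoised default synthetic reference (deterministic)
sharedRef <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- syntheticReference()
    ref
  }
})

# write a segment FASTA from a named list id -> c(header_tail, sequence)
writeTestFasta <- function(records, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(records, function(r) c(paste0(">", r[[1L]]), r[[2L]])))
  writeLines(lines, path)
  path
}

# a minimal hand-built anchored reference: one functional V/J/C per chain
# (plus a TRB D), with known anchor offsets
tinyReference <- function() {
  v <- function() {
    paste0(strrep("ATGGCA", 20L),          # 40 codons, stop-free
           "GAAATC", strrep("CTG", 9L),    # filler
           "TGT", "GCC", "AGC")            # Cys anchor, 2 trailing codons
  }
  j <- "GCAAAC" |> paste0("TTT", "GGA", "CAA", "GGC", strrep("ACC", 5L))
  cseq <- strrep("GCA", 40L)
  fa <- writeTestFasta(list(
    list("TRAV1*01|TRA|V|functional", v()),
    list("TRAJ1*01|TRA|J|functional", j),
    list("TRAC*01|TRA|C|functional", cseq),
    list("TRBV1*01|TRB|V|functional", v()),
    list("TRBD1*01|TRB|D|functional", "GGGACAGGGGGC"),
    list("TRBJ1*01|TRB|J|functional", j),
    list("TRBC1*01|TRB|C|functional", cseq)))
  annotateAnchors(readSegmentFasta(fa))
}

# deterministic distinct 9-mers (base-4 encoding of an index)
randomDnaFixture <- function(i) {
  digits <- integer(9L)
  for (j in 9:1) {
    digits[j] <- i %% 4L
    i <- i %/% 4L
  }
  paste0(c("A", "C", "G", "T")[digits + 1L], collapse = "")
}

# small annotation table builder for clonotype tests
annRow <- function(barcode, chain, cdr3_nt, productive = TRUE,
                   v_call = "V*01", j_call = "J*01") {
  data.frame(barcode = barcode, contig_id = paste0(barcode, "_", chain),
             chain = chain, v_call = v_call, j_call = j_call,
             cdr3_nt = cdr3_nt,
             cdr3_aa = if (is.na(cdr3_nt)) NA_character_ else strrep("A", nchar(cdr3_nt) %/% 3L),
             productive = productive, contig_length = 500L,
             stringsAsFactors = FALSE)
}
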