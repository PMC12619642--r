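# AIRR Rearrangement TSV input/output and MSA threading.
#
# Threading re-expresses a query's V (or J) segment in the column coordinates
# of the reference MSA using only the pairwise alignment already present in
# the AIRR annotation (no re-alignment). Insertions relative to the germline
# are dropped; uncovered MSA columns become 'N' (emission probability 1), so
# every query lives in a common lattice of length L.

airr_required_cols <- function(segment) {
  p <- if (segment == "V") "v" else "j"
  c("sequence_id", paste0(p, "_call"),
    paste0(p, "_sequence_alignment"), paste0(p, "_germline_alignment"),
    paste0(p, "_germline_start"), paste0(p, "_germline_end"))
}

# Reads the full table (all columns as character so passthrough columns are
# preserved verbatim) and computes a per-row validity mask for the chosen
# segment. Shared by read_airr() and run_detection().
.read_airr_table <- function(path, segment = c("V", "J")) {
  segment <- match.arg(segment)
  if (!file.exists(path)) stop_parameter(sprintf("file not found: %s", path))
  tab <- data.table::fread(path, sep = "\t", header = TRUE, quote = "",
                           na.strings = "", colClasses = "character",
                           data.table = TRUE, showProgress = FALSE)
  req <- airr_required_cols(segment)
  missing <- setdiff(req, names(tab))
  if (length(missing)) {
    stop_schema(sprintf("AIRR file %s is missing required column(s): %s",
                        path, paste(missing, collapse = ", ")))
  }
  if (nrow(tab) == 0L) {
    return(list(table = tab, valid = logical(0), start = integer(0),
                end = integer(0), segment = segment))
  }
  start <- suppressWarnings(as.integer(tab[[req[5L]]]))
  end <- suppressWarnings(as.integer(tab[[req[6L]]]))
  valid <- rep(TRUE, nrow(tab))
  for (cc in req) valid <- valid & !is.na(tab[[cc]]) & nzchar(tab[[cc]])
  valid <- valid & !is.na(start) & !is.na(end) & start >= 1L & end >= start
  list(table = tab, valid = valid, start = start, end = end, segment = segment)
}

#' Read an AIRR Rearrangement TSV
#'
#' Reads a tab-separated AIRR Rearrangement file and returns the rows that
#' carry all fields required for the chosen segment. Rows missing a required
#' field (or with inconsistent germline coordinates) are skipped with a
#' warning; the skip count is attached as attribute `n_skipped`. All other
#' input columns are passed through untouched.
#'
#' Required columns for V analysis: `sequence_id`, `v_call`,
#' `v_sequence_alignment`, `v_germline_alignment`, `v_germline_start`,
#' `v_germline_end` (1-based inclusive positions in the ungapped germline);
#' for J analysis the `j_*` analogues.
#'
#' @param path Path to the TSV file.
#' @param segment `"V"` (default) or `"J"`.
#' @return A data.frame of valid records in file order, with attribute
#'   `n_skipped`.
#' @export
read_airr <- function(path, segment = c("V", "J")) {
  parsed <- .read_airr_table(path, segment)
  n_skipped <- sum(!parsed$valid)
  if (n_skipped > 0L) {
    warning(sprintf("%d record(s) in %s missing required %s fields were skipped",
                    n_skipped, path, parsed$segment), call. = FALSE)
  }
  out <- as.data.frame(parsed$table[parsed$valid, , drop = FALSE])
  p <- if (parsed$segment == "V") "v" else "j"
  out[[paste0(p, "_germline_start")]] <- parsed$start[parsed$valid]
  out[[paste0(p, "_germline_end")]] <- parsed$end[parsed$valid]
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Count differences from reference (DFR) in a pairwise alignment
#'
#' Counts positions where both alignment strings carry a plain nucleotide
#' (`A`, `C`, `G`, `T`) and the nucleotides differ. Gap and `N` columns never
#' count, so the measure is symmetric in its two arguments. Used as a cheap
#' prefilter: sequences nearly identical to their best-matching germline
#' cannot be detectable chimeras.
#'
#' @param sequence_alignment,germline_alignment Equal-length aligned strings
#'   (vectorized: pairs are processed elementwise).
#' @return Integer vector of mismatch counts.
#' @examples
#' compute_dfr("ACGT", "AGGA")  # 2
#' compute_dfr("AC-T", "ACGT")  # 0
#' @export
compute_dfr <- function(sequence_alignment, germline_alignment) {
  if (length(sequence_alignment) != length(germline_alignment)) {
    stop_malformed("alignment string vectors have different lengths")
  }
  mapply(function(s, g) {
    a <- chars1(normalize_aligned(s))
    b <- chars1(normalize_aligned(g))
    if (length(a) != length(b)) {
      stop_malformed("sequence and germline alignment strings differ in length")
    }
    sum(a %in% NTS & b %in% NTS & a != b)
  }, sequence_alignment, germline_alignment, USE.NAMES = FALSE)
}

#' Thread an AIRR record onto the reference MSA
#'
#' Re-expresses the query's aligned segment in MSA column coordinates using
#' the record's existing pairwise alignment against its assigned germline
#' allele (the first allele listed in `v_call`/`j_call`). Walking the pairwise
#' alignment: each germline-ungapped position `p` (counted from
#' `v_germline_start`) maps to MSA column `ungapped_to_column[[allele]][p]`
#' and receives the query character at that pairwise column (`-` for a query
#' deletion); pairwise columns where the germline side is a gap are query
#' insertions and are dropped; MSA columns never written — before/after the
#' aligned interval and the assigned allele's own gap columns — are `N`.
#'
#' @param record A single AIRR record (one-row data.frame or named list).
#' @param msa A `reference_msa`.
#' @param segment `"V"` (default) or `"J"`.
#' @return A `threaded_query`: list with `sequence_id`, `columns` (length-L
#'   string over `{A,C,G,T,-,N}`), `assigned_allele`, `n_insertions_dropped`,
#'   and `dfr`.
#' @export
thread_query <- function(record, msa, segment = c("V", "J")) {
  segment <- match.arg(segment)
  stopifnot(inherits(msa, "reference_msa"))
  p <- if (segment == "V") "v" else "j"
  call_str <- record[[paste0(p, "_call")]]
  allele <- trimws(strsplit(call_str, ",", fixed = TRUE)[[1L]][1L])
  if (!allele %in% msa$allele) {
    stop_unknown_allele(sprintf("assigned allele '%s' is absent from the reference MSA", allele))
  }
  g <- chars1(normalize_aligned(record[[paste0(p, "_germline_alignment")]]))
  q <- chars1(normalize_aligned(record[[paste0(p, "_sequence_alignment")]]))
  if (length(g) != length(q)) {
    stop_malformed(sprintf(
      "record '%s': sequence and germline alignment strings differ in length",
      record$sequence_id))
  }
  if (any(!q %in% c(NTS, "-", "N")) || any(!g %in% c(NTS, "-", "N"))) {
    stop_character(sprintf("record '%s': invalid character in alignment strings",
                           record$sequence_id))
  }
  start <- as.integer(record[[paste0(p, "_germline_start")]])
  end <- as.integer(record[[paste0(p, "_germline_end")]])
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop_malformed(sprintf("record '%s': invalid germline coordinates", record$sequence_id))
  }
  germ_idx <- which(g != "-")
  if (length(germ_idx) != end - start + 1L) {
    stop_malformed(sprintf(
      "record '%s': germline alignment spans %d ungapped positions but coordinates give %d",
      record$sequence_id, length(germ_idx), end - start + 1L))
  }
  map <- msa$ungapped_to_column[[allele]]
  if (end > length(map)) {
    stop_malformed(sprintf(
      "record '%s': germline end %d exceeds ungapped length %d of allele %s",
      record$sequence_id, end, length(map), allele))
  }
  cols <- map[start:end]
  out <- rep("N", msa$L)
  out[cols] <- q[germ_idx]
  structure(
    list(sequence_id = record$sequence_id %||% NA_character_,
         columns = paste(out, collapse = ""),
         chars = out,
         assigned_allele = allele,
         n_insertions_dropped = sum(g == "-" & q != "-"),
         dfr = sum(g %in% NTS & q %in% NTS & g != q)),
    class = "threaded_query"
  )
}

#' Write an AIRR table augmented with chimera calls
#'
#' Appends `chimera_probability` (decimal in `[0,1]`, empty for skipped
#' rows), `chimeric` (`T`/`F`), and — when Viterbi output is present —
#' `chimeric_alignments` (parent alleles with 1-based inclusive MSA column
#' ranges, `/`-separated) and `recombination_breakpoints` (MSA columns,
#' `/`-separated) after all input columns. Output is a deterministic TSV
#' with a header, tab separators and `\n` line endings.
#'
#' @param records Data.frame of input records.
#' @param calls Data.frame of calls aligned 1:1 with `records` by
#'   `sequence_id` (as produced by [run_detection()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_airr_with_calls <- function(records, calls, path) {
  if (nrow(records) != nrow(calls) ||
      !identical(as.character(records$sequence_id), as.character(calls$sequence_id))) {
    stop_alignment("records and calls are not aligned 1:1 by sequence_id")
  }
  out <- data.table::as.data.table(records)
  out[["chimera_probability"]] <-
    ifelse(is.na(calls$chimera_probability), "", sprintf("%.8f", calls$chimera_probability))
  out[["chimeric"]] <- ifelse(calls$chimeric, "T", "F")
  if ("chimeric_alignments" %in% names(calls)) {
    out[["chimeric_alignments"]] <- calls$chimeric_alignments %||% ""
    out[["recombination_breakpoints"]] <- calls$recombination_breakpoints %||% ""
  }
  if ("skipped_reason" %in% names(calls)) {
    out[["skipped_reason"]] <- ifelse(is.na(calls$skipped_reason), "", calls$skipped_reason)
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "", eol = "\n",
                     col.names = TRUE)
  invisible(path)
}
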