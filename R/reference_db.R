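# Germline reference database: an aligned set of V (or J) alleles whose
# columns define the HMM's coordinate system.

new_reference_msa <- function(allele, seq) {
  if (anyDuplicated(allele)) {
    stop_db(sprintf("duplicate allele name(s) in reference set: %s",
                    paste(unique(allele[duplicated(allele)]), collapse = ", ")))
  }
  L <- nchar(seq[1L])
  mat <- do.call(rbind, strsplit(seq, "", fixed = TRUE))
  rownames(mat) <- allele
  u2c <- lapply(seq_len(nrow(mat)), function(i) which(mat[i, ] != "-"))
  names(u2c) <- allele
  gene <- sub("\\*.*$", "", allele)
  family <- sub("-.*$", "", gene)
  structure(
    list(allele = allele, gene = gene, family = family, seq = seq,
         G = length(allele), L = L, mat = mat, ungapped_to_column = u2c),
    class = "reference_msa"
  )
}

msa_subset <- function(msa, idx) new_reference_msa(msa$allele[idx], msa$seq[idx])

#' Read an aligned germline allele database from FASTA
#'
#' Loads a multiple sequence alignment of germline V (or J) alleles. All
#' records must have identical aligned length; IMGT-style `.` gaps are mapped
#' to `-` and sequences are case-folded to uppercase. Gene and family labels
#' are parsed from the allele names following IMGT nomenclature (gene = text
#' before `*`, family = text before the first `-`).
#'
#' @param path Path to a multi-record FASTA file (wrapped or unwrapped).
#' @return A `reference_msa` object: a list with elements `allele`, `gene`,
#'   `family`, `seq` (aligned sequences), `G` (allele count), `L` (column
#'   count), and `ungapped_to_column` (per-allele map from 1-based ungapped
#'   position to MSA column).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">A*01", "ACGT-A", ">A*02", "ACGTTA"), fa)
#' msa <- read_reference_msa(fa)
#' msa$G; msa$L
#' @export
read_reference_msa <- function(path) {
  if (!file.exists(path)) stop_parameter(sprintf("file not found: %s", path))
  x <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  seqs <- unname(normalize_aligned(as.character(x)))
  if (length(seqs) < 2L) {
    stop_db("reference database too small: at least 2 aligned alleles are required")
  }
  len <- nchar(seqs)
  if (length(unique(len)) != 1L) {
    bad <- which(len != len[1L])[1L]
    stop_alignment(sprintf(
      "record '%s' has aligned length %d, expected %d: input is not a flush alignment",
      nm[bad], len[bad], len[1L]))
  }
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop_character(sprintf("record '%s' contains characters outside {A,C,G,T,N,-,.}",
                           nm[which(bad)[1L]]))
  }
  new_reference_msa(nm, seqs)
}

#' Write an aligned germline allele database to FASTA
#'
#' Inverse of [read_reference_msa()]; allele names, order, and aligned
#' sequences round-trip exactly.
#'
#' @param msa A `reference_msa`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_msa <- function(msa, path) {
  stopifnot(inherits(msa, "reference_msa"))
  x <- Biostrings::BStringSet(stats::setNames(msa$seq, msa$allele))
  Biostrings::writeXStringSet(x, filepath = path, width = 80L)
  invisible(path)
}

#' @export
print.reference_msa <- function(x, ...) {
  cat(sprintf("reference_msa: %d alleles x %d columns (%d genes, %d families)\n",
              x$G, x$L, length(unique(x$gene)), length(unique(x$family))))
  invisible(x)
}

#' Uniformly subsample alleles from a reference database
#'
#' Draws `n_alleles` alleles uniformly without replacement, keeping the input
#' order of the retained alleles. Columns are not re-aligned, so the result
#' stays in the same coordinate system — this emulates running detection
#' against an incomplete germline database.
#'
#' @param msa A `reference_msa`.
#' @param n_alleles Number of alleles to keep (between 2 and `msa$G`).
#' @param seed Optional integer seed; the draw is deterministic given the seed
#'   and the caller's RNG stream is left untouched.
#' @return A `reference_msa` with exactly `n_alleles` alleles.
#' @export
subsample_genotype <- function(msa, n_alleles, seed = NULL) {
  stopifnot(inherits(msa, "reference_msa"))
  if (!is_count(n_alleles) || n_alleles < 2L || n_alleles > msa$G) {
    stop_parameter(sprintf("`n_alleles` must be an integer in [2, %d]", msa$G))
  }
  idx <- sort(with_seed(seed, sample.int(msa$G, n_alleles)))
  msa_subset(msa, idx)
}

#' Sample a synthetic genotype: one allele per gene
#'
#' Emulates a personalized germline genotype by selecting, uniformly at
#' random, exactly one allele for every gene present in the database (genes
#' are the text before `*` in allele names).
#'
#' @param allele_db A `reference_msa` containing the full allele database.
#' @param seed Optional integer seed for a deterministic draw.
#' @return A `reference_msa` with one allele per gene, in database order.
#' @export
sample_synthetic_genotype <- function(allele_db, seed = NULL) {
  stopifnot(inherits(allele_db, "reference_msa"))
  if (any(!grepl("*", allele_db$allele, fixed = TRUE))) {
    bad <- allele_db$allele[!grepl("*", allele_db$allele, fixed = TRUE)][1L]
    stop_airrchimera(
      sprintf("allele name '%s' has no '*' separator; cannot group alleles by gene", bad),
      "airrchimera_naming_error")
  }
  genes <- unique(allele_db$gene)
  idx <- with_seed(seed, vapply(genes, function(g) {
    cand <- which(allele_db$gene == g)
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }, integer(1L)))
  msa_subset(allele_db, sort(unname(idx)))
}

# Ungapped sequence of allele i (used by tests and the simulator).
ungapped_seq <- function(msa, i) gsub("-", "", msa$seq[i], fixed = TRUE)
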