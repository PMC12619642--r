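# Repertoire simulation with ground-truth chimera labels.
#
# Sequences are generated directly in MSA column coordinates, so the AIRR
# alignment fields can be synthesized exactly (no external aligner) and
# re-threading a simulated record reproduces the generated sequence.

# Per-site uniform substitution on plain-nucleotide positions of a character
# vector; draws from the caller's RNG stream.
.mutate_chars <- function(chars, rate) {
  if (rate <= 0) return(chars)
  idx <- which(chars %in% NTS)
  if (!length(idx)) return(chars)
  hit <- idx[stats::runif(length(idx)) < rate]
  if (length(hit)) {
    pick <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- ALT_BASES[cbind(match(chars[hit], NTS), pick)]
  }
  chars
}

#' Uniform per-site mutation of an aligned sequence
#'
#' Each plain-nucleotide position is independently substituted with
#' probability `rate`; the replacement is drawn uniformly from the three
#' other bases (so a mutated position never equals the original). Gap and N
#' positions are untouched. Uses the current RNG stream; wrap in a seeded
#' context for reproducibility.
#'
#' @param aligned_seq Aligned sequence (string over `{A,C,G,T,-,N}`).
#' @param rate Per-site substitution probability in `[0, 0.5)`.
#' @return The mutated string.
#' @export
mutate_uniform <- function(aligned_seq, rate) {
  if (!is.numeric(rate) || rate < 0 || rate >= 0.5) {
    stop_parameter("`rate` must be in [0, 0.5)")
  }
  paste(.mutate_chars(chars1(normalize_aligned(aligned_seq)), rate), collapse = "")
}

#' Generate one chimeric sequence from two parents
#'
#' Both parents are first mutated uniformly at `shm_rate`, then joined at a
#' breakpoint drawn uniformly from columns `2..L`: the output takes parent A
#' for columns `1..bp-1` and parent B from `bp` on. (Breakpoint 1 is
#' excluded: it would be indistinguishable from a pure parent-B sequence.)
#'
#' @param parent_a,parent_b Lists with `name` and `seq` (aligned, equal
#'   length), e.g. `list(name = msa$allele[i], seq = msa$seq[i])`.
#' @param shm_rate Per-site mutation rate applied to both parents.
#' @return A list with `seq` (the chimeric string), `chars`, and
#'   `breakpoint_column`.
#' @export
make_chimera <- function(parent_a, parent_b, shm_rate = 0) {
  if (identical(parent_a$name, parent_b$name)) {
    stop_parameter("chimera parents must be distinct alleles")
  }
  a <- .mutate_chars(chars1(normalize_aligned(parent_a$seq)), shm_rate)
  b <- .mutate_chars(chars1(normalize_aligned(parent_b$seq)), shm_rate)
  L <- length(a)
  if (length(b) != L) stop_parameter("chimera parents must have equal aligned length")
  bp <- sample(2:L, 1L)
  list(seq = paste(c(a[seq_len(bp - 1L)], b[bp:L]), collapse = ""),
       chars = c(a[seq_len(bp - 1L)], b[bp:L]),
       breakpoint_column = bp)
}

#' Synthesize an IMGT-style aligned germline V set
#'
#' Generates a fully synthetic aligned allele database with the hierarchical
#' divergence structure of real germline V loci: families diverge strongly
#' from a common ancestor, genes within a family diverge moderately (typical
#' inter-gene distances of a few tens of nucleotides, the range in which
#' chimera formation and detection are both effective), and alleles of the
#' same gene differ by only a few substitutions. A fraction of genes carry a
#' short deletion, so the alignment contains gap columns. Allele names
#' follow IMGT nomenclature (`SIMV<family>-<gene>*<allele>`).
#'
#' @param n_families Number of gene families.
#' @param genes_per_family Genes per family.
#' @param max_alleles_per_gene Each gene gets 1..this many alleles
#'   (uniformly).
#' @param L Aligned length in columns.
#' @param family_divergence Per-site divergence of each family founder from
#'   the ancestor.
#' @param gene_divergence Per-site divergence of each gene from its family
#'   founder.
#' @param allele_substitutions Substitution count range (vector to sample
#'   from) between a gene's alleles.
#' @param deletion_prob Probability a gene carries a deletion block.
#' @param deletion_length Length of the deletion block in columns.
#' @param seed Optional integer seed.
#' @return A `reference_msa` labelled as synthetic.
#' @export
synthesize_germline_msa <- function(n_families = 6L, genes_per_family = 8L,
                                    max_alleles_per_gene = 3L, L = 300L,
                                    family_divergence = 0.20,
                                    gene_divergence = 0.06,
                                    allele_substitutions = 1:2,
                                    deletion_prob = 0.2, deletion_length = 3L,
                                    seed = NULL) {
  with_seed(seed, {
    ancestor <- sample(NTS, L, replace = TRUE)
    allele <- character(0)
    seqs <- character(0)
    for (f in seq_len(n_families)) {
      founder <- .mutate_chars(ancestor, family_divergence)
      for (g in seq_len(genes_per_family)) {
        gene_seq <- .mutate_chars(founder, gene_divergence)
        if (stats::runif(1) < deletion_prob) {
          pos <- sample.int(L - deletion_length + 1L, 1L)
          gene_seq[pos:(pos + deletion_length - 1L)] <- "-"
        }
        n_all <- sample.int(max_alleles_per_gene, 1L)
        base_name <- sprintf("SIMV%d-%d", f, g)
        for (a in seq_len(n_all)) {
          al <- gene_seq
          if (a > 1L) {
            nsub <- if (length(allele_substitutions) == 1L) allele_substitutions
                    else sample(allele_substitutions, 1L)
            nt_pos <- which(al %in% NTS)
            sub_at <- sample(nt_pos, min(nsub, length(nt_pos)))
            pick <- sample.int(3L, length(sub_at), replace = TRUE)
            al[sub_at] <- ALT_BASES[cbind(match(al[sub_at], NTS), pick)]
          }
          allele <- c(allele, sprintf("%s*%02d", base_name, a))
          seqs <- c(seqs, paste(al, collapse = ""))
        }
      }
    }
    new_reference_msa(allele, seqs)
  })
}

#' Simulate an AIRR-shaped repertoire with ground-truth chimera labels
#'
#' Exactly `round(n_sequences * chimerism_rate)` sequences are chimeric:
#' two distinct genotype alleles, each uniformly mutated at `shm_rate`,
#' joined at a uniform breakpoint ([make_chimera()]). The rest are single
#' alleles uniformly mutated at `shm_rate`. A flat per-site sequencing-error
#' substitution is applied afterwards (before AIRR field synthesis, so
#' re-threading reproduces the simulated sequence at any error rate).
#' `v_call` is assigned as the genotype allele with the minimum Hamming
#' distance over informative columns (ties to the first in database order),
#' mimicking an aligner's best hit rather than leaking the true parent. The
#' AIRR alignment fields are synthesized by ungapping each record against
#' its assigned allele's MSA row.
#'
#' @param genotype A `reference_msa` (G >= 2), e.g. from
#'   [sample_synthetic_genotype()].
#' @param n_sequences Number of sequences.
#' @param chimerism_rate Fraction of chimeric sequences (default 0.05).
#' @param shm_rate Per-site somatic hypermutation rate in `[0, 0.5)`.
#' @param seq_error_rate Flat per-site sequencing-error rate in `[0, 0.1]`.
#' @param seed Optional integer seed; identical config + seed gives
#'   identical output.
#' @return A list with `airr` (AIRR-shaped data.frame consumable by
#'   [run_detection()]) and `truth` (one row per sequence: `sequence_id`,
#'   `is_chimera`, `parent_alleles` (`/`-separated), `breakpoint_column`,
#'   `true_shm_rate`, and `sequence_msa`, the ground-truth threaded string
#'   in MSA coordinates).
#' @export
simulate_dataset <- function(genotype, n_sequences, chimerism_rate = 0.05,
                             shm_rate = 0, seq_error_rate = 0, seed = NULL) {
  stopifnot(inherits(genotype, "reference_msa"))
  if (genotype$G < 2L) stop_db("simulation needs a genotype with G >= 2 alleles")
  if (!is_count(n_sequences) || n_sequences < 1L) {
    stop_parameter("`n_sequences` must be a positive integer")
  }
  if (chimerism_rate < 0 || chimerism_rate > 1) {
    stop_parameter("`chimerism_rate` must be in [0, 1]")
  }
  if (shm_rate < 0 || shm_rate >= 0.5) stop_parameter("`shm_rate` must be in [0, 0.5)")
  if (seq_error_rate < 0 || seq_error_rate > 0.1) {
    stop_parameter("`seq_error_rate` must be in [0, 0.1]")
  }
  n <- as.integer(n_sequences)
  G <- genotype$G
  L <- genotype$L
  mat <- genotype$mat
  tmat <- t(mat)                      # L x G, for vectorized Hamming distance
  t_is_nt <- matrix(tmat %in% NTS, nrow = L)
  ungapped_len <- lengths(genotype$ungapped_to_column)

  with_seed(seed, {
    n_chim <- round(n * chimerism_rate)
    is_chim <- rep(FALSE, n)
    if (n_chim > 0L) is_chim[sample.int(n, n_chim)] <- TRUE

    v_call <- character(n)
    seq_aln <- character(n)
    germ_aln <- character(n)
    germ_end <- integer(n)
    parents <- character(n)
    bp_col <- rep(NA_integer_, n)
    seq_msa <- character(n)

    for (i in seq_len(n)) {
      if (is_chim[i]) {
        pr <- sample.int(G, 2L)
        ch <- make_chimera(list(name = genotype$allele[pr[1L]], seq = genotype$seq[pr[1L]]),
                           list(name = genotype$allele[pr[2L]], seq = genotype$seq[pr[2L]]),
                           shm_rate = shm_rate)
        q <- ch$chars
        parents[i] <- paste(genotype$allele[pr], collapse = "/")
        bp_col[i] <- ch$breakpoint_column
      } else {
        src <- sample.int(G, 1L)
        q <- .mutate_chars(mat[src, ], shm_rate)
        parents[i] <- genotype$allele[src]
      }
      q <- .mutate_chars(q, seq_error_rate)

      q_is_nt <- q %in% NTS
      d <- colSums((tmat != q) & t_is_nt & q_is_nt)
      assigned <- which.min(d)  # ties -> first in database order
      v_call[i] <- genotype$allele[assigned]
      a_chars <- mat[assigned, ]
      keep <- !(a_chars == "-" & q == "-")
      seq_aln[i] <- paste(q[keep], collapse = "")
      germ_aln[i] <- paste(a_chars[keep], collapse = "")
      germ_end[i] <- ungapped_len[[assigned]]
      thr <- q
      thr[a_chars == "-"] <- "N"
      seq_msa[i] <- paste(thr, collapse = "")
    }

    ids <- sprintf("sim-%06d", seq_len(n))
    airr <- data.frame(
      sequence_id = ids, v_call = v_call,
      v_sequence_alignment = seq_aln, v_germline_alignment = germ_aln,
      v_germline_start = 1L, v_germline_end = germ_end,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      sequence_id = ids, is_chimera = is_chim, parent_alleles = parents,
      breakpoint_column = bp_col, true_shm_rate = shm_rate,
      sequence_msa = seq_msa, stringsAsFactors = FALSE
    )
    list(airr = airr, truth = truth)
  })
}

#' Write a simulated dataset to disk
#'
#' Writes `<prefix>.airr.tsv` (consumable by [run_detection()]),
#' `<prefix>.truth.tsv`, and — when the genotype is supplied —
#' `<prefix>.genotype.fasta` for reproducibility.
#'
#' @param sim Result of [simulate_dataset()].
#' @param out_prefix Output path prefix.
#' @param genotype Optional `reference_msa` to write alongside.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulated_dataset <- function(sim, out_prefix, genotype = NULL) {
  paths <- c(airr = paste0(out_prefix, ".airr.tsv"),
             truth = paste0(out_prefix, ".truth.tsv"))
  data.table::fwrite(sim$airr, paths[["airr"]], sep = "\t", quote = FALSE,
                     na = "", eol = "\n")
  data.table::fwrite(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     na = "", eol = "\n")
  if (!is.null(genotype)) {
    paths[["genotype"]] <- paste0(out_prefix, ".genotype.fasta")
    write_reference_msa(genotype, paths[["genotype"]])
  }
  invisible(paths)
}
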