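# Shared fixtures and independent reference implementations for tests.
# Everything here is built in code at test time; no files ship with the
# package.

NT4 <- c("A", "C", "G", "T")

rand_seq <- function(L, alphabet = NT4, prob = NULL) {
  paste(sample(alphabet, L, replace = TRUE, prob = prob), collapse = "")
}

make_msa <- function(names, seqs) airrchimera:::new_reference_msa(names, seqs)

write_fasta_tmp <- function(names, seqs, width = NULL) {
  path <- tempfile(fileext = ".fasta")
  lines <- character(0)
  for (i in seq_along(names)) {
    s <- seqs[i]
    body <- if (is.null(width)) s else {
      starts <- seq(1, nchar(s), by = width)
      substring(s, starts, pmin(starts + width - 1, nchar(s)))
    }
    lines <- c(lines, paste0(">", names[i]), body)
  }
  writeLines(lines, path)
  path
}

write_airr_tmp <- function(df) {
  path <- tempfile(fileext = ".tsv")
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "", eol = "\n")
  path
}

# A randomized small HMM instance: random aligned references (with optional
# gaps), random query over {A,C,G,T,-,N}, random rates/psi/mu.
random_instance <- function(seed, Gmax = 5, Kmax = 3, Lmax = 50,
                            gaps = TRUE) {
  set.seed(seed)
  G <- sample(2:Gmax, 1)
  K <- sample(seq_len(Kmax), 1)
  L <- sample(5:Lmax, 1)
  alphabet <- if (gaps) c(NT4, "-") else NT4
  prob <- if (gaps) c(rep(0.23, 4), 0.08) else NULL
  seqs <- replicate(G, rand_seq(L, alphabet, prob))
  msa <- make_msa(sprintf("R%d*01", seq_len(G)), seqs)
  rates <- sort(runif(K, 0, 0.35))
  psi <- runif(1, 1e-4, 0.1)
  mu <- runif(1, 0, 0.1)
  spec <- hmm_spec(msa, rates = rates, psi = psi, mu = mu)
  query <- rand_seq(L, c(NT4, "-", "N"), c(rep(0.21, 4), 0.08, 0.08))
  list(spec = spec, query = query, G = G, K = K, L = L)
}

# Dense transition matrix re-derived from first principles (independent of
# the package's internal constructor): self-transitions keep 1 - psi - mu
# (1 - psi when K = 1, where the rate-switch channel has no targets), mu is
# split over the K - 1 same-reference same-class alternatives, and psi over
# the (G - 1) K chimeric states of other references.
ref_transition_matrix <- function(G, K, psi, mu) {
  n <- 2 * G * K
  ref <- rep(rep(seq_len(G), each = K), 2)
  chim <- rep(c(FALSE, TRUE), each = G * K)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    A[i, j] <-
      if (i == j) { if (K > 1) 1 - psi - mu else 1 - psi }
      else if (ref[i] == ref[j] && chim[i] == chim[j]) mu / (K - 1)
      else if (ref[i] != ref[j] && chim[j]) psi / ((G - 1) * K)
      else 0
  }
  A
}

# Emission matrix (n states x L) from the printed piecewise rule.
ref_emission_matrix <- function(spec, query) {
  obs <- strsplit(toupper(query), "")[[1]]
  G <- spec$G; K <- spec$K
  n <- 2 * G * K
  b <- matrix(NA_real_, n, spec$L)
  for (s in seq_len(n)) {
    g <- ((s - 1) %% (G * K)) %/% K + 1
    m <- spec$rates[(s - 1) %% K + 1]
    ref <- spec$msa$mat[g, ]
    uninf <- ref %in% c("-", "N") | obs %in% c("-", "N")
    b[s, ] <- ifelse(uninf, 1, ifelse(obs == ref, 1 - m, m / 3))
  }
  b
}

# Exhaustive path enumeration: log-probability of every state sequence.
# Only for tiny instances (n^L paths). Returns the path matrix and log probs.
enumerate_paths <- function(spec, query) {
  G <- spec$G; K <- spec$K; L <- spec$L
  n <- 2 * G * K
  stopifnot(n^L <= 4^8 + 1)
  A <- ref_transition_matrix(G, K, spec$psi, spec$mu)
  b <- ref_emission_matrix(spec, query)
  pi0 <- c(rep(1 / (G * K), G * K), rep(0, G * K))
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), L)))
  lp <- log(pi0[paths[, 1]]) + log(b[cbind(paths[, 1], 1)])
  for (t in 2:L) {
    lp <- lp + log(A[cbind(paths[, t - 1], paths[, t])]) + log(b[cbind(paths[, t], t)])
  }
  list(paths = paths, logp = lp, n = n)
}

# Brute-force pairwise AUC (Mann-Whitney with half-credit for ties).
brute_auc <- function(labels, scores) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Small gapless genotype with divergent alleles for end-to-end fixtures.
fixture_genotype <- function(seed = 42) {
  synthesize_germline_msa(n_families = 4, genes_per_family = 3,
                          max_alleles_per_gene = 1, L = 300,
                          deletion_prob = 0, seed = seed)
}

# Discriminating columns of two aligned parent rows: both plain nucleotides
# and different.
discriminating_columns <- function(msa, allele_a, allele_b) {
  a <- msa$mat[match(allele_a, msa$allele), ]
  b <- msa$mat[match(allele_b, msa$allele), ]
  which(a %in% NT4 & b %in% NT4 & a != b)
}
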