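# The chimera HMM: emissions, forward/backward/Viterbi, Baum-Welch.

test_that("emission probabilities follow the piecewise model exactly", {
  expect_identical(emission_prob("A", "A", 0.005), 0.995)
  expect_identical(emission_prob("A", "C", 0.03), 0.01)
  expect_identical(emission_prob("A", "N", 0.2), 1)
  expect_identical(emission_prob("A", "-", 0.2), 1)
  expect_identical(emission_prob("-", "A", 0.2), 1)
  expect_identical(emission_prob("N", "G", 0.2), 1)
  expect_identical(emission_prob("G", "G", 0), 1)
  expect_identical(emission_prob("G", "T", 0), 0)
  # vectorized over a reference row
  expect_equal(emission_prob(c("A", "C", "-", "T"), c("A", "T", "G", "N"), 0.3),
               c(0.7, 0.1, 1, 1))
  expect_error(emission_prob("A", "X", 0.1), class = "airrchimera_character_error")
  expect_error(emission_prob("A", "A", 1), class = "airrchimera_parameter_error")
})

test_that("structured linear-time forward agrees with the dense oracle", {
  for (seed in 1:40) {
    inst <- random_instance(seed)
    f <- chmm_forward(inst$query, inst$spec)
    o <- chmm_forward_oracle(inst$query, inst$spec)
    expect_lt(abs(f$chimera_posterior - o$chimera_posterior), 1e-9)
    expect_lt(abs(f$log_likelihood - o$log_likelihood), 1e-8)
  }
})

test_that("forward posterior behaves as the model predicts on canonical queries", {
  set.seed(11)
  s1 <- rand_seq(100)
  ch1 <- strsplit(s1, "")[[1]]
  ch2 <- ch1
  flip <- sample(100, 30)
  ch2[flip] <- vapply(ch1[flip], function(x) sample(setdiff(NT4, x), 1), "")
  msa <- make_msa(c("R1*01", "R2*01"), c(s1, paste(ch2, collapse = "")))
  spec <- hmm_spec(msa, rates = 0.005, psi = 0.002, mu = 0)

  # pure reference: low posterior; agrees with the oracle
  f_pure <- chmm_forward(s1, spec)
  expect_lt(f_pure$chimera_posterior, 0.01)
  expect_lt(abs(f_pure$chimera_posterior -
                chmm_forward_oracle(s1, spec)$chimera_posterior), 1e-9)

  # half/half chimera: posterior near 1
  chim <- paste0(substr(s1, 1, 50), substr(paste(ch2, collapse = ""), 51, 100))
  f_chim <- chmm_forward(chim, spec)
  expect_gt(f_chim$chimera_posterior, 0.99)
  expect_lt(abs(f_chim$chimera_posterior -
                chmm_forward_oracle(chim, spec)$chimera_posterior), 1e-9)

  # psi = 0: no path can enter a chimeric state
  spec0 <- hmm_spec(msa, rates = 0.005, psi = 0, mu = 0.002)
  expect_identical(chmm_forward(chim, spec0)$chimera_posterior, 0)

  # all-N query: posterior is purely transition-driven, 1 - (1 - psi)^(L-1)
  msa10 <- make_msa(c("R1*01", "R2*01"),
                    c(rand_seq(10), rand_seq(10)))
  for (K in c(1L, 3L)) {
    specN <- hmm_spec(msa10, rates = seq(0.01, 0.05, length.out = K),
                      psi = 0.01, mu = if (K > 1) 0.03 else 0.002)
    fN <- chmm_forward(strrep("N", 10), specN)
    expect_equal(fN$chimera_posterior, 1 - (1 - 0.01)^9, tolerance = 1e-12)
    expect_equal(chmm_forward_oracle(strrep("N", 10), specN)$chimera_posterior,
                 fN$chimera_posterior, tolerance = 1e-12)
  }
})

test_that("implied transition matrix rows are stochastic and the posterior is normalized", {
  for (K in c(1L, 4L)) {
    A <- airrchimera:::dense_transition_matrix(5L, K, 0.01, 0.04)
    expect_equal(rowSums(A), rep(1, 2 * 5 * K), tolerance = 1e-12)
  }
  inst <- random_instance(99)
  f <- chmm_forward(inst$query, inst$spec, retain_lattice = TRUE)
  # scaled columns each sum to 1, so P(chimera|O) + P(non-chimera|O) = 1
  expect_equal(colSums(f$alpha), rep(1, inst$L), tolerance = 1e-12)
})

test_that("posterior is invariant under reference permutation and monotone in psi", {
  inst <- random_instance(7)
  msa <- inst$spec$msa
  set.seed(1)
  perm <- sample(msa$G)
  msa_p <- make_msa(msa$allele[perm], msa$seq[perm])
  spec_p <- hmm_spec(msa_p, rates = inst$spec$rates, psi = inst$spec$psi,
                     mu = inst$spec$mu)
  expect_lt(abs(chmm_forward(inst$query, inst$spec)$chimera_posterior -
                chmm_forward(inst$query, spec_p)$chimera_posterior), 1e-12)

  msa2 <- make_msa(c("R1*01", "R2*01"), c(rand_seq(40), rand_seq(40)))
  post <- vapply(c(0.001, 0.005, 0.02, 0.1), function(psi) {
    chmm_forward(strrep("N", 40), hmm_spec(msa2, rates = 0.01, psi = psi))$chimera_posterior
  }, numeric(1))
  expect_true(all(diff(post) > 0))
})

test_that("backward lattice is consistent with forward at every column", {
  for (seed in 1:15) {
    inst <- random_instance(seed + 100)
    f <- chmm_forward(inst$query, inst$spec, retain_lattice = TRUE)
    b <- chmm_backward(inst$query, inst$spec, scales = f$scales)
    gamma <- f$alpha * b
    expect_equal(colSums(gamma), rep(1, inst$L), tolerance = 1e-9)
  }
  # L = 1: backward is all ones under the scaling convention
  msa <- make_msa(c("R1*01", "R2*01"), c("A", "C"))
  spec <- hmm_spec(msa, rates = 0.1)
  expect_equal(as.numeric(chmm_backward("A", spec)), rep(1, 4))
})

test_that("posterior state marginals match exhaustive path enumeration", {
  for (seed in 1:3) {
    set.seed(seed + 300)
    L <- 6L
    msa <- make_msa(c("R1*01", "R2*01"), c(rand_seq(L), rand_seq(L)))
    spec <- hmm_spec(msa, rates = runif(1, 0.01, 0.2),
                     psi = runif(1, 0.01, 0.1), mu = 0.01)
    query <- rand_seq(L, c(NT4, "N"), c(rep(0.22, 4), 0.12))
    enum <- enumerate_paths(spec, query)
    w <- exp(enum$logp - max(enum$logp))
    w <- w / sum(w)
    f <- chmm_forward(query, spec, retain_lattice = TRUE)
    b <- chmm_backward(query, spec, scales = f$scales)
    gamma <- f$alpha * b
    for (t in seq_len(L)) {
      marg <- vapply(seq_len(enum$n), function(s) sum(w[enum$paths[, t] == s]),
                     numeric(1))
      expect_equal(gamma[, t], marg, tolerance = 1e-9)
    }
    # chimera posterior equals the enumerated chimeric-terminal mass
    chim_states <- (enum$n / 2 + 1):enum$n
    expect_equal(f$chimera_posterior, sum(w[enum$paths[, L] %in% chim_states]),
                 tolerance = 1e-9)
  }
})

test_that("Viterbi decodes a constant path for pure queries and localizes breakpoints", {
  set.seed(5)
  s1 <- rand_seq(100)
  ch1 <- strsplit(s1, "")[[1]]
  ch2 <- ch1
  informative <- seq(5, 100, by = 5)  # parents differ at every 5th column
  ch2[informative] <- vapply(ch1[informative], function(x) sample(setdiff(NT4, x), 1), "")
  msa <- make_msa(c("R1*01", "R2*01"), c(s1, paste(ch2, collapse = "")))
  spec <- hmm_spec(msa, rates = 0.005, psi = 0.002, mu = 0.002)

  v_pure <- chmm_viterbi(s1, spec)
  expect_equal(length(unique(v_pure$state_path)), 1L)
  expect_equal(nrow(v_pure$events), 0L)
  expect_equal(format_recombination(v_pure$events, spec$L), "")

  # chimera switching R1 -> R2 at column 50: the breakpoint is identifiable
  # up to the interval between the flanking informative columns (45, 50]
  chim <- paste0(substr(s1, 1, 49), paste(ch2[50:100], collapse = ""))
  v <- chmm_viterbi(chim, spec)
  expect_equal(nrow(v$events), 1L)
  expect_equal(v$events$from_allele, "R1*01")
  expect_equal(v$events$to_allele, "R2*01")
  expect_gte(v$events$breakpoint_column, 46L)
  expect_lte(v$events$breakpoint_column, 50L)

  # once in a chimeric state a path never returns to the non-chimeric half
  GK <- spec$G * spec$K
  in_chim <- v$state_path > GK
  expect_true(all(diff(in_chim) >= 0))
})

test_that("Viterbi matches exhaustive enumeration and is bounded by the forward likelihood", {
  for (seed in 1:5) {
    set.seed(seed + 400)
    L <- 8L
    msa <- make_msa(c("R1*01", "R2*01"), c(rand_seq(L), rand_seq(L)))
    spec <- hmm_spec(msa, rates = runif(1, 0.01, 0.3),
                     psi = runif(1, 0.005, 0.1), mu = 0.02)
    query <- rand_seq(L, c(NT4, "N"), c(rep(0.22, 4), 0.12))
    enum <- enumerate_paths(spec, query)
    v <- chmm_viterbi(query, spec)
    best <- max(enum$logp)
    expect_equal(v$log_prob, best, tolerance = 1e-9)
    ord <- order(enum$logp, decreasing = TRUE)
    if (enum$logp[ord[1]] - enum$logp[ord[2]] > 1e-9) {
      expect_equal(v$state_path, unname(enum$paths[ord[1], ]))
    }
  }
  for (seed in 1:20) {
    inst <- random_instance(seed + 500)
    expect_lte(chmm_viterbi(inst$query, inst$spec)$log_prob,
               chmm_forward(inst$query, inst$spec)$log_likelihood + 1e-10)
  }
})

test_that("Baum-Welch recovers planted rates, floors at zero mismatches, and ascends", {
  geno <- fixture_genotype()
  spec <- hmm_spec(geno, rates = 0.05, mode = "BW")

  # identical query -> rate at the 1e-6 floor for its reference
  bw0 <- baum_welch_rates(geno$seq[3], spec)
  expect_equal(unname(bw0$rates[3]), 1e-6)

  # quick recovery check (the full 50-replicate study is in the acceptance suite)
  set.seed(21)
  err <- vapply(1:10, function(i) {
    src <- (i %% geno$G) + 1L
    q <- mutate_uniform(geno$seq[src], 0.10)
    abs(unname(baum_welch_rates(q, spec)$rates[src]) - 0.10)
  }, numeric(1))
  expect_lt(mean(err), 0.03)

  # EM ascent: log-likelihood trace is non-decreasing
  set.seed(22)
  for (i in 1:5) {
    q <- mutate_uniform(geno$seq[sample(geno$G, 1)], runif(1, 0, 0.2))
    tr <- baum_welch_rates(q, spec, init_rate = 0.2)$log_likelihood_trace
    expect_true(all(diff(tr) > -1e-8))
  }

  expect_error(baum_welch_rates(geno$seq[1], hmm_spec(geno, rates = 0.05)),
               class = "airrchimera_mode_error")
})

test_that("posterior threshold is strict and DB/BW calls agree on unmutated repertoires", {
  expect_true(posterior_threshold(0.99, 0.95))
  expect_false(posterior_threshold(0.95, 0.95))
  expect_false(posterior_threshold(0.0, 0.95))
  expect_error(posterior_threshold(0.5, 1), class = "airrchimera_parameter_error")

  geno <- fixture_genotype()
  sim <- simulate_dataset(geno, 1000, chimerism_rate = 0.05, shm_rate = 0,
                          seq_error_rate = 0, seed = 33)
  spec_db <- hmm_spec(geno, rates = 0.005, psi = 0.002, mu = 0.002, mode = "DB")
  spec_bw <- hmm_spec(geno, rates = 0.05, psi = 0.002, mu = 0.002, mode = "BW")
  agree <- vapply(sim$truth$sequence_msa, function(q) {
    db_call <- posterior_threshold(chmm_forward(q, spec_db), 0.95)
    bw_call <- posterior_threshold(baum_welch_rates(q, spec_bw)$forward, 0.95)
    db_call == bw_call
  }, logical(1), USE.NAMES = FALSE)
  expect_gte(mean(agree), 0.99)
})
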