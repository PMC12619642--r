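# The chimera-detecting HMM.
#
# States are (germline allele, mutation-rate category) pairs, duplicated into
# a non-chimeric and a chimeric copy; only transitions into the chimeric copy
# of a *different* allele are allowed (template switching), so any lattice
# path ending in a chimeric state switched at least once and the Forward mass
# of the chimeric half at the final column is P(O, chimera). Underflow is
# controlled by per-column normalization with an accumulated log scale, which
# keeps the linear-time algebra in plain arithmetic.

#' Construct an HMM specification
#'
#' Bundles the reference MSA with the model parameters: the mutation-rate
#' categories, the per-column probability `psi` of switching to a different
#' reference (template switching), and the per-column probability `mu` of
#' switching rate category within the same reference. The state count is
#' `2 * G * K`; within each half, states are ordered reference-major, rate
#' category fastest.
#'
#' @param msa A `reference_msa` with at least 2 alleles.
#' @param rates Numeric vector of K mutation rates in `[0, 0.5)`. BW mode
#'   requires K = 1 (the single rate is the Baum-Welch initialization).
#' @param psi Per-column template-switch probability (>= 0; `psi + mu < 1`).
#' @param mu Per-column rate-category switch probability (>= 0). With K = 1
#'   there are no alternative rate categories, so the `mu` channel is inert
#'   and self-transitions keep probability `1 - psi`.
#' @param mode `"DB"` (discretized rate grid) or `"BW"` (Baum-Welch
#'   per-reference rate estimation).
#' @return An `hmm_spec` object.
#' @export
hmm_spec <- function(msa, rates, psi = 0.002, mu = 0.002, mode = c("DB", "BW")) {
  mode <- match.arg(mode)
  stopifnot(inherits(msa, "reference_msa"))
  if (msa$G < 2L) stop_db("reference database too small: the HMM needs G >= 2 alleles")
  rates <- as.numeric(rates)
  if (length(rates) < 1L || any(is.na(rates)) || any(rates < 0) || any(rates >= 0.5)) {
    stop_parameter("`rates` must be K >= 1 values in [0, 0.5)")
  }
  if (mode == "BW" && length(rates) != 1L) {
    stop_mode("BW mode uses a single rate category (K = 1)")
  }
  if (!is.numeric(psi) || psi < 0 || !is.numeric(mu) || mu < 0 || psi + mu >= 1) {
    stop_parameter("need psi >= 0, mu >= 0 and psi + mu < 1")
  }
  structure(
    list(msa = msa, rates = rates, K = length(rates), G = msa$G, L = msa$L,
         psi = psi, mu = mu, mode = mode,
         ref_is_nt = matrix(msa$mat %in% NTS, nrow = msa$G)),
    class = "hmm_spec"
  )
}

#' @export
print.hmm_spec <- function(x, ...) {
  cat(sprintf("hmm_spec (%s): G=%d references, K=%d rate(s), L=%d columns, psi=%g, mu=%g\n",
              x$mode, x$G, x$K, x$L, x$psi, x$mu))
  invisible(x)
}

#' Emission probability of an observed nucleotide
#'
#' The piecewise emission model: `1 - m` when the observation matches the
#' reference nucleotide, `m/3` when both are plain nucleotides and they
#' differ, and 1 when either side is a gap (`-`) or an ambiguous `N` —
#' a gap or N can neither support nor contradict any reference, so it leaves
#' the lattice untouched.
#'
#' @param ref_nt,obs_nt Characters in `{A,C,G,T,-,N}` (vectorized).
#' @param m Mutation rate(s) in `[0, 1)`.
#' @return Numeric vector of emission probabilities.
#' @examples
#' emission_prob("A", "A", 0.005)  # 0.995
#' emission_prob("A", "C", 0.03)   # 0.01
#' emission_prob("A", "N", 0.2)    # 1
#' @export
emission_prob <- function(ref_nt, obs_nt, m) {
  ref_nt <- normalize_aligned(ref_nt)
  obs_nt <- normalize_aligned(obs_nt)
  ok <- c(NTS, "-", "N")
  if (any(!ref_nt %in% ok) || any(!obs_nt %in% ok)) {
    stop_character("nucleotide characters must be in {A,C,G,T,-,N}")
  }
  if (any(m < 0) || any(m >= 1)) stop_parameter("mutation rate must be in [0, 1)")
  uninf <- ref_nt %in% c("-", "N") | obs_nt %in% c("-", "N")
  ifelse(uninf, 1, ifelse(obs_nt == ref_nt, 1 - m, m / 3))
}

# Coerce a query (threaded_query, length-L string, or character vector of
# single characters) to a validated character vector of MSA columns.
as_obs_chars <- function(query, L) {
  obs <- if (inherits(query, "threaded_query")) {
    query$chars %||% chars1(query$columns)
  } else if (is.character(query) && length(query) == 1L && nchar(query) > 1L) {
    chars1(query)
  } else if (is.character(query)) {
    query
  } else {
    stop_parameter("`query` must be a threaded_query or a character sequence")
  }
  obs <- normalize_aligned(obs)
  if (length(obs) != L) {
    stop_lattice(sprintf("query length %d does not match the MSA's %d columns",
                         length(obs), L))
  }
  if (any(!obs %in% c(NTS, "-", "N"))) {
    stop_character("query contains characters outside {A,C,G,T,-,N}")
  }
  obs
}

# Emission codes: G x L integer matrix; 0 match, 1 mismatch, 2 uninformative.
obs_codes <- function(spec, obs) {
  G <- spec$G
  mm <- spec$msa$mat != rep(obs, each = G)
  codes <- matrix(0L, G, spec$L)
  codes[mm] <- 1L
  codes[!spec$ref_is_nt] <- 2L
  codes[, obs %in% c("-", "N")] <- 2L
  codes
}

# rates may be NULL (use spec$rates for every reference) or a per-reference
# override: a length-G vector or G x K matrix (used by BW mode).
rate_matrix <- function(spec, rates = NULL) {
  if (is.null(rates)) {
    matrix(spec$rates, spec$G, spec$K, byrow = TRUE)
  } else if (is.matrix(rates)) {
    stopifnot(nrow(rates) == spec$G)
    rates
  } else {
    stopifnot(length(rates) == spec$G)
    matrix(rates, spec$G, 1L)
  }
}

#' Forward algorithm: chimera posterior in O(L G K)
#'
#' Computes the Forward lattice with the structured induction (self term,
#' same-reference rate-switch term, and a cross-reference term feeding only
#' chimeric states of other references), with per-column rescaling. The
#' chimera posterior is the normalized mass of the chimeric half of the
#' final column.
#'
#' @param query A `threaded_query` or a length-L sequence over
#'   `{A,C,G,T,-,N}`.
#' @param spec An `hmm_spec`.
#' @param rates Optional per-reference rate override (length-G vector or
#'   G x K matrix); used internally by BW mode.
#' @param retain_lattice Keep the scaled alpha lattice (needed for
#'   Baum-Welch / posterior marginals).
#' @return A `chmm_forward` list: `log_likelihood` (log P(O)),
#'   `chimera_posterior` (P(chimera | O)), `scales`, and optionally `alpha`
#'   (the 2GK x L column-normalized lattice).
#' @export
chmm_forward <- function(query, spec, rates = NULL, retain_lattice = FALSE) {
  stopifnot(inherits(spec, "hmm_spec"))
  obs <- as_obs_chars(query, spec$L)
  res <- chmm_forward_cpp(obs_codes(spec, obs), rate_matrix(spec, rates),
                          spec$psi, spec$mu, retain_lattice)
  structure(res, class = "chmm_forward")
}

#' @export
print.chmm_forward <- function(x, ...) {
  cat(sprintf("chmm_forward: P(chimera|O) = %.6g, log P(O) = %.4f\n",
              x$chimera_posterior, x$log_likelihood))
  invisible(x)
}

#' Dense-matrix Forward oracle (quadratic reference implementation)
#'
#' Identical contract to [chmm_forward()], computed by explicit dense
#' transition-matrix multiplication in O(L (GK)^2). Intended for small
#' instances and used as the independent reference for validating the
#' structured linear-time induction.
#'
#' @inheritParams chmm_forward
#' @return As [chmm_forward()] (always retains the lattice).
#' @export
chmm_forward_oracle <- function(query, spec, rates = NULL) {
  stopifnot(inherits(spec, "hmm_spec"))
  obs <- as_obs_chars(query, spec$L)
  G <- spec$G; L <- spec$L
  rm_ <- rate_matrix(spec, rates)
  K <- ncol(rm_)  # effective rate-category count (a BW override has K = 1)
  n <- 2L * G * K
  if (G * K > 200L) stop_parameter("oracle is intended for small instances (G*K <= 200)")
  A <- dense_transition_matrix(G, K, spec$psi, spec$mu)
  ref_of <- rep(rep(seq_len(G), each = K), 2L)
  rate_of <- rep(rep(seq_len(ncol(rm_)), G), 2L)
  chim <- rep(c(FALSE, TRUE), each = G * K)
  # emissions recomputed from first principles (independent of obs_codes)
  bmat <- matrix(NA_real_, n, L)
  for (i in seq_len(n)) {
    bmat[i, ] <- emission_prob(spec$msa$mat[ref_of[i], ], obs, rm_[ref_of[i], rate_of[i]])
  }
  pi0 <- ifelse(chim, 0, 1 / (G * K))
  alpha <- matrix(0, n, L)
  scales <- numeric(L)
  a <- pi0 * bmat[, 1L]
  scales[1L] <- sum(a)
  a <- a / scales[1L]
  alpha[, 1L] <- a
  if (L > 1L) for (t in 2:L) {
    a <- as.numeric(crossprod(A, a)) * bmat[, t]
    scales[t] <- sum(a)
    a <- a / scales[t]
    alpha[, t] <- a
  }
  structure(list(log_likelihood = sum(log(scales)),
                 chimera_posterior = sum(a[chim]),
                 scales = scales, alpha = alpha),
            class = "chmm_forward")
}

# The implied dense transition matrix; every row sums to 1.
dense_transition_matrix <- function(G, K, psi, mu) {
  n <- 2L * G * K
  self_p <- if (K > 1L) 1 - psi - mu else 1 - psi
  mu_p <- if (K > 1L) mu / (K - 1) else 0
  cross_p <- psi / ((G - 1) * K)
  ref_of <- rep(rep(seq_len(G), each = K), 2L)
  chim <- rep(c(FALSE, TRUE), each = G * K)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    A[i, j] <- if (i == j) self_p
      else if (ref_of[i] == ref_of[j] && chim[i] == chim[j]) mu_p
      else if (ref_of[i] != ref_of[j] && chim[j]) cross_p
      else 0
  }
  A
}

#' Backward algorithm (scaled lattice)
#'
#' Linear-time backward pass under the scaling convention of
#' [chmm_forward()]: with `alpha` and `beta` both from the shared scales,
#' `alpha * beta` gives posterior state marginals and each column of the
#' product sums to 1 (equivalently, the unscaled identity
#' \eqn{\sum_i \alpha_t(i)\beta_t(i) = P(O)} holds at every column).
#'
#' @inheritParams chmm_forward
#' @param scales Column scales from a forward pass on the same query; if
#'   omitted the forward pass is run internally.
#' @return A 2GK x L matrix of scaled backward values.
#' @export
chmm_backward <- function(query, spec, rates = NULL, scales = NULL) {
  stopifnot(inherits(spec, "hmm_spec"))
  obs <- as_obs_chars(query, spec$L)
  codes <- obs_codes(spec, obs)
  rm_ <- rate_matrix(spec, rates)
  if (is.null(scales)) {
    scales <- chmm_forward_cpp(codes, rm_, spec$psi, spec$mu, FALSE)$scales
  }
  chmm_backward_cpp(codes, rm_, spec$psi, spec$mu, scales)
}

#' Viterbi decoding: most likely path, parents, and breakpoints
#'
#' Maximum-probability state path under the same model, computed in
#' O(L G K) by precomputing, per column, the global best and the best
#' predecessor with a different reference (plus per-reference top-2 scores
#' for the rate-switch channel). Ties break toward the lowest state index.
#' Reference switches along the path become recombination events; the
#' breakpoint is the first MSA column (1-based) held by the new reference.
#'
#' @inheritParams chmm_forward
#' @return A `chmm_viterbi` list: `state_path` (length-L state indices),
#'   `log_prob`, and `events` (data.frame with `from_allele`, `to_allele`,
#'   `breakpoint_column`; zero rows for a non-chimeric path).
#' @export
chmm_viterbi <- function(query, spec, rates = NULL) {
  stopifnot(inherits(spec, "hmm_spec"))
  obs <- as_obs_chars(query, spec$L)
  res <- chmm_viterbi_cpp(obs_codes(spec, obs), rate_matrix(spec, rates),
                          spec$psi, spec$mu)
  path <- res$path
  GK <- spec$G * spec$K
  refs <- ((path - 1L) %% GK) %/% spec$K + 1L
  sw <- which(refs[-1L] != refs[-length(refs)]) + 1L
  events <- data.frame(
    from_allele = spec$msa$allele[refs[sw - 1L]],
    to_allele = spec$msa$allele[refs[sw]],
    breakpoint_column = as.integer(sw),
    stringsAsFactors = FALSE
  )
  structure(list(state_path = path, log_prob = res$log_prob, events = events),
            class = "chmm_viterbi")
}

#' @export
print.chmm_viterbi <- function(x, ...) {
  cat(sprintf("chmm_viterbi: log prob %.4f, %d recombination event(s)\n",
              x$log_prob, nrow(x$events)))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Baum-Welch re-estimation of per-reference mutation rates
#'
#' BW mode: two states per reference (non-chimeric/chimeric), one continuous
#' mutation rate per reference re-estimated by EM. Each iteration runs the
#' scaled forward/backward pass at the current rates and sets every
#' reference's new rate to its expected mismatch emissions over its expected
#' informative emissions, where expectations weight columns by posterior
#' state occupancy (that reference's chimeric and non-chimeric states
#' pooled) and only columns with a plain nucleotide on both sides count.
#' Rates are clamped to `[1e-6, 0.5]`.
#'
#' @param query A `threaded_query` or length-L sequence.
#' @param spec An `hmm_spec` with `mode = "BW"` (K = 1).
#' @param init_rate Starting rate for every reference, in (0, 0.5).
#' @param max_iter Maximum EM iterations.
#' @param tol Stop when the largest rate change falls below this.
#' @return A list: `rates` (named per-allele estimates), `forward` (the
#'   final [chmm_forward()] result at the fitted rates, whose
#'   `chimera_posterior` is the BW-mode output), `n_iter`, and
#'   `log_likelihood_trace`.
#' @export
baum_welch_rates <- function(query, spec, init_rate = 0.05, max_iter = 10L,
                             tol = 1e-3) {
  stopifnot(inherits(spec, "hmm_spec"))
  if (spec$mode != "BW" || spec$K != 1L) {
    stop_mode("baum_welch_rates requires an hmm_spec with mode = 'BW' (K = 1)")
  }
  if (!is.numeric(init_rate) || init_rate <= 0 || init_rate >= 0.5) {
    stop_parameter("`init_rate` must be in (0, 0.5)")
  }
  obs <- as_obs_chars(query, spec$L)
  codes <- obs_codes(spec, obs)
  G <- spec$G
  informative <- codes != 2L
  mismatch <- codes == 1L
  rates <- rep(init_rate, G)
  trace <- numeric(0)
  n_iter <- 0L
  for (iter in seq_len(max_iter)) {
    rm_ <- matrix(rates, G, 1L)
    fw <- chmm_forward_cpp(codes, rm_, spec$psi, spec$mu, TRUE)
    bw <- chmm_backward_cpp(codes, rm_, spec$psi, spec$mu, fw$scales)
    gamma <- fw$alpha * bw
    occ <- gamma[seq_len(G), , drop = FALSE] + gamma[G + seq_len(G), , drop = FALSE]
    num <- rowSums(occ * mismatch)
    den <- rowSums(occ * informative)
    new_rates <- ifelse(den > 0, num / den, rates)
    new_rates <- pmin(pmax(new_rates, 1e-6), 0.5)
    trace <- c(trace, fw$log_likelihood)
    n_iter <- iter
    delta <- max(abs(new_rates - rates))
    rates <- new_rates
    if (delta < tol) break
  }
  final <- chmm_forward(obs, spec, rates = rates, retain_lattice = FALSE)
  trace <- c(trace, final$log_likelihood)
  list(rates = stats::setNames(rates, spec$msa$allele), forward = final,
       n_iter = n_iter, log_likelihood_trace = trace)
}

#' Threshold a chimera posterior
#'
#' A query is called chimeric iff its posterior strictly exceeds the
#' threshold (default 0.95).
#'
#' @param result A `chmm_forward` result or a bare posterior probability.
#' @param threshold Detection threshold in (0, 1).
#' @return Logical.
#' @export
posterior_threshold <- function(result, threshold = 0.95) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop_parameter("`threshold` must be in (0, 1)")
  }
  p <- if (inherits(result, "chmm_forward")) result$chimera_posterior else result
  p > threshold
}
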