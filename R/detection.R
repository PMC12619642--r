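# End-to-end detection: load database and AIRR file, thread queries, run the
# HMM in the configured mode, apply the threshold and DFR prefilter, and
# write the augmented AIRR table.

#' Build a detection configuration
#'
#' Receptor presets follow the locus biology: TCR loci lack somatic
#' hypermutation, so TCR data defaults to DB mode with a single fixed
#' mutation rate of 0.005 that absorbs sequencing error; immunoglobulin data
#' defaults to BW mode, re-estimating a continuous per-reference mutation
#' rate initialized at 0.05. When DB mode is forced for IG data, SHM is
#' discretized into a grid of 15 rate categories evenly spaced over
#' [0, 0.25].
#'
#' @param receptor `"IG"` or `"TCR"`.
#' @param mode `"DB"` or `"BW"`; default derived from `receptor`.
#' @param segment `"V"` (default) or `"J"`. J analysis reuses the V presets.
#' @param threshold Posterior probability above which a query is called
#'   chimeric (strictly greater; default 0.95).
#' @param fixed_rate Single DB-mode rate used for TCR data (default 0.005).
#' @param rate_grid DB-mode rate grid used for IG data (default 15 values
#'   over [0, 0.25]).
#' @param bw_init BW-mode initialization rate (default 0.05).
#' @param psi Per-column prior probability of switching to a different
#'   reference (default 0.002).
#' @param mu Per-column prior probability of switching rate category within
#'   the same reference (default 0.002).
#' @param min_dfr Minimum differences-from-reference; rows below it skip HMM
#'   evaluation and pass through as non-chimeric (0 = off).
#' @param detailed Compute Viterbi parents/breakpoints for every row rather
#'   than only for flagged rows.
#' @param seed Reserved; detection itself is deterministic.
#' @return A `detection_config` list.
#' @export
detection_config <- function(receptor = c("IG", "TCR"), mode = NULL,
                             segment = c("V", "J"), threshold = 0.95,
                             fixed_rate = 0.005,
                             rate_grid = seq(0, 0.25, length.out = 15),
                             bw_init = 0.05, psi = 0.002, mu = 0.002,
                             min_dfr = 0L, detailed = FALSE, seed = NULL) {
  if (!is.character(receptor) || !all(receptor %in% c("IG", "TCR"))) {
    stop_parameter("`receptor` must be \"IG\" or \"TCR\"")
  }
  receptor <- match.arg(receptor)
  segment <- match.arg(segment)
  mode <- if (is.null(mode)) {
    if (receptor == "TCR") "DB" else "BW"
  } else {
    match.arg(mode, c("DB", "BW"))
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop_parameter("`threshold` must be in (0, 1)")
  }
  if (!is_count(min_dfr) || min_dfr < 0) stop_parameter("`min_dfr` must be a non-negative integer")
  structure(
    list(receptor = receptor, mode = mode, segment = segment,
         threshold = threshold, fixed_rate = fixed_rate,
         rate_grid = rate_grid, bw_init = bw_init, psi = psi, mu = mu,
         min_dfr = as.integer(min_dfr), detailed = isTRUE(detailed),
         seed = seed),
    class = "detection_config"
  )
}

#' Receptor-specific preset configuration
#'
#' @param receptor `"IG"` or `"TCR"`.
#' @return A `detection_config`: TCR gives DB mode with a fixed 0.005 rate;
#'   IG gives BW mode initialized at 0.05. All other fields at defaults.
#' @export
apply_receptor_preset <- function(receptor) {
  detection_config(receptor = receptor)
}

#' Format recombination events as allele blocks with column ranges
#'
#' Serializes a Viterbi event list as contiguous template blocks:
#' `"alleleA(1-150)/alleleB(151-296)"`, with 1-based inclusive MSA column
#' ranges covering `1..L`. Returns `""` for an empty event list.
#'
#' @param events Data.frame of events from [chmm_viterbi()].
#' @param L MSA column count.
#' @return A single string.
#' @export
format_recombination <- function(events, L) {
  if (is.null(events) || nrow(events) == 0L) return("")
  bps <- events$breakpoint_column
  starts <- c(1L, bps)
  ends <- c(bps - 1L, L)
  alleles <- c(events$from_allele[1L], events$to_allele)
  paste0(alleles, "(", starts, "-", ends, ")", collapse = "/")
}

#' Run chimera detection on an AIRR file
#'
#' For each row: thread onto the MSA, optionally skip rows below the DFR
#' prefilter (passed through as non-chimeric without HMM evaluation), score
#' with the Forward algorithm (DB mode) or Baum-Welch rate estimation
#' (BW mode), call at the threshold, and Viterbi-decode flagged rows (all
#' rows with `detailed = TRUE`). Rows that are malformed or whose assigned
#' allele is absent from the MSA are passed through annotated, never
#' dropped, so the output has exactly one row per input row. Processing is
#' order-preserving and deterministic.
#'
#' @param airr_path Input AIRR Rearrangement TSV.
#' @param msa_path FASTA of the aligned germline database.
#' @param config A `detection_config`.
#' @param out_path Output TSV path (input columns plus call columns).
#' @return Invisibly, a list with `counts` (`evaluated`, `skipped`,
#'   `flagged`) and `calls` (per-row data.frame including a Viterbi `events`
#'   list-column).
#' @export
run_detection <- function(airr_path, msa_path, config, out_path) {
  stopifnot(inherits(config, "detection_config"))
  msa <- read_reference_msa(msa_path)
  parsed <- .read_airr_table(airr_path, config$segment)
  tab <- parsed$table
  n <- nrow(tab)

  rates <- if (config$mode == "BW") {
    config$bw_init
  } else if (config$receptor == "TCR") {
    config$fixed_rate
  } else {
    config$rate_grid
  }
  spec <- hmm_spec(msa, rates = rates, psi = config$psi, mu = config$mu,
                   mode = config$mode)

  p <- if (config$segment == "V") "v" else "j"
  f_id <- as.character(tab$sequence_id)
  f_call <- tab[[paste0(p, "_call")]]
  f_seq <- tab[[paste0(p, "_sequence_alignment")]]
  f_germ <- tab[[paste0(p, "_germline_alignment")]]

  prob <- rep(NA_real_, n)
  chim <- rep(FALSE, n)
  skip <- rep(NA_character_, n)
  align_str <- rep("", n)
  bp_str <- rep("", n)
  events <- vector("list", n)
  empty_events <- data.frame(from_allele = character(0), to_allele = character(0),
                             breakpoint_column = integer(0), stringsAsFactors = FALSE)
  unknown <- integer(0)
  names(unknown) <- character(0)

  for (i in seq_len(n)) {
    events[[i]] <- empty_events
    if (!parsed$valid[i]) { skip[i] <- "malformed"; next }
    rec <- list(sequence_id = f_id[i], v_call = f_call[i],
                v_sequence_alignment = f_seq[i], v_germline_alignment = f_germ[i],
                v_germline_start = parsed$start[i], v_germline_end = parsed$end[i])
    if (config$segment == "J") {
      names(rec) <- c("sequence_id", "j_call", "j_sequence_alignment",
                      "j_germline_alignment", "j_germline_start", "j_germline_end")
    }
    tq <- tryCatch(
      thread_query(rec, msa, config$segment),
      airrchimera_unknown_allele = function(e) {
        al <- trimws(strsplit(f_call[i], ",", fixed = TRUE)[[1L]][1L])
        unknown[al] <<- (if (al %in% names(unknown)) unknown[[al]] else 0L) + 1L
        skip[i] <<- "unknown_allele"
        NULL
      },
      airrchimera_malformed_record = function(e) { skip[i] <<- "malformed"; NULL },
      airrchimera_character_error = function(e) { skip[i] <<- "malformed"; NULL }
    )
    if (is.null(tq)) next
    if (config$min_dfr > 0L && tq$dfr < config$min_dfr) {
      skip[i] <- "below_min_dfr"
      next
    }
    if (config$mode == "DB") {
      prob[i] <- chmm_forward(tq, spec)$chimera_posterior
      qrates <- NULL
    } else {
      bwres <- baum_welch_rates(tq, spec, init_rate = config$bw_init)
      prob[i] <- bwres$forward$chimera_posterior
      qrates <- unname(bwres$rates)
    }
    chim[i] <- prob[i] > config$threshold
    if (chim[i] || config$detailed) {
      vt <- chmm_viterbi(tq, spec, rates = qrates)
      events[[i]] <- vt$events
      align_str[i] <- format_recombination(vt$events, msa$L)
      bp_str[i] <- paste(vt$events$breakpoint_column, collapse = "/")
    }
  }

  for (al in names(unknown)) {
    message(sprintf("allele '%s' named in %s_call is absent from the MSA (%d row(s) skipped)",
                    al, tolower(p), unknown[[al]]))
  }

  calls <- data.frame(sequence_id = f_id %||% character(0),
                      chimera_probability = prob, chimeric = chim,
                      skipped_reason = skip,
                      chimeric_alignments = align_str,
                      recombination_breakpoints = bp_str,
                      stringsAsFactors = FALSE)
  calls$events <- events
  write_airr_with_calls(as.data.frame(tab), calls[setdiff(names(calls), "events")],
                        out_path)
  counts <- list(evaluated = sum(is.na(skip)), skipped = sum(!is.na(skip)),
                 flagged = sum(chim))
  message(sprintf("airrchimera: %d evaluated, %d skipped, %d flagged",
                  counts$evaluated, counts$skipped, counts$flagged))
  invisible(list(counts = counts, calls = calls))
}
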