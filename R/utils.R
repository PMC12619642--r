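# Internal helpers shared across modules.

NTS <- c("A", "C", "G", "T")

# row i = the three substitution alternatives for NTS[i]
ALT_BASES <- matrix(c("C", "G", "T",
                      "A", "G", "T",
                      "A", "C", "T",
                      "A", "C", "G"), nrow = 4L, byrow = TRUE,
                    dimnames = list(NTS, NULL))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers (run_detection, tests) can react per failure
# mode instead of string-matching messages.
stop_airrchimera <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "airrchimera_error", "error", "condition")))
}

stop_parameter <- function(msg) stop_airrchimera(msg, "airrchimera_parameter_error")
stop_db        <- function(msg) stop_airrchimera(msg, "airrchimera_db_error")
stop_alignment <- function(msg) stop_airrchimera(msg, "airrchimera_alignment_error")
stop_character <- function(msg) stop_airrchimera(msg, "airrchimera_character_error")
stop_schema    <- function(msg) stop_airrchimera(msg, "airrchimera_schema_error")
stop_malformed <- function(msg) stop_airrchimera(msg, "airrchimera_malformed_record")
stop_unknown_allele <- function(msg) stop_airrchimera(msg, "airrchimera_unknown_allele")
stop_mode      <- function(msg) stop_airrchimera(msg, "airrchimera_mode_error")
stop_evaluation <- function(msg) stop_airrchimera(msg, "airrchimera_evaluation_error")
stop_lattice   <- function(msg) stop_airrchimera(msg, "airrchimera_lattice_error")

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_parameter("`seed` must be a single non-missing number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Uppercase and map IMGT '.' gaps onto '-'.
normalize_aligned <- function(x) chartr(".", "-", toupper(x))

chars1 <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)
}
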