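# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Classed error constructor. Every validation failure in the package throws a
# condition inheriting from c("cc_error_<class>", "cc_error", "error").
cc_abort <- function(message, class = "invalid_argument", ...) {
  cond <- structure(
    class = c(paste0("cc_error_", class), "cc_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so that library code never perturbs user-level reproducibility.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Polynomial rolling hash (mod a 31-bit prime) of a character
# representation; stamps output files with a configuration fingerprint
# without external dependencies. Not cryptographic, just a fingerprint.
cc_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

stopifnot_count <- function(x, name, min = 0) {
  if (!is_count(x) || x < min) {
    cc_abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
}
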