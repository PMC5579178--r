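# Internal helpers shared across the package.

#' Round half away from zero
#'
#' Lung-RADS thresholds are applied to diameters rounded to the nearest
#' whole millimetre; halves round up (8.5 -> 9), unlike [base::round()]
#' which rounds halves to even.
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, halves away from zero.
#' @keywords internal
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state.  All user-facing randomness in the package goes through this, so
# results are reproducible from a single integer seed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer.", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Fan a single user seed out into independent named substreams (cohort
# generation, tie-breaking, ...) so each component is reproducible on its
# own.  Keeps results inside the 32-bit integer range R requires.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483629)
}

# stop() with a consistent class so callers/tests can distinguish user
# errors (bad arguments), data errors (invalid input values) and schema
# errors (malformed files).
abort_nodulerisk <- function(msg, class) {
  stop(structure(
    class = c(class, "nodulerisk_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

abort_data   <- function(msg) abort_nodulerisk(msg, "nodulerisk_data_error")
abort_schema <- function(msg) abort_nodulerisk(msg, "nodulerisk_schema_error")
abort_usage  <- function(msg) abort_nodulerisk(msg, "nodulerisk_usage_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
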