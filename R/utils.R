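#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Classed error helper so callers can condition on failure modes.
#' @noRd
cb_stop <- function(message, class = "cytoboot_error", call. = FALSE) {
  stop(errorCondition(message, class = c(class, "cytoboot_error", "error", "condition")))
}

cb_warn <- function(message) warning(message, call. = FALSE)

#' Round half away from zero (base round() is round-half-even).
#' @noRd
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Deterministically derive a 32-bit seed from a master seed and string tags.
#'
#' A small multiplicative hash over the tag characters; stays below 2^31 so
#' the result is always a valid R integer seed.
#' @noRd
derive_seed <- function(seed, ...) {
  tag <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  h <- 17
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

#' Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Group-wise column medians.
#'
#' @param values numeric matrix (rows = observations).
#' @param f grouping factor of length nrow(values).
#' @return matrix levels(f) x ncol(values) of medians; rows with no
#'   observations are NA.
#' @noRd
medians_by_group <- function(values, f) {
  f <- as.factor(f)
  idx <- split(seq_along(f), f)
  out <- matrix(NA_real_, nrow = nlevels(f), ncol = ncol(values),
                dimnames = list(levels(f), colnames(values)))
  for (j in seq_len(ncol(values))) {
    x <- values[, j]
    out[, j] <- vapply(idx, function(i) {
      if (length(i) == 0L) NA_real_ else stats::median(x[i])
    }, numeric(1))
  }
  out
}
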