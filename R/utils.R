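#' @keywords internal
"_PACKAGE"

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulator and trainer calls are pure
#' functions of their arguments (including the seed) and never disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  force(code)
}

#' Derive a child seed from a parent seed and a stage label
#'
#' Deterministic, collision-resistant enough for pipeline stage seeding, and
#' always a valid 32-bit R integer.
#'
#' @param seed parent integer seed.
#' @param label character stage label.
#' @return integer seed.
#' @keywords internal
derive_seed <- function(seed, label) {
  h <- utf8ToInt(paste0(label, ":", seed))
  acc <- as.numeric(seed) %% 2147483647
  for (v in h) acc <- (acc * 131 + v) %% 2147483647
  as.integer(acc)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Filled-disc mask
#' @keywords internal
disc_mask <- function(h, w, cx, cy, radius) {
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  (xs - cx)^2 + (ys - cy)^2 <= radius^2
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
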