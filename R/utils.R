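# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
soft_threshold <- function(x, tau) {
  sign(x) * pmax(abs(x) - tau, 0)
}

#' @keywords internal
#' @noRd
spectral_radius <- function(A) {
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' @keywords internal
#' @noRd
block_diag <- function(blocks) {
  stopifnot(length(blocks) >= 1L)
  blocks <- lapply(blocks, as.matrix)
  nr <- vapply(blocks, nrow, integer(1))
  nc <- vapply(blocks, ncol, integer(1))
  out <- matrix(0, sum(nr), sum(nc))
  r0 <- c(0L, cumsum(nr))
  c0 <- c(0L, cumsum(nc))
  for (i in seq_along(blocks)) {
    out[(r0[i] + 1L):r0[i + 1L], (c0[i] + 1L):c0[i + 1L]] <- blocks[[i]]
  }
  out
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
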