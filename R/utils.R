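# Internal helpers: seed fan-out, logging, checksums.

#' Derive a stage seed from a master seed
#'
#' Deterministic counter scheme: stage seeds are
#' `(master * 1000003 + counter) mod (2^31 - 1)`, keeping every derived seed a
#' valid 32-bit integer. Used by all stochastic stages so a single master seed
#' reproduces a full pipeline run, including every knockoff iteration.
#'
#' @param master integer master seed.
#' @param counter non-negative integer offset (stage or iteration index).
#' @return an integer seed.
#' @export
derive_seed <- function(master, counter = 0L) {
  as.integer((as.numeric(master) * 1000003 + as.numeric(counter)) %% 2147483647)
}

rk_log <- function(fmt, ..., verbose = getOption("rewirekit.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

#' @noRd
file_checksum <- function(path) unname(tools::md5sum(path))

# Dense numeric matrix from Matrix or base input, preserving dimnames.
as_dense <- function(m) {
  if (is(m, "Matrix")) as.matrix(m) else as.matrix(m)
}
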