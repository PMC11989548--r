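#' Patient profile fixtures
#'
#' Emits the printed clinical serum profiles - [LDL]:[HDL] ratios 160:50,
#' 140:50 and 90:60, plus the 160:40 variant - followed by `n_extra`
#' synthetic profiles drawn by seeded multiplicative jitter (uniform within
#' +/-10%) around the printed ones.  The same seed always yields the same
#' list; the jitter is the only randomness in the package.
#'
#' @param n_extra Number of additional jittered profiles (>= 0).
#' @param seed Integer RNG seed for the jitter.
#' @return A list of [patient_profile()] objects, the first four being the
#'   printed profiles in the order above.
#' @examples
#' make_fixtures(0)            # the four printed profiles
#' make_fixtures(2, seed = 7)  # plus two jittered ones
#' @export
make_fixtures <- function(n_extra = 0L, seed = 1L) {
  if (!is.numeric(n_extra) || length(n_extra) != 1L || n_extra < 0 ||
      n_extra != round(n_extra)) {
    stop("`n_extra` must be a non-negative integer", call. = FALSE)
  }
  base <- list(
    patient_profile(160, 50),
    patient_profile(140, 50),
    patient_profile(90, 60),
    patient_profile(160, 40)
  )
  if (n_extra == 0L) return(base)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  extras <- lapply(seq_len(n_extra), function(i) {
    parent <- base[[sample.int(length(base), 1L)]]
    jit <- stats::runif(2, 0.9, 1.1)
    patient_profile(parent$ldl * jit[1L], parent$hdl * jit[2L],
                    label = sprintf("synthetic-%d (of %s)", i, parent$label))
  })
  c(base, extras)
}
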