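#' Derive a reproducible sub-stream seed
#'
#' One master seed drives a whole run; each stage (layout, heights, leaves,
#' biomass, sensor noise, ...) draws from its own derived stream so adding a
#' stage never perturbs the draws of earlier stages. The derivation hashes
#' the stage label and an optional index into a 31-bit integer.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @param index optional integer (e.g. plot number) further separating
#'   streams within a stage.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  s <- (as.double(master) * 48271 + h * 69621 + as.double(index) * 16807)
  as.integer(s %% 2147483647)
}

# evaluate `expr` under a derived seed, restoring the caller's RNG state
with_stage_seed <- function(master, stage, index = 0L, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(master, stage, index))
  expr
}
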