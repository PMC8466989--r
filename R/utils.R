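#' @keywords internal
"_PACKAGE"

#' The eleven environmental factors tracked per sample
#'
#' Soil moisture (%), pH, dissolved organic carbon and dissolved nitrogen
#' (ug/g dry soil), total carbon and nitrogen (%), C/N ratio, and four
#' potential extracellular enzyme activities (beta-glucosidase BG,
#' cellobiohydrolase CBH, leucine aminopeptidase LAP, chitinase NAG; nmol
#' MUF per g dry weight per hour).
#'
#' @export
env_factor_names <- function() {
  c("moisture", "pH", "DOC", "DN", "Ctot", "Ntot", "CN",
    "BG", "CBH", "LAP", "NAG")
}

#' Recognised soil horizon labels, from surface downwards
#' @export
horizon_levels <- function() c("topsoil", "cryoOM", "subsoil", "permafrost")

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stop() with a consistent prefix, no call echo
abort <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
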