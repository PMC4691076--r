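#' @importFrom stats coef cor lm pbinom qnorm rbinom rpois runif sd setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#'
#' All stochastic operations in the package draw from seeds passed explicitly
#' through this helper, so a pipeline run is reproducible end to end and never
#' perturbs the caller's random number stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

# sub-stream seeds: keep below 2^31 - 1
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

#' Classify a variant by its REF/ALT alleles
#'
#' @param ref,alt character vectors of reference and alternate alleles.
#' @return character vector with values `"SNV"`, `"MNV"`, `"INS"` or `"DEL"`.
#' @examples
#' variant_kind(c("A", "TT", "A", "CAA"), c("G", "CC", "AT", "C"))
#' @export
variant_kind <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  out <- character(length(ref))
  out[nr == 1L & na == 1L] <- "SNV"
  out[nr > 1L & na == nr] <- "MNV"
  out[na > nr] <- "INS"
  out[na < nr] <- "DEL"
  out
}

variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

# shared empty calls frame (column contract for both callers)
empty_calls <- function() {
  data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), af = numeric(), depth = integer(),
    alt_count = integer(), caller = character(), quality = numeric(),
    quality_band = character(), p_value = numeric(), kind = character(),
    hp_len = integer(),
    stringsAsFactors = FALSE
  )
}
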