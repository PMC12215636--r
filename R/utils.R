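#' Convert calendar ages between cal BP and CE
#'
#' All internal computation uses calibrated years before present
#' (cal BP, datum 1950 CE); the common-era scale is used at input/output
#' edges only.
#'
#' @param cal_bp calendar age(s) in cal BP.
#' @param ce calendar age(s) in years CE.
#' @return Numeric vector on the other scale.
#' @examples
#' calbp_to_ce(700)   # 1250
#' ce_to_calbp(1950)  # 0
#' @export
calbp_to_ce <- function(cal_bp) 1950 - cal_bp

#' @rdname calbp_to_ce
#' @export
ce_to_calbp <- function(ce) 1950 - ce

# Polynomial rolling hash over the deparsed object; used only to stamp
# output files so a rerun with a changed configuration is detectable.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

# Derive n independent sub-seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

# Maximal runs of TRUE in a logical vector, as a two-column matrix of
# first/last indices.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cbind(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
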