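`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' The seven histological subtype codes recognized by the package
#' @return Character vector of subtype codes.
#' @export
sts_subtypes <- function() c("UPS", "MLS", "SS", "MFS", "LMS", "FS", "MPNST")

#' The four subtypes used for the discrimination ANOVA
#' @return Character vector of subtype codes.
#' @export
discrimination_subtypes <- function() c("UPS", "MFS", "MLS", "SS")

# accepts 0/1, true/false, yes/no (any case); returns logical
parse_bool <- function(x, what = "value") {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x0))
  out[x0 %in% c("1", "true", "yes", "t")] <- TRUE
  out[x0 %in% c("0", "false", "no", "f")] <- FALSE
  if (anyNA(out)) {
    stopf("cannot interpret %s '%s' as boolean", what, x0[which(is.na(out))[1L]])
  }
  out
}

# derive a child RNG seed from a master seed; keeps results < 2^31
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + stream * 7919L
}

# format a number the way screening tables print p-values
format_sci <- function(x, digits = 3) {
  toupper(formatC(x, format = "e", digits = digits - 1))
}
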