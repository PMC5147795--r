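#' Lexical variation metrics of a stimulus text
#'
#' Computes the three standard lexical variation measures of a text from its
#' count of distinct word types and total word tokens:
#'
#' * type-token ratio, `TTR = n_type / n_token`;
#' * word variation index,
#'   `OVIX = log(n_token) / log(2 - log(n_type) / log(n_token))`;
#' * word variation ratio, `OVR = log(n_type) / log(n_token)`.
#'
#' All logarithms are natural. OVIX (Swedish "ordvariationsindex") is a
#' length-compensated measure of lexical diversity widely used for Swedish
#' school texts; OVR is its ratio analogue.
#'
#' @param n_type number of distinct word types (`1 <= n_type <= n_token`).
#' @param n_token total number of word tokens (`>= 2`).
#' @return an object of class `text_variation_metrics`: a list with fields
#'   `n_type`, `n_token`, `ttr`, `ovix`, `ovr`. `ttr` and `ovr` are
#'   fractions in (0, 1]; `ovix` is dimensionless.
#' @section Domain: when `n_type == n_token` the OVIX denominator is
#'   `log(1) = 0` and OVIX is undefined; this raises a domain error rather
#'   than returning `Inf`.
#' @examples
#' text_variation_metrics(33, 46)
#' @export
text_variation_metrics <- function(n_type, n_token) {
  stopifnot(length(n_type) == 1L, length(n_token) == 1L)
  if (!is.finite(n_type) || !is.finite(n_token) ||
      n_type != round(n_type) || n_token != round(n_token))
    stop_domain("n_type and n_token must be integers")
  if (n_token < 2) stop_domain("n_token must be at least 2")
  if (n_type < 1 || n_type > n_token)
    stop_domain("n_type must satisfy 1 <= n_type <= n_token")

  lr <- log(n_type) / log(n_token)
  denom_arg <- 2 - lr
  if (denom_arg <= 0 || denom_arg == 1)
    stop_domain("OVIX undefined: log(2 - log(n_type)/log(n_token)) ",
                "is zero or its argument non-positive (n_type = ", n_type,
                ", n_token = ", n_token, ")")
  out <- list(n_type = n_type, n_token = n_token,
              ttr = n_type / n_token,
              ovix = log(n_token) / log(denom_arg),
              ovr = lr)
  class(out) <- "text_variation_metrics"
  out
}

#' @export
print.text_variation_metrics <- function(x, ...) {
  cat(sprintf("Text variation metrics (%d types / %d tokens)\n",
              x$n_type, x$n_token))
  cat(sprintf("  TTR:  %5.1f%%\n", 100 * x$ttr))
  cat(sprintf("  OVIX: %5.1f\n", x$ovix))
  cat(sprintf("  OVR:  %5.1f%%\n", 100 * x$ovr))
  invisible(x)
}
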