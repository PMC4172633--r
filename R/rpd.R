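#' Relative power difference between two contestants
#'
#' Computes the signed, bounded contrast between the power of a focal side
#' \eqn{i} and an opponent \eqn{j},
#' \deqn{RPD = (P_i - P_j) / (P_i + P_j),}
#' which is positive when the focal side is stronger, negative when the
#' opponent is stronger, zero at equality, and always strictly inside
#' \eqn{(-1, 1)} for positive inputs.  Because the contrast is scale-free it
#' is comparable across power measures with very different units (energy
#' consumption, military personnel, population, a capability share).
#'
#' A log-ratio variant \eqn{\log(P_i / P_j)} is available for sensitivity
#' analysis; it shares the sign convention and antisymmetry but is unbounded
#' and requires strictly positive inputs.
#'
#' @param p_i Nonnegative power of the focal side (vectorised).
#' @param p_j Nonnegative power of the opponent side (vectorised).
#' @param method `"bounded"` (default) for the normalised contrast, or
#'   `"logratio"` for `log(p_i / p_j)`.
#' @return Numeric vector of signed relative power differences.
#' @examples
#' rpd(3, 1)   #  0.5
#' rpd(1, 3)   # -0.5
#' rpd(5, 5)   #  0
#' @export
rpd <- function(p_i, p_j, method = c("bounded", "logratio")) {
  method <- match.arg(method)
  if (length(p_i) != length(p_j))
    stop("'p_i' and 'p_j' must have the same length")
  bad <- !is.na(p_i) & !is.na(p_j) & (p_i < 0 | p_j < 0)
  if (any(bad))
    stop("power values must be nonnegative (first offending pair at position ",
         which(bad)[1L], ")")
  if (method == "bounded") {
    tot <- p_i + p_j
    zero <- !is.na(tot) & tot == 0
    if (any(zero))
      stop("relative power difference undefined: both powers zero ",
           "(first offending pair at position ", which(zero)[1L], ")")
    (p_i - p_j) / tot
  } else {
    zero <- !is.na(p_i) & !is.na(p_j) & (p_i == 0 | p_j == 0)
    if (any(zero))
      stop("log-ratio relative power difference requires strictly positive ",
           "powers (first offending pair at position ", which(zero)[1L], ")")
    log(p_i / p_j)
  }
}

#' @rdname rpd
#' @export
relative_power_difference <- rpd
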