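## Exact non-negative big integers for solution counting.
##
## Counts of co-optimal reconciliations routinely exceed 2^53 (the
## paper-scale instances reach 10^47 and beyond), so counting cannot run
## in doubles.  No installed package provides arbitrary precision, hence
## this small limb implementation: little-endian vectors of base-1e6
## limbs stored as doubles.  Limb products are below 1e12 and convolution
## sums stay far under 2^53, so all carries are exact.

BN_BASE <- 1e6

#' Exact big natural numbers
#'
#' `bignat(x)` converts a non-negative integer-valued double below 2^53
#' to an exact big natural.  Arithmetic: `bn_add`, `bn_mul`; comparison:
#' `bn_cmp` (sign of a - b); `as.character` prints the full decimal
#' expansion and `as.numeric` converts back (possibly losing precision
#' above 2^53).
#'
#' @param x Non-negative integer-valued number.
#' @return An object of class `bignat`.
#' @export
bignat <- function(x) {
  x <- as.numeric(x)
  stopifnot(length(x) == 1L, !is.na(x), x >= 0, x == floor(x), x < 2^53)
  limbs <- numeric(0)
  repeat {
    limbs <- c(limbs, x %% BN_BASE)
    x <- (x - x %% BN_BASE) / BN_BASE
    if (x == 0) break
  }
  structure(limbs, class = "bignat")
}

bn_norm <- function(limbs) {
  carry <- 0
  out <- numeric(length(limbs))
  for (i in seq_along(limbs)) {
    v <- limbs[i] + carry
    out[i] <- v %% BN_BASE
    carry <- (v - out[i]) / BN_BASE
  }
  while (carry > 0) {
    out <- c(out, carry %% BN_BASE)
    carry <- (carry - carry %% BN_BASE) / BN_BASE
  }
  while (length(out) > 1L && out[length(out)] == 0)
    out <- out[-length(out)]
  structure(out, class = "bignat")
}

#' @rdname bignat
#' @param a,b `bignat` objects.
#' @export
bn_add <- function(a, b) {
  la <- unclass(a); lb <- unclass(b)
  len <- max(length(la), length(lb))
  bn_norm(c(la, numeric(len - length(la))) +
          c(lb, numeric(len - length(lb))))
}

#' @rdname bignat
#' @export
bn_mul <- function(a, b) {
  la <- unclass(a); lb <- unclass(b)
  if ((length(la) == 1L && la == 0) || (length(lb) == 1L && lb == 0))
    return(bignat(0))
  width <- length(la) + length(lb) + 2L
  carry_fixed <- function(v) {
    carry <- 0
    for (j in seq_along(v)) {
      s <- v[j] + carry
      v[j] <- s %% BN_BASE
      carry <- (s - v[j]) / BN_BASE
    }
    stopifnot(carry == 0)
    v
  }
  out <- numeric(width)
  for (i in seq_along(la)) {
    if (la[i] == 0) next
    idx <- i + seq_along(lb) - 1L
    out[idx] <- out[idx] + la[i] * lb
    ## interleave carrying to keep partial sums well under 2^53
    if (i %% 8L == 0L) out <- carry_fixed(out)
  }
  bn_norm(out)
}

#' @rdname bignat
#' @export
bn_cmp <- function(a, b) {
  la <- unclass(a); lb <- unclass(b)
  if (length(la) != length(lb)) return(sign(length(la) - length(lb)))
  for (i in rev(seq_along(la))) {
    if (la[i] != lb[i]) return(sign(la[i] - lb[i]))
  }
  0L
}

#' @export
as.character.bignat <- function(x, ...) {
  limbs <- rev(unclass(x))
  paste0(limbs[1], paste(sprintf("%06.0f", limbs[-1]), collapse = ""))
}

#' @export
as.double.bignat <- function(x, ...) {
  sum(unclass(x) * BN_BASE^(seq_along(unclass(x)) - 1))
}

#' @export
format.bignat <- function(x, ...) as.character(x)

#' @export
print.bignat <- function(x, ...) {
  cat(as.character(x), "\n")
  invisible(x)
}
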