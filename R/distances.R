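# Pairwise sequence distances: raw differences, p-distance, and the Kimura
# two-parameter (K80) model. All pairwise statistics use pairwise deletion of
# sites that are not comparable (gap or ambiguity in either sequence).

#' Kimura two-parameter distance from transition/transversion proportions
#'
#' `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` where `P` and `Q` are the
#' observed proportions of transitional and transversional differences.
#' Saturated pairs (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) are flagged with an
#' infinite distance and a warning.
#'
#' @param P Transition difference proportion(s).
#' @param Q Transversion difference proportion(s).
#' @return Numeric distance(s); `Inf` where the logarithms are undefined.
#' @export
#' @examples
#' k80_distance(0.1, 0.05)
k80_distance <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  sat <- w1 <= 0 | w2 <= 0
  if (any(sat)) warn("saturated pair(s): K80 distance undefined, returning Inf")
  d <- ifelse(sat, Inf, -0.5 * log(pmax(w1, .Machine$double.xmin)) -
                0.25 * log(pmax(w2, .Machine$double.xmin)))
  d[P == 0 & Q == 0] <- 0
  d
}

# transition = both purines (A,G -> codes 1,3) or both pyrimidines (C,T -> 2,4)
is_transition_pair <- function(x, y) (x %% 2L) == (y %% 2L)

#' Pairwise distance matrix for an alignment
#'
#' @param aln Alignment tibble.
#' @param model `"differences"` (number of differing comparable sites),
#'   `"p"` (proportion), or `"K80"`.
#' @return A symmetric numeric matrix with zero diagonal, sequence ids as
#'   dimnames, and attribute `model`.
#' @export
distance_matrix <- function(aln, model = c("K80", "p", "differences")) {
  model <- match.arg(model)
  code <- encode_alignment(aln)
  n <- nrow(code)
  d <- matrix(0, n, n, dimnames = list(rownames(code), rownames(code)))
  for (i in seq_len(max(n - 1, 0))) {
    xi <- code[i, ]
    for (j in (i + 1):n) {
      xj <- code[j, ]
      valid <- xi > 0L & xj > 0L
      nc <- sum(valid)
      if (nc == 0) {
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      diffs <- valid & (xi != xj)
      nd <- sum(diffs)
      val <- switch(model,
        differences = nd,
        p = nd / nc,
        K80 = {
          ts <- sum(is_transition_pair(xi[diffs], xj[diffs]))
          suppressWarnings(k80_distance(ts / nc, (nd - ts) / nc))
        })
      d[i, j] <- d[j, i] <- val
    }
  }
  if (any(is.infinite(d))) warn("saturated pair(s) in K80 distance matrix")
  attr(d, "model") <- model
  d
}
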