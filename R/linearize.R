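#' Linearization parameters
#'
#' The two knobs of error-bounded streamline compression. `met` (maximum
#' error threshold, mm) bounds how far any discarded point may lie from the
#' straight chord that replaces it; `met = 0` removes only exactly collinear
#' points (within 1e-12 mm, to absorb float noise). `mld` (maximum
#' linearization distance, mm) bounds the Euclidean distance between
#' consecutive kept points, which both caps the cost of backward
#' verification and fixes the extended-neighborhood size used by
#' [select_progressive()]; `Inf` disables it.
#'
#' The defaults (0.2 mm, 5 mm) are the configuration used throughout the
#' reference experiments on probabilistic tractograms.
#'
#' @param met maximum error threshold, mm, `>= 0`.
#' @param mld maximum linearization distance, mm, `> 0` or `Inf`.
#' @return An object of class `linearization_params`.
#' @export
linearization_params <- function(met = 0.2, mld = 5) {
  if (!is.numeric(met) || length(met) != 1L || is.na(met) || met < 0)
    stop("'met' must be a single number >= 0", call. = FALSE)
  if (!is.numeric(mld) || length(mld) != 1L || is.na(mld) || mld <= 0)
    stop("'mld' must be a single number > 0 (possibly Inf)", call. = FALSE)
  structure(list(met = met, mld = mld), class = "linearization_params")
}

#' Perpendicular distance from a point to a line
#'
#' Distance (mm) from `p` to the *infinite* line through `a` and `b`,
#' by the cross-product formula `|(p-a) x (b-a)| / |b-a|`. Symmetric in
#' `a, b`; zero iff `p` is collinear with them. This is the collinearity
#' test applied during backward verification.
#'
#' @param p,a,b numeric 3-vectors (mm); `a != b`.
#' @return Distance in mm.
#' @examples
#' perpendicular_distance(c(0, 1, 0), c(0, 0, 0), c(2, 0, 0))  # 1
#' @export
perpendicular_distance <- function(p, a, b) {
  u <- b - a
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("degenerate line: a == b", call. = FALSE)
  v <- p - a
  cx <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  sqrt(sum(cx^2)) / nu
}

# Vectorized distance of rows of P to the infinite line a->b.
line_distances <- function(P, a, b) {
  u <- b - a
  nu <- sqrt(sum(u^2))
  V <- sweep(P, 2, a)
  cx1 <- u[2] * V[, 3] - u[3] * V[, 2]
  cx2 <- u[3] * V[, 1] - u[1] * V[, 3]
  cx3 <- u[1] * V[, 2] - u[2] * V[, 1]
  sqrt(cx1^2 + cx2^2 + cx3^2) / nu
}

#' Linearize one streamline
#'
#' Greedy forward scan with backward verification. From the last kept point,
#' the candidate end point is extended one input point at a time; at each
#' extension every intermediate point is re-tested against the chord from
#' the last kept point to the candidate (backward verification). Three cases
#' can occur:
#'
#' * Case A — every intermediate point is within `met` of the chord and the
#'   candidate is within `mld` of the last kept point: the candidate
#'   advances.
#' * Case B — an intermediate point exceeds `met`: the previous candidate
#'   (the last end point that passed) is kept and the scan restarts from it.
#' * Case C — the candidate's Euclidean distance from the last kept point
#'   strictly exceeds `mld`: same restart.
#'
#' Keeping the last *passing* candidate (rather than the violating point)
#' guarantees by construction that every discarded point lies within `met`
#' of its enclosing kept chord. The output is a subsequence of the input;
#' both endpoints are always kept. Input steps longer than `mld` violate the
#' precondition; both endpoints of such a step are kept unchanged and the
#' output `mld` bound then only holds relative to the input's longest step.
#'
#' @param s streamline matrix (n x 3, world mm).
#' @param params a [linearization_params()].
#' @return The compressed streamline (subsequence of the input rows).
#' @examples
#' s <- cbind(seq(0, 30, by = 0.5), 0, 0)
#' nrow(linearize_streamline(s, linearization_params(met = 0.1, mld = 10)))  # 4
#' @export
linearize_streamline <- function(s, params = linearization_params()) {
  s <- streamline(s)
  met <- max(params$met, 1e-12)
  mld <- params$mld
  n <- nrow(s)
  kept <- logical(n)
  kept[1L] <- TRUE
  i <- 1L                 # last kept index
  j <- 2L                 # candidate index (i+1 passes vacuously)
  while (j < n) {
    nxt <- j + 1L
    within_mld <- sqrt(sum((s[nxt, ] - s[i, ])^2)) <= mld
    ok <- within_mld &&
      all(line_distances(s[(i + 1L):(nxt - 1L), , drop = FALSE],
                         s[i, ], s[nxt, ]) <= met)
    if (ok) {
      j <- nxt            # Case A: extend the candidate
    } else {
      kept[j] <- TRUE     # Case B or C: keep the last passing candidate
      i <- j
      j <- j + 1L
    }
  }
  kept[n] <- TRUE
  s[kept, , drop = FALSE]
}

#' Linearize a whole tractogram
#'
#' Applies [linearize_streamline()] to every streamline and reports the
#' compression achieved.
#'
#' @param t a [tractogram()].
#' @param params a [linearization_params()].
#' @return A list with elements `tractogram` (the compressed tractogram) and
#'   `report`, a `compression_report` with fields `points_before`,
#'   `points_after`, `point_reduction` (fraction of points discarded, in
#'   `[0,1]`) and `per_streamline_ratios` (the same fraction per
#'   streamline).
#' @export
linearize_tractogram <- function(t, params = linearization_params()) {
  if (!inherits(t, "tractogram")) stop("'t' must be a tractogram", call. = FALSE)
  out <- lapply(t$streamlines, linearize_streamline, params = params)
  before <- vapply(t$streamlines, nrow, integer(1))
  after <- vapply(out, nrow, integer(1))
  report <- structure(
    list(points_before = sum(before), points_after = sum(after),
         point_reduction = if (sum(before) > 0) 1 - sum(after) / sum(before) else 0,
         per_streamline_ratios = 1 - after / before),
    class = "compression_report")
  list(tractogram = tractogram(out, t$ref), report = report)
}

#' @export
print.compression_report <- function(x, ...) {
  cat(sprintf("Compression: %d -> %d points (%.1f%% discarded)\n",
              x$points_before, x$points_after, 100 * x$point_reduction))
  invisible(x)
}
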