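#' Median + MAD retention rule on a value distribution
#'
#' Computes the Median and raw Median Absolute Deviation of a vector of
#' SL values and retains the values strictly greater than
#' `Median + 1 * MAD`.
#'
#' @param v numeric vector of SL values (one per channel pair).
#' @return list with `median`, `mad`, `threshold`, `retained` (the
#'   surviving values) and `keep` (logical mask over `v`).
#' @examples
#' mad_rule(c(0.1, 0.2, 0.3, 0.4, 0.5))  # threshold 0.4, retains 0.5
#' @export
mad_rule <- function(v) {
  v <- as.numeric(v)
  if (length(unique(v)) < 2L) {
    stop("degenerate SL distribution: fewer than 2 distinct values",
         call. = FALSE)
  }
  med <- median(v)
  mad_v <- median(abs(v - med))
  if (mad_v == 0) {
    stop("degenerate SL distribution: MAD is zero", call. = FALSE)
  }
  thr <- med + mad_v
  keep <- v > thr
  if (!any(keep)) {
    stop("empty network: no SL value exceeds Median + 1 MAD", call. = FALSE)
  }
  list(median = med, mad = mad_v, threshold = thr,
       retained = v[keep], keep = keep)
}

#' Median + MAD thresholding of an average SL matrix
#'
#' The distribution of SL values (upper triangle, diagonal excluded) is
#' summarised by its Median and Median Absolute Deviation (MAD, raw —
#' no normal-consistency constant), and only entries strictly greater
#' than `Median + 1 * MAD` are retained; all other entries are set to
#' zero.  This keeps the connectivity backbone without assuming a
#' Gaussian SL distribution.
#'
#' @param sl an `sl_matrix` (averaged over epochs).
#' @return object of class `thresholded_sl`: list with `values`
#'   (symmetric matrix, sub-threshold entries zeroed), `threshold`,
#'   `median`, `mad`, `N` (number of retained entries over the full
#'   matrix) and `edge_count` (retained upper-triangle entries).
#' @examples
#' m <- matrix(0, 4, 4)
#' m[upper.tri(m)] <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.45)
#' m <- m + t(m)
#' mad_threshold(structure(m, class = c("sl_matrix", "matrix")))
#' @export
mad_threshold <- function(sl) {
  v <- unclass(sl)
  stopifnot(is.matrix(v), nrow(v) == ncol(v))
  rule <- mad_rule(v[upper.tri(v)])
  keep <- v > rule$threshold
  diag(keep) <- FALSE
  out <- ifelse(keep, v, 0)
  structure(list(values = out, threshold = rule$threshold,
                 median = rule$median,
                 mad = rule$mad, N = sum(out != 0),
                 edge_count = sum(out[upper.tri(out)] != 0)),
            class = "thresholded_sl")
}

#' @export
print.thresholded_sl <- function(x, ...) {
  cat(sprintf("<thresholded_sl> %d nodes, %d edges (threshold %.4f)\n",
              nrow(x$values), x$edge_count, x$threshold))
  invisible(x)
}

#' Mean retained SL value
#'
#' The mean of the non-zero entries of a thresholded SL matrix — the
#' overall probability of functional connectivity across the array.
#'
#' @param t a `thresholded_sl`.
#' @return scalar mean of retained SL values.
#' @export
sl_mean <- function(t) {
  stopifnot(inherits(t, "thresholded_sl"))
  if (t$N == 0L) stop("empty network: no retained SL values", call. = FALSE)
  sum(t$values) / t$N
}

#' Distance-bias check of a thresholded SL matrix
#'
#' Squared Pearson correlation between the vectorised upper-triangle
#' entries of the thresholded SL matrix (zeros included) and the
#' corresponding inter-sensor Euclidean distances.  Values near zero
#' certify that connectivity does not merely reflect sensor proximity
#' (volume-conduction-like bias).
#'
#' @param t a `thresholded_sl`.
#' @param arr a [make_sensor_array()] `sensor_array` of matching size.
#' @return scalar r-squared in `[0, 1]`.
#' @export
distance_bias_r2 <- function(t, arr) {
  stopifnot(inherits(t, "thresholded_sl"), inherits(arr, "sensor_array"))
  if (nrow(t$values) != nrow(arr$M_Eu)) {
    stop("SL matrix and sensor array dimensions do not match", call. = FALSE)
  }
  x <- arr$M_Eu[upper.tri(arr$M_Eu)]
  y <- t$values[upper.tri(t$values)]
  if (var(x) == 0 || var(y) == 0) {
    stop("undefined r-squared: zero variance", call. = FALSE)
  }
  stats::cor(x, y)^2
}

#' Subject-level network QC
#'
#' A subject is included when (1) the distance-bias r-squared of both
#' condition networks is below `r2_max`, and (2) the rest and
#' prehension networks have exactly the same number of retained edges
#' (the fixed-degree requirement for comparing graph measures across
#' conditions).
#'
#' @param rest,preh `thresholded_sl` matrices for the two conditions.
#' @param arr matching `sensor_array`.
#' @param r2_max inclusion bound on the distance-bias r-squared
#'   (default 0.1).
#' @param require_equal_degree enforce condition (2) (default TRUE).
#' @return object of class `subject_qc`: list with `r2_rest`,
#'   `r2_prehension`, `degree_rest`, `degree_prehension`, `included`.
#' @export
subject_qc <- function(rest, preh, arr, r2_max = 0.1,
                       require_equal_degree = TRUE) {
  stopifnot(inherits(rest, "thresholded_sl"),
            inherits(preh, "thresholded_sl"))
  if (!identical(dim(rest$values), dim(preh$values))) {
    stop("condition matrices have mismatched dimensions", call. = FALSE)
  }
  r2r <- distance_bias_r2(rest, arr)
  r2p <- distance_bias_r2(preh, arr)
  ok <- r2r < r2_max && r2p < r2_max
  if (require_equal_degree) {
    ok <- ok && rest$edge_count == preh$edge_count
  }
  structure(list(r2_rest = r2r, r2_prehension = r2p,
                 degree_rest = rest$edge_count,
                 degree_prehension = preh$edge_count,
                 included = ok),
            class = "subject_qc")
}

#' @export
print.subject_qc <- function(x, ...) {
  cat(sprintf(
    "<subject_qc> r2 rest %.3f / prehension %.3f, edges %d / %d -> %s\n",
    x$r2_rest, x$r2_prehension, x$degree_rest, x$degree_prehension,
    if (x$included) "included" else "excluded"))
  invisible(x)
}
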