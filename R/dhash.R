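#' Difference hash (dHash) of an image patch
#'
#' The classic 64-bit perceptual fingerprint: the patch is resampled to
#' 9 columns x 8 rows by area averaging, and bit `(r, c)` is 1 iff
#' `pixel(r, c) > pixel(r, c + 1)` (strict comparison; equal neighbours
#' give 0). Bits are packed row-major. Because only the sign pattern of
#' horizontal differences is kept, the hash is invariant to any positive
#' uniform brightness scaling.
#'
#' @param patch Numeric matrix (rows = image rows) of grayscale values;
#'   any positive scale (0-1 or 0-255) works.
#' @return Object of class `dhash64`: an integer vector of 64 bits.
#' @export
dhash <- function(patch) {
  if (is.null(dim(patch)) || nrow(patch) < 1 || ncol(patch) < 1 ||
      length(patch) == 0) {
    stop("hash failure: empty or degenerate patch", call. = FALSE)
  }
  small <- area_resize(patch, out_rows = 8L, out_cols = 9L)
  # strict ">" with a scale-relative guard so exactly-equal neighbours are
  # never separated by resampling round-off
  eps <- 1e-9 * max(1, max(abs(small)))
  structure(as.integer(t(small[, 1:8] - small[, 2:9] > eps)),
            class = "dhash64")
}

#' Area-average image resampling
#'
#' Resamples a matrix to a target size by exact area averaging: each output
#' pixel is the mean of the input region it covers, with fractional border
#' pixels weighted by their overlap. This is the box-filter ("INTER_AREA")
#' downsampling rule.
#'
#' @param img Numeric matrix.
#' @param out_rows,out_cols Target size.
#' @return `out_rows x out_cols` numeric matrix.
#' @export
area_resize <- function(img, out_rows, out_cols) {
  wr <- overlap_weights(nrow(img), out_rows)   # out_rows x in_rows
  wc <- overlap_weights(ncol(img), out_cols)   # out_cols x in_cols
  wr %*% img %*% t(wc)
}

# weight matrix W (n_out x n_in): W[i, j] = fraction of output cell i
# covered by input cell j, normalized to sum 1 per row
overlap_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1
    j1 <- ceiling(hi)
    for (j in j0:min(j1, n_in)) {
      W[i, j] <- min(hi, j) - max(lo, j - 1)
    }
  }
  W / scale
}

#' Hamming distance between two 64-bit hashes
#' @param h1,h2 `dhash64` objects.
#' @return Integer in `[0, 64]`.
#' @export
hash_hamming <- function(h1, h2) sum(unclass(h1) != unclass(h2))

#' Appearance similarity score from two hashes
#'
#' `1 - hamming/64`, in `[0, 1]`; 1 means identical sign patterns.
#'
#' @param h1,h2 `dhash64` objects.
#' @return Similarity in `[0, 1]`.
#' @export
hash_similarity <- function(h1, h2) 1 - hash_hamming(h1, h2) / 64

#' @export
print.dhash64 <- function(x, ...) {
  bits <- unclass(x)
  hex <- vapply(seq(1, 64, by = 4), function(i) {
    sprintf("%x", sum(bits[i:(i + 3)] * c(8, 4, 2, 1)))
  }, character(1))
  cat("<dhash64>", paste(hex, collapse = ""), "\n")
  invisible(x)
}
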