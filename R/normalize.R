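# Normalization and adaptively thresholded low-rank (ALRA-style)
# imputation. The normalized value is ln(CPM/100 + 1); imputation forms a
# rank-k approximation, zeroes entries below each gene's own noise
# magnitude, moment-matches the surviving values and restores observed
# positives.

#' Log-CPM normalization
#'
#' Transforms every entry to `ln(CPM/100 + 1)`, where CPM is counts per
#' million within the cell. Zeros map exactly to zero; a cell's normalized
#' vector is invariant to scaling all its counts by a constant. For a
#' single-species matrix, rownames are reduced to the prefix-free gene
#' symbols so that reference tables (which use plain symbols) match
#' directly.
#'
#' @param x a [tagged_counts()] (typically species-restricted and
#'   QC-passed) or a numeric matrix of counts.
#' @return A dense genes x cells matrix with attribute
#'   `provenance = "raw_lognorm"`.
#' @export
normalize_log_cpm <- function(x) {
  if (inherits(x, "tagged_counts")) {
    m <- as.matrix(x$counts)
    if (length(unique(x$genes$species)) == 1L &&
        !anyDuplicated(x$genes$symbol))
      rownames(m) <- x$genes$symbol
  } else {
    m <- as.matrix(x)
  }
  totals <- colSums(m)
  if (any(totals == 0))
    stop("cell(s) with zero total counts reached normalization: ",
         paste(utils::head(colnames(m)[totals == 0], 5L), collapse = ", "),
         call. = FALSE)
  e <- log1p(sweep(m, 2L, totals, "/") * 1e6 / 100)
  attr(e, "provenance") <- "raw_lognorm"
  e
}

# Randomized SVD (Gaussian sketch, oversampling, subspace power iterations
# with re-orthogonalization). Exact when k + oversample reaches min(dim).
.rsvd <- function(A, k, oversample = 10, power_iter = 2) {
  m <- nrow(A); n <- ncol(A)
  l <- min(k + oversample, m, n)
  if (min(m, n) <= max(150, 2 * l)) {
    # small problems: the exact factorization is cheap and removes
    # sketching error entirely
    s <- svd(A, nu = min(k, m, n), nv = min(k, m, n))
    k <- min(k, length(s$d))
    return(list(d = s$d[seq_len(k)], u = s$u, v = s$v))
  }
  omega <- matrix(stats::rnorm(n * l), n, l)
  Y <- A %*% omega
  Q <- qr.Q(qr(Y))
  for (i in seq_len(power_iter)) {
    Z <- crossprod(A, Q)
    Z <- qr.Q(qr(Z))
    Y <- A %*% Z
    Q <- qr.Q(qr(Y))
  }
  B <- crossprod(Q, A)
  s <- svd(B, nu = min(k, l), nv = min(k, l))
  k <- min(k, length(s$d))
  list(d = s$d[seq_len(k)],
       u = Q %*% s$u[, seq_len(k), drop = FALSE],
       v = s$v[, seq_len(k), drop = FALSE])
}

#' Choose the imputation rank from the singular spectrum
#'
#' Computes the leading `max_rank` singular values (randomized SVD), their
#' consecutive spacings `s_k = sigma_k - sigma_{k+1}`, and a noise spacing
#' level estimated as mean + `noise_mult` * SD of the last `noise_window`
#' spacings. Returns the largest `k` whose spacing exceeds that level
#' (minimum 1). Deterministic given `seed`.
#'
#' @param e a normalized expression matrix.
#' @param max_rank number of leading singular values to examine; clipped
#'   (with a warning) when the matrix is smaller.
#' @param seed integer seed for the randomized SVD; `NULL` leaves the RNG
#'   state alone.
#' @param noise_window,noise_mult noise-level estimation constants.
#' @return A positive integer rank.
#' @export
choose_rank <- function(e, max_rank = 100, seed = NULL,
                        noise_window = 20, noise_mult = 6) {
  stopifnot(ncol(e) >= 2L)
  if (!is.null(seed)) set.seed(seed)
  kmax <- min(max_rank, nrow(e) - 1L, ncol(e) - 1L)
  if (kmax < max_rank)
    warning(sprintf("max_rank clipped to %d for a %d x %d matrix",
                    kmax, nrow(e), ncol(e)))
  d <- .rsvd(e, kmax)$d
  s <- -diff(d)
  if (length(s) < 2L) return(1L)
  w <- utils::tail(s, min(noise_window, length(s)))
  thresh <- mean(w) + noise_mult * stats::sd(w)
  hit <- which(s > thresh)
  # never report beyond the numerical rank (guards exactly-degenerate input)
  num_rank <- sum(d > d[1L] * 1e-10)
  hit <- hit[hit <= num_rank]
  if (length(hit) == 0L) 1L else max(hit)
}

#' Adaptively thresholded low-rank imputation
#'
#' Fills in technical dropout in a log-normalized matrix: (1) form the
#' rank-`k` approximation; (2) per gene, zero every entry smaller than the
#' magnitude of that gene's most negative approximated value — the gene's
#' own noise scale (genes with no negative entries keep all values);
#' (3) clamp remaining negatives to zero; (4) per gene, affinely rescale
#' the surviving nonzero values to match the mean and SD of the gene's
#' observed nonzero values (genes with fewer than two observed nonzeros are
#' passed through); (5) restore every observed-positive entry that ended up
#' zero to its observed value. The result is non-negative and never zeroes
#' an observed positive.
#'
#' @param e a `raw_lognorm` matrix from [normalize_log_cpm()].
#' @param k target rank, typically from [choose_rank()]; clipped (with a
#'   warning) to the matrix dimensions.
#' @param seed seed for the randomized SVD; `NULL` leaves the RNG alone.
#' @return The imputed matrix with attributes `provenance = "imputed"` and
#'   `chosen_rank = k`.
#' @export
alra_impute <- function(e, k, seed = NULL) {
  stopifnot(is.matrix(e), k >= 1)
  if (!is.null(seed)) set.seed(seed)
  kb <- min(nrow(e), ncol(e))
  if (k > kb) {
    warning(sprintf("k clipped from %d to the matrix rank bound %d", k, kb))
    k <- kb
  }
  s <- .rsvd(e, k)
  ak <- s$u %*% (s$d * t(s$v))

  row_min <- apply(ak, 1L, min)
  thr <- ifelse(row_min < 0, abs(row_min), -Inf)  # -Inf: keep all values
  ak[ak < thr] <- 0
  ak[ak < 0] <- 0

  for (g in seq_len(nrow(e))) {
    obs <- e[g, ][e[g, ] > 0]
    if (length(obs) < 2L) next
    nz <- ak[g, ] != 0
    if (!any(nz)) next
    y <- ak[g, nz]
    sd_y <- stats::sd(y)
    scale <- if (is.na(sd_y) || sd_y == 0) 1 else stats::sd(obs) / sd_y
    ak[g, nz] <- (y - mean(y)) * scale + mean(obs)
  }
  ak[ak < 0] <- 0

  restore <- e > 0 & ak == 0
  ak[restore] <- e[restore]
  dimnames(ak) <- dimnames(e)
  attr(ak, "provenance") <- "imputed"
  attr(ak, "chosen_rank") <- as.integer(k)
  ak
}
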