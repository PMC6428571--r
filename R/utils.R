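# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(x) {
  out <- unname(DNA_COMP[x])
  if (anyNA(out)) stop("non-ACGT allele encountered: ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

is_palindromic <- function(a1, a2) a1 == unname(DNA_COMP[a2])

#' Assign contiguous blocks of (nearly) equal size
#'
#' Splits `n` ordered items into `b` contiguous blocks whose sizes differ by
#' at most one, as used by all block-jackknife routines in the package.
#'
#' @param n number of items (in genomic order).
#' @param b requested number of blocks; reduced to `n` when `b > n`.
#' @return integer vector of length `n` with block ids `1..b`.
#' @keywords internal
#' @noRd
block_assign <- function(n, b) {
  b <- min(b, n)
  sort(rep_len(seq_len(b), n))
}

# Delete-one-block jackknife of an arbitrary statistic.
# theta_fun(keep_idx) must return a scalar. Returns the full-sample
# estimate, jackknife SE and a normal-approximation two-sided P value.
block_jackknife <- function(n, n_blocks, theta_fun) {
  blocks <- block_assign(n, n_blocks)
  b <- max(blocks)
  theta_full <- theta_fun(seq_len(n))
  theta_i <- vapply(seq_len(b), function(k) theta_fun(which(blocks != k)),
                    numeric(1))
  theta_bar <- mean(theta_i)
  se <- sqrt((b - 1) / b * sum((theta_i - theta_bar)^2))
  p <- if (se > 0) 2 * stats::pnorm(-abs(theta_full / se)) else NA_real_
  list(estimate = theta_full, se = se, p = p, n_blocks = b,
       leave_one_out = theta_i)
}

# Fast delete-one-block jackknife for a Pearson correlation: block-wise
# sufficient statistics make each leave-one-out r an O(1) update.
pearson_jackknife <- function(x, y, n_blocks) {
  n <- length(x)
  blocks <- block_assign(n, n_blocks)
  b <- max(blocks)
  sx <- rowsum(x, blocks); sy <- rowsum(y, blocks)
  sxx <- rowsum(x * x, blocks); syy <- rowsum(y * y, blocks)
  sxy <- rowsum(x * y, blocks); cnt <- tabulate(blocks, b)
  tx <- sum(sx); ty <- sum(sy); txx <- sum(sxx); tyy <- sum(syy)
  txy <- sum(sxy)
  r_from <- function(n., sx., sy., sxx., syy., sxy.) {
    num <- sxy. - sx. * sy. / n.
    den <- sqrt((sxx. - sx.^2 / n.) * (syy. - sy.^2 / n.))
    num / den
  }
  r_full <- r_from(n, tx, ty, txx, tyy, txy)
  r_i <- r_from(n - cnt, tx - sx, ty - sy, txx - sxx, tyy - syy, txy - sxy)
  r_bar <- mean(r_i)
  se <- sqrt((b - 1) / b * sum((r_i - r_bar)^2))
  p <- if (is.finite(se) && se > 0) 2 * stats::pnorm(-abs(r_full / se)) else NA_real_
  list(estimate = r_full, se = se, p = p, n_blocks = b)
}

# Moore-Penrose pseudo-inverse restricted to the numerically non-null
# eigenspace of a symmetric matrix; returns the inverse and the rank.
sym_pinv <- function(s, tol = 1e-10) {
  e <- eigen(s, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), 1e-300)
  rank <- sum(keep)
  if (rank == 0L) return(list(inv = matrix(0, nrow(s), ncol(s)), rank = 0L))
  v <- e$vectors[, keep, drop = FALSE]
  list(inv = v %*% (t(v) / e$values[keep]), rank = rank)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
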