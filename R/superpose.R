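# Rigid-body least-squares superposition (Kabsch) with iterative outlier
# rejection, the engine behind the per-domain RMSD table.

#' Root-mean-square deviation of paired points (no fitting)
#'
#' @param P,Q Numeric matrices with 3 columns and equal row count.
#' @return `sqrt(mean(rowSums((P - Q)^2)))` in the coordinate units
#'   (Angstrom for alpha carbons).
#' @examples
#' rmsd(matrix(0, 2, 3), matrix(c(1, 7, 0, 0, 0, 0), 2, 3)) # sqrt((1+49)/2) = 5
#' @export
rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) abort("P and Q must have identical dimensions")
  if (nrow(P) < 1L) abort("need at least one pair")
  sqrt(mean(rowSums((P - Q)^2)))
}

#' Optimal rigid superposition of two point sets (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD of
#' `R %*% p + t` onto `Q` over all rigid transforms, via SVD of the
#' cross-covariance matrix. A reflection in the least-squares solution is
#' corrected by flipping the sign of the smallest singular direction, so the
#' returned rotation always has determinant +1.
#'
#' @param P,Q Numeric n x 3 matrices, n >= 3, matched row-by-row; `P` is
#'   moved onto `Q`.
#' @param pairs Optional 2-column matrix of position labels carried into the
#'   result (`retained_pairs`).
#' @return A `glun_superposition` object: `rotation` (3 x 3), `translation`
#'   (length 3), `rmsd`, `n`, `retained_pairs`, `cycles_run = 0`.
#' @export
kabsch <- function(P, Q, pairs = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3) abort("P and Q must be matched n x 3 matrices")
  n <- nrow(P)
  if (n < 3L) abort("need at least 3 point pairs for superposition")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  if (max(svd(P0)$d) < 1e-9) abort("degenerate geometry: points are coincident")
  H <- crossprod(P0, Q0) # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- as.numeric(cq - R %*% cp)
  moved <- sweep(P %*% t(R), 2, t_vec, "+")
  structure(
    list(
      rotation = R, translation = t_vec,
      rmsd = rmsd(moved, Q), n = n,
      retained_pairs = pairs, cycles_run = 0L, rmsd_all = NULL
    ),
    class = "glun_superposition"
  )
}

#' Apply a superposition to coordinates or to a chain
#'
#' @param fit A `glun_superposition`.
#' @param x An n x 3 matrix or a `glun_chain` (NA coordinates pass through).
#' @return The transformed matrix or chain.
#' @export
apply_superposition <- function(fit, x) {
  if (inherits(x, "glun_chain")) {
    m <- cbind(x$x, x$y, x$z)
    ok <- stats::complete.cases(m)
    m[ok, ] <- sweep(m[ok, , drop = FALSE] %*% t(fit$rotation), 2, fit$translation, "+")
    df <- as_tibble(x)
    df$x <- m[, 1]; df$y <- m[, 2]; df$z <- m[, 3]
    return(as_chain(df, source_label = attr(x, "source_label")))
  }
  sweep(as.matrix(x) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Superpose two chains with iterative outlier rejection
#'
#' Fits chain `a` onto chain `b` over the seed residue pairing, then runs up
#' to `cycles` rounds in which pairs whose post-fit alpha-carbon distance
#' exceeds `reject_cutoff` are discarded and the fit recomputed, stopping
#' early when no pair is rejected. This mirrors the refine cycles of
#' align-style superposition tools; the reported `rmsd` is over the retained
#' pairs, `rmsd_all` over all seed pairs under the final transform.
#'
#' @param a,b `glun_chain` tibbles (any numbering, matched via `pairing`).
#' @param pairing A data frame with columns `pos_a`, `pos_b` giving the seed
#'   residue correspondence (e.g. from [global_align()]); defaults to
#'   matching identical positions present in both chains.
#' @param cycles Maximum rejection rounds (default 5).
#' @param reject_cutoff Distance threshold in Angstrom (default 2.0).
#' @return A `glun_superposition` (transform maps `a` into `b`'s frame).
#' @export
superpose <- function(a, b, pairing = NULL, cycles = 5L, reject_cutoff = 2.0) {
  if (is.null(pairing)) {
    shared <- intersect(a$pos, b$pos)
    pairing <- tibble(pos_a = shared, pos_b = shared)
  }
  ia <- match(pairing$pos_a, a$pos)
  ib <- match(pairing$pos_b, b$pos)
  ok <- !is.na(ia) & !is.na(ib)
  P <- cbind(a$x, a$y, a$z)[ia[ok], , drop = FALSE]
  Q <- cbind(b$x, b$y, b$z)[ib[ok], , drop = FALSE]
  keep <- stats::complete.cases(P) & stats::complete.cases(Q)
  P <- P[keep, , drop = FALSE]; Q <- Q[keep, , drop = FALSE]
  pairs <- cbind(pos_a = pairing$pos_a[ok][keep], pos_b = pairing$pos_b[ok][keep])
  if (nrow(P) < 3L) abort("seed pairing provides fewer than 3 structured pairs")
  seed_pairs <- pairs
  fit <- kabsch(P, Q, pairs = pairs)
  cycles_run <- 0L
  for (i in seq_len(cycles)) {
    moved <- apply_superposition(fit, P)
    dist <- sqrt(rowSums((moved - Q)^2))
    rej <- dist > reject_cutoff
    if (!any(rej)) break
    if (sum(!rej) < 3L) abort("superposition collapsed: fewer than 3 pairs retained")
    P <- P[!rej, , drop = FALSE]; Q <- Q[!rej, , drop = FALSE]
    pairs <- pairs[!rej, , drop = FALSE]
    fit <- kabsch(P, Q, pairs = pairs)
    cycles_run <- cycles_run + 1L
  }
  fit$cycles_run <- cycles_run
  # all-pair RMSD under the final transform, for tools that report both
  ia <- match(seed_pairs[, "pos_a"], a$pos); ib <- match(seed_pairs[, "pos_b"], b$pos)
  Pa <- cbind(a$x, a$y, a$z)[ia, , drop = FALSE]
  Qa <- cbind(b$x, b$y, b$z)[ib, , drop = FALSE]
  ok_all <- stats::complete.cases(Pa) & stats::complete.cases(Qa)
  fit$rmsd_all <- rmsd(apply_superposition(fit, Pa[ok_all, , drop = FALSE]), Qa[ok_all, , drop = FALSE])
  fit
}

#' @export
print.glun_superposition <- function(x, ...) {
  cat(sprintf(
    "<glun_superposition> rmsd = %.4f A over %d pairs (%d rejection cycle%s%s)\n",
    x$rmsd, x$n, x$cycles_run, if (x$cycles_run == 1L) "" else "s",
    if (is.null(x$rmsd_all)) "" else sprintf("; all-pair rmsd = %.4f A", x$rmsd_all)
  ))
  invisible(x)
}

#' Tidy a superposition: one row per retained residue pair
#'
#' @param x A `glun_superposition`.
#' @param ... Unused.
#' @return Tibble with `pos_a`, `pos_b`.
#' @export
tidy.glun_superposition <- function(x, ...) {
  if (is.null(x$retained_pairs)) return(tibble(pos_a = integer(), pos_b = integer()))
  as_tibble(as.data.frame(x$retained_pairs))
}

#' One-row summary of a superposition fit
#'
#' @param x A `glun_superposition`.
#' @param ... Unused.
#' @return Tibble with `rmsd`, `rmsd_all`, `n_retained`, `cycles_run`,
#'   `rotation_angle_deg`.
#' @export
glance.glun_superposition <- function(x, ...) {
  tibble(
    rmsd = x$rmsd, rmsd_all = x$rmsd_all %||% NA_real_,
    n_retained = x$n, cycles_run = x$cycles_run,
    rotation_angle_deg = rotation_angle(x$rotation)
  )
}

#' Angle of a rotation matrix, in degrees
#'
#' @param R A 3 x 3 rotation matrix.
#' @return Rotation angle in `[0, 180]` degrees.
#' @export
rotation_angle <- function(R) {
  ctheta <- (sum(diag(R)) - 1) / 2
  acos(pmin(1, pmax(-1, ctheta))) * 180 / pi
}
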