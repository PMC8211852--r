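#' Contact matrix container
#'
#' Binned, symmetric, sparse contact counts for all chromosome pairs of a
#' genome. Cis matrices are stored per chromosome as full symmetric sparse
#' matrices (the diagonal counted once); trans matrices per ordered
#' chromosome pair. Balancing weights, when computed, live alongside the cis
#' matrices with `NA` marking masked (low-coverage) bins.
#'
#' @name contact_matrix
#' @keywords internal
NULL

.cm_new <- function(genome, binsize, mats, weights = NULL) {
  cis <- names(genome$chrom_lengths)
  cis_total <- sum(vapply(cis, function(ch) {
    m <- mats[[ch]]
    if (is.null(m)) 0 else (sum(m) + sum(Matrix::diag(m))) / 2
  }, numeric(1)))
  trans_total <- sum(vapply(setdiff(names(mats), cis),
                            function(k) sum(mats[[k]]), numeric(1)))
  structure(list(genome = genome, binsize = binsize, mats = mats,
                 weights = weights, cis_total = cis_total,
                 trans_total = trans_total),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix: binsize", format(x$binsize, big.mark = ","), "bp;",
      "cis total", format(round(x$cis_total), big.mark = ","), ";",
      "trans total", format(round(x$trans_total), big.mark = ","), "\n")
  cat("  chromosomes:", paste(names(x$genome$chrom_lengths), collapse = ", "),
      if (!is.null(x$weights)) "(balanced)" else "(raw)", "\n")
  invisible(x)
}

.trans_key <- function(c1, c2) paste(c1, c2, sep = "|")

#' Extract the cis matrix of one chromosome
#' @param cm a `contact_matrix`.
#' @param chrom chromosome name.
#' @param balanced if `TRUE` and weights exist, return the balanced matrix
#'   `w_i M_ij w_j` (masked bins zeroed).
#' @return a sparse symmetric matrix.
#' @export
cis_matrix <- function(cm, chrom, balanced = FALSE) {
  m <- cm$mats[[chrom]]
  if (is.null(m)) {
    nb <- n_bins(cm$genome, cm$binsize)[[chrom]]
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(nb, nb))
  }
  if (balanced) {
    if (is.null(cm$weights[[chrom]])) stop("matrix not balanced for ", chrom)
    w <- cm$weights[[chrom]]
    w[is.na(w)] <- 0
    m <- Matrix::Diagonal(x = w) %*% m %*% Matrix::Diagonal(x = w)
  }
  m
}

#' Extract a trans matrix for an ordered chromosome pair
#' @param cm a `contact_matrix`.
#' @param c1,c2 chromosome names in genome order (`c1` before `c2`).
#' @return sparse matrix with rows = bins of `c1`, cols = bins of `c2`.
#' @export
trans_matrix <- function(cm, c1, c2) {
  m <- cm$mats[[.trans_key(c1, c2)]]
  if (is.null(m)) {
    nb <- n_bins(cm$genome, cm$binsize)
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(nb[[c1]], nb[[c2]]))
  }
  m
}

#' Bin contact records into a contact matrix
#'
#' Positions are 1-based; the bin index is `floor((pos - 1) / binsize)`, so
#' position 40,000 falls in bin 0 and 40,001 in bin 1 at 40-kb bins.
#' Record orientation is canonicalized (chromosomes in genome order, lower
#' bin first within a chromosome); total count is conserved exactly.
#'
#' @param records data.frame with columns `chrom1`, `pos1`, `chrom2`, `pos2`
#'   and optionally `count` (default 1 per record).
#' @param genome a `genome_model`.
#' @param binsize bin size in bp.
#' @return a `contact_matrix`.
#' @export
bin_contacts <- function(records, genome, binsize) {
  lens <- genome$chrom_lengths
  chroms <- names(lens)
  if (nrow(records) > 0) {
    .check_within(records$chrom1, records$pos1, lens, "contact records")
    .check_within(records$chrom2, records$pos2, lens, "contact records")
  }
  cnt <- if (is.null(records$count)) rep(1, nrow(records)) else records$count
  nb <- n_bins(genome, binsize)
  b1 <- pos_to_bin(records$pos1, binsize)
  b2 <- pos_to_bin(records$pos2, binsize)
  o1 <- match(records$chrom1, chroms)
  o2 <- match(records$chrom2, chroms)
  # canonical orientation: chrom order, then bin order
  flip <- o1 > o2 | (o1 == o2 & b1 > b2)
  c1 <- ifelse(flip, records$chrom2, records$chrom1)
  c2 <- ifelse(flip, records$chrom1, records$chrom2)
  i1 <- ifelse(flip, b2, b1)
  i2 <- ifelse(flip, b1, b2)
  mats <- list()
  for (ch in chroms) {
    sel <- which(c1 == ch & c2 == ch)
    n <- nb[[ch]]
    if (length(sel) == 0) next
    up <- Matrix::sparseMatrix(i = i1[sel] + 1L, j = i2[sel] + 1L,
                               x = cnt[sel], dims = c(n, n))
    m <- up + Matrix::t(up)
    Matrix::diag(m) <- Matrix::diag(up)   # diagonal stored once
    mats[[ch]] <- m
  }
  for (a in seq_along(chroms)) for (b in seq_along(chroms)) {
    if (b <= a) next
    sel <- which(c1 == chroms[a] & c2 == chroms[b])
    if (length(sel) == 0) next
    mats[[.trans_key(chroms[a], chroms[b])]] <-
      Matrix::sparseMatrix(i = i1[sel] + 1L, j = i2[sel] + 1L, x = cnt[sel],
                           dims = c(nb[[a]], nb[[b]]))
  }
  .cm_new(genome, binsize, mats)
}

# ---- Knight-Ruiz balancing ---------------------------------------------------

# Inner-outer Newton iteration for matrix balancing (conjugate-gradient inner
# solves, as in the original algorithm). A must be symmetric nonnegative with
# fully supported rows; returns x with x*(Ax) ~= 1.
.kr_newton <- function(A, tol = 1e-6, delta = 0.1, Delta = 3, max_outer = 300) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9; etamax <- 0.1; eta <- etamax
  rt <- tol^2
  v <- x * as.numeric(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  outer <- 0
  while (rout > rt && outer < max_outer) {
    outer <- outer + 1
    k <- 0; y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.numeric(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > 200) break
    }
    x <- x * y
    v <- x * as.numeric(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta; eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), 0.5 * tol / res_norm)
  }
  list(x = x, converged = rout <= rt, iterations = outer)
}

# plain Sinkhorn fallback: alternating scaling to unit row sums
.sinkhorn <- function(A, tol = 1e-6, max_iter = 3000) {
  n <- nrow(A)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    r <- x * as.numeric(A %*% x)
    dev <- max(abs(r - 1))
    if (dev < tol) return(list(x = x, converged = TRUE, iterations = it))
    x <- x / sqrt(r)
  }
  list(x = x, converged = FALSE, iterations = max_iter)
}

#' Knight-Ruiz matrix balancing
#'
#' Computes per-bin weights `w` such that the row sums of `w_i M_ij w_j` are
#' equal (normalized to 1) over unmasked bins, using the Knight-Ruiz
#' inner-outer Newton iteration with a Sinkhorn fallback on non-convergence.
#' Bins with zero marginal, or with marginal below the 1st percentile of the
#' nonzero marginals, are masked (`NA` weight) before balancing.
#'
#' @param m a `contact_matrix` (all cis matrices are balanced and the weights
#'   stored) or a single square symmetric matrix.
#' @param tol relative row-sum deviation tolerance.
#' @param max_iterations maximum outer iterations.
#' @param chrom when `m` is a `contact_matrix`, restrict to these chromosomes.
#' @return for a plain matrix: numeric weight vector (`NA` on masked bins)
#'   with attributes `converged` and `iterations`. For a `contact_matrix`:
#'   the matrix with `$weights` filled in and a `$balance_report` attribute.
#' @export
kr_balance <- function(m, tol = 1e-6, max_iterations = 300, chrom = NULL) {
  if (inherits(m, "contact_matrix")) {
    chroms <- if (is.null(chrom)) names(m$genome$chrom_lengths) else chrom
    if (is.null(m$weights)) m$weights <- list()
    report <- list()
    for (ch in chroms) {
      w <- kr_balance(cis_matrix(m, ch), tol = tol,
                      max_iterations = max_iterations)
      m$weights[[ch]] <- w
      report[[ch]] <- list(converged = attr(w, "converged"),
                           iterations = attr(w, "iterations"))
    }
    m$balance_report <- report
    return(m)
  }
  A <- if (inherits(m, "Matrix")) m else Matrix::Matrix(m)
  if (nrow(A) != ncol(A)) stop("kr_balance requires a square cis matrix")
  n <- nrow(A)
  marg <- as.numeric(Matrix::rowSums(A))
  nz <- marg[marg > 0]
  cut <- if (length(nz) > 0) stats::quantile(nz, 0.01, type = 1) else 0
  keep <- which(marg > 0 & marg >= cut)
  if (length(keep) < 2) stop("degenerate input: fewer than 2 unmasked bins")
  Asub <- as.matrix(A[keep, keep, drop = FALSE])
  # pre-scale so the Newton iteration starts near the fixed point
  sc <- mean(Matrix::rowSums(Asub))
  fit <- .kr_newton(Asub / sc, tol = tol, max_outer = max_iterations)
  if (!fit$converged) fit <- .sinkhorn(Asub / sc, tol = tol)
  w <- rep(NA_real_, n)
  w[keep] <- fit$x / sqrt(sc)
  structure(w, converged = fit$converged, iterations = fit$iterations)
}

#' Mean contact value by genomic distance
#'
#' Expected (distance-decay) profile of a cis matrix: the mean value at each
#' bin separation over unmasked bin pairs. Masked bins are excluded from both
#' numerator and denominator.
#'
#' @param cm a `contact_matrix`.
#' @param chrom chromosome name.
#' @param balanced use balanced values if weights are available.
#' @return data.frame with columns `distance` (bins), `mean`, `npairs`,
#'   classed `decay_profile`.
#' @export
expected_by_distance <- function(cm, chrom, balanced = !is.null(cm$weights[[chrom]])) {
  M <- as.matrix(cis_matrix(cm, chrom, balanced = balanced))
  if (balanced) {
    w <- cm$weights[[chrom]]
    M[is.na(w), ] <- NA
    M[, is.na(w)] <- NA
  }
  n <- nrow(M)
  means <- numeric(n); npairs <- integer(n)
  for (d in 0:(n - 1)) {
    v <- M[cbind(seq_len(n - d), seq_len(n - d) + d)]
    npairs[d + 1] <- sum(!is.na(v))
    means[d + 1] <- if (npairs[d + 1] > 0) mean(v, na.rm = TRUE) else NA_real_
  }
  structure(data.frame(distance = 0:(n - 1), mean = means, npairs = npairs),
            class = c("decay_profile", "data.frame"))
}

#' Normalize matrices to a common cis depth
#'
#' Scales every matrix by `target / cis_total` so all matrices share the same
#' cis total; within-matrix entry ratios are unchanged.
#'
#' @param matrices a `contact_matrix` or list of them.
#' @param target target cis total (default 1e6).
#' @return the scaled matrix or list of matrices.
#' @export
cis_depth_normalize <- function(matrices, target = 1e6) {
  one <- inherits(matrices, "contact_matrix")
  if (one) matrices <- list(matrices)
  out <- lapply(matrices, function(cm) {
    if (cm$cis_total <= 0) stop("degenerate input: zero cis total")
    f <- target / cm$cis_total
    cm$mats <- lapply(cm$mats, function(m) m * f)
    cm$cis_total <- cm$cis_total * f
    cm$trans_total <- cm$trans_total * f
    cm$depth_factor <- f
    cm
  })
  if (one) out[[1]] else out
}

# pooled (summed) matrix over a list of contact_matrix on the same grid
.pool_matrices <- function(cms) {
  base <- cms[[1]]
  keys <- unique(unlist(lapply(cms, function(cm) names(cm$mats))))
  mats <- list()
  for (k in keys) {
    acc <- NULL
    for (cm in cms) {
      m <- cm$mats[[k]]
      if (is.null(m)) next
      acc <- if (is.null(acc)) m else acc + m
    }
    mats[[k]] <- acc
  }
  .cm_new(base$genome, base$binsize, mats)
}

#' Pool (sum) contact matrices across samples
#' @param cms list of `contact_matrix` objects on the same genome and binsize.
#' @return pooled `contact_matrix`.
#' @export
pool_matrices <- function(cms) {
  stopifnot(length(cms) >= 1)
  bs <- unique(vapply(cms, function(x) x$binsize, numeric(1)))
  if (length(bs) != 1) stop("matrices on different bin grids")
  .pool_matrices(cms)
}
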