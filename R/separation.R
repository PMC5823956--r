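#' Separation parameters
#'
#' Parameters of the blind source separation applied to the `N + 1`
#' region-mean traces of one ROI.
#'
#' The NMF objective minimised is
#' \deqn{E = \tfrac12\|F - V S\|^2 + \alpha\,l_1 (\|V\|_1 + \|S\|_1)
#'       + \alpha(1 - l_1)(\|V\|^2 + \|S\|^2),}
#' where the squared norms carry the convention \eqn{\|A\|^2 =
#' \tfrac12\sum A_{ij}^2} and \eqn{\|A\|_1 = \sum |A_{ij}|}. The penalty is
#' applied exactly as written, unnormalised by the matrix dimensions.
#'
#' @param alpha Sparseness regularizer, `>= 0` (default 0.1).
#' @param l1_ratio Mix between element-wise L1 and squared-Frobenius
#'   penalties, in `[0, 1]` (default 0.5).
#' @param max_iterations Iteration cap (default 2000).
#' @param tolerance Relative objective-change stopping threshold
#'   (default 1e-4).
#' @param n_components Number of separated signals; defaults to the number
#'   of input regions (`N + 1`).
#' @param method `"nmf"` (recommended) or `"ica"`.
#' @param random_seed Optional integer fixing any stochastic fallback
#'   (the nndsvd initialisation itself is deterministic).
#' @return Object of class `separation_params`.
#' @export
separation_params <- function(alpha = 0.1, l1_ratio = 0.5,
                              max_iterations = 2000L, tolerance = 1e-4,
                              n_components = NULL, method = c("nmf", "ica"),
                              random_seed = NULL) {
  stopifnot(alpha >= 0, l1_ratio >= 0, l1_ratio <= 1,
            max_iterations >= 1, tolerance > 0)
  structure(list(alpha = alpha, l1_ratio = l1_ratio,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, n_components = n_components,
                 method = match.arg(method), random_seed = random_seed),
            class = "separation_params")
}

## non-negative double SVD initialisation (deterministic); zero entries are
## replaced by mean(X) so that multiplicative updates can move them
nndsvd_init <- function(x, k) {
  sv <- svd(x, nu = k, nv = k)
  m <- nrow(x); tt <- ncol(x)
  w <- matrix(0, m, k); h <- matrix(0, k, tt)
  w[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  h[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k >= 2) for (j in 2:k) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    upn <- sqrt(sum(up^2)); unn <- sqrt(sum(un^2))
    vpn <- sqrt(sum(vp^2)); vnn <- sqrt(sum(vn^2))
    if (upn * vpn >= unn * vnn) {
      sig <- upn * vpn
      if (sig > 0) {
        w[, j] <- sqrt(sv$d[j] * sig) * up / upn
        h[j, ] <- sqrt(sv$d[j] * sig) * vp / vpn
      }
    } else {
      sig <- unn * vnn
      w[, j] <- sqrt(sv$d[j] * sig) * un / unn
      h[j, ] <- sqrt(sv$d[j] * sig) * vn / vnn
    }
  }
  eps <- mean(x)
  w[w <= 0] <- eps
  h[h <= 0] <- eps
  list(w = w, h = h)
}

## the regularized objective, with the 1/2-inside-the-norm convention
nmf_objective <- function(x, w, h, alpha, l1_ratio) {
  d <- x - w %*% h
  0.25 * sum(d^2) +
    alpha * l1_ratio * (sum(abs(w)) + sum(abs(h))) +
    0.5 * alpha * (1 - l1_ratio) * (sum(w^2) + sum(h^2))
}

## hierarchical alternating least squares: exact block coordinate descent on
## 2E = 1/2||X-WH||_F^2 (standard Frobenius) + l1reg*L1 + l2reg*sum-sq, so
## the objective is non-increasing by construction
sparse_nmf <- function(x, k, alpha, l1_ratio, max_iter, tol) {
  init <- nndsvd_init(x, k)
  w <- init$w; h <- init$h
  l1reg <- 2 * alpha * l1_ratio
  l2reg <- alpha * (1 - l1_ratio)
  eps <- .Machine$double.eps
  obj <- nmf_objective(x, w, h, alpha, l1_ratio)
  history <- obj
  sumx2 <- sum(x^2)
  for (it in seq_len(max_iter)) {
    wtx <- crossprod(w, x); wtw <- crossprod(w)
    for (j in seq_len(k)) {
      den <- wtw[j, j] + 2 * l2reg
      if (den <= eps) { h[j, ] <- 0; next }
      # full-row product plus the diagonal term back: algebraically equal to
      # excluding row j, but avoids copying the k-1 remaining rows of h
      num <- wtx[j, ] - drop(wtw[j, ] %*% h) + wtw[j, j] * h[j, ] - l1reg
      num <- num / den
      num[num < 0] <- 0
      h[j, ] <- num
    }
    xht <- tcrossprod(x, h); hht <- tcrossprod(h)
    for (j in seq_len(k)) {
      den <- hht[j, j] + 2 * l2reg
      if (den <= eps) { w[, j] <- 0; next }
      num <- xht[, j] -
        w[, -j, drop = FALSE] %*% hht[-j, j, drop = FALSE] - l1reg
      w[, j] <- pmax(0, num / den)
    }
    # objective via the Gram identity ||X-WH||^2 = ||X||^2 - 2<W,XH'> +
    # <W'W,HH'> (xht and hht stay valid: the w loop does not touch x or h),
    # avoiding the m x T reconstruction; w, h >= 0 so the l1 term needs no
    # abs. Equal to nmf_objective() up to ~1e-9 relative cancellation error.
    wtw2 <- crossprod(w)
    newobj <- 0.25 * (sumx2 - 2 * sum(w * xht) + sum(wtw2 * hht)) +
      alpha * l1_ratio * (sum(w) + sum(h)) +
      0.5 * alpha * (1 - l1_ratio) * (sum(diag(wtw2)) + sum(diag(hht)))
    history <- c(history, newobj)
    if (abs(obj - newobj) <= tol * max(obj, eps)) { obj <- newobj; break }
    obj <- newobj
  }
  list(w = w, h = h, objective_history = history, iterations = it)
}

#' Select the somatic component from a separation
#'
#' Normalises each column of the mixing matrix to sum 1 (the relative
#' presence of each separated signal in each region), picks the column with
#' the largest relative presence in the ROI row (row 1), breaking ties by
#' the lowest column index, and returns the somatic trace rescaled by the
#' selected signal's raw contribution to the ROI:
#' `somatic = mixing[1, j] * separated[j, ]`.
#'
#' @param mixing `(N+1) x k` non-negative mixing matrix.
#' @param separated `k x T` matrix of separated signals.
#' @return List with `selected_index` (1-based column), `somatic_trace`,
#'   and `relative_presence` (the column-normalised mixing matrix; all-zero
#'   columns are left as `NA` and excluded from selection with a warning).
#' @export
select_somatic <- function(mixing, separated) {
  stopifnot(is.matrix(mixing), is.matrix(separated),
            ncol(mixing) == nrow(separated))
  colsums <- colSums(mixing)
  dead <- colsums <= 0
  if (any(dead)) {
    warning(sum(dead), " all-zero mixing column(s) excluded from selection")
    colsums[dead] <- NA_real_
  }
  rel <- sweep(mixing, 2, colsums, "/")
  presence <- rel[1, ]
  presence[dead] <- -Inf
  if (all(!is.finite(presence)) || max(presence, na.rm = TRUE) <= 0)
    stop("no separated signal has any presence in the ROI row")
  j <- which.max(presence)  # which.max takes the lowest index on ties
  ties <- sum(presence == presence[j], na.rm = TRUE)
  if (ties > 1)
    message("tie in ROI relative presence across ", ties,
            " components; selected the lowest index")
  list(selected_index = j,
       somatic_trace = mixing[1, j] * separated[j, ],
       relative_presence = rel)
}

#' Blind source separation of region traces
#'
#' Demixes the `N + 1` region-mean traces of one ROI by sparse non-negative
#' matrix factorization (or ICA, see [separation_params()]), then selects and
#' rescales the somatic component with [select_somatic()].
#'
#' @param traces A `trace_matrix` (row 1 = ROI) or `(N+1) x T` matrix.
#' @param params A [separation_params()] object.
#' @return Object of class `separation_result`: `mixing` (`(N+1) x k`),
#'   `separated` (`k x T`), `relative_presence`, `selected_index`,
#'   `somatic_trace`, `objective_history` (NMF only), `method`.
#' @export
separate_traces <- function(traces, params = separation_params()) {
  if (params$method == "ica") return(separate_ica(traces, params))
  x <- if (inherits(traces, "trace_matrix")) traces$values else traces
  check_separation_input(x)
  if (any(x < 0)) {
    warning(sum(x < 0), " negative trace entries clipped to 0 for NMF")
    x[x < 0] <- 0
  }
  if (all(x == 0)) stop("all-zero traces: nothing to separate")
  k <- if (is.null(params$n_components)) nrow(x) else params$n_components
  if (ncol(x) < k)
    stop("need at least as many frames as components (", k, ")")
  if (!is.null(params$random_seed)) set.seed(params$random_seed)
  fit <- sparse_nmf(x, k, params$alpha, params$l1_ratio,
                    params$max_iterations, params$tolerance)
  sel <- select_somatic(fit$w, fit$h)
  structure(list(mixing = fit$w, separated = fit$h,
                 relative_presence = sel$relative_presence,
                 selected_index = sel$selected_index,
                 somatic_trace = sel$somatic_trace,
                 objective_history = fit$objective_history,
                 iterations = fit$iterations, method = "nmf"),
            class = "separation_result")
}

check_separation_input <- function(x) {
  if (!is.matrix(x)) stop("traces must be a matrix or trace_matrix")
  if (anyNA(x) || any(!is.finite(x))) stop("traces contain non-finite values")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf(
    "<separation_result (%s): %d regions, %d components, selected #%d>\n",
    x$method, nrow(x$mixing), ncol(x$mixing), x$selected_index))
  invisible(x)
}

## symmetric FastICA with the logcosh contrast, on pre-whitened data
fastica_core <- function(z, k, max_iter, tol) {
  p <- nrow(z); n <- ncol(z)
  w <- matrix(stats::rnorm(k * p), k, p)
  sym_decorrelate <- function(w) {
    e <- eigen(tcrossprod(w), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*%
      t(e$vectors) %*% w
  }
  w <- sym_decorrelate(w)
  for (it in seq_len(max_iter)) {
    wu <- w %*% z
    g <- tanh(wu)
    gp <- rowMeans(1 - g^2)
    w1 <- g %*% t(z) / n - diag(gp, k) %*% w
    w1 <- sym_decorrelate(w1)
    delta <- max(abs(abs(rowSums(w1 * w)) - 1))
    w <- w1
    if (delta < tol) return(list(w = w, converged = TRUE, iterations = it))
  }
  list(w = w, converged = FALSE, iterations = max_iter)
}

#' ICA-based separation of region traces
#'
#' FastICA alternative to the NMF separation: the traces are centred and
#' whitened, unmixed with the symmetric logcosh FastICA, each component is
#' sign-flipped so its skewness is non-negative (calcium transients are
#' positive-going), and the somatic component is selected by relative
#' presence computed on the absolute mixing weights. Unlike NMF, ICA can
#' return negative mixing weights and trace values.
#'
#' @inheritParams separate_traces
#' @return A `separation_result` (see [separate_traces()]).
#' @export
separate_ica <- function(traces, params = separation_params(method = "ica")) {
  x <- if (inherits(traces, "trace_matrix")) traces$values else traces
  check_separation_input(x)
  vr <- apply(x, 1, stats::var)
  if (any(vr == 0)) {
    warning(sum(vr == 0), " zero-variance region trace(s) dropped for ICA")
    x <- x[vr > 0, , drop = FALSE]
    if (nrow(x) < 2) stop("fewer than 2 usable traces for ICA")
  }
  k <- if (is.null(params$n_components)) nrow(x) else
    min(params$n_components, nrow(x))
  n <- ncol(x)
  ctr <- rowMeans(x)
  xc <- x - ctr
  cv <- tcrossprod(xc) / n
  e <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(k)
  kmat <- diag(1 / sqrt(pmax(e$values[keep], 1e-12)), k) %*%
    t(e$vectors[, keep, drop = FALSE])
  z <- kmat %*% xc
  if (!is.null(params$random_seed)) set.seed(params$random_seed)
  fit <- fastica_core(z, k, params$max_iterations, max(params$tolerance, 1e-6))
  if (!fit$converged)
    stop("ICA did not converge within ", fit$iterations, " iterations")
  s <- fit$w %*% z
  # regions x components; pseudo-inverse of the unmixing-after-whitening map
  mixing <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(pmax(e$values[keep], 1e-12)), k) %*% t(fit$w)
  # orient components so skewness >= 0
  for (j in seq_len(k)) {
    sj <- s[j, ]
    sk <- mean((sj - mean(sj))^3)
    if (sk < 0) { s[j, ] <- -sj; mixing[, j] <- -mixing[, j] }
  }
  sel <- select_somatic(abs(mixing), s)
  somatic <- mixing[1, sel$selected_index] * s[sel$selected_index, ]
  if (mixing[1, sel$selected_index] < 0) somatic <- -somatic
  structure(list(mixing = mixing, separated = s,
                 relative_presence = sel$relative_presence,
                 selected_index = sel$selected_index,
                 somatic_trace = somatic,
                 objective_history = NULL,
                 iterations = fit$iterations, method = "ica"),
            class = "separation_result")
}
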