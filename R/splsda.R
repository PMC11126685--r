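#' Parameters for sparse PLS discriminant analysis
#'
#' @param n_components Number of latent components (default 2).
#' @param keepX Number of features retained per component; recycled to
#'   `n_components` (default 100 each).
#' @param max_iter Power-iteration cap per component (default 500).
#' @param tol Convergence tolerance on the weight vector (default 1e-9).
#' @param log1p Apply `log1p` to the counts before scaling (off by default;
#'   counts are used as-is).
#' @return A list of class `splsda_params`.
#' @export
splsda_params <- function(n_components = 2L, keepX = 100L, max_iter = 500L,
                          tol = 1e-9, log1p = FALSE) {
  if (n_components < 1L) stop("n_components must be >= 1")
  if (any(keepX < 1L)) stop("keepX must be >= 1")
  keepX <- rep_len(as.integer(keepX), n_components)
  structure(list(n_components = as.integer(n_components), keepX = keepX,
                 max_iter = as.integer(max_iter), tol = tol, log1p = log1p),
            class = "splsda_params")
}

## Column-center and unit-variance scale; zero-variance columns get scale 1
## and are flagged so their loadings can be pinned to zero.
scale_matrix <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  const <- !is.finite(sdv) | sdv < 1e-12
  sdv[const] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  list(X = Xs, constant = const)
}

#' Fit a sparse PLS-DA model on an orthogroup count matrix
#'
#' The count matrix is column-centered and unit-variance scaled; the class
#' membership is coded as a two-column indicator matrix, also centered and
#' scaled. For each component the dominant singular pair of `t(X) %*% Y` is
#' found by power iteration; the X-weight is soft-thresholded so that exactly
#' `keepX` entries survive (threshold = the `(keepX+1)`-th largest absolute
#' weight, ties broken by ascending feature order), re-normalized to unit
#' norm; species scores are `X %*% weight`; X is then deflated by regressing
#' it on the score. Zero-variance features always receive a zero loading so
#' feature indices stay stable.
#'
#' @param m Count matrix (species rows, family columns), already filtered.
#' @param groups Named character vector mapping species to `"focal"`/`"other"`
#'   (any two labels work).
#' @param params An [splsda_params()] object.
#' @param y_coding `"indicator"` (two centered/scaled indicator columns, the
#'   default) or `"pm1"` (a single centered/scaled ±1 column; identical
#'   component-1 support for two classes).
#' @return An object of class `splsda_model`: per-component `loadings`
#'   (p x h matrix, unit-norm sparse columns), `scores` (n x h), `selected`
#'   (list of family-id vectors), `explained_variance` (fraction of the total
#'   variance of scaled X captured per component, computed on the undeflated
#'   X with scores orthogonalized in fit order), plus the scaled `X` and
#'   class labels.
#' @export
fit_splsda <- function(m, groups, params = splsda_params(),
                       y_coding = c("indicator", "pm1")) {
  y_coding <- match.arg(y_coding)
  stopifnot(inherits(params, "splsda_params"))
  groups <- groups[intersect(names(groups), rownames(m))]
  if (length(unique(groups)) != 2L) stop("exactly two classes are required")
  if (min(table(groups)) < 2L) stop("need at least 2 species per class")
  m <- m[names(groups), , drop = FALSE]
  X0 <- if (params$log1p) log1p(m) else m
  sc <- scale_matrix(X0)
  X <- sc$X
  p <- ncol(X); n <- nrow(X)

  lev <- sort(unique(groups))
  Y0 <- if (y_coding == "indicator") {
    cbind(as.numeric(groups == lev[1]), as.numeric(groups == lev[2]))
  } else {
    matrix(ifelse(groups == lev[1], 1, -1), ncol = 1)
  }
  Y <- scale_matrix(Y0)$X

  keepX <- pmin(params$keepX, sum(!sc$constant))
  if (any(keepX < params$keepX)) {
    warning("keepX clipped to the number of non-constant features (",
            sum(!sc$constant), ")")
  }

  Xh <- X
  loadings <- matrix(0, p, params$n_components,
                     dimnames = list(colnames(m), NULL))
  scores <- matrix(0, n, params$n_components, dimnames = list(rownames(m), NULL))
  selected <- vector("list", params$n_components)
  for (h in seq_len(params$n_components)) {
    M <- crossprod(Xh, Y)              # p x q
    w <- M[, 1]
    if (sqrt(sum(w^2)) < 1e-300) w <- rowSums(M)
    w <- w / sqrt(sum(w^2))
    v <- NULL
    converged <- FALSE
    for (it in seq_len(params$max_iter)) {
      v <- crossprod(M, w); v <- v / sqrt(sum(v^2))
      w_new <- M %*% v; w_new <- w_new / sqrt(sum(w_new^2))
      if (sum((abs(w_new) - abs(w))^2) < params$tol) {
        w <- as.numeric(w_new); converged <- TRUE
        break
      }
      w <- as.numeric(w_new)
    }
    if (!converged) {
      stop("power iteration did not converge within ", params$max_iter,
           " iterations on component ", h)
    }
    w[sc$constant] <- 0
    ## order-statistic soft threshold: exact keepX support, ties by feature id
    ord <- order(-abs(w), seq_along(w))
    keep_idx <- ord[seq_len(keepX[h])]
    lambda <- if (keepX[h] < sum(abs(w) > 0)) abs(w[ord[keepX[h] + 1L]]) else 0
    w_st <- numeric(p)
    w_st[keep_idx] <- sign(w[keep_idx]) * pmax(abs(w[keep_idx]) - lambda, 0)
    nrm <- sqrt(sum(w_st^2))
    if (nrm < 1e-300) stop("all thresholded weights vanished on component ", h)
    w_st <- w_st / nrm
    t_h <- as.numeric(Xh %*% w_st)
    loadings[, h] <- w_st
    scores[, h] <- t_h
    selected[[h]] <- colnames(m)[keep_idx]
    ## deflate X by its least-squares regression on the score
    pl <- crossprod(Xh, t_h) / sum(t_h^2)
    Xh <- Xh - tcrossprod(t_h, pl)
  }

  model <- structure(list(
    loadings = loadings, scores = scores, selected = selected,
    keepX = keepX, X = X, groups = groups, y_coding = y_coding,
    params = params
  ), class = "splsda_model")
  model$explained_variance <- explained_variance(model)
  model
}

#' Explained-variance fractions of a sparse PLS-DA fit
#'
#' Fraction of the squared Frobenius norm of the scaled (undeflated) data
#' matrix captured by the projection onto each component score, with scores
#' orthogonalized in fit order (Gram-Schmidt) so the fractions are additive.
#'
#' @param model An `splsda_model`.
#' @param X Scaled data matrix; defaults to the one stored in the model.
#' @return Numeric vector of per-component fractions in `[0, 1]`, sum <= 1.
#' @export
explained_variance <- function(model, X = model$X) {
  total <- sum(X^2)
  if (total <= 0) stop("all-zero data matrix: explained variance undefined")
  Tm <- model$scores
  h <- ncol(Tm)
  frac <- numeric(h)
  basis <- NULL
  for (k in seq_len(h)) {
    t_k <- Tm[, k]
    if (!is.null(basis)) {
      t_k <- t_k - basis %*% crossprod(basis, t_k)
    }
    nrm <- sqrt(sum(t_k^2))
    if (nrm < 1e-12) { frac[k] <- 0; next }
    t_k <- t_k / nrm
    frac[k] <- sum(as.numeric(crossprod(X, t_k))^2) / total
    basis <- cbind(basis, t_k)
  }
  frac
}

#' Top contributing families of a component
#'
#' @param model An `splsda_model`.
#' @param component Component index (default 1).
#' @param k Number of families to return; must not exceed the component's
#'   keepX.
#' @return Data frame of family, loading, rank; sorted by absolute loading
#'   descending, ties broken by family id.
#' @export
top_contributors <- function(model, component = 1L, k = 100L) {
  if (k <= 0) stop("k must be positive")
  if (component < 1L || component > ncol(model$loadings)) {
    stop("component out of range")
  }
  if (k > model$keepX[component]) {
    stop("k exceeds keepX (", model$keepX[component], ") of component ", component)
  }
  w <- model$loadings[, component]
  ord <- order(-abs(w), names(w))
  top <- ord[seq_len(k)]
  data.frame(family = names(w)[top], loading = unname(w[top]), rank = seq_len(k),
             stringsAsFactors = FALSE)
}

#' @export
print.splsda_model <- function(x, ...) {
  cat("sPLS-DA fit:", ncol(x$loadings), "component(s), keepX =",
      paste(x$keepX, collapse = ", "), "\n")
  cat("explained variance (X):",
      paste(sprintf("%.3f", x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}
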