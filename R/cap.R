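#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i) between nonnegative profiles;
#' bounded in [0, 1]. Rows that are entirely zero have no defined distance
#' and are rejected by name rather than silently dropped.
#'
#' @param x nonnegative numeric matrix, rows = plants, cols = compounds.
#' @return symmetric `dist`-free square matrix with zero diagonal and the
#'   row labels of `x`.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("Bray-Curtis requires nonnegative entries")
  rs <- rowSums(x)
  if (any(rs == 0)) {
    bad <- rownames(x)[rs == 0]
    if (is.null(bad)) bad <- which(rs == 0)
    stop("all-zero emission row(s), distance undefined: ",
         paste(bad, collapse = ", "))
  }
  man <- as.matrix(stats::dist(x, method = "manhattan"))
  d <- man / outer(rs, rs, "+")
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres the Gower matrix G = (I - 11'/n)(-D^2/2)(I - 11'/n) and
#' eigendecomposes it. Coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues; negative-eigenvalue axes, which
#' arise because Bray-Curtis is non-Euclidean, are discarded and counted.
#' Total inertia is trace(G) = sum of all eigenvalues (positive real part
#' plus the negative "imaginary" part), the convention of distance-based
#' RDA software, so percent-explained values are comparable to published
#' tables.
#'
#' @param d square dissimilarity matrix.
#' @param correction `"none"` (default) or `"sqrt"` to take the square
#'   root of the dissimilarities first (a metricising correction).
#' @return list of class `pcoa_result`: `coordinates` (n x k), `eigenvalues`
#'   (all, descending), `total_inertia`, `positive_inertia`,
#'   `n_negative` (count of discarded axes), `labels`.
#' @export
pcoa <- function(d, correction = c("none", "sqrt")) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 objects for PCoA")
  if (any(abs(d - t(d)) > 1e-10)) stop("dissimilarity matrix not symmetric")
  if (correction == "sqrt") d <- sqrt(d)
  A <- -0.5 * d^2
  # G = (I - 11'/n) A (I - 11'/n): subtract row means, then the column
  # means of the row-swept matrix (which completes the double centring)
  G <- sweep(A, 1, rowMeans(A))
  G <- sweep(G, 2, colMeans(G))
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(d)
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 total_inertia = sum(e$values),
                 positive_inertia = sum(e$values[pos]),
                 n_negative = sum(e$values < -tol),
                 labels = rownames(d)),
            class = "pcoa_result")
}

#' Constrained analysis of principal coordinates (CAP)
#'
#' Multivariate least squares of the PCoA coordinates on a sequential
#' model matrix built from `formula` and `data` (treatment contrasts,
#' terms in formula order). Inertia is decomposed sequentially: each
#' term's fitted inertia is the increase in explained sum of squares when
#' the term enters, so per-term inertias sum exactly to the constrained
#' inertia.
#'
#' @param pc a [pcoa()] result (or a distance matrix, which is passed
#'   through [pcoa()] first).
#' @param formula one-sided model formula of the constraints.
#' @param data data.frame of explanatory variables, rows aligned with the
#'   distance labels.
#' @param comm optional community (plant x compound) matrix used for
#'   species scores in biplots.
#' @return list of class `cap_model`: `terms`, `term_inertia`, `term_df`,
#'   `constrained_inertia`, `residual_inertia`, `total_inertia`,
#'   `residual_df`, `site_scores` (constrained axes), `biplot` (environment
#'   arrows), `species_scores` (if `comm` given), plus internals used by
#'   [sequential_perm_test()].
#' @export
cap_fit <- function(pc, formula, data, comm = NULL) {
  if (!inherits(pc, "pcoa_result")) pc <- pcoa(pc)
  Y <- pc$coordinates
  n <- nrow(Y)
  if (nrow(data) != n) stop("design rows (", nrow(data),
                            ") do not match distance labels (", n, ")")
  old_c <- options(contrasts = c("contr.treatment", "contr.poly"))
  on.exit(options(old_c))
  tt <- stats::terms(formula)
  labels <- attr(tt, "term.labels")
  if (!length(labels)) {
    X <- matrix(1, n, 1)
    asgn <- 0L
  } else {
    X <- stats::model.matrix(formula, data)
    asgn <- attr(X, "assign")
  }
  if (qr(X)$rank < ncol(X)) {
    qx <- qr(X)
    aliased <- colnames(X)[qx$pivot[seq.int(qx$rank + 1, ncol(X))]]
    stop("model matrix rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  ss <- function(M) sum(M^2)
  # sequential decomposition: grow the matrix term by term
  term_inertia <- numeric(length(labels))
  term_df <- integer(length(labels))
  prev_fit <- ss(qr.fitted(qr(X[, asgn == 0, drop = FALSE]), Y))
  for (k in seq_along(labels)) {
    cols <- asgn <= k
    fit_k <- ss(qr.fitted(qr(X[, cols, drop = FALSE]), Y))
    term_inertia[k] <- fit_k - prev_fit
    term_df[k] <- sum(asgn == k)
    prev_fit <- fit_k
  }
  qrf <- qr(X)
  fitted <- qr.fitted(qrf, Y)
  resid <- Y - fitted
  constrained <- ss(fitted) - ss(qr.fitted(qr(X[, asgn == 0, drop = FALSE]), Y))
  residual <- ss(resid)
  residual_df <- n - qrf$rank
  # constrained axes: eigen of the fitted coordinates
  fc <- scale(fitted, scale = FALSE)
  sv <- svd(fc)
  keep <- sv$d > max(sv$d) * 1e-8
  site_scores <- sv$u[, keep, drop = FALSE] %*%
    diag(sv$d[keep], sum(keep))
  rownames(site_scores) <- rownames(Y)
  colnames(site_scores) <- paste0("CAP", seq_len(sum(keep)))
  # environment arrows: correlations of numeric model columns with axes
  Xc <- X[, asgn > 0, drop = FALSE]
  biplot <- if (ncol(Xc) && ncol(site_scores)) {
    suppressWarnings(stats::cor(Xc, site_scores))
  } else NULL
  species_scores <- if (!is.null(comm) && ncol(site_scores)) {
    suppressWarnings(stats::cor(as.matrix(comm), site_scores))
  } else NULL
  structure(list(terms = labels, term_inertia = term_inertia,
                 term_df = term_df,
                 constrained_inertia = constrained,
                 residual_inertia = residual,
                 total_inertia = pc$total_inertia,
                 positive_inertia = pc$positive_inertia,
                 n_negative_axes = pc$n_negative,
                 residual_df = residual_df,
                 site_scores = site_scores, biplot = biplot,
                 species_scores = species_scores,
                 Y = Y, X = X, assign = asgn),
            class = "cap_model")
}

#' Sequential permutation tests of CAP model terms
#'
#' Pseudo-F for each term uses its sequential (order-of-entry) inertia
#' over the full-model residual inertia, each divided by its df. Rows of
#' the coordinate matrix are permuted freely; under each permutation the
#' whole sequential decomposition is recomputed. p-values are
#' `(1 + #{F* >= F_obs}) / (1 + n_perm)`, so the smallest attainable p is
#' `1/(n_perm + 1)`.
#'
#' When `interaction_block = TRUE`, all interaction terms (labels
#' containing `:`) are additionally tested jointly after the main
#' effects, reported as one `interactions` row.
#'
#' @param model a [cap_fit()] result.
#' @param n_perm number of permutations (>= 19).
#' @param seed integer seed.
#' @param interaction_block test all interactions as one block after the
#'   main effects.
#' @return data.frame: `term`, `df`, `inertia`, `F`, `p_value`,
#'   `n_perm`, `seed`.
#' @export
sequential_perm_test <- function(model, n_perm = 999, seed = 1L,
                                 interaction_block = TRUE) {
  stopifnot(inherits(model, "cap_model"))
  if (n_perm < 19) stop("n_perm must be >= 19")
  Y <- model$Y; X <- model$X; asgn <- model$assign
  n <- nrow(Y)
  labels <- model$terms
  inter <- grepl(":", labels, fixed = TRUE)
  qr_list <- lapply(seq_along(labels), function(k) {
    qr(X[, asgn <= k, drop = FALSE])
  })
  qr0 <- qr(X[, asgn == 0, drop = FALSE])
  qrf <- qr(X)
  main_qr <- if (any(inter)) {
    qr(X[, asgn %in% c(0, which(!inter)), drop = FALSE])
  } else NULL
  ss <- function(M) sum(M^2)
  resid_df <- model$residual_df

  stats_for <- function(Yp) {
    fits <- vapply(qr_list, function(q) ss(qr.fitted(q, Yp)), 0)
    base <- ss(qr.fitted(qr0, Yp))
    seq_in <- diff(c(base, fits))
    res <- ss(Yp) - if (length(fits)) fits[length(fits)] else base
    # note ss(Yp) includes no intercept part: Y columns are centred
    Fs <- (seq_in / model$term_df) / (res / resid_df)
    out <- Fs
    if (any(inter) && interaction_block) {
      main_fit <- ss(qr.fitted(main_qr, Yp))
      block_in <- fits[length(fits)] - main_fit
      block_df <- sum(model$term_df[inter])
      out <- c(out, (block_in / block_df) / (res / resid_df))
    }
    out
  }
  obs <- stats_for(Y)
  rng <- local_rng(seed)
  on.exit(rng())
  exceed <- numeric(length(obs))
  for (b in seq_len(n_perm)) {
    Yp <- Y[sample.int(n), , drop = FALSE]
    exceed <- exceed + (stats_for(Yp) >= obs - 1e-12)
  }
  p <- (1 + exceed) / (1 + n_perm)
  term <- labels
  df <- model$term_df
  inertia <- model$term_inertia
  if (any(inter) && interaction_block) {
    term <- c(term, "interactions")
    df <- c(df, sum(model$term_df[inter]))
    inertia <- c(inertia, sum(model$term_inertia[inter]))
  }
  data.frame(term = term, df = df, inertia = inertia, F = obs,
             p_value = p, n_perm = n_perm, seed = as.integer(seed),
             stringsAsFactors = FALSE)
}

#' Percent of total inertia explained by the constraints
#'
#' @param model a [cap_fit()] result.
#' @param digits rounding for the `display` element (integer percent, as
#'   in published tables).
#' @return list `proportion`, `percent`, `display`.
#' @export
percent_inertia <- function(model, digits = 0) {
  stopifnot(inherits(model, "cap_model"))
  prop <- model$constrained_inertia / model$total_inertia
  list(proportion = prop, percent = 100 * prop,
       display = round(100 * prop, digits))
}
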