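# Linear inverse operator for source reconstruction of scalp epochs. The
# forward/inverse problem itself (head model, distributed inverse) is
# consumed as input: any sensors-to-sources linear operator with a
# source-to-region membership works. For synthetic cohorts the operator is
# the noise-regularized (ridge) pseudo-inverse of the generator's mixing
# matrix, prewhitened with the sensor noise covariance.

#' Build a linear inverse operator from a mixing (leadfield) matrix
#'
#' The leadfield is prewhitened with the sensor noise covariance,
#' `Lw = C^(-1/2) L`, and inverted with ridge regularization
#' `K = (Lw' Lw + lambda * tr(Lw' Lw)/S * I)^(-1) Lw'`. With an identity
#' covariance the whitening is a no-op.
#'
#' @param mixing Sensors x sources leadfield matrix.
#' @param source_rois Region label of each source column.
#' @param noise_cov Sensor noise covariance (default identity).
#' @param lambda Ridge regularization fraction (default 0.1 of the
#'   trace-normalized Gram diagonal).
#' @return Object of class `inverse_operator` with the source-space kernel,
#'   whitener and region membership.
#' @export
make_inverse_operator <- function(mixing, source_rois,
                                  noise_cov = NULL, lambda = 0.1) {
  L <- as.matrix(mixing)
  stopifnot(length(source_rois) == ncol(L))
  nc <- nrow(L)
  if (is.null(noise_cov)) noise_cov <- diag(nc)
  e <- eigen(noise_cov, symmetric = TRUE)
  ev <- pmax(e$values, max(e$values) * 1e-10)
  whitener <- e$vectors %*% diag(1 / sqrt(ev), nc) %*% t(e$vectors)
  Lw <- whitener %*% L
  G <- crossprod(Lw)
  reg <- lambda * sum(diag(G)) / ncol(L)
  K <- solve(G + reg * diag(ncol(L)), t(Lw))
  structure(list(kernel = K, whitener = whitener,
                 source_rois = source_rois, lambda = lambda),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> %d sensor(s) -> %d source(s) in %d region(s)\n",
              ncol(x$kernel), nrow(x$kernel), length(unique(x$source_rois))))
  invisible(x)
}

#' Estimate a sensor noise covariance from control epochs
#'
#' Diagonal covariance (per-sensor variance) pooled over all control
#' trials, the epochs free of epileptic activity.
#'
#' @param epochs A scalp `epochset` of the control condition.
#' @return Diagonal covariance matrix.
#' @export
noise_covariance <- function(epochs) {
  d <- dim(epochs$trials)
  v <- vapply(seq_len(d[2]), function(c) {
    stats::var(as.numeric(epochs$trials[, c, ]))
  }, numeric(1))
  diag(v, d[2])
}

#' Region time courses from scalp epochs
#'
#' Whitens the sensors, projects every trial through the inverse kernel,
#' and summarizes each region by the first temporal singular vector of its
#' member source time series (all orientations stacked), scaled by the
#' singular value. The SVD sign is fixed so the correlation with the
#' region-mean series is non-negative.
#'
#' @param scalp_epochs A scalp `epochset`.
#' @param inv An [make_inverse_operator()].
#' @return An `epochset` whose "channels" are regions.
#' @export
roi_timecourses <- function(scalp_epochs, inv) {
  stopifnot(inherits(inv, "inverse_operator"))
  d <- dim(scalp_epochs$trials)
  if (ncol(inv$kernel) != d[2]) stop("operator does not match sensor count")
  rois <- unique(inv$source_rois)
  members <- lapply(rois, function(r) which(inv$source_rois == r))
  if (any(lengths(members) == 0L)) stop("region with zero member sources")
  out <- array(0, dim = c(d[1], length(rois), d[3]))
  KW <- inv$kernel %*% inv$whitener
  for (k in seq_len(d[1])) {
    S <- KW %*% scalp_epochs$trials[k, , ]
    for (r in seq_along(rois)) {
      Y <- S[members[[r]], , drop = FALSE]
      if (nrow(Y) == 1L) {
        out[k, r, ] <- Y[1, ]
      } else {
        sv <- svd(Y, nu = 1, nv = 1)
        series <- sv$d[1] * sv$v[, 1]
        mn <- colMeans(Y)
        if (sum(series * mn) < 0) series <- -series
        out[k, r, ] <- series
      }
    }
  }
  new_epochset(out, scalp_epochs$condition, scalp_epochs$window,
               scalp_epochs$fs, scalp_epochs$t0, rois)
}
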