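# Small deterministic fixtures shared across test files.

# A minimal two-patient configuration for structural/pipeline tests.
tiny_cfg <- function(...) {
  args <- utils::modifyList(list(n_patients = 2L,
                                 n_epochs_per_condition = 6L,
                                 duration = 90, seed = 7L),
                            list(...))
  do.call(synth_config, args)
}

# One default-configuration patient, generated once per test run.
default_patient <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_patient(synth_config(), 1)
    cache
  }
})

# Single-channel epoch set built from a trial x sample matrix.
epochs_from_matrix <- function(trials, fs, window = NULL, t0 = 0,
                               condition = "IED", labels = NULL) {
  if (is.matrix(trials)) {
    trials <- array(trials, dim = c(nrow(trials), 1L, ncol(trials)))
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(dim(trials)[2]))
  iednet:::new_epochset(trials, condition, window, fs, t0, labels)
}

# Trials of two channels sharing a band-limited oscillation with a constant
# phase lag, plus unit white noise.
lagged_pair_trials <- function(n_trials, n, fs, f_low, f_high, lag, gain,
                               noise_sd = 1) {
  tr <- array(0, dim = c(n_trials, 2L, n))
  for (k in seq_len(n_trials)) {
    A <- iednet:::band_noise_analytic(n, fs, f_low, f_high)
    tr[k, 1, ] <- gain * Re(A) + noise_sd * stats::rnorm(n)
    tr[k, 2, ] <- gain * Re(A * exp(-1i * lag)) + noise_sd * stats::rnorm(n)
  }
  tr
}

# Exhaustive-path oracle for weighted shortest-path distances on small
# graphs (lengths 1/w), independent of the package's implementation.
brute_distances <- function(W) {
  n <- nrow(W)
  L <- 1 / W
  L[is.na(L)] <- Inf
  diag(L) <- 0
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      inner <- setdiff(seq_len(n), c(i, j))
      best <- L[i, j]
      for (k in 0:length(inner)) {
        combs <- if (k == 0) list(integer(0)) else
          utils::combn(inner, k, simplify = FALSE)
        for (cmb in combs) {
          for (ord in perms(cmb)) {
            path <- c(i, ord, j)
            len <- sum(L[cbind(path[-length(path)], path[-1])])
            if (len < best) best <- len
          }
        }
      }
      D[i, j] <- best
    }
  }
  D
}

# Direct triple-summation oracle for the Onnela clustering coefficient.
brute_onnela <- function(W) {
  A <- W
  A[is.na(A)] <- 0
  diag(A) <- 0
  A <- A / max(A)
  n <- nrow(A)
  C <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(A[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          s <- s + (A[i, j] * A[i, h] * A[j, h])^(1 / 3)
        }
      }
    }
    C[i] <- s / (k * (k - 1))
  }
  C
}
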