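# Photon-by-photon likelihood evaluation.
#
# The likelihood of a trajectory with colors c_i and arrival times t_i is
#   L = 1^T prod_{i=N..2} [ F(c_i) exp(K (t_i - t_{i-1})) ] F(c_1) p0,
# evaluated left-to-right with per-photon renormalization of the state
# vector (the naive product underflows beyond ~1e3 photons). Propagators
# come from one eigendecomposition of K; if the eigenbasis is
# ill-conditioned the evaluation falls back to scaling-and-squaring matrix
# exponentials per gap. Complex eigenvalues of non-reversible generators are
# handled in complex arithmetic and the imaginary residue is checked.

#' Log-likelihood of one photon trajectory segment
#'
#' @param photons Photon table of a single trajectory (columns `time`,
#'   `channel`); an empty table gives `ln L = 0`.
#' @param model A [fret_model()] whose channels cover the photon labels
#'   (merge two-color segments with [combine_channels()] first).
#' @return A `fret_loglik` list: `loglik` (natural log), `n_photons`.
#' @export
segment_loglik <- function(photons, model) {
  photons <- tibble::as_tibble(photons)
  if (nrow(photons) == 0) {
    return(structure(list(loglik = 0, n_photons = 0L), class = "fret_loglik"))
  }
  chan <- match(photons$channel, model$channels)
  if (anyNA(chan)) {
    bad <- setdiff(unique(photons$channel), model$channels)
    stop("channel(s) ", paste(bad, collapse = ", "),
         " not emitted by a ", paste(model$channels, collapse = "/"),
         " model", call. = FALSE)
  }
  res <- cpp_segment_loglik(photons$time, chan - 1L, model$K, model$emission,
                            model$p0)
  structure(list(loglik = res$loglik, n_photons = nrow(photons),
                 spectral = res$spectral),
            class = "fret_loglik")
}

#' @export
print.fret_loglik <- function(x, ...) {
  cat("ln L = ", format(x$loglik, digits = 10), "  (", x$n_photons,
      " photons)\n", sep = "")
  invisible(x)
}

# spectral propagator bundle for R-side evaluation (partial products,
# Viterbi oracle work); mirrors the C++ fallback logic
spectral_propagator <- function(K) {
  e <- eigen(K)
  cnd <- tryCatch(kappa(e$vectors, exact = TRUE), error = function(err) Inf)
  ok <- is.finite(cnd) && cnd < 1e8
  list(values = e$values, vectors = e$vectors,
       inv = if (ok) solve(e$vectors) else NULL, ok = ok, K = K)
}

propagate <- function(sp, dt) {
  if (sp$ok) {
    P <- Re(sp$vectors %*% (exp(sp$values * dt) * sp$inv))
  } else {
    P <- expm_ss(sp$K * dt)
  }
  P[P < 0] <- 0
  P
}

# scaling-and-squaring matrix exponential (Pade-free; Taylor at scaled
# argument with squaring), used only as the degenerate-spectrum fallback
expm_ss <- function(A) {
  n <- nrow(A)
  s <- max(0L, ceiling(log2(max(1e-300, norm(A, "1")))) + 1L)
  As <- A / 2^s
  P <- diag(n)
  term <- diag(n)
  for (k in 1:20) {
    term <- term %*% As / k
    P <- P + term
    if (max(abs(term)) < 1e-18) break
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

#' Chunked evaluation of the segment likelihood
#'
#' Splits the photon sequence into `n_chunks` contiguous chunks, forms each
#' chunk's matrix product of `F(c_i) exp(K dt_i)` factors, and combines the
#' chunk matrices in order. This is the associative-partial-product contract
#' behind parallel evaluation: the result is split-invariant and equals
#' [segment_loglik()] to high accuracy for any split.
#'
#' @inheritParams segment_loglik
#' @param n_chunks Number of contiguous chunks (`>= 1`).
#' @return A `fret_loglik` list.
#' @export
partial_products <- function(photons, model, n_chunks = 1) {
  stopifnot(n_chunks >= 1)
  photons <- tibble::as_tibble(photons)
  N <- nrow(photons)
  if (N == 0) {
    return(structure(list(loglik = 0, n_photons = 0L), class = "fret_loglik"))
  }
  chan <- match(photons$channel, model$channels)
  if (anyNA(chan)) stop("photon channels incompatible with model", call. = FALSE)
  sp <- spectral_propagator(model$K)
  ns <- nrow(model$K)
  Fd <- function(i) model$emission[, chan[i]]
  # factor i (for photons 2..N): F(c_i) %*% P(dt_i)
  idx <- if (N >= 2) 2:N else integer(0)
  splits <- split(idx, ceiling(seq_along(idx) * n_chunks / max(1, length(idx)))) |>
    Filter(f = function(v) length(v) > 0)
  logscale <- 0
  chunks <- lapply(splits, function(iv) {
    # later factors multiply on the left, so accumulate factor_i %*% M
    M <- diag(ns)
    for (i in iv) {
      M <- (Fd(i) * propagate(sp, photons$time[i] - photons$time[i - 1])) %*% M
      s <- max(abs(M))
      if (s > 0 && (s > 1e100 || s < 1e-100)) {
        M <- M / s
        logscale <<- logscale + log(s)
      }
    }
    M
  })
  v <- Fd(1) * model$p0
  for (M in chunks) {
    v <- M %*% v
    sv <- max(abs(v))
    if (sv > 0 && (sv > 1e100 || sv < 1e-100)) {
      v <- v / sv
      logscale <- logscale + log(sv)
    }
  }
  s <- sum(v)
  if (s <= 0 || !is.finite(s)) stop("non-finite chunked likelihood", call. = FALSE)
  structure(list(loglik = log(s) + logscale, n_photons = N),
            class = "fret_loglik")
}
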