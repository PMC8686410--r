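## Linear-chain CRF: path scoring, exact log-partition via the forward
## recursion in log space, maximum-likelihood gradients via forward-backward
## marginals, and Viterbi decoding with a deterministic tie-break.
##
## A path y_1..y_T over K tags is scored
##   start[y_1] + sum_t e[t, y_t] + sum_t transitions[y_{t-1}, y_t] + end[y_T]
## and the model assigns it probability exp(score - logZ).

#' Create linear-chain CRF parameters
#'
#' @param labels Tag labels; defaults to the 7-tag BIO alphabet.
#' @param transitions K x K matrix, entry (i, j) scoring the move from tag i
#'   to tag j. Defaults to zeros.
#' @param start,end Length-K vectors scoring the first and last tag.
#' @return A `crf_params` object.
#' @export
crf_params <- function(labels = bio_tags(),
                       transitions = NULL, start = NULL, end = NULL) {
  K <- length(labels)
  if (is.null(transitions)) transitions <- matrix(0, K, K)
  if (is.null(start)) start <- numeric(K)
  if (is.null(end)) end <- numeric(K)
  stopifnot(identical(dim(transitions), c(K, K)),
            length(start) == K, length(end) == K,
            # -Inf is allowed so hard transition constraints can be expressed
            all(is.finite(transitions) | transitions == -Inf),
            all(is.finite(start) | start == -Inf),
            all(is.finite(end) | end == -Inf))
  structure(list(labels = labels, K = K, transitions = transitions,
                 start = start, end = end),
            class = "crf_params")
}

tag_indices <- function(tags, params) {
  if (is.numeric(tags)) {
    idx <- as.integer(tags)
  } else {
    idx <- match(tags, params$labels)
  }
  if (anyNA(idx) || any(idx < 1L) || any(idx > params$K)) {
    stop("tag sequence contains labels outside the CRF alphabet")
  }
  idx
}

check_emissions <- function(e, params) {
  stopifnot(is.matrix(e), ncol(e) == params$K, nrow(e) >= 1L)
}

#' Score a tag path under the CRF
#'
#' @param e Emission score matrix, T x K.
#' @param params A [crf_params()] object.
#' @param tags Tag path: character labels or integer indices, length T.
#' @return The (unnormalized) path score, a single number.
#' @export
path_score <- function(e, params, tags) {
  check_emissions(e, params)
  y <- tag_indices(tags, params)
  if (length(y) != nrow(e)) {
    stop("tag path length ", length(y), " does not match emissions rows ", nrow(e))
  }
  T_ <- length(y)
  s <- params$start[y[1]] + sum(e[cbind(seq_len(T_), y)]) + params$end[y[T_]]
  if (T_ > 1L) {
    s <- s + sum(params$transitions[cbind(y[-T_], y[-1])])
  }
  s
}

logsumexp <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

## Forward recursion in log space (numerically stable):
## alpha[t, j] = e[t, j] + logsumexp_i(alpha[t-1, i] + transitions[i, j]).
crf_alpha <- function(e, params) {
  T_ <- nrow(e)
  alpha <- matrix(NA_real_, T_, params$K)
  alpha[1, ] <- params$start + e[1, ]
  if (T_ > 1L) {
    for (t in 2:T_) {
      M <- alpha[t - 1, ] + params$transitions  # M[i, j], recycled by column
      alpha[t, ] <- e[t, ] + apply(M, 2, logsumexp)
    }
  }
  alpha
}

## Backward recursion; beta[t, i] sums over continuations after position t
## (beta excludes e[t, ] itself, includes the end scores).
crf_beta <- function(e, params) {
  T_ <- nrow(e)
  beta <- matrix(NA_real_, T_, params$K)
  beta[T_, ] <- params$end
  if (T_ > 1L) {
    for (t in (T_ - 1L):1L) {
      M <- params$transitions + rep(beta[t + 1, ] + e[t + 1, ], each = params$K)
      beta[t, ] <- apply(M, 1, logsumexp)
    }
  }
  beta
}

#' Log-partition function of the CRF
#'
#' `log` of the sum over all K^T tag paths of `exp(path_score)`, computed by
#' the forward recursion in log space.
#'
#' @inheritParams path_score
#' @return A single number, always `>= path_score(e, params, y)` for any `y`.
#' @export
crf_log_partition <- function(e, params) {
  check_emissions(e, params)
  alpha <- crf_alpha(e, params)
  logsumexp(alpha[nrow(e), ] + params$end)
}

#' Negative log-likelihood of a gold tag path
#'
#' `crf_log_partition(e, params) - path_score(e, params, gold)`; non-negative.
#'
#' @inheritParams path_score
#' @param gold The gold tag path.
#' @return A single non-negative number.
#' @export
crf_nll <- function(e, params, gold) {
  crf_log_partition(e, params) - path_score(e, params, gold)
}

#' Gradients of the CRF negative log-likelihood
#'
#' Computed by forward-backward: the gradient with respect to each score is
#' the model expectation of its feature count minus the gold count.
#'
#' @inheritParams crf_nll
#' @return List with `emissions` (T x K), `transitions` (K x K), `start`,
#'   `end` (length K), and the scalar `nll`.
#' @export
crf_grad <- function(e, params, gold) {
  check_emissions(e, params)
  y <- tag_indices(gold, params)
  T_ <- nrow(e); K <- params$K
  stopifnot(length(y) == T_)
  alpha <- crf_alpha(e, params)
  beta <- crf_beta(e, params)
  logZ <- logsumexp(alpha[T_, ] + params$end)
  # unary marginals P(y_t = k)
  mu <- exp(alpha + beta - logZ)
  d_e <- mu
  d_e[cbind(seq_len(T_), y)] <- d_e[cbind(seq_len(T_), y)] - 1
  d_start <- mu[1, ]
  d_start[y[1]] <- d_start[y[1]] - 1
  d_end <- mu[T_, ]
  d_end[y[T_]] <- d_end[y[T_]] - 1
  d_trans <- matrix(0, K, K)
  if (T_ > 1L) {
    for (t in 1:(T_ - 1L)) {
      # pairwise marginals P(y_t = i, y_{t+1} = j)
      lp <- outer(alpha[t, ], beta[t + 1, ] + e[t + 1, ], "+") +
        params$transitions - logZ
      d_trans <- d_trans + exp(lp)
    }
    for (t in 1:(T_ - 1L)) {
      d_trans[y[t], y[t + 1]] <- d_trans[y[t], y[t + 1]] - 1
    }
  }
  nll <- logZ - path_score(e, params, y)
  list(emissions = d_e, transitions = d_trans, start = d_start, end = d_end,
       nll = nll)
}

#' Viterbi decoding
#'
#' Returns a maximum-score tag path. Ties are broken deterministically toward
#' the lowest tag index at every backtrace step (so with the default alphabet,
#' toward `O`).
#'
#' @inheritParams path_score
#' @return Character vector of tag labels of length `nrow(e)`.
#' @export
crf_viterbi <- function(e, params) {
  check_emissions(e, params)
  T_ <- nrow(e); K <- params$K
  delta <- params$start + e[1, ]
  back <- matrix(NA_integer_, T_, K)
  if (T_ > 1L) {
    for (t in 2:T_) {
      cand <- delta + params$transitions  # K x K: cand[i, j] = delta[i] + trans[i, j]
      best <- apply(cand, 2, which.max)  # which.max takes the first (lowest index) on ties
      back[t, ] <- best
      delta <- cand[cbind(best, seq_len(K))] + e[t, ]
    }
  }
  final <- delta + params$end
  y <- integer(T_)
  y[T_] <- which.max(final)
  if (T_ > 1L) {
    for (t in T_:2) y[t - 1L] <- back[t, y[t]]
  }
  params$labels[y]
}
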