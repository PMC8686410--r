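## LSTM encoder with hand-derived backpropagation through time.
##
## A single cell keeps gates stacked in one 4H x (D+H) parameterisation:
## rows 1..H input gate i, H+1..2H forget gate f, 2H+1..3H candidate g,
## 3H+1..4H output gate o. The bidirectional encoder runs one cell left to
## right and an independent cell over the reversed sequence, concatenating
## the hidden states position-wise (2H per position).

sigmoid <- function(x) 1 / (1 + exp(-x))

## Parameter container for one direction. Initialization is uniform on
## [-1/sqrt(H), 1/sqrt(H)] (the classic LSTM heuristic) with the forget-gate
## bias raised to 1 so early training does not erase state.
lstm_init <- function(input_dim, hidden) {
  r <- 1 / sqrt(hidden)
  H4 <- 4L * hidden
  b <- numeric(H4)
  b[(hidden + 1L):(2L * hidden)] <- 1
  list(W = matrix(stats::runif(H4 * input_dim, -r, r), H4, input_dim),
       U = matrix(stats::runif(H4 * hidden, -r, r), H4, hidden),
       b = b, hidden = hidden)
}

## Forward pass over X (input_dim x T). Returns hidden states H (hidden x T)
## plus the activation cache needed for the backward pass.
lstm_forward <- function(p, X) {
  H <- p$hidden; T_ <- ncol(X)
  Zx <- p$W %*% X + p$b
  I <- F_ <- G <- O <- C <- TC <- Hs <- matrix(0, H, T_)
  h <- numeric(H); c <- numeric(H)
  ii <- 1:H; fi <- (H + 1L):(2L * H); gi <- (2L * H + 1L):(3L * H); oi <- (3L * H + 1L):(4L * H)
  for (t in seq_len(T_)) {
    z <- Zx[, t] + p$U %*% h
    i <- sigmoid(z[ii]); f <- sigmoid(z[fi]); g <- tanh(z[gi]); o <- sigmoid(z[oi])
    c <- f * c + i * g
    tc <- tanh(c)
    h <- o * tc
    I[, t] <- i; F_[, t] <- f; G[, t] <- g; O[, t] <- o
    C[, t] <- c; TC[, t] <- tc; Hs[, t] <- h
  }
  list(H = Hs, cache = list(X = X, I = I, F = F_, G = G, O = O, C = C, TC = TC))
}

## Backward pass: dH_out is the loss gradient at each hidden state
## (hidden x T). Returns parameter gradients and the input gradient dX.
lstm_backward <- function(p, fwd, dH_out) {
  H <- p$hidden; ca <- fwd$cache; Hs <- fwd$H
  T_ <- ncol(dH_out)
  dZ <- matrix(0, 4L * H, T_)
  dh_next <- numeric(H); dc_next <- numeric(H)
  for (t in T_:1L) {
    dh <- dH_out[, t] + dh_next
    i <- ca$I[, t]; f <- ca$F[, t]; g <- ca$G[, t]; o <- ca$O[, t]; tc <- ca$TC[, t]
    c_prev <- if (t > 1L) ca$C[, t - 1L] else numeric(H)
    do_ <- dh * tc
    dc <- dc_next + dh * o * (1 - tc^2)
    di <- dc * g; dg <- dc * i; df <- dc * c_prev
    dc_next <- dc * f
    dz <- c(di * i * (1 - i), df * f * (1 - f), dg * (1 - g^2), do_ * o * (1 - o))
    dZ[, t] <- dz
    dh_next <- as.vector(crossprod(p$U, dz))
  }
  dU <- if (T_ > 1L) dZ[, 2:T_, drop = FALSE] %*% t(Hs[, 1:(T_ - 1L), drop = FALSE])
        else matrix(0, 4L * H, H)
  list(W = dZ %*% t(ca$X), U = dU, b = rowSums(dZ),
       X = crossprod(p$W, dZ))
}

## Bidirectional encoding: rows 1..H are the forward states, H+1..2H the
## backward states (computed over the reversed sequence and re-reversed).
bilstm_forward <- function(pf, pb, X) {
  T_ <- ncol(X)
  fwd <- lstm_forward(pf, X)
  bwd <- lstm_forward(pb, X[, T_:1L, drop = FALSE])
  list(H = rbind(fwd$H, bwd$H[, T_:1L, drop = FALSE]), fwd = fwd, bwd = bwd)
}

bilstm_backward <- function(pf, pb, enc, dH) {
  H <- pf$hidden; T_ <- ncol(dH)
  gf <- lstm_backward(pf, enc$fwd, dH[1:H, , drop = FALSE])
  gb <- lstm_backward(pb, enc$bwd,
                      dH[(H + 1L):(2L * H), T_:1L, drop = FALSE])
  list(fwd = gf, bwd = gb,
       X = gf$X + gb$X[, T_:1L, drop = FALSE])
}
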