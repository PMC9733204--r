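# Gated recurrent unit used by the decoder.
#
#   r = sigmoid(Wr x + Ur h + br)          reset gate
#   u = sigmoid(Wu x + Uu h + bu)          update gate
#   n = tanh(Wn x + Un (r * h) + bn)       candidate state
#   h' = (1 - u) * n + u * h

gru_params <- function(m, input_dim, init_scale = 0.1) {
  ru <- function(nr, nc) matrix(stats::runif(nr * nc, -init_scale, init_scale), nr, nc)
  list(Wr = ru(m, input_dim), Ur = ru(m, m), br = numeric(m),
       Wu = ru(m, input_dim), Uu = ru(m, m), bu = numeric(m),
       Wn = ru(m, input_dim), Un = ru(m, m), bn = numeric(m),
       m = m, input_dim = input_dim)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

gru_forward <- function(x, h_prev, params) {
  r <- as.numeric(.sigmoid(params$Wr %*% x + params$Ur %*% h_prev + params$br))
  u <- as.numeric(.sigmoid(params$Wu %*% x + params$Uu %*% h_prev + params$bu))
  rh <- r * h_prev
  n <- as.numeric(tanh(params$Wn %*% x + params$Un %*% rh + params$bn))
  h <- (1 - u) * n + u * h_prev
  list(h = h, x = x, h_prev = h_prev, r = r, u = u, n = n, rh = rh)
}

.zero_like_gru <- function(params) {
  list(Wr = params$Wr * 0, Ur = params$Ur * 0, br = params$br * 0,
       Wu = params$Wu * 0, Uu = params$Uu * 0, bu = params$bu * 0,
       Wn = params$Wn * 0, Un = params$Un * 0, bn = params$bn * 0)
}

gru_backward <- function(cache, dh, params, acc) {
  dh <- as.numeric(dh)
  u <- cache$u; n <- cache$n; r <- cache$r; h_prev <- cache$h_prev
  du <- dh * (h_prev - n)
  dn <- dh * (1 - u)
  dh_prev <- dh * u
  dzn <- dn * (1 - n^2)
  acc$Wn <- acc$Wn + outer(dzn, as.numeric(cache$x))
  acc$Un <- acc$Un + outer(dzn, cache$rh)
  acc$bn <- acc$bn + dzn
  drh <- as.numeric(crossprod(params$Un, dzn))
  dr <- drh * h_prev
  dh_prev <- dh_prev + drh * r
  dzu <- du * u * (1 - u)
  acc$Wu <- acc$Wu + outer(dzu, as.numeric(cache$x))
  acc$Uu <- acc$Uu + outer(dzu, h_prev)
  acc$bu <- acc$bu + dzu
  dh_prev <- dh_prev + as.numeric(crossprod(params$Uu, dzu))
  dzr <- dr * r * (1 - r)
  acc$Wr <- acc$Wr + outer(dzr, as.numeric(cache$x))
  acc$Ur <- acc$Ur + outer(dzr, h_prev)
  acc$br <- acc$br + dzr
  dh_prev <- dh_prev + as.numeric(crossprod(params$Ur, dzr))
  dx <- as.numeric(crossprod(params$Wr, dzr)) +
    as.numeric(crossprod(params$Wu, dzu)) +
    as.numeric(crossprod(params$Wn, dzn))
  list(acc = acc, dx = dx, dh_prev = dh_prev)
}
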