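# Stack-augmented recurrent cell.
#
# One step of the cell, given input x_t, previous hidden h_{t-1} and previous
# stack s_{t-1} (a depth p x width k matrix, top element in row 1):
#
#   h_t = sigmoid(U x_t + R h_{t-1} + P s_{t-1}[1,])
#   a_t = softmax(A h_t)                    (PUSH, POP, NO-OP probabilities)
#   v_t = sigmoid(D h_t)                    (value pushed, a width-k vector)
#   s_t[1,] = a[PUSH] v_t + a[POP] s_{t-1}[2,] + a[NOOP] s_{t-1}[1,]
#   s_t[i,] = a[PUSH] s_{t-1}[i-1,] + a[POP] s_{t-1}[i+1,] + a[NOOP] s_{t-1}[i,]
#
# The stack has fixed depth: a PUSH discards the bottom element, a POP pulls
# a zero row in at the bottom.

PUSH <- 1L; POP <- 2L; NOOP <- 3L

#' Create parameters for a stack-augmented recurrent cell
#'
#' @param m Hidden size.
#' @param k Stack width (length of one stack element).
#' @param input_dim Length of the input vector at each step.
#' @param init_scale Half-width of the uniform initialization interval.
#' @return List of class `stack_cell_params` with matrices `A` (3 x m),
#'   `D` (k x m), `U` (m x input_dim), `R` (m x m), `P` (m x k) and the
#'   dimensions `m`, `k`, `input_dim`.
#' @export
stack_cell_params <- function(m, k, input_dim, init_scale = 0.1) {
  ru <- function(nr, nc) matrix(stats::runif(nr * nc, -init_scale, init_scale), nr, nc)
  structure(list(A = ru(3L, m), D = ru(k, m), U = ru(m, input_dim),
                 R = ru(m, m), P = ru(m, k), m = m, k = k, input_dim = input_dim),
            class = "stack_cell_params")
}

#' Stack-operation probabilities from a hidden state
#'
#' Softmax over `A %*% h`: the (PUSH, POP, NO-OP) probability triple that
#' soft-controls the differentiable stack.
#'
#' @param h Hidden state vector (length m).
#' @param params `stack_cell_params`.
#' @return Numeric 3-vector summing to 1, names `push`, `pop`, `noop`.
#' @export
action_distribution <- function(h, params) {
  if (length(h) != params$m) stop("hidden state has length ", length(h),
                                  " but cell expects m = ", params$m)
  z <- as.numeric(params$A %*% h)
  z <- z - max(z)
  e <- exp(z)
  stats::setNames(e / sum(e), c("push", "pop", "noop"))
}

#' Soft stack update
#'
#' Blends the three discrete stack operations with the probabilities in
#' `action`: row 1 (the top) becomes
#' `a[push]*push_value + a[pop]*prev[2,] + a[noop]*prev[1,]`, and every
#' deeper row mixes its shifted neighbours the same way. The depth is fixed:
#' pushing discards the bottom row and popping pulls a zero row in.
#'
#' @param prev Stack matrix, depth p x width k (top at row 1).
#' @param action Probability 3-vector (push, pop, noop).
#' @param push_value Width-k vector of values in `[0, 1]`.
#' @return The updated p x k stack matrix.
#' @export
update_stack <- function(prev, action, push_value) {
  action <- as.numeric(action)
  if (length(action) != 3L || any(action < 0) || abs(sum(action) - 1) > 1e-6)
    stop("action must be a probability 3-vector")
  p <- nrow(prev)
  down <- rbind(matrix(push_value, nrow = 1L), prev[-p, , drop = FALSE])
  up <- rbind(prev[-1L, , drop = FALSE], matrix(0, 1L, ncol(prev)))
  action[PUSH] * down + action[POP] * up + action[NOOP] * prev
}

#' Hidden-state update of the stack cell
#'
#' `sigmoid(U x + R h_prev + P s_top)` where `s_top` is the top row of the
#' previous stack.
#'
#' @param x Input vector.
#' @param h_prev Previous hidden state.
#' @param stack_prev Previous stack matrix (or NULL for a stack-less cell,
#'   in which case the stack-read term is dropped).
#' @param params `stack_cell_params`.
#' @return New hidden state vector (entries in (0, 1)).
#' @export
update_hidden <- function(x, h_prev, stack_prev, params) {
  if (length(x) != params$input_dim) stop("input has length ", length(x),
                                          " but cell expects ", params$input_dim)
  z <- params$U %*% x + params$R %*% h_prev
  if (!is.null(stack_prev)) z <- z + params$P %*% stack_prev[1L, ]
  as.numeric(1 / (1 + exp(-z)))
}

#' One full step of the stack-augmented cell
#'
#' The hidden state is updated first, reading the top of the *previous*
#' stack; the stack is then updated using action and push-value computed
#' from the *new* hidden state.
#'
#' @inheritParams update_hidden
#' @return List with `h` (new hidden), `stack` (new stack), `action`
#'   (probability triple), and `push_value`.
#' @export
cell_step <- function(x, h_prev, stack_prev, params) {
  h <- update_hidden(x, h_prev, stack_prev, params)
  if (is.null(stack_prev)) {
    return(list(h = h, stack = NULL, action = NULL, push_value = NULL))
  }
  a <- action_distribution(h, params)
  v <- as.numeric(1 / (1 + exp(-(params$D %*% h))))
  s <- update_stack(stack_prev, a, v)
  list(h = h, stack = s, action = a, push_value = v)
}

#' Discrete pushdown-automaton oracle
#'
#' Literal hard-stack semantics used to verify the continuous cell: PUSH
#' shifts every element one row down (discarding the bottom) and writes the
#' value on top; POP shifts everything one row up and zero-fills the bottom;
#' NO-OP leaves the stack unchanged.
#'
#' @param initial Stack matrix (depth p x width k).
#' @param trace List of steps; each step is a list with `op` (one of
#'   `"push"`, `"pop"`, `"noop"`) and, for pushes, `value` (width-k vector).
#' @return The final stack matrix.
#' @export
pushdown_oracle <- function(initial, trace) {
  s <- initial
  p <- nrow(s)
  for (step in trace) {
    op <- step$op
    if (op == "push") {
      s <- rbind(matrix(step$value, nrow = 1L), s[-p, , drop = FALSE])
    } else if (op == "pop") {
      s <- rbind(s[-1L, , drop = FALSE], matrix(0, 1L, ncol(s)))
    } else if (op != "noop") {
      stop("unknown stack operation: ", op)
    }
  }
  s
}

# ---- backward pass -------------------------------------------------------

# Forward step retaining everything the backward pass needs.
.cell_forward <- function(x, h_prev, stack_prev, params) {
  pre <- params$U %*% x + params$R %*% h_prev
  if (!is.null(stack_prev)) pre <- pre + params$P %*% stack_prev[1L, ]
  h <- as.numeric(1 / (1 + exp(-pre)))
  if (is.null(stack_prev)) {
    return(list(h = h, stack = NULL, x = x, h_prev = h_prev, stack_prev = NULL))
  }
  az <- as.numeric(params$A %*% h)
  az <- az - max(az)
  ea <- exp(az)
  a <- ea / sum(ea)
  v <- as.numeric(1 / (1 + exp(-(params$D %*% h))))
  s <- update_stack(stack_prev, a, v)
  list(h = h, stack = s, x = x, h_prev = h_prev, stack_prev = stack_prev,
       a = a, v = v)
}

.zero_like_cell <- function(params) {
  list(A = params$A * 0, D = params$D * 0, U = params$U * 0,
       R = params$R * 0, P = params$P * 0)
}

# Backward through one cell step. cache is the list from .cell_forward;
# dh/dstack are the gradients of the loss w.r.t. this step's outputs.
# Returns gradients w.r.t. parameters (accumulated into `acc`), the input,
# and the previous hidden/stack states.
.cell_backward <- function(cache, dh, dstack, params, acc) {
  h <- cache$h
  dh <- as.numeric(dh)
  dstack_prev <- NULL
  if (!is.null(cache$stack_prev)) {
    sp <- cache$stack_prev
    p <- nrow(sp)
    a <- cache$a
    v <- cache$v
    if (is.null(dstack)) dstack <- sp * 0
    down <- rbind(matrix(v, nrow = 1L), sp[-p, , drop = FALSE])
    up <- rbind(sp[-1L, , drop = FALSE], matrix(0, 1L, ncol(sp)))
    da <- c(sum(dstack * down), sum(dstack * up), sum(dstack * sp))
    dv <- a[PUSH] * dstack[1L, ]
    # d stack_prev: row j feeds rows j+1 (push), j-1 (pop), j (noop)
    dsp <- a[NOOP] * dstack
    dsp[-p, ] <- dsp[-p, , drop = FALSE] + a[PUSH] * dstack[-1L, , drop = FALSE]
    dsp[-1L, ] <- dsp[-1L, , drop = FALSE] + a[POP] * dstack[-p, , drop = FALSE]
    # softmax backward
    dza <- a * (da - sum(da * a))
    acc$A <- acc$A + outer(dza, h)
    dh <- dh + as.numeric(crossprod(params$A, dza))
    # push-value sigmoid backward
    dzv <- dv * v * (1 - v)
    acc$D <- acc$D + outer(dzv, h)
    dh <- dh + as.numeric(crossprod(params$D, dzv))
    dstack_prev <- dsp
  }
  dpre <- dh * h * (1 - h)
  acc$U <- acc$U + outer(dpre, as.numeric(cache$x))
  acc$R <- acc$R + outer(dpre, as.numeric(cache$h_prev))
  dx <- as.numeric(crossprod(params$U, dpre))
  dh_prev <- as.numeric(crossprod(params$R, dpre))
  if (!is.null(cache$stack_prev)) {
    acc$P <- acc$P + outer(dpre, cache$stack_prev[1L, ])
    dstack_prev[1L, ] <- dstack_prev[1L, ] + as.numeric(crossprod(params$P, dpre))
  }
  list(acc = acc, dx = dx, dh_prev = dh_prev, dstack_prev = dstack_prev)
}
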