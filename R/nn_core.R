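# Minimal neural-network machinery: parameter containers, initializers,
# activations, optimizers, and a recursive tree-map over parameter lists.
# All layers in this package are written as explicit forward/backward pairs
# over base-R matrices; analytic gradients are verified against finite
# differences in the test suite.

.nn_sigmoid <- function(x) 1 / (1 + exp(-x))

.nn_init <- function(nr, nc, scale = NULL) {
  # uniform Glorot-style init; consumes the caller's RNG stream
  if (is.null(scale)) scale <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

.nn_zeros <- function(nr, nc = NULL) {
  if (is.null(nc)) numeric(nr) else matrix(0, nr, nc)
}

# apply f(param, companion) elementwise over two parallel nested lists
.tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(.tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

.tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, .tree_map, f = f)
    names(out) <- names(a)
    out
  } else {
    f(a)
  }
}

.tree_sum <- function(a, f = length) {
  if (is.list(a)) sum(vapply(a, .tree_sum, numeric(1), f = f)) else f(a)
}

#' Count trainable parameters in a parameter tree
#'
#' Sums the sizes of every numeric leaf of a (possibly nested) parameter
#' list. Shared parameter groups must appear once in the tree.
#'
#' @param params A nested list of numeric vectors/matrices/arrays, or a
#'   model object with a \code{$params} element.
#' @return Integer parameter count.
#' @export
count_parameters <- function(params) {
  if (is.list(params) && !is.null(params$params)) params <- params$params
  as.integer(.tree_sum(params, length))
}

# ---- optimizers -----------------------------------------------------------

.opt_init <- function(params, method = c("adam", "adagrad")) {
  method <- match.arg(method)
  st <- list(method = method, t = 0L)
  if (method == "adam") {
    st$m <- .tree_map(params, function(p) p * 0)
    st$v <- .tree_map(params, function(p) p * 0)
  } else {
    # initial accumulator 0.1 (the reference Adagrad default) keeps the
    # first updates proportional to the gradient instead of +/- lr
    st$g2 <- .tree_map(params, function(p) p * 0 + 0.1)
  }
  st
}

.opt_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  if (state$method == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state$m <- .tree_map2(state$m, grads, function(m, g) b1 * m + (1 - b1) * g)
    state$v <- .tree_map2(state$v, grads, function(v, g) b2 * v + (1 - b2) * g^2)
    corr <- lr * sqrt(1 - b2^state$t) / (1 - b1^state$t)
    upd <- .tree_map2(state$m, state$v,
                      function(m, v) corr * m / (sqrt(v) + eps))
    params <- .tree_map2(params, upd, function(p, u) p - u)
  } else {
    state$g2 <- .tree_map2(state$g2, grads, function(s, g) s + g^2)
    scale <- .tree_map2(grads, state$g2,
                        function(g, s) lr * g / sqrt(s))
    params <- .tree_map2(params, scale, function(p, u) p - u)
  }
  list(params = params, state = state)
}

# accumulate two gradient trees
.grad_add <- function(a, b) .tree_map2(a, b, `+`)

# inverted-dropout mask; NULL means identity (inference)
.dropout_mask <- function(dim1, dim2, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(dim1 * dim2, 1L, 1 - rate) / (1 - rate), dim1, dim2)
}
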