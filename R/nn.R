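# Internal conv-net plumbing shared by the U-Net variants, the backbone and
# the multi-scale head. Feature maps travel as (H*W) x C matrices (pixel
# (i, j), zero-based, in row i + j*H); conv weights as (k*k*Cin) x Cout.

nn_init_conv <- function(k, cin, cout) {
  # He-scaled Gaussian init; draws from the session RNG so callers control seeds
  list(W = matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                  k * k * cin, cout),
       b = numeric(cout), k = k, cin = cin, cout = cout, type = "conv")
}

nn_init_tconv <- function(cin, cout) {
  list(W = matrix(rnorm(cin * 4 * cout, sd = sqrt(2 / (4 * cin))),
                  cin, 4 * cout),
       b = numeric(cout), cin = cin, cout = cout, type = "tconv")
}

nn_relu <- function(x) (x > 0) * x
nn_relu_bw <- function(x, g) (x > 0) * g
nn_leaky <- function(x, slope) ifelse(x > 0, x, slope * x)
nn_leaky_bw <- function(x, g, slope) ifelse(x > 0, g, slope * g)
nn_sigmoid <- function(x) 1 / (1 + exp(-x))

nn_softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Adam over an arbitrarily nested list of parameter arrays (leaves named W / b)
adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else array(0, dim = dim(p) %||% length(p))
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (nm in keys) {
        if (is.null(g[[nm]])) next
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# accumulate g2 into g1 (same nesting); used for batch-averaged gradients
grad_add <- function(g1, g2, w = 1) {
  if (is.null(g1)) return(rapply(g2, function(x) w * x, how = "replace"))
  f <- function(a, b) {
    if (is.list(a)) Map(f, a, b) else a + w * b
  }
  f(g1, g2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic local RNG scope
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Seed every random source used by the package
#'
#' All randomness in gmstage (weight initialisation, shuffling, augmentation,
#' dropout, phantom sampling) flows through R's base RNG, so a single call
#' makes any subsequent computation reproducible. Seeding is idempotent.
#'
#' @param seed Non-negative integer seed.
#' @return Invisibly, the seed.
#' @export
set_global_seeds <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  set.seed(as.integer(seed))
  invisible(as.integer(seed))
}
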