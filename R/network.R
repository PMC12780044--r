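#' Committor network specification
#'
#' Describes a feed-forward committor network: a sequence of linear
#' compressions (each followed by ELU and, during training, dropout),
#' each optionally followed by a residual block (`resnet_depth` sublayers
#' `a <- a + elu(V a + c)`), and a final purely linear unit producing the
#' scalar logit `q`. The committor is `phi = sigmoid(q)`; using a single
#' logit is mathematically identical to a two-output softmax.
#'
#' The published architectures for the lipid flip-flop and pore-nucleation
#' problems (`68 -> 46 -> 31 -> 21 -> 14 -> 10 -> 1` and
#' `147 -> 85 -> 50 -> 29 -> 14 -> 17 -> 1`, residual depth 4) build with
#' `network_spec(c(68, 46, 31, 21, 14, 10, 1), resnet_depth = 4)` etc.
#'
#' @param widths layer widths from input to the final scalar unit; the
#'   last width must be 1.
#' @param resnet_depth number of residual sublayers after each
#'   compression (0 = plain multilayer perceptron).
#' @param dropout dropout probability on compression activations during
#'   training.
#' @param l2 L2 penalty coefficient on weights.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(widths, resnet_depth = 0L, dropout = 0.1,
                         l2 = 1e-4) {
  widths <- as.integer(widths)
  if (length(widths) < 2) stop("need at least input and output widths.", call. = FALSE)
  if (widths[length(widths)] != 1L) {
    stop("the final width must be 1 (scalar logit).", call. = FALSE)
  }
  if (any(widths <= 0)) stop("widths must be positive.", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("invalid dropout probability.", call. = FALSE)
  structure(list(widths = widths, resnet_depth = as.integer(resnet_depth),
                 dropout = dropout, l2 = l2),
            class = "network_spec")
}

#' Build a committor network
#'
#' Instantiates the network of a [network_spec()] with deterministic
#' He-style initialization under the given seed. Feature standardization
#' parameters default to identity and are set during training.
#'
#' @param spec a `network_spec` (or a widths vector).
#' @param seed integer seed for weight initialization.
#' @param feature_names optional character manifest of input features.
#' @return A `committor_mlp` model.
#' @examples
#' m <- build_network(network_spec(c(2, 4, 1)), seed = 1)
#' n_parameters(m)
#' @export
build_network <- function(spec, seed = 1, feature_names = NULL) {
  if (!inherits(spec, "network_spec")) spec <- network_spec(spec)
  set.seed(seed)
  w <- spec$widths
  n_stage <- length(w) - 1L
  stages <- vector("list", n_stage)
  for (i in seq_len(n_stage)) {
    fan_in <- w[i]
    W <- matrix(rnorm(w[i + 1] * w[i], sd = sqrt(2 / fan_in)), w[i + 1], w[i])
    b <- numeric(w[i + 1])
    res <- list()
    if (i < n_stage && spec$resnet_depth > 0) {
      res <- lapply(seq_len(spec$resnet_depth), function(r) {
        list(V = matrix(rnorm(w[i + 1]^2, sd = sqrt(1 / w[i + 1])) * 0.1,
                        w[i + 1], w[i + 1]),
             c = numeric(w[i + 1]))
      })
    }
    stages[[i]] <- list(W = W, b = b, res = res)
  }
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(w[1]))
  structure(list(spec = spec, stages = stages,
                 x_center = numeric(w[1]), x_scale = rep(1, w[1]),
                 feature_names = feature_names),
            class = c("committor_mlp", "committor_model"))
}

elu <- function(z) ifelse(z > 0, z, expm1(z))
elu_prime <- function(z) ifelse(z > 0, 1, exp(z))

# Forward pass. X is N x d raw features; dropout masks (list per stage,
# already scaled by 1/(1-p)) are used only during training.
mlp_forward <- function(net, X, masks = NULL) {
  n_stage <- length(net$stages)
  H <- sweep(sweep(X, 2, net$x_center), 2, net$x_scale, "/")
  cache <- list(H_in = vector("list", n_stage), Z = vector("list", n_stage),
                S = vector("list", n_stage), Ares = vector("list", n_stage),
                masks = masks)
  for (i in seq_len(n_stage - 1L)) {
    st <- net$stages[[i]]
    cache$H_in[[i]] <- H
    Z <- H %*% t(st$W) + rep(st$b, each = nrow(H))
    cache$Z[[i]] <- Z
    A <- elu(Z)
    if (!is.null(masks)) A <- A * masks[[i]]
    if (length(st$res) > 0) {
      Ss <- vector("list", length(st$res))
      As <- vector("list", length(st$res))
      for (r in seq_along(st$res)) {
        As[[r]] <- A
        S <- A %*% t(st$res[[r]]$V) + rep(st$res[[r]]$c, each = nrow(A))
        Ss[[r]] <- S
        A <- A + elu(S)
      }
      cache$S[[i]] <- Ss
      cache$Ares[[i]] <- As
    }
    H <- A
  }
  st <- net$stages[[n_stage]]
  cache$H_in[[n_stage]] <- H
  q <- as.numeric(H %*% t(st$W) + st$b)
  list(q = q, cache = cache)
}

# Backward pass: given dL/dq (length N), return parameter gradients (same
# nesting as net$stages) and dL/dX (raw feature scale).
mlp_backward <- function(net, cache, dq) {
  n_stage <- length(net$stages)
  grads <- vector("list", n_stage)
  st <- net$stages[[n_stage]]
  H <- cache$H_in[[n_stage]]
  grads[[n_stage]] <- list(W = matrix(colSums(H * dq), 1L),
                           b = sum(dq), res = list())
  D <- matrix(dq, ncol = 1) %*% st$W  # N x w_last
  for (i in rev(seq_len(n_stage - 1L))) {
    st <- net$stages[[i]]
    gres <- list()
    if (length(st$res) > 0) {
      gres <- vector("list", length(st$res))
      for (r in rev(seq_along(st$res))) {
        S <- cache$S[[i]][[r]]
        A_in <- cache$Ares[[i]][[r]]
        dS <- D * elu_prime(S)
        gres[[r]] <- list(V = t(dS) %*% A_in, c = colSums(dS))
        D <- D + dS %*% st$res[[r]]$V
      }
    }
    if (!is.null(cache$masks)) D <- D * cache$masks[[i]]
    dZ <- D * elu_prime(cache$Z[[i]])
    grads[[i]] <- list(W = t(dZ) %*% cache$H_in[[i]], b = colSums(dZ),
                       res = gres)
    D <- dZ %*% st$W
  }
  dX <- sweep(D, 2, net$x_scale, "/")
  list(grads = grads, dX = dX)
}

flatten_params <- function(stages) {
  unlist(lapply(stages, function(st) {
    c(as.numeric(st$W), st$b,
      unlist(lapply(st$res, function(rr) c(as.numeric(rr$V), rr$c))))
  }))
}

unflatten_params <- function(stages, theta) {
  pos <- 1L
  take <- function(n) {
    v <- theta[pos:(pos + n - 1L)]
    pos <<- pos + n
    v
  }
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    stages[[i]]$W <- matrix(take(length(st$W)), nrow(st$W), ncol(st$W))
    stages[[i]]$b <- take(length(st$b))
    for (r in seq_along(st$res)) {
      stages[[i]]$res[[r]]$V <-
        matrix(take(length(st$res[[r]]$V)), nrow(st$res[[r]]$V))
      stages[[i]]$res[[r]]$c <- take(length(st$res[[r]]$c))
    }
  }
  stages
}

# mask vector marking weight (not bias) entries in the flat parameter
# vector, for the L2 penalty
weight_mask <- function(stages) {
  unlist(lapply(stages, function(st) {
    c(rep(1, length(st$W)), rep(0, length(st$b)),
      unlist(lapply(st$res, function(rr)
        c(rep(1, length(rr$V)), rep(0, length(rr$c))))))
  }))
}

#' Number of trainable parameters
#' @param model a `committor_mlp`.
#' @export
n_parameters <- function(model) {
  length(flatten_params(model$stages))
}
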