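#' Committor model interface
#'
#' All committor models expose `predict_phi()` (probability in (0,1)),
#' `committor_logit()` (the raw logit `q = ln[phi / (1 - phi)]`) and,
#' where meaningful, `committor_gradient()` (the input gradient
#' `d phi / d x`). Implementations: the trainable network
#' (`committor_mlp`), a per-site lookup table for discrete chains
#' (`committor_table`), and an arbitrary function wrapper
#' (`committor_fn`).
#'
#' @param model a committor model.
#' @param x matrix of feature rows (or a vector for a single frame).
#' @return `predict_phi()` and `committor_logit()` return a numeric
#'   vector with one entry per row of `x`.
#' @name committor-interface
NULL

as_feature_matrix <- function(x, d = NULL) {
  if (is.null(dim(x))) {
    if (!is.null(d) && d > 1 && length(x) == d) matrix(x, nrow = 1)
    else matrix(x, ncol = if (is.null(d)) 1 else d)
  } else as.matrix(x)
}

#' @rdname committor-interface
#' @export
predict_phi <- function(model, x) UseMethod("predict_phi")

#' @rdname committor-interface
#' @export
committor_logit <- function(model, x) UseMethod("committor_logit")

#' @rdname committor-interface
#' @export
committor_gradient <- function(model, x) UseMethod("committor_gradient")

#' @export
committor_logit.committor_mlp <- function(model, x) {
  X <- as_feature_matrix(x, model$spec$widths[1])
  mlp_forward(model, X)$q
}

#' @export
predict_phi.committor_mlp <- function(model, x) {
  stats::plogis(committor_logit(model, x))
}

#' @export
committor_gradient.committor_mlp <- function(model, x) {
  X <- as_feature_matrix(x, model$spec$widths[1])
  fw <- mlp_forward(model, X)
  phi <- stats::plogis(fw$q)
  dq_dx <- mlp_backward(model, fw$cache, rep(1, length(fw$q)))$dX
  dq_dx * (phi * (1 - phi))
}

#' Committor lookup table for discrete chains
#'
#' @param phi_by_site committor value per site.
#' @export
committor_table <- function(phi_by_site) {
  structure(list(phi = as.numeric(phi_by_site)),
            class = c("committor_table", "committor_model"))
}

#' @export
predict_phi.committor_table <- function(model, x) {
  model$phi[as.integer(as_feature_matrix(x)[, 1])]
}

#' @export
committor_logit.committor_table <- function(model, x) {
  p <- pmin(pmax(predict_phi(model, x), 1e-12), 1 - 1e-12)
  log(p / (1 - p))
}

#' Wrap a function as a committor model
#'
#' @param phi_fn function taking a feature matrix, returning phi per row.
#' @param grad_fn optional gradient function (matrix in, matrix out).
#' @export
committor_fn <- function(phi_fn, grad_fn = NULL) {
  structure(list(phi_fn = phi_fn, grad_fn = grad_fn),
            class = c("committor_fn", "committor_model"))
}

#' @export
predict_phi.committor_fn <- function(model, x) {
  model$phi_fn(as_feature_matrix(x))
}

#' @export
committor_logit.committor_fn <- function(model, x) {
  p <- pmin(pmax(predict_phi(model, x), 1e-12), 1 - 1e-12)
  log(p / (1 - p))
}

#' @export
committor_gradient.committor_fn <- function(model, x) {
  X <- as_feature_matrix(x)
  if (!is.null(model$grad_fn)) return(model$grad_fn(X))
  # central finite differences as a fallback
  h <- 1e-5
  g <- matrix(0, nrow(X), ncol(X))
  for (j in seq_len(ncol(X))) {
    Xp <- X; Xp[, j] <- Xp[, j] + h
    Xm <- X; Xm[, j] <- Xm[, j] - h
    g[, j] <- (model$phi_fn(Xp) - model$phi_fn(Xm)) / (2 * h)
  }
  g
}

#' Shooting-outcome negative log-likelihood
#'
#' The committor model is trained by minimizing the negative
#' log-likelihood of shooting outcomes,
#' `-(1/N) sum_i ln[ C(n_i, k_i) phi_i^k_i (1 - phi_i)^(n_i - k_i) ]`,
#' where `k_i` counts how often the `n_i` trial segments from shooting
#' point `i` hit the designated final state. Predicted probabilities are
#' clamped to `[eps, 1 - eps]` (`eps = 1e-7`) because the likelihood is
#' unbounded at 0/1 with mismatched `k`.
#'
#' @param records tibble with columns `n`, `k` and feature columns (any
#'   column named `x` or `x1`, `x2`, ...).
#' @param model a committor model, or a numeric vector of predicted
#'   `phi` values (one per record).
#' @param eps clamping bound.
#' @return Mean negative log-likelihood (scalar).
#' @examples
#' r <- tibble::tibble(x = 0, n = 2, k = 1)
#' nll_loss(r, 0.5)   # -log(2 * 0.25)
#' @export
nll_loss <- function(records, model, eps = 1e-7) {
  stopifnot(nrow(records) > 0, all(records$k >= 0), all(records$k <= records$n))
  phi <- if (is.numeric(model)) model
         else predict_phi(model, record_features(records))
  phi <- pmin(pmax(phi, eps), 1 - eps)
  -mean(lchoose(records$n, records$k) + records$k * log(phi) +
          (records$n - records$k) * log(1 - phi))
}

#' Extract the feature matrix of a record table
#'
#' Feature columns are `x` or `x1`, `x2`, ... (in numeric order).
#'
#' @param records a tibble of shooting records.
#' @param feature_cols optional explicit column names.
#' @export
record_features <- function(records, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    nm <- names(records)
    feature_cols <- nm[grepl("^x[0-9]*$", nm)]
    idx <- suppressWarnings(as.integer(sub("^x", "", feature_cols)))
    idx[is.na(idx)] <- 0L
    feature_cols <- feature_cols[order(idx)]
  }
  if (length(feature_cols) == 0) stop("no feature columns found.", call. = FALSE)
  as.matrix(records[, feature_cols, drop = FALSE])
}

#' Train a committor model on shooting records
#'
#' Minimizes the shooting-outcome negative log-likelihood (plus an L2
#' penalty on weights) with the Adam optimizer. Records tagged with a
#' `chain_id` column are split by chain for validation: the chains in
#' `val_chains` (default: the last chain) are held out, and training
#' stops at the minimum validation loss (early stopping with
#' `patience`). Records from restraint/seeding runs can simply be
#' included in `records` - they carry shooting outcomes like any other.
#'
#' @param records tibble with feature columns, `n`, `k` and optionally
#'   `chain_id`.
#' @param spec a [network_spec()] or widths vector (input width must
#'   match the number of feature columns).
#' @param epochs_max maximum number of epochs.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size (`Inf` = full batch).
#' @param val_chains chain ids held out for validation (`NULL`: last
#'   chain if a `chain_id` column exists, else a random 20% split).
#' @param patience epochs without validation improvement before stopping.
#' @param seed seed for initialization, shuffling and dropout.
#' @param verbose print progress?
#' @return The trained `committor_mlp`, with `$history` (tibble of epoch,
#'   training and validation loss) and `$best_epoch` attached.
#' @export
train_committor <- function(records, spec, epochs_max = 500, lr = 1e-3,
                            batch_size = 256, val_chains = NULL,
                            patience = 50, seed = 1, verbose = FALSE) {
  X <- record_features(records)
  if (!inherits(spec, "network_spec")) spec <- network_spec(spec)
  stopifnot(spec$widths[1] == ncol(X))
  net <- build_network(spec, seed = seed,
                       feature_names = colnames(X))
  set.seed(seed + 1L)
  n <- nrow(records)
  if (is.null(val_chains) && "chain_id" %in% names(records) &&
      length(unique(records$chain_id)) >= 2) {
    val_chains <- max(records$chain_id)
  }
  if (!is.null(val_chains) && "chain_id" %in% names(records)) {
    is_val <- records$chain_id %in% val_chains
  } else {
    is_val <- runif(n) < 0.2
  }
  if (all(is_val) || !any(is_val)) {
    is_val <- seq_len(n) %in% sample.int(n, max(1, round(0.2 * n)))
  }
  net$x_center <- colMeans(X[!is_val, , drop = FALSE])
  net$x_scale <- pmax(apply(X[!is_val, , drop = FALSE], 2, sd), 1e-8)
  Xt <- X[!is_val, , drop = FALSE]
  Xv <- X[is_val, , drop = FALSE]
  kt <- records$k[!is_val]; nt <- records$n[!is_val]
  kv <- records$k[is_val]; nv <- records$n[is_val]
  nt_tot <- length(kt)
  bs <- min(batch_size, nt_tot)

  theta <- flatten_params(net$stages)
  wmask <- weight_mask(net$stages)
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8; t_step <- 0
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  hist_train <- hist_val <- numeric(epochs_max)
  n_stage <- length(net$stages)
  since_best <- 0L

  eval_loss <- function(net, X, k, nn) {
    q <- mlp_forward(net, X)$q
    phi <- pmin(pmax(stats::plogis(q), 1e-7), 1 - 1e-7)
    -mean(lchoose(nn, k) + k * log(phi) + (nn - k) * log(1 - phi))
  }

  for (epoch in seq_len(epochs_max)) {
    ord <- if (bs < nt_tot) sample.int(nt_tot) else seq_len(nt_tot)
    for (start in seq(1, nt_tot, by = bs)) {
      idx <- ord[start:min(start + bs - 1, nt_tot)]
      Xb <- Xt[idx, , drop = FALSE]
      masks <- NULL
      if (spec$dropout > 0) {
        masks <- lapply(seq_len(n_stage - 1L), function(i) {
          w <- net$spec$widths[i + 1]
          matrix((runif(length(idx) * w) > spec$dropout) / (1 - spec$dropout),
                 length(idx), w)
        })
      }
      fw <- mlp_forward(net, Xb, masks)
      phi <- stats::plogis(fw$q)
      dq <- (nt[idx] * phi - kt[idx]) / length(idx)
      if (any(!is.finite(dq))) {
        stop(sprintf("training diverged (non-finite loss gradient) at epoch %d",
                     epoch), call. = FALSE)
      }
      bw <- mlp_backward(net, fw$cache, dq)
      g <- flatten_params(bw$grads) + 2 * spec$l2 * wmask * theta
      t_step <- t_step + 1
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mh <- m / (1 - b1^t_step)
      vh <- v / (1 - b2^t_step)
      theta <- theta - lr * mh / (sqrt(vh) + adam_eps)
      net$stages <- unflatten_params(net$stages, theta)
    }
    hist_train[epoch] <- eval_loss(net, Xt, kt, nt)
    hist_val[epoch] <- eval_loss(net, Xv, kv, nv)
    if (!is.finite(hist_train[epoch])) {
      stop(sprintf("training diverged (NaN loss) at epoch %d", epoch),
           call. = FALSE)
    }
    if (hist_val[epoch] < best$loss - 1e-6) {
      best <- list(loss = hist_val[epoch], theta = theta, epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= patience) break
    }
    if (verbose && epoch %% 50 == 0) {
      message(sprintf("epoch %d  train %.4f  val %.4f", epoch,
                      hist_train[epoch], hist_val[epoch]))
    }
  }
  net$stages <- unflatten_params(net$stages, best$theta)
  net$best_epoch <- best$epoch
  n_ep <- epoch
  net$history <- tibble::tibble(epoch = seq_len(n_ep),
                                train = hist_train[seq_len(n_ep)],
                                validation = hist_val[seq_len(n_ep)])
  net
}

#' Transition-path probability of a committor value
#'
#' For two-way shooting the probability that a shot from a point with
#' committor `phi` produces a transition path is
#' `P(TP | x) = 2 phi (1 - phi)`.
#'
#' @param phi committor value(s) in `[0, 1]`.
#' @export
p_tp <- function(phi) {
  stopifnot(all(phi >= 0 & phi <= 1))
  2 * phi * (1 - phi)
}

#' @export
print.committor_mlp <- function(x, ...) {
  cat("<committor_mlp> widths:", paste(x$spec$widths, collapse = " -> "),
      " resnet depth:", x$spec$resnet_depth, "\n")
  cat("  parameters:", n_parameters(x), "\n")
  if (!is.null(x$best_epoch)) cat("  best epoch:", x$best_epoch, "\n")
  invisible(x)
}

#' @export
tidy.committor_mlp <- function(x, ...) {
  if (is.null(x$history)) return(tibble::tibble())
  tidyr::pivot_longer(x$history, c("train", "validation"),
                      names_to = "split", values_to = "loss")
}

#' @export
glance.committor_mlp <- function(x, ...) {
  tibble::tibble(
    n_parameters = n_parameters(x),
    n_layers = length(x$spec$widths) - 1L,
    resnet_depth = x$spec$resnet_depth,
    best_epoch = if (is.null(x$best_epoch)) NA_integer_ else x$best_epoch,
    val_loss = if (is.null(x$history)) NA_real_
               else min(x$history$validation)
  )
}
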