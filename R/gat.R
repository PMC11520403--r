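# Core model mathematics: masked multi-head graph attention, residual
# fusion, MLP pair classifier, stable binary cross-entropy, and analytic
# backpropagation for all of it. Matrices throughout; no NN framework.

leaky_relu <- function(x, slope) x * (x > 0) + slope * x * (x <= 0)
leaky_relu_grad <- function(x, slope) (x > 0) + slope * (x <= 0)

elu <- function(x) ifelse(x > 0, x, expm1(x))
elu_grad <- function(x) ifelse(x > 0, 1, exp(x))
relu <- function(x) pmax(x, 0)
relu_grad <- function(x) (x > 0) * 1

activation_fns <- function(name) {
  switch(name,
         elu = list(f = elu, g = elu_grad),
         relu = list(f = relu, g = relu_grad),
         identity = list(f = identity, g = function(x) 1 + 0 * x),
         stop("unknown activation: ", name, call. = FALSE))
}

sigmoid <- function(x) 1 / (1 + exp(-x))
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' Single-pair attention logit
#'
#' The unnormalized attention directed to node i from node j:
#' `LeakyReLU(a . [W x_i || W x_j])` for one head with weight matrix `W` and
#' attention vector `a`. Exposed mainly for study and testing; the model
#' computes all pairs at once.
#'
#' @param W weight matrix, k x p (maps an encoding to a head embedding).
#' @param a attention vector of length 2k.
#' @param x_i,x_j encoding vectors of length p.
#' @param leaky_slope negative slope of the LeakyReLU.
#' @return scalar logit.
#' @export
attention_logits <- function(W, a, x_i, x_j, leaky_slope = 0.2) {
  k <- nrow(W)
  if (ncol(W) != length(x_i) || length(x_i) != length(x_j))
    stop("shape mismatch between W and x", call. = FALSE)
  if (length(a) != 2 * k)
    stop("attention vector must have length 2k", call. = FALSE)
  pre <- sum(a[seq_len(k)] * (W %*% x_i)) + sum(a[k + seq_len(k)] * (W %*% x_j))
  leaky_relu(pre, leaky_slope)
}

#' Masked softmax attention coefficients
#'
#' Normalizes a vector of attention logits over a neighborhood:
#' `alpha_ij = exp(logit_ij) / sum_r exp(logit_ir)` over `r` in the
#' neighborhood, zero elsewhere. Numerically stabilized by max subtraction.
#'
#' @param logits numeric vector of logits for all candidate neighbors.
#' @param neighborhood logical or 0/1 vector marking the neighborhood; must
#'   contain at least one member.
#' @return vector of coefficients summing to 1 over the neighborhood.
#' @export
attention_coefficients <- function(logits, neighborhood = rep(TRUE, length(logits))) {
  keep <- as.logical(neighborhood)
  if (!any(keep)) stop("empty neighborhood", call. = FALSE)
  z <- ifelse(keep, logits, -Inf)
  e <- exp(z - max(z))
  e / sum(e)
}

# --- parameter initialisation -------------------------------------------

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_gat_params <- function(p, k, h, n_layers) {
  lapply(seq_len(n_layers), function(l) {
    lapply(seq_len(h), function(t) {
      list(W = glorot(p, k), a = stats::runif(2 * k, -0.3, 0.3))
    })
  })
}

init_mlp_params <- function(d_in, hidden) {
  widths <- c(d_in, hidden, 1L)
  lapply(seq_len(length(widths) - 1L), function(i) {
    list(W = glorot(widths[i], widths[i + 1]), b = numeric(widths[i + 1]))
  })
}

# --- GAT forward / backward ---------------------------------------------

# One masked multi-head attention layer over an n x p input.
# Returns the k*h-wide output plus everything backward needs.
gat_layer_fwd <- function(X_in, adj, heads, leaky_slope, act) {
  n <- nrow(X_in)
  mask0 <- adj == 0
  outs <- vector("list", length(heads))
  caches <- vector("list", length(heads))
  for (t in seq_along(heads)) {
    W <- heads[[t]]$W; a <- heads[[t]]$a
    k <- ncol(W)
    H <- X_in %*% W
    f <- drop(H %*% a[seq_len(k)])
    g <- drop(H %*% a[k + seq_len(k)])
    P <- matrix(f, n, n) + matrix(g, n, n, byrow = TRUE)
    pre <- leaky_relu(P, leaky_slope)
    z <- pre
    z[mask0] <- -Inf
    mx <- apply(z, 1, max)          # rows nonempty by construction
    E <- exp(z - mx)
    alpha <- E / rowSums(E)
    Mpre <- alpha %*% H
    outs[[t]] <- act$f(Mpre)
    caches[[t]] <- list(H = H, P = P, alpha = alpha, Mpre = Mpre)
  }
  list(out = do.call(cbind, outs), caches = caches)
}

gat_layer_bwd <- function(dOut, X_in, heads, caches, leaky_slope, act) {
  n <- nrow(X_in)
  dX_in <- matrix(0, n, ncol(X_in))
  grads <- vector("list", length(heads))
  col0 <- 0L
  for (t in seq_along(heads)) {
    W <- heads[[t]]$W; a <- heads[[t]]$a
    k <- ncol(W)
    cc <- caches[[t]]
    dHead <- dOut[, col0 + seq_len(k), drop = FALSE]
    col0 <- col0 + k
    dM <- dHead * act$g(cc$Mpre)
    dalpha <- dM %*% t(cc$H)
    dH <- t(cc$alpha) %*% dM
    rs <- rowSums(cc$alpha * dalpha)
    dE <- cc$alpha * (dalpha - rs)
    dP <- dE * leaky_relu_grad(cc$P, leaky_slope)
    df <- rowSums(dP)
    dg <- colSums(dP)
    dH <- dH + outer(df, a[seq_len(k)]) + outer(dg, a[k + seq_len(k)])
    da <- c(drop(t(cc$H) %*% df), drop(t(cc$H) %*% dg))
    dW <- t(X_in) %*% dH
    dX_in <- dX_in + dH %*% t(W)
    grads[[t]] <- list(W = dW, a = da)
  }
  list(dX_in = dX_in, grads = grads)
}

gat_forward <- function(X, adj, layers, leaky_slope, act) {
  inputs <- vector("list", length(layers))
  caches <- vector("list", length(layers))
  cur <- X
  for (l in seq_along(layers)) {
    inputs[[l]] <- cur
    fw <- gat_layer_fwd(cur, adj, layers[[l]], leaky_slope, act)
    caches[[l]] <- fw$caches
    cur <- fw$out
  }
  list(Z = cur, inputs = inputs, caches = caches)
}

gat_backward <- function(dZ, fw, layers, leaky_slope, act) {
  grads <- vector("list", length(layers))
  d <- dZ
  for (l in rev(seq_along(layers))) {
    bw <- gat_layer_bwd(d, fw$inputs[[l]], layers[[l]], fw$caches[[l]],
                        leaky_slope, act)
    grads[[l]] <- bw$grads
    d <- bw$dX_in
  }
  grads
}

# --- MLP ----------------------------------------------------------------

mlp_forward <- function(Feat, layers, act) {
  As <- list(Feat)
  Zs <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    Zs[[i]] <- sweep(As[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    As[[i + 1]] <- if (i < length(layers)) act$f(Zs[[i]]) else Zs[[i]]
  }
  list(logits = drop(As[[length(As)]]), As = As, Zs = Zs)
}

mlp_backward <- function(dlogits, fw, layers, act) {
  L <- length(layers)
  grads <- vector("list", L)
  dZ <- matrix(dlogits, ncol = 1)
  for (i in rev(seq_len(L))) {
    grads[[i]] <- list(W = t(fw$As[[i]]) %*% dZ, b = colSums(dZ))
    if (i > 1) {
      dA <- dZ %*% t(layers[[i]]$W)
      dZ <- dA * act$g(fw$Zs[[i - 1]])
    } else {
      dFeat <- dZ %*% t(layers[[i]]$W)
    }
  }
  list(grads = grads, dFeat = dFeat)
}

#' Binary cross-entropy loss on logits
#'
#' Mean over pairs of `-[y log s(z) + (1-y) log(1 - s(z))]` with `s` the
#' sigmoid, evaluated in the numerically stable logits form
#' `softplus(z) - y z`.
#'
#' @param logits real-valued scores.
#' @param labels 0/1 vector of the same length.
#' @return nonnegative scalar.
#' @export
bce_loss <- function(logits, labels) {
  if (length(logits) != length(labels))
    stop("logits and labels differ in length", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0 or 1", call. = FALSE)
  mean(softplus(logits) - labels * logits)
}

# --- full model ----------------------------------------------------------

# model: list(params, config, adjacency (Ax, Ay), X, Y, id lookups)
# pairs given as integer indices (pi into proteins, dj into drugs) + labels.
model_forward <- function(params, cfg, X, Y, Ax, Ay, pi, dj,
                          feat_mask = NULL) {
  act <- activation_fns(cfg$activation)
  mact <- activation_fns(cfg$mlp_activation)
  if (cfg$use_gat) {
    fwx <- gat_forward(X, Ax, params$protein, cfg$leaky_slope, act)
    fwy <- gat_forward(Y, Ay, params$drug, cfg$leaky_slope, act)
    Zx <- fwx$Z; Zy <- fwy$Z
  } else {
    fwx <- fwy <- NULL
    Zx <- matrix(0, nrow(X), ncol(X))
    Zy <- matrix(0, nrow(Y), ncol(Y))
  }
  Px <- Zx + cfg$beta * X
  Py <- Zy + cfg$gamma * Y
  Feat <- cbind(Px[pi, , drop = FALSE], Py[dj, , drop = FALSE])
  if (!is.null(feat_mask)) Feat <- Feat * feat_mask
  fwm <- mlp_forward(Feat, params$mlp, mact)
  list(logits = fwm$logits, fwx = fwx, fwy = fwy, fwm = fwm,
       Zx = Zx, Zy = Zy)
}

model_loss_grads <- function(params, cfg, X, Y, Ax, Ay, pi, dj, labels,
                             feat_mask = NULL) {
  act <- activation_fns(cfg$activation)
  mact <- activation_fns(cfg$mlp_activation)
  fw <- model_forward(params, cfg, X, Y, Ax, Ay, pi, dj, feat_mask)
  npairs <- length(labels)
  loss <- bce_loss(fw$logits, labels)
  dlogits <- (sigmoid(fw$logits) - labels) / npairs
  bwm <- mlp_backward(dlogits, fw$fwm, params$mlp, mact)
  grads <- list(mlp = bwm$grads)
  if (!is.null(feat_mask)) bwm$dFeat <- bwm$dFeat * feat_mask
  if (cfg$use_gat) {
    p <- ncol(X)
    dPx_pairs <- bwm$dFeat[, seq_len(p), drop = FALSE]
    dPy_pairs <- bwm$dFeat[, p + seq_len(ncol(Y)), drop = FALSE]
    dZx <- matrix(0, nrow(X), p)
    dZy <- matrix(0, nrow(Y), ncol(Y))
    accx <- rowsum(dPx_pairs, group = pi)
    dZx[as.integer(rownames(accx)), ] <- accx
    accy <- rowsum(dPy_pairs, group = dj)
    dZy[as.integer(rownames(accy)), ] <- accy
    grads$protein <- gat_backward(dZx, fw$fwx, params$protein,
                                  cfg$leaky_slope, act)
    grads$drug <- gat_backward(dZy, fw$fwy, params$drug,
                               cfg$leaky_slope, act)
  }
  grads <- grads[names(params)]  # match the parameter-tree element order
  list(loss = loss, grads = grads, logits = fw$logits)
}

# --- parameter-tree utilities and Adam ----------------------------------

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}
tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(f, x[[i]], y[[i]])
    out
  } else f(x, y)
}
tree_flatten <- function(x) {
  if (is.list(x)) unlist(lapply(x, tree_flatten), use.names = FALSE)
  else as.numeric(x)
}
tree_unflatten <- function(skeleton, values) {
  i <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    out <- x
    out[] <- values[i + seq_len(n)]
    i <<- i + n
    out
  }
  res <- fill(skeleton)
  stopifnot(i == length(values))
  res
}

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
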