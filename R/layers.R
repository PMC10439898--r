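# Network building blocks on the autodiff tape.
#
# Layers are plain lists of parameter nodes (created once, He-initialised)
# plus any mutable state (batch-norm running moments live in environments).
# Forward functions assemble the graph per call.

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

layer_conv3d <- function(kh, kw, kt, cin, cout) {
  list(w = ad_param(he_init(c(kh, kw, kt, cin, cout), kh * kw * kt * cin)),
       b = ad_param(numeric(cout)))
}

# transposed conv filter layout: (kh, kw, kt, cout, cin)
layer_convt3d <- function(kh, kw, kt, cin, cout) {
  list(w = ad_param(he_init(c(kh, kw, kt, cout, cin), kh * kw * kt * cin)),
       b = ad_param(numeric(cout)))
}

layer_dense <- function(din, dout) {
  list(w = ad_param(he_init(c(dout, din), din)),
       b = ad_param(numeric(dout)))
}

layer_norm_affine <- function(C) {
  list(gamma = ad_param(rep(1, C)), beta = ad_param(numeric(C)))
}

layer_batchnorm <- function(C) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(C)
  st$running_var <- rep(1, C)
  list(gamma = ad_param(rep(1, C)), beta = ad_param(numeric(C)), state = st)
}

# largest divisor of C not exceeding g
gn_groups <- function(C, g) {
  for (k in seq(min(g, C), 1L)) if (C %% k == 0L) return(k)
  1L
}

fwd_conv <- function(layer, x, stride = c(1, 1, 1), pad = c(0, 0, 0)) {
  ad_conv3d(x, layer$w, layer$b, stride = stride, pad = pad)
}

fwd_convt <- function(layer, x, stride = c(2, 2, 1)) {
  ad_convt3d(x, layer$w, layer$b, stride = stride)
}

fwd_bn <- function(layer, x, training) {
  ad_batchnorm(x, layer$gamma, layer$beta, layer$state, training = training)
}

# Randomized leaky rectifier: slope drawn per call during training,
# fixed at the range midpoint for evaluation.
fwd_rrelu <- function(x, range = c(1 / 8, 1 / 3), training = TRUE) {
  slope <- if (training) stats::runif(1, range[1], range[2]) else mean(range)
  ad_leaky(x, slope)
}

# Squeeze-and-excitation channel attention.
layer_se <- function(C, reduction = 8) {
  mid <- max(2L, C %/% reduction)
  list(fc1 = layer_dense(C, mid), fc2 = layer_dense(mid, C))
}

fwd_se <- function(layer, x) {
  s <- ad_global_avgpool(x)                 # (C, N)
  s <- ad_relu(ad_dense(s, layer$fc1$w, layer$fc1$b))
  s <- ad_sigmoid(ad_dense(s, layer$fc2$w, layer$fc2$b))
  ad_scale_channels(x, s)
}

# Recursively collect parameter nodes with stable path names.
collect_params <- function(x, prefix = "") {
  if (inherits(x, "ad_node")) {
    if (x$is_param) return(stats::setNames(list(x), prefix)) else return(list())
  }
  if (is.list(x)) {
    out <- list()
    nm <- names(x) %||% rep("", length(x))
    for (i in seq_along(x)) {
      key <- if (nzchar(nm[i])) nm[i] else as.character(i)
      out <- c(out, collect_params(x[[i]],
                                   if (nzchar(prefix)) paste0(prefix, ".", key) else key))
    }
    return(out)
  }
  list()
}

# Collect batch-norm state environments with stable path names.
collect_states <- function(x, prefix = "") {
  if (is.environment(x) && !inherits(x, "ad_node"))
    return(stats::setNames(list(x), prefix))
  if (is.list(x) && !inherits(x, "ad_node")) {
    out <- list()
    nm <- names(x) %||% rep("", length(x))
    for (i in seq_along(x)) {
      key <- if (nzchar(nm[i])) nm[i] else as.character(i)
      out <- c(out, collect_states(x[[i]],
                                   if (nzchar(prefix)) paste0(prefix, ".", key) else key))
    }
    return(out)
  }
  list()
}

#' Number of trainable parameters of a model component
#' @param x a model, path or layer structure
#' @return integer count
#' @export
n_parameters <- function(x) {
  sum(vapply(collect_params(x), function(p) length(p$v), numeric(1)))
}
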