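# Parameter initialization helpers. A model is a flat named list of
# ad_tensor parameters (env `P`), a buffer environment for running
# normalization statistics, and the config that built it.

init_uniform <- function(dims, fan_in) {
  b <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -b, b), dim = dims)
}

# conv weight (k, k, cin_g, cout) + bias (cout)
add_conv <- function(P, name, k, cin, cout, groups = 1L) {
  cing <- cin %/% groups
  fan_in <- k * k * cing
  P[[paste0(name, ".w")]] <- ad_tensor(init_uniform(c(k, k, cing, cout), fan_in),
                                       requires_grad = TRUE)
  P[[paste0(name, ".b")]] <- ad_tensor(init_uniform(c(cout), fan_in),
                                       requires_grad = TRUE)
  P
}

# dense matrix (rout x rin), optional bias
add_linear <- function(P, name, rin, rout, bias = TRUE) {
  P[[paste0(name, ".w")]] <- ad_tensor(init_uniform(c(rout, rin), rin),
                                       requires_grad = TRUE)
  if (bias)
    P[[paste0(name, ".b")]] <- ad_tensor(init_uniform(c(rout), rin),
                                         requires_grad = TRUE)
  P
}

add_norm <- function(P, name, C) {
  P[[paste0(name, ".g")]] <- ad_tensor(rep(1, C), requires_grad = TRUE)
  P[[paste0(name, ".b")]] <- ad_tensor(rep(0, C), requires_grad = TRUE)
  P
}

conv_fw <- function(P, name, x, k, stride = 1L, groups = 1L, pad = NULL) {
  ad_conv2d(x, P[[paste0(name, ".w")]], P[[paste0(name, ".b")]],
            k = k, stride = stride, pad = pad, groups = groups)
}

bn_fw <- function(P, name, x, buf, training) {
  ad_batchnorm(x, P[[paste0(name, ".g")]], P[[paste0(name, ".b")]],
               buf, name, training)
}

ln_fw <- function(P, name, x) {
  ad_layernorm_ch(x, P[[paste0(name, ".g")]], P[[paste0(name, ".b")]])
}
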