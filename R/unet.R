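# U-Net encoder-decoder with skip connections, built on the nn_core ops.
# Depth d halves the spatial grid d times; inputs must be divisible by 2^d
# (the segmenter pads reflectively when they are not).

unet_init <- function(in_ch = 1L, base = 8L, depth = 3L) {
  params <- list()
  c_prev <- in_ch
  for (i in seq_len(depth)) {
    params[[paste0("enc", i)]] <- nn_conv3_init(c_prev, base * 2^(i - 1L))
    c_prev <- base * 2^(i - 1L)
  }
  params[["bott"]] <- nn_conv3_init(base * 2^(depth - 1L), base * 2^depth)
  for (i in rev(seq_len(depth))) {
    up_ch <- if (i == depth) base * 2^depth else base * 2^i
    params[[paste0("dec", i)]] <-
      nn_conv3_init(up_ch + base * 2^(i - 1L), base * 2^(i - 1L))
  }
  params[["head"]] <- nn_conv1_init(base, 1L)
  attr(params, "arch") <- list(in_ch = in_ch, base = base, depth = depth)
  params
}

unet_forward <- function(params, x, cache = FALSE) {
  arch <- attr(params, "arch")
  depth <- arch$depth
  cc <- if (cache) list(enc_cols = list(), enc_act = list(), pool = list(),
                        dec_cols = list(), dec_in_ch = integer(depth),
                        dec_act = list(), x = x) else NULL
  a <- x
  enc_act <- list()
  pool_arg <- list()
  for (i in seq_len(depth)) {
    cv <- nn_conv3_fwd(a, params[[paste0("enc", i)]])
    act <- nn_relu(cv$out)
    enc_act[[i]] <- act
    pl <- nn_pool2_fwd(act)
    a <- pl$out
    if (cache) {
      cc$enc_cols[[i]] <- cv$cols
      cc$enc_act[[i]] <- act
      cc$pool[[i]] <- pl$arg
    }
  }
  cv <- nn_conv3_fwd(a, params$bott)
  a <- nn_relu(cv$out)
  if (cache) {
    cc$bott_cols <- cv$cols
    cc$bott_in_dim <- dim(enc_act[[depth]])  # pooled dims derive from this
    cc$bott_act <- a
  }
  for (i in rev(seq_len(depth))) {
    up <- nn_up2_fwd(a)
    cat_in <- nn_cat(up, enc_act[[i]])
    cv <- nn_conv3_fwd(cat_in, params[[paste0("dec", i)]])
    a <- nn_relu(cv$out)
    if (cache) {
      cc$dec_cols[[i]] <- cv$cols
      cc$dec_in_ch[i] <- dim(cat_in)[3]
      cc$dec_act[[i]] <- a
    }
  }
  logits <- nn_conv1_fwd(a, params$head)
  prob <- nn_sigmoid(logits)
  if (cache) {
    cc$last_act <- a
    list(prob = prob, cache = cc)
  } else {
    prob
  }
}

# Backward pass from d(loss)/d(logits); returns grads named like params.
unet_backward <- function(params, cache, glogit) {
  arch <- attr(params, "arch")
  depth <- arch$depth
  base <- arch$base
  grads <- list()

  hb <- nn_conv1_bwd(cache$last_act, params$head, glogit)
  grads$head <- list(W = hb$gW, b = hb$gb)

  g <- hb$gx
  gskip <- vector("list", depth)
  for (i in seq_len(depth)) {        # decoder levels, shallow to deep
    g <- nn_relu_bwd(cache$dec_act[[i]], g)
    d_out <- dim(cache$dec_act[[i]])
    cb <- nn_conv3_bwd(cache$dec_cols[[i]], params[[paste0("dec", i)]],
                       g, d_out[1], d_out[2], cache$dec_in_ch[i])
    grads[[paste0("dec", i)]] <- list(W = cb$gW, b = cb$gb)
    up_ch <- if (i == depth) base * 2^depth else base * 2^i
    gup <- cb$gx[, , seq_len(up_ch), drop = FALSE]
    gskip[[i]] <- cb$gx[, , up_ch + seq_len(dim(cb$gx)[3] - up_ch),
                        drop = FALSE]
    g <- nn_up2_bwd(gup)             # into the next-deeper activation
  }

  g <- nn_relu_bwd(cache$bott_act, g)
  bd <- dim(cache$bott_act)
  cb <- nn_conv3_bwd(cache$bott_cols, params$bott, g, bd[1], bd[2],
                     base * 2^(depth - 1L))
  grads$bott <- list(W = cb$gW, b = cb$gb)
  g <- cb$gx                          # grad into pooled enc_depth output

  for (i in rev(seq_len(depth))) {
    gact <- nn_pool2_bwd(g, cache$pool[[i]], dim(cache$enc_act[[i]])) +
      gskip[[i]]
    gact <- nn_relu_bwd(cache$enc_act[[i]], gact)
    d_out <- dim(cache$enc_act[[i]])
    c_in <- if (i == 1L) arch$in_ch else base * 2^(i - 2L)
    cb <- nn_conv3_bwd(cache$enc_cols[[i]], params[[paste0("enc", i)]],
                       gact, d_out[1], d_out[2], c_in)
    grads[[paste0("enc", i)]] <- list(W = cb$gW, b = cb$gb)
    g <- cb$gx
  }
  grads[names(params)]
}
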