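test_that("preset geometries follow the reference layouts", {
  sp <- preset_specs()
  expect_equal(sp$ihc$L_c, 2560)
  expect_equal(sp$anf_l$L_c, 16384)
  expect_equal(sp$ihc$L_c, sp$ihc$L_l + sp$ihc$L + sp$ihc$L_r)
  expect_equal(sp$anf_h$L_l, 7936)
  expect_equal(sp$anf_h$n_total, 28)
  # bottleneck lengths: L_c / 2^N
  expect_equal(sp$ihc$L_c / 2^(sp$ihc$n_total / 2), 320)
  expect_equal(sp$anf_h$L_c / 2^(sp$anf_h$n_total / 2), 1)
})

test_that("closed-form parameter counts reproduce the reference totals", {
  sp <- preset_specs()
  expect_identical(count_trainable_params(sp$ihc), 1317505L)
  expect_identical(count_trainable_params(sp$anf_l), 1248449L)
  expect_identical(count_trainable_params(sp$anf_h), 1250177L)
  expect_identical(count_trainable_params(sp$anf_m), 1250177L)
  total <- sum(vapply(sp, count_trainable_params, integer(1)))
  expect_identical(total, 5066308L)
  # the PReLU surplus is exactly one slope per filter on all but the last layer
  expect_identical(count_trainable_params(sp$anf_h) -
                     count_trainable_params(sp$anf_l), 27L * 64L)
})

test_that("closed-form count equals introspection of the built network", {
  set.seed(12)
  for (i in 1:20) {
    N <- sample(2:4, 1)
    k <- sample(c(2, 4, 8, 16), 1)
    F <- sample(c(2, 3, 5, 8), 1)
    L <- 2^N * sample(2:6, 1)
    acts <- sample(c("tanh", "sigmoid", "prelu"), 2, replace = TRUE)
    spec <- surrogate_spec(L, 0, 0, 2 * N, F, k, acts[1], acts[2])
    net <- build_surrogate(spec, seed = i)
    expect_identical(introspect_params(net),
                     as.numeric(count_trainable_params(spec)))
  }
})

test_that("geometry contracts: halving/doubling, divisibility, cropping", {
  spec <- desk_specs()$ihc
  net <- build_surrogate(spec, seed = 2)
  x <- matrix(stats::rnorm(spec$L_c), ncol = 1)
  fw <- periphnet:::network_forward(net, x, 1L)
  # encoder layer n output length is L_c / 2^n, exactly
  N <- spec$n_total / 2
  for (n in seq_len(N))
    expect_equal(nrow(fw$caches[[n]]$A), spec$L_c / 2^n)
  expect_equal(nrow(fw$out), spec$L_c)

  expect_error(surrogate_predict(net, stats::rnorm(spec$L_c + 1)), "multiple")
  expect_error(surrogate_spec(100, 0, 0, 6, 8, 8), "multiple")

  expect_equal(length(crop_context(stats::rnorm(2560), 256, 256)), 2048)
  expect_equal(length(crop_context(stats::rnorm(16384), 7936, 256)), 8192)
  v <- stats::rnorm(64)
  expect_identical(crop_context(v, 0, 0), v)
  expect_error(crop_context(v, 10, 10, L = 64), "mismatch")
})

test_that("zero input propagates to zero output through odd activations", {
  spec <- surrogate_spec(64, 0, 0, 4, 4, 8, "tanh", "tanh")
  net <- build_surrogate(spec, seed = 5)     # biases initialise to zero
  y <- surrogate_predict(net, numeric(64))
  expect_true(all(y == 0))
})

test_that("channel extrapolation is weight-sharing: equivariance properties", {
  spec <- desk_specs()$ihc
  net <- build_surrogate(spec, seed = 8)
  x1 <- stats::rnorm(spec$L_c)
  # identical channels give bitwise-identical outputs
  y <- surrogate_predict(net, cbind(x1, x1, x1))
  expect_identical(y[, 1], y[, 2])
  expect_identical(y[, 1], y[, 3])
  # a single channel equals the multi-channel column
  y1 <- surrogate_predict(net, x1)
  expect_identical(y1[, 1], y[, 1])
  # permuting input channels permutes outputs identically
  x2 <- stats::rnorm(spec$L_c); x3 <- stats::rnorm(spec$L_c)
  ya <- surrogate_predict(net, cbind(x1, x2, x3))
  yb <- surrogate_predict(net, cbind(x3, x1, x2))
  expect_identical(ya[, c(3, 1, 2)], yb)
})

test_that("module merging sums parameters and respects geometry", {
  a <- build_surrogate(desk_specs()$ihc, seed = 1)
  b <- build_surrogate(desk_specs()$anf, seed = 2)
  chain <- merge_modules(list(a, b))
  expect_equal(introspect_params(chain),
               introspect_params(a) + introspect_params(b))

  # single-element chain is identical to the element
  solo <- merge_modules(list(a))
  x <- stats::rnorm(desk_specs()$ihc$L_c)
  expect_identical(chain_predict(solo, x, crop = FALSE),
                   surrogate_predict(a, x))

  # composite output length equals the last stage's L for an L_c input
  lc <- desk_specs()$anf$L_c
  out <- chain_predict(chain, stats::rnorm(lc), crop = TRUE)
  expect_equal(nrow(out), desk_specs()$anf$L)

  # insufficient upstream context is an explicit geometry error
  expect_error(chain_predict(chain, stats::rnorm(512)), "context")
})

test_that("models round-trip through save/load with a manifest", {
  net <- build_surrogate(surrogate_spec(32, 0, 0, 4, 3, 4), seed = 3)
  path <- tempfile(fileext = ".rds")
  save_surrogate(net, path)
  expect_true(file.exists(paste0(path, ".json")))
  man <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(man$n_params, introspect_params(net))
  net2 <- load_surrogate(path)
  x <- stats::rnorm(32)
  expect_identical(surrogate_predict(net, x), surrogate_predict(net2, x))
})
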