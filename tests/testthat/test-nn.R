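# The neural-network engine underlying backbones and the subnet.

test_that("convolution agrees with a direct sliding-window computation", {
  x <- withr::with_seed(22, array(rnorm(7 * 6 * 2 * 2), dim = c(7, 6, 2, 2)))
  built <- afse:::with_seed(5, afse:::nn_build_stack(
    list(afse:::layer_conv(3, c(3, 3))), c(7L, 6L, 2L)))$layers[[1]]
  out <- afse:::conv_forward(built, x)$out
  W <- built$W
  brute <- array(0, dim = c(7, 6, 3, 2))
  for (s in 1:2) for (f in 1:3) for (r in 1:7) for (cc in 1:6) {
    acc <- built$b[f]
    for (ch in 1:2) for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; c2 <- cc + dc
      if (rr >= 1 && rr <= 7 && c2 >= 1 && c2 <= 6) {
        wi <- (ch - 1) * 9 + (dc + 1) * 3 + (dr + 1) + 1
        acc <- acc + x[rr, c2, ch, s] * W[wi, f]
      }
    }
    brute[r, cc, f, s] <- acc
  }
  expect_equal(out, brute, tolerance = 1e-12)
})

test_that("backpropagation matches numerical gradients", {
  net <- afse:::nn_network(
    list(afse:::layer_conv(2, 3), afse:::layer_relu(), afse:::layer_avgpool(2, 2),
         afse:::layer_gap(), afse:::layer_batchnorm(), afse:::layer_dense(3)),
    c(6L, 6L, 1L), seed = 3)
  x <- withr::with_seed(23, array(rnorm(6 * 6 * 4), dim = c(6, 6, 1, 4)))
  y <- c(0L, 1L, 2L, 0L)
  loss_of <- function(net) {
    fw <- afse:::stack_forward(net$layers, x, training = TRUE)
    p <- afse:::softmax_rows(fw$out)
    sum(-rowSums(one_hot(y, 3) * log(p))) / 4
  }
  fw <- afse:::stack_forward(net$layers, x, training = TRUE)
  p <- afse:::softmax_rows(fw$out)
  bw <- afse:::stack_backward(fw$layers, fw$caches, (p - one_hot(y, 3)) / 4)
  num_grad <- function(setter, value) {
    e <- 1e-5
    (loss_of(setter(net, value + e)) - loss_of(setter(net, value - e))) / (2 * e)
  }
  expect_equal(bw$grads[[1]]$W[1, 1],
               num_grad(function(n, v) { n$layers[[1]]$W[1, 1] <- v; n },
                        net$layers[[1]]$W[1, 1]), tolerance = 1e-5)
  expect_equal(bw$grads[[6]]$W[2, 3],
               num_grad(function(n, v) { n$layers[[6]]$W[2, 3] <- v; n },
                        net$layers[[6]]$W[2, 3]), tolerance = 1e-5)
  expect_equal(bw$grads[[5]]$gamma[1],
               num_grad(function(n, v) { n$layers[[5]]$gamma[1] <- v; n },
                        net$layers[[5]]$gamma[1]), tolerance = 1e-5)
})

test_that("categorical cross-entropy matches its closed forms and a hand sum", {
  expect_equal(categorical_cross_entropy(c(0, 1, 0, 0), c(0, 1, 0, 0)), 0)
  expect_equal(categorical_cross_entropy(rep(0.25, 4), c(1, 0, 0, 0)), log(4))
  p <- withr::with_seed(24, { v <- runif(4); v / sum(v) })
  y <- c(0, 0, 1, 0)
  expect_equal(categorical_cross_entropy(p, y), -sum(y * log(p)))
  expect_error(categorical_cross_entropy(c(0.5, 0.2), c(1, 0)), "probability")
})

test_that("the learning-rate staircase follows the printed schedule", {
  expect_equal(lr_at_epoch(30), 0.1)
  expect_equal(lr_at_epoch(61), 0.01)
  expect_equal(lr_at_epoch(200), 0.0001)
  expect_equal(lr_at_epoch(0), 0.1)
  expect_equal(lr_at_epoch(c(60, 120, 121, 180, 181)),
               c(0.1, 0.01, 0.001, 0.001, 0.0001))
})

test_that("dropout rate approaching zero reproduces the plain forward pass", {
  x <- withr::with_seed(25, matrix(rnorm(40), 8, 5))
  net0 <- afse:::nn_network(list(afse:::layer_dense(3)), 5L, seed = 2)
  netd <- afse:::nn_network(list(afse:::layer_dropout(0), afse:::layer_dense(3)),
                            5L, seed = 2)
  out0 <- afse:::stack_forward(net0$layers, x, training = TRUE)$out
  outd <- afse:::stack_forward(netd$layers, x, training = TRUE)$out
  expect_equal(out0, outd)
})

test_that("training reduces loss on separable data, deterministically by seed", {
  X <- withr::with_seed(26, rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 3), 30)))
  y <- rep(0:1, each = 30)
  net <- afse:::nn_network(list(afse:::layer_dense(8), afse:::layer_relu(),
                                afse:::layer_dense(2)), 2L, seed = 1)
  tr1 <- afse:::nn_train(net, X, y, epochs = 15, batch_size = 10,
                         schedule = lr_schedule(0L, 0.05), seed = 9)
  tr2 <- afse:::nn_train(net, X, y, epochs = 15, batch_size = 10,
                         schedule = lr_schedule(0L, 0.05), seed = 9)
  expect_lt(tr1$history$loss[15], tr1$history$loss[1])
  expect_identical(tr1$history, tr2$history)
})
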