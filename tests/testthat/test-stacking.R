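test_that("stack coordinates follow the mixed-radix stride rule", {
  ord <- axis_order(channel_names())
  expect_equal(unlist(stack_coordinates(rep(0.5, 10), ord)), c(x = 0, y = 0))
  expect_equal(unlist(stack_coordinates(rep(1.5, 10), ord)),
               c(x = 242, y = 242))
  # incrementing the innermost x channel (rank 9 = g_pCa) moves x by 1
  code <- rep(0.5, 10)
  code2 <- code; code2[9] <- 1.0
  xy1 <- stack_coordinates(code, ord)
  xy2 <- stack_coordinates(code2, ord)
  expect_equal(xy2$x - xy1$x, 1)
  expect_equal(xy2$y, xy1$y)
  # outermost x channel (rank 1) has stride 81
  code3 <- code; code3[1] <- 1.0
  expect_equal(stack_coordinates(code3, ord)$x - xy1$x, 81)
})

test_that("stacking is a bijection onto the pixel grid", {
  ord <- axis_order(channel_names())
  codes <- enumerate_scenarios()
  xy <- stack_coordinates(codes, ord)
  expect_true(all(xy$x >= 0 & xy$x <= 242))
  expect_true(all(xy$y >= 0 & xy$y <= 242))
  key <- xy$x * 243 + xy$y
  expect_equal(sort(key), 0:(59049 - 1))
})

test_that("the neighbor-difference objective behaves as specified", {
  expect_equal(map_objective(matrix(7, 5, 5)), 0)
  expect_equal(map_objective(matrix(c(0, 2, 1, 3), 2, 2)), 12)
  set.seed(3)
  m <- matrix(rnorm(81), 9, 9)
  expect_equal(map_objective(m), map_objective(t(m)))
  expect_gt(map_objective(m), 0)
})

test_that("grids are filled per the stride rule and validated", {
  f <- synth_scalar_field(weights = c(3, 1))
  ord <- axis_order(c("ch1", "ch2"))
  g <- build_grid(f, ord, value = "value")
  expect_equal(dim(unclass(g)), c(3, 3))
  # ch1 on x (stride 1), ch2 on y: cell (y+1, x+1) holds the matching value
  for (r in seq_len(nrow(f))) {
    xy <- stack_coordinates(as.numeric(f[r, c("level_ch1", "level_ch2")]),
                            ord)
    expect_equal(unclass(g)[xy$y + 1, xy$x + 1], f$value[r])
  }
  # constant table gives a constant grid, objective 0
  fc <- f; fc$value <- 5
  expect_equal(map_objective(build_grid(fc, ord, "value")), 0)
  # missing scenarios are an error naming absent indices
  expect_error(build_grid(f[-4, ], ord, "value"), "missing indices: 3")
})

test_that("x/y group swap leaves the objective unchanged", {
  f <- synth_scalar_field(weights = c(8, 4, 2, 1), noise_sd = 0.3, seed = 6)
  chs <- c("ch1", "ch2", "ch3", "ch4")
  for (p in list(chs, rev(chs), c("ch2", "ch4", "ch1", "ch3"))) {
    swapped <- p[c(2, 1, 4, 3)]  # exchange x- and y-axis assignments
    o1 <- map_objective(build_grid(f, axis_order(p), "value"))
    o2 <- map_objective(build_grid(f, axis_order(swapped), "value"))
    expect_equal(o1, o2)
  }
})

test_that("exhaustive optimization recovers planted sensitivity rankings", {
  # field driven by one channel only: that channel goes outermost (for two
  # channels there is a single ordering modulo the x/y swap)
  f2 <- synth_scalar_field(weights = c(5, 0.001))
  fit2 <- optimize_axis_order(f2, "value", method = "exhaustive")
  expect_equal(fit2$order$channels[1], "ch1")
  expect_equal(fit2$order$x_group, "ch1")
  expect_equal(fit2$order$y_group, "ch2")

  # additive field with weights 8 > 4 > 2 > 1 recovers the weight ordering
  # up to the x/y swap equivalence (the canonical form may be the swapped
  # interleaving, which stacks identically)
  f4 <- synth_scalar_field(weights = c(4, 8, 1, 2))
  fit4 <- optimize_axis_order(f4, "value", method = "exhaustive")
  ranking <- c("ch2", "ch1", "ch4", "ch3")
  swapped <- ranking[c(2, 1, 4, 3)]
  expect_true(identical(fit4$order$channels, ranking) ||
              identical(fit4$order$channels, swapped))
  # outermost positions carry the two largest weights
  expect_setequal(fit4$order$channels[1:2], c("ch2", "ch1"))

  # refusal above 7 channels without an explicit override
  f8 <- data.frame(matrix(0.5, 1, 8))
  names(f8) <- paste0("level_ch", 1:8)
  f8$value <- 0
  expect_error(optimize_axis_order(f8, "value", method = "exhaustive"),
               "force = TRUE")
})

test_that("the heuristic matches the exhaustive optimum on planted fields", {
  set.seed(21)
  for (i in 1:20) {
    w <- sample(c(1, 2, 4, 8) * runif(4, 0.8, 1.2))
    f <- synth_scalar_field(weights = w, noise_sd = 0.2, seed = 1000 + i)
    ex <- optimize_axis_order(f, "value", method = "exhaustive")
    he <- optimize_axis_order(f, "value", method = "heuristic",
                              seed = i, n_iter = 300)
    expect_equal(he$objective, ex$objective)
  }
})
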