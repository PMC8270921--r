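test_that("leading-eight presets match the published corner tables", {
  l3 <- leading_eight("L3")
  expect_equal(unname(l3$assessment), c(1, 0, 1, 1, 1, 0, 1, 1))
  expect_equal(unname(l3$behaviour), c(1, 0, 1, 0))
  l6 <- leading_eight("L6")
  expect_equal(unname(l6$assessment), c(1, 0, 0, 1, 1, 0, 0, 1))
  expect_equal(unname(l6$behaviour), c(1, 0, 1, 0))
  expect_identical(leading_eight("SS"), norm_table(
    leading_eight("L3")$assessment, leading_eight("L3")$behaviour,
    name = "L3"))
  expect_error(leading_eight("L9"), "valid names")
})

test_that("every leading-eight norm shares the characteristic slopes", {
  for (nm in paste0("L", 1:8)) {
    s <- norm_slopes(nm)
    expect_equal(s[["Ay"]], 1, info = nm)
    expect_equal(s[["By"]], 1, info = nm)
    expect_equal(s[["Ax"]], 0, info = nm)
    expect_equal(s[["Bx"]], 0, info = nm)
    a1C0 <- leading_eight(nm)$assessment[["a_1C0"]]
    expect_equal(s[["Az"]], 1 - a1C0, info = nm)
    expect_true(s[["Az"]] %in% c(0, 1), info = nm)
  }
})

test_that("norm_table validates its corners", {
  expect_error(norm_table(c(1, 0, 1, 1, 1, 0, 1, 2), c(1, 0, 1, 0)),
               "\\[0, 1\\]")
  expect_error(norm_table(rep(0.5, 7), rep(0.5, 4)), "8 corner values")
  shuffled <- setNames(runif(8), sample(c(
    "a_1C1", "a_1D1", "a_1C0", "a_1D0", "a_0C1", "a_0D1", "a_0C0", "a_0D0")))
  tab <- norm_table(shuffled, c(1, 0, 1, 0))
  expect_equal(tab$assessment[["a_0D1"]], shuffled[["a_0D1"]])
})

test_that("interpolated Simple Standing reduces to yz - z + 1 and beta = y", {
  ss <- interpolate_norm("L3")
  g <- expand.grid(x = seq(0, 1, 0.25), y = seq(0, 1, 0.25),
                   z = seq(0, 1, 0.25))
  expect_equal(ss$alpha(g$x, g$y, g$z), g$y * g$z - g$z + 1)
  expect_equal(ss$beta(g$x, g$y), g$y)
  expect_equal(ss$alpha(0.5, 0.5, 0.5), 0.75)
  expect_true(ss$cooperative)
})

test_that("interpolation reproduces corners exactly and stays in [0,1]", {
  set.seed(101)
  g <- expand.grid(x = seq(0, 1, 0.2), y = seq(0, 1, 0.2),
                   z = seq(0, 1, 0.2))
  for (rep in 1:10) {
    tab <- random_norm_table()
    np <- interpolate_norm(tab)
    for (u in c(0, 1)) for (v in c(0, 1)) {
      for (X in c(0, 1)) {
        key <- sprintf("a_%d%s%d", u, if (X == 1) "C" else "D", v)
        expect_equal(np$alpha(u, X, v), tab$assessment[[key]])
      }
      expect_equal(np$beta(u, v), tab$behaviour[[sprintf("b_%d%d", u, v)]])
    }
    av <- np$alpha(g$x, g$y, g$z)
    expect_true(all(av >= 0 & av <= 1))
  }
})

test_that("constant norm interpolates to the constant function", {
  one <- interpolate_norm(norm_table(rep(1, 8), rep(1, 4)))
  expect_equal(one$alpha(c(0, 0.3, 1), c(0.2, 0.5, 1), c(0.9, 0, 1)),
               rep(1, 3))
  expect_equal(one$beta(c(0, 0.4), c(1, 0.2)), rep(1, 2))
  expect_equal(unclass(norm_slopes(one)), c(Ax = 0, Ay = 0, Az = 0,
                                            Bx = 0, By = 0),
               ignore_attr = TRUE)
})

test_that("finite-difference slopes equal corner-difference slopes for
           multilinear norms", {
  set.seed(202)
  for (rep in 1:10) {
    np <- interpolate_norm(random_norm_table())
    exact <- norm_slopes(np)
    fd_np <- np
    fd_np$table <- NULL  # force the finite-difference path
    for (h in c(1e-3, 1e-6)) {
      fd <- norm_slopes(fd_np, h = h)
      expect_equal(unclass(fd), unclass(exact), tolerance = 1e-8)
    }
  }
})

test_that("slopes of specific norms are as derived", {
  expect_equal(unclass(norm_slopes("L3")),
               c(Ax = 0, Ay = 1, Az = 0, Bx = 0, By = 1),
               ignore_attr = TRUE)
  expect_equal(norm_slopes("L6")[["Az"]], 1)
  sn <- slope_norm(0.2, 0.9, 0.1, 0.2, 0.8)
  expect_equal(unclass(norm_slopes(sn)),
               c(Ax = 0.2, Ay = 0.9, Az = 0.1, Bx = 0.2, By = 0.8),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("curvatures: interpolated norms have vanishing pure second
           partials and exact mixed ones", {
  cv <- norm_curvatures("L3")
  expect_equal(cv[["Axx"]], 0)
  expect_equal(cv[["Ayy"]], 0)
  expect_equal(cv[["Azz"]], 0)
  expect_equal(cv[["Ayz"]], 1)  # 1 - 0 - 1 + 1
  expect_equal(cv[["Bxy"]], 0)  # 1 - 0 - 1 + 0
  # smooth non-multilinear norm: alpha = x y z^2, known second partials
  np <- structure(list(alpha = function(x, y, z) x * y * z^2,
                       beta = function(x, y) x * y^2,
                       table = NULL, cooperative = TRUE),
                  class = "norm_pair")
  cv2 <- norm_curvatures(np, h = 1e-4)
  expect_equal(cv2[["Azz"]], 2, tolerance = 1e-2)
  expect_equal(cv2[["Axy"]], 1, tolerance = 1e-2)
  expect_equal(cv2[["Ayz"]], 2, tolerance = 1e-2)
  expect_equal(cv2[["Byy"]], 2, tolerance = 1e-2)
  expect_equal(cv2[["Bxx"]], 0, tolerance = 1e-2)
})

test_that("mutant offsets subtract from the base norm with clamping", {
  off <- mutant_offset(delta1 = 0.02)
  mut <- offset_norm("L3", off)
  expect_equal(mut$alpha(1, 1, 1), 0.98)
  # at (1, 0, 1) the offset is -delta1 and base alpha is 0, so the mutant
  # assigns a slightly positive reputation
  expect_equal(off$delta(1, 0, 1), -0.02)
  expect_equal(mut$alpha(1, 0, 1), 0.02)
  # offset derivatives at the cooperative point: only the action slope
  expect_equal(unname(off$dpart), c(0, 0.04, 0), tolerance = 1e-8)
  # zero offset leaves the norm unchanged on a grid
  null_mut <- offset_norm("L3", mutant_offset(delta1 = 0, eta1 = 0))
  g <- expand.grid(x = seq(0, 1, 0.5), y = seq(0, 1, 0.5),
                   z = seq(0, 1, 0.5))
  base <- interpolate_norm("L3")
  expect_equal(null_mut$alpha(g$x, g$y, g$z), base$alpha(g$x, g$y, g$z))
  expect_error(mutant_offset(delta1 = -0.1), "non-negative")
  expect_warning(mutant_offset(delta1 = 0.5), "magnitude")
})

test_that("clamping is applied at evaluation but raw offsets are kept", {
  off <- mutant_offset(delta1 = 0.1, eta1 = 0.1,
                       delta = function(x, y, z) 0.1 + 0 * x,
                       eta = function(x, y) 0.1 + 0 * x)
  mut <- offset_norm("L3", off)
  expect_equal(mut$alpha(1, 0, 1), 0)        # clamped at 0
  expect_equal(mut$alpha_raw(1, 0, 1), -0.1) # raw kept for analysis
})

test_that("random corner norms are seeded, cooperative, and recover L3 when
           forced to its corners", {
  n1 <- random_corner_norm(seed = 99)
  n2 <- random_corner_norm(seed = 99)
  expect_equal(n1$table$assessment, n2$table$assessment)
  expect_equal(n1$alpha(1, 1, 1), 1)
  expect_equal(unname(n1$table$behaviour), c(1, 0, 1, 0))
  free <- random_corner_norm(seed = 99, fix_cooperative = FALSE)
  expect_false(free$table$assessment[["a_1C1"]] == 1)
  # forcing all corners to the L3 values reproduces the closed form
  forced <- interpolate_norm(norm_table(leading_eight("L3")$assessment,
                                        leading_eight("L3")$behaviour))
  g <- expand.grid(x = seq(0, 1, 0.25), y = seq(0, 1, 0.25),
                   z = seq(0, 1, 0.25))
  expect_equal(forced$alpha(g$x, g$y, g$z), g$y * g$z - g$z + 1)
})

test_that("corner projection accepts multilinear norms and rejects others", {
  mut <- offset_norm("L3", mutant_offset(delta1 = 0.02))
  proj <- as_corner_norm(mut)
  expect_equal(proj$table$assessment[["a_1C1"]], 0.98)
  curved <- structure(list(alpha = function(x, y, z) (x * y * z)^2,
                           beta = function(x, y) x * y, table = NULL),
                      class = "norm_pair")
  expect_error(as_corner_norm(curved), "not corner-representable")
})

test_that("norm files round-trip through the key-value format", {
  tab <- norm_table(c(1, 0, 0.25, 1, 1, 0, 1, 0.5), c(1, 0, 0.75, 0),
                    name = "demo")
  path <- withr::local_tempfile(fileext = ".txt")
  write_norm(tab, path)
  back <- read_norm(path)
  expect_equal(back$assessment, tab$assessment)
  expect_equal(back$behaviour, tab$behaviour)
  expect_equal(read_norm("SS")$assessment, leading_eight("L3")$assessment)
  expect_error(read_norm("no/such/file.txt"), "neither a preset")
})
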