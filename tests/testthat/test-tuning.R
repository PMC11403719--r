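test_that("unresponsive units are identified and counted", {
  r <- cbind(c(1, 0, 2), c(0, 0, 0), c(0, 1, 0), c(0.5, 0.5, 0.5))
  ex <- exclude_unresponsive(r)
  expect_equal(ex$responsive, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(ex$fraction_unresponsive, 0.25)
})

test_that("population vector preference recovers canonical cases", {
  dirs <- rbind(c(0, 0), c(180, 0), c(0, 90), c(90, 0))
  ## respond only to the first stimulus -> preference (0, 0)
  p1 <- population_vector_preference(cbind(c(1, 0, 0, 0)), dirs)
  expect_equal(c(p1$azimuth, p1$elevation), c(0, 0))
  ## equal antipodal responses cancel -> undefined
  p2 <- population_vector_preference(cbind(c(1, 1, 0, 0)), dirs)
  expect_false(p2$defined)
  ## equal responses to orthogonal directions -> bisector (45 deg away)
  p3 <- population_vector_preference(cbind(c(1, 0, 0, 1)), dirs)
  expect_equal(p3$azimuth, 45)
  expect_equal(p3$elevation, 0)
})

test_that("tuning index spans its range and matches a brute-force evaluation", {
  set.seed(61)
  dirs <- cbind(runif(10, -180, 180), runif(10, -90, 90))
  E <- sph_to_cart(dirs[, 1], dirs[, 2])
  r <- matrix(runif(10 * 6), 10, 6)
  ti <- tuning_index(r, dirs)
  brute <- sapply(1:6, function(j) {
    num <- sqrt(sum(colSums(r[, j] * E)^2))
    den <- sum(abs(r[, j]) * sqrt(rowSums(E^2)))
    num / den
  })
  expect_equal(ti, brute, tolerance = 1e-12)
  expect_true(all(ti >= 0 & ti <= 1))
  ## single-stimulus response -> 1; antipodal cancellation -> 0
  d2 <- rbind(c(0, 0), c(180, 0))
  expect_equal(tuning_index(cbind(c(1, 0)), d2), 1)
  expect_equal(tuning_index(cbind(c(1, 1)), d2), 0, tolerance = 1e-12)
  ## scale invariance
  expect_equal(tuning_index(5 * r, dirs), ti)
})

test_that("preference difference equals the acos of the dot product", {
  set.seed(62)
  a <- matrix(rnorm(30), 10); b <- matrix(rnorm(30), 10)
  d <- preference_difference(a, b)
  brute <- sapply(1:10, function(i) {
    acos(max(-1, min(1, sum(a[i, ] * b[i, ]) /
                       sqrt(sum(a[i, ]^2) * sum(b[i, ]^2))))) * 180 / pi
  })
  expect_equal(d, brute, tolerance = 1e-9)
  expect_equal(preference_difference(rbind(c(1, 0, 0)), rbind(c(2, 0, 0))), 0)
  expect_equal(preference_difference(rbind(c(1, 0, 0)), rbind(c(0, 1, 0))), 90)
})

test_that("sparseness reproduces the hand-computed cases", {
  expect_equal(sparseness(c(1, 0, 0, 0)), 1)          # one-hot
  expect_equal(sparseness(c(2, 2, 2, 2)), 0)          # constant
  expect_equal(sparseness(c(1, 1, 0, 0)), 2 / 3)      # (1 - 1/2) / (3/4)
  expect_true(is.na(sparseness(c(0, 0))))
  expect_error(sparseness(c(-1, 1)), "non-negative")
  ## in [0, 1] for arbitrary non-negative vectors
  set.seed(63)
  for (i in 1:50) {
    s <- sparseness(runif(sample(3:30, 1))^3)
    expect_true(s >= 0 && s <= 1)
  }
})

test_that("the sparseness report averages both axes and counts exclusions", {
  r <- rbind(c(1, 0, 0), c(1, 1, 1), c(0, 0, 0))
  rep <- sparseness_report(r)
  expect_equal(rep$population$mean, mean(c(1, 0)))    # zero row excluded
  expect_equal(rep$population$n_excluded, 1)
  expect_equal(rep$fraction_unresponsive, 0)
})

test_that("axis proximity counts poles and respects the threshold", {
  ## one unit on the +lateral pole, one 31 deg away from every pole
  v31 <- sph_to_cart(31, 0)
  prefs <- rbind(c(-1, 0, 0), drop(v31))
  tab <- axis_proximity_table(prefs, "T")
  expect_equal(tab$count[tab$axis == "lateral"], 1L)
  expect_equal(sum(tab$count), 1L)
  ## brute-force scan over a synthetic population
  set.seed(64)
  P <- sph_to_cart(runif(300, -180, 180), runif(300, -90, 90))
  tabT <- axis_proximity_table(P, "T")
  brute <- function(j) sum(acos(pmin(1, abs(P[, j]))) * 180 / pi <= 30)
  expect_equal(tabT$count[tabT$axis == "lateral"], brute(1))
  expect_equal(tabT$count[tabT$axis == "fore-aft"], brute(3))
  expect_equal(tabT$count[tabT$axis == "vertical"], brute(2))
  tabR <- axis_proximity_table(P, "R")
  expect_equal(tabR$count[tabR$axis == "yaw"], brute(2))
})

test_that("RF interpolation is exact at protocol nodes and constant-preserving", {
  dirs <- protocol_dirs()
  ## constant responses -> constant surface
  surf <- interpolate_rf(rep(2.5, 514), dirs)
  expect_true(all(abs(surf$values - 2.5) < 1e-12))
  expect_equal(dim(surf$values), c(17, 33))           # 561 sample points
  ## node exactness: evaluate the mesh that contains the protocol nodes
  set.seed(65)
  r <- runif(514)
  s2 <- interpolate_rf(r, dirs, mesh_az = sort(unique(dirs[, 1])),
                       mesh_el = sort(unique(dirs[, 2][abs(dirs[, 2]) < 90])))
  for (i in sample(514, 25)) {
    if (abs(dirs[i, 2]) == 90) next
    ri <- match(dirs[i, 2], s2$elevation)
    ci <- match(dirs[i, 1], s2$azimuth)
    expect_equal(s2$values[ri, ci], r[i], tolerance = 1e-9)
  }
  ## lambert vertical coordinate is sin(elevation)
  expect_equal(surf$lambert_y, sin(surf$elevation * pi / 180))
})

test_that("a synthetic directional unit's interpolated peak sits at its preference", {
  dirs <- protocol_dirs()
  E <- sph_to_cart(dirs[, 1], dirs[, 2])
  target <- sph_to_cart(33.75, 11.25)
  r <- exp(3 * (E %*% t(target) - 1))                 # von Mises on the sphere
  surf <- interpolate_rf(drop(r), dirs)
  pk <- which(surf$values == max(surf$values), arr.ind = TRUE)[1, ]
  expect_lte(abs(wrap_angle(surf$azimuth[pk[2]] - 33.75)), 11.25)
  expect_lte(abs(surf$elevation[pk[1]] - 11.25), 11.25)
})

test_that("composite maps equal the mean of individual maps", {
  dirs <- protocol_dirs()
  set.seed(66)
  R <- matrix(runif(514 * 4), 514, 4)
  comp <- interpolate_rf(R, dirs, composite = TRUE)
  indiv <- interpolate_rf(R, dirs)
  expect_equal(comp$values, apply(indiv$values, c(1, 2), mean), tolerance = 1e-12)
})

test_that("tuning width matches the analytic half width of a synthetic unit", {
  dirs <- protocol_dirs()
  ## azimuth von Mises (concentration 3), flat in elevation (pole stimuli
  ## set to the ridge maximum): half-max crossing at ~39.77 deg of azimuth
  r <- exp(3 * (cos((dirs[, 1] - 90) * pi / 180) - 1))
  r[abs(dirs[, 2]) == 90] <- 1
  tw <- tuning_width(r, dirs)
  expect_false(tw$flagged)
  ## within ~1.5 mesh steps of the analytic value: the peak may sit anywhere
  ## on the flat ridge, adding up to one elevation step to the distance
  expect_lt(abs(tw$width - 2 * acos(1 - log(2) / 3) * 180 / pi / 2), 5.5)
  ## rescaling moves only the (tied) ridge argmax, not the width materially
  tw2 <- tuning_width(10 * r, dirs)
  expect_equal(tw2$width, tw$width, tolerance = 0.1)
  expect_true(tuning_width(rep(1, 514), dirs)$flagged)
})

test_that("peak discriminability finds the steepest point of a sinusoidal unit", {
  h <- seq(0, 345, by = 15)
  r <- 1 + sin(h * pi / 180)
  pd <- peak_discriminability(r, h)
  expect_false(pd$flagged)
  ## |d sin| peaks where cos = +-1: at 0/180/360
  expect_lt(min(abs(c(pd$heading, pd$heading - 180, pd$heading - 360))), 2)
  ## offset invariance and the constant-unit flag
  pd2 <- peak_discriminability(r + 5, h)
  expect_equal(pd2$heading, pd$heading)
  expect_true(peak_discriminability(rep(3, 24), h)$flagged)
})

test_that("the per-unit tuning summary assembles all statistics", {
  dirs <- protocol_dirs()
  E <- sph_to_cart(dirs[, 1], dirs[, 2])
  set.seed(67)
  prefs <- sph_to_cart(runif(3, -180, 180), runif(3, -45, 45))
  rt <- exp(8 * (E %*% t(prefs) - 1))
  rr <- exp(8 * (E %*% t(prefs[c(2, 3, 1), ]) - 1))
  ts <- tuning_summary(rt, rr, dirs)
  expect_equal(nrow(ts), 3)
  expect_true(all(ts$responsive))
  expect_true(all(ts$hti > 0.4 & ts$hti <= 1))
  expect_true(all(is.finite(ts$tuning_width)))
  ## recovered preferences are close to the generating ones
  rec <- sph_to_cart(ts$t_azimuth, ts$t_elevation)
  expect_lt(max(angle_between(rec, prefs)), 11.25)
})
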