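test_that("generator counting: activation probability 1 gives F x E rows", {
  m <- emitter_model(n_clusters = 2, cluster_diameter_nm = 100,
                     emitters_per_cluster = 3, frames = 50,
                     activation_prob = 1, sigma_true_nm = 0,
                     background_per_um2 = 0)
  tab <- simulate_localizations(m, seed = 1)
  expect_equal(nrow(tab), 50 * 6)
  # zero localization error: every localization sits on an emitter
  em <- attr(tab, "emitters")
  d <- sqrt((tab$x_nm - em$x_nm[tab$truth_id])^2 +
              (tab$y_nm - em$y_nm[tab$truth_id])^2)
  expect_true(all(d == 0))
  # frames are sorted in file order
  expect_true(all(diff(tab$frame) >= 0))
})

test_that("per-emitter localization scatter matches sigma_true", {
  m <- emitter_model(n_clusters = 1, cluster_diameter_nm = 0,
                     emitters_per_cluster = 1, frames = 4000,
                     activation_prob = 1, sigma_true_nm = 12,
                     background_per_um2 = 0)
  tab <- simulate_localizations(m, seed = 2)
  expect_equal(sd(tab$x_nm), 12, tolerance = 0.05)
  expect_equal(sd(tab$y_nm), 12, tolerance = 0.05)
})

test_that("localization tables round-trip through CSV", {
  tab <- simulate_localizations(emitter_model(frames = 200), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_localizations(tab, path)
  tab2 <- read_localizations(path)
  expect_equal(tab2$x_nm, tab$x_nm)
  expect_equal(tab2$frame, tab$frame)
  expect_equal(readLines(path, n = 1), "frame,x_nm,y_nm,truth_id")
})

test_that("nn_precision recovers the generator precision on sparse emitters", {
  tab <- simulate_localizations(sparse_emitter_model(sigma = 12), seed = 7)
  pe <- nn_precision(tab)
  expect_equal(pe$sigma_nm, 12, tolerance = 0.1)
  expect_gte(pe$n_pairs, 100)
  expect_true(pe$ci_nm[1] <= pe$sigma_nm && pe$sigma_nm <= pe$ci_nm[2])
})

test_that("degenerate zero-error tables give near-zero precision", {
  tab <- simulate_localizations(sparse_emitter_model(sigma = 1e-6), seed = 4)
  pe <- nn_precision(tab)
  expect_lt(pe$sigma_nm, 1)
})

test_that("nn_precision is invariant to translation and rotation", {
  tab <- simulate_localizations(sparse_emitter_model(sigma = 12,
                                                     frames = 2500), seed = 9)
  pe0 <- nn_precision(tab)
  shifted <- dplyr::mutate(tab, x_nm = x_nm + 5000, y_nm = y_nm - 2000)
  th <- 0.7
  rotated <- dplyr::mutate(tab,
                           x2 = cos(th) * x_nm - sin(th) * y_nm,
                           y2 = sin(th) * x_nm + cos(th) * y_nm,
                           x_nm = x2, y_nm = y2)
  expect_equal(nn_precision(shifted)$sigma_nm, pe0$sigma_nm, tolerance = 1e-6)
  expect_equal(nn_precision(rotated)$sigma_nm, pe0$sigma_nm, tolerance = 1e-6)
})

test_that("precision recovery is unbiased with calibrated intervals", {
  # 20 seeded replicates per sigma at a reduced frame count
  for (sig in c(5, 12, 20)) {
    est <- numeric(20); cover <- logical(20)
    for (k in 1:20) {
      tab <- simulate_localizations(sparse_emitter_model(sigma = sig,
                                                         frames = 2000),
                                    seed = 100 * sig + k)
      pe <- nn_precision(tab, seed = k)
      est[k] <- pe$sigma_nm
      cover[k] <- pe$ci_nm[1] <= sig && sig <= pe$ci_nm[2]
    }
    expect_lt(abs(mean(est) - sig) / sig, 0.1)
    expect_gte(mean(cover), 0.8)
  }
})

test_that("cluster identification recovers planted centromere-sized domains", {
  m <- emitter_model(n_clusters = 8, cluster_diameter_nm = 200,
                     emitters_per_cluster = 40, frames = 1500,
                     activation_prob = 0.01, sigma_true_nm = 12,
                     background_per_um2 = 1e-4)
  tab <- simulate_localizations(m, seed = 5)
  cr <- cluster_centromeres(tab, radius = 50, min_points = 10,
                            sigma_loc_nm = 12)
  expect_equal(nrow(cr$clusters), 8)
  expect_lt(abs(mean(cr$clusters$diameter_nm) - 200) / 200, 0.15)
  # recovered centroids match the planted centres one-to-one
  em <- attr(tab, "emitters")
  ctr <- dplyr::summarise(em, x = mean(x_nm), y = mean(y_nm),
                          .by = "cluster")
  nearest <- vapply(seq_len(8), function(k) {
    min(sqrt((cr$clusters$x_nm - ctr$x[k])^2 +
               (cr$clusters$y_nm - ctr$y[k])^2))
  }, 0)
  expect_true(all(nearest < 50))
})

test_that("single emitter yields one cluster at its position", {
  m <- emitter_model(n_clusters = 1, cluster_diameter_nm = 0,
                     emitters_per_cluster = 1, frames = 30,
                     activation_prob = 1, sigma_true_nm = 5,
                     background_per_um2 = 0)
  tab <- simulate_localizations(m, seed = 6)
  cr <- cluster_centromeres(tab, radius = 50, min_points = 1)
  expect_equal(nrow(cr$clusters), 1)
  em <- attr(tab, "emitters")
  expect_lt(sqrt((cr$clusters$x_nm - em$x_nm)^2 +
                   (cr$clusters$y_nm - em$y_nm)^2), 5)
})

test_that("sub-percolation background produces no clusters", {
  m <- emitter_model(n_clusters = 0, emitters_per_cluster = 0,
                     frames = 5000, background_per_um2 = 0.002,
                     fov_nm = 4000)
  tab <- simulate_localizations(m, seed = 8)
  expect_gt(nrow(tab), 50)
  cr <- cluster_centromeres(tab, radius = 50, min_points = 10)
  expect_equal(nrow(cr$clusters), 0)
})

test_that("cluster count is invariant to row order", {
  m <- emitter_model(n_clusters = 4, emitters_per_cluster = 20,
                     frames = 400, activation_prob = 0.02)
  tab <- simulate_localizations(m, seed = 10)
  cr1 <- cluster_centromeres(tab, radius = 50, min_points = 10)
  set.seed(1)
  tab2 <- tab[sample.int(nrow(tab)), ]
  cr2 <- cluster_centromeres(tab2, radius = 50, min_points = 10)
  expect_equal(nrow(cr2$clusters), nrow(cr1$clusters))
  expect_equal(sort(cr2$clusters$n), sort(cr1$clusters$n))
})

test_that("rendered maps bin correctly and blurring conserves intensity", {
  tab <- tibble::tibble(frame = 1L, x_nm = 105, y_nm = 42, truth_id = 1L)
  mp <- render_map(tab, pixel_nm = 10, blur_sigma_px = 0)
  expect_equal(sum(mp$intensity), 1)
  expect_equal(sum(mp$intensity > 0), 1)
  # two clusters 1 um apart remain two distinct maxima after blurring
  m <- emitter_model(n_clusters = 2, cluster_diameter_nm = 100,
                     emitters_per_cluster = 10, frames = 300,
                     activation_prob = 0.05, sigma_true_nm = 12,
                     background_per_um2 = 0, fov_nm = 2000,
                     min_separation = 1000)
  tab2 <- simulate_localizations(m, seed = 11)
  mp2 <- render_map(tab2, pixel_nm = 10, blur_sigma_px = 1)
  expect_equal(sum(mp2$intensity), nrow(tab2), tolerance = 1e-6)
  # peak finding: local maxima above half the global max form two islands
  img <- mp2$intensity
  thresh <- img > 0.2 * max(img)
  comp <- EBImage::bwlabel(EBImage::Image(thresh * 1))
  expect_equal(max(EBImage::imageData(comp)), 2)
})
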