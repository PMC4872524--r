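# Synthetic single-molecule localization (PALM) data and estimators:
# nearest-neighbour localization precision (NeNA) and density-based
# cluster identification for centromere-sized structures.
#
# Coordinates in nm throughout.

#' Synthetic emitter model for PALM acquisitions
#'
#' Emitters are grouped in circular clusters (uniform within a disc of the
#' stated diameter, emulating centromere-sized Cenpa domains); in every
#' frame each emitter is independently active with probability
#' `activation_prob`, and an active emitter yields one localization at its
#' true position plus isotropic Gaussian error `sigma_true`.  False
#' localizations are added uniformly over the field of view at
#' `background_per_um2` per frame.
#'
#' Cluster centres are laid out on a jittered grid with at least
#' `min_separation` between centres, so planted clusters stay resolvable.
#'
#' @param n_clusters number of emitter clusters.
#' @param cluster_diameter_nm cluster size (nm); 0 gives point sources.
#' @param emitters_per_cluster emitters in each cluster.
#' @param frames number of acquisition frames.
#' @param activation_prob per-frame, per-emitter activation probability.
#' @param sigma_true_nm localization error SD per coordinate (nm).
#' @param background_per_um2 false localizations per um^2 per frame.
#' @param fov_nm square field-of-view side (nm).
#' @param min_separation minimum centre-to-centre cluster distance (nm).
#' @return A list of class `emitter_model`.
#' @export
emitter_model <- function(n_clusters = 8, cluster_diameter_nm = 200,
                          emitters_per_cluster = 40, frames = 5000,
                          activation_prob = 0.01, sigma_true_nm = 12,
                          background_per_um2 = 1e-4, fov_nm = 4000,
                          min_separation = 600) {
  stopifnot(n_clusters >= 0, cluster_diameter_nm >= 0, frames >= 1,
            activation_prob >= 0, activation_prob <= 1, sigma_true_nm >= 0,
            background_per_um2 >= 0)
  structure(as.list(environment()), class = "emitter_model")
}

# jittered-grid cluster centres with guaranteed separation
place_clusters <- function(n, fov, min_sep) {
  if (n == 0) return(matrix(numeric(), 0, 2))
  g <- ceiling(sqrt(n))
  pitch <- fov / g
  if (pitch < min_sep) min_sep <- 0.8 * pitch
  centres <- expand.grid(i = seq_len(g), j = seq_len(g))[seq_len(n), ]
  jit <- (pitch - min_sep) / 2
  cbind(
    (centres$i - 0.5) * pitch + stats::runif(n, -jit, jit),
    (centres$j - 0.5) * pitch + stats::runif(n, -jit, jit)
  )
}

#' Simulate a localization table from an emitter model
#'
#' @param model an [emitter_model()].
#' @param seed RNG seed.
#' @return A tibble of class `localization_table`: `frame`, `x_nm`, `y_nm`,
#'   `truth_id` (emitter index, `NA` for background), sorted by frame.
#'   Ground-truth emitter positions are attached as
#'   `attr(, "emitters")`.
#' @export
simulate_localizations <- function(model, seed = 1L) {
  stopifnot(inherits(model, "emitter_model"))
  set.seed(seed)
  ctr <- place_clusters(model$n_clusters, model$fov_nm, model$min_separation)
  E <- model$n_clusters * model$emitters_per_cluster
  if (E > 0) {
    # uniform in a disc of the cluster diameter
    th <- stats::runif(E, 0, 2 * pi)
    rad <- model$cluster_diameter_nm / 2 * sqrt(stats::runif(E))
    cl <- rep(seq_len(model$n_clusters), each = model$emitters_per_cluster)
    ex <- ctr[cl, 1] + rad * cos(th)
    ey <- ctr[cl, 2] + rad * sin(th)
  } else {
    ex <- ey <- numeric(); cl <- integer()
  }
  emitters <- tibble::tibble(truth_id = seq_len(E), cluster = cl,
                             x_nm = ex, y_nm = ey)

  # activations: E x frames Bernoulli draws, kept sparse
  act <- which(matrix(stats::runif(E * model$frames) < model$activation_prob,
                      E, model$frames), arr.ind = TRUE)
  n_loc <- nrow(act)
  loc <- tibble::tibble(
    frame = act[, 2],
    x_nm = ex[act[, 1]] + stats::rnorm(n_loc, 0, model$sigma_true_nm),
    y_nm = ey[act[, 1]] + stats::rnorm(n_loc, 0, model$sigma_true_nm),
    truth_id = act[, 1]
  )
  n_bg <- stats::rpois(1, model$background_per_um2 * (model$fov_nm / 1000)^2 *
                         model$frames)
  if (n_bg > 0) {
    bg <- tibble::tibble(
      frame = sample.int(model$frames, n_bg, replace = TRUE),
      x_nm = stats::runif(n_bg, 0, model$fov_nm),
      y_nm = stats::runif(n_bg, 0, model$fov_nm),
      truth_id = NA_integer_
    )
    loc <- dplyr::bind_rows(loc, bg)
  }
  out <- dplyr::arrange(loc, .data$frame)
  out <- tibble::new_tibble(out, class = "localization_table")
  attr(out, "emitters") <- emitters
  attr(out, "model") <- model
  out
}

#' Read / write localization tables as CSV
#'
#' Plain CSV with header `frame,x_nm,y_nm[,truth_id]`; extra columns are
#' tolerated and kept.
#'
#' @param path file path.
#' @param table a localization table.
#' @return `read_localizations()` returns a `localization_table` tibble.
#' @export
read_localizations <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("frame", "x_nm", "y_nm")
  if (!all(need %in% names(tab))) {
    rlang::abort("localization CSV needs columns frame, x_nm, y_nm",
                 class = "traploop_invalid_argument")
  }
  if (any(tab$frame < 0) || any(!is.finite(tab$x_nm)) || any(!is.finite(tab$y_nm))) {
    rlang::abort("localizations must have non-negative frames and finite coordinates",
                 class = "traploop_invalid_argument")
  }
  tibble::new_tibble(dplyr::arrange(tab, .data$frame),
                     class = "localization_table")
}

#' @rdname read_localizations
#' @export
write_localizations <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

# nearest-neighbour distances between localizations in adjacent frames
adjacent_frame_nn <- function(table, max_pair_distance) {
  sp <- split(data.frame(x = table$x_nm, y = table$y_nm), table$frame)
  fr <- as.integer(names(sp))
  out <- vector("list", length(fr))
  for (k in seq_along(fr)) {
    nxt <- match(fr[k] + 1L, fr)
    if (is.na(nxt)) next
    a <- sp[[k]]; b <- sp[[nxt]]
    if (!nrow(a) || !nrow(b)) next
    d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2
    nn <- sqrt(matrixStats_rowMins(d2))
    out[[k]] <- nn[nn <= max_pair_distance]
  }
  unlist(out)
}

matrixStats_rowMins <- function(m) {
  # row minima without extra deps
  do.call(pmin, c(asplit(m, 2), list(na.rm = TRUE)))
}

# negative log-likelihood of the NeNA mixture on [0, R]:
# same-emitter displacements: Rayleigh(scale s = sqrt(2) sigma), truncated;
# false pairs: uniform in the plane, i.e. density proportional to r
nena_nll <- function(par, r, R) {
  s <- exp(par[1])
  w <- stats::plogis(par[2])
  p_ray <- (r / s^2) * exp(-r^2 / (2 * s^2)) / (1 - exp(-R^2 / (2 * s^2)))
  p_bg <- 2 * r / R^2
  -sum(log(pmax(w * p_ray + (1 - w) * p_bg, 1e-300)))
}

fit_nena <- function(r, R, sigma_start = 15) {
  fit <- stats::optim(c(log(sqrt(2) * sigma_start), 0), nena_nll, r = r, R = R,
                      method = "Nelder-Mead")
  c(sigma = exp(fit$par[1]) / sqrt(2), weight = stats::plogis(fit$par[2]))
}

#' Nearest-neighbour localization precision (NeNA)
#'
#' Estimates the localization precision from nearest-neighbour distances
#' between localizations in adjacent frames: a molecule localized in two
#' consecutive frames yields a 2-D displacement whose length is Rayleigh
#' distributed with scale sqrt(2) x sigma, while false pairs contribute a
#' background rising linearly with distance.  The two-component mixture is
#' fit by maximum likelihood on all pair distances below
#' `max_pair_distance`; the confidence interval is a nonparametric
#' bootstrap over pairs.
#'
#' The estimator assumes sparse activation: in densely active clusters the
#' nearest adjacent-frame neighbour is usually a *different* molecule of
#' the same cluster and the same-emitter signal is swamped.
#'
#' @param table a localization table (tibble with `frame`, `x_nm`, `y_nm`).
#' @param max_pair_distance pairing window (nm).
#' @param boot bootstrap replicates for the CI.
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `precision_estimate`: `sigma_nm`, `ci_nm`,
#'   `n_pairs`, `background_weight`.
#' @export
nn_precision <- function(table, max_pair_distance = 100, boot = 100,
                         conf = 0.9, seed = 1L) {
  if (length(unique(table$frame)) < 2) {
    rlang::abort("need localizations in at least two frames",
                 class = "traploop_estimation_error")
  }
  r <- adjacent_frame_nn(table, max_pair_distance)
  if (length(r) < 100) {
    rlang::abort(sprintf(
      "only %d candidate pairs within %g nm (need >= 100): too sparse",
      length(r), max_pair_distance), class = "traploop_estimation_error")
  }
  est <- fit_nena(r, max_pair_distance)
  set.seed(seed)
  bs <- replicate(boot, {
    fit_nena(r[sample.int(length(r), replace = TRUE)], max_pair_distance,
             sigma_start = max(est["sigma"], 1))["sigma"]
  })
  ci <- unname(stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  structure(list(
    sigma_nm = unname(est["sigma"]),
    ci_nm = ci, conf = conf,
    n_pairs = length(r),
    background_weight = unname(1 - est["weight"]),
    pair_distances = r
  ), class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf("<precision_estimate> sigma = %.2f nm (%d%% CI %.2f-%.2f), %d pairs, %.0f%% false-pair weight\n",
              x$sigma_nm, round(100 * x$conf), x$ci_nm[1], x$ci_nm[2],
              x$n_pairs, 100 * x$background_weight))
  invisible(x)
}

#' @method tidy precision_estimate
#' @export
tidy.precision_estimate <- function(x, ...) {
  tibble::tibble(sigma_nm = x$sigma_nm, ci_lo_nm = x$ci_nm[1],
                 ci_hi_nm = x$ci_nm[2], n_pairs = x$n_pairs,
                 background_weight = x$background_weight)
}

#' @method glance precision_estimate
#' @export
glance.precision_estimate <- function(x, ...) tidy(x)

# exact fixed-radius connected components via union-find on spatial bins
radius_components <- function(x, y, radius) {
  n <- length(x)
  if (n == 0) return(integer())
  w <- radius / sqrt(2)            # same-bin points are always linked
  bx <- floor(x / w); by <- floor(y / w)
  key <- paste(bx, by)
  bin <- match(key, unique(key))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  # link all points within each bin to the bin's first point
  firsts <- tapply(seq_len(n), bin, `[`, 1L)
  for (i in seq_len(n)) if (firsts[bin[i]] != i) union_(firsts[bin[i]], i)
  # candidate bin pairs within reach: offsets up to 2 bins
  binpts <- split(seq_len(n), bin)
  bkey <- do.call(rbind, strsplit(unique(key), " "))
  bxi <- as.numeric(bkey[, 1]); byi <- as.numeric(bkey[, 2])
  binmap <- new.env(hash = TRUE)
  for (b in seq_along(bxi)) assign(paste(bxi[b], byi[b]), b, envir = binmap)
  offsets <- expand.grid(di = -2:2, dj = -2:2)
  offsets <- offsets[offsets$di > 0 | (offsets$di == 0 & offsets$dj > 0), ]
  for (b in seq_along(bxi)) {
    for (o in seq_len(nrow(offsets))) {
      nb <- mget(paste(bxi[b] + offsets$di[o], byi[b] + offsets$dj[o]),
                 envir = binmap, ifnotfound = list(NULL))[[1]]
      if (is.null(nb)) next
      ia <- binpts[[b]]; ib <- binpts[[nb]]
      # all points of a bin share one component (same-bin pre-union), so
      # one root comparison decides whether this pair can contribute
      if (find(ia[1]) == find(ib[1])) next
      d2 <- outer(x[ia], x[ib], "-")^2 + outer(y[ia], y[ib], "-")^2
      hit <- which(d2 <= radius^2, arr.ind = TRUE)
      if (nrow(hit)) {
        for (h in seq_len(nrow(hit))) union_(ia[hit[h, 1]], ib[hit[h, 2]])
      }
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  match(comp, unique(comp))
}

#' Identify localization clusters (centromere-sized domains)
#'
#' Density-based clustering: two localizations are connected if within
#' `radius`; clusters are connected components with at least `min_points`
#' members.  The cluster diameter is reported as the Gaussian-equivalent
#' full width 2 sqrt(2) x RMS distance to the centroid, with the
#' localization error removed in quadrature (RMS^2 - 2 sigma_loc^2, one
#' sigma_loc per coordinate).
#'
#' @param table a localization table.
#' @param radius linkage radius (nm).
#' @param min_points minimum localizations per reported cluster.
#' @param sigma_loc_nm localization precision used for the quadrature
#'   correction (e.g. from [nn_precision()]); 0 disables it.
#' @return Object of class `cluster_report`; `tidy()` gives the per-cluster
#'   table (centroid, count, diameter estimate).
#' @export
cluster_centromeres <- function(table, radius = 50, min_points = 10,
                                sigma_loc_nm = 0) {
  if (!nrow(table)) {
    return(structure(list(clusters = tibble::tibble(
      cluster = integer(), x_nm = numeric(), y_nm = numeric(),
      n = integer(), diameter_nm = numeric()),
      radius = radius, min_points = min_points), class = "cluster_report"))
  }
  comp <- radius_components(table$x_nm, table$y_nm, radius)
  df <- tibble::tibble(comp = comp, x = table$x_nm, y = table$y_nm)
  cl <- df |>
    dplyr::summarise(n = dplyr::n(), x_nm = mean(.data$x), y_nm = mean(.data$y),
                     ms = mean((.data$x - mean(.data$x))^2 +
                                 (.data$y - mean(.data$y))^2),
                     .by = "comp") |>
    dplyr::filter(.data$n >= min_points) |>
    dplyr::arrange(dplyr::desc(.data$n))
  cl <- dplyr::mutate(
    cl,
    diameter_nm = 2 * sqrt(2) * sqrt(pmax(.data$ms - 2 * sigma_loc_nm^2, 0)),
    cluster = dplyr::row_number()) |>
    dplyr::select("cluster", "x_nm", "y_nm", "n", "diameter_nm")
  structure(list(clusters = cl, radius = radius, min_points = min_points,
                 sigma_loc_nm = sigma_loc_nm), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %d clusters (radius %g nm, >= %d points)\n",
              nrow(x$clusters), x$radius, x$min_points))
  if (nrow(x$clusters)) {
    cat(sprintf("  mean diameter %.0f nm, mean %d localizations\n",
                mean(x$clusters$diameter_nm), round(mean(x$clusters$n))))
  }
  invisible(x)
}

#' @method tidy cluster_report
#' @export
tidy.cluster_report <- function(x, ...) x$clusters

#' @method glance cluster_report
#' @export
glance.cluster_report <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters),
                 mean_diameter_nm = mean(x$clusters$diameter_nm),
                 mean_points = mean(x$clusters$n),
                 radius = x$radius, min_points = x$min_points)
}

#' Render a localization map
#'
#' 2-D histogram of localizations at the stated pixel size, optionally
#' blurred with a Gaussian kernel.  The grid is padded so that blurring
#' conserves total intensity.
#'
#' @param table a localization table.
#' @param pixel_nm pixel size (nm).
#' @param blur_sigma_px Gaussian blur SD in pixels (0 = none).
#' @return A list of class `palm_map`: `intensity` matrix, `pixel_nm`,
#'   `origin_nm`.
#' @export
render_map <- function(table, pixel_nm = 10, blur_sigma_px = 1) {
  stopifnot(pixel_nm > 0, blur_sigma_px >= 0)
  pad <- ceiling(6 * max(blur_sigma_px, 1))
  x0 <- min(table$x_nm) - pad * pixel_nm
  y0 <- min(table$y_nm) - pad * pixel_nm
  ix <- floor((table$x_nm - x0) / pixel_nm) + 1L
  iy <- floor((table$y_nm - y0) / pixel_nm) + 1L
  nx <- max(ix) + pad; ny <- max(iy) + pad
  img <- matrix(tabulate(ix + (iy - 1L) * nx, nbins = nx * ny), nx, ny)
  if (blur_sigma_px > 0) {
    half <- ceiling(6 * blur_sigma_px)
    k <- stats::dnorm(-half:half, sd = blur_sigma_px)
    k <- k / sum(k)
    img <- apply(img, 2, function(col) stats::filter(c(rep(0, half), col, rep(0, half)), k,
                                                     sides = 2)[half + seq_along(col)])
    img <- t(apply(img, 1, function(row) stats::filter(c(rep(0, half), row, rep(0, half)), k,
                                                       sides = 2)[half + seq_along(row)]))
  }
  structure(list(intensity = img, pixel_nm = pixel_nm, origin_nm = c(x0, y0)),
            class = "palm_map")
}

#' @export
print.palm_map <- function(x, ...) {
  cat(sprintf("<palm_map> %d x %d px at %g nm/px, total intensity %.4g\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_nm,
              sum(x$intensity)))
  invisible(x)
}

#' @method tidy palm_map
#' @export
tidy.palm_map <- function(x, ...) {
  tibble::tibble(
    x_nm = x$origin_nm[1] + (rep(seq_len(nrow(x$intensity)), times = ncol(x$intensity)) - 0.5) * x$pixel_nm,
    y_nm = x$origin_nm[2] + (rep(seq_len(ncol(x$intensity)), each = nrow(x$intensity)) - 0.5) * x$pixel_nm,
    intensity = as.vector(x$intensity)
  )
}
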