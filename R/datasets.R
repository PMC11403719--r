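#' Optic-flow dataset container
#'
#' A `flow_dataset` bundles `n` instantaneous optic-flow fields with their
#' self-motion labels and generation metadata.  The flow is stored as two
#' `n x p` matrices `u` and `v` (`p = grid_size^2` image points, camera
#' grid order); `labels` is an `n x 5` matrix with columns `t_azimuth`,
#' `t_elevation` (deg), `r_pitch`, `r_yaw`, `r_roll` (deg/s); `split` tags
#' each sample `"train"`, `"validation"` or `"test"` (or `NA` for
#' diagnostic sets).
#'
#' @param name Dataset name.
#' @param u,v Flow component matrices (cm/s).
#' @param labels `n x 5` label matrix.
#' @param split Optional character vector of split tags.
#' @param camera The [camera_model()] used.
#' @param meta List of generation metadata (seed, scene parameters, ...).
#' @return An object of class `"flow_dataset"`.
#' @export
flow_dataset <- function(name, u, v, labels, split = NULL, camera = camera_model(),
                         meta = list()) {
  stopifnot(is.matrix(u), is.matrix(v), all(dim(u) == dim(v)),
            nrow(labels) == nrow(u), ncol(labels) == 5)
  colnames(labels) <- c("t_azimuth", "t_elevation", "r_pitch", "r_yaw", "r_roll")
  structure(list(name = name, u = u, v = v, labels = labels,
                 split = split, camera = camera, meta = meta),
            class = "flow_dataset")
}

#' @export
print.flow_dataset <- function(x, ...) {
  cat(sprintf("Optic-flow dataset '%s': %d samples on a %d x %d grid\n",
              x$name, nrow(x$u), x$camera$grid_size, x$camera$grid_size))
  if (!is.null(x$split)) print(table(x$split))
  invisible(x)
}

#' Number of samples in a flow dataset
#' @param x A `flow_dataset`.
#' @param ... Unused.
#' @return Integer sample count.
#' @export
nsamples <- function(x, ...) UseMethod("nsamples")

#' @export
nsamples.flow_dataset <- function(x, ...) nrow(x$u)

#' Subset a flow dataset by sample index or split tag
#' @param x A `flow_dataset`.
#' @param i Integer/logical index, or one of `"train"`, `"validation"`,
#'   `"test"` to select a split.
#' @param ... Unused.
#' @export
`[.flow_dataset` <- function(x, i, ...) {
  if (is.character(i) && length(i) == 1 && !is.null(x$split)) i <- which(x$split == i)
  flow_dataset(x$name, x$u[i, , drop = FALSE], x$v[i, , drop = FALSE],
               x$labels[i, , drop = FALSE],
               split = if (!is.null(x$split)) x$split[i],
               camera = x$camera, meta = x$meta)
}

## internal: stack flow fields for a table of motions
flow_matrix <- function(Tm, Rm, depth_list, camera) {
  n <- nrow(Tm)
  p <- length(camera$x)
  u <- matrix(0, n, p); v <- matrix(0, n, p)
  for (i in seq_len(n)) {
    ff <- optic_flow(Tm[i, ], Rm[i, ], depth_list[[i]], camera)
    u[i, ] <- ff$u; v[i, ] <- ff$v
  }
  list(u = u, v = v)
}

#' Generate the TR360 dataset: full-sphere translation and rotation
#'
#' Simulated self-motion toward a frontoparallel plane (half of the
#' samples) or over a ground plane (the other half).  Translation speed
#' (m/s), rotation speed (deg/s) and frontoparallel depth (m) are crossed
#' factorially and the crossing is replicated to reach the target count;
#' translation and rotation *directions* are drawn uniformly anew for
#' every sample, azimuth on `[-180, 180)` and elevation on `[-90, 90]`.
#' Samples are shuffled and tagged with a 50/25/25 train/validation/test
#' split (6,030/3,015/3,015 at the default size of 12,060).
#'
#' @param seed Integer RNG seed; recorded in `meta`.
#' @param t_speeds,r_speeds,depths Factorial condition levels.
#' @param n_frontoparallel,n_ground Sample counts per scene type; each
#'   must be a multiple of its factorial cell count.
#' @param camera A [camera_model()].
#' @return A [flow_dataset()] named `"TR360"`.
#' @examples
#' ds <- make_tr360(seed = 1, n_frontoparallel = 45, n_ground = 9)
#' table(ds$split)
#' @export
make_tr360 <- function(seed = 1,
                       t_speeds = c(0.5, 1, 1.5),
                       r_speeds = c(0, 5, 10),
                       depths = c(2, 4, 8, 16, 32),
                       n_frontoparallel = 6030,
                       n_ground = 6030,
                       camera = camera_model()) {
  cell_fp <- length(t_speeds) * length(r_speeds) * length(depths)
  cell_gr <- length(t_speeds) * length(r_speeds)
  if (n_frontoparallel %% cell_fp != 0 || n_ground %% cell_gr != 0)
    stop("sample counts must be multiples of the factorial cell counts")
  cond_fp <- expand.grid(t = t_speeds, r = r_speeds, d = depths)
  cond_gr <- expand.grid(t = t_speeds, r = r_speeds, d = NA_real_)
  cond <- rbind(cond_fp[rep(seq_len(cell_fp), n_frontoparallel / cell_fp), ],
                cond_gr[rep(seq_len(cell_gr), n_ground / cell_gr), ])
  n <- nrow(cond)
  set.seed(seed)
  t_az <- stats::runif(n, -180, 180); t_el <- stats::runif(n, -90, 90)
  r_az <- stats::runif(n, -180, 180); r_el <- stats::runif(n, -90, 90)
  Tm <- sph_to_cart(t_az, t_el) * cond$t
  Rm <- sph_to_cart(r_az, r_el) * cond$r
  Z_ground <- depth_map(ground_scene(), camera)
  depth_list <- lapply(seq_len(n), function(i)
    if (is.na(cond$d[i])) Z_ground else rep(cond$d[i], length(camera$x)))
  fl <- flow_matrix(Tm, Rm, depth_list, camera)
  labels <- cbind(t_az, t_el, Rm)
  idx <- sample.int(n)
  n_train <- round(n / 2); n_val <- round(n / 4)
  split <- rep(c("train", "validation", "test"),
               c(n_train, n_val, n - n_train - n_val))
  flow_dataset("TR360", fl$u[idx, ], fl$v[idx, ], labels[idx, ],
               split = split, camera = camera,
               meta = list(seed = seed, t_speeds = t_speeds,
                           r_speeds = r_speeds, depths = depths,
                           scene = cond$d[idx]))
}

#' Generate the Ben Hamed translation / rotation test sets
#'
#' Pure-translation (`kind = "T"`) or pure-rotation (`kind = "R"`)
#' optic flow toward a frontoparallel plane, emulating the restricted
#' stimuli of classic MSTd decoding studies.  The translation set draws
#' heading directions uniformly within 45 degrees of straight-ahead in
#' both azimuth and elevation, with observer speed uniform on
#' `[0.5, 2]` m/s.  The rotation set combines pitch and yaw only (no
#' roll), with the rotation-axis direction uniform in the pitch-yaw plane
#' and net speed uniform on `[0, 10]` deg/s.  Frontoparallel depths
#' `{1, 2, 4, 8}` m are crossed with replication.
#'
#' @param kind `"T"` or `"R"`.
#' @param seed Integer RNG seed.
#' @param n Number of samples (default 10,000; must be a multiple of the
#'   number of depths).
#' @param depths Frontoparallel plane depths (m).
#' @param camera A [camera_model()].
#' @return A [flow_dataset()] named `"BenHamedT"` or `"BenHamedR"`.
#' @export
make_benhamed <- function(kind = c("T", "R"), seed = 1, n = 10000,
                          depths = c(1, 2, 4, 8), camera = camera_model()) {
  kind <- match.arg(kind)
  if (n %% length(depths) != 0) stop("n must be a multiple of the number of depths")
  d <- rep(depths, n / length(depths))
  set.seed(seed)
  if (kind == "T") {
    az <- 90 + stats::runif(n, -45, 45)     # straight-ahead is azimuth 90
    el <- stats::runif(n, -45, 45)
    spd <- stats::runif(n, 0.5, 2)
    Tm <- sph_to_cart(az, el) * spd
    Rm <- matrix(0, n, 3)
    labels <- cbind(az, el, Rm)
  } else {
    phi <- stats::runif(n, 0, 2 * pi)       # axis direction in the pitch-yaw plane
    spd <- stats::runif(n, 0, 10)
    Rm <- cbind(spd * cos(phi), spd * sin(phi), 0)
    Tm <- matrix(0, n, 3)
    labels <- cbind(0, 0, Rm)
  }
  depth_list <- lapply(d, function(di) rep(di, length(camera$x)))
  fl <- flow_matrix(Tm, Rm, depth_list, camera)
  flow_dataset(paste0("BenHamed", kind), fl$u, fl$v, labels,
               camera = camera,
               meta = list(seed = seed, kind = kind, depths = depths,
                           depth_of_sample = d))
}

## internal: the 514 diagnostic directions (32 azimuths x 16 elevations + 2 poles)
protocol_directions <- function() {
  az <- seq(-180, 180 - 11.25, by = 11.25)                 # 32 azimuths
  el <- seq(-90 + 5.625, 90 - 5.625, by = 11.25)           # 16 elevations
  g <- expand.grid(azimuth = az, elevation = el, KEEP.OUT.ATTRS = FALSE)
  rbind(as.matrix(g), cbind(azimuth = c(0, 0), elevation = c(-90, 90)))
}

#' Generate the deterministic tuning test protocols
#'
#' 514 diagnostic optic-flow stimuli: 512 regular combinations of azimuth
#' (32 values, 11.25 degree steps around the full circle) and elevation
#' (16 values, an 11.25 degree ladder symmetric about the horizontal and
#' excluding the poles), plus the two vertical poles.  `kind = "T"` gives
#' pure translation in each direction; `kind = "R"` pure rotation about
#' each axis direction.  The protocol is deterministic: no randomness is
#' involved.
#'
#' @param kind `"T"` or `"R"`.
#' @param t_speed Translation speed (m/s) for the T protocol.
#' @param r_speed Rotation speed (deg/s) for the R protocol.
#' @param depth Frontoparallel scene depth (m).
#' @param camera A [camera_model()].
#' @return A [flow_dataset()] named `"TestProtocolT"` or
#'   `"TestProtocolR"`.
#' @examples
#' tp <- make_test_protocol("T")
#' nsamples(tp)  # 514
#' @export
make_test_protocol <- function(kind = c("T", "R"), t_speed = 1, r_speed = 5,
                               depth = 4, camera = camera_model()) {
  kind <- match.arg(kind)
  dirs <- protocol_directions()
  n <- nrow(dirs)
  E <- sph_to_cart(dirs[, "azimuth"], dirs[, "elevation"])
  if (kind == "T") {
    Tm <- E * t_speed; Rm <- matrix(0, n, 3)
    labels <- cbind(dirs[, "azimuth"], dirs[, "elevation"], Rm)
  } else {
    Rm <- E * r_speed; Tm <- matrix(0, n, 3)
    labels <- cbind(dirs[, "azimuth"], dirs[, "elevation"], Rm)
  }
  depth_list <- rep(list(rep(depth, length(camera$x))), n)
  fl <- flow_matrix(Tm, Rm, depth_list, camera)
  flow_dataset(paste0("TestProtocol", kind), fl$u, fl$v, labels,
               camera = camera,
               meta = list(kind = kind, t_speed = t_speed, r_speed = r_speed,
                           depth = depth, directions = dirs))
}

#' Read and write flow datasets
#'
#' Datasets are serialized with R's native RDS format, which round-trips
#' all fields and labels bit-exactly.  [write_labels_csv()] additionally
#' exports the label matrix as CSV for use outside R.
#'
#' @param x A `flow_dataset`.
#' @param path File path.
#' @return `read_flow_dataset()` returns the restored `flow_dataset`;
#'   the writers return `path` invisibly.
#' @export
write_flow_dataset <- function(x, path) {
  stopifnot(inherits(x, "flow_dataset"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_flow_dataset
#' @export
read_flow_dataset <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "flow_dataset")) stop("file does not contain a flow_dataset")
  x
}

#' @rdname write_flow_dataset
#' @export
write_labels_csv <- function(x, path) {
  stopifnot(inherits(x, "flow_dataset"))
  utils::write.csv(as.data.frame(x$labels), path, row.names = FALSE)
  invisible(path)
}
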