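#' Normalize a raw intensity vector to a unit-rate Poisson code
#'
#' Input samples are rate-coded: each channel of the sample drives an
#' independent Poisson spike train whose rate is proportional to the raw
#' intensity. Because the datasets of interest are magnitude-insensitive
#' (class identity lives in the direction of the vector, not its length),
#' the rate vector is L2-normalized to a total magnitude of one spike per
#' time unit; all timing constants in the simulator are relative to that
#' unit.
#'
#' @param raw Numeric vector of non-negative intensities with at least one
#'   strictly positive component.
#' @return Numeric vector of the same length with L2 norm 1, proportional to
#'   `raw`.
#' @examples
#' normalize_rates(c(3, 4))   # c(0.6, 0.8)
#' @export
normalize_rates <- function(raw) {
  if (!is.numeric(raw) || length(raw) == 0L) {
    stop("`raw` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(raw)) || any(raw < 0)) {
    stop("`raw` must be finite and non-negative", call. = FALSE)
  }
  nrm <- sqrt(sum(raw^2))
  if (nrm == 0) {
    stop("silent sample: all-zero intensity vector cannot be rate-coded",
         call. = FALSE)
  }
  raw / nrm
}

#' Draw one exponential interarrival time for a Poisson spike train
#'
#' @param rate Spike rate (spikes per time unit), `>= 0`. A silent channel
#'   (`rate == 0`) never spikes and returns `Inf`.
#' @return A single interarrival time. Uses the R random number generator,
#'   so results are reproducible under [set.seed()].
#' @export
sample_interarrival <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0) {
    stop("`rate` must be a single non-negative number", call. = FALSE)
  }
  if (rate == 0) return(Inf)
  stats::rexp(1L, rate = rate)
}

#' Draw the next input spike from a multi-channel Poisson process
#'
#' The superposition of independent Poisson channels is itself Poisson with
#' rate `sum(rates)`; the spiking channel is categorical with probabilities
#' `rates / sum(rates)`. This is the draw the event-driven simulator makes
#' between events instead of stepping time on a grid.
#'
#' @param rates Non-negative numeric vector of per-channel rates with at
#'   least one positive entry.
#' @return List with `dt` (time until the spike) and `channel` (1-based
#'   index of the spiking channel).
#' @export
next_input_event <- function(rates) {
  if (any(rates < 0) || !any(rates > 0)) {
    stop("`rates` must be non-negative with at least one positive entry",
         call. = FALSE)
  }
  total <- sum(rates)
  list(
    dt = stats::rexp(1L, rate = total),
    channel = sample.int(length(rates), 1L, prob = rates)
  )
}

#' Escalate input firing rates by a multiplicative factor
#'
#' During inference (and during training of the non-dopaminergic baselines)
#' a sample that fails to elicit enough output spikes within a recognition
#' window has its firing rates increased and is presented again; the
#' direction of the rate vector is preserved, only its magnitude grows.
#'
#' @param rates Numeric rate vector.
#' @param step Number of escalation steps applied (`>= 0`).
#' @param factor Multiplicative escalation factor per step.
#' @return `rates * factor^step`.
#' @export
escalate_rates <- function(rates, step, factor = 1.5) {
  if (length(step) != 1L || is.na(step) || step < 0) {
    stop("`step` must be a single non-negative count", call. = FALSE)
  }
  rates * factor^step
}

idx_magic <- c(images = 2051L, labels = 2049L)

open_idx_connection <- function(path) {
  head <- readBin(path, "raw", n = 2L)
  if (length(head) == 2L && head[1] == as.raw(0x1f) && head[2] == as.raw(0x8b)) {
    gzfile(path, "rb")
  } else {
    file(path, "rb")
  }
}

#' Read an IDX-format array file (MNIST layout)
#'
#' Reads the big-endian IDX container used by the MNIST distribution:
#' magic number 2051 (`0x00000803`) for unsigned-byte image tensors and
#' 2049 (`0x00000801`) for label vectors. Gzipped files are detected from
#' their magic bytes and decompressed transparently.
#'
#' @param path Path to an `.idx`/`.idx.gz`-style file.
#' @param what Either `"images"` or `"labels"`; the file's magic number must
#'   match.
#' @return For images, an integer matrix with one flattened image per row
#'   (values 0-255) with attribute `dims` holding the original row/column
#'   counts; for labels, an integer vector.
#' @seealso [write_idx()], [read_idx_dataset()]
#' @export
read_idx <- function(path, what = c("images", "labels")) {
  what <- match.arg(what)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- open_idx_connection(path)
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (length(magic) != 1L) {
    stop("IDX format error at offset 0: truncated magic number in ", path,
         call. = FALSE)
  }
  if (magic != idx_magic[[what]]) {
    stop(sprintf(
      "IDX format error at offset 0: magic %d does not match expected %d for %s",
      magic, idx_magic[[what]], what), call. = FALSE)
  }
  if (what == "labels") {
    n <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    payload <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
    if (length(payload) != n) {
      stop(sprintf("IDX format error at offset %d: expected %d labels, got %d",
                   8L, n, length(payload)), call. = FALSE)
    }
    payload
  } else {
    hdr <- readBin(con, "integer", n = 3L, size = 4L, endian = "big")
    if (length(hdr) != 3L) {
      stop("IDX format error at offset 4: truncated image header", call. = FALSE)
    }
    n <- hdr[1]; nr <- hdr[2]; nc <- hdr[3]
    payload <- readBin(con, "integer", n = n * nr * nc, size = 1L,
                       signed = FALSE)
    if (length(payload) != n * nr * nc) {
      stop(sprintf(
        "IDX format error at offset %d: expected %d bytes of pixel data, got %d",
        16L, n * nr * nc, length(payload)), call. = FALSE)
    }
    m <- matrix(payload, nrow = n, ncol = nr * nc, byrow = TRUE)
    attr(m, "dims") <- c(nr, nc)
    m
  }
}

#' Write an array to an IDX-format file (MNIST layout)
#'
#' Inverse of [read_idx()]; used to export synthetic datasets in the same
#' interchange format as MNIST. Values are stored as unsigned bytes, so
#' they must lie in 0-255 (synthetic real-valued samples are scaled by the
#' caller, see [write_idx_dataset()]).
#'
#' @param x Integer matrix (one image per row) for `what = "images"`, or an
#'   integer vector of labels.
#' @param path Output path; a `".gz"` suffix triggers gzip compression.
#' @param what `"images"` or `"labels"`.
#' @param dims Row/column counts for images; defaults to the `dims`
#'   attribute of `x`, or a 1-by-ncol layout.
#' @return `path`, invisibly.
#' @export
write_idx <- function(x, path, what = c("images", "labels"), dims = NULL) {
  what <- match.arg(what)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(idx_magic[[what]], con, size = 4L, endian = "big")
  if (what == "labels") {
    x <- as.integer(x)
    writeBin(length(x), con, size = 4L, endian = "big")
    writeBin(as.raw(x), con)
  } else {
    if (is.null(dims)) dims <- attr(x, "dims")
    if (is.null(dims)) dims <- c(1L, ncol(x))
    writeBin(nrow(x), con, size = 4L, endian = "big")
    writeBin(as.integer(dims[1]), con, size = 4L, endian = "big")
    writeBin(as.integer(dims[2]), con, size = 4L, endian = "big")
    writeBin(as.raw(as.integer(t(x))), con)
  }
  invisible(path)
}

#' Read paired IDX image/label files as a dataset
#'
#' @param images_path,labels_path Paths to the image and label IDX files.
#' @return A `cfn_dataset`: list with `x` (numeric matrix, one raw sample
#'   per row), `y` (integer class labels, 0-based as in MNIST) and
#'   `class_order` (default ascending).
#' @export
read_idx_dataset <- function(images_path, labels_path) {
  x <- read_idx(images_path, "images")
  y <- read_idx(labels_path, "labels")
  if (nrow(x) != length(y)) {
    stop(sprintf("IDX format error: %d images but %d labels", nrow(x),
                 length(y)), call. = FALSE)
  }
  new_dataset(matrix(as.numeric(x), nrow = nrow(x)), as.integer(y))
}

#' Export a dataset to paired IDX files
#'
#' Real-valued samples are rescaled per sample to the 0-255 byte range (a
#' lossless operation up to quantization for the magnitude-insensitive,
#' direction-coded data this package works with).
#'
#' @param dataset A `cfn_dataset`.
#' @param images_path,labels_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_idx_dataset <- function(dataset, images_path, labels_path) {
  x <- dataset$x
  scale <- apply(x, 1L, max)
  scale[scale == 0] <- 1
  xi <- round(sweep(x, 1L, scale, "/") * 255)
  write_idx(matrix(as.integer(xi), nrow = nrow(xi)), images_path, "images")
  write_idx(dataset$y, labels_path, "labels")
  invisible(c(images_path, labels_path))
}

new_dataset <- function(x, y, class_order = NULL) {
  if (nrow(x) != length(y)) stop("sample/label count mismatch", call. = FALSE)
  if (is.null(class_order)) class_order <- sort(unique(y))
  structure(list(x = x, y = as.integer(y), class_order = as.integer(class_order)),
            class = "cfn_dataset")
}

#' @export
print.cfn_dataset <- function(x, ...) {
  cat(sprintf("<cfn_dataset> %d samples x %d channels, %d classes (%s)\n",
              nrow(x$x), ncol(x$x), length(unique(x$y)),
              paste(x$class_order, collapse = ", ")))
  invisible(x)
}

#' Configuration for the synthetic clustered-data generator
#'
#' The generator emulates the structure that makes rate-coded image data
#' learnable by an angular (direction-based) classifier: non-negative,
#' sparse samples that form tight clusters within a class and are well
#' separated in angle between classes, with class identity independent of
#' vector magnitude. Targets are expressed as mean dot products between
#' L2-normalized samples: within a cluster the mean pairwise dot product
#' must reach at least `intra_dot_min`; between classes it must stay below
#' `inter_dot_max`.
#'
#' @param dim Number of input channels.
#' @param n_classes Number of classes.
#' @param clusters_per_class Cluster centers per class.
#' @param samples_per_class Samples generated per class.
#' @param intra_dot_min Minimum acceptable mean within-cluster dot product.
#' @param inter_dot_max Maximum acceptable mean between-class dot product.
#' @param noise_sd Standard deviation of the per-channel Gaussian noise
#'   added to a cluster center (then clipped at zero and re-normalized).
#' @param sparsity Fraction of channels that are zero in each cluster
#'   center.
#' @param max_retries Center draws attempted before giving up on the dot
#'   product targets.
#' @return A `cfn_synth_config` list.
#' @export
synthetic_config <- function(dim = 64L, n_classes = 4L, clusters_per_class = 3L,
                             samples_per_class = 60L, intra_dot_min = 0.9,
                             inter_dot_max = 0.65, noise_sd = 0.02,
                             sparsity = 0.55, max_retries = 20L) {
  cfg <- list(dim = as.integer(dim), n_classes = as.integer(n_classes),
              clusters_per_class = as.integer(clusters_per_class),
              samples_per_class = as.integer(samples_per_class),
              intra_dot_min = intra_dot_min, inter_dot_max = inter_dot_max,
              noise_sd = noise_sd, sparsity = sparsity,
              max_retries = as.integer(max_retries))
  if (!(cfg$inter_dot_max > 0 && cfg$inter_dot_max < cfg$intra_dot_min &&
        cfg$intra_dot_min <= 1)) {
    stop("require 0 < inter_dot_max < intra_dot_min <= 1", call. = FALSE)
  }
  if (cfg$dim < cfg$n_classes * cfg$clusters_per_class) {
    stop("`dim` must be at least n_classes * clusters_per_class", call. = FALSE)
  }
  structure(cfg, class = "cfn_synth_config")
}

# Centers mimic the geometry of L2-normalized handwritten-digit data: a
# block of "core" channels carried by every class (the shared ink mass that
# makes different digits overlap at a dot product well above zero), a few
# channels private to each class, and cluster-specific channels. Two hard
# geometric constraints shape the defaults. First, the per-weight cap of
# 0.2 means a weight vector can only represent supports of at least 25
# channels without distortion, so centers carry ~29 active channels at
# dim 64 (sparsity 0.55). Second, catastrophic reuse (the failure mode the
# baselines must be able to exhibit) requires trained representations of
# old classes to sit angularly closer to a new class than unused random
# weight vectors do; the core intensity scale 2.0 puts the between-class
# dot product (~0.58) above the dense-random-to-class dot product (~0.50).
draw_centers <- function(cfg) {
  dim <- cfg$dim
  n_core <- max(1L, round(dim * 0.125))
  p <- max(1L, (dim - n_core) %/% (4L * cfg$n_classes))  # private per class
  support_size <- max(n_core + p + 1L, round(dim * (1 - cfg$sparsity)))
  q <- support_size - n_core - p                         # cluster-specific
  core <- seq_len(n_core)
  priv_all <- n_core + seq_len(p * cfg$n_classes)
  pool <- setdiff(seq_len(dim), c(core, priv_all))
  centers <- vector("list", cfg$n_classes)
  for (c_idx in seq_len(cfg$n_classes)) {
    priv <- n_core + ((c_idx - 1L) * p + 1L):(c_idx * p)
    cl <- matrix(0, nrow = cfg$clusters_per_class, ncol = dim)
    for (k in seq_len(cfg$clusters_per_class)) {
      extra <- sample(pool, min(length(pool), q))
      v <- numeric(dim)
      v[core] <- (abs(stats::rnorm(n_core)) + 0.4) * 2.0
      v[priv] <- abs(stats::rnorm(p)) + 0.4
      v[extra] <- abs(stats::rnorm(length(extra))) + 0.4
      cl[k, ] <- v / sqrt(sum(v^2))
    }
    centers[[c_idx]] <- cl
  }
  centers
}

mean_dot <- function(a, b = NULL) {
  if (is.null(b)) {
    g <- a %*% t(a)
    mean(g[upper.tri(g)])
  } else {
    mean(a %*% t(b))
  }
}

#' Generate a synthetic angularly clustered dataset
#'
#' Draws sparse non-negative unit cluster centers (with a per-class block
#' of private channels to guarantee angular separation between classes),
#' then produces samples as `center + N(0, noise_sd)` clipped at zero and
#' L2-normalized. Realized dot product targets are checked on the samples;
#' centers are redrawn (up to `max_retries`) if violated.
#'
#' @param cfg A [synthetic_config()].
#' @return A `cfn_dataset` with attributes `centers` (list of per-class
#'   center matrices), `cluster` (per-sample cluster id), and `realized`
#'   (achieved mean within-cluster and between-class dot products). Samples
#'   are grouped by class in ascending class order (0-based labels).
#' @export
generate_synthetic <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "cfn_synth_config"))
  for (attempt in seq_len(cfg$max_retries)) {
    centers <- draw_centers(cfg)
    n <- cfg$n_classes * cfg$samples_per_class
    x <- matrix(0, nrow = n, ncol = cfg$dim)
    y <- integer(n)
    cluster <- integer(n)
    row <- 0L
    for (c_idx in seq_len(cfg$n_classes)) {
      for (s in seq_len(cfg$samples_per_class)) {
        k <- ((s - 1L) %% cfg$clusters_per_class) + 1L
        v <- centers[[c_idx]][k, ] + stats::rnorm(cfg$dim, 0, cfg$noise_sd)
        v <- pmax(v, 0)
        if (all(v == 0)) v <- centers[[c_idx]][k, ]   # degenerate noise draw
        row <- row + 1L
        x[row, ] <- v / sqrt(sum(v^2))
        y[row] <- c_idx - 1L
        cluster[row] <- k
      }
    }
    # realized targets, measured on the generated samples
    intra <- mean(vapply(seq_len(cfg$n_classes), function(c_idx) {
      vals <- vapply(seq_len(cfg$clusters_per_class), function(k) {
        rows <- which(y == c_idx - 1L & cluster == k)
        if (length(rows) < 2L) return(NA_real_)
        mean_dot(x[rows, , drop = FALSE])
      }, numeric(1))
      mean(vals, na.rm = TRUE)
    }, numeric(1)))
    pairs <- utils::combn(cfg$n_classes, 2L)
    inter <- mean(apply(pairs, 2L, function(p2) {
      mean_dot(x[y == p2[1] - 1L, , drop = FALSE],
               x[y == p2[2] - 1L, , drop = FALSE])
    }))
    if ((is.nan(intra) || intra >= cfg$intra_dot_min) && inter <= cfg$inter_dot_max) {
      ds <- new_dataset(x, y)
      attr(ds, "centers") <- centers
      attr(ds, "cluster") <- cluster
      attr(ds, "realized") <- c(intra_dot = intra, inter_dot = inter)
      return(ds)
    }
  }
  stop(sprintf(
    "synthetic targets unattainable after %d retries (intra %.3f < %.3f or inter %.3f > %.3f)",
    cfg$max_retries, intra, cfg$intra_dot_min, inter, cfg$inter_dot_max),
    call. = FALSE)
}

#' Split a dataset into training and test partitions
#'
#' Stratified by class: within each class a fixed fraction is held out for
#' testing. Uses the R RNG for the within-class permutation.
#'
#' @param dataset A `cfn_dataset`.
#' @param test_frac Fraction of each class held out for testing.
#' @return List with `train` and `test`, both `cfn_dataset`s.
#' @export
split_dataset <- function(dataset, test_frac = 0.2) {
  y <- dataset$y
  test_idx <- unlist(lapply(unique(y), function(cl) {
    rows <- which(y == cl)
    sample(rows, max(1L, round(length(rows) * test_frac)))
  }))
  train_idx <- setdiff(seq_along(y), test_idx)
  list(
    train = new_dataset(dataset$x[train_idx, , drop = FALSE], y[train_idx],
                        dataset$class_order),
    test = new_dataset(dataset$x[test_idx, , drop = FALSE], y[test_idx],
                       dataset$class_order)
  )
}
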