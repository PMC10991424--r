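#' Specification for the synthetic single-cell image generator
#'
#' Describes a population of synthetic single cells with a known
#' co-expression structure: each cell carries a low-dimensional latent
#' factor vector (drawn around one of a few latent cell-type centroids),
#' and every marker's true mean intensity is a monotone function of a
#' linear combination of those factors.  Because the links are monotone,
#' rank-based ground truth (Spearman) is exact, which is what makes the
#' generator usable as an oracle for the imputation and panel-selection
#' machinery.
#'
#' Cell geometry follows the preprocessed single-cell convention the
#' pipeline produces from real data: an axis-aligned elliptical cell mask
#' centred in a 32x32 crop, a concentric elliptical nucleus, background
#' zeroed.  Nuclear markers paint the nucleus, membrane markers a ~2 px
#' rim, cytoplasmic markers the cell body minus the nucleus, so pixel-level
#' metrics (SSIM) have genuine structure to measure.
#'
#' @param n_cells number of cells to simulate.
#' @param markers marker names; the first must be `"DAPI"`.
#' @param n_cell_types number of latent cell-type centroids.
#' @param loading_matrix `C x F` matrix mapping latent factors to the
#'   linear predictor of each marker (rows follow `markers`).
#' @param response per-marker link name: `"identity"`, `"sqrt"` or
#'   `"saturating"` (recycled if length 1).
#' @param noise_sd per-marker Gaussian pixel-noise SD in intensity units
#'   (recycled if length 1).
#' @param compartment per-marker compartment: `"nuclear"`, `"membrane"` or
#'   `"cytoplasm"`.
#' @param nucleus_radius,cell_radius 2-vectors: sampling range in px.
#' @param eccentricity 2-vector: range of ellipse eccentricity.
#' @param n_cores number of TMA cores the cells are spread over.
#' @param cores_per_batch cores per staining batch.
#' @param batch_gain,batch_offset optional per-batch intensity distortion
#'   (length `n_batches` vectors, or single values recycled); defaults
#'   leave intensities untouched. Used to exercise histogram matching.
#' @param seed integer RNG seed; the generator is bit-reproducible in it.
#'
#' @return an object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_cells = 1000,
                           markers = c("DAPI", "CD45", "PanCK", "CD3",
                                       "Ki67", "ECad"),
                           n_cell_types = 3,
                           loading_matrix = default_loading(markers),
                           response = "identity",
                           noise_sd = 2,
                           compartment = default_compartments(markers),
                           nucleus_radius = c(4.5, 6),
                           cell_radius = c(7, 10),
                           eccentricity = c(0.3, 0.7),
                           n_cores = 4,
                           cores_per_batch = 2,
                           batch_gain = 1,
                           batch_offset = 0,
                           seed = 1L) {
  C <- length(markers)
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (anyDuplicated(markers)) stop("marker names must be unique")
  if (markers[1] != "DAPI") stop("the first marker must be DAPI")
  loading_matrix <- as.matrix(loading_matrix)
  if (nrow(loading_matrix) != C) stop("loading_matrix must have one row per marker")
  response <- rep_len(response, C)
  bad <- setdiff(response, c("identity", "sqrt", "saturating"))
  if (length(bad)) stop("unknown (non-monotone?) link: ", paste(bad, collapse = ", "))
  noise_sd <- rep_len(noise_sd, C)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  compartment <- rep_len(compartment, C)
  stopifnot(all(compartment %in% c("nuclear", "membrane", "cytoplasm")))
  if (max(cell_radius) > 16) stop("cell radius exceeds the crop half-width (16 px)")
  if (min(cell_radius) <= max(nucleus_radius))
    stop("nucleus radius must be smaller than cell radius")
  if (n_cores < 1 || cores_per_batch < 1) stop("counts must be >= 1")
  structure(list(
    n_cells = as.integer(n_cells), markers = markers,
    n_cell_types = as.integer(n_cell_types),
    loading_matrix = loading_matrix, response = response,
    noise_sd = noise_sd, compartment = compartment,
    nucleus_radius = nucleus_radius, cell_radius = cell_radius,
    eccentricity = eccentricity, n_cores = as.integer(n_cores),
    cores_per_batch = as.integer(cores_per_batch),
    batch_gain = batch_gain, batch_offset = batch_offset,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Default rank-2 loading matrix
#'
#' Rank-2 structure in which DAPI carries the first latent factor and CD45
#' (the second marker) the second; every other marker mixes both, so the
#' pair `{DAPI, CD45}` statistically determines the whole panel.
#' Magnitudes are chosen so true means stay well inside 8-bit range after
#' compartment concentration.
#'
#' @param markers marker names (>= 2).
#' @return a `length(markers) x 2` matrix.
#' @export
default_loading <- function(markers) {
  C <- length(markers)
  stopifnot(C >= 2)
  base <- rbind(c(0.22, 0.00), c(0.00, 0.22))
  extra <- cbind(seq(0.18, 0.05, length.out = max(C - 2, 1)),
                 seq(0.04, 0.18, length.out = max(C - 2, 1)))
  L <- rbind(base, extra[seq_len(max(C - 2, 0)), , drop = FALSE])
  rownames(L) <- markers
  L
}

default_compartments <- function(markers) {
  comp <- rep(c("membrane", "cytoplasm", "nuclear"), length.out = length(markers))
  comp[1] <- "nuclear"  # DAPI
  comp
}

apply_link <- function(x, link) {
  switch(link,
         identity = x,
         sqrt = sqrt(pmax(x, 0)),
         saturating = pmax(x, 0) / (pmax(x, 0) + 0.3),
         stop("unknown link: ", link))
}

#' Markers that suffice to predict the whole panel
#'
#' The smallest marker subset whose loading rows span the row space of the
#' full loading matrix, i.e. whose true mean intensities linearly determine
#' every other marker's true mean (before the monotone link).  Found by
#' exhaustive search over subsets ordered by size, ties broken by channel
#' index.
#'
#' @param loading_matrix `C x F` loading matrix with marker rownames.
#' @return character vector of marker names.
#' @export
informative_markers <- function(loading_matrix) {
  L <- as.matrix(loading_matrix)
  C <- nrow(L)
  r <- qr(L)$rank
  for (k in seq_len(C)) {
    subsets <- utils::combn(C, k, simplify = FALSE)
    for (s in subsets) {
      if (qr(L[s, , drop = FALSE])$rank == r) {
        nm <- rownames(L)
        return(if (is.null(nm)) as.character(s) else nm[s])
      }
    }
  }
  rownames(L)
}

ellipse_mask <- function(a, b, cx = 16.5, cy = 16.5, p = 32L) {
  xs <- matrix(rep(seq_len(p), each = p), p, p)   # column index
  ys <- matrix(rep(seq_len(p), times = p), p, p)  # row index
  ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
}

#' Generate a synthetic single-cell image stack with ground truth
#'
#' Simulates `n_cells` background-zeroed, centre- and axis-aligned 32x32
#' single-cell crops whose per-marker within-mask mean intensities equal a
#' known function of latent per-cell factors (plus optional pixel noise).
#' Cells are assigned to TMA cores and staining batches.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements `stack` (a [cell_image_stack()]) and
#'   `truth` (class `"ground_truth"`: per-cell `factors`, `cell_type`,
#'   `true_means` N x C matrix, and the `informative` marker set).
#' @examples
#' sim <- generate_stack(synthetic_spec(n_cells = 20, seed = 1))
#' sim$stack
#' head(sim$truth$true_means)
#' @export
generate_stack <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$n_cells; C <- length(spec$markers)
  FF <- ncol(spec$loading_matrix)
  p <- crop_size()

  # latent cell types: deterministic, well-spread centroids (golden-ratio
  # lattice in factor space) so the benchmark's difficulty does not swing
  # with the seed; per-cell variation comes from the jitter below
  g <- (sqrt(5) - 1) / 2
  centroids <- outer(seq_len(spec$n_cell_types), seq_len(FF),
                     function(t, f) 0.25 + 0.65 * ((t * g^f) %% 1))
  type <- sample.int(spec$n_cell_types, n, replace = TRUE)
  factors <- pmin(pmax(centroids[type, , drop = FALSE] +
                         matrix(stats::rnorm(n * FF, 0, 0.15), n, FF),
                       0.05), 1)

  lin <- factors %*% t(spec$loading_matrix)       # N x C
  means <- matrix(0, n, C, dimnames = list(NULL, spec$markers))
  for (c in seq_len(C))
    means[, c] <- pmin(pmax(255 * apply_link(lin[, c], spec$response[c]), 0), 255)

  # core / batch bookkeeping
  core_id <- sprintf("core%03d", sample(rep_len(seq_len(spec$n_cores), n)))
  batch_of_core <- (seq_len(spec$n_cores) - 1L) %/% spec$cores_per_batch + 1L
  n_batches <- max(batch_of_core)
  gain <- rep_len(spec$batch_gain, n_batches)
  offset <- rep_len(spec$batch_offset, n_batches)
  core_num <- as.integer(sub("core", "", core_id))
  batch_id <- sprintf("batch%02d", batch_of_core[core_num])

  # morphology
  a <- stats::runif(n, spec$cell_radius[1], spec$cell_radius[2])
  ecc <- stats::runif(n, spec$eccentricity[1], spec$eccentricity[2])
  b <- a * sqrt(1 - ecc^2)
  rn <- pmin(stats::runif(n, spec$nucleus_radius[1], spec$nucleus_radius[2]),
             b - 1)

  data <- array(0L, dim = c(p, p, C, n))
  mask <- array(FALSE, dim = c(p, p, n))
  for (i in seq_len(n)) {
    cellm <- ellipse_mask(a[i], b[i])
    nucm <- ellipse_mask(rn[i], rn[i])
    rim <- cellm & !ellipse_mask(a[i] - 2, b[i] - 2)
    cyto <- cellm & !nucm
    mask[, , i] <- cellm
    n_mask <- sum(cellm)
    bi <- batch_of_core[core_num[i]]
    for (c in seq_len(C)) {
      comp <- switch(spec$compartment[c],
                     nuclear = nucm, membrane = rim, cytoplasm = cyto)
      n_comp <- sum(comp)
      if (n_comp == 0L) comp <- cellm
      n_comp <- sum(comp)
      v <- means[i, c] * n_mask / n_comp
      px <- rep(v, n_comp)
      if (spec$noise_sd[c] > 0)
        px <- px + stats::rnorm(n_comp, 0, spec$noise_sd[c])
      px <- px * gain[bi] + offset[bi]
      ch <- matrix(0, p, p)
      ch[comp] <- pmin(pmax(px, 0), 255)
      data[, , c, i] <- as.integer(round(ch))
    }
  }

  stack <- cell_image_stack(
    data, mask, spec$markers,
    cell_id = sprintf("cell%06d", seq_len(n)),
    core_id = core_id, batch_id = batch_id
  )
  truth <- structure(list(
    factors = factors, cell_type = type, true_means = means,
    informative = informative_markers(spec$loading_matrix)
  ), class = "ground_truth")
  list(stack = stack, truth = truth)
}
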