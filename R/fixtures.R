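#' Configuration for a synthetic PanNET cohort
#'
#' Describes a simulated cohort with the statistical structure the scoring
#' pipeline assumes: cases with three slides each, per-slide infiltration
#' scores drawn inside the band of the case label, tissue maps with one
#' dominant tumor blob whose border irregularity grows with the slide score,
#' and per-patch nucleus populations whose "parenchyma-like" admixture decays
#' exponentially with hop distance from the tumor-parenchyma interface.
#'
#' @param n_cases Number of cases.
#' @param slides_per_case Slides per case. The case-level banding rule is
#'   defined for exactly three slides, so only 3 is accepted.
#' @param ips_proportions Probabilities of the three case classes
#'   (IPS1, IPS2, IPS3); must sum to 1. Default is the 7/18/10 split of a
#'   35-case surgical cohort.
#' @param grid_shape `c(rows, cols)` of the patch grid per slide (>= 8 each).
#' @param border_irregularity Length-5 non-negative vector mapping slide
#'   score 1..5 to the roughness of the tumor border.
#' @param mixing_floor,mixing_slope The parenchyma-like mixing fraction of an
#'   interface patch (hop distance 0) on a slide with score s is
#'   `m0(s) = mixing_floor + mixing_slope * (s - 1)`.
#' @param mixing_decay Positive rate: the mixing fraction at hop distance d
#'   is `m0(s) * exp(-mixing_decay * d)`.
#' @param n_nuclei Expected number of nuclei per patch.
#' @param patch_size Patch edge length in pixels (nucleus centroids are drawn
#'   in these coordinates).
#' @param feature_noise Multiplier (> 0) on the within-component standard
#'   deviations of the nucleus morphology mixture; below 1 makes the
#'   class signal sharper.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 35,
                          slides_per_case = 3,
                          ips_proportions = c(7, 18, 10) / 35,
                          grid_shape = c(20, 20),
                          border_irregularity = c(0, 0.35, 0.7, 1.05, 1.4),
                          mixing_floor = 0.08,
                          mixing_slope = 0.16,
                          mixing_decay = 1,
                          n_nuclei = 45,
                          patch_size = 256,
                          feature_noise = 1,
                          seed = 1L) {
  check_scalar_number(n_cases, "n_cases", lower = 1)
  if (n_cases != as.integer(n_cases)) abort("`n_cases` must be an integer")
  check_scalar_number(slides_per_case, "slides_per_case", lower = 1)
  if (slides_per_case != 3) {
    abort("the case-level banding rule requires exactly 3 slides per case")
  }
  if (length(ips_proportions) != 3 || any(ips_proportions < 0)) {
    abort("`ips_proportions` must be 3 non-negative probabilities")
  }
  if (abs(sum(ips_proportions) - 1) > 1e-9) {
    abort("`ips_proportions` must sum to 1 (within 1e-9)")
  }
  if (length(grid_shape) != 2 || any(grid_shape < 8)) {
    abort("`grid_shape` must be two dimensions, each >= 8")
  }
  if (length(border_irregularity) != 5 || any(border_irregularity < 0)) {
    abort("`border_irregularity` must map slide scores 1..5 to roughness >= 0")
  }
  check_scalar_number(mixing_decay, "mixing_decay", lower = 1e-12)
  check_scalar_number(mixing_floor, "mixing_floor", lower = 0, upper = 1)
  check_scalar_number(mixing_slope, "mixing_slope", lower = 0)
  check_scalar_number(n_nuclei, "n_nuclei", lower = 1)
  check_scalar_number(feature_noise, "feature_noise", lower = 1e-12)
  structure(
    list(
      n_cases = as.integer(n_cases),
      slides_per_case = 3L,
      ips_proportions = as.numeric(ips_proportions),
      grid_shape = as.integer(grid_shape),
      border_irregularity = as.numeric(border_irregularity),
      mixing_floor = mixing_floor,
      mixing_slope = mixing_slope,
      mixing_decay = mixing_decay,
      n_nuclei = n_nuclei,
      patch_size = as.integer(patch_size),
      feature_noise = feature_noise,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Ordered slide-score triples compatible with each case band.
band_triples <- function(label) {
  tr <- expand.grid(s1 = 1:5, s2 = 1:5, s3 = 1:5)
  tot <- rowSums(tr)
  keep <- switch(label,
    IPS1 = tot >= 3 & tot <= 6,
    IPS2 = tot >= 7 & tot <= 9,
    IPS3 = tot >= 10 & tot <= 15,
    abort("unknown IPS label")
  )
  as.matrix(tr[keep, , drop = FALSE])
}

#' Generate a synthetic cohort
#'
#' Draws case labels from `ips_proportions`, samples each case's three slide
#' scores uniformly from the integer triples whose total falls in the label's
#' band (3-6 / 7-9 / 10-15), and synthesises one tissue map per slide. The
#' whole cohort is a deterministic function of `cfg$seed`.
#'
#' Nucleus populations are not materialised here; they are drawn on demand
#' (see [synthesize_nuclei()] and [build_cohort_graphs()]) from seeds derived
#' deterministically from the cohort seed, so the same patches always receive
#' the same nuclei.
#'
#' @param cfg A [cohort_config()].
#' @param maps Synthesise the tissue maps (default). `maps = FALSE` returns
#'   the manifest and slide scores only (the `tissue_map` column is `NULL`),
#'   which is cheap at large `n_cases`; labels and scores are identical
#'   either way.
#' @return An object of class `synthetic_cohort`: a list with
#'   \describe{
#'     \item{config}{the generating configuration,}
#'     \item{cases}{tibble with `case_id`, `ips_label`, `slide_id_1..3`,}
#'     \item{slides}{tibble with `slide_id`, `case_id`, `slide_index`,
#'       `slide_score` and a `tissue_map` list-column of label matrices.}
#'   }
#' @examples
#' coh <- generate_cohort(cohort_config(n_cases = 4, seed = 7))
#' coh$cases
#' @export
generate_cohort <- function(cfg, maps = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"))
  triples <- lapply(setNames(IPS_LEVELS, IPS_LEVELS), band_triples)
  drawn <- withr::with_seed(cfg$seed, {
    labels <- sample(IPS_LEVELS, cfg$n_cases, replace = TRUE,
                     prob = cfg$ips_proportions)
    scores <- t(vapply(labels, function(l) {
      tr <- triples[[l]]
      tr[sample.int(nrow(tr), 1L), ]
    }, numeric(3)))
    list(labels = labels, scores = scores)
  })
  labels <- drawn$labels
  scores <- drawn$scores
  case_id <- sprintf("case_%03d", seq_len(cfg$n_cases))
  slide_id <- function(i, j) sprintf("%s_s%d", case_id[i], j)

  cases <- tibble(
    case_id = case_id,
    ips_label = ips_factor(labels),
    slide_id_1 = slide_id(seq_len(cfg$n_cases), 1),
    slide_id_2 = slide_id(seq_len(cfg$n_cases), 2),
    slide_id_3 = slide_id(seq_len(cfg$n_cases), 3)
  )

  slides <- tidyr::expand_grid(i = seq_len(cfg$n_cases), j = 1:3)
  map_list <- if (maps) {
    purrr::map2(slides$i, slides$j, function(i, j) {
      s <- scores[i, j]
      synthesize_tissue_map(
        slide_score = s,
        grid_shape = cfg$grid_shape,
        roughness = cfg$border_irregularity[s],
        seed = derive_seed(cfg$seed, i, j)
      )
    })
  } else {
    rep(list(NULL), nrow(slides))
  }
  slides <- tibble(
    slide_id = slide_id(slides$i, slides$j),
    case_id = case_id[slides$i],
    slide_index = slides$j,
    slide_score = as.integer(scores[cbind(slides$i, slides$j)]),
    tissue_map = map_list
  )
  structure(list(config = cfg, cases = cases, slides = slides),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d cases, %d slides (%dx%d patch grid)\n",
              nrow(x$cases), nrow(x$slides),
              x$config$grid_shape[1], x$config$grid_shape[2]))
  print(summarize_cohort(x$cases))
  invisible(x)
}

#' Synthesise one slide's tissue map
#'
#' Builds a patch-grid tissue map containing a single central tumor blob whose
#' radial boundary is perturbed by a harmonic noise series scaled by
#' `roughness`; slides with higher infiltration scores use larger roughness
#' and therefore have longer, more irregular borders per unit area. The blob
#' is surrounded by non-neoplastic parenchyma with diagonal stroma bands, and
#' a one-patch background margin frames the grid. Any satellite tumor
#' fragments created by the perturbation are relabelled to parenchyma so that
#' exactly one tumor component exists.
#'
#' @param slide_score Integer 1..5.
#' @param grid_shape `c(rows, cols)`, each at least 8.
#' @param roughness Non-negative boundary roughness; 0 gives a convex
#'   disc-like blob.
#' @param seed Integer seed.
#' @return Integer matrix of tissue codes (see [tissue_levels()]) with a
#'   `"legend"` attribute.
#' @export
synthesize_tissue_map <- function(slide_score, grid_shape, roughness = 0,
                                  seed = 1L) {
  check_scalar_number(slide_score, "slide_score", lower = 1, upper = 5)
  check_scalar_number(roughness, "roughness", lower = 0)
  if (length(grid_shape) != 2 || any(grid_shape < 8)) {
    abort("grid too small to host a tumor blob (need at least 8x8)")
  }
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  withr::with_seed(seed, {
    cy <- (nr + 1) / 2 + runif(1, -0.5, 0.5)
    cx <- (nc + 1) / 2 + runif(1, -0.5, 0.5)
    r0 <- 0.30 * min(nr, nc)
    K <- 6L
    amp <- rnorm(K)
    phase <- runif(K, 0, 2 * pi)
    row_i <- matrix(seq_len(nr), nr, nc)
    col_j <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    dy <- row_i - cy; dx <- col_j - cx
    theta <- atan2(dy, dx)
    noise <- Reduce(`+`, lapply(seq_len(K), function(k) {
      amp[k] * cos(k * theta + phase[k]) / k
    }))
    r_theta <- r0 * (1 + 0.22 * roughness * noise)
    r_theta <- pmin(pmax(r_theta, 1.5), 0.47 * min(nr, nc))
    pannet <- sqrt(dy^2 + dx^2) <= r_theta

    grid <- matrix(tissue_code("NNPP"), nr, nc)
    band <- sin(2 * pi * (0.9 * row_i + 1.4 * col_j) / (0.9 * min(nr, nc)) +
                  runif(1, 0, 2 * pi))
    grid[band > 0.55] <- tissue_code("stroma")
    grid[pannet] <- tissue_code("PanNET")
    grid[c(1, nr), ] <- tissue_code("background")
    grid[, c(1, nc)] <- tissue_code("background")
  })
  grid <- keep_largest_tumor_component(grid)
  if (!any(grid == tissue_code("PanNET"))) {
    abort("grid too small to host a tumor blob")
  }
  attr(grid, "legend") <- tissue_levels()
  grid
}

# Relabel all but the largest 4-connected PanNET component to NNPP.
keep_largest_tumor_component <- function(grid) {
  comp <- label_components(grid == tissue_code("PanNET"), connectivity = 4L)
  if (comp$n_components <= 1L) return(grid)
  sizes <- tabulate(comp$labels[comp$labels > 0L], comp$n_components)
  keep <- which.max(sizes)
  drop <- comp$labels > 0L & comp$labels != keep
  grid[drop] <- tissue_code("NNPP")
  grid
}

#' Boundary-length to area ratio of the tumor blob
#'
#' Boundary length is counted as the number of exposed faces of tumor cells
#' (4-neighbour faces adjacent to a non-tumor cell or to the grid edge);
#' area is the number of tumor cells. More irregular borders give larger
#' ratios at comparable area.
#'
#' @param map Tissue map matrix (see [synthesize_tissue_map()]).
#' @return A single number, boundary length / area.
#' @export
boundary_area_ratio <- function(map) {
  tum <- map == tissue_code("PanNET")
  area <- sum(tum)
  if (area == 0) abort("map contains no tumor cells")
  nr <- nrow(tum); nc <- ncol(tum)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- tum
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  exposed <- (core & !pad[1:nr, 2:(nc + 1)]) +
    (core & !pad[3:(nr + 2), 2:(nc + 1)]) +
    (core & !pad[2:(nr + 1), 1:nc]) +
    (core & !pad[2:(nr + 1), 3:(nc + 2)])
  sum(exposed) / area
}

#' Parenchyma-like mixing fraction of a patch
#'
#' The fraction of parenchyma-like nuclei expected in a tumor patch at hop
#' distance `d` on a slide with score `slide_score`:
#' `m0(s) * exp(-mixing_decay * d)` with
#' `m0(s) = mixing_floor + mixing_slope * (s - 1)`, truncated to at most 1.
#' Interface patches (`d = 0`) are therefore the most class-informative, and
#' the signal vanishes in the `d -> Inf` limit.
#'
#' @inheritParams cohort_config
#' @param slide_score Integer slide score 1..5.
#' @param d Non-negative hop distance.
#' @return Mixing fraction in `[0, 1]`.
#' @export
mixing_fraction <- function(slide_score, d, mixing_floor = 0.08,
                            mixing_slope = 0.16, mixing_decay = 1) {
  check_scalar_number(d, "d", lower = 0)
  m0 <- mixing_floor + mixing_slope * (slide_score - 1)
  min(1, m0) * exp(-mixing_decay * d)
}

# Morphology mixture components: means and sds of
# (area px^2, eccentricity, solidity, mean intensity, perimeter px).
NUCLEUS_FEATURES <- c("area", "eccentricity", "solidity", "intensity",
                      "perimeter")
component_params <- function() {
  list(
    tumor = list(mean = c(300, 0.45, 0.95, 0.35, 65),
                 sd = c(40, 0.08, 0.02, 0.05, 6)),
    parenchyma = list(mean = c(180, 0.75, 0.85, 0.60, 55),
                      sd = c(30, 0.08, 0.04, 0.05, 6))
  )
}

#' Synthesise a patch's nucleus population
#'
#' Draws nucleus centroids uniformly in the patch and morphology feature
#' vectors from a two-component Gaussian mixture ("tumor-like" and
#' "parenchyma-like"). For tumor patches the parenchyma-like mixing fraction
#' is [mixing_fraction()]; non-tumor patches are entirely parenchyma-like.
#' Features are truncated to their natural ranges (eccentricity in \[0,1\],
#' solidity and intensity in (0,1\], area and perimeter positive).
#'
#' @param patch_label Tissue label of the patch (one of [tissue_levels()]).
#' @param hop_distance Non-negative hop distance from the interface.
#' @param slide_score Integer slide score 1..5.
#' @param n_nuclei Number of nuclei (>= 1).
#' @param seed Integer seed; identical seeds give identical nuclei.
#' @param mixing_floor,mixing_slope,mixing_decay See [cohort_config()].
#' @param patch_size Patch edge length in pixels.
#' @param feature_noise Multiplier on component standard deviations.
#' @return Tibble with columns `x`, `y`, the five morphology features
#'   (`area`, `eccentricity`, `solidity`, `intensity`, `perimeter`) and the
#'   generating `component`.
#' @export
synthesize_nuclei <- function(patch_label, hop_distance, slide_score, n_nuclei,
                              seed = 1L, mixing_floor = 0.08,
                              mixing_slope = 0.16, mixing_decay = 1,
                              patch_size = 256, feature_noise = 1) {
  check_scalar_number(n_nuclei, "n_nuclei", lower = 1)
  check_scalar_number(hop_distance, "hop_distance", lower = 0)
  n <- as.integer(n_nuclei)
  m <- if (identical(patch_label, "PanNET")) {
    mixing_fraction(slide_score, hop_distance, mixing_floor, mixing_slope,
                    mixing_decay)
  } else {
    1
  }
  pars <- component_params()
  drawn <- withr::with_seed(seed, {
    comp <- ifelse(runif(n) < m, "parenchyma", "tumor")
    x <- runif(n, 0, patch_size)
    y <- runif(n, 0, patch_size)
    is_par <- comp == "parenchyma"
    mu <- matrix(pars$tumor$mean, n, 5, byrow = TRUE)
    sdv <- matrix(pars$tumor$sd, n, 5, byrow = TRUE)
    if (any(is_par)) {
      mu[is_par, ] <- matrix(pars$parenchyma$mean, sum(is_par), 5, byrow = TRUE)
      sdv[is_par, ] <- matrix(pars$parenchyma$sd, sum(is_par), 5, byrow = TRUE)
    }
    feats <- mu + matrix(rnorm(n * 5), n, 5) * sdv * feature_noise
    list(comp = comp, x = x, y = y, feats = feats)
  })
  comp <- drawn$comp; x <- drawn$x; y <- drawn$y; feats <- drawn$feats
  colnames(feats) <- NUCLEUS_FEATURES
  feats[, "area"] <- pmax(feats[, "area"], 5)
  feats[, "perimeter"] <- pmax(feats[, "perimeter"], 5)
  feats[, "eccentricity"] <- pmin(pmax(feats[, "eccentricity"], 0), 1)
  feats[, "solidity"] <- pmin(pmax(feats[, "solidity"], 0.05), 1)
  feats[, "intensity"] <- pmin(pmax(feats[, "intensity"], 0), 1)
  dplyr::bind_cols(tibble(x = x, y = y), as_tibble(feats),
                   tibble(component = unname(comp)))
}

#' Render a tissue patch or whole slide as an RGB image
#'
#' Paints each tissue class as a flat colour tile with light Gaussian texture
#' noise, so that the image-facing operations (tiling, stain normalisation,
#' patch feature extraction) can be exercised without real slides. This is a
#' synthetic raster, not a histology simulation.
#'
#' @param label Tissue label (one of [tissue_levels()]).
#' @param patch_size Edge length in pixels.
#' @param seed Integer seed for the texture noise.
#' @return `patch_size x patch_size x 3` array with values in `[0, 1]`.
#' @export
render_tissue_patch <- function(label, patch_size = 16, seed = 1L) {
  base <- switch(label,
    background = c(0.99, 0.99, 0.99),
    PanNET = c(0.55, 0.35, 0.62),
    NNPP = c(0.85, 0.58, 0.70),
    stroma = c(0.93, 0.78, 0.85),
    abort(paste0("unknown tissue label: ", label))
  )
  noise_sd <- if (identical(label, "background")) 0.002 else 0.04
  withr::with_seed(seed, {
    img <- array(rep(base, each = patch_size^2), c(patch_size, patch_size, 3))
    img <- img + array(rnorm(length(img), 0, noise_sd), dim(img))
  })
  pmin(pmax(img, 0), 1)
}

#' @rdname render_tissue_patch
#' @param map Tissue map matrix.
#' @return For `render_slide()`, a `(rows * patch_size) x (cols * patch_size)
#'   x 3` array.
#' @export
render_slide <- function(map, patch_size = 16, seed = 1L) {
  nr <- nrow(map); nc <- ncol(map)
  img <- array(0, c(nr * patch_size, nc * patch_size, 3))
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      tile <- render_tissue_patch(tissue_label(map[i, j]), patch_size,
                                  seed = derive_seed(seed, i, j))
      img[(i - 1) * patch_size + seq_len(patch_size),
          (j - 1) * patch_size + seq_len(patch_size), ] <- tile
    }
  }
  img
}

#' Read and write case manifests
#'
#' The manifest is a CSV with columns `case_id`, `slide_id_1`, `slide_id_2`,
#' `slide_id_3`, `ips_label`, one row per case.
#'
#' @param cases Tibble of cases (as in [generate_cohort()]).
#' @param path File path.
#' @return `read_case_manifest()` returns the manifest tibble with
#'   `ips_label` as a factor.
#' @export
write_case_manifest <- function(cases, path) {
  need <- c("case_id", "slide_id_1", "slide_id_2", "slide_id_3", "ips_label")
  stopifnot(all(need %in% names(cases)))
  readr::write_csv(cases[need], path)
  invisible(path)
}

#' @rdname write_case_manifest
#' @export
read_case_manifest <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  out$ips_label <- ips_factor(out$ips_label)
  out
}
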