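# Tissue classes are stored as integer codes 0..3 in map matrices.
TISSUE_LEVELS <- c("background", "PanNET", "NNPP", "stroma")

#' Tissue class labels
#'
#' The four patch-level tissue classes used throughout the pipeline:
#' `background` (no tissue), `PanNET` (tumor), `NNPP` (non-neoplastic
#' pancreatic parenchyma) and `stroma`. Map matrices store them as the
#' integer codes 0, 1, 2, 3 in this order.
#'
#' @return Character vector of the four class names.
#' @export
tissue_levels <- function() TISSUE_LEVELS

IPS_LEVELS <- c("IPS1", "IPS2", "IPS3")

#' Infiltration pattern score labels
#'
#' @return Character vector `c("IPS1", "IPS2", "IPS3")`, ordered from
#'   non/minimally to highly infiltrative.
#' @export
ips_levels <- function() IPS_LEVELS

ips_factor <- function(x) factor(as.character(x), levels = IPS_LEVELS)

tissue_code <- function(label) {
  i <- match(label, TISSUE_LEVELS)
  if (anyNA(i)) abort(paste0("unknown tissue label: ", label[is.na(i)][1]))
  i - 1L
}

tissue_label <- function(code) TISSUE_LEVELS[code + 1L]

# Deterministic sub-stream seed derived from a base seed and integer keys.
# Kept strictly below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.double(seed) %% 2147483629
  for (k in keys) h <- (h * 48271 + as.double(k) + 1) %% 2147483629
  as.integer(h)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
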